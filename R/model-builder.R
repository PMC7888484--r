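#' Gaussian short-range surface coupling
#'
#' Builds the homogeneous, isotropic short-range structural connectivity on
#' the cortical meshes: for every vertex, Gaussian weights
#' `g(d) = exp(-d^2 / (2 sigma^2))` over same-hemisphere vertices within
#' `cutoff_multiplier * sigma` geodesic distance (graph distance along mesh
#' edges), then each row normalized to sum 1, the discrete analogue of a
#' unit-mass kernel.  The two hemispheres are separate meshes, so
#' interhemispheric short-range weights are exactly zero.
#'
#' The mesh-sampling lower bound of 207.78 micrometres on `sigma` (the -3 dB
#' spatial-frequency cutoff for a mesh of ~125 micrometre edges) is enforced
#' as a warning, not an error.
#'
#' @param geometry a [model_geometry()].
#' @param sigma kernel standard deviation, mm.
#' @param cutoff_multiplier support radius in units of `sigma` (default 8).
#' @return A `short_range_sc`: list with `weights` (sparse row-stochastic
#'   vertex x vertex matrix), `sigma`, `cutoff_multiplier`.
#' @export
build_short_range <- function(geometry, sigma, cutoff_multiplier = 8) {
  stopifnot(inherits(geometry, "model_geometry"))
  abort_if(!is_scalar(sigma) || sigma <= 0, "sigma must be positive")
  if (sigma < min_sampling_sigma_mm()) {
    warning(sprintf(
      "sigma = %.4g mm is below the mesh-sampling lower bound of %.5f mm",
      sigma, min_sampling_sigma_mm()), call. = FALSE)
  }
  ed <- mesh_edges(geometry)
  nv <- nrow(geometry$vertices)
  trip <- geodesic_neighbors_cpp(nv, ed$edges - 1L, ed$lengths,
                                 cutoff_multiplier * sigma)
  w <- exp(-trip$d^2 / (2 * sigma^2))
  W <- Matrix::sparseMatrix(i = trip$i + 1L, j = trip$j + 1L, x = w,
                            dims = c(nv, nv))
  rs <- Matrix::rowSums(W)
  rs[rs == 0] <- 1
  W <- Matrix::Diagonal(x = 1 / rs) %*% W
  structure(list(weights = methods::as(W, "CsparseMatrix"),
                 sigma = sigma,
                 cutoff_multiplier = cutoff_multiplier),
            class = "short_range_sc")
}

#' Delayed long-range area-to-area coupling
#'
#' Attaches conduction delays (`distance / speed`, with distances in mm and
#' speed in m/s, i.e. mm/ms) to a directed non-negative weight matrix
#' (rows = targets, columns = sources) and rescales the weights by a single
#' global factor so the maximum in-strength (row sum) equals 1.  Unity
#' maximum in-strength keeps the coupled network subcritical: the coupling
#' gain can never exceed the local dissipation.
#'
#' @param weights square non-negative matrix, target x source.
#' @param distances symmetric non-negative matrix, mm.
#' @param speed conduction speed, m/s.
#' @param area_sizes optional node counts per area (used by the simulator's
#'   source-averaging; defaults to 1 per area).
#' @return A `long_range_sc`: `weights` (normalized), `distances`, `speed`,
#'   `delays_ms`, `area_sizes`, `scale` (the factor divided out).
#' @export
build_long_range <- function(weights, distances, speed = 1,
                             area_sizes = NULL) {
  weights <- as.matrix(weights)
  distances <- as.matrix(distances)
  abort_if(nrow(weights) != ncol(weights), "weights must be square")
  abort_if(any(weights < 0), "weights must be non-negative")
  abort_if(!identical(dim(weights), dim(distances)),
           "distances must match weights")
  abort_if(any(distances < 0), "distances must be non-negative")
  abort_if(!is_scalar(speed) || speed <= 0, "speed must be positive")
  diag(weights) <- 0
  s <- max(rowSums(weights))
  abort_if(s == 0, "cannot normalize an all-zero weight matrix")
  area_sizes <- area_sizes %||% rep(1L, nrow(weights))
  abort_if(length(area_sizes) != nrow(weights),
           "area_sizes must have one entry per area")
  structure(list(weights = weights / s,
                 distances = distances,
                 speed = speed,
                 delays_ms = distances / speed,
                 area_sizes = as.integer(area_sizes),
                 scale = s),
            class = "long_range_sc")
}

#' Mirror right-hemisphere connectivity blocks into a full matrix
#'
#' Given the right-target blocks of a connectome (right-from-right and
#' right-from-left) and the homolog pairing, fills in the left-target
#' blocks as homolog-permuted copies, so the full matrix is invariant under
#' the homolog permutation applied to rows and columns.
#'
#' @param right_block |R| x |R| weights, right targets from right sources.
#' @param cross_block |R| x |R| weights, right targets from left sources
#'   (columns ordered as the homologs of the rows).
#' @param area_homolog_map involution over all areas.
#' @param right_ids indices of the right-hemisphere areas (row/col order of
#'   the blocks).
#' @return Full area x area weight matrix.
#' @export
mirror_connectome <- function(right_block, cross_block, area_homolog_map,
                              right_ids) {
  A <- length(area_homolog_map)
  right_ids <- as.integer(right_ids)
  left_ids <- area_homolog_map[right_ids]
  abort_if(anyNA(left_ids) || any(left_ids < 1L) || any(left_ids > A),
           "homolog map does not cover the right areas")
  abort_if(length(intersect(left_ids, right_ids)) > 0,
           "homolog map sends right areas onto themselves")
  nr <- length(right_ids)
  abort_if(!all(dim(right_block) == nr) || !all(dim(cross_block) == nr),
           "block dimensions must match right_ids")
  W <- matrix(0, A, A)
  W[right_ids, right_ids] <- right_block
  W[right_ids, left_ids] <- cross_block
  W[left_ids, left_ids] <- right_block
  W[left_ids, right_ids] <- cross_block
  diag(W) <- 0
  W
}

#' Symmetry scores of a directed weight matrix
#'
#' `Q0 = ||C - C'|| / ||C + C'||` and `Q1 = ||C - C'|| / ||2 C||` with the
#' Frobenius norm.  Both vanish for a symmetric matrix; `Q1 = 1` for an
#' antisymmetric one.
#'
#' @param weights square matrix.
#' @return List with `Q0` and `Q1`.
#' @export
symmetry_scores <- function(weights) {
  weights <- as.matrix(weights)
  abort_if(nrow(weights) != ncol(weights), "matrix must be square")
  abort_if(all(weights == 0), "symmetry scores undefined for a zero matrix")
  fr <- function(M) sqrt(sum(M^2))
  list(Q0 = fr(weights - t(weights)) / fr(weights + t(weights)),
       Q1 = fr(weights - t(weights)) / fr(2 * weights))
}

#' Parcellate a cortical mesh from a labeled voxel volume
#'
#' Labels each vertex by majority vote of the `k_votes` labeled voxels
#' nearest to a probe point pushed `probe_depth` mm along the inward vertex
#' normal, then corrects isolated vertices and single-vertex holes by
#' neighbour majority.
#'
#' @param geometry a [model_geometry()] (its `region_map` is ignored).
#' @param volume list with `labels` (3-D integer array, 0 = unlabeled),
#'   `origin` (mm position of voxel \[1,1,1\] centre) and `spacing` (mm).
#' @param probe_depth probe depth along the inward normal, mm (default 0.2).
#' @param k_votes number of nearest labeled voxels to vote (default 5).
#' @return Integer region map per vertex; `NA` where the probe exits the
#'   volume.
#' @export
parcellate_mesh <- function(geometry, volume, probe_depth = 0.2,
                            k_votes = 5L) {
  stopifnot(inherits(geometry, "model_geometry"))
  labels <- volume$labels
  abort_if(length(dim(labels)) != 3L, "volume$labels must be a 3-D array")
  origin <- volume$origin
  spacing <- volume$spacing
  lab_idx <- which(labels > 0, arr.ind = TRUE)
  abort_if(nrow(lab_idx) == 0L, "volume contains no labels")
  lab_xyz <- sweep(sweep(lab_idx - 1, 2, spacing, "*"), 2, origin, "+")
  lab_val <- labels[lab_idx]
  normals <- vertex_normals(geometry)
  probes <- geometry$vertices - probe_depth * normals
  lo <- origin - spacing / 2
  hi <- origin + (dim(labels) - 0.5) * spacing
  out <- integer(nrow(probes))
  for (v in seq_len(nrow(probes))) {
    p <- probes[v, ]
    if (any(p < lo) || any(p > hi)) {
      out[v] <- NA_integer_
      next
    }
    d2 <- (lab_xyz[, 1] - p[1])^2 + (lab_xyz[, 2] - p[2])^2 +
      (lab_xyz[, 3] - p[3])^2
    k <- min(k_votes, length(d2))
    near <- lab_val[order(d2)[seq_len(k)]]
    tab <- table(near)
    out[v] <- as.integer(names(tab)[which.max(tab)])
  }
  # correction pass: reassign isolated vertices / fill single-vertex holes
  adj <- mesh_adjacency(geometry)
  corrected <- out
  for (v in seq_along(out)) {
    nb <- adj[[v]]
    if (length(nb) == 0L) next
    nb_lab <- out[nb]
    nb_lab <- nb_lab[!is.na(nb_lab)]
    if (length(nb_lab) == 0L) next
    if (is.na(out[v]) || !any(nb_lab == out[v])) {
      tab <- table(nb_lab)
      corrected[v] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  corrected
}

#' Analytic constants of the Gaussian short-range kernel
#'
#' `gaussian_attenuation_db()` gives the amplitude attenuation, in dB, of
#' the unnormalized kernel at a given lag relative to lag 0;
#' `gaussian_tail_mass()` gives the two-sided probability mass beyond
#' `k_sigma` standard deviations, in percent; `min_sampling_sigma_mm()`
#' returns the mesh-sampling lower bound on `sigma` (mm) adopted for the
#' short-range kernel warning.
#'
#' @param lag lag at which to evaluate the kernel, same units as `sigma`.
#' @param sigma kernel standard deviation.
#' @return A scalar.
#' @export
gaussian_attenuation_db <- function(lag, sigma = 1) {
  20 * log10(exp(-lag^2 / (2 * sigma^2)))
}

#' @rdname gaussian_attenuation_db
#' @param k_sigma tail boundary in units of sigma.
#' @export
gaussian_tail_mass <- function(k_sigma = 2) {
  100 * 2 * stats::pnorm(-k_sigma)
}

#' @rdname gaussian_attenuation_db
#' @export
min_sampling_sigma_mm <- function() 0.20778

#' Default short-range kernel width sweep
#'
#' Six kernel widths evenly spaced over 500-1000 micrometres, in mm.
#' @return Numeric vector of length 6.
#' @export
default_sigma_sweep <- function() seq(0.5, 1.0, by = 0.1)

#' Write / read a connectome as TVB-style text files
#'
#' `write_connectome_tvb` writes `weights.txt` (row-major target x source),
#' `tract_lengths.txt` and `centres.txt` into a directory;
#' `read_connectome_tvb` reads such a directory or a zip archive of it.
#'
#' @param long a `long_range_sc`.
#' @param path directory to create.
#' @param centres optional area x 3 centroid matrix for `centres.txt`.
#' @export
write_connectome_tvb <- function(long, path, centres = NULL) {
  stopifnot(inherits(long, "long_range_sc"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(long$weights, file.path(path, "weights.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(long$distances, file.path(path, "tract_lengths.txt"),
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(centres)) {
    utils::write.table(centres, file.path(path, "centres.txt"),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_connectome_tvb
#' @param speed conduction speed passed to [build_long_range()].
#' @export
read_connectome_tvb <- function(path, speed = 1) {
  if (grepl("\\.zip$", path)) {
    tmp <- tempfile("tvbzip")
    utils::unzip(path, exdir = tmp)
    inner <- list.dirs(tmp, recursive = FALSE)
    path <- if (length(inner) == 1L &&
                !file.exists(file.path(tmp, "weights.txt"))) inner else tmp
  }
  W <- as.matrix(utils::read.table(file.path(path, "weights.txt")))
  D <- as.matrix(utils::read.table(file.path(path, "tract_lengths.txt")))
  dimnames(W) <- dimnames(D) <- NULL
  build_long_range(W, D, speed)
}
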