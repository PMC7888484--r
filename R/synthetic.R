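#' Specification for synthetic model inputs
#'
#' Describes a scaled-down two-hemisphere brain model: two rectangular
#' spherical cortical patches (one per hemisphere, mirror images), a
#' k-means parcellation into homolog area pairs, lumped subcortical
#' centroids, and a mirrored log-normal long-range connectome with
#' distance-derived delays.  All generators are pure functions of the spec
#' and its seed.
#'
#' @param n_vertices_per_hemisphere vertices per cortical patch.
#' @param n_cortical_areas_per_hemisphere cortical areas per hemisphere.
#' @param n_subcortical_areas_per_hemisphere lumped subcortical areas per
#'   hemisphere.
#' @param connection_density fraction of off-diagonal long-range entries
#'   that are non-zero, in (0, 1].
#' @param weight_meanlog,weight_sdlog log-normal weight-law parameters.
#' @param conduction_speed axonal conduction speed in m/s (1 mm/ms).
#' @param seed integer seed threaded through every generator.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_vertices_per_hemisphere = 200L,
                           n_cortical_areas_per_hemisphere = 6L,
                           n_subcortical_areas_per_hemisphere = 4L,
                           connection_density = 0.6,
                           weight_meanlog = 0,
                           weight_sdlog = 1,
                           conduction_speed = 1,
                           seed = 1L) {
  abort_if(!is_count(n_vertices_per_hemisphere), "vertex count must be positive")
  abort_if(!is_count(n_cortical_areas_per_hemisphere), "area count must be positive")
  abort_if(!(is.numeric(n_subcortical_areas_per_hemisphere) &&
             n_subcortical_areas_per_hemisphere >= 0 &&
             n_subcortical_areas_per_hemisphere ==
               round(n_subcortical_areas_per_hemisphere)),
           "subcortical count must be a non-negative integer")
  abort_if(!(is_scalar(connection_density) && connection_density > 0 &&
             connection_density <= 1), "connection_density must be in (0,1]")
  abort_if(!is_scalar(conduction_speed) || conduction_speed <= 0,
           "conduction_speed must be positive")
  abort_if(n_vertices_per_hemisphere < n_cortical_areas_per_hemisphere,
           "fewer vertices than cortical areas")
  structure(list(
    n_vertices_per_hemisphere = as.integer(n_vertices_per_hemisphere),
    n_cortical_areas_per_hemisphere = as.integer(n_cortical_areas_per_hemisphere),
    n_subcortical_areas_per_hemisphere =
      as.integer(n_subcortical_areas_per_hemisphere),
    connection_density = connection_density,
    weight_meanlog = weight_meanlog,
    weight_sdlog = weight_sdlog,
    conduction_speed = conduction_speed,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Zig-zag triangulation between two vertex rows (index vectors), using the
# normalized position along each row to keep triangles well shaped when the
# rows have different lengths.
triangulate_strip <- function(row_a, row_b) {
  na <- length(row_a); nb <- length(row_b)
  ta <- if (na > 1) seq(0, 1, length.out = na) else 0
  tb <- if (nb > 1) seq(0, 1, length.out = nb) else 0
  tris <- matrix(integer(0), ncol = 3L)
  i <- 1L; j <- 1L
  while (i < na || j < nb) {
    adv_a <- if (i < na && j < nb) ta[i + 1L] <= tb[j + 1L] else i < na
    if (adv_a) {
      tris <- rbind(tris, c(row_a[i], row_b[j], row_a[i + 1L]))
      i <- i + 1L
    } else {
      tris <- rbind(tris, c(row_a[i], row_b[j], row_b[j + 1L]))
      j <- j + 1L
    }
  }
  tris
}

# One rectangular patch of a sphere: n vertices laid out in rows of nearly
# equal length over (elevation, azimuth), triangulated row strips.
spherical_patch <- function(n, radius, half_angle = 0.6) {
  nr <- max(2L, round(sqrt(n)))
  base <- n %/% nr
  counts <- rep(base, nr)
  extra <- n - base * nr
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts <- counts[counts > 0]
  nr <- length(counts)
  thetas <- seq(-half_angle, half_angle, length.out = nr)
  rows <- vector("list", nr)
  verts <- matrix(0, n, 3L)
  idx <- 0L
  for (r in seq_len(nr)) {
    nc <- counts[r]
    phis <- if (nc > 1) seq(-half_angle, half_angle, length.out = nc) else 0
    ids <- idx + seq_len(nc)
    verts[ids, ] <- radius * cbind(cos(thetas[r]) * cos(phis),
                                   cos(thetas[r]) * sin(phis),
                                   sin(thetas[r]))
    rows[[r]] <- ids
    idx <- idx + nc
  }
  tris <- do.call(rbind, lapply(seq_len(nr - 1L), function(r) {
    triangulate_strip(rows[[r]], rows[[r + 1L]])
  }))
  list(vertices = verts, triangles = tris)
}

# Orient all triangles so their normal points away from `center`.
orient_outward <- function(vertices, triangles, center) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  cc <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ctr <- (a + b + cc) / 3
  out <- sweep(ctr, 2, center)
  flip <- rowSums(nrm * out) < 0
  triangles[flip, ] <- triangles[flip, c(1, 3, 2)]
  triangles
}

#' Generate synthetic two-hemisphere model geometry
#'
#' Builds a mirror-image pair of rectangular spherical cortical patches,
#' parcellates the right patch by seeded k-means on vertex positions
#' (labels copied to the mirrored left vertices, so areas come in exact
#' homolog pairs), and places subcortical centroids in the interior.
#'
#' @param spec a [synthetic_spec()].
#' @return A [model_geometry()].
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_vertices_per_hemisphere
  m <- spec$n_cortical_areas_per_hemisphere
  s <- spec$n_subcortical_areas_per_hemisphere
  radius <- 4                       # mm; sets mm-scale inter-area distances
  offset <- 1.5                     # mm between sphere centres
  patch <- spherical_patch(n, radius)
  c_right <- c(offset, 0, 0)
  # rotate local +z (patch axis) onto +x, then translate
  rot <- matrix(c(0, 0, -1,  0, 1, 0,  1, 0, 0), 3L, 3L, byrow = TRUE)
  v_right <- patch$vertices %*% t(rot)
  v_right <- sweep(v_right, 2, c_right, "+")
  t_right <- orient_outward(v_right, patch$triangles, c_right)
  v_left <- v_right
  v_left[, 1] <- -v_left[, 1]
  t_left <- t_right[, c(1, 3, 2), drop = FALSE]   # mirroring flips winding

  labels_right <- with_seed(spec$seed, {
    km <- stats::kmeans(v_right, centers = min(m, n), nstart = 10L,
                        iter.max = 50L)
    # relabel deterministically by lexicographic order of cluster centres
    ord <- order(km$centers[, 1], km$centers[, 2], km$centers[, 3])
    match(km$cluster, ord)
  })
  # left vertices are the mirrored right vertices -> same cluster index
  region_map <- c(labels_right, labels_right + m)  # left ids 1..m, right m+1..2m
  vertices <- rbind(v_left, v_right)
  triangles <- rbind(t_left, t_right + n)
  hemisphere <- rep(c("left", "right"), each = n)

  sub_right <- if (s > 0) {
    with_seed(spec$seed + 1L, {
      u <- matrix(stats::rnorm(3L * s), s, 3L)
      u[, 1] <- abs(u[, 1]) + 0.5
      u <- u / sqrt(rowSums(u^2))
      sweep(0.45 * radius * u, 2, c_right, "+")
    })
  } else matrix(numeric(0), ncol = 3L)
  sub_left <- sub_right
  if (s > 0) sub_left[, 1] <- -sub_left[, 1]
  subcortical <- rbind(sub_left, sub_right)       # left ids first

  homolog <- c(seq_len(m) + m, seq_len(m),
               if (s > 0) c(2L * m + s + seq_len(s), 2L * m + seq_len(s)))
  model_geometry(vertices, triangles, hemisphere, region_map, m,
                 subcortical, homolog)
}

#' Generate a mirrored synthetic long-range connectome
#'
#' Draws the right-hemisphere-target blocks (right-from-right and
#' right-from-left) with Bernoulli support at the spec's density and
#' log-normal weights, then mirrors them through the homolog permutation so
#' the full matrix is invariant under swapping left and right labels.
#' Delays are centroid Euclidean distances divided by the conduction speed;
#' the weight matrix is normalized to unit maximum in-strength.
#'
#' @param geometry a [model_geometry()].
#' @param spec the [synthetic_spec()] used to build it.
#' @return A `long_range_sc` (see [build_long_range()]).
#' @export
make_connectome <- function(geometry, spec) {
  stopifnot(inherits(geometry, "model_geometry"),
            inherits(spec, "synthetic_spec"))
  A <- n_areas(geometry)
  hemi <- area_hemispheres(geometry)
  right_ids <- which(hemi == "right")
  P <- geometry$area_homolog
  W <- matrix(0, A, A)
  W[right_ids, ] <- with_seed(spec$seed + 2L, {
    mask <- matrix(stats::rbinom(length(right_ids) * A, 1L,
                                 spec$connection_density),
                   length(right_ids), A)
    wts <- matrix(stats::rlnorm(length(right_ids) * A,
                                spec$weight_meanlog, spec$weight_sdlog),
                  length(right_ids), A)
    mask * wts
  })
  # mirror: W[P(i), P(j)] = W[i, j] for right-target rows i
  W[P[right_ids], ] <- W[right_ids, P]
  diag(W) <- 0
  cent <- area_centroids(geometry)
  dist_mm <- as.matrix(stats::dist(cent))
  build_long_range(W, dist_mm, spec$conduction_speed,
                   area_sizes = area_sizes(geometry))
}

#' Build a model with planted response-cluster structure
#'
#' Partitions the areas of a synthetic model into `k` spatially compact
#' blocks (k-means on area centroids) and plants a uniform all-to-all
#' connectome within each block, with inter-block weights a small fraction
#' of the intra-block weight.  Stimulating any area of a block then evokes
#' a response whose dominant spatial pattern is the block's collective
#' slow mode, confined to the block; the returned labels are the ground
#' truth for the DRN clustering pipeline.
#'
#' Short intra-block conduction delays (relative to the oscillation
#' period) keep each block's slow mode real-valued and shared across
#' stimulation sites; a high `conduction_speed` in the spec is the
#' cleanest planted regime.
#'
#' @param k number of planted blocks.
#' @param spec a [synthetic_spec()].
#' @param inter_block_ratio inter-block weight relative to intra-block
#'   (default 0.01; 0 decouples the blocks exactly).
#' @param alpha short-range coupling fraction for the returned model
#'   (default 0: long-range only).
#' @return List with `model` (a [coupled_model()]) and `block_of_area`
#'   (integer labels).
#' @export
make_planted_cluster_model <- function(k, spec, inter_block_ratio = 0.01,
                                       alpha = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  abort_if(!is_count(k), "k must be a positive count")
  geometry <- make_geometry(spec)
  A <- n_areas(geometry)
  abort_if(k > A, "k exceeds the number of areas")
  cent <- area_centroids(geometry)
  block <- with_seed(spec$seed + 3L, {
    km <- stats::kmeans(cent, min(k, A), nstart = 10L, iter.max = 50L)
    ord <- order(km$centers[, 1], km$centers[, 2], km$centers[, 3])
    match(km$cluster, ord)
  })
  W <- matrix(inter_block_ratio, A, A)
  W[outer(block, block, "==")] <- 1
  diag(W) <- 0
  long <- build_long_range(W, as.matrix(stats::dist(cent)),
                           spec$conduction_speed,
                           area_sizes = area_sizes(geometry))
  short <- if (alpha > 0) build_short_range(geometry, sigma = 0.5) else NULL
  model <- coupled_model(geometry, short = short, long = long,
                         local = local_params(), alpha = alpha)
  list(model = model, block_of_area = block)
}

#' Generate a synthetic voltage-sensitive-dye stack with known onsets
#'
#' Tiles a square pixel grid into `n_regions` rectangular regions, embeds a
#' ramp-and-decay fluorescence transient with a planted onset per region on
#' top of a constant baseline, and adds Gaussian pixel noise.  Baseline
#' frames precede every onset.
#'
#' @param n_regions number of regions.
#' @param onset_times_ms planted onsets (ms after stimulus), one per region.
#' @param noise_sd Gaussian pixel noise standard deviation (fluorescence
#'   units; baseline is 100).
#' @param seed integer seed.
#' @param amplitudes peak fractional amplitude per region (default 0.05,
#'   i.e. 5% above baseline); a zero entry makes that region silent.
#' @param grid_size pixels per side.
#' @param frame_interval_ms frame spacing.
#' @param baseline_frames frames before the stimulus.
#' @return A `vsd_stack`: list with `frames` (H x W x T array),
#'   `frame_interval_ms`, `baseline_frames`, `stim_frame`, and
#'   `ground_truth` (`onsets_ms`, `region_of_pixel`, `amplitudes`).
#' @export
make_vsd_stack <- function(n_regions, onset_times_ms, noise_sd = 0,
                           seed = 1L, amplitudes = rep(0.05, n_regions),
                           grid_size = 48L, frame_interval_ms = 1,
                           baseline_frames = 20L) {
  abort_if(!is_count(n_regions), "n_regions must be a positive count")
  abort_if(length(onset_times_ms) != n_regions,
           "one onset per region required")
  abort_if(!is_scalar(noise_sd) || noise_sd < 0,
           "noise_sd must be non-negative")
  abort_if(any(onset_times_ms < 0), "onsets must be non-negative")
  # fast rise so the 20%-of-peak crossing stays within one frame of the
  # planted onset; slow exponential decay
  rise_ms <- 2; tau_ms <- 30; baseline_level <- 100
  n_post <- ceiling((max(onset_times_ms) + 5 * tau_ms) / frame_interval_ms)
  n_frames <- baseline_frames + n_post
  abort_if(any(onset_times_ms > n_post * frame_interval_ms),
           "onsets exceed the stack duration")
  ncols <- ceiling(sqrt(n_regions))
  nrows <- ceiling(n_regions / ncols)
  px_col <- pmin(floor((col(matrix(0, grid_size, grid_size)) - 1) /
                         (grid_size / ncols)), ncols - 1)
  px_row <- pmin(floor((row(matrix(0, grid_size, grid_size)) - 1) /
                         (grid_size / nrows)), nrows - 1)
  region_of_pixel <- px_row * ncols + px_col + 1L
  region_of_pixel[region_of_pixel > n_regions] <- NA_integer_
  t_post <- (seq_len(n_frames) - baseline_frames - 1L) * frame_interval_ms
  transient <- function(onset, amp) {
    s <- numeric(n_frames)
    up <- t_post >= onset & t_post < onset + rise_ms
    s[up] <- (t_post[up] - onset) / rise_ms
    dn <- t_post >= onset + rise_ms
    s[dn] <- exp(-(t_post[dn] - onset - rise_ms) / tau_ms)
    amp * s
  }
  frames <- array(baseline_level, dim = c(grid_size, grid_size, n_frames))
  for (r in seq_len(n_regions)) {
    if (amplitudes[r] == 0) next
    sig <- baseline_level * transient(onset_times_ms[r], amplitudes[r])
    mask <- which(region_of_pixel == r)
    for (f in which(sig != 0)) {
      sl <- frames[, , f]
      sl[mask] <- sl[mask] + sig[f]
      frames[, , f] <- sl
    }
  }
  if (noise_sd > 0) {
    frames <- frames + with_seed(seed, {
      array(stats::rnorm(length(frames), 0, noise_sd), dim = dim(frames))
    })
  }
  structure(list(
    frames = frames,
    frame_interval_ms = frame_interval_ms,
    baseline_frames = as.integer(baseline_frames),
    stim_frame = as.integer(baseline_frames) + 1L,
    ground_truth = list(onsets_ms = onset_times_ms,
                        region_of_pixel = region_of_pixel,
                        amplitudes = amplitudes)
  ), class = "vsd_stack")
}

#' Generate functional-network templates and sensory-pathway fixtures
#'
#' Templates assign each area a contribution level in
#' \{none, medium, high\}; pathways are short ordered chains of directed
#' edges between existing areas.
#'
#' @param geometry a [model_geometry()].
#' @param seed integer seed.
#' @param n_templates,n_pathways how many of each to generate.
#' @return List with `templates` (of [functional_template()]) and
#'   `pathways` (of [pathway_definition()]).
#' @export
make_templates_and_pathways <- function(geometry, seed = 1L,
                                        n_templates = 3L, n_pathways = 2L) {
  stopifnot(inherits(geometry, "model_geometry"))
  A <- n_areas(geometry)
  with_seed(seed, {
    templates <- lapply(seq_len(n_templates), function(i) {
      lv <- sample(c("none", "medium", "high"), A, replace = TRUE,
                   prob = c(0.6, 0.25, 0.15))
      if (!any(lv != "none")) lv[sample(A, 1L)] <- "high"
      functional_template(paste0("template_", i), lv)
    })
    pathways <- lapply(seq_len(n_pathways), function(i) {
      len <- sample(3:min(6, A), 1L)
      chain <- sample(A, len)
      pathway_definition(paste0("pathway_", i),
                         cbind(source = chain[-len], target = chain[-1]),
                         n_areas = A)
    })
    list(templates = templates, pathways = pathways)
  })
}
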