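#' Non-oscillatory amplitude envelope of oscillatory signals
#'
#' Magnitude of the analytic signal (Hilbert transform), computed per
#' signal via the FFT; turns the gamma-band damped oscillations into the
#' smooth responses a voltage-sensitive-dye signal resembles.
#'
#' @param x a `trajectory` (the envelope of `psi1` is taken), a numeric
#'   matrix (signals in rows) or a numeric vector.
#' @return Same shape as the input signals.
#' @export
envelope <- function(x) {
  if (inherits(x, "trajectory")) {
    out <- x
    out$psi1 <- envelope(x$psi1)
    return(out)
  }
  if (is.matrix(x)) {
    return(t(apply(x, 1, envelope_vec)))
  }
  envelope_vec(x)
}

envelope_vec <- function(v) {
  n <- length(v)
  if (n < 2L) return(abs(v))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(v) * h, inverse = TRUE) / n)
}

#' Focal plane of the virtual imaging camera
#'
#' An orthographic camera plane (infinite focal length) with a square
#' pixel grid, placed `depth_offset` mm below the cortical surface along
#' the inward plane normal.
#'
#' @param origin plane centre, mm (before the depth offset).
#' @param normal unit vector pointing from the plane toward the camera.
#' @param extent_mm physical side length of the imaged square, mm.
#' @param n_px pixels per side (default 128).
#' @param depth_offset shift of the plane along `-normal`, mm (default 1).
#' @param up approximate in-plane "up" direction used to fix the axes.
#' @return A `focal_plane` with orthonormal in-plane axes `e1`, `e2`.
#' @export
focal_plane <- function(origin, normal, extent_mm, n_px = 128L,
                        depth_offset = 1, up = c(0, 0, 1)) {
  normal <- normal / sqrt(sum(normal^2))
  u <- up - sum(up * normal) * normal
  if (sqrt(sum(u^2)) < 1e-8) {
    up <- c(0, 1, 0)
    u <- up - sum(up * normal) * normal
  }
  e2 <- u / sqrt(sum(u^2))
  e1 <- c(e2[2] * normal[3] - e2[3] * normal[2],
          e2[3] * normal[1] - e2[1] * normal[3],
          e2[1] * normal[2] - e2[2] * normal[1])
  structure(list(origin = origin - depth_offset * normal, normal = normal,
                 e1 = e1, e2 = e2, extent_mm = extent_mm,
                 n_px = as.integer(n_px), depth_offset = depth_offset),
            class = "focal_plane")
}

#' Orthographic projection of node values onto the focal plane
#'
#' Projects the visible cortical vertices (outward normal with a positive
#' component toward the camera) onto the plane; each pixel holds the mean
#' of the values projecting into it, `NA` where no vertex projects.
#'
#' @param node_values numeric vector over nodes (only the cortical
#'   vertices are imaged) or over vertices.
#' @param geometry a [model_geometry()].
#' @param plane a [focal_plane()].
#' @return `n_px` x `n_px` matrix.
#' @export
project_to_plane <- function(node_values, geometry, plane) {
  nv <- nrow(geometry$vertices)
  vals <- node_values[seq_len(nv)]
  normals <- vertex_normals(geometry)
  visible <- as.numeric(normals %*% plane$normal) > 0
  abort_if(!any(visible), "no vertex is visible from the camera side")
  rel <- sweep(geometry$vertices[visible, , drop = FALSE], 2, plane$origin)
  u <- as.numeric(rel %*% plane$e1)
  w <- as.numeric(rel %*% plane$e2)
  half <- plane$extent_mm / 2
  px <- floor((u + half) / plane$extent_mm * plane$n_px) + 1L
  py <- floor((w + half) / plane$extent_mm * plane$n_px) + 1L
  keep <- px >= 1L & px <= plane$n_px & py >= 1L & py <= plane$n_px
  img <- matrix(NA_real_, plane$n_px, plane$n_px)
  if (any(keep)) {
    key <- (py[keep] - 1L) * plane$n_px + px[keep]
    means <- tapply(vals[visible][keep], key, mean)
    img[as.integer(names(means))] <- as.numeric(means)
  }
  img
}

#' Image a simulated trajectory as a virtual VSD stack
#'
#' Hilbert envelope of the cortical `psi1` signals projected frame by
#' frame onto the focal plane.
#'
#' @param traj a `trajectory`.
#' @param geometry the model geometry.
#' @param plane a [focal_plane()].
#' @return A `vsd_stack` whose frames are in model amplitude units.
#' @export
observe_trajectory <- function(traj, geometry, plane) {
  env <- envelope(traj$psi1[seq_len(nrow(geometry$vertices)), ,
                            drop = FALSE])
  frames <- array(NA_real_, dim = c(plane$n_px, plane$n_px,
                                    length(traj$times)))
  for (f in seq_along(traj$times)) {
    frames[, , f] <- project_to_plane(env[, f], geometry, plane)
  }
  onset <- traj$meta$onset_s %||% 0
  dt_ms <- traj$record_interval * 1000
  structure(list(frames = frames, frame_interval_ms = dt_ms,
                 baseline_frames = max(1L, sum(traj$times < onset)),
                 stim_frame = max(1L, sum(traj$times < onset)) + 1L,
                 ground_truth = NULL),
            class = "vsd_stack")
}

#' Percent fluorescence change from baseline
#'
#' `100 * (F - F0) / F0` per pixel, with `F0` the per-pixel mean over the
#' baseline frames.  Pixels with non-positive baseline are masked `NA`.
#'
#' @param stack a `vsd_stack`.
#' @param baseline_span frame indices of the baseline (default
#'   `1:stack$baseline_frames`).
#' @return The stack with frames replaced by percent dF/F0.
#' @export
dff0 <- function(stack, baseline_span = NULL) {
  stopifnot(inherits(stack, "vsd_stack"))
  baseline_span <- baseline_span %||% seq_len(stack$baseline_frames)
  f0 <- apply(stack$frames[, , baseline_span, drop = FALSE], c(1, 2), mean)
  f0[f0 <= 0] <- NA_real_
  out <- stack
  out$frames <- 100 * sweep(sweep(stack$frames, c(1, 2), f0), c(1, 2),
                            f0, "/")
  out$units <- "percent"
  out
}

#' Activation onset of a signal: 20%-of-peak crossing
#'
#' First post-stimulus time at which the signal strictly exceeds
#' `threshold_frac` of its post-stimulus peak, with linear interpolation
#' between samples (`interpolate = FALSE` reports the first exceeding
#' sample time).
#'
#' @param signal numeric vector.
#' @param times_ms sample times, ms.
#' @param stim_time_ms stimulus time (default 0); earlier samples are
#'   ignored.
#' @param threshold_frac fraction of the peak (default 0.2).
#' @param interpolate sub-frame linear interpolation (default TRUE).
#' @return Onset in ms, or `NA` if the post-stimulus peak is not positive
#'   (region excluded).
#' @export
activation_onset <- function(signal, times_ms, stim_time_ms = 0,
                             threshold_frac = 0.2, interpolate = TRUE) {
  post <- which(times_ms >= stim_time_ms)
  abort_if(length(post) == 0L, "no post-stimulus samples")
  s <- signal[post]
  tt <- times_ms[post]
  peak <- max(s)
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  thr <- threshold_frac * peak
  k <- which(s > thr)[1]
  if (is.na(k)) return(NA_real_)
  if (!interpolate || k == 1L) return(tt[k])
  s0 <- s[k - 1L]; s1 <- s[k]
  if (s1 == s0) return(tt[k])
  tt[k - 1L] + (thr - s0) / (s1 - s0) * (tt[k] - tt[k - 1L])
}

#' Temporal activation order of regions
#'
#' Sorts regions by activation onset (ties broken by region index order);
#' regions with no onset are excluded.  The stimulated region is kept in
#' the sequence but flagged, since cross-condition comparisons drop the
#' first (stimulated) element.
#'
#' @param onsets_ms named numeric vector of onsets (NA = excluded).
#' @param stimulated optional name of the stimulated region.
#' @return An `activation_sequence`: `regions` (ordered labels),
#'   `onsets_ms` (same order), `stimulated`.
#' @export
activation_order <- function(onsets_ms, stimulated = NULL) {
  labs <- names(onsets_ms) %||% as.character(seq_along(onsets_ms))
  keep <- !is.na(onsets_ms)
  labs <- labs[keep]
  on <- onsets_ms[keep]
  ord <- order(on, seq_along(on))
  structure(list(regions = labs[ord], onsets_ms = unname(on[ord]),
                 stimulated = stimulated),
            class = "activation_sequence")
}

#' @export
print.activation_sequence <- function(x, ...) {
  cat("activation sequence:", paste(x$regions, collapse = " -> "), "\n")
  invisible(x)
}

#' Region-level activation sequence of a VSD stack
#'
#' Averages the percent dF/F0 signal within each region, finds each
#' region's 20%-of-peak onset and returns the activation order.
#'
#' @param stack a `vsd_stack` (raw fluorescence; dF/F0 is applied
#'   internally) with a `region_of_pixel` map in `ground_truth`, or an
#'   explicit `region_of_pixel` argument.
#' @param region_of_pixel integer matrix mapping pixels to regions.
#' @param stimulated optional stimulated-region label.
#' @param threshold_frac,interpolate passed to [activation_onset()].
#' @return An `activation_sequence`.
#' @export
stack_activation_sequence <- function(stack, region_of_pixel = NULL,
                                      stimulated = NULL,
                                      threshold_frac = 0.2,
                                      interpolate = TRUE) {
  stopifnot(inherits(stack, "vsd_stack"))
  region_of_pixel <- region_of_pixel %||% stack$ground_truth$region_of_pixel
  abort_if(is.null(region_of_pixel), "no region map available")
  dstack <- if (identical(stack$units, "percent")) stack else dff0(stack)
  n_frames <- dim(dstack$frames)[3]
  times_ms <- (seq_len(n_frames) - dstack$stim_frame) *
    dstack$frame_interval_ms
  regions <- sort(unique(region_of_pixel[!is.na(region_of_pixel)]))
  onsets <- vapply(regions, function(r) {
    mask <- which(region_of_pixel == r)
    sig <- vapply(seq_len(n_frames), function(f) {
      mean(dstack$frames[, , f][mask], na.rm = TRUE)
    }, numeric(1))
    activation_onset(sig, times_ms, stim_time_ms = 0,
                     threshold_frac = threshold_frac,
                     interpolate = interpolate)
  }, numeric(1))
  names(onsets) <- as.character(regions)
  activation_order(onsets, stimulated = stimulated)
}

#' Normalized Kendall tau distance between two orderings
#'
#' Number of adjacent transpositions needed to convert one sequence into
#' the other, divided by the maximum `n(n-1)/2`.
#'
#' @param a,b sequences (vectors) over the same element set, length >= 2.
#' @return Scalar in \[0, 1\].
#' @export
kendall_distance <- function(a, b) {
  a <- as.character(unlist(a, use.names = FALSE))
  b <- as.character(unlist(b, use.names = FALSE))
  abort_if(length(a) < 2L, "sequences must have length >= 2")
  abort_if(length(a) != length(b) || !setequal(a, b) ||
           anyDuplicated(a) > 0 || anyDuplicated(b) > 0,
           "sequences must order the same element set")
  n <- length(a)
  pos <- match(a, b)
  disc <- 0L
  for (i in seq_len(n - 1L)) {
    disc <- disc + sum(pos[i] > pos[(i + 1L):n])
  }
  disc / (n * (n - 1L) / 2)
}

#' Similarity of two activation sequences
#'
#' The seven-step comparison of two region activation orders: (1) take
#' the sequences, (2) drop the first (stimulated) element of each,
#' (3) keep the length-`subseq_len` prefixes, (4) substitute the
#' non-overlapping elements of the second prefix by the non-overlapping
#' elements of the first, pairwise in order of appearance, so both
#' prefixes share one element set, (5) compute the normalized Kendall
#' transposition distance, (6) similarity = 1 - distance, (7) scale by
#' the fraction of overlapping elements between the original prefixes.
#'
#' @param a,b sequences (character vectors or `activation_sequence`s).
#' @param subseq_len prefix length after dropping the first element.
#' @param distance_digits optional rounding of the step-5 distance (e.g. 2
#'   to match two-decimal reporting); `NULL` keeps it exact.
#' @return Scalar in \[0, 1\], with attributes `distance` and `overlap`.
#' @export
sequence_similarity <- function(a, b, subseq_len,
                                distance_digits = NULL) {
  if (inherits(a, "activation_sequence")) a <- a$regions
  if (inherits(b, "activation_sequence")) b <- b$regions
  a <- as.character(a); b <- as.character(b)
  abort_if(length(a) < subseq_len + 1L || length(b) < subseq_len + 1L,
           "sequences too short for the requested subsequence length")
  pa <- a[-1][seq_len(subseq_len)]
  pb <- b[-1][seq_len(subseq_len)]
  overlap <- intersect(pa, pb)
  n_ov <- length(overlap)
  sub_a <- setdiff(pa, pb)        # in order of appearance in pa
  sub_b_pos <- which(!(pb %in% pa))
  pb_sub <- pb
  pb_sub[sub_b_pos] <- sub_a[seq_along(sub_b_pos)]
  d <- kendall_distance(pa, pb_sub)
  if (!is.null(distance_digits)) d <- round(d, distance_digits)
  out <- (1 - d) * (n_ov / subseq_len)
  attr(out, "distance") <- d
  attr(out, "overlap") <- n_ov
  out
}

#' Benchmark activation-sequence similarities across conditions
#'
#' Computes the all-pairs similarity matrix of one condition's sequences
#' (diagonal removed), takes a per-row percentile as that region's
#' expected-similarity threshold, and optionally thresholds and binarizes
#' a cross-condition similarity matrix row by row, reporting its
#' diagonal.
#'
#' @param sequences_a named list of sequences (one per stimulated region).
#' @param subseq_len prefix length for [sequence_similarity()].
#' @param percentile row percentile for the threshold (50, 75 or 90).
#' @param sequences_b optional second condition, same names.
#' @param distance_digits passed to [sequence_similarity()].
#' @return List with `similarity` (within-condition matrix, `NA`
#'   diagonal), `thresholds`, and when `sequences_b` is given `cross`,
#'   `binarized`, `diagonal`.
#' @export
similarity_benchmark <- function(sequences_a, subseq_len, percentile = 50,
                                 sequences_b = NULL,
                                 distance_digits = NULL) {
  n <- length(sequences_a)
  abort_if(n < 3L, "need at least three regions")
  abort_if(!percentile %in% c(50, 75, 90),
           "percentile must be 50, 75 or 90")
  nm <- names(sequences_a) %||% as.character(seq_len(n))
  S <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      S[i, j] <- as.numeric(sequence_similarity(
        sequences_a[[i]], sequences_a[[j]], subseq_len,
        distance_digits = distance_digits))
    }
  }
  thr <- apply(S, 1, function(r) {
    stats::quantile(r, probs = percentile / 100, na.rm = TRUE,
                    names = FALSE)
  })
  out <- list(similarity = S, thresholds = thr, percentile = percentile)
  if (!is.null(sequences_b)) {
    X <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        X[i, j] <- as.numeric(sequence_similarity(
          sequences_a[[i]], sequences_b[[j]], subseq_len,
          distance_digits = distance_digits))
      }
    }
    B <- (X >= thr) * 1
    out$cross <- X
    out$binarized <- B
    out$diagonal <- diag(B)
  }
  out
}

#' Write / read a VSD stack as multi-page TIFF
#'
#' Frames are rescaled to \[0, 1\] for storage; the scale, frame interval
#' and baseline length travel in a sidecar JSON file.
#'
#' @param stack a `vsd_stack`.
#' @param path TIFF file path.
#' @export
write_vsd_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "vsd_stack"))
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(f) {
    (stack$frames[, , f] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(lo = lo, scale = scale,
                            frame_interval_ms = stack$frame_interval_ms,
                            baseline_frames = stack$baseline_frames,
                            stim_frame = stack$stim_frame),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_vsd_tiff
#' @export
read_vsd_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) {
    frames[, , f] <- pages[[f]] * meta$scale + meta$lo
  }
  structure(list(frames = frames,
                 frame_interval_ms = meta$frame_interval_ms,
                 baseline_frames = meta$baseline_frames,
                 stim_frame = meta$stim_frame, ground_truth = NULL),
            class = "vsd_stack")
}

#' Write / read activation sequences as JSON
#'
#' @param sequences named list of `activation_sequence` objects or
#'   character vectors.
#' @param path file path.
#' @export
write_sequences_json <- function(sequences, path) {
  obj <- lapply(sequences, function(s) {
    if (inherits(s, "activation_sequence")) {
      list(regions = s$regions, onsets_ms = s$onsets_ms,
           stimulated = s$stimulated)
    } else list(regions = as.character(s))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sequences_json
#' @export
read_sequences_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(s) {
    structure(list(regions = as.character(s$regions),
                   onsets_ms = as.numeric(s$onsets_ms %||% rep(NA_real_,
                     length(s$regions))),
                   stimulated = s$stimulated %||% NULL),
              class = "activation_sequence")
  })
}
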