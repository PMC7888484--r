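#' Decompose an induced response into its spatial principal components
#'
#' Eigen-decomposition of the node-by-node covariance of the induced
#' response over the analysis window (default 250-750 ms after stimulus
#' onset).  The smallest set of leading components reaching `var_target`
#' of the total variance is kept, capped at `max_components`; each
#' component is a unit-norm spatial pattern with a deterministic sign
#' (largest-magnitude entry positive).  The result is the
#' stimulation-site-specific dynamically responsive network (ss-DRN).
#'
#' @param induced an induced-response `trajectory`.
#' @param window length-2 window in seconds relative to the stimulus onset
#'   (default `c(0.25, 0.75)`); absolute if the trajectory has no onset.
#' @param var_target variance fraction to cover (default 0.99).
#' @param max_components cap on retained components (default 3).
#' @return An `ss_drn`: `components` (node x k), `variance_fractions`,
#'   `coverage`, `covered` (logical: did k components reach the target),
#'   `site`, `alpha`, `sigma`, `window`.
#' @export
decompose_response <- function(induced, window = c(0.25, 0.75),
                               var_target = 0.99, max_components = 3L) {
  onset <- induced$meta$onset_s %||% NA_real_
  w <- if (is.finite(onset)) onset + window else window
  sel <- which(induced$times >= w[1] & induced$times <= w[2])
  abort_if(length(sel) < 2L, "analysis window outside the trajectory")
  X <- induced$psi1[, sel, drop = FALSE]
  Xc <- X - rowMeans(X)
  total_var <- sum(Xc^2) / (length(sel) - 1L)
  abort_if(total_var == 0, "constant trajectory has no principal components")
  cov_nodes <- Xc %*% t(Xc) / (length(sel) - 1L)
  eg <- eigen(cov_nodes, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  fractions <- vals / sum(vals)
  k <- which(cumsum(fractions) >= var_target)[1]
  covered <- !is.na(k) && k <= max_components
  k <- min(if (is.na(k)) max_components else k, max_components)
  comps <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    imax <- which.max(abs(comps[, j]))
    if (comps[imax, j] < 0) comps[, j] <- -comps[, j]
  }
  structure(list(components = comps,
                 variance_fractions = fractions[seq_len(k)],
                 coverage = sum(fractions[seq_len(k)]),
                 covered = covered,
                 site = induced$meta$site,
                 alpha = induced$meta$alpha,
                 sigma = induced$meta$sigma,
                 window = window),
            class = "ss_drn")
}

#' Similarity of two response eigenspaces
#'
#' Mean over corresponding (rank-ordered) component pairs of the absolute
#' dot product of the unit eigenvectors.  Absolute values make the measure
#' invariant to the arbitrary sign of principal components.  If the
#' component counts differ, the shorter prefix is compared and the result
#' carries a `truncated` attribute.
#'
#' @param a,b `ss_drn` objects over the same nodes.
#' @return Scalar in \[0, 1\].
#' @export
eigenspace_similarity <- function(a, b) {
  abort_if(nrow(a$components) != nrow(b$components),
           "eigenspaces span different node sets")
  ka <- ncol(a$components); kb <- ncol(b$components)
  k <- min(ka, kb)
  sims <- vapply(seq_len(k), function(j) {
    abs(sum(a$components[, j] * b$components[, j]))
  }, numeric(1))
  out <- mean(sims)
  if (ka != kb) attr(out, "truncated") <- TRUE
  out
}

#' Select the number of clusters by the gap statistic
#'
#' Tibshirani gap statistic with `B` uniform reference data sets drawn
#' over the feature bounding box; the estimate is the smallest `k` with
#' `Gap(k) >= Gap(k+1) - s(k+1)`.
#'
#' Degenerate features are resolved before the statistic is computed:
#' observations whose profiles coincide to within `dup_tol` (relative to
#' the feature range) are collapsed, and when no more than `max(k_range)`
#' distinct profiles remain, their count is returned directly — with
#' within-cluster dispersions at numerical-noise level the log-dispersion
#' curve of the gap statistic is meaningless, while the distinct profiles
#' already are the clustering.  All-identical features give `1`.
#'
#' @param features numeric matrix, observations in rows.
#' @param k_range candidate cluster counts (default `1:8`, clipped to the
#'   sample count).
#' @param B reference sets (default 50).
#' @param seed integer seed.
#' @param dup_tol relative tolerance below which two feature profiles
#'   count as identical (default 1e-3).
#' @return Estimated number of clusters.
#' @export
select_k_gap <- function(features, k_range = 1:8, B = 50L, seed = 1L,
                         dup_tol = 1e-3) {
  features <- as.matrix(features)
  scale <- max(abs(features), 1e-300)
  groups <- integer(nrow(features))
  reps <- integer(0)              # row index representing each group
  for (i in seq_len(nrow(features))) {
    hit <- 0L
    for (g in seq_along(reps)) {
      if (max(abs(features[i, ] - features[reps[g], ])) <= dup_tol * scale) {
        hit <- g
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      hit <- length(reps)
    }
    groups[i] <- hit
  }
  n_distinct <- length(reps)
  if (n_distinct == 1L) return(1L)
  if (n_distinct <= max(k_range)) return(n_distinct)
  k_max <- min(max(k_range), n_distinct - 1L, nrow(features) - 1L)
  if (k_max < 2L) return(1L)
  gap <- with_seed(seed, {
    cluster::clusGap(features,
                     FUNcluster = function(x, k) {
                       suppressWarnings(
                         stats::kmeans(x, k, nstart = 50L, iter.max = 50L))
                     },
                     K.max = k_max, B = B, spaceH0 = "original",
                     verbose = FALSE)
  })
  tab <- gap$Tab
  keep <- intersect(seq_len(k_max), k_range)
  khat <- cluster::maxSE(tab[keep, "gap"], tab[keep, "SE.sim"],
                         method = "Tibs2001SEmax")
  keep[khat]
}

#' Cluster ss-DRNs by their similarity profiles
#'
#' Each ss-DRN is represented by its row of the pairwise
#' [eigenspace_similarity()] matrix; k-means (50 restarts, seeded) with
#' the cluster count estimated by [select_k_gap()] unless given.
#'
#' @param ssdrns list of `ss_drn` objects (length >= 2).
#' @param seed integer seed.
#' @param k optional fixed cluster count.
#' @param k_range candidates for the gap statistic.
#' @param B gap-statistic reference sets.
#' @return Integer cluster labels.
#' @export
cluster_ssdrns <- function(ssdrns, seed = 1L, k = NULL, k_range = 1:8,
                           B = 50L) {
  abort_if(length(ssdrns) < 2L, "need at least two ss-DRNs")
  n <- length(ssdrns)
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      S[i, j] <- S[j, i] <- as.numeric(eigenspace_similarity(ssdrns[[i]],
                                                             ssdrns[[j]]))
    }
  }
  if (is.null(k)) k <- select_k_gap(S, k_range = k_range, B = B, seed = seed)
  if (k == 1L) return(rep(1L, n))
  if (k >= n) return(seq_len(n))   # every ss-DRN its own cluster
  with_seed(seed + 1L, {
    as.integer(suppressWarnings(
      stats::kmeans(S, k, nstart = 50L, iter.max = 100L))$cluster)
  })
}

#' Optimal rotation aligning one eigenspace onto another
#'
#' Kabsch/Procrustes alignment: the orthogonal `R` minimizing
#' `||movable %*% R - reference||_F`, from the SVD of
#' `t(movable) %*% reference`.  By default reflections are allowed
#' (`proper = FALSE`), because principal components carry arbitrary signs
#' and an odd number of sign flips is an improper orthogonal transform
#' that the alignment must absorb; `proper = TRUE` applies the
#' determinant correction of the rigid-body Kabsch variant.  A
#' rank-deficient cross-covariance is aligned in the spanned subspace and
#' flagged with a `deficient` attribute.
#'
#' @param movable,reference node x k matrices (same node count).
#' @param proper restrict to proper rotations (determinant +1)?
#' @return k x k orthogonal matrix.
#' @export
kabsch_align <- function(movable, reference, proper = FALSE) {
  abort_if(nrow(movable) != nrow(reference),
           "bases span different node sets")
  M <- crossprod(movable, reference)
  sv <- svd(M)
  if (proper) {
    d <- sign(det(sv$u %*% t(sv$v)))
    if (d == 0) d <- 1
    D <- diag(c(rep(1, ncol(M) - 1L), d), ncol(M))
    R <- sv$u %*% D %*% t(sv$v)
  } else {
    R <- sv$u %*% t(sv$v)
  }
  if (any(sv$d < 1e-12 * max(sv$d, 1))) attr(R, "deficient") <- TRUE
  R
}

# Zero-pad an ss-DRN's components to `k` columns for alignment.
pad_components <- function(components, k = 3L) {
  if (ncol(components) >= k) return(components[, seq_len(k), drop = FALSE])
  cbind(components, matrix(0, nrow(components), k - ncol(components)))
}

#' Aggregate a cluster of ss-DRNs into a DRN
#'
#' The cluster basis is the member with the highest mean similarity to the
#' other members (ties: first in list order); every member is
#' Kabsch-aligned onto it, the aligned components are averaged columnwise
#' and re-normalized to unit norm.
#'
#' @param cluster_members non-empty list of `ss_drn` objects.
#' @param cluster_id optional label stored on the result.
#' @return A `drn`: `components` (node x 3), `member_sites`, `cluster_id`.
#' @export
build_drn <- function(cluster_members, cluster_id = NA_integer_) {
  abort_if(length(cluster_members) == 0L, "empty cluster")
  n <- length(cluster_members)
  if (n == 1L) {
    basis_idx <- 1L
  } else {
    mean_sim <- vapply(seq_len(n), function(i) {
      mean(vapply(setdiff(seq_len(n), i), function(j) {
        as.numeric(eigenspace_similarity(cluster_members[[i]],
                                         cluster_members[[j]]))
      }, numeric(1)))
    }, numeric(1))
    basis_idx <- which.max(mean_sim)
  }
  basis <- pad_components(cluster_members[[basis_idx]]$components)
  acc <- matrix(0, nrow(basis), 3L)
  for (m in cluster_members) {
    comp <- pad_components(m$components)
    acc <- acc + comp %*% kabsch_align(comp, basis)
  }
  avg <- acc / n
  for (j in seq_len(3L)) {
    nrm <- sqrt(sum(avg[, j]^2))
    if (nrm > 0) avg[, j] <- avg[, j] / nrm
  }
  structure(list(components = avg,
                 member_sites = vapply(cluster_members, function(m)
                   as.integer(m$site %||% NA_integer_), integer(1)),
                 cluster_id = cluster_id),
            class = "drn")
}

#' Pairwise component correlations across a DRN catalog: recurring motifs
#'
#' Pearson-correlates every component of every DRN with every other,
#' tests each correlation (two-sided), Bonferroni-corrects the
#' significance level by the total number of components, assigns agreement
#' tiers (strong: r > 0.8; good: 0.6 < r <= 0.8; moderate:
#' 0.5 < r <= 0.6), and reports the connected components of the
#' significant strong/good graph as motifs.
#'
#' @param drns list of `drn` objects (>= 2).
#' @param alpha_level familywise significance level (default 0.01).
#' @return A `motif_table`: `correlations`, `p_values`, `significant`,
#'   `tiers` (character matrix), `component_ids`, `motifs` (list of
#'   component index vectors, size > 1 only).
#' @export
motif_analysis <- function(drns, alpha_level = 0.01) {
  abort_if(length(drns) < 2L, "need at least two DRNs")
  comp_list <- list()
  ids <- character(0)
  for (d in seq_along(drns)) {
    comps <- drns[[d]]$components
    for (j in seq_len(ncol(comps))) {
      if (all(comps[, j] == 0)) next
      comp_list[[length(comp_list) + 1L]] <- comps[, j]
      ids <- c(ids, sprintf("drn%d_c%d", d, j))
    }
  }
  nc <- length(comp_list)
  X <- do.call(cbind, comp_list)
  corr <- stats::cor(X)
  nobs <- nrow(X)
  tstat <- corr * sqrt((nobs - 2) / pmax(1 - corr^2, 1e-300))
  pval <- 2 * stats::pt(-abs(tstat), df = nobs - 2)
  diag(pval) <- NA_real_
  sig <- pval < alpha_level / nc
  tier <- function(r) {
    ifelse(r > 0.8, "strong",
           ifelse(r > 0.6, "good",
                  ifelse(r > 0.5, "moderate", "none")))
  }
  tiers <- matrix(tier(corr), nc, nc, dimnames = list(ids, ids))
  diag(tiers) <- NA_character_
  edge <- sig & tiers %in% c("strong", "good")
  edge[is.na(edge)] <- FALSE
  edge <- matrix(edge, nc, nc)
  # connected components of the strong/good graph
  comp_label <- seq_len(nc)
  repeat {
    changed <- FALSE
    for (i in seq_len(nc)) {
      nb <- which(edge[i, ])
      if (length(nb)) {
        new <- min(comp_label[c(i, nb)])
        if (any(comp_label[c(i, nb)] != new)) {
          comp_label[c(i, nb)] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  groups <- split(seq_len(nc), comp_label)
  motifs <- groups[vapply(groups, length, integer(1)) > 1L]
  names(motifs) <- NULL
  dimnames(corr) <- dimnames(pval) <- list(ids, ids)
  structure(list(correlations = corr, p_values = pval,
                 significant = sig, tiers = tiers, component_ids = ids,
                 motifs = motifs, alpha_level = alpha_level),
            class = "motif_table")
}

#' Extract the DRN catalog from a set of induced responses
#'
#' Convenience driver: decompose every induced trajectory, cluster the
#' ss-DRNs and aggregate each cluster into a DRN.
#'
#' @param induced_list list of induced `trajectory` objects.
#' @param seed integer seed for clustering.
#' @param window,var_target,max_components passed to
#'   [decompose_response()].
#' @param k,k_range,B passed to [cluster_ssdrns()].
#' @return List with `ssdrns`, `labels`, `drns`.
#' @export
extract_drns <- function(induced_list, seed = 1L, window = c(0.25, 0.75),
                         var_target = 0.99, max_components = 3L,
                         k = NULL, k_range = 1:8, B = 50L) {
  ssdrns <- lapply(induced_list, decompose_response, window = window,
                   var_target = var_target, max_components = max_components)
  labels <- cluster_ssdrns(ssdrns, seed = seed, k = k, k_range = k_range,
                           B = B)
  drns <- lapply(sort(unique(labels)), function(cl) {
    build_drn(ssdrns[labels == cl], cluster_id = cl)
  })
  list(ssdrns = ssdrns, labels = labels, drns = drns)
}
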