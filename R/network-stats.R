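#' Graph-theoretic measures of a long-range connectome
#'
#' Degrees from the binarized matrix, strengths from the weights
#' (rows = targets, so row sums are in-measures), and the
#' weighted-directed clustering coefficient of Fagiolo, computed on
#' weights scaled by their maximum.  Also returns the direct afferent
#' (incoming) and efferent (outgoing) weight vectors per area.
#'
#' @param weights square non-negative matrix, target x source.
#' @return A data frame with one row per area (`in_degree`, `out_degree`,
#'   `total_degree`, `in_strength`, `out_strength`, `total_strength`,
#'   `clustering_coefficient`) and attributes `afferent`, `efferent`
#'   (the weight matrix rows / columns).
#' @export
graph_measures <- function(weights) {
  W <- as.matrix(weights)
  abort_if(nrow(W) != ncol(W), "weights must be square")
  abort_if(any(W < 0), "weights must be non-negative")
  A <- (W > 0) * 1
  in_deg <- rowSums(A)
  out_deg <- colSums(A)
  in_str <- rowSums(W)
  out_str <- colSums(W)
  cc <- fagiolo_clustering(W)
  out <- data.frame(area = seq_len(nrow(W)),
                    in_degree = in_deg, out_degree = out_deg,
                    total_degree = in_deg + out_deg,
                    in_strength = in_str, out_strength = out_str,
                    total_strength = in_str + out_str,
                    clustering_coefficient = cc)
  attr(out, "afferent") <- W       # row i: weights into area i
  attr(out, "efferent") <- t(W)    # row i: weights out of area i
  out
}

# Fagiolo (2007) weighted-directed clustering coefficient, as distributed
# in the Rubinov-Sporns brain-connectivity toolbox.  W is scaled by its
# maximum so triangle intensities lie in [0, 1].
fagiolo_clustering <- function(W) {
  mx <- max(W)
  if (mx == 0) return(rep(0, nrow(W)))
  # W here is target x source; Fagiolo's convention is source x target
  Wd <- t(W) / mx
  A <- (Wd > 0) * 1
  Wc <- Wd^(1 / 3)
  S <- Wc + t(Wc)
  cyc <- diag(S %*% S %*% S) / 2
  d_tot <- rowSums(A) + colSums(A)
  d_bi <- diag(A %*% A)
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  out <- ifelse(denom > 0, cyc / denom, 0)
  as.numeric(out)
}

#' Bhattacharyya coefficient between two non-negative vectors
#'
#' `sum(sqrt(p * q))` after normalizing both vectors to sum 1; the amount
#' of overlap between two distributions (1 iff proportional, 0 for
#' disjoint supports).
#'
#' @param p,q non-negative vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
bhattacharyya <- function(p, q) {
  abort_if(length(p) != length(q), "vectors must have equal length")
  abort_if(any(p < 0) || any(q < 0), "entries must be non-negative")
  abort_if(sum(p) == 0 || sum(q) == 0, "zero vector has no distribution")
  sum(sqrt((p / sum(p)) * (q / sum(q))))
}

#' Coarse-grain a node pattern to the area level
#'
#' Squares the pattern entries, sums them within each area (subcortical
#' nodes pass through as single-area squared values) and scales the
#' resulting area vector to unit Euclidean norm.
#'
#' @param pattern numeric vector over all network nodes.
#' @param geometry a [model_geometry()].
#' @return Unit-norm non-negative vector over areas.
#' @export
coarse_grain <- function(pattern, geometry) {
  areas <- node_areas(geometry)
  abort_if(length(pattern) != length(areas),
           "pattern length does not match the node count")
  v <- as.numeric(tapply(pattern^2, factor(areas, levels = seq_len(
    n_areas(geometry))), sum, default = 0))
  nrm <- sqrt(sum(v^2))
  abort_if(nrm == 0, "zero pattern cannot be coarse-grained")
  v / nrm
}

#' Functional-network template over areas
#'
#' Encodes per-area contribution levels (none/medium/high as 0/0.5/1) as a
#' unit-norm vector comparable with coarse-grained DRN components.
#'
#' @param name template name.
#' @param levels character vector over areas, entries in
#'   `c("none", "medium", "high")`.
#' @return A `functional_template`.
#' @export
functional_template <- function(name, levels) {
  abort_if(!all(levels %in% c("none", "medium", "high")),
           "levels must be none/medium/high")
  enc <- c(none = 0, medium = 0.5, high = 1)[levels]
  nrm <- sqrt(sum(enc^2))
  abort_if(nrm == 0, "template with no contributing area")
  structure(list(name = name, levels = levels,
                 encoded = as.numeric(enc / nrm)),
            class = "functional_template")
}

#' Ordered sensory-pathway definition
#'
#' @param name modality name.
#' @param edges two-column matrix or data frame (`source`, `target` area
#'   ids), ordered along the pathway.
#' @param n_areas number of areas in the model the pathway refers to.
#' @return A `pathway_definition`.
#' @export
pathway_definition <- function(name, edges, n_areas) {
  edges <- as.matrix(edges)
  abort_if(ncol(edges) != 2L || nrow(edges) < 1L,
           "edges must be a two-column matrix with at least one edge")
  storage.mode(edges) <- "integer"
  abort_if(any(edges < 1L) || any(edges > n_areas),
           "pathway references an unknown area")
  colnames(edges) <- c("source", "target")
  structure(list(name = name, edges = edges, n_edges = nrow(edges)),
            class = "pathway_definition")
}

#' Correlate a response pattern with a structural predictor
#'
#' Statistic per `method` (Pearson or Kendall correlation, or the
#' Bhattacharyya coefficient for non-negative patterns) with a seeded
#' permutation null obtained by shuffling the predictor across areas;
#' p-values are Bonferroni-scaled by the announced family size.
#'
#' @param component response pattern (per area or node).
#' @param predictor structural measure vector of the same length.
#' @param method `"pearson"`, `"kendall"` or `"bhattacharyya"`.
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @param family_size Bonferroni family size (default 1).
#' @return List with `statistic`, `p_raw`, `p_corrected`, `method`,
#'   `n_perm`.  The permutation p-value floor is `1/(n_perm + 1)`.
#' @export
correlate_response_with_structure <- function(component, predictor,
                                              method = c("pearson",
                                                         "kendall",
                                                         "bhattacharyya"),
                                              n_perm = 10000L, seed = 1L,
                                              family_size = 1L) {
  method <- match.arg(method)
  abort_if(length(component) != length(predictor),
           "component and predictor lengths differ")
  stat_fun <- switch(method,
    pearson = function(x, y) stats::cor(x, y),
    kendall = function(x, y) stats::cor(x, y, method = "kendall"),
    bhattacharyya = function(x, y) bhattacharyya(x, y))
  if (method != "bhattacharyya") {
    abort_if(stats::sd(component) == 0 || stats::sd(predictor) == 0,
             "correlation undefined for constant input")
  }
  obs <- stat_fun(component, predictor)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_fun(component, sample(predictor))
    }, numeric(1))
  })
  p_raw <- if (method == "bhattacharyya") {
    (1 + sum(perm >= obs)) / (n_perm + 1)
  } else {
    (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  }
  list(statistic = obs, p_raw = p_raw,
       p_corrected = min(1, p_raw * family_size),
       method = method, n_perm = n_perm)
}

#' Compare DRN components against functional-network templates
#'
#' Coarse-grains each DRN component to areas, then computes Pearson
#' correlation and Bhattacharyya overlap against each encoded template,
#' with seeded permutation p-values Bonferroni-corrected by the family
#' size (#templates x #components) and agreement tiers on the Pearson
#' correlation (0.8 / 0.6 / 0.5 thresholds).
#'
#' @param drns list of `drn` objects.
#' @param templates list of [functional_template()] objects.
#' @param geometry the [model_geometry()] shared by both.
#' @param n_perm,seed permutation controls.
#' @return Tidy data frame: one row per (drn, component, template).
#' @export
compare_templates <- function(drns, templates, geometry, n_perm = 1000L,
                              seed = 1L) {
  family <- length(templates) * 3L
  rows <- list()
  for (d in seq_along(drns)) {
    comps <- drns[[d]]$components
    for (j in seq_len(ncol(comps))) {
      if (all(comps[, j] == 0)) next
      cg <- coarse_grain(comps[, j], geometry)
      for (tm in seq_along(templates)) {
        enc <- templates[[tm]]$encoded
        pear <- correlate_response_with_structure(cg, enc, "pearson",
                                                  n_perm = n_perm,
                                                  seed = seed,
                                                  family_size = family)
        bh <- correlate_response_with_structure(cg, enc, "bhattacharyya",
                                                n_perm = n_perm,
                                                seed = seed,
                                                family_size = family)
        r <- pear$statistic
        rows[[length(rows) + 1L]] <- data.frame(
          drn = d, component = j, template = templates[[tm]]$name,
          pearson = r, pearson_p = pear$p_corrected,
          bhattacharyya = bh$statistic, bhattacharyya_p = bh$p_corrected,
          tier = if (r > 0.8) "strong" else if (r > 0.6) "good"
                 else if (r > 0.5) "moderate" else "none")
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "family_size") <- family
  out
}

#' Embedding score of a pathway in a connectome
#'
#' Colors each pathway edge `j -> i` with
#' `q = c_ij^2 / (in_strength_i * out_strength_j)` (strength mode) or
#' `q = c_ij^2 / (max_in_i * max_out_j)` (max mode, always <= 1), and
#' aggregates as the mean over the `N` pathway edges.  Zero-weight edges
#' score 0 and are flagged; edges with a zero denominator are excluded
#' with a warning.
#'
#' @param pathway a [pathway_definition()].
#' @param weights square non-negative matrix, target x source.
#' @param mode `"strength"` or `"max"`.
#' @return An `embedding_score`: `q` per edge, `RU` (mean), `mode`,
#'   `zero_weight_edges`, `excluded_edges`.
#' @export
pathway_embedding <- function(pathway, weights, mode = c("strength", "max")) {
  mode <- match.arg(mode)
  W <- as.matrix(weights)
  abort_if(any(pathway$edges > nrow(W)),
           "pathway references an area outside the matrix")
  src <- pathway$edges[, "source"]
  tgt <- pathway$edges[, "target"]
  w_edge <- W[cbind(tgt, src)]
  denom <- if (mode == "strength") {
    rowSums(W)[tgt] * colSums(W)[src]
  } else {
    apply(W, 1, max)[tgt] * apply(W, 2, max)[src]
  }
  q <- rep(NA_real_, length(w_edge))
  zero_w <- w_edge == 0
  bad <- denom == 0 & !zero_w
  q[zero_w] <- 0
  ok <- !zero_w & !bad
  q[ok] <- w_edge[ok]^2 / denom[ok]
  if (any(bad)) {
    warning(sprintf("%d pathway edge(s) excluded (zero denominator)",
                    sum(bad)), call. = FALSE)
  }
  structure(list(q = q, RU = mean(q[!bad]), mode = mode,
                 zero_weight_edges = which(zero_w),
                 excluded_edges = which(bad)),
            class = "embedding_score")
}

#' Areas holding a given fraction of the total response energy
#'
#' Ranks areas by descending energy and returns the shortest prefix whose
#' cumulative share strictly exceeds `fraction` of the total.
#'
#' @param energies non-negative per-area energies.
#' @param fraction share to exceed (default 0.99).
#' @return Integer vector of area indices, in descending-energy order.
#' @export
top_energy_areas <- function(energies, fraction = 0.99) {
  abort_if(any(energies < 0), "energies must be non-negative")
  abort_if(all(energies == 0), "all energies are zero")
  ord <- order(-energies, seq_along(energies))
  share <- cumsum(energies[ord]) / sum(energies)
  n <- which(share > fraction)[1]
  if (is.na(n)) n <- length(energies)
  ord[seq_len(n)]
}

#' Bilateral symmetry classification of a response
#'
#' Pearson-correlates the per-area activity on the left with the activity
#' at the homolog areas on the right; a significant positive correlation
#' is symmetric, a significant negative one antisymmetric, anything else
#' supports neither.
#'
#' @param left_activity per-area activity, left hemisphere.
#' @param right_activity activity at the homolog areas, same order.
#' @param alpha_level significance level (default 0.05).
#' @return List with `classification` (`"symmetric"`, `"antisymmetric"`,
#'   `"none"`), `r`, `p`, `flagged` (constant input).
#' @export
bilateral_symmetry <- function(left_activity, right_activity,
                               alpha_level = 0.05) {
  abort_if(length(left_activity) != length(right_activity),
           "hemisphere vectors must be homolog-aligned")
  abort_if(length(left_activity) < 3L, "need at least three homolog pairs")
  if (stats::sd(left_activity) == 0 || stats::sd(right_activity) == 0) {
    return(list(classification = "none", r = NA_real_, p = NA_real_,
                flagged = TRUE))
  }
  ct <- stats::cor.test(left_activity, right_activity)
  cls <- if (ct$p.value < alpha_level) {
    if (ct$estimate > 0) "symmetric" else "antisymmetric"
  } else "none"
  list(classification = cls, r = unname(ct$estimate), p = ct$p.value,
       flagged = FALSE)
}

#' Write / read template and pathway fixtures as YAML
#'
#' @param templates list of [functional_template()].
#' @param pathways list of [pathway_definition()].
#' @param path file path.
#' @param n_areas area count for validation on read.
#' @export
write_fixtures_yaml <- function(templates, pathways, path) {
  obj <- list(
    templates = lapply(templates, function(t)
      list(name = t$name, levels = as.list(t$levels))),
    pathways = lapply(pathways, function(p)
      list(name = p$name,
           edges = lapply(seq_len(nrow(p$edges)), function(i)
             list(source = p$edges[i, "source"],
                  target = p$edges[i, "target"])))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_fixtures_yaml
#' @export
read_fixtures_yaml <- function(path, n_areas) {
  obj <- yaml::read_yaml(path)
  templates <- lapply(obj$templates, function(t)
    functional_template(t$name, unlist(t$levels)))
  pathways <- lapply(obj$pathways, function(p) {
    ed <- do.call(rbind, lapply(p$edges, function(e)
      c(source = e$source, target = e$target)))
    pathway_definition(p$name, ed, n_areas)
  })
  list(templates = templates, pathways = pathways)
}
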