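test_that("graph measures match hand-enumerated values", {
  gm <- graph_measures(matrix(c(0, 1, 2, 0), 2, byrow = TRUE))
  expect_equal(gm$in_strength, c(1, 2))
  expect_equal(gm$out_strength, c(2, 1))
  expect_equal(gm$in_degree, c(1, 1))
  expect_equal(gm$out_degree, c(1, 1))
  expect_equal(gm$total_degree, c(2, 2))
  z <- graph_measures(matrix(0, 3, 3))
  expect_true(all(z$total_strength == 0))
  expect_true(all(z$clustering_coefficient == 0))
  withr::with_seed(11, {
    S <- matrix(runif(16), 4); S <- S + t(S); diag(S) <- 0
    gs <- graph_measures(S)
    expect_equal(gs$in_strength, gs$out_strength)
  })
})

test_that("graph measures agree with brute force on random 3-node digraphs", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      W <- matrix(runif(9) * rbinom(9, 1, 0.6), 3); diag(W) <- 0
      gm <- graph_measures(W)
      A <- (W > 0) * 1
      expect_equal(gm$in_degree, rowSums(A))
      expect_equal(gm$out_degree, colSums(A))
      expect_equal(gm$in_strength, rowSums(W))
      expect_equal(gm$out_strength, colSums(W))
      # Fagiolo coefficient by scalar triple enumeration (source x target
      # convention, weights scaled by their maximum; zero diagonal makes
      # the degenerate j = i / k = j triples vanish)
      Wd <- t(W) / max(max(W), 1e-300)
      S <- Wd^(1 / 3) + t(Wd)^(1 / 3)
      Ad <- (Wd > 0) * 1
      cc_hand <- numeric(3)
      for (i in 1:3) {
        cyc <- 0
        for (j in 1:3) for (k in 1:3) {
          cyc <- cyc + S[i, j] * S[j, k] * S[k, i]
        }
        cyc <- cyc / 2
        dt <- sum(Ad[i, ]) + sum(Ad[, i])
        db <- sum(Ad[i, ] * Ad[, i])
        den <- dt * (dt - 1) - 2 * db
        cc_hand[i] <- if (den > 0) cyc / den else 0
      }
      expect_equal(gm$clustering_coefficient, cc_hand)
    }
  })
})

test_that("bhattacharyya coefficient identities and bounds", {
  expect_equal(bhattacharyya(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(bhattacharyya(c(2, 4, 6), c(1, 2, 3)), 1)  # proportional
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 0)
  expect_equal(bhattacharyya(rep(1, 4), c(1, 0, 0, 0)), 0.5)
  withr::with_seed(13, {
    for (rep in 1:10) {
      p <- runif(8); q <- runif(8)
      b <- bhattacharyya(p, q)
      expect_equal(b, bhattacharyya(q, p))
      expect_lte(b, 1 + 1e-12)
      expect_gte(b, 0)
    }
  })
  expect_error(bhattacharyya(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("coarse graining squares, sums within areas and normalizes", {
  g <- strip_geometry()   # 2 areas, 9 vertices each, no subcortex
  pat <- numeric(18)
  pat[1] <- 0.6          # area 1
  pat[10] <- 0.8         # area 2
  cg <- coarse_grain(pat, g)
  expect_equal(cg, c(0.36, 0.64) / sqrt(0.36^2 + 0.64^2))
  # pattern confined to one area gives a one-hot vector
  one <- numeric(18); one[2] <- 1
  expect_equal(coarse_grain(one, g), c(1, 0))
  # uniform pattern over equal-sized areas gives a uniform vector
  expect_equal(coarse_grain(rep(1, 18), g), rep(1, 2) / sqrt(2))
})

test_that("structure correlation statistics and permutation nulls behave", {
  withr::with_seed(14, {
    x <- rnorm(50)
    r <- correlate_response_with_structure(x, x, "pearson",
                                           n_perm = 200L, seed = 1L)
    expect_equal(r$statistic, 1)
    expect_equal(r$p_raw, 1 / 201)
    # Kendall tau of (1,2,3,4) vs (1,2,4,3): one discordant pair of six
    k <- correlate_response_with_structure(c(1, 2, 3, 4), c(1, 2, 4, 3),
                                           "kendall", n_perm = 50L)
    expect_equal(k$statistic, 2 / 3, tolerance = 1e-12)
    # independent predictor: small correlation, non-significant
    y <- rnorm(200); z <- rnorm(200)
    nul <- correlate_response_with_structure(y, z, "pearson",
                                             n_perm = 500L, seed = 2L)
    expect_lt(abs(nul$statistic), 0.2)
    expect_gt(nul$p_raw, 0.05)
    expect_error(correlate_response_with_structure(rep(1, 5), rnorm(5),
                                                   "pearson"),
                 "constant")
  })
})

test_that("permutation p-values are uniform on the grid under the null", {
  withr::with_seed(15, {
    ps <- vapply(1:60, function(i) {
      correlate_response_with_structure(rnorm(12), rnorm(12), "pearson",
                                        n_perm = 99L, seed = i)$p_raw
    }, numeric(1))
    # exchangeable null: p approximately uniform; KS as a sanity gate
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  })
})

test_that("template comparison flags exact matches and corrects the family", {
  g <- strip_geometry()
  n <- 18L
  comps <- cbind(c(rep(0.5, 9), rep(0.1, 9)))
  comps <- comps / sqrt(sum(comps^2))
  drn <- structure(list(components = cbind(comps,
                                           matrix(0, n, 2)),
                        member_sites = 1L, cluster_id = 1L),
                   class = "drn")
  cg <- coarse_grain(drn$components[, 1], g)
  templates <- list(
    functional_template("match", c("high", "medium")),
    functional_template("anti", c("none", "high")))
  # make the matching template exactly the coarse-grained component
  templates[[1]]$encoded <- cg
  res <- compare_templates(list(drn), templates, g, n_perm = 99L,
                           seed = 1L)
  expect_equal(attr(res, "family_size"), 6L)
  row <- res[res$template == "match", ]
  expect_equal(row$pearson, 1)
  expect_identical(row$tier, "strong")
  expect_equal(row$bhattacharyya, 1, tolerance = 1e-12)
})

test_that("pathway embedding reproduces hand-computed scores", {
  # 3-node toy: weights 2,1 into target 1; 2,1 out of source 2
  W <- matrix(0, 3, 3)
  W[1, 2] <- 2; W[1, 3] <- 1; W[3, 2] <- 1
  pw <- pathway_definition("toy", cbind(source = 2, target = 1), 3)
  q_str <- pathway_embedding(pw, W, mode = "strength")
  expect_equal(q_str$q, 4 / 9)
  expect_equal(q_str$RU, 4 / 9)
  # a graph containing only the pathway edge scores 1 in both modes
  W1 <- matrix(0, 2, 2); W1[2, 1] <- 3
  pw1 <- pathway_definition("single", cbind(1, 2), 2)
  expect_equal(pathway_embedding(pw1, W1, "strength")$RU, 1)
  expect_equal(pathway_embedding(pw1, W1, "max")$RU, 1)
  # max mode bounded by one and invariant under global scaling
  withr::with_seed(16, {
    Wr <- matrix(runif(25), 5); diag(Wr) <- 0
    pwr <- pathway_definition("rand", cbind(c(1, 2, 4), c(3, 5, 2)), 5)
    qm <- pathway_embedding(pwr, Wr, "max")
    expect_true(all(qm$q <= 1 + 1e-12))
    qm2 <- pathway_embedding(pwr, 13 * Wr, "max")
    expect_equal(qm$q, qm2$q)
    qs <- pathway_embedding(pwr, Wr, "strength")
    expect_true(all(qs$q >= 0 & qs$q < 1))
  })
  # zero-weight edge scores zero and is flagged
  pw0 <- pathway_definition("zero", cbind(source = 3, target = 2), 3)
  q0 <- pathway_embedding(pw0, W, "strength")
  expect_equal(q0$q, 0)
  expect_equal(q0$zero_weight_edges, 1L)
})

test_that("top energy areas implement the strict cumulative rule", {
  expect_equal(top_energy_areas(c(0, 5, 0)), 2L)
  # uniform energies over 100 areas: 99 reach exactly 0.99, so all 100
  expect_length(top_energy_areas(rep(1, 100)), 100L)
  expect_equal(top_energy_areas(c(0.995, 0.005)), 1L)
  expect_equal(top_energy_areas(c(0.985, 0.015)), c(1L, 2L))
  expect_error(top_energy_areas(c(0, 0)), "zero")
})

test_that("bilateral symmetry classifies mirrored, inverted and null activity", {
  withr::with_seed(17, {
    left <- runif(20)
    expect_identical(bilateral_symmetry(left, left)$classification,
                     "symmetric")
    expect_identical(bilateral_symmetry(left, -left)$classification,
                     "antisymmetric")
    hits <- sum(vapply(1:40, function(i) {
      bilateral_symmetry(rnorm(20), rnorm(20))$classification != "none"
    }, logical(1)))
    expect_lte(hits, 6)   # ~5% false positives expected
    flat <- bilateral_symmetry(rep(1, 5), runif(5))
    expect_identical(flat$classification, "none")
    expect_true(flat$flagged)
  })
})
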