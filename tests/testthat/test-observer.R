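test_that("envelope recovers amplitudes of oscillatory signals", {
  t <- seq(0, 1, by = 1e-3)
  x <- 2.5 * sin(2 * pi * 40 * t)
  env <- envelope(x)
  mid <- t > 0.1 & t < 0.9
  expect_true(all(abs(env[mid] - 2.5) / 2.5 < 0.01))
  expect_equal(envelope(rep(0, 100)), rep(0, 100))
  damp <- exp(-3 * t) * sin(2 * pi * 40 * t)
  envd <- envelope(damp)
  core <- t > 0.15 & t < 0.6
  expect_true(all(abs(envd[core] - exp(-3 * t[core])) /
                    exp(-3 * t[core]) < 0.02))
})

test_that("focal-plane projection places vertices in the right pixels", {
  g <- tiny_geometry()
  spec <- tiny_spec()
  # camera looking down +x at the right hemisphere
  plane <- focal_plane(origin = c(6, 0, 0), normal = c(1, 0, 0),
                       extent_mm = 12, n_px = 64L, depth_offset = 0)
  vals <- seq_len(nrow(g$vertices))
  img <- project_to_plane(vals, g, plane)
  expect_equal(dim(img), c(64L, 64L))
  expect_gt(sum(!is.na(img)), 0)
  # uniform values give a uniform image over covered pixels
  u <- project_to_plane(rep(3.5, nrow(g$vertices)), g, plane)
  expect_true(all(u[!is.na(u)] == 3.5))
  # a vertex on the plane maps to its own in-plane pixel
  v <- g$vertices[which(g$hemisphere == "right")[1], ]
  rel <- v - plane$origin
  py <- floor((sum(rel * plane$e1) + 6) / 12 * 64) + 1
  pz <- floor((sum(rel * plane$e2) + 6) / 12 * 64) + 1
  expect_false(is.na(img[py, pz]))
})

test_that("dF/F0 is a percent change, gain invariant and masks dead pixels", {
  stk <- make_vsd_stack(2L, c(5, 12), noise_sd = 0, seed = 1L)
  d <- dff0(stk)
  # baseline frames are exactly 0%
  expect_true(all(abs(d$frames[, , 1:stk$baseline_frames]) < 1e-9))
  # F = 1.002 F0 reads 0.2%
  stk2 <- stk
  stk2$frames[] <- 100
  stk2$frames[, , 30] <- 100 * 1.002
  d2 <- dff0(stk2)
  expect_equal(d2$frames[1, 1, 30], 0.2, tolerance = 1e-9)
  stk2$frames[, , 30] <- 50
  expect_equal(dff0(stk2)$frames[1, 1, 30], -50)
  # global gain invariance
  stk3 <- stk
  stk3$frames <- stk$frames * 7.3
  expect_equal(dff0(stk3)$frames, d$frames, tolerance = 1e-9)
})

test_that("activation onset crosses 20% of peak with interpolation", {
  t <- seq(0, 100, by = 1)
  ramp <- pmin(t / 100, 1)
  expect_equal(activation_onset(ramp, t), 20)
  step <- as.numeric(t >= 37)
  expect_equal(activation_onset(step, t, interpolate = FALSE), 37)
  expect_lte(abs(activation_onset(step, t) - 37), 1)
  expect_true(is.na(activation_onset(rep(0, 101), t)))
  # threshold is strict: a plateau at exactly 20% does not trigger
  flat <- c(rep(0, 10), rep(0.2, 10), rep(1, 10))
  on <- activation_onset(flat, seq_len(30), interpolate = FALSE)
  expect_equal(on, 21)
})

test_that("activation order sorts by onset with index tie-breaks", {
  seqn <- activation_order(c(A = 5, B = 3, C = 9))
  expect_identical(seqn$regions, c("B", "A", "C"))
  expect_equal(seqn$onsets_ms, c(3, 5, 9))
  ties <- activation_order(c(A = 4, B = 4, C = 1))
  expect_identical(ties$regions, c("C", "A", "B"))
  drop <- activation_order(c(A = 4, B = NA, C = 1))
  expect_identical(drop$regions, c("C", "A"))
})

test_that("kendall distance matches worked values and a bubble-sort oracle", {
  expect_equal(kendall_distance(c("A", "B", "C"), c("A", "B", "C")), 0)
  expect_equal(kendall_distance(c("A", "B", "C", "D"),
                                c("D", "C", "B", "A")), 1)
  d <- kendall_distance(strsplit("BCDE", "")[[1]],
                        strsplit("CDBE", "")[[1]])
  expect_equal(d, 1 / 3, tolerance = 1e-12)
  expect_equal(round(d, 2), 0.33)
  # oracle: count of adjacent transpositions via bubble sort
  bubble_count <- function(a, b) {
    p <- match(a, b)
    n <- length(p); count <- 0L
    repeat {
      swapped <- FALSE
      for (i in seq_len(n - 1L)) {
        if (p[i] > p[i + 1L]) {
          p[c(i, i + 1L)] <- p[c(i + 1L, i)]
          count <- count + 1L
          swapped <- TRUE
        }
      }
      if (!swapped) break
    }
    count
  }
  withr::with_seed(21, {
    for (n in 2:6) {
      for (rep in 1:10) {
        a <- sample(LETTERS[1:n])
        b <- sample(LETTERS[1:n])
        expect_equal(kendall_distance(a, b),
                     bubble_count(a, b) / (n * (n - 1) / 2))
      }
    }
  })
  expect_error(kendall_distance(c("A", "B"), c("A", "C")), "element set")
})

test_that("sequence similarity reproduces the worked examples", {
  # full pipeline from originals with the two-decimal distance convention
  s <- sequence_similarity(strsplit("ABCDEF", "")[[1]],
                           strsplit("ACHBFG", "")[[1]],
                           subseq_len = 4, distance_digits = 2)
  expect_equal(as.numeric(s), 0.335)
  expect_equal(attr(s, "distance"), 0.33)
  expect_equal(attr(s, "overlap"), 2L)
  # processed pair with full overlap: 1 - 2/3 = 1/3
  s2 <- sequence_similarity(c("X", "A", "B", "C", "D"),
                            c("Y", "C", "B", "D", "A"), subseq_len = 4)
  expect_equal(as.numeric(s2), 1 / 3, tolerance = 1e-12)
  # originals GABCD vs HCFEA: overlap 2 of 4, similarity 1/6
  s3 <- sequence_similarity(strsplit("GABCD", "")[[1]],
                            strsplit("HCFEA", "")[[1]], subseq_len = 4)
  expect_equal(as.numeric(s3), 1 / 6, tolerance = 1e-12)
  # identical sequences are maximally similar
  s4 <- sequence_similarity(strsplit("ABCDE", "")[[1]],
                            strsplit("ABCDE", "")[[1]], subseq_len = 4)
  expect_equal(as.numeric(s4), 1)
  expect_error(sequence_similarity(c("A", "B"), c("A", "B"),
                                   subseq_len = 4), "too short")
})

test_that("sequence similarity stays in [0,1]; asymmetries are bounded", {
  withr::with_seed(22, {
    asym <- 0
    for (rep in 1:30) {
      a <- sample(LETTERS[1:10], 7)
      b <- sample(LETTERS[1:10], 7)
      sab <- as.numeric(sequence_similarity(a, b, 4))
      sba <- as.numeric(sequence_similarity(b, a, 4))
      expect_gte(sab, 0); expect_lte(sab, 1)
      asym <- max(asym, abs(sab - sba))
    }
    # step-4 substitution is positional, so the measure is symmetric up
    # to the substitution pairing; flag if wildly asymmetric
    expect_lte(asym, 0.5)
  })
})

test_that("similarity benchmark thresholds and binarizes per row", {
  seqs <- list(r1 = c("A", "B", "C", "D", "E", "F"),
               r2 = c("B", "A", "C", "D", "E", "F"),
               r3 = c("C", "B", "A", "D", "E", "F"),
               r4 = c("D", "C", "B", "A", "E", "F"))
  bm <- similarity_benchmark(seqs, subseq_len = 4, percentile = 50)
  expect_true(all(is.na(diag(bm$similarity))))
  expect_length(bm$thresholds, 4L)
  # identical cross condition: diagonal similarity 1 >= any row threshold
  bm2 <- similarity_benchmark(seqs, subseq_len = 4, percentile = 50,
                              sequences_b = seqs)
  expect_true(all(diag(bm2$cross) == 1))
  expect_true(all(bm2$diagonal == 1))
  # order invariance of thresholds
  bm3 <- similarity_benchmark(seqs[c(3, 1, 4, 2)], subseq_len = 4,
                              percentile = 50)
  expect_equal(unname(sort(bm3$thresholds)), unname(sort(bm$thresholds)))
  # constant similarities give that constant as the threshold
  const <- list(a = c("X", "A", "B", "C", "D"),
                b = c("Y", "A", "B", "C", "D"),
                c = c("Z", "A", "B", "C", "D"))
  bmc <- similarity_benchmark(const, subseq_len = 4)
  expect_true(all(bmc$thresholds == 1))
})

test_that("TIFF and JSON round-trips preserve stacks and sequences", {
  stk <- make_vsd_stack(2L, c(5, 12), noise_sd = 0.2, seed = 4L,
                        grid_size = 16L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_vsd_tiff(stk, path)
  back <- read_vsd_tiff(path)
  expect_equal(back$frames, stk$frames, tolerance = 1e-3)
  expect_equal(back$frame_interval_ms, stk$frame_interval_ms)
  seqs <- list(r1 = activation_order(c(A = 1, B = 3)),
               r2 = activation_order(c(A = 4, B = 2)))
  sp <- withr::local_tempfile(fileext = ".json")
  write_sequences_json(seqs, sp)
  back2 <- read_sequences_json(sp)
  expect_identical(back2$r1$regions, seqs$r1$regions)
  expect_equal(back2$r2$onsets_ms, seqs$r2$onsets_ms)
})

test_that("virtual observer images a simulated run end to end", {
  g <- tiny_geometry()
  sc <- tiny_connectome()
  m <- coupled_model(g, long = sc, alpha = 0)
  tr <- simulate_model(m, stimulus_spec(1, onset_s = 0.02),
                       horizon_s = 0.25, record_interval = 1e-3)
  plane <- focal_plane(origin = c(-6, 0, 0), normal = c(-1, 0, 0),
                       extent_mm = 12, n_px = 32L, depth_offset = 1)
  stk <- observe_trajectory(tr, g, plane)
  expect_equal(dim(stk$frames)[1:2], c(32L, 32L))
  expect_equal(dim(stk$frames)[3], length(tr$times))
  expect_gt(max(stk$frames, na.rm = TRUE), 0)
})
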