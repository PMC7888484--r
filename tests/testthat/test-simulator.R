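test_that("local flow has the right fixed point, hand values and Hopf frequency", {
  expect_equal(local_rhs(c(0, 0), 0), c(0, 0))
  expect_equal(local_rhs(c(1, 0), 0, local_params(1, 1, 1)), c(-2, -1))
  # origin linearization at defaults: stable focus (complex pair, Re < 0)
  p <- local_params()
  J <- matrix(c(-p$eta * p$gamma, p$eta, -p$eta * p$epsilon, 0),
              2, byrow = TRUE)
  ev <- eigen(J)$values
  expect_true(all(Re(ev) < 0))
  expect_true(all(abs(Im(ev)) > 0))
  expect_equal(natural_frequency(p), abs(Im(ev[1])) / (2 * pi))
  # closed form: eta = 2*pi, eps = 1, gamma = 0 gives exactly 1 Hz
  expect_equal(natural_frequency(local_params(2 * pi, 0, 1)), 1)
  expect_error(natural_frequency(local_params(1, 2, 1)), "overdamped")
})

test_that("rest state is exactly preserved and stimulated runs stay causal", {
  g <- toy_geometry()
  A <- 4L
  W <- matrix(0, A, A); W[2, 1] <- 1
  D <- matrix(0, A, A); D[2, 1] <- 4   # 4 mm at 1 m/s = 4 ms
  long <- build_long_range(W, D, 1,
                           area_sizes = drnkit:::area_sizes(g))
  m <- coupled_model(g, long = long, alpha = 0)
  rest <- simulate_model(m, NULL, horizon_s = 0.05,
                         record_interval = 1e-3)
  expect_true(all(rest$psi1 == 0))
  expect_true(all(rest$psi2 == 0))
  # target area 2 must stay exactly silent before onset + delay
  tr <- simulate_model(m, stimulus_spec(1, onset_s = 0.002),
                       horizon_s = 0.1, record_interval = 40e-6)
  am <- area_mean_traj(tr, g)
  before <- tr$times < 0.002 + 0.004
  expect_true(all(am[2, before] == 0))
  expect_gt(max(abs(am[2, !before])), 0)
  # unconnected areas never move
  expect_true(all(am[3, ] == 0))
  expect_true(all(am[4, ] == 0))
})

test_that("isolated node rings at the natural frequency and decays", {
  tr <- isolated_node_response(5, horizon_s = 1, record_interval = 1e-3)
  x <- tr$psi1[1, ]
  # subcriticality: tail amplitude under 1% of the peak
  tail <- abs(x[tr$times > 0.9])
  expect_lt(max(tail), 0.01 * max(abs(x)))
  # FFT peak within 2% of the closed-form natural frequency
  sel <- tr$times > 0.05 & tr$times <= 0.55   # 500 ms of ring-down
  sp <- Mod(stats::fft(x[sel]))^2
  freqs <- (seq_along(sp) - 1) / 0.5
  half <- seq_len(floor(length(sp) / 2))
  f_peak <- freqs[half][which.max(sp[half])]
  expect_lt(abs(f_peak - natural_frequency()) / natural_frequency(), 0.02)
})

test_that("delay integrator matches an independent fine-step reference", {
  g <- toy_geometry()
  A <- 4L
  W <- matrix(0, A, A)
  W[2, 1] <- 1; W[1, 3] <- 0.5; W[3, 2] <- 0.8; W[4, 1] <- 0.3
  D <- matrix(0, A, A)
  D[2, 1] <- 2; D[1, 3] <- 4; D[3, 2] <- 1; D[4, 1] <- 3
  long <- build_long_range(W, D, 1, area_sizes = drnkit:::area_sizes(g))
  m <- coupled_model(g, long = long, alpha = 0)
  tr <- simulate_model(m, stimulus_spec(1, amplitude = 5),
                       dt = 40e-6, horizon_s = 0.4,
                       record_interval = 1e-3)
  am <- area_mean_traj(tr, g)
  ref <- reference_delay_heun(long$weights, long$delays_ms, stim_area = 1L,
                              amplitude = 5, dt = 4e-6, horizon_s = 0.4)
  expect_lt(max(abs(am - ref$psi1)), 1e-4)
})

test_that("delay integrator agrees with deSolve's dede solver", {
  skip_if_not_installed("deSolve")
  g <- toy_geometry()
  A <- 4L
  W <- matrix(0, A, A)
  W[2, 1] <- 1; W[1, 3] <- 0.5; W[3, 2] <- 0.8; W[4, 1] <- 0.3
  D <- matrix(0, A, A)
  D[2, 1] <- 2; D[1, 3] <- 4; D[3, 2] <- 1; D[4, 1] <- 3
  long <- build_long_range(W, D, 1, area_sizes = drnkit:::area_sizes(g))
  m <- coupled_model(g, long = long, alpha = 0)
  tr <- simulate_model(m, stimulus_spec(1, amplitude = 5),
                       dt = 40e-6, horizon_s = 0.4, record_interval = 1e-3)
  am <- area_mean_traj(tr, g)
  p <- local_params()
  Wn <- long$weights; taus <- long$delays_ms * 1e-3
  rhs <- function(t, y, parms) {
    p1 <- y[1:A]; p2 <- y[A + 1:A]
    coup <- numeric(A)
    for (i in 1:A) for (j in 1:A) if (Wn[i, j] > 0) {
      lag <- t - taus[i, j]
      coup[i] <- coup[i] + Wn[i, j] *
        (if (lag <= 0) 0 else deSolve::lagvalue(lag, j))
    }
    u <- as.numeric(t >= 0 & t < 1 / p$eta) * 5
    list(c(p$eta * (p2 - p$gamma * p1 - p1^3 + c(u, 0, 0, 0) + coup),
           -p$eta * p$epsilon * p1))
  }
  ref <- deSolve::dede(y = rep(0, 2 * A), times = seq(0, 0.4, by = 1e-3),
                       func = rhs, parms = NULL, atol = 1e-10,
                       rtol = 1e-10, hmax = 1e-5)
  expect_lt(max(abs(am - t(ref[, 2:(A + 1)]))), 1e-4)
})

test_that("alpha endpoints isolate the two coupling routes", {
  g <- tiny_geometry()
  sc <- tiny_connectome()
  sr <- build_short_range(g, 0.5)
  # alpha = 1: no short-range path between hemispheres, so the
  # contralateral cortex stays exactly silent
  m1 <- coupled_model(g, short = sr, long = NULL, alpha = 1)
  left_area <- 1L
  tr1 <- simulate_model(m1, stimulus_spec(left_area), horizon_s = 0.2,
                        record_interval = 1e-3)
  right_nodes <- which(g$hemisphere == "right")
  expect_true(all(tr1$psi1[right_nodes, ] == 0))
  expect_gt(max(abs(tr1$psi1)), 0)
  # alpha = 0: the short-range matrix is unused
  m0a <- coupled_model(g, short = sr, long = sc, alpha = 0)
  m0b <- coupled_model(g, short = NULL, long = sc, alpha = 0)
  t0a <- simulate_model(m0a, stimulus_spec(left_area), horizon_s = 0.1,
                        record_interval = 1e-3)
  t0b <- simulate_model(m0b, stimulus_spec(left_area), horizon_s = 0.1,
                        record_interval = 1e-3)
  expect_identical(t0a$psi1, t0b$psi1)
})

test_that("stimulus calibration yields a unit peak with local linearity", {
  amp <- calibrate_stimulus()
  tr <- isolated_node_response(amp, horizon_s = 0.2,
                               record_interval = 40e-6)
  peak <- max(abs(tr$psi1))
  expect_gte(peak, 0.99)
  expect_lte(peak, 1.01)
  tr2 <- isolated_node_response(2 * amp, horizon_s = 0.2,
                                record_interval = 40e-6)
  expect_gt(max(abs(tr2$psi1)), 1)
  # linear regime: far below the unit peak (where the cubic is
  # negligible) the peak scales proportionally with the amplitude
  tr3 <- isolated_node_response(0.01 * amp, horizon_s = 0.2,
                                record_interval = 40e-6)
  tr4 <- isolated_node_response(0.001 * amp, horizon_s = 0.2,
                                record_interval = 40e-6)
  expect_lt(abs(max(abs(tr3$psi1)) / (10 * max(abs(tr4$psi1))) - 1), 0.05)
})

test_that("induced response subtracts the isolated reference at stimulated nodes", {
  g <- toy_geometry()
  A <- 4L
  long <- build_long_range(matrix(c(0, 1, 1, 0, rep(0, 12)), 4, 4),
                           matrix(1, 4, 4) - diag(4), 1,
                           area_sizes = drnkit:::area_sizes(g))
  # fully disconnected: delete all links by alpha = 0 and zero source use
  W0 <- matrix(0, A, A); W0[2, 1] <- 1e-300
  long0 <- build_long_range(W0 * 1e300, matrix(0, A, A), 1,
                            area_sizes = drnkit:::area_sizes(g))
  long0$weights[] <- 0
  m <- coupled_model(g, long = long0, alpha = 0)
  iso <- isolated_node_response(5, horizon_s = 0.1, record_interval = 1e-3)
  tr <- simulate_model(m, stimulus_spec(1), horizon_s = 0.1,
                       record_interval = 1e-3)
  ind <- induced_response(tr, iso)
  expect_true(all(abs(ind$psi1[ind$stimulated_nodes, ]) < 1e-12))
  # unstimulated nodes pass through unchanged
  other <- setdiff(seq_len(nrow(tr$psi1)), ind$stimulated_nodes)
  expect_identical(ind$psi1[other, ], tr$psi1[other, ])
  expect_error(induced_response(tr, isolated_node_response(
    5, horizon_s = 0.05, record_interval = 1e-3)), "grids")
})

test_that("response energy integrates squared amplitude over the window", {
  # unit sinusoid over a 0.6 s window integrates to ~A^2 T / 2 = 0.3
  times <- seq(0, 1, by = 1e-3)
  x <- sin(2 * pi * 40 * times)
  traj <- structure(list(times = times, psi1 = rbind(x),
                         psi2 = rbind(0 * x), record_interval = 1e-3,
                         stimulated_nodes = integer(0),
                         meta = list(onset_s = 0)),
                    class = "trajectory")
  e <- response_energy(traj, window = c(0.2, 0.8))
  expect_equal(e, 0.3, tolerance = 1e-3)
  zero <- traj; zero$psi1[] <- 0
  expect_equal(response_energy(zero, window = c(0.2, 0.8)), 0)
  expect_error(response_energy(traj, window = c(1.5, 1.6)),
               "fewer than two")
})

test_that("sweep plans enumerate the full grid deterministically", {
  plan <- run_plan(1:512, seq(0, 1, by = 0.2), default_sigma_sweep())
  expect_equal(nrow(plan), 18432L)
  expect_equal(nrow(run_plan(1:2, c(0, 1), c(0.5, 1))), 8L)
  expect_error(run_plan(c(1, 1), 0.4, 0.5), "duplicate")
  # rerunning a trial reproduces it bitwise
  g <- toy_geometry()
  long <- build_long_range(matrix(c(0, 1, 0.5, 0, rep(0, 12)), 4, 4),
                           matrix(2, 4, 4) - 2 * diag(4), 1,
                           area_sizes = drnkit:::area_sizes(g))
  t1 <- run_catalog(g, long, sites = 1L, alphas = 0, sigmas = 0.5,
                    horizon_s = 0.05, record_interval = 1e-3)
  t2 <- run_catalog(g, long, sites = 1L, alphas = 0, sigmas = 0.5,
                    horizon_s = 0.05, record_interval = 1e-3)
  expect_identical(t1[[1]]$psi1, t2[[1]]$psi1)
})

test_that("state dimension counts two variables per node", {
  expect_equal(state_dimension(14400L), 28800L)
  g <- tiny_geometry()
  m <- coupled_model(g, long = tiny_connectome(), alpha = 0)
  expect_equal(state_dimension(m),
               2L * (nrow(g$vertices) + nrow(g$subcortical_centroids)))
})

test_that("subcritical decay holds across a small synthetic sweep", {
  g <- tiny_geometry()
  sc <- tiny_connectome()
  trajs <- run_catalog(g, sc, sites = c(1L, 5L), alphas = c(0, 0.4),
                       sigmas = 0.5, horizon_s = 1)
  for (tr in trajs) {
    peak <- max(abs(tr$psi1))
    expect_gt(peak, 0)
    tail <- max(abs(tr$psi1[, tr$times > 0.9]))
    expect_lt(tail, 0.01 * peak)
  }
})
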