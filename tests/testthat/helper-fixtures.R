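# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

tiny_spec <- function(seed = 7L) {
  synthetic_spec(n_vertices_per_hemisphere = 60L,
                 n_cortical_areas_per_hemisphere = 4L,
                 n_subcortical_areas_per_hemisphere = 2L,
                 seed = seed)
}

tiny_geometry <- function() memo("tiny_geometry", function() {
  make_geometry(tiny_spec())
})

tiny_connectome <- function() memo("tiny_connectome", function() {
  make_connectome(tiny_geometry(), tiny_spec())
})

# Minimal two-hemisphere geometry (3 vertices / 1 triangle / 1 area per
# hemisphere + 1 subcortical node each): point-area toys for integrator
# oracles, with 4 areas in total.
toy_geometry <- function() memo("toy_geometry", function() {
  make_geometry(synthetic_spec(n_vertices_per_hemisphere = 3L,
                               n_cortical_areas_per_hemisphere = 1L,
                               n_subcortical_areas_per_hemisphere = 1L,
                               seed = 1L))
})

# A thin two-row strip mesh per hemisphere (5 + 4 vertices), small enough
# for brute-force geodesic oracles.
strip_geometry <- function() memo("strip_geometry", function() {
  xs <- seq(0, 2, length.out = 5)
  bottom <- cbind(1 + xs, 0, 0)
  top <- cbind(1 + xs[-5] + 0.25, 0.5, 0)
  v_right <- rbind(bottom, top)
  tri <- rbind(c(1, 2, 6), c(2, 7, 6), c(2, 3, 7), c(3, 8, 7),
               c(3, 4, 8), c(4, 9, 8), c(4, 5, 9))
  v_left <- v_right
  v_left[, 1] <- -v_left[, 1]
  model_geometry(vertices = rbind(v_left, v_right),
                 triangles = rbind(tri[, c(1, 3, 2)], tri + 9L),
                 hemisphere = rep(c("left", "right"), each = 9L),
                 region_map = rep(c(1L, 2L), each = 9L),
                 n_cortical_per_hemisphere = 1L,
                 subcortical_centroids = NULL,
                 area_homolog = c(2L, 1L))
})

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Reference delay integrator: Heun's method of steps at a 10x finer step
# with dense history and linear interpolation of delayed area means.
# Independent of the compiled path (plain R, interpolated delays).
reference_delay_heun <- function(weights, delays_ms, stim_area, amplitude,
                                 local = local_params(), dt = 4e-6,
                                 horizon_s = 0.5, duration_s = 1 / local$eta,
                                 record_interval = 1e-3) {
  A <- nrow(weights)
  n_steps <- round(horizon_s / dt)
  eta <- local$eta; gam <- local$gamma; eps <- local$epsilon
  taus <- delays_ms * 1e-3
  h1 <- matrix(0, A, n_steps + 1L)   # dense psi1 history
  p1 <- numeric(A); p2 <- numeric(A)
  lagged <- function(j, t_q, step) {
    if (t_q <= 0) return(0)
    s <- t_q / dt
    s0 <- floor(s)
    w <- s - s0
    (1 - w) * h1[j, s0 + 1L] + w * h1[j, min(s0 + 2L, step + 1L)]
  }
  coup_at <- function(t_q, step) {
    out <- numeric(A)
    for (i in seq_len(A)) {
      acc <- 0
      for (j in seq_len(A)) {
        if (weights[i, j] != 0) {
          acc <- acc + weights[i, j] * lagged(j, t_q - taus[i, j], step)
        }
      }
      out[i] <- acc
    }
    out
  }
  drive <- function(t0, t1) {
    lo <- max(t0, 0); hi <- min(t1, duration_s)
    frac <- if (hi > lo) (hi - lo) / (t1 - t0) else 0
    amp <- numeric(A); amp[stim_area] <- amplitude * frac
    amp
  }
  rec_every <- round(record_interval / dt)
  rec1 <- matrix(0, A, n_steps %/% rec_every + 1L)
  times <- numeric(ncol(rec1))
  ri <- 1L
  for (step in seq_len(n_steps)) {
    t <- (step - 1L) * dt
    u <- drive(t, t + dt)
    c1 <- coup_at(t, step - 1L)
    f11 <- eta * (p2 - gam * p1 - p1^3 + u + c1)
    f12 <- -eta * eps * p1
    q1 <- p1 + dt * f11
    q2 <- p2 + dt * f12
    h1[, step + 1L] <- q1              # provisional for interpolation
    c2 <- coup_at(t + dt, step)
    f21 <- eta * (q2 - gam * q1 - q1^3 + u + c2)
    f22 <- -eta * eps * q1
    p1 <- p1 + 0.5 * dt * (f11 + f21)
    p2 <- p2 + 0.5 * dt * (f12 + f22)
    h1[, step + 1L] <- p1
    if (step %% rec_every == 0L) {
      ri <- ri + 1L
      rec1[, ri] <- p1
      times[ri] <- step * dt
    }
  }
  list(times = times, psi1 = rec1)
}

# Area-mean trajectories of a network run (areas respond coherently when
# alpha = 0, so area means are the point-area reference quantities).
area_mean_traj <- function(traj, geometry) {
  na <- drnkit:::node_areas(geometry)
  t(vapply(seq_len(max(na)), function(a) {
    colMeans(traj$psi1[na == a, , drop = FALSE])
  }, numeric(length(traj$times))))
}
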