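#' Local two-variable oscillator parameters
#'
#' Each network location carries a two-variable flow
#' \deqn{\dot\psi_1 = \eta(\psi_2 - \gamma\psi_1 - \psi_1^3 + u),\qquad
#'       \dot\psi_2 = -\eta\,\varepsilon\,\psi_1,}
#' a stable focus close to an Andronov-Hopf bifurcation for the default
#' parameterization, responding to perturbations with gamma-band damped
#' oscillations.  `gamma` is the damping (a surrogate for the local
#' excitation/inhibition balance), `epsilon` the restoring coefficient and
#' `eta` the characteristic rate in 1/s; the defaults put the natural
#' frequency near 42 Hz.
#'
#' @param eta characteristic rate, 1/s.
#' @param gamma damping, dimensionless.
#' @param epsilon restoring coefficient, dimensionless.
#' @return A `local_params` object.
#' @export
local_params <- function(eta = 76.74, gamma = 1.21, epsilon = 12.3083) {
  abort_if(!is_scalar(eta) || eta <= 0, "eta must be positive")
  abort_if(!is_scalar(gamma), "gamma must be a finite scalar")
  abort_if(!is_scalar(epsilon), "epsilon must be a finite scalar")
  structure(list(eta = eta, gamma = gamma, epsilon = epsilon),
            class = "local_params")
}

#' Right-hand side of the local two-variable flow
#'
#' @param state numeric length-2 vector `(psi1, psi2)`.
#' @param drive external input added inside the `eta(...)` bracket.
#' @param params a [local_params()].
#' @return Length-2 derivative vector.
#' @export
local_rhs <- function(state, drive = 0, params = local_params()) {
  abort_if(!all(is.finite(state)) || length(state) != 2L,
           "state must be a finite length-2 vector")
  p1 <- state[1]; p2 <- state[2]
  c(params$eta * (p2 - params$gamma * p1 - p1^3 + drive),
    -params$eta * params$epsilon * p1)
}

#' Natural frequency of the linearized local model
#'
#' Imaginary part of the origin-Jacobian eigenvalues over `2*pi`:
#' `eta * sqrt(epsilon - gamma^2/4) / (2*pi)` Hz.  Errors in the
#' overdamped regime (`epsilon <= gamma^2/4`), where the origin is a node
#' and no oscillation exists.
#'
#' @param params a [local_params()].
#' @return Frequency in Hz.
#' @export
natural_frequency <- function(params = local_params()) {
  disc <- params$epsilon - params$gamma^2 / 4
  abort_if(disc <= 0, "overdamped regime: epsilon <= gamma^2/4")
  params$eta * sqrt(disc) / (2 * pi)
}

#' Default stimulation period, ms
#'
#' The characteristic time `1/eta` of the local model, the duration of the
#' uniform rectangular stimulation pulse.
#' @param params a [local_params()].
#' @return Duration in ms.
#' @export
stimulation_period_ms <- function(params = local_params()) 1000 / params$eta

#' Quarter-cycle time of an oscillation
#'
#' The delay scale over which transmission is most effective for a
#' harmonic oscillation: a quarter of the period.
#' @param freq_hz oscillation frequency in Hz.
#' @return Time in ms.
#' @export
quarter_cycle_ms <- function(freq_hz) {
  abort_if(!is_scalar(freq_hz) || freq_hz <= 0, "frequency must be positive")
  1000 / (4 * freq_hz)
}

#' Assemble a coupled two-scale model
#'
#' @param geometry a [model_geometry()].
#' @param short a `short_range_sc` from [build_short_range()], or `NULL`
#'   when `alpha = 0`.
#' @param long a `long_range_sc` from [build_long_range()], or `NULL` when
#'   `alpha = 1`.
#' @param local a [local_params()].
#' @param alpha short-range coupling fraction in \[0, 1\] (`alpha = 1`:
#'   pure short-range, `alpha = 0`: pure long-range).
#' @return A `coupled_model`.
#' @export
coupled_model <- function(geometry, short = NULL, long = NULL,
                          local = local_params(), alpha = 0.4) {
  stopifnot(inherits(geometry, "model_geometry"))
  abort_if(!is_scalar(alpha) || alpha < 0 || alpha > 1,
           "alpha must lie in [0, 1]")
  abort_if(alpha > 0 && is.null(short),
           "short-range coupling required when alpha > 0")
  abort_if(alpha < 1 && is.null(long),
           "long-range coupling required when alpha < 1")
  if (!is.null(short)) {
    abort_if(nrow(short$weights) != nrow(geometry$vertices),
             "short-range matrix does not match the vertex count")
  }
  if (!is.null(long)) {
    abort_if(nrow(long$weights) != n_areas(geometry),
             "long-range matrix does not match the area count")
  }
  structure(list(geometry = geometry, short = short, long = long,
                 local = local, alpha = alpha),
            class = "coupled_model")
}

#' Number of state variables of a coupled model
#'
#' Two state variables per network node (cortical vertices plus lumped
#' subcortical areas).
#' @param model a [coupled_model()], or a node count.
#' @return Integer state dimension.
#' @export
state_dimension <- function(model) {
  nn <- if (inherits(model, "coupled_model")) n_nodes(model$geometry)
        else as.integer(model)
  2L * nn
}

#' Focal stimulation specification
#'
#' A uniform rectangular current pulse delivered to every node of a target
#' area (or to the vertices within `focus_radius` of the area centre) for
#' one characteristic time `1/eta`, driving the first state variable.
#'
#' @param target_area area id to stimulate.
#' @param amplitude drive amplitude in units of `eta` (the pulse enters the
#'   flow as `eta * amplitude`); default 5.
#' @param duration_s pulse duration, s; default `1/eta` of the default
#'   local model.
#' @param onset_s pulse onset, s.
#' @param focus_radius optional radius (mm) around the area centroid;
#'   `NULL` stimulates the whole area uniformly.
#' @return A `stimulus_spec`.
#' @export
stimulus_spec <- function(target_area, amplitude = 5,
                          duration_s = 1 / 76.74, onset_s = 0,
                          focus_radius = NULL) {
  abort_if(!is_count(target_area), "target_area must be an area id")
  abort_if(!is_scalar(amplitude), "amplitude must be a finite scalar")
  abort_if(!is_scalar(duration_s) || duration_s <= 0,
           "duration must be positive")
  abort_if(!is_scalar(onset_s) || onset_s < 0, "onset must be non-negative")
  structure(list(target_area = as.integer(target_area),
                 amplitude = amplitude, duration_s = duration_s,
                 onset_s = onset_s, focus_radius = focus_radius),
            class = "stimulus_spec")
}

stimulated_node_mask <- function(model, stimulus) {
  geometry <- model$geometry
  nn <- n_nodes(geometry)
  areas <- node_areas(geometry)
  abort_if(stimulus$target_area > n_areas(geometry),
           "target_area outside the model")
  mask <- areas == stimulus$target_area
  if (!is.null(stimulus$focus_radius) &&
      stimulus$target_area <= 2L * geometry$n_cortical_per_hemisphere) {
    centre <- colMeans(
      geometry$vertices[geometry$region_map == stimulus$target_area, ,
                        drop = FALSE])
    nv <- nrow(geometry$vertices)
    d <- sqrt(colSums((t(geometry$vertices) - centre)^2))
    mask[seq_len(nv)] <- mask[seq_len(nv)] & d <= stimulus$focus_radius
    abort_if(!any(mask), "focus radius contains no node of the target area")
  }
  mask
}

#' Simulate focal stimulation of the coupled model
#'
#' Integrates the delay-coupled network with Heun's method at fixed step
#' `dt`, recording every `record_interval`.  Long-range inputs are the
#' time-delayed area means of the source areas' first state variable;
#' short-range inputs are instantaneous.  Delays are rounded to integer
#' multiples of `dt`; the delayed history starts at the resting fixed
#' point (zero), so a model without stimulus stays identically at rest.
#'
#' @param model a [coupled_model()].
#' @param stimulus a [stimulus_spec()], or `NULL` for a rest run.
#' @param dt integration step, s (default 40e-6).
#' @param horizon_s total simulated time, s.
#' @param record_interval recording interval, s (default 1e-3; use `dt`
#'   for full-rate recording).
#' @return A `trajectory`: `times` (s), `psi1`, `psi2` (node x time),
#'   `record_interval`, `stimulated_nodes`, `meta`.
#' @export
simulate_model <- function(model, stimulus, dt = 40e-6, horizon_s = 1,
                           record_interval = 1e-3) {
  stopifnot(inherits(model, "coupled_model"))
  abort_if(!is_scalar(dt) || dt <= 0, "dt must be positive")
  abort_if(!is_scalar(horizon_s) || horizon_s <= 0,
           "horizon must be positive")
  if (!is.null(stimulus)) {
    abort_if(horizon_s <= stimulus$onset_s + stimulus$duration_s,
             "horizon must extend beyond the stimulus")
  }
  geometry <- model$geometry
  nn <- n_nodes(geometry)
  nv <- nrow(geometry$vertices)
  amp <- numeric(nn)
  if (!is.null(stimulus)) {
    amp[stimulated_node_mask(model, stimulus)] <- stimulus$amplitude
  }
  if (model$alpha < 1) {
    C <- model$long$weights
    dsteps <- matrix(as.integer(round(model$long$delays_ms * 1e-3 / dt)),
                     nrow(C), ncol(C))
    asz <- as.numeric(area_sizes(geometry))
  } else {
    C <- matrix(0, 0, 0)
    dsteps <- matrix(0L, 0, 0)
    asz <- numeric(0)
  }
  use_short <- !is.null(model$short) && model$alpha > 0
  S <- if (use_short) model$short$weights else
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(1, 1))
  record_every <- max(1L, as.integer(round(record_interval / dt)))
  n_steps <- as.integer(round(horizon_s / dt))
  if (model$alpha < 1 && nrow(C) > 0) {
    asz <- as.numeric(area_sizes(geometry))
  }
  res <- heun_delay_cpp(S, use_short, C, dsteps,
                        as.integer(node_areas(geometry)) - 1L, asz,
                        model$alpha, model$local$eta, model$local$gamma,
                        model$local$epsilon, amp,
                        if (is.null(stimulus)) -1 else stimulus$onset_s,
                        if (is.null(stimulus)) 0 else stimulus$duration_s,
                        dt, n_steps, record_every, nv)
  structure(list(times = as.numeric(res$times),
                 psi1 = res$psi1, psi2 = res$psi2,
                 record_interval = record_every * dt,
                 stimulated_nodes = which(amp != 0),
                 meta = list(site = if (is.null(stimulus)) NA_integer_
                             else stimulus$target_area,
                             alpha = model$alpha,
                             sigma = if (is.null(model$short)) NA_real_
                             else model$short$sigma,
                             dt = dt,
                             onset_s = if (is.null(stimulus)) NA_real_
                             else stimulus$onset_s)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$psi1), "nodes x", length(x$times),
      "samples; site", x$meta$site, "alpha", x$meta$alpha, "\n")
  invisible(x)
}

#' Response of a single isolated node to the default pulse
#'
#' Integrates one uncoupled local model under the rectangular stimulation
#' pulse, on the same grid as a network run; the reference subtracted when
#' isolating the network-induced response.
#'
#' @param amplitude pulse amplitude (units of `eta`).
#' @param local a [local_params()].
#' @param duration_s,onset_s pulse timing, s.
#' @param dt,horizon_s,record_interval as in [simulate_model()].
#' @return A `trajectory` with a single node.
#' @export
isolated_node_response <- function(amplitude = 5, local = local_params(),
                                   duration_s = 1 / local$eta, onset_s = 0,
                                   dt = 40e-6, horizon_s = 1,
                                   record_interval = 1e-3) {
  S <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(1, 1))
  record_every <- max(1L, as.integer(round(record_interval / dt)))
  n_steps <- as.integer(round(horizon_s / dt))
  res <- heun_delay_cpp(S, FALSE, matrix(0, 0, 0), matrix(0L, 0, 0),
                        0L, numeric(0), 1, local$eta, local$gamma,
                        local$epsilon, amplitude, onset_s, duration_s,
                        dt, n_steps, record_every, 1L)
  structure(list(times = as.numeric(res$times), psi1 = res$psi1,
                 psi2 = res$psi2, record_interval = record_every * dt,
                 stimulated_nodes = 1L,
                 meta = list(site = NA_integer_, alpha = NA_real_,
                             sigma = NA_real_, dt = dt, onset_s = onset_s)),
            class = "trajectory")
}

#' Calibrate the pulse amplitude for a unit peak response
#'
#' Searches the amplitude for which the default rectangular pulse evokes a
#' damped oscillation with `max |psi1| = 1` on a single isolated node.
#'
#' @param local a [local_params()].
#' @param target_peak desired peak (default 1).
#' @param interval amplitude search bracket.
#' @param dt,horizon_s integration controls (a short horizon suffices: the
#'   peak occurs during or just after the pulse).
#' @return The calibrated amplitude (units of `eta`).
#' @export
calibrate_stimulus <- function(local = local_params(), target_peak = 1,
                               interval = c(1e-3, 50), dt = 40e-6,
                               horizon_s = 0.2) {
  peak_of <- function(a) {
    tr <- isolated_node_response(a, local, dt = dt, horizon_s = horizon_s,
                                 record_interval = dt)
    max(abs(tr$psi1))
  }
  f <- function(a) peak_of(a) - target_peak
  lo <- f(interval[1]); hi <- f(interval[2])
  abort_if(lo * hi > 0, "amplitude search interval does not bracket the peak")
  stats::uniroot(f, interval, tol = 1e-4)$root
}

#' Stimulation-induced component of a network response
#'
#' Subtracts the isolated-node response from the network response at the
#' stimulated nodes; unstimulated nodes carry induced activity already and
#' are returned unchanged.
#'
#' @param network_traj network `trajectory`.
#' @param isolated_traj single-node `trajectory` on the same time grid.
#' @param stimulated_nodes node indices; defaults to the ones recorded in
#'   `network_traj`.
#' @return A `trajectory` of induced activity.
#' @export
induced_response <- function(network_traj, isolated_traj,
                             stimulated_nodes = network_traj$stimulated_nodes) {
  abort_if(!isTRUE(all.equal(network_traj$times, isolated_traj$times)),
           "time grids do not match")
  out <- network_traj
  if (length(stimulated_nodes)) {
    out$psi1[stimulated_nodes, ] <-
      sweep(out$psi1[stimulated_nodes, , drop = FALSE], 2,
            isolated_traj$psi1[1, ])
    out$psi2[stimulated_nodes, ] <-
      sweep(out$psi2[stimulated_nodes, , drop = FALSE], 2,
            isolated_traj$psi2[1, ])
  }
  out
}

#' Per-node response energy over a time window
#'
#' Trapezoidal integral of `psi1^2` over the window (default 0.2 s to
#' 0.8 s after the stimulus onset).
#'
#' @param traj a `trajectory`.
#' @param window length-2 numeric, window in seconds (absolute trajectory
#'   time).
#' @return Numeric vector of per-node energies.
#' @export
response_energy <- function(traj, window = NULL) {
  onset <- traj$meta$onset_s
  if (is.null(window)) {
    abort_if(is.na(onset %||% NA_real_),
             "no stimulus onset recorded; give a window explicitly")
    window <- onset + c(0.2, 0.8)
  }
  sel <- which(traj$times >= window[1] & traj$times <= window[2])
  abort_if(length(sel) < 2L, "window contains fewer than two samples")
  tt <- traj$times[sel]
  sq <- traj$psi1[, sel, drop = FALSE]^2
  dt_pair <- diff(tt)
  as.numeric(0.5 * (sq[, -length(sel), drop = FALSE] +
                    sq[, -1, drop = FALSE]) %*% dt_pair)
}

#' Enumerate a stimulation sweep
#'
#' Builds the deterministic trial grid of a parameter sweep: one trial per
#' (site, alpha, sigma) combination.
#'
#' @param sites stimulation site (area) ids.
#' @param alphas short-range fractions.
#' @param sigmas short-range kernel widths, mm.
#' @return Data frame with one row per trial.
#' @export
run_plan <- function(sites, alphas = seq(0, 1, by = 0.2),
                     sigmas = default_sigma_sweep()) {
  abort_if(length(sites) == 0 || length(alphas) == 0 || length(sigmas) == 0,
           "grids must be non-empty")
  abort_if(anyDuplicated(sites) > 0 || anyDuplicated(alphas) > 0 ||
           anyDuplicated(sigmas) > 0, "duplicate grid entries")
  expand.grid(site = sites, alpha = alphas, sigma = sigmas,
              KEEP.OUT.ATTRS = FALSE)
}

#' Run a full stimulation sweep
#'
#' Simulates one trial per (site, alpha, sigma), rebuilding the
#' short-range coupling per sigma, and subtracts the isolated-node
#' reference to return induced responses with provenance.
#'
#' @param geometry a [model_geometry()].
#' @param long a `long_range_sc`.
#' @param sites,alphas,sigmas sweep grids (see [run_plan()]).
#' @param local a [local_params()].
#' @param amplitude,dt,horizon_s,record_interval simulation controls.
#' @return List of induced `trajectory` objects, in [run_plan()] order.
#' @export
run_catalog <- function(geometry, long, sites, alphas = 0.4, sigmas = 0.5,
                        local = local_params(), amplitude = 5,
                        dt = 40e-6, horizon_s = 1, record_interval = 1e-3) {
  plan <- run_plan(sites, alphas, sigmas)
  iso <- isolated_node_response(amplitude, local,
                                duration_s = 1 / local$eta, dt = dt,
                                horizon_s = horizon_s,
                                record_interval = record_interval)
  shorts <- list()
  lapply(seq_len(nrow(plan)), function(r) {
    sg <- as.character(plan$sigma[r])
    if (plan$alpha[r] > 0 && is.null(shorts[[sg]])) {
      shorts[[sg]] <<- build_short_range(geometry, plan$sigma[r])
    }
    model <- coupled_model(geometry,
                           short = if (plan$alpha[r] > 0) shorts[[sg]],
                           long = if (plan$alpha[r] < 1) long,
                           local = local, alpha = plan$alpha[r])
    traj <- simulate_model(model,
                           stimulus_spec(plan$site[r], amplitude,
                                         duration_s = 1 / local$eta),
                           dt = dt, horizon_s = horizon_s,
                           record_interval = record_interval)
    induced_response(traj, iso)
  })
}
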