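# Time integration of the coupled shape/density system: explicit Euler with
# a conservative finite-volume density update, automatic step-size bound,
# occasional arclength re-discretization (round geometry), steady-state
# detection and snapshotting.

#' Simulation run configuration
#'
#' @param t_end end time (s).
#' @param dt time step; `NULL` (default) uses [stable_dt_bound()]
#'   recomputed as the contour evolves.
#' @param record_dt spacing of summary records and candidate snapshots (s);
#'   default `t_end / 400`.
#' @param safety safety factor applied to the stability bound.
#' @param resample_ratio re-discretize the contour when
#'   `max(ds)/min(ds)` exceeds this ratio (round geometry).
#' @param resample_every force a re-discretization after this many steps
#'   (round geometry).
#' @param steady_tol relative amplitude change below which the run is
#'   declared steady (together with a constant protrusion count).
#' @param steady_window_frac window of the steadiness test, as a fraction of
#'   elapsed time.
#' @param min_time do not declare steadiness before this time (s); defaults
#'   to `0.05 * t_end`.
#' @param count_threshold protrusion-count threshold fraction (see
#'   [count_protrusions()]).
#' @param amp_floor absolute amplitude (um) below which no protrusions are
#'   counted.
#' @param max_snapshots cap on stored snapshots (thinned by 2 when full).
#' @return a `run_config` list.
#' @export
run_config <- function(t_end = 600, dt = NULL, record_dt = NULL,
                       safety = 0.2, resample_ratio = 1.5,
                       resample_every = 200, steady_tol = 1e-4,
                       steady_window_frac = 0.05, min_time = NULL,
                       count_threshold = 0.1, amp_floor = 0.02,
                       max_snapshots = 40) {
  stopifnot(t_end > 0, is.null(dt) || dt > 0)
  if (is.null(record_dt)) record_dt <- t_end / 400
  if (is.null(min_time)) min_time <- 0.05 * t_end
  cfg <- list(t_end = t_end, dt = dt, record_dt = record_dt, safety = safety,
              resample_ratio = resample_ratio,
              resample_every = resample_every, steady_tol = steady_tol,
              steady_window_frac = steady_window_frac, min_time = min_time,
              count_threshold = count_threshold, amp_floor = amp_floor,
              max_snapshots = max_snapshots)
  class(cfg) <- "run_config"
  cfg
}

#' Stable time-step bound for the explicit Euler scheme
#'
#' Combines the stiffness bounds of the bending force (ds^4), the tension
#' force (ds^2), the pinning spring, and the second- and fourth-order
#' protein-transport operators, each with its explicit-Euler stability
#' constant, times a safety factor.
#'
#' @param state `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @param safety multiplicative safety factor (default 0.2).
#' @return maximal stable dt (s).
#' @export
stable_dt_bound <- function(state, p, safety = 0.2) {
  p <- validate_params(p)
  g <- state_geometry(state)
  ds <- min(g$elen)
  phimax <- max(max(state$phi), p$phi_bar)
  u <- (g$L - state$L_init) / state$L_init
  lamL <- if (p$lam_nl == 0) p$lam else p$lam * (1 + p$lam_nl * expm1(u / p$u0))
  lam_abs <- abs(lamL) + p$alpha_adh * phimax +
    0.5 * p$kappa * (p$Hbar * phimax)^2
  d2 <- p$D + p$Lambda * p$kappa * p$Hbar^2 * phimax +
    p$Lambda * p$J_bind * p$n_s * phimax
  d4 <- p$Lambda * p$J_bind * phimax  # J n_s phi lg2 with lg2 = 1/n_s
  eps <- 1e-300
  b <- c(p$xi * ds^4 / (8 * p$kappa),
         p$xi * ds^2 / (4 * lam_abs + eps),
         p$xi / (p$gamma + eps),
         ds^2 / (4 * d2 + eps),
         ds^4 / (16 * d4 + eps))
  safety * min(b)
}

#' Advance a state by one explicit Euler step
#'
#' Shape update along the normal and conservative density update with the
#' same dt; an internal positivity guard sub-steps (halving dt) if the
#' coverage field would leave (0, 1).
#'
#' @param state `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @param dt time step (s); should not exceed [stable_dt_bound()].
#' @return the advanced state.
#' @export
step <- function(state, p, dt) {
  p <- validate_params(p)
  stopifnot(dt > 0)
  if (inherits(state, "flat_state")) {
    r <- cpp_run_flat(state$h, state$phi, state$dx, unclass(p),
                      state$L_init, dt, 1L)
    if (r$status == 2) stop("time step failed (positivity guard exhausted)")
    state$h <- r$h; state$phi <- r$phi; state$t <- state$t + dt
  } else {
    r <- cpp_run_round(state$x, state$y, state$phi, unclass(p),
                       state$L_init, state$A_pref, dt, 1L, Inf)
    if (r$status == 2) stop("time step failed (positivity guard exhausted)")
    state$x <- r$x; state$y <- r$y; state$phi <- r$phi
    state$t <- state$t + dt
  }
  state
}

#' Amplitude field of a state
#'
#' Height above the mean shape (flat geometry) or radius about the centroid
#' minus the mean radius (round geometry); the field protrusions are counted
#' on.
#'
#' @param state `flat_state` or `contour_state`.
#' @return numeric per-node amplitude (um).
#' @export
amplitude_field <- function(state) {
  if (inherits(state, "flat_state")) {
    state$h - mean(state$h)
  } else {
    g <- cpp_geom_round(state$x, state$y)
    cx <- sum(state$x * g$ds) / sum(g$ds)
    cy <- sum(state$y * g$ds) / sum(g$ds)
    r <- sqrt((state$x - cx)^2 + (state$y - cy)^2)
    r - sum(r * g$ds) / sum(g$ds)
  }
}

record_row <- function(state, p, cfg) {
  g <- state_geometry(state)
  a <- amplitude_field(state)
  fb <- force_breakdown_raw(state, p)
  if (inherits(state, "flat_state")) {
    net <- abs(sum((fb$f_actin + fb$f_tension_adh) * p$w * g$ds))
    cx <- NA_real_; cy <- NA_real_; area <- NA_real_
  } else {
    fx <- sum((fb$f_actin + fb$f_tension_adh) * g$nx * p$w * g$ds)
    fy <- sum((fb$f_actin + fb$f_tension_adh) * g$ny * p$w * g$ds)
    net <- sqrt(fx^2 + fy^2)
    cx <- sum(state$x * g$ds) / sum(g$ds)
    cy <- sum(state$y * g$ds) / sum(g$ds)
    area <- g$area
  }
  c(t = state$t,
    max_amplitude = max(abs(a)),
    n_protrusions = count_protrusions(
      state, threshold_fraction = cfg$count_threshold,
      amp_floor = cfg$amp_floor),
    net_force = net,
    centroid_x = cx, centroid_y = cy,
    L = g$L, A_enc = area,
    M_total = sum(state$phi * g$ds))
}

#' Detect a steady state in a trajectory summary
#'
#' The run is steady when, over a trailing window covering
#' `window_frac` of the elapsed time, the relative change of the maximum
#' amplitude falls below `tol` and the protrusion count is constant.
#'
#' @param summary trajectory summary data.frame (columns `t`,
#'   `max_amplitude`, `n_protrusions`).
#' @param tol relative amplitude tolerance.
#' @param window_frac trailing window as a fraction of elapsed time.
#' @param amp_floor absolute amplitude scale for near-flat states.
#' @return list with `steady` (logical) and `t_ss` (time steadiness was
#'   reached, NA if not steady).
#' @export
detect_steady_state <- function(summary, tol = 1e-4, window_frac = 0.05,
                                amp_floor = 0.02) {
  n <- nrow(summary)
  if (n < 6) return(list(steady = FALSE, t_ss = NA_real_))
  tn <- summary$t[n]
  win <- summary$t >= (1 - window_frac) * tn
  if (sum(win) < 3) return(list(steady = FALSE, t_ss = NA_real_))
  a <- summary$max_amplitude[win]
  scale <- max(a[length(a)], amp_floor)
  steady <- (max(a) - min(a)) <= tol * scale &&
    length(unique(summary$n_protrusions[win])) == 1
  list(steady = steady, t_ss = if (steady) tn else NA_real_)
}

#' Run a simulation
#'
#' Integrates the coupled shape/density dynamics with explicit Euler until
#' `t_end` or a detected steady state.  The flat geometry keeps periodic
#' boundary conditions and the mean-subtracted actin force; the round
#' geometry applies the re-discretization policy (equal-arclength resampling
#' with conservative density transfer) and records centroid drift.
#'
#' @param state0 initial `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @param cfg a [run_config()].
#' @return object of class `trajectory`: list with `state` (final),
#'   `summary` (time series data.frame), `snapshots` (list of states),
#'   `reason` (termination reason), `p`, `cfg`.
#' @export
run <- function(state0, p, cfg = run_config()) {
  p <- validate_params(p)
  state <- state0
  flat <- inherits(state, "flat_state")
  n_rec_max <- as.integer(ceiling(cfg$t_end / cfg$record_dt)) + 2L
  recmat <- matrix(NA_real_, n_rec_max, 9)
  colnames(recmat) <- c("t", "max_amplitude", "n_protrusions", "net_force",
                        "centroid_x", "centroid_y", "L", "A_enc", "M_total")
  n_rec <- 1L
  recmat[1, ] <- as.numeric(record_row(state, p, cfg))
  snaps <- list(state)
  reason <- "t_end"
  steps_since_resample <- 0L
  t_next_rec <- cfg$record_dt
  repeat {
    if (state$t >= cfg$t_end - 1e-12) break
    dt <- if (is.null(cfg$dt)) stable_dt_bound(state, p, cfg$safety) else
      min(cfg$dt, stable_dt_bound(state, p, cfg$safety))
    t_target <- min(t_next_rec, cfg$t_end)
    nst <- max(1L, as.integer(ceiling((t_target - state$t) / dt - 1e-9)))
    if (!flat) nst <- min(nst, cfg$resample_every)
    if (flat) {
      r <- cpp_run_flat(state$h, state$phi, state$dx, unclass(p),
                        state$L_init, dt, nst)
      if (r$status == 2) stop("time step failed at t = ", state$t)
      state$h <- r$h; state$phi <- r$phi
      state$t <- state$t + r$t_done
    } else {
      r <- cpp_run_round(state$x, state$y, state$phi, unclass(p),
                         state$L_init, state$A_pref, dt, nst,
                         cfg$resample_ratio)
      if (r$status == 2) stop("time step failed at t = ", state$t)
      state$x <- r$x; state$y <- r$y; state$phi <- r$phi
      state$t <- state$t + r$t_done
      steps_since_resample <- steps_since_resample + r$steps_done
      if (r$status == 1 || steps_since_resample >= cfg$resample_every) {
        state <- resample_contour(state)
        steps_since_resample <- 0L
      }
    }
    if (state$t >= t_next_rec - 1e-9) {
      n_rec <- n_rec + 1L
      recmat[n_rec, ] <- as.numeric(record_row(state, p, cfg))
      t_next_rec <- t_next_rec + cfg$record_dt
      snaps[[length(snaps) + 1]] <- state
      if (length(snaps) > cfg$max_snapshots)
        snaps <- snaps[seq(1, length(snaps), by = 2)]
      if (state$t >= cfg$min_time) {
        summ <- as.data.frame(recmat[seq_len(n_rec), , drop = FALSE])
        ss <- detect_steady_state(summ, cfg$steady_tol,
                                  cfg$steady_window_frac, cfg$amp_floor)
        if (ss$steady) { reason <- "steady_state"; break }
      }
    }
  }
  summ <- as.data.frame(recmat[seq_len(n_rec), , drop = FALSE])
  rownames(summ) <- NULL
  out <- list(state = state, summary = summ, snapshots = snaps,
              reason = reason, p = p, cfg = cfg)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$summary)
  cat(sprintf(
    "trajectory: %d records to t = %.4g s (%s); final amplitude %.4g um, %d protrusion(s)\n",
    n, x$summary$t[n], x$reason, x$summary$max_amplitude[n],
    x$summary$n_protrusions[n]))
  invisible(x)
}
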