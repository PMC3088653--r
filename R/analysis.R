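# Quantitative observables: protrusion counting, coalescence time and its
# scaling with the fastest growth rate, parameter scans, net active forces,
# the crescent transition, steady-state current balance, and the cortical
# actin layer profile.

#' Count membrane protrusions
#'
#' A protrusion is a contiguous (periodic) excursion of the amplitude field
#' (height above the mean shape for the flat geometry, radius above the mean
#' radius for the round geometry) above `threshold_fraction` times the
#' global maximum amplitude.  Returns 0 when the maximum amplitude is below
#' the absolute noise floor.
#'
#' @param shape a `flat_state`/`contour_state`, or a numeric amplitude
#'   vector (periodic).
#' @param threshold_fraction counting threshold as a fraction of the maximum
#'   amplitude (default 0.1).
#' @param amp_floor absolute noise floor (um).
#' @return integer protrusion count.
#' @export
count_protrusions <- function(shape, threshold_fraction = 0.1,
                              amp_floor = 0.02) {
  a <- if (is.numeric(shape)) shape - mean(shape) else amplitude_field(shape)
  stopifnot(length(a) >= 3)
  amax <- max(a)
  if (amax < amp_floor) return(0L)
  above <- a >= threshold_fraction * amax
  if (all(above)) return(1L)
  # count periodic runs of TRUE
  rshift <- c(above[length(above)], above[-length(above)])
  as.integer(sum(above & !rshift))
}

#' Coalescence time from a trajectory summary
#'
#' The time at which the protrusion count last drops to 1 and stays at 1
#' through the end of the (steady) trajectory.  Returns `NA` (with
#' `attr(, "defined") = FALSE`) if a single persistent protrusion never
#' forms.
#'
#' @param x a `trajectory` or its summary data.frame.
#' @return numeric tau_c (s), `NA` if undefined.
#' @export
coalescence_time <- function(x) {
  summ <- if (inherits(x, "trajectory")) x$summary else x
  n <- nrow(summ)
  cnt <- summ$n_protrusions
  if (n == 0 || cnt[n] != 1) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  i <- n
  while (i > 1 && cnt[i - 1] == 1) i <- i - 1
  out <- summ$t[i]
  attr(out, "defined") <- TRUE
  out
}

scenario_flat <- function(p, N, L, seed, eps = NULL) {
  init_flat(p, N = N, L = L,
            spec = init_spec("uniform_random_noise", noise_amplitude = eps,
                             rng_seed = seed))
}

#' Coalescence-time scan against the fastest growth rate
#'
#' For each driver value (adhesion strength or actin coefficient) the flat
#' system is simulated from seeded noise to its single-protrusion steady
#' state; the median coalescence time over `seeds` is paired with the
#' fastest linear growth rate `omega_max`, and a log-log slope is fitted
#' over the large-`omega_max` subset (the near-critical points stall and
#' fall above a 1/omega_max law).
#'
#' @param p `model_params`.
#' @param driver `"alpha"` or `"A"`.
#' @param driver_values vector of driver values (all unstable).
#' @param seeds RNG seeds; the median tau_c per value is used.
#' @param N,L flat grid size and domain length.
#' @param t_max simulation time cap (s).
#' @param fit_frac fraction of the scan (largest omega_max values) used in
#'   the log-log fit.
#' @param cfg_extra named list of [run_config()] overrides.
#' @return list with `table` (driver, omega_max, tau_c, n_ok), `slope`,
#'   `intercept` (NA with fewer than 3 fitted points).
#' @export
coalescence_scan <- function(p, driver = c("alpha", "A"), driver_values,
                             seeds = 1:3, N = 128, L = 10, t_max = 4000,
                             fit_frac = 0.5, cfg_extra = list()) {
  driver <- match.arg(driver)
  field <- if (driver == "alpha") "alpha_adh" else "A_actin"
  rows <- lapply(driver_values, function(v) {
    p2 <- p; p2[[field]] <- v
    om <- most_unstable_mode(p2)$omega_max
    taus <- vapply(seeds, function(s) {
      st <- scenario_flat(p2, N, L, s)
      cfg <- do.call(run_config, c(list(t_end = t_max), cfg_extra))
      tr <- run(st, p2, cfg)
      as.numeric(coalescence_time(tr))
    }, numeric(1))
    data.frame(driver = v, omega_max = om,
               tau_c = stats::median(taus, na.rm = TRUE),
               n_ok = sum(!is.na(taus)))
  })
  tab <- do.call(rbind, rows)
  bad <- tab$n_ok == 0
  if (any(bad))
    warning(sum(bad), " driver value(s) never coalesced; excluded from fit")
  fit_tab <- tab[!bad & is.finite(tab$tau_c), ]
  ord <- order(fit_tab$omega_max, decreasing = TRUE)
  k <- max(3, ceiling(nrow(fit_tab) * fit_frac))
  sub <- fit_tab[ord[seq_len(min(k, nrow(fit_tab)))], ]
  if (nrow(sub) < 3) {
    return(list(table = tab, slope = NA_real_, intercept = NA_real_))
  }
  fit <- stats::lm(log(tau_c) ~ log(omega_max), data = sub)
  list(table = tab, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fit_subset = sub)
}

#' Protrusion count at the cellular time scale, against driver strength
#'
#' Simulates to `min(T_cell, steady state)` for each driver value and counts
#' protrusions, reproducing the non-monotone profile: zero below the
#' critical driving, a maximal plateau (set by the marginal wavelength) just
#' above it, decreasing toward one at strong driving.
#'
#' @inheritParams coalescence_scan
#' @param T_cell sampling time representing the cellular time scale (s).
#' @param seed RNG seed of the initial noise.
#' @return data.frame (driver, count, t_sampled).
#' @export
protrusion_count_vs_driver <- function(p, driver = c("alpha", "A"),
                                       driver_values, T_cell, seed = 1,
                                       N = 128, L = 10, cfg_extra = list()) {
  driver <- match.arg(driver)
  stopifnot(T_cell > 0)
  field <- if (driver == "alpha") "alpha_adh" else "A_actin"
  rows <- lapply(driver_values, function(v) {
    p2 <- p; p2[[field]] <- v
    st <- scenario_flat(p2, N, L, seed)
    cfg <- do.call(run_config, c(list(t_end = T_cell), cfg_extra))
    tr <- run(st, p2, cfg)
    n <- nrow(tr$summary)
    data.frame(driver = v, count = tr$summary$n_protrusions[n],
               t_sampled = tr$summary$t[n])
  })
  do.call(rbind, rows)
}

#' Net active force on a closed contour
#'
#' Vector sum over nodes of the active normal forces (actin plus the
#' adhesion part of the tension force) times `w ds`, reported raw and
#' normalized by the integrated absolute active force.  At an actin-only
#' steady state the normalized magnitude is close to zero; an adhesion-only
#' steady state retains a finite polar force (global drift).
#'
#' @param c a `contour_state`.
#' @param p `model_params`.
#' @return list with `vector` (Fx, Fy), `magnitude`, `normalized`.
#' @export
net_active_force <- function(c, p) {
  stopifnot(inherits(c, "contour_state"))
  fb <- force_breakdown_raw(c, p)
  g <- cpp_geom_round(c$x, c$y)
  f <- fb$f_actin + fb$f_tension_adh
  fx <- sum(f * g$nx * p$w * g$ds)
  fy <- sum(f * g$ny * p$w * g$ds)
  norm <- sum(abs(f) * p$w * g$ds)
  mag <- sqrt(fx^2 + fy^2)
  list(vector = c(fx, fy), magnitude = mag,
       normalized = if (norm > 0) mag / norm else 0)
}

#' Steady-state shape scan over the actin force (crescent transition)
#'
#' With adhesion off, increasing actin driving first dents the circular
#' steady state (a small concave dip) and then abruptly produces a
#' crescent.  Classification is by the dip depth relative to the mean
#' radius; the minimal coverage in the dip is reported (the dip is depleted
#' of protein at strong driving).
#'
#' @param p `model_params` (alpha_adh forced to 0).
#' @param A_values increasing actin-coefficient values.
#' @param N contour nodes.
#' @param t_max simulation time cap per run (s).
#' @param crescent_threshold dip depth / mean radius above which the shape
#'   is classified as a crescent.
#' @param seed RNG seed.
#' @param cfg_extra [run_config()] overrides.
#' @return data.frame (A, shape_class, dip_depth, min_phi_dip).
#' @export
crescent_scan <- function(p, A_values, N = 128, t_max = 3000,
                          crescent_threshold = 0.35, seed = 1,
                          cfg_extra = list()) {
  p$alpha_adh <- 0
  rows <- lapply(A_values, function(A) {
    p2 <- p; p2$A_actin <- A
    if (A == 0) {
      st <- init_round(p2, N = N,
                       spec = init_spec(noise_amplitude = 0, rng_seed = seed))
      g <- cpp_geom_round(st$x, st$y)
      return(data.frame(A = A, shape_class = "circular", dip_depth = 0,
                        min_phi_dip = min(st$phi)))
    }
    st <- init_round(p2, N = N, spec = init_spec(rng_seed = seed))
    cfg <- do.call(run_config, c(list(t_end = t_max), cfg_extra))
    tr <- run(st, p2, cfg)
    a <- amplitude_field(tr$state)
    g <- cpp_geom_round(tr$state$x, tr$state$y)
    rbar <- mean(sqrt((tr$state$x - mean(tr$state$x))^2 +
                        (tr$state$y - mean(tr$state$y))^2))
    dip <- -min(a) / rbar
    cls <- if (dip > crescent_threshold) "crescent" else
      if (dip > 0.02) "circular_with_dip" else "circular"
    # minimal coverage inside the dip region (nodes below mean radius)
    dipnodes <- a < 0.5 * min(a)
    data.frame(A = A, shape_class = cls, dip_depth = dip,
               min_phi_dip = min(tr$state$phi[dipnodes]))
  })
  do.call(rbind, rows)
}

#' Steady-state current balance and density-curvature tracking
#'
#' At steady state the dominant currents (curvature attraction vs the
#' dispersion flux) balance, giving H ~ Hbar * phi + const along the
#' contour; the residual of that relation and the rank correlation between
#' phi and -H quantify how closely the density follows the curvature.
#'
#' @param state a state at (or near) steady state.
#' @param p `model_params`.
#' @param require_steady error if the caller does not assert steadiness.
#' @return list with `residual` (rms of H - Hbar*phi - const, normalized by
#'   the larger of sd(H) and rms(H) so uniform-curvature states are
#'   well-conditioned) and `rank_correlation` (Spearman, phi vs -H).
#' @export
steady_state_density_curvature_check <- function(state, p,
                                                 require_steady = TRUE) {
  g <- state_geometry(state)
  H <- g$H
  phi <- state$phi
  resid_field <- H - p$Hbar * phi
  resid_field <- resid_field - sum(resid_field * g$ds) / sum(g$ds)
  h_scale <- max(stats::sd(H), sqrt(sum(H^2 * g$ds) / sum(g$ds)), 1e-12)
  residual <- sqrt(sum(resid_field^2 * g$ds) / sum(g$ds)) / h_scale
  rho <- suppressWarnings(
    stats::cor(phi, -H, method = "spearman"))
  list(residual = residual, rank_correlation = rho)
}

#' Visible cortical actin layer thickness
#'
#' Filaments nucleated at the membrane treadmill inward at velocity `v` and
#' depolymerize at rate `k_d`, so their number decays exponentially with
#' distance; the visible layer ends where the density crosses the detection
#' threshold: `d = (v / k_d) * log(n0 / n_th)`.
#'
#' @param k_d depolymerization (severing) rate (1/s).
#' @param v treadmilling velocity (um/s).
#' @param n0 filament density at the membrane.
#' @param n_th detection threshold density.
#' @return layer thickness d (um).
#' @export
actin_layer_thickness <- function(k_d, v, n0, n_th) {
  stopifnot(k_d > 0, v > 0, n0 > 0, n_th > 0)
  if (n_th > n0) stop("detection threshold exceeds the membrane density")
  (v / k_d) * log(n0 / n_th)
}
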