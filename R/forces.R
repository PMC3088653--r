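# Free energy and normal forces.
#
# The free energy is Helfrich-based: curvature mismatch against the protein
# spontaneous curvature, tension (nonlinearly hardening with contour
# extension) reduced locally by adhesion, harmonic pinning (flat geometry),
# protein mixing entropy with saturation density n_s, and bulk + gradient
# (surface) aggregation terms, all integrated over dA = w ds.
#
# Forces are exact analytic gradients of this *discrete* functional
# (implemented in src/membrane.cpp), so central-difference variations of
# free_energy() reproduce them to rounding error.  Two potential-density
# metric forces are deliberately absent from the dynamics: the entropic
# contour-expansion force (neglected as small, following the model the
# package implements) and the analogous bulk-aggregation metric force.

tension_potential <- function(L, L0, p) {
  u <- (L - L0) / L0
  if (p$lam_nl == 0) return(p$lam * (L - L0))
  p$lam * ((L - L0) + p$lam_nl * p$u0 * L0 * (exp(u / p$u0) - 1 - u / p$u0))
}

entropy_density <- function(phi, p) {
  if (any(phi <= 0 | phi >= 1))
    warning("phi at 0 or 1: entropy evaluated with clamped log arguments")
  ph <- pmin(pmax(phi, 1e-12), 1 - 1e-12)
  p$temperature * p$n_s * (ph * log(ph) + (1 - ph) * log(1 - ph))
}

#' Free energy of a membrane state
#'
#' Evaluates the discrete free energy whose exact gradients are the
#' conservative forces of the model.  Quadrature is node values times
#' `w * ds_i`; the gradient-aggregation term lives on edges.
#'
#' @param state `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @param parts if `TRUE`, return the named per-term breakdown instead of
#'   the scalar total.
#' @return total energy in kBT (or a named list of term energies).
#' @export
free_energy <- function(state, p, parts = FALSE) {
  p <- validate_params(p)
  g <- state_geometry(state)
  phi <- state$phi
  flat <- inherits(state, "flat_state")
  L0 <- state$L_init
  cc <- g$H - p$Hbar * phi
  dphi <- (phi[c(2:length(phi), 1)] - phi)
  terms <- list(
    curvature = p$w * p$kappa / 2 * sum(g$ds * cc^2),
    tension = p$w * tension_potential(g$L, L0, p),
    adhesion = -p$alpha_adh * p$w * sum(phi * g$ds),
    spring = if (flat) p$gamma * p$w / 2 * sum(state$h^2 * state$dx) else 0,
    entropy = p$w * sum(entropy_density(phi, p) * g$ds),
    agg_bulk = -p$w * p$J_bind * p$n_s / 2 * sum(phi^2 * g$ds),
    agg_grad = p$w * p$J_bind * p$n_s * (1 / p$n_s) / 2 *
      sum(dphi^2 / g$elen))
  if (parts) return(terms)
  sum(unlist(terms))
}

force_breakdown_raw <- function(state, p) {
  p <- validate_params(p)
  if (inherits(state, "flat_state")) {
    cpp_forces_flat(state$h, state$phi, state$dx, unclass(p), state$L_init)
  } else {
    cpp_forces_round(state$x, state$y, state$phi, unclass(p), state$L_init,
                     state$A_pref)
  }
}

#' Per-node normal force breakdown and normal velocity
#'
#' Populates all force components of the equations of motion for the given
#' geometry (spring flat-only; area pressure round-only; actin force
#' mean-subtracted in the flat geometry) and returns the normal velocity
#' `v_n = f_total / xi`.
#'
#' @param state `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @return list with `vn` (per-node normal velocity, um/s) and `breakdown`,
#'   a data.frame with columns `s`, `f_curv`, `f_tension`, `f_spring`,
#'   `f_agg`, `f_actin`, `f_area`, `f_total` (forces per unit membrane
#'   area, kBT/um^3).
#' @export
assemble_normal_velocity <- function(state, p) {
  fr <- force_breakdown_raw(state, p)
  n <- length(state$phi)
  s <- c(0, cumsum(fr$ds))[seq_len(n)]
  flat <- inherits(state, "flat_state")
  br <- data.frame(
    s = s,
    f_curv = fr$f_curv,
    f_tension = fr$f_tension,
    f_spring = if (flat) fr$f_spring else rep(0, n),
    f_agg = fr$f_agg,
    f_actin = fr$f_actin,
    f_area = if (flat) rep(0, n) else fr$f_area,
    f_total = fr$f_total)
  list(vn = fr$vn, breakdown = br, lam_eff = fr$lam_eff, L = fr$L)
}

#' @rdname force_components
#' @export
force_curvature <- function(state, p) force_breakdown_raw(state, p)$f_curv

#' Individual force components
#'
#' Accessors for single components of the normal force (per unit membrane
#' area).  `force_tension` includes the adhesion reduction (the
#' `-alpha * phi * H` protrusive term); `force_spring` is defined in the
#' flat geometry only and `force_area_pressure` in the round geometry only.
#'
#' @param state `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @return numeric per-node force vector (kBT/um^3).
#' @name force_components
#' @export
force_tension <- function(state, p) force_breakdown_raw(state, p)$f_tension

#' @rdname force_components
#' @export
force_spring <- function(state, p) {
  if (!inherits(state, "flat_state"))
    stop("the pinning spring acts in the flat geometry only")
  force_breakdown_raw(state, p)$f_spring
}

#' @rdname force_components
#' @export
force_aggregation <- function(state, p) force_breakdown_raw(state, p)$f_agg

#' @rdname force_components
#' @export
force_actin <- function(state, p) force_breakdown_raw(state, p)$f_actin

#' @rdname force_components
#' @export
force_area_pressure <- function(state, p) {
  if (!inherits(state, "contour_state"))
    stop("the area pressure acts in the round geometry only")
  force_breakdown_raw(state, p)$f_area
}

#' Adhesion part of the tension force
#'
#' The `+alpha * phi`-weighted metric force (protrusive at convex points),
#' reported separately for net-force diagnostics.
#'
#' @inheritParams force_components
#' @return numeric per-node force vector.
#' @export
force_adhesion_part <- function(state, p)
  force_breakdown_raw(state, p)$f_tension_adh

#' Effective membrane tension
#'
#' `lam_eff(L, phi_i) = lam(L) - alpha * phi_i` where `lam(L)` hardens
#' nonlinearly with the relative contour extension `(L - L0)/L0` (strength
#' `lam_nl`, onset scale `u0`).  Can be locally negative when adhesion is
#' strong at high coverage.
#'
#' @inheritParams force_components
#' @return per-node effective tension (kBT/um^2).
#' @export
effective_tension <- function(state, p) {
  p <- validate_params(p)
  g <- state_geometry(state)
  u <- (g$L - state$L_init) / state$L_init
  lamL <- if (p$lam_nl == 0) p$lam else
    p$lam * (1 + p$lam_nl * expm1(u / p$u0))
  lamL - p$alpha_adh * state$phi
}
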