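# Protein transport on the evolving contour.
#
# The tangential current has four parts, each a mobility-times-potential-
# gradient (or Fickian) term evaluated at edge centres of the finite-volume
# mesh:
#   J_curv = Lambda kappa Hbar phi dH/ds     (curvature sensing; for
#            Hbar < 0 it carries proteins toward more protrusive, more
#            negative-H regions)
#   J_disp = -Lambda kappa Hbar^2 phi dphi/ds  (membrane resistance to
#            aggregation of curved proteins; stabilising)
#   J_agg  = Lambda J_bind n_s phi (dphi/ds + lg^2 d3phi/ds3)  (direct
#            binding; up-gradient, destabilising, with a protein-scale
#            gradient cutoff lg^2 = 1/n_s)
#   J_diff = -D dphi/ds                       (thermal diffusion)
#
# The conservation law is realised in finite-volume form: the per-cell mass
# m_i = phi_i ds_i is updated by edge-current differences and phi is
# recovered on the post-move metric, which implements the covariant dilution
# term exactly and conserves total mass to rounding error.

flux_breakdown_raw <- function(state, p) {
  p <- validate_params(p)
  g <- state_geometry(state)
  cpp_fluxes(state$phi, g$H, g$elen, g$ds, unclass(p))
}

#' Per-edge protein current breakdown
#'
#' Edge `e` connects nodes `e` and `e + 1` (periodic); currents are protein
#' mass per unit time per unit contour thickness, positive along increasing
#' arclength.
#'
#' @param state `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @return data.frame with columns `J_curv`, `J_disp`, `J_agg`, `J_diff`,
#'   `J_total`.
#' @export
flux_breakdown <- function(state, p) {
  fl <- flux_breakdown_raw(state, p)
  as.data.frame(fl)
}

#' @rdname flux_components
#' @export
flux_curvature <- function(state, p) flux_breakdown_raw(state, p)$J_curv

#' Individual protein current components
#'
#' @param state `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @return per-edge current vector.
#' @name flux_components
#' @export
flux_dispersion <- function(state, p) flux_breakdown_raw(state, p)$J_disp

#' @rdname flux_components
#' @export
flux_aggregation <- function(state, p) flux_breakdown_raw(state, p)$J_agg

#' @rdname flux_components
#' @export
flux_diffusion <- function(state, p) flux_breakdown_raw(state, p)$J_diff

#' Rate of change of the protein coverage field
#'
#' dphi/dt = -(divergence of the total current along the contour) plus the
#' covariant dilution term from the local rate of change of the line
#' element, evaluated for a given normal-velocity field.  The discrete sum
#' `sum(dphi/dt * ds) + sum(phi * d(ds)/dt)` vanishes identically (mass
#' conservation).
#'
#' @param state `flat_state` or `contour_state`.
#' @param p `model_params`.
#' @param vn per-node normal velocity (um/s); defaults to the model's own
#'   [assemble_normal_velocity()].
#' @return per-node dphi/dt (1/s).
#' @export
density_rate <- function(state, p, vn = NULL) {
  if (is.null(vn)) vn <- assemble_normal_velocity(state, p)$vn
  g <- state_geometry(state)
  fl <- flux_breakdown_raw(state, p)
  n <- length(state$phi)
  Jm <- fl$J_total[c(n, seq_len(n - 1))]
  div <- (fl$J_total - Jm)
  # rate of change of the node line element under normal motion:
  # d(ds)/dt = -H vn ds (continuum identity under the package convention)
  dds_dt <- -g$H * vn * g$ds
  (-div - state$phi * dds_dt) / g$ds
}
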