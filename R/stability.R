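# Linear stability analysis: dispersion relations for the flat and round
# geometries, instability classification, critical boundaries, and the round
# equilibrium state.  The 2x2 linearizations are the continuum limits of the
# discrete dynamics; the test suite cross-checks their growth rates against
# the nonlinear simulator.

flat_matrix <- function(q, p) {
  lg2 <- 1 / p$n_s
  # metric coupling of the uniform curvature-mismatch energy acts as an
  # extra effective tension (kappa/2) (Hbar phi_bar)^2
  lam_star <- p$lam - p$alpha_adh * p$phi_bar +
    0.5 * p$kappa * (p$Hbar * p$phi_bar)^2
  m11 <- -(p$kappa * q^4 + lam_star * q^2 + p$gamma) / p$xi
  m12 <- (-p$kappa * p$Hbar * q^2 + p$A_actin) / p$xi
  m21 <- -p$Lambda * p$kappa * p$Hbar * p$phi_bar * q^4
  m22 <- -(p$Lambda * p$kappa * p$Hbar^2 * p$phi_bar + p$D -
             p$Lambda * p$J_bind * p$n_s * p$phi_bar) * q^2 -
    p$Lambda * p$J_bind * p$n_s * p$phi_bar * lg2 * q^4
  list(m11 = m11, m12 = m12, m21 = m21, m22 = m22)
}

eig2 <- function(m11, m12, m21, m22) {
  tr <- m11 + m22
  disc <- (m11 - m22)^2 + 4 * m12 * m21
  if (any(disc < 0)) {
    # complex pair: report real parts, flag via attribute
    sq <- sqrt(as.complex(disc))
    wp <- (tr + sq) / 2
    wm <- (tr - sq) / 2
    out <- list(omega_minus = Re(wm), omega_plus = Re(wp), real = disc >= 0,
                im = Im(wp))
    return(out)
  }
  sq <- sqrt(disc)
  list(omega_minus = (tr - sq) / 2, omega_plus = (tr + sq) / 2,
       real = rep(TRUE, length(tr)), im = rep(0, length(tr)))
}

#' Dispersion relation of the flat geometry
#'
#' Eigenvalue branches of the 2x2 linearization of the coupled
#' height/coverage dynamics about the uniform flat state, at wavevector(s)
#' `q`.  Both branches are real for this model; `omega_minus` is always
#' non-positive.
#'
#' @param q wavevector(s), 1/um, `q >= 0`.
#' @param p `model_params`.
#' @return data.frame with columns `q`, `omega_minus`, `omega_plus` (1/s).
#' @export
dispersion_flat <- function(q, p) {
  p <- validate_params(p)
  stopifnot(all(q >= 0))
  m <- flat_matrix(q, p)
  e <- eig2(m$m11, m$m12, m$m21, m$m22)
  data.frame(q = q, omega_minus = e$omega_minus, omega_plus = e$omega_plus)
}

#' Dispersion relation of the round geometry
#'
#' Eigenvalues of the linearization about the equilibrium circle for integer
#' angular modes `m`.  Mode m = 1 is the neutral translation mode (zero
#' growth rate, exactly).  The area-preserving pressure enters only the
#' m = 0 mode, the spring term is absent, and the actin force is not
#' mean-subtracted, matching the round equations of motion.
#'
#' @param m integer mode number(s) (>= 0).
#' @param p `model_params`.
#' @param equilibrium result of [equilibrium_round_state()]; computed if
#'   missing.
#' @return data.frame with columns `q` (mode number), `omega_minus`,
#'   `omega_plus`.
#' @export
dispersion_round <- function(m, p, equilibrium = NULL) {
  p <- validate_params(p)
  if (any(m != round(m)) || any(m < 0))
    stop("round-geometry modes must be non-negative integers")
  if (is.null(equilibrium)) equilibrium <- equilibrium_round_state(p)
  R <- equilibrium$R_eq
  phi0 <- equilibrium$phi_0
  H0 <- -1 / R
  c0 <- H0 - p$Hbar * phi0
  q <- m / R
  Hm <- (1 - m^2) / R^2
  lg2 <- 1 / p$n_s
  lam_prime <- if (p$lam_nl == 0) 0 else p$lam * p$lam_nl / (p$u0 * 2 * pi * R)
  f_rho <- -p$kappa * ((-q^2 + H0^2) * Hm + 2 * H0 * c0 * Hm) +
    0.5 * p$kappa * (2 * c0 * H0 * Hm + c0^2 * Hm) +
    (p$lam - p$alpha_adh * phi0) * Hm +
    ifelse(m == 0,
           lam_prime * 2 * pi * H0 -
             p$K_area * 2 * pi * R / (pi * p$R0^2), 0)
  f_phi <- (-p$Hbar) * (-p$kappa * (-q^2 + H0^2) + p$kappa * c0 * H0) -
    p$alpha_adh * H0 + p$A_actin
  t_rho <- p$Lambda * p$kappa * p$Hbar * phi0 * q^2 * Hm
  t_phi <- -(p$Lambda * p$kappa * p$Hbar^2 * phi0 + p$D -
               p$Lambda * p$J_bind * p$n_s * phi0) * q^2 -
    p$Lambda * p$J_bind * p$n_s * phi0 * lg2 * q^4
  # covariant dilution couples d(phi)/dt to d(rho)/dt: solve the generalized
  # problem with B = [[1, 0], [-phi0 H0, 1]]
  om <- mapply(function(a, b, c_, d_) {
    M <- matrix(c(a / p$xi, c_, b / p$xi, d_), 2, 2)
    B <- matrix(c(1, -phi0 * H0, 0, 1), 2, 2)
    ev <- eigen(solve(B, M), only.values = TRUE)$values
    ev <- ev[order(Re(ev))]
    c(Re(ev[1]), Re(ev[2]), max(abs(Im(ev))))
  }, f_rho, f_phi, t_rho, t_phi)
  if (any(om[3, ] > 1e-12))
    warning("complex eigenvalue pair in round dispersion; real parts reported")
  data.frame(q = m, omega_minus = om[1, ], omega_plus = om[2, ])
}

max_growth <- function(p, q_grid) {
  d <- dispersion_flat(q_grid, p)
  max(d$omega_plus)
}

default_q_grid <- function(L = 20, ds_min = 20 / 256, n = 400) {
  exp(seq(log(2 * pi / L), log(pi / ds_min), length.out = n))
}

#' Most unstable mode of the flat dispersion relation
#'
#' Grid scan over log-spaced wavevectors followed by golden-section
#' refinement of the growth-rate maximum.
#'
#' @param p `model_params`.
#' @param q_grid wavevector grid to scan (default 400 log-spaced points).
#' @return list with `q_max` (1/um), `omega_max` (1/s) and
#'   `lambda_max = 2*pi/q_max` (um).  Errors if the system is stable.
#' @export
most_unstable_mode <- function(p, q_grid = default_q_grid()) {
  d <- dispersion_flat(q_grid, p)
  i <- which.max(d$omega_plus)
  if (d$omega_plus[i] <= 0)
    stop("system is linearly stable: no unstable mode")
  lo <- q_grid[max(1, i - 1)]
  hi <- q_grid[min(length(q_grid), i + 1)]
  opt <- stats::optimize(function(q) dispersion_flat(q, p)$omega_plus,
                         c(lo, hi), maximum = TRUE,
                         tol = 1e-10 * (hi - lo) + 1e-12)
  list(q_max = opt$maximum, omega_max = opt$objective,
       lambda_max = 2 * pi / opt$maximum)
}

#' Classify the linear regime of the flat system
#'
#' Scans the dispersion relation and classifies the parameter set as
#' `stable` (no growing mode), `typeI` (unstable band extending to q -> 0)
#' or `typeII` (band bounded away from zero).
#'
#' @param p `model_params`.
#' @param q_grid wavevector grid.
#' @return list with `regime`, the scanned `dispersion` table, the
#'   `unstable_band` (q1, q2, or NULL), and `q_max`/`omega_max` when
#'   unstable.
#' @export
classify_regime <- function(p, q_grid = default_q_grid()) {
  d <- dispersion_flat(q_grid, p)
  up <- d$omega_plus > 0
  if (!any(up)) {
    return(list(regime = "stable", dispersion = d, unstable_band = NULL,
                q_max = NA_real_, omega_max = NA_real_))
  }
  i1 <- which(up)[1]
  i2 <- rev(which(up))[1]
  f <- function(q) dispersion_flat(q, p)$omega_plus
  q1 <- if (i1 == 1) {
    # does the band extend to q -> 0?  probe well below the grid
    if (f(q_grid[1] * 1e-3) > 0) 0 else
      stats::uniroot(f, c(q_grid[1] * 1e-3, q_grid[1]))$root
  } else stats::uniroot(f, c(q_grid[i1 - 1], q_grid[i1]))$root
  q2 <- if (i2 == length(q_grid)) q_grid[i2] else
    stats::uniroot(f, c(q_grid[i2], q_grid[i2 + 1]))$root
  mu <- most_unstable_mode(p, q_grid)
  regime <- if (q1 <= 0) "typeI" else "typeII"
  list(regime = regime, dispersion = d, unstable_band = c(q1, q2),
       q_max = mu$q_max, omega_max = mu$omega_max)
}

#' Critical driver strength of the flat instability
#'
#' Bisection on the maximal growth rate as a function of the adhesion
#' strength (`axis = "alpha"`) or the actin force coefficient
#' (`axis = "A"`), all other parameters fixed.
#'
#' @param p `model_params` (the value on the chosen axis is ignored).
#' @param axis `"alpha"` or `"A"`.
#' @param lower,upper bracketing interval; `upper = NULL` auto-expands by
#'   doubling until the system is unstable.
#' @param rel_tol relative tolerance of the bisection.
#' @param q_grid wavevector grid for the growth-rate scan.
#' @return list with `value` (the critical alpha_c or A_c) and `q_c` (the
#'   marginal wavevector).
#' @export
critical_boundary <- function(p, axis = c("alpha", "A"), lower = 0,
                              upper = NULL, rel_tol = 1e-4,
                              q_grid = default_q_grid()) {
  axis <- match.arg(axis)
  field <- if (axis == "alpha") "alpha_adh" else "A_actin"
  gmax <- function(v) {
    p2 <- p; p2[[field]] <- v
    max_growth(p2, q_grid)
  }
  if (gmax(lower) > 0)
    stop("system already unstable at the lower bracket")
  if (is.null(upper)) {
    upper <- max(1, 2 * (p$lam + 0.5 * p$kappa * (p$Hbar * p$phi_bar)^2) /
                   if (axis == "alpha") p$phi_bar else 1)
    k <- 0
    while (gmax(upper) <= 0) {
      upper <- upper * 2
      k <- k + 1
      if (k > 40) stop("no sign change: system stable up to huge driving")
    }
  } else if (gmax(upper) <= 0) {
    stop("no sign change in the bracketing interval")
  }
  while ((upper - lower) > rel_tol * upper) {
    mid <- (upper + lower) / 2
    if (gmax(mid) > 0) upper <- mid else lower <- mid
  }
  vc <- (upper + lower) / 2
  p2 <- p; p2[[field]] <- upper * (1 + 10 * rel_tol)
  d <- dispersion_flat(q_grid, p2)
  list(value = vc, q_c = d$q[which.max(d$omega_plus)])
}

#' Equilibrium circle of the round geometry
#'
#' Solves the uniform normal-force balance (curvature + tension with
#' adhesion + actin + area pressure) for the circle radius, with the uniform
#' coverage set by the total protein mass and the circumference.  The
#' preferred projected area is `pi * R0^2`.
#'
#' @param p `model_params`.
#' @param M_total total protein mass; default `phi_bar * 2 * pi * R0`.
#' @return list with `R_eq` (um), `phi_0`, and the residual force
#'   `f_residual` at the root.
#' @export
equilibrium_round_state <- function(p, M_total = NULL) {
  p <- validate_params(p)
  if (is.null(M_total)) M_total <- p$phi_bar * 2 * pi * p$R0
  stopifnot(M_total > 0)
  A0 <- pi * p$R0^2
  fnet <- function(R) {
    phi0 <- M_total / (2 * pi * R)
    H0 <- -1 / R
    c0 <- H0 - p$Hbar * phi0
    f_curv <- -p$kappa * H0^2 * c0 + 0.5 * p$kappa * c0^2 * H0
    f_tens <- (p$lam - p$alpha_adh * phi0) * H0
    f_act <- p$A_actin * phi0
    f_area <- -p$K_area * (pi * R^2 - A0) / A0
    f_curv + f_tens + f_act + f_area
  }
  # the net force is not monotone in R (curvature mismatch vs area
  # pressure): scan, then refine the sign change closest to R0
  Rg <- seq(0.2 * p$R0, 3 * p$R0, length.out = 400)
  fg <- vapply(Rg, fnet, numeric(1))
  sc <- which(fg[-1] * fg[-length(fg)] <= 0)
  if (length(sc) == 0) stop("no equilibrium radius in bracket")
  i <- sc[which.min(abs(Rg[sc] - p$R0))]
  r <- stats::uniroot(fnet, c(Rg[i], Rg[i + 1]), tol = 1e-14)
  phi0 <- M_total / (2 * pi * r$root)
  if (phi0 <= 0 || phi0 >= 1)
    stop("equilibrium coverage out of (0, 1)")
  list(R_eq = r$root, phi_0 = phi0, f_residual = fnet(r$root))
}
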