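#' Model parameters for the membrane contour model
#'
#' Collects and validates all physical constants of the coupled
#' membrane-shape / curved-protein model.  Units are micrometres, seconds and
#' k_BT throughout: curvatures in 1/um, tensions in kBT/um^2, forces per unit
#' membrane area in kBT/um^3.
#'
#' @param xi effective friction coefficient of the membrane (kBT s / um^4):
#'   normal velocity is total normal force per unit area divided by `xi`.
#' @param D lateral diffusion coefficient of the membrane protein (um^2/s).
#' @param phi_bar mean fractional area coverage of the protein (0-1).
#' @param n_s saturating protein density (1/um^2).
#' @param kappa membrane bending rigidity (kBT).
#' @param Hbar intrinsic (spontaneous) curvature of the protein (1/um);
#'   negative values are convex proteins, the regime where protrusive
#'   instabilities exist.
#' @param lam bare membrane tension (kBT/um^2).
#' @param gamma harmonic pinning spring constant (kBT/um^4); flat geometry
#'   only.
#' @param J_bind direct protein-protein binding interaction energy (kBT).
#' @param K_area effective bulk modulus for the cell's projected area
#'   (kBT/um^3); round geometry only.
#' @param R0 reference cell radius (um).
#' @param Lambda protein mobility (um^4 / (kBT s)).
#' @param lam_nl dimensionless non-linear tension parameter; 0 switches the
#'   tension hardening off.
#' @param A_actin actin protrusive force coefficient (kBT/um^3 per unit phi).
#' @param alpha_adh adhesion strength: negative, phi-proportional
#'   contribution to the effective tension (kBT/um^2 per unit phi).
#' @param w membrane strip thickness entering the area element dA = w ds (um).
#' @param temperature k_BT scale of the entropy term (in kBT units, so 1).
#' @param u0 relative contour extension at which the non-linear tension
#'   hardening sets in (dimensionless).
#'
#' @return A validated object of class `model_params` (a named list).
#' @export
model_params <- function(xi = 2000, D = 0.02, phi_bar = 0.1, n_s = 10,
                         kappa = 100, Hbar = -10, lam = 100, gamma = 10,
                         J_bind = 20, K_area = 2000, R0 = 3, Lambda = 0.002,
                         lam_nl = 1, A_actin = 0, alpha_adh = 0, w = 1,
                         temperature = 1, u0 = 0.05) {
  p <- list(xi = xi, D = D, phi_bar = phi_bar, n_s = n_s, kappa = kappa,
            Hbar = Hbar, lam = lam, gamma = gamma, J_bind = J_bind,
            K_area = K_area, R0 = R0, Lambda = Lambda, lam_nl = lam_nl,
            A_actin = A_actin, alpha_adh = alpha_adh, w = w,
            temperature = temperature, u0 = u0)
  class(p) <- "model_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks positivity/range constraints and warns when the spontaneous
#' curvature is not convex (`Hbar >= 0`), since the protrusive instability
#' requires convex membrane proteins.
#'
#' @param p a `model_params` object or a named list with the same fields.
#' @return the validated `model_params` object (invisibly the same values).
#' @export
validate_params <- function(p) {
  if (!inherits(p, "model_params")) {
    stopifnot(is.list(p))
    class(p) <- "model_params"
  }
  num1 <- function(v, nm) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a single finite number")
  }
  for (nm in c("xi", "D", "phi_bar", "n_s", "kappa", "Hbar", "lam", "gamma",
               "J_bind", "K_area", "R0", "Lambda", "lam_nl", "A_actin",
               "alpha_adh", "w", "temperature", "u0")) num1(p[[nm]], nm)
  if (p$xi <= 0) stop("xi must be > 0")
  if (p$kappa <= 0) stop("kappa must be > 0")
  if (p$n_s <= 0) stop("n_s must be > 0")
  if (p$w <= 0) stop("w must be > 0")
  if (p$R0 <= 0) stop("R0 must be > 0")
  if (p$u0 <= 0) stop("u0 must be > 0")
  for (nm in c("D", "Lambda", "lam_nl", "K_area", "gamma", "A_actin",
               "alpha_adh", "temperature")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  }
  if (p$phi_bar <= 0 || p$phi_bar >= 1)
    stop("phi_bar must lie strictly between 0 and 1")
  if (p$Hbar >= 0)
    warning("Hbar >= 0: protrusive instabilities require convex membrane ",
            "proteins (Hbar < 0)")
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Membrane contour model parameters (um, s, kBT):\n")
  v <- unlist(x)
  for (nm in names(v)) cat(sprintf("  %-11s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' Initial-condition specification
#'
#' Describes how the protein coverage field is perturbed at t = 0: either
#' i.i.d. uniform noise of maximal amplitude `noise_amplitude` added to the
#' mean coverage and then mean-corrected, or a localized Gaussian bump
#' renormalized to the prescribed total mass.
#'
#' @param kind one of `"uniform_random_noise"` or `"gaussian_density"`.
#' @param noise_amplitude maximal deviation of phi from `phi_bar` (epsilon).
#'   If `NULL`, defaults to `0.01 * phi_bar` at state construction.
#' @param gaussian_center centre of the Gaussian bump, as a fraction of the
#'   contour length (flat) or an angle in radians (round).
#' @param gaussian_width standard deviation of the bump (um along the
#'   contour).
#' @param rng_seed integer seed recorded in the run manifest; initial fields
#'   are bit-reproducible given the seed.
#' @return an object of class `init_spec`.
#' @export
init_spec <- function(kind = c("uniform_random_noise", "gaussian_density"),
                      noise_amplitude = NULL, gaussian_center = 0,
                      gaussian_width = 0.5, rng_seed = 1L) {
  kind <- match.arg(kind)
  if (!is.null(noise_amplitude)) {
    stopifnot(is.numeric(noise_amplitude), length(noise_amplitude) == 1,
              noise_amplitude >= 0)
  }
  s <- list(kind = kind, noise_amplitude = noise_amplitude,
            gaussian_center = gaussian_center,
            gaussian_width = gaussian_width,
            rng_seed = as.integer(rng_seed))
  class(s) <- "init_spec"
  s
}

phi_field <- function(spec, p, s_coord, ds, L) {
  eps <- spec$noise_amplitude
  if (is.null(eps)) eps <- 0.01 * p$phi_bar
  N <- length(s_coord)
  if (spec$kind == "uniform_random_noise") {
    if (eps > p$phi_bar)
      stop("noise amplitude exceeds phi_bar: coverage would go negative")
    set.seed(spec$rng_seed)
    noise <- stats::runif(N, -eps, eps)
    noise <- noise - mean(noise)         # exact mean coverage
    mx <- max(abs(noise))
    if (mx > eps) noise <- noise * (eps / mx)  # keep the maximal amplitude
    phi <- p$phi_bar + noise
  } else {
    d <- abs(s_coord - spec$gaussian_center)
    d <- pmin(d, L - d)                  # periodic distance
    bump <- exp(-0.5 * (d / spec$gaussian_width)^2)
    M_target <- p$phi_bar * L
    base <- 1e-3 * p$phi_bar             # small uniform background
    scale <- (M_target - base * sum(ds)) / sum(bump * ds)
    phi <- base + scale * bump           # total mass exactly M_target
    if (any(phi >= 1))
      stop("gaussian bump too concentrated: phi would exceed saturation")
  }
  phi
}

#' Initialize a flat periodic membrane state
#'
#' The membrane starts flat (`h = 0`) with the protein coverage field set by
#' the initial-condition spec.
#'
#' @param p `model_params`.
#' @param N number of grid nodes (>= 16).
#' @param L domain length in um.
#' @param spec an [init_spec()].
#' @return object of class `flat_state`: fields `x`, `h`, `phi`, `t`,
#'   `L_init`, `dx`.
#' @export
init_flat <- function(p, N = 256, L = 20, spec = init_spec()) {
  p <- validate_params(p)
  stopifnot(N >= 16, L > 0)
  dx <- L / N
  x <- seq(0, L - dx, by = dx)
  phi <- phi_field(spec, p, x, rep(dx, N), L)
  st <- list(x = x, h = rep(0, N), phi = phi, t = 0, L_init = L, dx = dx)
  class(st) <- "flat_state"
  st
}

#' Initialize a round (closed contour) membrane state
#'
#' Nodes are placed on the equilibrium circle where the uniform normal force
#' vanishes (see [equilibrium_round_state()]); the protein field is perturbed
#' as in [init_flat()].  The preferred projected area is `pi * R0^2`, the
#' same preference used by the equilibrium solve, so the generated state has
#' (numerically) zero normal velocity when unperturbed.
#'
#' @param p `model_params`.
#' @param N number of contour nodes (>= 32).
#' @param spec an [init_spec()].
#' @param M_total total protein mass (area coverage integrated over contour
#'   length); default `phi_bar * 2 * pi * R0`.
#' @return object of class `contour_state`: fields `x`, `y`, `phi`, `t`,
#'   `A_pref`, `L_init`, `M_total`.
#' @export
init_round <- function(p, N = 256, spec = init_spec(), M_total = NULL) {
  p <- validate_params(p)
  stopifnot(N >= 32)
  if (is.null(M_total)) M_total <- p$phi_bar * 2 * pi * p$R0
  eq <- equilibrium_round_state(p, M_total)
  th <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
  A_pref <- pi * p$R0^2
  # polish the continuum radius so the *discrete* N-gon has zero net
  # uniform normal force (the polygon quadrature shifts it by O(ds^2))
  fdisc <- function(R) {
    x <- R * cos(th); y <- R * sin(th)
    elen <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
    Ld <- sum(elen)
    fr <- cpp_forces_round(x, y, rep(M_total / Ld, N), unclass(p), Ld,
                           A_pref)
    mean(fr$f_total)
  }
  R <- tryCatch(
    stats::uniroot(fdisc, eq$R_eq * c(0.97, 1.03), tol = 1e-14)$root,
    error = function(e) eq$R_eq)
  x <- R * cos(th)
  y <- R * sin(th)
  elen <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  L <- sum(elen)
  ds <- (elen + c(elen[length(elen)], elen[-length(elen)])) / 2
  phi0d <- M_total / L
  if (spec$kind == "uniform_random_noise") {
    phi <- phi_field(spec, p, th * R, ds, L)
    phi <- phi * (phi0d / p$phi_bar)   # uniform level is the equilibrium one
  } else {
    pg <- p; pg$phi_bar <- phi0d
    phi <- phi_field(spec, pg, th * R, ds, L)
  }
  st <- list(x = x, y = y, phi = phi, t = 0, A_pref = A_pref,
             L_init = L, M_total = sum(phi * ds))
  class(st) <- "contour_state"
  validate_contour_state(st)
}

validate_contour_state <- function(st) {
  stopifnot(length(st$x) == length(st$y), length(st$x) == length(st$phi))
  if (any(st$phi < 0 | st$phi > 1))
    stop("phi out of [0, 1]")
  a <- enclosed_area_xy(st$x, st$y)
  if (a <= 0) stop("contour must be oriented counterclockwise (area > 0)")
  if (cpp_self_intersects(st$x, st$y)) stop("contour self-intersects")
  st
}

#' @export
print.flat_state <- function(x, ...) {
  cat(sprintf(
    "flat membrane state: N = %d, L = %g um, t = %.4g s, max|h| = %.4g um\n",
    length(x$h), x$L_init, x$t, max(abs(x$h))))
  invisible(x)
}

#' @export
print.contour_state <- function(x, ...) {
  g <- cpp_geom_round(x$x, x$y)
  cat(sprintf(
    "closed contour state: N = %d, L = %.4g um, area = %.4g um^2, t = %.4g s\n",
    length(x$x), g$L, g$area, x$t))
  invisible(x)
}
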