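# Discrete differential geometry of the evolving contour.
#
# Sign convention (used everywhere in the package): the curvature of a
# counterclockwise circle of radius R is H = -1/R, so outward protrusions
# have H < 0 and match the convex spontaneous curvature Hbar < 0.

enclosed_area_xy <- function(x, y) {
  xp <- c(x[-1], x[1]); yp <- c(y[-1], y[1])
  0.5 * sum(x * yp - xp * y)
}

#' Geometry cache of a membrane state
#'
#' Per-node arclength elements, unit tangents/outward normals, signed
#' curvature, total length and (round geometry) enclosed area.
#'
#' @param state a `flat_state` or `contour_state`.
#' @return a list with fields `ds`, `elen` (per-edge lengths), `H`, `L` and,
#'   for contours, `area`, `nx`, `ny`, `tx`, `ty`.
#' @export
state_geometry <- function(state) {
  if (inherits(state, "flat_state")) {
    cpp_geom_flat(state$h, state$dx)
  } else if (inherits(state, "contour_state")) {
    cpp_geom_round(state$x, state$y)
  } else stop("unknown state class")
}

#' Signed curvature of a closed contour
#'
#' Local circumscribed-circle (Menger) curvature on node triples, signed so
#' that a counterclockwise circle of radius R has H = -1/R at every node;
#' second-order accurate in the node spacing on smooth contours.
#'
#' @param c a `contour_state`.
#' @return numeric vector of per-node curvatures (1/um).
#' @export
curvature_closed <- function(c) {
  stopifnot(inherits(c, "contour_state"))
  elen <- cpp_geom_round(c$x, c$y)$elen
  if (any(elen == 0)) stop("duplicate/coincident nodes")
  cpp_geom_round(c$x, c$y)$H
}

#' Linearized curvature of a flat membrane
#'
#' H = d^2 h / dx^2 by periodic central differences, the linearised form
#' used for the flat geometry: a peak has H < 0, consistent with the
#' closed-contour convention.
#'
#' @param s a `flat_state`.
#' @return numeric vector of per-node curvatures (1/um).
#' @export
curvature_flat_linearized <- function(s) {
  stopifnot(inherits(s, "flat_state"))
  cpp_geom_flat(s$h, s$dx)$H
}

#' Enclosed (projected) area of a closed contour
#'
#' Positive signed shoelace area; errors on self-intersecting contours.
#'
#' @param c a `contour_state`.
#' @return area in um^2.
#' @export
enclosed_area <- function(c) {
  stopifnot(inherits(c, "contour_state"))
  if (cpp_self_intersects(c$x, c$y)) stop("contour self-intersects")
  enclosed_area_xy(c$x, c$y)
}

# Periodic cubic-spline interpolation of a closed curve at new arclength
# positions (parameterised by cumulative chord length).
spline_closed <- function(x, y, s_new) {
  n <- length(x)
  elen <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  s <- c(0, cumsum(elen))
  xs <- stats::spline(s, c(x, x[1]), method = "periodic", xout = s_new)$y
  ys <- stats::spline(s, c(y, y[1]), method = "periodic", xout = s_new)$y
  list(x = xs, y = ys, L = s[n + 1], s = s[seq_len(n)])
}

#' Re-discretize a closed contour into equally spaced nodes
#'
#' Fits a periodic cubic spline through the nodes (chord-length
#' parameterisation, iterated once so spacing is uniform in the updated
#' chord length) and transfers the protein density conservatively with
#' [transfer_density()].
#'
#' @param c a `contour_state`.
#' @param N number of nodes of the resampled contour (default: unchanged).
#' @return a `contour_state` with (numerically) uniform node spacing and the
#'   same total protein mass.
#' @export
resample_contour <- function(c, N = length(c$x)) {
  stopifnot(inherits(c, "contour_state"))
  n_old <- length(c$x)
  # pass 1: uniform in old chord length
  sp <- spline_closed(c$x, c$y, seq(0, sp_L <- sum(sqrt(diff(c(c$x, c$x[1]))^2 +
    diff(c(c$y, c$y[1]))^2)), length.out = N + 1)[-(N + 1)])
  # pass 2: re-parameterise by the new chord length for near-exact uniformity
  sp2 <- spline_closed(sp$x, sp$y, seq(0, sum(sqrt(diff(c(sp$x, sp$x[1]))^2 +
    diff(c(sp$y, sp$y[1]))^2)), length.out = N + 1)[-(N + 1)])
  new <- list(x = sp2$x, y = sp2$y)
  phi_new <- transfer_density(c, new)
  out <- list(x = sp2$x, y = sp2$y, phi = phi_new, t = c$t,
              A_pref = c$A_pref, L_init = c$L_init, M_total = c$M_total)
  class(out) <- "contour_state"
  if (cpp_self_intersects(out$x, out$y))
    stop("contour self-intersects after resampling")
  out
}

#' Transfer protein density between discretizations of the same curve
#'
#' Piecewise-linear interpolation in (periodic) arclength followed by a
#' single global rescale so the total protein mass sum(phi * ds) is exactly
#' preserved.  If the rescale would push a node above saturation the excess
#' is clipped and redistributed (with a warning).
#'
#' @param old a `contour_state` (carrying `phi`).
#' @param new a list or `contour_state` with fields `x`, `y` on the same
#'   curve.
#' @return the new per-node phi vector.
#' @export
transfer_density <- function(old, new) {
  g_old <- cpp_geom_round(old$x, old$y)
  g_new <- cpp_geom_round(new$x, new$y)
  n_old <- length(old$x); n_new <- length(new$x)
  s_old <- c(0, cumsum(g_old$elen))[seq_len(n_old)]
  # locate new nodes on the old arclength coordinate via nearest projection:
  # both node sets parameterise the same curve, so cumulative arclength from
  # the shared starting point is the common coordinate.
  elen_new <- g_new$elen
  s_new <- c(0, cumsum(elen_new))[seq_len(n_new)]
  s_new <- s_new * (sum(g_old$elen) / sum(elen_new))  # same total length
  # anchor: new node 1 sits at the old curve point closest to it
  d0 <- sqrt((old$x - new$x[1])^2 + (old$y - new$y[1])^2)
  i0 <- which.min(d0)
  s_new <- (s_new + s_old[i0]) %% sum(g_old$elen)
  Lp <- sum(g_old$elen)
  phi_new <- stats::approx(x = c(s_old, Lp), y = c(old$phi, old$phi[1]),
                           xout = s_new, rule = 2)$y
  M_old <- sum(old$phi * g_old$ds)
  M_new <- sum(phi_new * g_new$ds)
  phi_new <- phi_new * (M_old / M_new)
  if (any(phi_new > 1)) {
    warning("density transfer near saturation: clipping and redistributing")
    for (k in 1:20) {
      over <- phi_new > 1
      if (!any(over)) break
      excess <- sum((phi_new[over] - 1) * g_new$ds[over])
      phi_new[over] <- 1
      room <- !over
      phi_new[room] <- phi_new[room] + excess / sum(g_new$ds[room])
    }
  }
  phi_new
}
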