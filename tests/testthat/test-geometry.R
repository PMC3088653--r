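# Discrete differential geometry: curvature convention, areas,
# resampling and conservative density transfer.

circle_state <- function(R = 3, N = 128, phi = 0.1) {
  th <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
  st <- list(x = R * cos(th), y = R * sin(th), phi = rep(phi, N), t = 0,
             A_pref = pi * R^2, L_init = 2 * pi * R,
             M_total = phi * 2 * pi * R)
  class(st) <- "contour_state"
  st
}

test_that("closed-contour curvature matches analytic values and converges", {
  # convention: ccw circle of radius R has H = -1/R at every node
  cc <- circle_state(R = 3, N = 128)
  expect_equal(curvature_closed(cc), rep(-1 / 3, 128), tolerance = 1e-12)

  # second-order convergence on an ellipse (refining halves the error)
  ellipse <- function(N, a = 2, b = 1) {
    t <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
    st <- list(x = a * cos(t), y = b * sin(t), phi = rep(0.1, N), t = 0,
               A_pref = pi * a * b, L_init = 1, M_total = 1)
    class(st) <- "contour_state"
    list(st = st, t = t, exact = -a * b /
           (a^2 * sin(t)^2 + b^2 * cos(t)^2)^1.5)
  }
  e1 <- ellipse(64); e2 <- ellipse(128)
  err1 <- max(abs(curvature_closed(e1$st) - e1$exact))
  err2 <- max(abs(curvature_closed(e2$st) - e2$exact))
  expect_gt(err1 / err2, 3)
  # curvature at the tip (a, 0) of the a=2, b=1 ellipse is -a/b^2 = -2
  expect_equal(curvature_closed(e2$st)[1], -2, tolerance = 5e-3)
})

test_that("linearized flat curvature is the periodic second difference", {
  p <- default_pars()
  st <- init_flat(p, N = 128, L = 10, spec = init_spec(noise_amplitude = 0))
  expect_identical(curvature_flat_linearized(st), rep(0, 128))
  q <- 2 * pi * 3 / 10
  st$h <- 0.01 * cos(q * st$x)
  H <- curvature_flat_linearized(st)
  expect_equal(H, -0.01 * q^2 * cos(q * st$x), tolerance = 2e-3)
  # halving dx drops the error ~4x (second order)
  st2 <- init_flat(p, N = 256, L = 10, spec = init_spec(noise_amplitude = 0))
  st2$h <- 0.01 * cos(q * st2$x)
  err1 <- max(abs(H + 0.01 * q^2 * cos(q * st$x)))
  err2 <- max(abs(curvature_flat_linearized(st2) +
                    0.01 * q^2 * cos(q * st2$x)))
  expect_gt(err1 / err2, 3.5)
})

test_that("flat and closed curvature conventions agree on a shallow bump", {
  # a big circle unrolled: same sign and magnitude within 2%
  p <- default_pars()
  R <- 200; N <- 4096
  th <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
  amp <- 0.05; m <- 64
  r <- R + amp * cos(m * th)
  ct <- list(x = r * cos(th), y = r * sin(th), phi = rep(0.1, N), t = 0,
             A_pref = pi * R^2, L_init = 2 * pi * R, M_total = 1)
  class(ct) <- "contour_state"
  Hround <- curvature_closed(ct)[1] - (-1 / R)  # subtract base curvature
  L <- 2 * pi * R
  fl <- init_flat(p, N = N, L = L, spec = init_spec(noise_amplitude = 0))
  fl$h <- amp * cos(2 * pi * m * fl$x / L)
  Hflat <- curvature_flat_linearized(fl)[1]
  expect_equal(sign(Hround), sign(Hflat))
  expect_equal(Hround, Hflat, tolerance = 0.02)
})

test_that("enclosed area: shoelace against a triangulation oracle", {
  cc <- circle_state(R = 3, N = 512)
  expect_equal(enclosed_area(cc), 9 * pi, tolerance = 1e-3)
  sq <- list(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), phi = rep(.1, 4), t = 0,
             A_pref = 1, L_init = 4, M_total = 0.4)
  class(sq) <- "contour_state"
  expect_identical(enclosed_area(sq), 1.0)
  # random star-shaped polygon vs fan-triangulation oracle
  set.seed(11)
  th <- sort(stats::runif(40, 0, 2 * pi))
  r <- stats::runif(40, 1, 2)
  poly <- list(x = r * cos(th), y = r * sin(th), phi = rep(.1, 40), t = 0,
               A_pref = 1, L_init = 1, M_total = 1)
  class(poly) <- "contour_state"
  tri <- sum(vapply(seq_along(th), function(i) {
    j <- if (i == length(th)) 1 else i + 1
    0.5 * (poly$x[i] * poly$y[j] - poly$x[j] * poly$y[i])
  }, numeric(1)))
  expect_equal(enclosed_area(poly), tri, tolerance = 1e-12)
  # self-intersecting contour is a hard error
  bow <- list(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0), phi = rep(.1, 4), t = 0,
              A_pref = 1, L_init = 1, M_total = 1)
  class(bow) <- "contour_state"
  expect_error(enclosed_area(bow), "self-intersect")
})

test_that("resampling gives uniform spacing and preserves shape and mass", {
  # clustered nodes on a circle
  R <- 3; N <- 128
  u <- seq(0, 1, length.out = N + 1)[-(N + 1)]
  th <- 2 * pi * (u + 0.08 * sin(2 * pi * u))  # non-uniform parameterisation
  st <- list(x = R * cos(th), y = R * sin(th),
             phi = 0.1 + 0.03 * cos(th), t = 0, A_pref = pi * R^2,
             L_init = 2 * pi * R, M_total = NA)
  class(st) <- "contour_state"
  st$M_total <- total_mass(st)
  rs <- resample_contour(st)
  g <- state_geometry(rs)
  expect_lt(max(g$elen) / min(g$elen), 1 + 1e-6)
  expect_equal(sqrt(rs$x^2 + rs$y^2), rep(R, N), tolerance = 1e-6)
  expect_equal(total_mass(rs), total_mass(st), tolerance = 1e-12)
  # idempotence on an already-uniform circle
  cc <- circle_state(R = 3, N = 128)
  rs2 <- resample_contour(cc)
  expect_equal(rs2$x, cc$x, tolerance = 1e-10)
  expect_equal(rs2$y, cc$y, tolerance = 1e-10)
})

test_that("density transfer is conservative and second-order accurate", {
  R <- 3
  mk <- function(N) {
    th <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
    st <- list(x = R * cos(th), y = R * sin(th),
               phi = 0.1 + 0.05 * sin(3 * th), t = 0, A_pref = pi * R^2,
               L_init = 2 * pi * R, M_total = NA)
    class(st) <- "contour_state"
    st
  }
  for (N in c(64, 128)) {
    st <- mk(N)
    th2 <- seq(0, 2 * pi, length.out = 2 * N + 1)[-(2 * N + 1)]
    new <- list(x = R * cos(th2), y = R * sin(th2))
    phi2 <- transfer_density(st, new)
    g2 <- cellcontour:::cpp_geom_round(new$x, new$y)
    g1 <- state_geometry(st)
    expect_equal(sum(phi2 * g2$ds), sum(st$phi * g1$ds), tolerance = 1e-12)
    err <- max(abs(phi2 - (0.1 + 0.05 * sin(3 * th2))))
    if (N == 64) err64 <<- err else expect_gt(err64 / err, 3)
  }
  # uniform stays uniform
  st <- mk(96); st$phi <- rep(0.2, 96)
  th2 <- seq(0, 2 * pi, length.out = 61)[-61]
  phi2 <- transfer_density(st, list(x = R * cos(th2), y = R * sin(th2)))
  expect_equal(diff(range(phi2)), 0, tolerance = 1e-9)
})

test_that("mass is conserved through chains of resample/transfer", {
  set.seed(3)
  st <- smooth_contour(N = 96)
  M0 <- total_mass(st)
  for (k in 1:10) st <- resample_contour(st, N = sample(c(80, 96, 120), 1))
  expect_lt(abs(total_mass(st) / M0 - 1), 1e-10)
})
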