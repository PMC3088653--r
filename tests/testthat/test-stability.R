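# Linear stability: dispersion branches, classification, critical
# boundaries, the round equilibrium, and consistency with the nonlinear
# simulator.

test_that("flat dispersion: passive membranes are stable, one branch always
           damped", {
  p <- default_pars(A_actin = 0, alpha_adh = 0)
  q <- default_q_grid(L = 20)
  d <- dispersion_flat(q, p)
  expect_true(all(d$omega_plus <= 0))
  # the lower branch stays negative for all q > 0 across parameter sets
  for (pars in list(default_pars(alpha_adh = 3000),
                    default_pars(A_actin = 3000),
                    default_pars(alpha_adh = 2000, A_actin = 1000),
                    default_pars(J_bind = 100))) {
    expect_true(all(dispersion_flat(q, pars)$omega_minus < 0))
  }
})

test_that("round dispersion: translation mode is neutral, passive modes
           damped", {
  p <- default_pars(alpha_adh = 2100)
  d <- dispersion_round(0:8, p)
  expect_lt(abs(d$omega_plus[d$q == 1]), 1e-6)   # m = 1: translation
  p0 <- default_pars()
  d0 <- dispersion_round(2:10, p0)
  expect_true(all(d0$omega_plus < 0))            # passive: m >= 2 damped
  expect_error(dispersion_round(1.5, p), "integer")
})

test_that("round dispersion approaches the flat one for large cells", {
  p <- default_pars(alpha_adh = 2100, gamma = 0, R0 = 300,
                    K_area = 2e5)
  eq <- equilibrium_round_state(p)
  mu <- most_unstable_mode(p)
  m <- round(mu$q_max * eq$R_eq)
  dr <- dispersion_round(m, p, eq)
  df <- dispersion_flat(m / eq$R_eq, p)
  expect_equal(dr$omega_plus, df$omega_plus, tolerance = 0.02)
})

test_that("regime classification: stable / type II / type I", {
  expect_equal(classify_regime(default_pars())$regime, "stable")
  ac <- critical_boundary(default_pars(), "alpha")$value
  cl2 <- classify_regime(default_pars(alpha_adh = 1.05 * ac))
  expect_equal(cl2$regime, "typeII")
  expect_gt(cl2$unstable_band[1], 0)
  # strong direct aggregation destabilises arbitrarily long wavelengths
  p1 <- default_pars(J_bind = 1300)
  cl1 <- classify_regime(p1)
  expect_equal(cl1$regime, "typeI")
  expect_equal(cl1$unstable_band[1], 0)
})

test_that("critical boundary: root property, bracketing, grid-scan oracle", {
  p <- default_pars()
  qg <- default_q_grid()
  cb <- critical_boundary(p, "alpha")
  g <- function(a) {
    p2 <- p; p2$alpha_adh <- a
    max(dispersion_flat(qg, p2)$omega_plus)
  }
  expect_lt(abs(g(cb$value)), 1e-4)            # marginal growth at the root
  expect_gt(g(1.01 * cb$value), 0)
  expect_lt(g(0.99 * cb$value), 0)
  # independent dense-grid oracle: zero crossing of max growth vs alpha
  agrid <- seq(0.9 * cb$value, 1.1 * cb$value, length.out = 200)
  gs <- vapply(agrid, g, numeric(1))
  cross <- agrid[which(gs > 0)[1]]
  expect_equal(cross, cb$value, tolerance = 2e-3)
  # no sign change in a stable bracket is an error
  expect_error(critical_boundary(p, "alpha", lower = 0,
                                 upper = 0.5 * cb$value), "sign change")
})

test_that("marginal wavevector shifts monotonically along the critical
           line", {
  p <- default_pars()
  A_vals <- seq(0, 1200, length.out = 5)
  qc <- vapply(A_vals, function(A) {
    p2 <- p; p2$A_actin <- A
    critical_boundary(p2, "alpha")$q_c
  }, numeric(1))
  # as actin driving increases (adhesion at onset decreases), q_c moves
  # monotonically
  expect_true(all(diff(qc) > 0) || all(diff(qc) < 0))
})

test_that("most unstable mode: local maximum and golden-section refinement", {
  p <- default_pars(alpha_adh = 2500)
  mu <- most_unstable_mode(p)
  for (d in c(-0.02, 0.02)) {
    expect_gte(mu$omega_max,
               dispersion_flat(mu$q_max * (1 + d), p)$omega_plus)
  }
  expect_equal(mu$lambda_max, 2 * pi / mu$q_max)
  expect_error(most_unstable_mode(default_pars()), "stable")
})

test_that("round equilibrium: scan oracle and passive large-K limit", {
  p <- default_pars(alpha_adh = 1800)
  eq <- equilibrium_round_state(p)
  expect_lt(abs(eq$f_residual), 1e-9)
  # brute-force 1-D scan of the net uniform force crosses zero at R_eq
  fnet <- function(R) {
    phi0 <- p$phi_bar * 2 * pi * p$R0 / (2 * pi * R)
    H0 <- -1 / R; c0 <- H0 - p$Hbar * phi0
    -p$kappa * H0^2 * c0 + 0.5 * p$kappa * c0^2 * H0 +
      (p$lam - p$alpha_adh * phi0) * H0 + p$A_actin * phi0 -
      p$K_area * (pi * R^2 - pi * p$R0^2) / (pi * p$R0^2)
  }
  Rg <- seq(2, 4, by = 1e-4)
  fg <- vapply(Rg, fnet, numeric(1))
  i <- which(fg[-1] * fg[-length(fg)] <= 0)[1]
  expect_equal(eq$R_eq, Rg[i], tolerance = 1e-4)
  # passive, very stiff area constraint: R_eq -> R0
  pk <- default_pars(K_area = 1e6)
  expect_equal(equilibrium_round_state(pk)$R_eq, pk$R0, tolerance = 1e-2)
})

test_that("sign of the predicted growth agrees with the simulator", {
  # for parameter sets straddling the critical line, seed the least-damped
  # (or fastest-growing) grid mode with its linear eigenvector -- so the
  # amplitude tracks a single branch, without transient cross-coupling
  # growth -- and compare the sign of its evolution over 60 s with the
  # dispersion prediction
  p0 <- default_pars()
  ac <- critical_boundary(p0, "alpha")$value
  Ac <- critical_boundary(p0, "A")$value
  cases <- list(
    default_pars(alpha_adh = 0.9 * ac),
    default_pars(alpha_adh = 1.25 * ac),
    default_pars(A_actin = 0.9 * Ac),
    default_pars(A_actin = 1.25 * Ac),
    default_pars(alpha_adh = 0.7 * ac, A_actin = 0.7 * Ac))
  L <- 10; N <- 64
  qs <- 2 * pi * (1:10) / L
  for (p in cases) {
    d <- dispersion_flat(qs, p)
    k <- which.max(d$omega_plus)
    q <- qs[k]; om <- d$omega_plus[k]
    m11 <- -(p$kappa * q^4 +
               (p$lam - p$alpha_adh * p$phi_bar +
                  0.5 * p$kappa * (p$Hbar * p$phi_bar)^2) * q^2 + p$gamma) /
      p$xi
    m12 <- (-p$kappa * p$Hbar * q^2 + p$A_actin) / p$xi
    vh <- m12; vp <- om - m11
    sc <- 1e-4 / max(abs(vh), abs(vp))
    st <- init_flat(p, N = N, L = L, spec = init_spec(noise_amplitude = 0))
    st$h <- sc * vh * cos(q * st$x)
    st$phi <- st$phi + sc * vp * cos(q * st$x)
    a0 <- max(abs(st$h - mean(st$h)))
    dt <- stable_dt_bound(st, p, 0.35)
    r <- cellcontour:::cpp_run_flat(st$h, st$phi, st$dx, unclass(p),
                                    st$L_init, dt,
                                    as.integer(ceiling(60 / dt)))
    a1 <- max(abs(r$h - mean(r$h)))
    expect_identical(a1 > a0, om > 0)
  }
})
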