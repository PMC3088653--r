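# Free energy and normal forces.  The central check is variational: each
# conservative force must equal the central-difference variation of its
# free-energy term (the defining property), on smooth non-trivial states.

test_that("free energy closed form, switch-offs and scaling", {
  p <- default_pars(A_actin = 0, alpha_adh = 0, gamma = 0)
  L <- 10; N <- 64
  st <- init_flat(p, N = N, L = L, spec = init_spec(noise_amplitude = 0))
  # uniform flat state: hand-evaluated integrand x L x w
  phb <- p$phi_bar
  ent <- p$temperature * p$n_s * (phb * log(phb) + (1 - phb) * log(1 - phb))
  expected <- L * p$w * (p$kappa / 2 * (p$Hbar * phb)^2 + ent -
                           p$J_bind * p$n_s / 2 * phb^2)
  expect_equal(free_energy(st, p), expected, tolerance = 1e-12)
  # curvature term vanishes under perfect mismatch H = Hbar phi (circle
  # with the matching uniform coverage)
  ct <- init_round(p, N = 96, spec = init_spec(noise_amplitude = 0))
  R <- sqrt(ct$x[1]^2 + ct$y[1]^2)
  ct$phi[] <- (-1 / R) / p$Hbar
  expect_lt(abs(free_energy(ct, p, parts = TRUE)$curvature), 1e-10)
  # energy is linear in the strip thickness w
  p2 <- p; p2$w <- 2 * p$w
  expect_equal(free_energy(st, p2), 2 * free_energy(st, p), tolerance = 1e-12)
  # clamped-entropy warning at the saturation boundary
  st3 <- st; st3$phi[1] <- 1
  expect_warning(free_energy(st3, p), "clamped")
})

test_that("variational oracle: flat forces match -dF/dh per term", {
  p <- default_pars(alpha_adh = 500, A_actin = 300, J_bind = 20)
  st <- smooth_flat(p)
  idx <- seq(1, 64, by = 5)
  cases <- list(
    list(terms = "curvature", f = force_curvature(st, p)),
    list(terms = c("tension", "adhesion"), f = force_tension(st, p)),
    list(terms = "spring", f = force_spring(st, p)),
    list(terms = "agg_grad", f = force_aggregation(st, p)))
  for (cs in cases) {
    num <- vapply(idx, function(i) numeric_force(st, p, cs$terms, i),
                  numeric(1))
    expect_lt(max(abs(num - cs$f[idx])), 1e-3 * max(abs(cs$f)))
  }
})

test_that("variational oracle: round forces match -dF/d(normal) per term", {
  p <- default_pars(alpha_adh = 500)
  for (seed in 1:3) {
    set.seed(seed)
    ct <- smooth_contour(p, N = 96,
                         r_amp = stats::runif(2, 0.01, 0.06),
                         phi_amp = stats::runif(2, 0.005, 0.03))
    idx <- seq(1, 96, by = 9)
    cases <- list(
      list(terms = "curvature", f = force_curvature(ct, p)),
      list(terms = c("tension", "adhesion"), f = force_tension(ct, p)),
      list(terms = "agg_grad", f = force_aggregation(ct, p)))
    for (cs in cases) {
      num <- vapply(idx, function(i) numeric_force(ct, p, cs$terms, i),
                    numeric(1))
      expect_lt(max(abs(num - cs$f[idx])), 1e-3 * max(abs(cs$f)))
    }
  }
})

test_that("curvature force: restoring on a seeded mode, uniform on circles", {
  p <- default_pars(J_bind = 0, alpha_adh = 0, A_actin = 0)
  L <- 10; N <- 128
  st <- init_flat(p, N = N, L = L, spec = init_spec(noise_amplitude = 0))
  expect_equal(diff(range(force_curvature(st, p))), 0, tolerance = 1e-12)
  q <- 2 * pi * 4 / L
  eps <- 1e-4
  st$h <- eps * cos(q * st$x)
  fc <- force_curvature(st, p)
  # leading order: -(kappa q^4 + (kappa/2) (Hbar phi_bar)^2 q^2) eps cos(qx),
  # the second piece being the metric coupling of the uniform mismatch
  coef <- p$kappa * q^4 + 0.5 * p$kappa * (p$Hbar * p$phi_bar)^2 * q^2
  expect_lt(max(abs(fc + coef * eps * cos(q * st$x))), 0.02 * coef * eps)
  ct <- init_round(p, N = 128, spec = init_spec(noise_amplitude = 0))
  expect_lt(diff(range(force_curvature(ct, p))),
            1e-10 * max(abs(force_curvature(ct, p))))
})

test_that("effective tension: limits and local negativity under adhesion", {
  p <- default_pars(lam_nl = 1)
  st <- init_flat(p, N = 64, L = 10, spec = init_spec(noise_amplitude = 0))
  # L = L0, phi = 0 -> bare tension exactly
  st0 <- st; st0$phi[] <- 0
  expect_equal(effective_tension(st0, p), rep(p$lam, 64), tolerance = 1e-14)
  # lam_nl = 0: independent of L
  p0 <- default_pars(lam_nl = 0)
  st2 <- st; st2$h <- 0.5 * sin(2 * pi * st2$x / 10)
  expect_equal(unique(effective_tension(st2, p0) + p0$alpha_adh * st2$phi),
               p0$lam)
  # extension raises the tension when lam_nl > 0
  expect_gt(effective_tension(st2, p)[1], p$lam)
  # strong adhesion at high coverage: locally negative effective tension
  p3 <- default_pars(alpha_adh = 900)
  st3 <- st; st3$phi[5] <- 0.2
  expect_lt(effective_tension(st3, p3)[5], 0)
  expect_gt(effective_tension(st3, p3)[1], 0)
})

test_that("tension force: zero on flat, lam/R inward on circles", {
  p <- default_pars(alpha_adh = 0, lam_nl = 0, J_bind = 0)
  st <- init_flat(p, N = 64, L = 10, spec = init_spec(noise_amplitude = 0))
  expect_equal(force_tension(st, p), rep(0, 64), tolerance = 1e-14)
  R <- 3; N <- 128
  th <- seq(0, 2 * pi, length.out = N + 1)[-(N + 1)]
  cc <- list(x = R * cos(th), y = R * sin(th), phi = rep(0.1, N), t = 0,
             A_pref = pi * R^2, L_init = 2 * pi * R * sin(pi / N) * N / pi *
               0.5 * 2, M_total = 1)
  cc$L_init <- N * 2 * R * sin(pi / N)  # discrete circumference (L = L0)
  class(cc) <- "contour_state"
  ft <- force_tension(cc, p)
  expect_lt(max(abs(ft + p$lam / R)), 2e-3 * p$lam / R)
})

test_that("spring force: linear restoring, flat geometry only", {
  p <- default_pars()
  st <- smooth_flat(p)
  expect_equal(force_spring(st, p), -p$gamma * st$h)
  st2 <- st; st2$h <- 2 * st$h
  expect_equal(force_spring(st2, p), 2 * force_spring(st, p))
  ct <- smooth_contour(p)
  expect_error(force_spring(ct, p), "flat")
})

test_that("aggregation force: switch-offs", {
  st <- smooth_flat()
  p0 <- default_pars(J_bind = 0)
  expect_equal(force_aggregation(st, p0), rep(0, 64))
  p <- default_pars()
  stu <- st; stu$phi[] <- 0.1
  expect_equal(force_aggregation(stu, p), rep(0, 64))
})

test_that("actin force: linear in phi, mean-subtracted only when flat", {
  p <- default_pars(A_actin = 500)
  st <- init_flat(p, N = 64, L = 10, spec = init_spec(noise_amplitude = 0))
  expect_equal(force_actin(st, p), rep(0, 64), tolerance = 1e-13)
  st$phi[] <- 0
  expect_equal(force_actin(st, p), rep(0, 64))
  ct <- init_round(p, N = 96, spec = init_spec(noise_amplitude = 0))
  fa <- force_actin(ct, p)
  expect_equal(fa, p$A_actin * ct$phi)  # no mean subtraction
  g <- state_geometry(ct)
  # uniform circle: outward force with zero vector sum by symmetry
  expect_lt(abs(sum(fa * g$nx * g$ds)), 1e-9 * sum(abs(fa) * g$ds))
})

test_that("area pressure: sign, zero point and linear slope", {
  p <- default_pars()
  ct <- init_round(p, N = 96, spec = init_spec(noise_amplitude = 0))
  ct$A_pref <- enclosed_area(ct)
  expect_lt(max(abs(force_area_pressure(ct, p))), 1e-9)
  grow <- ct; grow$x <- 1.1 * ct$x; grow$y <- 1.1 * ct$y
  expect_true(all(force_area_pressure(grow, p) < 0))     # inward
  # slope K/A_pref in the enclosed-area deviation
  a1 <- enclosed_area(grow) - ct$A_pref
  expect_equal(force_area_pressure(grow, p)[1],
               -p$K_area * a1 / ct$A_pref, tolerance = 1e-12)
  st <- smooth_flat(p)
  expect_error(force_area_pressure(st, p), "round")
})

test_that("assembled normal velocity: equilibria, components, friction", {
  p <- default_pars()
  st <- init_flat(p, N = 64, L = 10, spec = init_spec(noise_amplitude = 0))
  out <- assemble_normal_velocity(st, p)
  expect_equal(out$vn, rep(0, 64), tolerance = 1e-13)
  expect_equal(out$breakdown$f_total,
               with(out$breakdown, f_curv + f_tension + f_spring + f_agg +
                      f_actin + f_area))
  ct <- init_round(p, N = 128, spec = init_spec(noise_amplitude = 0))
  expect_lt(max(abs(assemble_normal_velocity(ct, p)$vn)), 1e-9)
  # doubling the friction halves the velocity pointwise
  st2 <- smooth_flat(p)
  p2 <- p; p2$xi <- 2 * p$xi
  expect_equal(assemble_normal_velocity(st2, p2)$vn,
               assemble_normal_velocity(st2, p)$vn / 2, tolerance = 1e-12)
})
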