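# Deterministic smooth test states used across test files.

default_pars <- function(...) {
  p <- model_params()
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  validate_params(p)
}

# flat state with smooth non-trivial h and phi fields
smooth_flat <- function(p = default_pars(), N = 64, L = 10,
                        h_amp = c(0.3, 0.1, 0.05),
                        phi_amp = c(0.03, 0.01)) {
  st <- init_flat(p, N = N, L = L, spec = init_spec(noise_amplitude = 0))
  x <- st$x
  st$h <- h_amp[1] * sin(2 * pi * x / L) + h_amp[2] * cos(6 * pi * x / L) +
    h_amp[3] * sin(10 * pi * x / L)
  st$phi <- p$phi_bar + phi_amp[1] * cos(4 * pi * x / L) +
    phi_amp[2] * sin(2 * pi * x / L)
  st
}

# closed contour: perturbed circle with smooth phi
smooth_contour <- function(p = default_pars(), N = 96,
                           r_amp = c(0.05, 0.02), phi_amp = c(0.03, 0.015)) {
  ct <- init_round(p, N = N, spec = init_spec(noise_amplitude = 0))
  th <- atan2(ct$y, ct$x)
  r0 <- sqrt(ct$x^2 + ct$y^2)
  r <- r0 * (1 + r_amp[1] * cos(3 * th) + r_amp[2] * sin(5 * th))
  ct$x <- r * cos(th)
  ct$y <- r * sin(th)
  ct$phi <- p$phi_bar + phi_amp[1] * cos(2 * th) + phi_amp[2] * sin(4 * th)
  ct
}

# central-difference variation of selected free-energy terms under a
# displacement of node i (flat: along h; round: along the outward normal)
numeric_force <- function(state, p, terms, i, d = 1e-6) {
  if (inherits(state, "flat_state")) {
    s1 <- state; s1$h[i] <- s1$h[i] + d
    s2 <- state; s2$h[i] <- s2$h[i] - d
    denom <- p$w * state$dx
  } else {
    g <- state_geometry(state)
    s1 <- state
    s1$x[i] <- s1$x[i] + d * g$nx[i]; s1$y[i] <- s1$y[i] + d * g$ny[i]
    s2 <- state
    s2$x[i] <- s2$x[i] - d * g$nx[i]; s2$y[i] <- s2$y[i] - d * g$ny[i]
    denom <- p$w * g$ds[i]
  }
  e1 <- free_energy(s1, p, parts = TRUE)
  e2 <- free_energy(s2, p, parts = TRUE)
  -(sum(unlist(e1[terms])) - sum(unlist(e2[terms]))) / (2 * d) / denom
}

total_mass <- function(state) {
  g <- state_geometry(state)
  sum(state$phi * g$ds)
}
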