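# Shared parameter sets and small oracles used across the suite.

# reduced two-oscillator reference parameters (pairwise gain convention)
two_osc_ref <- function(kappa = 30) {
  two_oscillator_params(omega0 = 1, g = 0.75, kappa = kappa, tau0 = 0.1,
                        alpha_tau = 1, eps = 0.01)
}

# all-to-all N-limit reference parameters (g/N convention)
meanfield_ref <- function(kappa = 80, alpha_tau = 1) {
  model_params(omega0 = 1, g = 1.5, kappa = kappa, tau0 = 0.1,
               alpha_tau = alpha_tau, eps = 0.01)
}

# injury reference parameters: long baseline lag destabilizes the
# fixed-delay network as coupling weakens (cos(omega0 * tau0) < 0)
injury_ref <- function(kappa = 80) {
  model_params(omega0 = 1, g = 1.5, kappa = kappa, tau0 = 2.0,
               alpha_tau = 1, eps = 0.01)
}

# closed-form phase-difference solution of the classical two-oscillator
# Kuramoto model (no delays): dDelta/dt = -2 g sin(Delta)
kuramoto_delta_closed_form <- function(t, Delta0, g) {
  2 * atan(tan(Delta0 / 2) * exp(-2 * g * t))
}

# independent quasi-polynomial root oracle: replace e^(-lambda*tau) by its
# Taylor series (converges fast for the small delays used in tests) and
# solve the resulting high-degree polynomial exactly with polyroot()
taylor_quasipoly_roots <- function(P, Q, tau, order = 30, box = 3) {
  tay <- (-tau)^(0:order) / factorial(0:order)
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a))
      out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
    out
  }
  padd <- function(a, b) {
    n <- max(length(a), length(b))
    c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
  }
  r <- polyroot(padd(P, conv(Q, tay)))
  # keep roots well inside the Taylor accuracy region
  r[abs(Re(r)) < box & abs(Im(r)) < box]
}

# damped fixed-point oracle for Omega = omega0 + geff * sin(-Omega * tau0)
fixed_point_frequency <- function(omega0, geff, tau0, start, damp = 0.2,
                                  iter = 5000) {
  Om <- start
  for (i in seq_len(iter))
    Om <- Om + damp * (omega0 + geff * sin(-Om * tau0) - Om)
  Om
}

# lazily computed, cached level curve + on-curve stability for the
# mean-field reference parameters (shared by several blocks)
meanfield_curve_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pm <- meanfield_ref()
      dg <- seq(0.02, 0.3, by = 0.005)
      curve <- solve_level_curve(dg, pm)
      curve$E <- vapply(seq_len(nrow(curve)), function(i)
        stability_E(curve$Omega[i], curve$delta[i], pm)$E, numeric(1))
      cache <<- curve
    }
    cache
  }
})
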