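test_that("smooth Heaviside matches the hard cutoff outside [0, eps]", {
  expect_identical(smooth_heaviside(-0.5, 0.01), 0)
  expect_identical(smooth_heaviside(0, 0.01), 0)
  expect_identical(smooth_heaviside(0.02, 0.01), 1)
  expect_identical(smooth_heaviside(0.01, 0.01), 1)
  expect_equal(smooth_heaviside(0.005, 0.01), 0.5)
  x <- seq(-0.02, 0.03, by = 1e-4)
  h <- smooth_heaviside(x, 0.01)
  expect_true(all(h >= 0 & h <= 1))
  expect_true(all(diff(h) >= 0))               # monotone
  expect_lt(max(abs(diff(h))), 2e-2)           # no jumps (C1 ramp)
  expect_error(smooth_heaviside(0.1, 0), "positive")
  expect_error(smooth_heaviside(0.1, -1), "positive")
})

test_that("phase velocities follow the delayed Kuramoto rule and stay bounded", {
  # single uncoupled oscillator runs at its natural frequency
  p1 <- model_params(omega0 = 0.7, g = 1)
  t1 <- topology(matrix(0L, 1, 1))
  expect_equal(phase_rhs(0.3, matrix(0, 1, 1), p1, t1), 0.7)

  # in-phase, zero lag: every oscillator at omega0
  p2 <- model_params(omega0 = 1, g = 1.5, tau0 = 0)
  expect_equal(phase_rhs(c(0.2, 0.2), matrix(0.2, 2, 2), p2,
                         two_oscillator_topology()),
               c(1, 1))

  # reduced two-oscillator form: pairwise gain 0.75 = global gain 1.5 at N=2
  thd <- matrix(NA_real_, 2, 2)
  thd[1, 2] <- 0.4; thd[2, 1] <- -0.1
  thd[is.na(thd)] <- 0
  expect_equal(phase_rhs(c(0, 0.5), thd, p2, two_oscillator_topology()),
               c(1 + 0.75 * sin(0.4), 1 + 0.75 * sin(-0.6)))

  # sine bound for random inputs
  set.seed(42)
  pn <- model_params(omega0 = 1.3, g = 2.2)
  tn <- dense_topology(6)
  for (k in 1:20) {
    v <- phase_rhs(runif(6, -10, 10), matrix(runif(36, -10, 10), 6, 6),
                   pn, tn)
    expect_true(all(v >= 1.3 - 2.2 - 1e-12 & v <= 1.3 + 2.2 + 1e-12))
  }

  expect_error(phase_rhs(c(0, 0, 0), matrix(0, 2, 2), p2,
                         two_oscillator_topology()),
               "shape mismatch")
})

test_that("delay velocities vanish at equilibrium and respect the cutoff", {
  p <- model_params(omega0 = 1, g = 1, kappa = 30, tau0 = 0.1,
                    alpha_tau = 1, eps = 0.01)
  topo <- two_oscillator_topology()
  # at baseline with equal phases nothing moves
  expect_equal(delay_rhs(matrix(0.1, 2, 2), c(0.4, 0.4), p, topo),
               matrix(0, 2, 2))
  # drift term vanishes at tau = tau0 > eps; forcing is kappa at +pi/2
  v <- delay_rhs(matrix(0.1, 2, 2), c(0, pi / 2), p, topo)
  expect_equal(v[1, 2], 30)    # theta_j - theta_i = +pi/2
  expect_equal(v[2, 1], -30 * smooth_heaviside(0.1, 0.01))  # H = 1 here
  expect_equal(v[2, 1], -30)
  # Heaviside floor: zero delay cannot move
  expect_equal(delay_rhs(matrix(0, 2, 2), c(0, 2), p, topo),
               matrix(0, 2, 2))
  # absent connections are frozen
  expect_equal(delay_rhs(matrix(0.5, 2, 2), c(0, 2), p, topo)[1, 1], 0)
  expect_error(delay_rhs(matrix(-0.1, 2, 2), c(0, 0), p, topo),
               "invariant")
})

test_that("delay flow cannot escape the invariant region [0, tau0 + kappa]", {
  set.seed(7)
  topo <- dense_topology(3)
  for (k in 1:25) {
    p <- model_params(omega0 = 1, g = 1, kappa = runif(1, 0, 50),
                      tau0 = runif(1, 0.05, 2), alpha_tau = runif(1, 0.1, 2),
                      eps = 0.01)
    th <- runif(3, -pi, pi)
    # upper boundary: drift dominates, velocity must point inward
    up <- delay_rhs(matrix(p$tau0 + p$kappa, 3, 3), th, p, topo)
    expect_true(all(up <= 1e-12))
    # lower boundary: cutoff stops outflow
    lo <- delay_rhs(matrix(0, 3, 3), th, p, topo)
    expect_true(all(lo == 0))
  }
})

test_that("equilibrium delay is the clamped fixed point, 2*pi-periodic", {
  p <- model_params(omega0 = 1, g = 1, kappa = 30, tau0 = 0.1)
  expect_equal(equilibrium_delay(0, p), 0.1)
  expect_equal(equilibrium_delay(-pi / 2, p), 0)
  expect_equal(equilibrium_delay(pi / 6, p), 0.1 + 30 * 0.5)
  d <- seq(-2 * pi, 2 * pi, length.out = 400)
  expect_equal(equilibrium_delay(d, p), equilibrium_delay(d + 2 * pi, p))
  expect_lt(max(abs(diff(equilibrium_delay(d, p)))), 30 * 0.04)  # continuous
})

test_that("locked-state residuals vanish exactly at computed roots", {
  # kappa = 0: residual reduces to the scalar fixed-point relation
  p0 <- two_osc_ref(kappa = 0)
  Om0 <- as.numeric(find_sync_frequencies(p0))
  net0 <- model_params(1, 1.5, 0, 0.1, 1, 0.01)
  r0 <- global_frequency_residual(Om0, c(0, 0), net0,
                                  two_oscillator_topology())
  expect_lt(max(abs(r0)), 1e-9)

  # kappa = 30 root with its arcsine offset
  p <- two_osc_ref()
  Om <- as.numeric(find_sync_frequencies(p))[3]   # 0.6263 state
  D <- offset_from_frequency(Om, p)
  net <- model_params(1, 1.5, 30, 0.1, 1, 0.01)
  r <- global_frequency_residual(Om, c(0, D), net,
                                 two_oscillator_topology())
  expect_lt(max(abs(r)), 1e-8)

  # frequency outside the sine-bound interval can never balance
  rbad <- global_frequency_residual(1 + 1.5 + 0.2, c(0, D), net,
                                    two_oscillator_topology())
  expect_true(all(abs(rbad) > 0.1))
})

test_that("rotational symmetry puts the ones vector in the kernel at lambda = 0", {
  set.seed(11)
  pm <- meanfield_ref()
  for (k in 1:5) {
    phi <- runif(20, -0.4, 0.4)
    Om <- runif(1, 0.6, 1.2)
    topo <- dense_topology(20)
    expect_lt(max(Mod(mlambda_matrix(0, Om, phi, pm, topo) %*% rep(1, 20))),
              1e-12)
    a <- topo$adjacency; diag(a) <- 0L
    expect_lt(max(Mod(mlambda_matrix(0, Om, phi, pm, topology(a)) %*%
                        rep(1, 20))), 1e-12)
  }
})

test_that("parameter and topology validation reject bad inputs", {
  expect_error(model_params(g = 0), "positive")
  expect_error(model_params(kappa = -1), "non-negative")
  expect_error(model_params(alpha_tau = 0), "positive")
  expect_warning(model_params(tau0 = 0.005, eps = 0.01), "eps")
  expect_error(topology(matrix(c(0, 2, 1, 0), 2, 2)), "0 or 1")
  expect_error(topology(matrix(0, 2, 3)), "square")
  expect_error(topology(matrix(0L, 2, 2), gamma = 1.5), "0, 1")
})
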