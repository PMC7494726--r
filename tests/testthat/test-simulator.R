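test_that("slope-matched history equals the model right-hand side at 0-", {
  p <- two_osc_ref()
  net <- model_params(1, 1.5, 30, 0.1, 1, 0.01)
  topo <- two_oscillator_topology()

  # consistent slope: patch leaves the linear history untouched
  p00 <- model_params(1, 1.5, 30, 0, 1, 0.01)
  ic0 <- initial_condition(1, c(0, 0))
  h0 <- make_initial_function(ic0, p00, topo, dt_patch = 0.05)
  tg <- seq(-0.2, 0, by = 0.001)
  expect_equal(h0$fun(tg), outer(tg, c(1, 1)), tolerance = 1e-12)

  # reference trial: matched slope of oscillator 2 is the Eq-(18)-form rhs
  ic <- initial_condition(0.727, c(0, 0.860))
  h <- make_initial_function(ic, net, topo, dt_patch = 0.05)
  expect_equal(h$slope0[2], 1 + 0.75 * sin(-0.727 * 0.1 - 0.860))
  expect_equal(h$slope0[1], 1 + 0.75 * sin(-0.727 * 0.1 + 0.860))

  # patch endpoint values/slopes and global deviation bound
  expect_equal(h$fun(0)[1, ], c(0, 0.860))
  tg <- seq(-0.05, 0, by = 1e-4)
  dev <- abs(h$fun(tg) - outer(tg, c(0.727, 0.727)) -
               rep(c(0, 0.860), each = length(tg)))
  expect_lt(max(dev), max(abs(h$slope0 - 0.727)) * 0.05)
  # slope at 0- by one-sided difference
  num_slope <- (h$fun(0) - h$fun(-1e-6)) / 1e-6
  expect_equal(as.numeric(num_slope), h$slope0, tolerance = 1e-4)
})

test_that("zero-delay, non-plastic limit matches the classical closed form", {
  p <- two_oscillator_params(kappa = 0, tau0 = 0, alpha_tau = 1)
  tr <- simulate_two_oscillator(p, Omega0 = 1, Delta0 = 0.8,
                                cfg = sim_config(dt = 0.001, t_end = 5))
  D_num <- tr$theta[, 2] - tr$theta[, 1]
  D_exact <- kuramoto_delta_closed_form(tr$times, 0.8, 0.75)
  expect_lt(max(abs(D_num - D_exact)), 1e-4)
})

test_that("without plasticity the delays stay pinned at the baseline lag", {
  p <- two_oscillator_params(kappa = 0, tau0 = 0.25, alpha_tau = 1)
  tr <- simulate_two_oscillator(p, 0.9, 0.5,
                                cfg = sim_config(dt = 0.005, t_end = 10,
                                                 tau_stride = 20L))
  sel <- rep(as.vector(tr$topology$adjacency == 1L), dim(tr$tau)[3])
  expect_true(all(abs(tr$tau[sel] - 0.25) < 1e-12))
})

test_that("non-plastic asymptotic frequency agrees with the root analysis", {
  p <- two_osc_ref(kappa = 0)
  Om_theory <- as.numeric(find_sync_frequencies(p))
  expect_length(Om_theory, 1)
  tr <- simulate_two_oscillator(p, 0.9, 0.3,
                                cfg = sim_config(dt = 0.005, t_end = 60))
  est <- sync_estimate(tr, 10)
  expect_lt(abs(est$Omega_hat - Om_theory), 1e-3)
})

test_that("halving the step leaves the asymptotic frequency unchanged to 1e-4", {
  p <- two_osc_ref()
  om <- vapply(c(0.005, 0.0025), function(dt) {
    tr <- simulate_two_oscillator(p, 0.473, 0.402,
                                  cfg = sim_config(dt = dt, t_end = 120))
    sync_estimate(tr, 20)$Omega_hat
  }, numeric(1))
  expect_lt(abs(diff(om)), 1e-4)
})

test_that("trajectories honor the delay and velocity invariants", {
  set.seed(5)
  for (k in 1:4) {
    p <- model_params(omega0 = 1, g = runif(1, 0.5, 2),
                      kappa = runif(1, 0, 20), tau0 = runif(1, 0.05, 0.5),
                      alpha_tau = runif(1, 0.2, 1.5), eps = 0.01)
    topo <- dense_topology(4)
    ic <- initial_condition(runif(1, 0.5, 1.5),
                            runif(4, -1, 1))
    tr <- simulate_network(p, topo, ic,
                           sim_config(dt = 0.01, t_end = 15,
                                      tau_stride = 25L))
    expect_true(all(tr$tau >= 0))
    expect_true(all(tr$tau <= p$tau0 + p$kappa + 1e-9))
    expect_true(all(tr$dtheta >= p$omega0 - p$g - 1e-9 &
                      tr$dtheta <= p$omega0 + p$g + 1e-9))
  }
})

test_that("a global phase shift rotates offsets and leaves the frequency alone", {
  p <- meanfield_ref(kappa = 10)
  set.seed(2)
  phi0 <- runif(3, -0.5, 0.5)
  cfg <- sim_config(dt = 0.01, t_end = 40)
  topo <- dense_topology(3)
  e1 <- sync_estimate(simulate_network(p, topo,
                                       initial_condition(0.9, phi0), cfg), 10)
  shift <- 0.4
  e2 <- sync_estimate(simulate_network(p, topo,
                                       initial_condition(0.9, phi0 + shift),
                                       cfg), 10)
  expect_equal(e2$Omega_hat, e1$Omega_hat, tolerance = 1e-8)
  expect_equal(wrap_phase(e2$phi_hat - e1$phi_hat), rep(shift, 3),
               tolerance = 1e-6)
  expect_equal(e2$delta2_hat, e1$delta2_hat, tolerance = 1e-8)
})

test_that("mid-run injury severs connections and records the event", {
  p <- model_params(1, 1.5, 0, 0.1, 1, 0.01)
  topo <- dense_topology(6)
  ic <- initial_condition(1, rep(0, 6))
  # gamma = 0: nothing changes
  tr0 <- simulate_network(p, topo, ic, sim_config(dt = 0.01, t_end = 4),
                          injury = list(gamma = 0, t_inj = 2, seed = 1))
  expect_identical(tr0$post_topology$adjacency, topo$adjacency)
  # gamma = 1: uncoupled afterwards, every velocity exactly omega0
  set.seed(1)
  ic2 <- initial_condition(0.8, runif(6, -1, 1))
  tr1 <- simulate_network(p, topo, ic2, sim_config(dt = 0.01, t_end = 4),
                          injury = list(gamma = 1, t_inj = 2, seed = 1))
  expect_true(all(tr1$post_topology$adjacency == 0L))
  post <- tr1$times >= 2 + 0.01
  expect_true(all(abs(tr1$dtheta[post, ] - 1) < 1e-12))
  expect_equal(tr1$events[[1]]$label, "injury")
  expect_error(simulate_network(p, topo, ic, sim_config(dt = 0.01, t_end = 4),
                                injury = list(gamma = 1.2, t_inj = 2)),
               "gamma")
})

test_that("a lag beyond the stored history is a hard error naming the horizon", {
  nhist <- 5L
  hist <- matrix(0, nhist + 1, 1)
  A <- matrix(1L, 1, 1)
  expect_error(
    kuradapt:::integrate_core(hist, matrix(1.0, 1, 1), matrix(1.0, 1, 1),
                              1, 1, 0, 1, 0.01, A, A, Inf,
                              0.01, 10L, 1L, 1L),
    "history horizon")
})

test_that("trajectory containers export tidily", {
  p <- two_osc_ref(kappa = 0)
  tr <- simulate_two_oscillator(p, 1, 0.1,
                                cfg = sim_config(dt = 0.01, t_end = 2))
  df <- as.data.frame(tr)
  expect_named(df, c("time", "oscillator", "theta", "dtheta"))
  expect_equal(nrow(df), 2 * length(tr$times))
  ds <- delay_summary(tr)
  expect_true(all(c("time", "q0.5") %in% names(ds)))
  expect_output(print(tr), "N = 2")
})
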