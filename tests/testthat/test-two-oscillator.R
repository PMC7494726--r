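test_that("the root function vanishes at locked frequencies and guards its domain", {
  p0 <- two_osc_ref(kappa = 0)
  Om0 <- as.numeric(find_sync_frequencies(p0))
  expect_lt(abs(root_function(Om0, p0)), 1e-10)
  # kappa = 0 closed form at omega0, and the zero-lag trivial root
  expect_equal(root_function(1, p0), 0.75 * sin(0.1))
  pz <- two_oscillator_params(kappa = 0, tau0 = 0)
  expect_equal(root_function(1, pz), 0)
  expect_error(root_function(2.5, two_osc_ref()), "arcsin")
})

test_that("root counts grow with the plasticity gain as 1, 1, 5", {
  counts <- vapply(c(0, 20, 30), function(k)
    length(as.numeric(find_sync_frequencies(two_osc_ref(kappa = k)))),
    integer(1))
  expect_identical(counts, c(1L, 1L, 5L))
})

test_that("every reported root is a validated, self-consistent lock", {
  for (k in c(0, 20, 30)) {
    p <- two_osc_ref(kappa = k)
    r <- find_sync_frequencies(p)
    roots <- as.numeric(r)
    if (length(roots) == 0) next
    expect_true(all(abs(root_function(roots, p)) < 1e-9))
    if (k > 0) {
      expect_true(all(roots >= p$omega0 - p$g & roots < p$omega0))
      D <- offset_from_frequency(roots, p)
      expect_true(all(p$tau0 - p$kappa * sin(D) < 0))
    }
  }
})

test_that("the two largest non-trivial plastic roots sit at 0.783 and 0.626", {
  roots <- sort(as.numeric(find_sync_frequencies(two_osc_ref())),
                decreasing = TRUE)
  expect_lt(abs(roots[2] - 0.783), 1e-3)
  expect_lt(abs(roots[3] - 0.626), 1e-3)
})

test_that("locked offsets follow the principal arcsine branch", {
  p <- two_osc_ref()
  expect_equal(offset_from_frequency(1, p), 0)
  expect_equal(offset_from_frequency(0.625, p), asin(0.5))
  expect_equal(offset_from_frequency(0.25, p), pi / 2)
  expect_error(offset_from_frequency(1.8, p), "outside")
})

test_that("characteristic polynomials carry the exact neutral mode", {
  p <- two_osc_ref()
  for (Om in c(0.31, 0.45, 0.626, 0.783, 0.95)) {
    cp <- char_polynomials(Om, p)
    expect_identical(cp$P[1] + cp$Q[1], 0)          # P(0) + Q(0) = 0
    expect_equal(cp$kappa_tilde, 1 - Om * 30 * cos(offset_from_frequency(Om, p)))
  }
  # non-plastic specialization: kappa_tilde = 1 and Q = -C12*C21*(lambda+1)
  p0 <- two_osc_ref(kappa = 0)
  cp0 <- char_polynomials(1, p0)    # Delta12 = 0 at Omega = omega0
  expect_equal(cp0$kappa_tilde, 1)
  expect_equal(cp0$Q, c(-cp0$C12 * cp0$C21, -cp0$C12 * cp0$C21))
  # alpha-aware variant reduces to the printed form at alpha_tau = 1
  cpa <- char_polynomials(0.626, p, alpha_aware = TRUE)
  cpp <- char_polynomials(0.626, p)
  expect_equal(cpa$P, cpp$P, tolerance = 1e-12)
  expect_equal(cpa$Q, cpp$Q, tolerance = 1e-12)
})

test_that("zero-delay branches classify the three largest locks as stable, unstable, stable", {
  p <- two_osc_ref()
  roots <- sort(as.numeric(find_sync_frequencies(p)), decreasing = TRUE)
  l3 <- zero_delay_branches(roots[3], p)   # Omega_1 = 0.626
  l2 <- zero_delay_branches(roots[2], p)   # Omega_2 = 0.783
  l1 <- zero_delay_branches(roots[1], p)   # Omega_3 = 0.917
  expect_lt(max(Re(l3)), 0)
  expect_gt(Re(l2[1]), 0)
  expect_lt(max(Re(l1)), 0)
  # deflation is exact: branches plus the neutral root reproduce the cubic
  cp <- char_polynomials(roots[2], p)
  s <- cp$P; s[1:2] <- s[1:2] + cp$Q
  rec <- Re(c(0 * l2[1],                       # constant term of l*(l-l1)(l-l2)
              l2[1] * l2[2],
              -(l2[1] + l2[2]),
              1 + 0i))
  expect_equal(s / s[4], rec, tolerance = 1e-10)
})

test_that("the stability table flags exactly the simulated attractors", {
  tab <- two_oscillator_stability(two_osc_ref())
  expect_equal(nrow(tab), 5)
  expect_identical(tab$stable, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(tab$tauE12, equilibrium_delay(tab$Delta12, two_osc_ref()))
})

test_that("the transcendental error map finds the eigenvalues it should", {
  p <- two_osc_ref()
  roots <- sort(as.numeric(find_sync_frequencies(p)), decreasing = TRUE)

  # the neutral eigenvalue is always present
  em <- transcendental_error_map(roots[3], p, re_range = c(-1.5, 0.5),
                                 im_range = c(-2, 2), resolution = 101)
  expect_true(any(Mod(em$candidates) < 1e-8))
  expect_true(all(em$error >= 0 & em$error <= 1))
  # at the stable lock every candidate is left of (or on) the axis
  expect_true(all(Re(em$candidates) < 1e-8))

  # at the unstable lock a candidate sits near the positive cubic root
  l2 <- zero_delay_branches(roots[2], p)
  em2 <- transcendental_error_map(roots[2], p, re_range = c(-1.5, 3.2),
                                  im_range = c(-2, 2), resolution = 101)
  expect_true(any(Re(em2$candidates) > 0))
  pos <- em2$candidates[Re(em2$candidates) > 0]
  expect_lt(min(Mod(pos - l2[1])), 0.2)

  # kappa = 0: candidates agree with an independent Taylor-polynomial oracle
  p0 <- two_osc_ref(kappa = 0)
  Om0 <- as.numeric(find_sync_frequencies(p0))
  cp0 <- char_polynomials(Om0, p0)
  em0 <- transcendental_error_map(Om0, p0, re_range = c(-2, 0.5),
                                  im_range = c(-3, 3), resolution = 121)
  oracle <- taylor_quasipoly_roots(cp0$P, cp0$Q, cp0$tau)
  oracle <- oracle[Re(oracle) > -2 & Re(oracle) < 0.5 & abs(Im(oracle)) < 3]
  for (z in em0$candidates)
    expect_lt(min(Mod(oracle - z)), 1e-5)

  expect_error(transcendental_error_map(0.6, p, re_range = c(1, 1)),
               "degenerate")
})
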