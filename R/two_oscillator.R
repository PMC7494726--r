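#' Parameters for the reduced two-oscillator network
#'
#' The reduced system
#' \deqn{\theta_1' = \omega_0 + g\sin(\theta_2(t-\tau_{12}(t)) - \theta_1),
#'       \quad
#'       \theta_2' = \omega_0 + g\sin(\theta_1(t-\tau_{21}(t)) - \theta_2)}
#' uses the *pairwise* gain convention: each connection carries the full
#' gain \code{g}. In the \eqn{g/N}-normalized network equation this
#' corresponds to a global gain of \eqn{2g}. All functions in this module
#' take \code{params$g} in the pairwise convention (e.g. \code{g = 0.75});
#' [simulate_two_oscillator()] performs the conversion internally.
#'
#' The reduced system evolves its delays at unit homeostatic rate (the
#' \eqn{\alpha_\tau} prefactor of the general plasticity rule is absorbed in
#' the reduced equations), which is what \code{alpha_tau = 1} encodes; the
#' closed-form analysis in this module is independent of \code{alpha_tau}.
#'
#' @param omega0,g,kappa,tau0,alpha_tau,eps as in [model_params()], with
#'   \code{g} the pairwise gain.
#' @return a [model_params()] object.
#' @export
two_oscillator_params <- function(omega0 = 1, g = 0.75, kappa = 30,
                                  tau0 = 0.1, alpha_tau = 1, eps = 0.01) {
  model_params(omega0 = omega0, g = g, kappa = kappa, tau0 = tau0,
               alpha_tau = alpha_tau, eps = eps)
}

#' Root function for two-oscillator synchronization frequencies
#'
#' In the strong-plasticity regime \eqn{\kappa \gg \tau^0} the delay from 1
#' to 2 decays to zero while the opposite delay settles at
#' \eqn{\tau^E_{12} = \tau^0 + \kappa\sin\Delta_{12} > 0}, and a locked state
#' at frequency \eqn{\Omega} with offset
#' \eqn{\Delta_{12} = \arcsin((\omega_0 - \Omega)/g)} must be a zero of
#' \deqn{\mathcal{R}_\kappa(\Omega) = \Omega - \omega_0 - g\sin\left(
#'   -\Omega\left(\tau^0 + \kappa\frac{\omega_0-\Omega}{g}\right) +
#'   \arcsin\frac{\omega_0-\Omega}{g}\right).}
#' For \code{kappa = 0} the oscillators lock in phase and the function falls
#' back to \eqn{\mathcal{R}_0(\Omega) = \Omega - \omega_0 +
#' g\sin(\Omega\tau^0)}.
#'
#' @param Omega candidate frequency (rad/s); vectorized.
#' @param params a [two_oscillator_params()]-style object (pairwise gain).
#' @return residual value(s); zero at synchronization frequencies.
#' @export
root_function <- function(Omega, params) {
  s <- (params$omega0 - Omega) / params$g
  if (any(abs(s) > 1))
    stop("|omega0 - Omega| > g: arcsin undefined; Omega must lie in ",
         "[omega0 - g, omega0 + g]")
  if (params$kappa == 0)
    return(Omega - params$omega0 + params$g * sin(Omega * params$tau0))
  Omega - params$omega0 -
    params$g * sin(-Omega * (params$tau0 + params$kappa * s) + asin(s))
}

#' Find candidate synchronization frequencies
#'
#' Scans \eqn{\mathcal{R}_\kappa} on a dense grid, refines every sign-change
#' bracket by bisection, and keeps roots satisfying the self-consistency
#' condition of the reduced analysis, \eqn{\tau^0 - \kappa\sin\Delta_{12} <
#' 0} (equivalently \eqn{\Omega < \omega_0 - g\tau^0/\kappa}); roots failing
#' it are returned in the \code{"excluded"} attribute. The default scan
#' interval is \eqn{[\omega_0 - g, \omega_0)} for \eqn{\kappa > 0} and
#' \eqn{[\omega_0 - g, \omega_0 + g]} for \eqn{\kappa = 0}.
#'
#' @param params two-oscillator parameters (pairwise gain).
#' @param interval scan interval; \code{NULL} for the defaults above.
#' @param n_grid number of scan points. The default 4000 comfortably
#'   resolves the oscillation scale \eqn{2\pi g/(\kappa|\Omega|)} of the
#'   root function at \eqn{\kappa = 30}.
#' @param tol bisection tolerance on \eqn{\Omega}.
#' @return sorted ascending vector of roots (possibly empty), with
#'   attribute \code{"excluded"} holding self-inconsistent roots.
#' @export
find_sync_frequencies <- function(params, interval = NULL, n_grid = 4000,
                                  tol = 1e-12) {
  w0 <- params$omega0; g <- params$g
  if (is.null(interval)) {
    interval <- if (params$kappa > 0) c(w0 - g, w0 - 1e-9) else
      c(w0 - g, w0 + g)
  }
  grid <- seq(interval[1], interval[2], length.out = n_grid)
  vals <- root_function(grid, params)
  roots <- numeric(0)
  sgn <- sign(vals)
  for (k in which(sgn[-1] * sgn[-n_grid] < 0)) {
    r <- stats::uniroot(function(x) root_function(x, params),
                        lower = grid[k], upper = grid[k + 1],
                        tol = tol)$root
    roots <- c(roots, r)
  }
  roots <- c(roots, grid[vals == 0])
  roots <- sort(unique(roots))
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  if (params$kappa > 0) {
    ok <- roots < w0 - g * params$tau0 / params$kappa
    excluded <- roots[!ok]
    roots <- roots[ok]
  } else excluded <- numeric(0)
  attr(roots, "excluded") <- excluded
  roots
}

#' Locked phase offset from the locked frequency
#'
#' \eqn{\Delta_{12} = \arcsin((\omega_0 - \Omega)/g)}, principal branch.
#'
#' @param Omega locked frequency (rad/s), in \eqn{[\omega_0-g, \omega_0]}.
#' @param params two-oscillator parameters (pairwise gain).
#' @return offset \eqn{\Delta_{12}} (rad).
#' @export
offset_from_frequency <- function(Omega, params) {
  s <- (params$omega0 - Omega) / params$g
  if (any(abs(s) > 1)) stop("(omega0 - Omega)/g outside [-1, 1]")
  asin(s)
}

#' Characteristic polynomials of a two-oscillator locked state
#'
#' The linearization about a locked state \eqn{(\Omega, \Delta_{12})} with a
#' single positive delay \eqn{\tau = \tau^E_{12}} leads to the
#' quasi-polynomial root equation
#' \eqn{P_\Omega(\lambda) + Q_\Omega(\lambda) e^{-\lambda\tau} = 0} with
#' \deqn{P_\Omega(\lambda) = \lambda^3 + (1 + C_{12} + C_{21})\lambda^2 +
#'   [\tilde\kappa C_{12} + (1 + C_{12})C_{21}]\lambda + C_{12}C_{21},}
#' \deqn{Q_\Omega(\lambda) = -C_{12}C_{21}(\lambda + 1),}
#' where \eqn{C_{12} = g\cos(-\Omega\tau^E_{12} + \Delta_{12})},
#' \eqn{C_{21} = g\cos\Delta_{12}}, \eqn{C_0 = \cos\Delta_{12}} and
#' \eqn{\tilde\kappa = 1 - \Omega\kappa C_0}. The structure guarantees
#' \eqn{P_\Omega(0) + Q_\Omega(0) = 0} (the neutral rotational mode).
#'
#' These coefficients arise from the unit-rate linearization of the delay
#' dynamics. With \code{alpha_aware = TRUE} the \eqn{(\lambda+1)} factors
#' originating from that linearization are replaced by
#' \eqn{(\lambda/\alpha_\tau + 1)} (a generalization that has not been
#' validated against simulation; default \code{FALSE} uses the unit-rate
#' form regardless of \code{params$alpha_tau}).
#'
#' @param Omega locked frequency (rad/s).
#' @param params two-oscillator parameters (pairwise gain).
#' @param alpha_aware use the \eqn{\alpha_\tau}-generalized factors.
#' @return a list with ascending coefficient vectors \code{P}, \code{Q},
#'   the delay \code{tau}, and constants \code{C12}, \code{C21}, \code{C0},
#'   \code{kappa_tilde}.
#' @export
char_polynomials <- function(Omega, params, alpha_aware = FALSE) {
  D <- offset_from_frequency(Omega, params)
  tauE <- equilibrium_delay(D, params)
  C12 <- params$g * cos(-Omega * tauE + D)
  C21 <- params$g * cos(D)
  C0 <- cos(D)
  okC0 <- Omega * params$kappa * C0
  if (!alpha_aware) {
    P <- c(C12 * C21,
           (1 - okC0) * C12 + (1 + C12) * C21,
           1 + C12 + C21,
           1)
    Q <- c(-C12 * C21, -C12 * C21)
  } else {
    a <- params$alpha_tau
    # u = lambda/a + 1; det expands to
    # (lambda*u + C12*u - C12*okC0)(lambda + C21) + C12*C21*okC0
    #   + [-C12*C21*u] e^{-lambda tau}
    u <- c(1, 1 / a)
    lam <- c(0, 1)
    left <- poly_add(poly_mul(lam, u), C12 * u)
    left <- poly_add(left, -C12 * okC0)
    P <- poly_add(poly_mul(left, c(C21, 1)), C12 * C21 * okC0)
    Q <- -C12 * C21 * u
  }
  list(P = P, Q = Q, tau = tauE, C12 = C12, C21 = C21, C0 = C0,
       kappa_tilde = 1 - okC0)
}

#' Non-zero eigenvalue branches under the zero-delay approximation
#'
#' With \eqn{\tau \approx 0} the eigenvalues are the roots of the cubic
#' \eqn{P_\Omega + Q_\Omega}, whose constant term vanishes identically
#' (neutral mode). Deflating the exact \eqn{\lambda = 0} root leaves the
#' quadratic \eqn{\lambda^2 + (1 + C_{12} + C_{21})\lambda +
#' (\tilde\kappa C_{12} + C_{21})}; its two roots are returned ordered by
#' descending real part. A locked state is classified stable when both
#' real parts are negative.
#'
#' @param Omega locked frequency (rad/s).
#' @param params two-oscillator parameters (pairwise gain).
#' @param alpha_aware see [char_polynomials()].
#' @return complex vector \code{c(lambda1, lambda2)}, descending real part.
#' @export
zero_delay_branches <- function(Omega, params, alpha_aware = FALSE) {
  cp <- char_polynomials(Omega, params, alpha_aware = alpha_aware)
  s <- poly_add(cp$P, cp$Q)
  stopifnot(abs(s[1]) < 1e-12)          # neutral mode: exact zero constant
  # deflate lambda = 0 and solve the remaining polynomial
  s <- s[-1]
  if (length(s) == 3) {                 # quadratic: closed form
    disc <- as.complex(s[2]^2 - 4 * s[3] * s[1])
    r <- c((-s[2] + sqrt(disc)) / (2 * s[3]),
           (-s[2] - sqrt(disc)) / (2 * s[3]))
  } else {
    r <- polyroot(s)
  }
  r[order(-Re(r))]
}

#' Stability table for all candidate locked states
#'
#' Runs [find_sync_frequencies()] and classifies every root by its
#' zero-delay eigenvalue branches.
#'
#' @param params two-oscillator parameters (pairwise gain).
#' @param ... passed to [find_sync_frequencies()].
#' @return data frame with columns \code{Omega}, \code{Delta12},
#'   \code{tauE12}, \code{re_lambda1}, \code{re_lambda2}, \code{stable}.
#' @export
two_oscillator_stability <- function(params, ...) {
  roots <- find_sync_frequencies(params, ...)
  rows <- lapply(as.numeric(roots), function(Om) {
    D <- offset_from_frequency(Om, params)
    lam <- zero_delay_branches(Om, params)
    data.frame(Omega = Om, Delta12 = D,
               tauE12 = equilibrium_delay(D, params),
               re_lambda1 = Re(lam[1]), re_lambda2 = Re(lam[2]),
               stable = max(Re(lam)) < 0)
  })
  if (length(rows) == 0)
    return(data.frame(Omega = numeric(0), Delta12 = numeric(0),
                      tauE12 = numeric(0), re_lambda1 = numeric(0),
                      re_lambda2 = numeric(0), stable = logical(0)))
  do.call(rbind, rows)
}

#' Error surface of the transcendental characteristic equation
#'
#' Evaluates \eqn{|P_\Omega(\lambda) + Q_\Omega(\lambda)e^{-\lambda\tau}|}
#' on a rectangular grid in the complex plane, normalized for display as
#' \eqn{\log(1 + \cdot)} scaled to \eqn{[0, 1]}. Grid local minima are
#' polished by complex Newton iteration; converged points with residual
#' below \code{threshold} are reported as candidate eigenvalues.
#'
#' @param Omega locked frequency (rad/s).
#' @param params two-oscillator parameters (pairwise gain).
#' @param re_range,im_range real/imaginary extents of the grid.
#' @param resolution grid points per axis.
#' @param threshold residual threshold for accepting a polished candidate.
#' @return a list with \code{re}, \code{im}, \code{error}
#'   (\code{resolution x resolution}, normalized) and \code{candidates}
#'   (complex vector).
#' @export
transcendental_error_map <- function(Omega, params,
                                     re_range = c(-2, 1),
                                     im_range = c(-3, 3),
                                     resolution = 201,
                                     threshold = 1e-6) {
  if (diff(re_range) <= 0 || diff(im_range) <= 0 || resolution < 3)
    stop("degenerate grid region")
  cp <- char_polynomials(Omega, params)
  re <- seq(re_range[1], re_range[2], length.out = resolution)
  im <- seq(im_range[1], im_range[2], length.out = resolution)
  lam <- outer(re, im, function(x, y) complex(real = x, imaginary = y))
  err <- Mod(quasipoly_eval(lam, cp$P, cp$Q, cp$tau))

  # local minima of the raw error surface (8-neighborhood)
  cand <- complex(0)
  for (i in 2:(resolution - 1)) for (j in 2:(resolution - 1)) {
    e <- err[i, j]
    if (e <= min(err[(i - 1):(i + 1), (j - 1):(j + 1)])) {
      z <- newton_quasipoly(lam[i, j], cp$P, cp$Q, cp$tau)
      if (!is.na(z) && Mod(quasipoly_eval(z, cp$P, cp$Q, cp$tau)) < threshold)
        cand <- c(cand, z)
    }
  }
  if (length(cand) > 1) {
    keep <- rep(TRUE, length(cand))
    for (k in seq_along(cand)[-1])
      if (any(Mod(cand[seq_len(k - 1)][keep[seq_len(k - 1)]] - cand[k]) < 1e-6))
        keep[k] <- FALSE
    cand <- cand[keep]
  }
  norm <- log1p(err)
  norm <- (norm - min(norm)) / max(1e-300, diff(range(norm)))
  list(re = re, im = im, error = norm, candidates = cand)
}

#' Simulate the reduced two-oscillator network
#'
#' Builds the N = 2 network (pairwise gain \code{params$g}, converted to the
#' \eqn{g/N} convention internally), with initial history
#' \eqn{\varphi_1 = \Omega_0 t}, \eqn{\varphi_2 = \Omega_0 t + \Delta_0}.
#'
#' @param params two-oscillator parameters (pairwise gain).
#' @param Omega0 initial frequency (rad/s).
#' @param Delta0 initial phase difference (rad).
#' @param cfg a [sim_config()]; default runs 200 s at dt = 0.005 s.
#' @param ... passed to [initial_condition()].
#' @return a \code{"kuramoto_trajectory"}.
#' @export
simulate_two_oscillator <- function(params, Omega0, Delta0,
                                    cfg = sim_config(t_end = 200), ...) {
  netp <- model_params(omega0 = params$omega0, g = 2 * params$g,
                       kappa = params$kappa, tau0 = params$tau0,
                       alpha_tau = params$alpha_tau, eps = params$eps)
  ic <- initial_condition(Omega0, c(0, Delta0), ...)
  simulate_network(netp, two_oscillator_topology(), ic, cfg)
}

# --- internal polynomial helpers (ascending coefficients) -------------------

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

poly_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
      out[i:(i + length(b) - 1)] + a[i] * b
  out
}

poly_eval <- function(coef, z) {
  out <- 0 * z
  for (k in rev(seq_along(coef))) out <- out * z + coef[k]
  out
}

quasipoly_eval <- function(lambda, P, Q, tau) {
  poly_eval(P, lambda) + poly_eval(Q, lambda) * exp(-lambda * tau)
}

poly_deriv <- function(coef) {
  if (length(coef) <= 1) return(0)
  coef[-1] * seq_len(length(coef) - 1)
}

newton_quasipoly <- function(z, P, Q, tau, maxit = 60, tol = 1e-13) {
  dP <- poly_deriv(P); dQ <- poly_deriv(Q)
  for (k in seq_len(maxit)) {
    f <- quasipoly_eval(z, P, Q, tau)
    df <- poly_eval(dP, z) +
      (poly_eval(dQ, z) - tau * poly_eval(Q, z)) * exp(-z * tau)
    if (Mod(df) < 1e-300) return(NA_complex_)
    znew <- z - f / df
    if (!is.finite(Re(znew)) || !is.finite(Im(znew))) return(NA_complex_)
    if (Mod(znew - z) < tol) return(znew)
    z <- znew
  }
  z
}
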