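#' Mean-field frequency residual with Gaussian offsets
#'
#' In the N-limit with i.i.d. Gaussian phase offsets of standard deviation
#' \eqn{\delta}, a synchronized state \eqn{(\Omega, \delta^2)} of the
#' all-to-all plastic-delay network must be a zero of
#' \deqn{\mathcal{R}(\Omega, \delta^2) = \omega_0 - \Omega +
#'   g\int \sin(-\Omega\tau^E(\Delta) + \Delta)\,
#'   \rho_\delta(\Delta)\, d\Delta,}
#' where \eqn{\rho_\delta} is the centered Gaussian density and, in the
#' small-offset form used throughout this module,
#' \eqn{\tau^E(\Delta) = \max(\tau^0 + \kappa\Delta, 0)}. The quadrature is
#' adaptive Gauss-Kronrod on \eqn{[-8\delta, 8\delta]}, split at the
#' integrand kink \eqn{\Delta = -\tau^0/\kappa} and at 0; the neglected
#' Gaussian tail mass beyond \eqn{8\delta} is below \eqn{10^{-15}}.
#'
#' @param Omega candidate frequency (rad/s).
#' @param delta offset standard deviation (rad), positive.
#' @param params a [model_params()] object (\eqn{g/N}-normalized gain, e.g.
#'   \code{g = 1.5}).
#' @param form \code{"linear"} for the small-offset delay law above
#'   (the model analyzed here), \code{"sin"} for the exact
#'   \eqn{\max(\tau^0 + \kappa\sin\Delta, 0)} variant (sensitivity checks
#'   only).
#' @param rel_tol quadrature relative tolerance.
#' @return the residual (rad/s).
#' @export
meanfield_residual <- function(Omega, delta, params, form = c("linear", "sin"),
                               rel_tol = 1e-9) {
  form <- match.arg(form)
  if (!is.numeric(delta) || delta <= 0) stop("'delta' must be positive")
  tauE <- tauE_fun(params, form)
  f <- function(D) sin(-Omega * tauE(D) + D) * stats::dnorm(D, sd = delta)
  params$omega0 - Omega + params$g *
    split_quad(f, delta, params, rel_tol = rel_tol)
}

#' Trace the synchronization level curve Omega(delta)
#'
#' For each \eqn{\delta} on the grid, finds the root of
#' [meanfield_residual()] in \eqn{\Omega \in [\omega_0-g, \omega_0+g]} by a
#' bracket scan followed by root refinement. A unique root is expected at
#' every \eqn{\delta}; if several brackets are found, the function stops
#' rather than silently picking one.
#'
#' @param delta_grid positive \eqn{\delta} values (rad).
#' @param params a [model_params()] object.
#' @param n_scan scan points over the \eqn{\Omega} interval.
#' @param ... passed to [meanfield_residual()].
#' @return data frame with columns \code{delta}, \code{Omega}.
#' @export
solve_level_curve <- function(delta_grid, params, n_scan = 400, ...) {
  w0 <- params$omega0; g <- params$g
  grid <- seq(w0 - g, w0 + g, length.out = n_scan)
  Omega <- vapply(delta_grid, function(d) {
    vals <- vapply(grid, function(Om) meanfield_residual(Om, d, params, ...),
                   numeric(1))
    sgn <- sign(vals)
    br <- which(sgn[-1] * sgn[-n_scan] < 0)
    if (length(br) == 0)
      stop("no sign change of the mean-field residual at delta = ", d)
    if (length(br) > 1)
      stop("multiple residual roots at delta = ", d,
           " (", length(br), " brackets); the level curve is not unique here")
    stats::uniroot(function(Om) meanfield_residual(Om, d, params, ...),
                   lower = grid[br], upper = grid[br + 1], tol = 1e-10)$root
  }, numeric(1))
  data.frame(delta = delta_grid, Omega = Omega)
}

#' Exponential-polynomial reduction of the mean-field eigenvalue equation
#'
#' The N-limit characteristic equation for a state \eqn{(\Omega, \delta^2)}
#' is \eqn{\lambda = g\int_0^\infty C_\Omega(\Delta)(e^{-\lambda
#' \tau^E(\Delta)} - 1)\rho_\delta(\Delta)d\Delta} with
#' \eqn{C_\Omega(\Delta) = \cos(-\Omega\tau^E(\Delta) + \Delta)}. Rescaling
#' \eqn{\lambda \to R\lambda} by a radius \eqn{R > \kappa} and expanding the
#' exponential in powers of \eqn{\lambda} up to degree \eqn{M} turns it into
#' \eqn{P(\lambda) + Q(\lambda)e^{-\lambda\tau^R} = 0} with
#' \eqn{\tau^R = \tau^0/R},
#' \deqn{P(\lambda) = \lambda + RgI_{-1}, \qquad
#'       Q(\lambda) = \sum_{m=0}^M I_m \lambda^m,}
#' \deqn{I_m = \frac{(-1)^{m+1}Rg}{m!}\left(\frac{\kappa}{R}\right)^m
#'       \int_0^\infty C_\Omega(\Delta)\Delta^m\rho_\delta(\Delta)d\Delta.}
#' Since \eqn{I_0 = -RgI_{-1}} analytically, \code{I[1]} is set from the
#' same quadrature value as \eqn{I_{-1}}, making the neutral-mode identity
#' \eqn{P(0) + Q(0) = 0} exact to machine precision.
#'
#' @param Omega,delta the candidate state.
#' @param params a [model_params()] object.
#' @param M polynomial degree (default 3; the expansion is only trusted up
#'   to cubic order).
#' @param R rescale radius, must exceed \code{kappa}; default
#'   \eqn{2\kappa} (or 1 when \eqn{\kappa = 0}).
#' @param rel_tol quadrature relative tolerance.
#' @return a list with ascending coefficients \code{P}, \code{Q}, the
#'   rescaled delay \code{tau_R}, \code{I_minus1}, \code{I} (components
#'   \eqn{I_0 \dots I_M}), and \code{R}.
#' @export
polynomial_reduction <- function(Omega, delta, params, M = 3, R = NULL,
                                 rel_tol = 1e-9) {
  if (is.null(R)) R <- max(2 * params$kappa, 1)
  if (R <= params$kappa) stop("rescale radius R must exceed kappa")
  if (M < 1) stop("polynomial degree M must be at least 1")
  g <- params$g
  J <- vapply(0:M, function(m) halfline_moment(Omega, delta, params, m,
                                               rel_tol = rel_tol),
              numeric(1))
  I_minus1 <- J[1]                       # C_Omega weight, m = 0 moment
  I <- vapply(0:M, function(m) {
    (-1)^(m + 1) * R * g / factorial(m) * (params$kappa / R)^m * J[m + 1]
  }, numeric(1))
  I[1] <- -R * g * I_minus1              # exact neutral-mode identity
  list(P = c(R * g * I_minus1, 1), Q = I, tau_R = params$tau0 / R,
       I_minus1 = I_minus1, I = I, R = R, M = M)
}

#' Stability statistic E of a mean-field state
#'
#' Solves the reduced polynomial \eqn{P + Q} (the \eqn{\tau^R \approx 0}
#' limit of the exponential-polynomial equation), discards the neutral
#' rotational root (\eqn{|\mathrm{Re}\,\lambda| \le} \code{zero_tol} on the
#' original eigenvalue scale), and reports
#' \eqn{E = \max \mathrm{Re}\,\lambda} over the remaining roots, rescaled
#' back by \eqn{1/R}. The state is classified stable when \eqn{E < 0}.
#'
#' @param Omega,delta the candidate state.
#' @param params a [model_params()] object.
#' @param M,R,rel_tol passed to [polynomial_reduction()].
#' @param zero_tol neutral-root tolerance on \eqn{\mathrm{Re}\,\lambda}.
#' @return an object of class \code{"stability_result"}: list with
#'   \code{eigenvalues} (original scale), \code{E}, \code{stable},
#'   \code{M}, \code{R}.
#' @export
stability_E <- function(Omega, delta, params, M = 3, R = NULL,
                        zero_tol = 1e-8, rel_tol = 1e-9) {
  red <- polynomial_reduction(Omega, delta, params, M = M, R = R,
                              rel_tol = rel_tol)
  coefs <- poly_add(red$P, red$Q)
  while (length(coefs) > 1 && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]
  lam <- polyroot(coefs) / red$R         # rescale back to original scale
  nonzero <- lam[abs(Re(lam)) > zero_tol]
  if (length(nonzero) == 0) {
    warning("all eigenvalues neutral at (Omega, delta) = (", Omega, ", ",
            delta, "); E undefined")
    E <- NA_real_
  } else E <- max(Re(nonzero))
  structure(list(eigenvalues = lam, E = E,
                 stable = isTRUE(E < 0), M = red$M, R = red$R),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Mean-field stability: E = %.6g (%s), M = %d, R = %g\n",
              x$E, if (isTRUE(x$stable)) "stable" else "unstable",
              x$M, x$R))
  invisible(x)
}

#' Sign-preserving logarithm
#'
#' \eqn{\mathrm{s.log}(x) = \mathrm{sgn}(x)\log(1+|x|)}: odd, monotone,
#' zero at zero. Used to display the strongly varying stability statistic.
#'
#' @param x numeric; vectorized.
#' @return transformed values.
#' @export
slog <- function(x) sign(x) * log1p(abs(x))

#' Stability map over a grid of candidate states
#'
#' Evaluates the stability statistic \eqn{E(\Omega, \delta^2)} on a grid
#' and returns both \eqn{\mathrm{sgn}\,E} and \eqn{\mathrm{s.log}\,E}.
#'
#' @param params a [model_params()] object.
#' @param Omega_range,delta_range extents; defaults cover
#'   \eqn{[\omega_0-g, \omega_0+g] \times (0, 0.5)}.
#' @param n_Omega,n_delta grid resolution.
#' @param ... passed to [stability_E()].
#' @return list with \code{Omega}, \code{delta}, \code{E}, \code{sgnE},
#'   \code{slogE} (matrices \code{n_Omega x n_delta}).
#' @export
stability_map <- function(params, Omega_range = NULL,
                          delta_range = c(0.01, 0.5),
                          n_Omega = 40, n_delta = 40, ...) {
  if (is.null(Omega_range))
    Omega_range <- c(params$omega0 - params$g, params$omega0 + params$g)
  Om <- seq(Omega_range[1], Omega_range[2], length.out = n_Omega)
  de <- seq(delta_range[1], delta_range[2], length.out = n_delta)
  E <- matrix(NA_real_, n_Omega, n_delta)
  for (i in seq_len(n_Omega)) for (j in seq_len(n_delta))
    E[i, j] <- stability_E(Om[i], de[j], params, ...)$E
  list(Omega = Om, delta = de, E = E, sgnE = sign(E), slogE = slog(E))
}

#' Residual of the un-reduced mean-field eigenvalue equation
#'
#' Evaluates \eqn{\lambda - g\int_0^\infty C_\Omega(\Delta)
#' (e^{-\lambda\tau^E(\Delta)} - 1)\rho_\delta(\Delta)d\Delta} at a complex
#' \eqn{\lambda}. Intended for validating the polynomial reduction at
#' sampled points; the exponential term grows without bound for
#' \eqn{\mathrm{Re}\,\lambda < 0} and large \eqn{\Delta}, which is why the
#' reduction, not this residual, is used for root finding.
#'
#' @param lambda complex eigenvalue candidate.
#' @param Omega,delta the candidate state.
#' @param params a [model_params()] object.
#' @param rel_tol quadrature relative tolerance.
#' @return complex residual.
#' @export
eigen_integral_residual <- function(lambda, Omega, delta, params,
                                    rel_tol = 1e-9) {
  tauE <- tauE_fun(params, "linear")
  CO <- function(D) cos(-Omega * tauE(D) + D)
  fre <- function(D) Re((exp(-lambda * tauE(D)) - 1)) * CO(D) *
    stats::dnorm(D, sd = delta)
  fim <- function(D) Im((exp(-lambda * tauE(D)) - 1)) * CO(D) *
    stats::dnorm(D, sd = delta)
  up <- 8 * delta
  re <- stats::integrate(fre, 0, up, rel.tol = rel_tol, abs.tol = 1e-12,
                         subdivisions = 2000L, stop.on.error = FALSE)$value
  im <- stats::integrate(fim, 0, up, rel.tol = rel_tol, abs.tol = 1e-12,
                         subdivisions = 2000L, stop.on.error = FALSE)$value
  lambda - params$g * complex(real = re, imaginary = im)
}

#' Synchronization frequency and stability of the non-plastic network
#'
#' With \eqn{\kappa = 0} (fixed delays) and effective coupling
#' \eqn{g_{eff} = (1-\gamma)g} after random removal of a fraction
#' \eqn{\gamma} of connections, the mean-field frequency solves
#' \eqn{\Omega = \omega_0 + g_{eff}\sin(-\Omega\tau^0)}, and the in-phase
#' state is stable if and only if \eqn{\cos(\Omega\tau^0) > 0}.
#'
#' @param params a [model_params()] object (its \code{kappa} is ignored;
#'   \eqn{\kappa = 0} semantics apply).
#' @param gamma insult index in \eqn{[0, 1]}.
#' @param n_scan scan points for root bracketing.
#' @return data frame with columns \code{Omega} and \code{stable}, one row
#'   per root (a single row \code{Omega = omega0} when \eqn{\gamma = 1}).
#' @export
nonplastic_baseline <- function(params, gamma = 0, n_scan = 2000) {
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
  geff <- (1 - gamma) * params$g
  w0 <- params$omega0; t0 <- params$tau0
  if (geff == 0)
    return(data.frame(Omega = w0, stable = TRUE))
  f <- function(Om) Om - w0 - geff * sin(-Om * t0)
  grid <- seq(w0 - geff, w0 + geff, length.out = n_scan)
  vals <- f(grid)
  sgn <- sign(vals)
  roots <- vapply(which(sgn[-1] * sgn[-n_scan] < 0), function(k)
    stats::uniroot(f, lower = grid[k], upper = grid[k + 1],
                   tol = 1e-12)$root, numeric(1))
  roots <- sort(unique(c(roots, grid[vals == 0])))
  data.frame(Omega = roots, stable = cos(roots * t0) > 0)
}

# --- internal quadrature helpers --------------------------------------------

tauE_fun <- function(params, form) {
  t0 <- params$tau0; k <- params$kappa
  if (form == "linear") {
    function(D) pmax(t0 + k * D, 0)
  } else {
    function(D) pmax(t0 + k * sin(D), 0)
  }
}

# integrate f over [-8 delta, 8 delta], splitting at the Heaviside kink
# -tau0/kappa and at 0
split_quad <- function(f, delta, params, rel_tol = 1e-9) {
  lo <- -8 * delta; hi <- 8 * delta
  pts <- c(lo, 0, hi)
  if (params$kappa > 0) {
    kink <- -params$tau0 / params$kappa
    if (kink > lo && kink < hi) pts <- sort(c(pts, kink))
  }
  total <- 0
  for (k in seq_len(length(pts) - 1)) {
    r <- stats::integrate(f, pts[k], pts[k + 1], rel.tol = rel_tol,
                          abs.tol = 1e-12, subdivisions = 2000L,
                          stop.on.error = FALSE)
    if (!r$message %in% c("OK", "roundoff error was detected"))
      stop("mean-field quadrature failed on [", pts[k], ", ", pts[k + 1],
           "]: ", r$message)
    total <- total + r$value
  }
  total
}

# half-line Gaussian moment against the cosine kernel:
# int_0^inf C_Omega(D) D^m rho_delta(D) dD
halfline_moment <- function(Omega, delta, params, m, rel_tol = 1e-9) {
  tauE <- tauE_fun(params, "linear")
  f <- function(D) cos(-Omega * tauE(D) + D) * D^m *
    stats::dnorm(D, sd = delta)
  r <- stats::integrate(f, 0, 8 * delta, rel.tol = rel_tol, abs.tol = 1e-13,
                        subdivisions = 2000L, stop.on.error = FALSE)
  if (!r$message %in% c("OK", "roundoff error was detected"))
    stop("half-line moment quadrature failed: ", r$message)
  r$value
}
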