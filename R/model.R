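#' Model parameters for the adaptive-delay Kuramoto network
#'
#' Bundles the scalar constants of the phase equation and of the delay
#' plasticity rule. The network phases obey
#' \deqn{\theta_i' = \omega_0 + (g/N) \sum_j a_{ij}
#'       \sin(\theta_j(t - \tau_{ij}(t)) - \theta_i(t)),}
#' while each conduction delay relaxes towards its baseline lag and is pushed
#' by the instantaneous phase difference,
#' \deqn{\alpha_\tau^{-1} \tau_{ij}' = H(\tau_{ij})
#'       [-(\tau_{ij} - \tau^0_{ij}) + \kappa \sin(\theta_j - \theta_i)],}
#' with \eqn{H} a smoothed Heaviside of width \code{eps} that keeps delays
#' non-negative.
#'
#' @param omega0 natural frequency (rad/s), common to all oscillators.
#' @param g global coupling gain (rad/s), must be positive. This is the gain
#'   of the \eqn{g/N}-normalized phase equation; see
#'   [two_oscillator_params()] for the pairwise convention used by the
#'   reduced two-oscillator analysis.
#' @param kappa plasticity gain \eqn{\kappa} (s), non-negative; \code{kappa = 0}
#'   recovers the classical fixed-delay network.
#' @param tau0 baseline conduction lag \eqn{\tau^0} (s), non-negative.
#' @param alpha_tau homeostatic rate constant \eqn{\alpha_\tau} (1/s), positive;
#'   sets the time scale of delay adaptation.
#' @param eps smoothing width \eqn{\varepsilon} (s) of the Heaviside cutoff.
#' @return an object of class \code{"model_params"}.
#' @export
model_params <- function(omega0 = 1, g = 1.5, kappa = 0, tau0 = 0.1,
                         alpha_tau = 1, eps = 0.01) {
  stopifnot(is.numeric(omega0), length(omega0) == 1L, is.finite(omega0))
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0)
    stop("'g' must be a positive finite scalar")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0)
    stop("'kappa' must be a non-negative scalar")
  if (!is.numeric(tau0) || length(tau0) != 1L || tau0 < 0)
    stop("'tau0' must be a non-negative scalar")
  if (!is.numeric(alpha_tau) || length(alpha_tau) != 1L || alpha_tau <= 0)
    stop("'alpha_tau' must be a positive scalar")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("'eps' must be a positive scalar")
  if (tau0 > 0 && eps >= tau0)
    warning("Heaviside width 'eps' is not small compared to 'tau0'; ",
            "the smoothed cutoff will distort small delays")
  structure(list(omega0 = omega0, g = g, kappa = kappa, tau0 = tau0,
                 alpha_tau = alpha_tau, eps = eps),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Adaptive-delay Kuramoto model parameters\n")
  cat(sprintf("  omega0 = %g rad/s, g = %g rad/s, kappa = %g s\n",
              x$omega0, x$g, x$kappa))
  cat(sprintf("  tau0 = %g s, alpha_tau = %g 1/s, eps = %g s\n",
              x$tau0, x$alpha_tau, x$eps))
  invisible(x)
}

#' Network topology
#'
#' A binary adjacency matrix \eqn{a_{ij}} (\eqn{a_{ij} = 1} when oscillator
#' \eqn{j} projects to \eqn{i}) together with the insult index used to
#' generate it, if any.
#'
#' @param adjacency square 0/1 matrix.
#' @param gamma insult index in \eqn{[0, 1]} recorded for provenance
#'   (0 for a dense network).
#' @param seed RNG seed used at generation time, or \code{NULL}.
#' @return an object of class \code{"topology"} with fields \code{n},
#'   \code{adjacency}, \code{gamma}, \code{seed}.
#' @seealso [dense_topology()], [sparse_topology()], [two_oscillator_topology()]
#' @export
topology <- function(adjacency, gamma = 0, seed = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
    stop("'gamma' must lie in [0, 1]")
  storage.mode(adjacency) <- "integer"
  structure(list(n = nrow(adjacency), adjacency = adjacency,
                 gamma = gamma, seed = seed),
            class = "topology")
}

#' All-to-all topology
#'
#' Dense adjacency with every entry equal to 1, including the diagonal, which
#' is the convention of the mean-field analysis (self-terms carry
#' \eqn{\Delta_{ii} = 0} and behave like any other connection).
#'
#' @param n number of oscillators.
#' @return a [topology()] object.
#' @export
dense_topology <- function(n) {
  topology(matrix(1L, n, n), gamma = 0)
}

#' Reduced two-oscillator topology
#'
#' \eqn{a_{12} = a_{21} = 1} with self-terms removed
#' (\eqn{a_{11} = a_{22} = 0}).
#'
#' @return a [topology()] object with \code{n = 2}.
#' @export
two_oscillator_topology <- function() {
  topology(matrix(c(0L, 1L, 1L, 0L), 2, 2), gamma = 0)
}

#' Smoothed Heaviside cutoff
#'
#' C1 smoothstep used by the delay plasticity rule to shut adaptation off as
#' a delay reaches zero: exactly 0 for \code{tau <= 0}, exactly 1 for
#' \code{tau >= eps}, and the cubic \eqn{3x^2 - 2x^3} with
#' \eqn{x = \tau/\varepsilon} in between (monotone, value 1/2 at the
#' midpoint).
#'
#' @param tau delay value(s) (s); vectorized.
#' @param eps smoothing width (s), positive.
#' @return values in \eqn{[0, 1]}.
#' @export
smooth_heaviside <- function(tau, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("'eps' must be a positive scalar")
  x <- pmin(pmax(tau / eps, 0), 1)
  x * x * (3 - 2 * x)
}

#' Phase velocities of the network
#'
#' Right-hand side of the delayed Kuramoto equation, given the current phases
#' and the matrix of delayed presynaptic phases.
#'
#' @param theta_now length-N vector of current phases (rad).
#' @param theta_delayed N x N matrix; entry \code{[i, j]} is
#'   \eqn{\theta_j(t - \tau_{ij})}. Only entries with \eqn{a_{ij} = 1} are
#'   read.
#' @param params a [model_params()] object. \code{params$omega0} may also be a
#'   length-N vector of per-oscillator frequencies.
#' @param topology a [topology()] object.
#' @return length-N vector of phase velocities (rad/s), each within
#'   \eqn{[\omega_0 - g, \omega_0 + g]}.
#' @export
phase_rhs <- function(theta_now, theta_delayed, params, topology) {
  n <- topology$n
  theta_delayed <- as.matrix(theta_delayed)
  if (length(theta_now) != n || !all(dim(theta_delayed) == c(n, n)))
    stop("shape mismatch: need length-", n, " phases and a ", n, "x", n,
         " delayed-phase matrix")
  a <- topology$adjacency
  s <- rowSums(a * sin(theta_delayed - theta_now))
  params$omega0 + params$g / n * s
}

#' Delay velocities of the network
#'
#' Right-hand side of the delay plasticity rule. Delays on absent connections
#' (\eqn{a_{ij} = 0}) are not evolved and return velocity 0.
#'
#' @param tau_now N x N matrix of current delays (s), non-negative.
#' @param theta_now length-N vector of current phases (rad).
#' @param params a [model_params()] object.
#' @param topology a [topology()] object.
#' @return N x N matrix of delay velocities (s/s).
#' @export
delay_rhs <- function(tau_now, theta_now, params, topology) {
  n <- topology$n
  tau_now <- as.matrix(tau_now)
  if (!all(dim(tau_now) == c(n, n)) || length(theta_now) != n)
    stop("shape mismatch in delay_rhs")
  if (any(tau_now < 0))
    stop("invariant violation: negative delay passed to delay_rhs")
  dphi <- t(outer(theta_now, theta_now, `-`))  # [i,j] = theta_j - theta_i
  v <- params$alpha_tau * smooth_heaviside(tau_now, params$eps) *
    (-(tau_now - params$tau0) + params$kappa * sin(dphi))
  v * (topology$adjacency == 1L)
}

#' Equilibrium delay at a locked state
#'
#' Fixed point of the plasticity rule for a constant phase difference
#' \eqn{\Delta_{ij}}: \eqn{\tau^E = \max(\tau^0 + \kappa \sin\Delta, 0)}.
#'
#' @param delta phase difference \eqn{\Delta_{ij} = \phi_j - \phi_i} (rad);
#'   vectorized.
#' @param params a [model_params()] object.
#' @return equilibrium delay(s) (s).
#' @export
equilibrium_delay <- function(delta, params) {
  pmax(params$tau0 + params$kappa * sin(delta), 0)
}

#' Residuals of the locked-state frequency condition
#'
#' A candidate synchronized state \eqn{(\Omega, \phi)} must satisfy, for every
#' oscillator,
#' \deqn{\Omega = \omega_0 + (g/N)\sum_j a_{ij}
#'       \sin(-\Omega \tau^E_{ij} + \Delta_{ij})}
#' with \eqn{\tau^E_{ij}} the equilibrium delays of [equilibrium_delay()].
#' This returns the per-oscillator residuals (all approximately zero iff the
#' state is a solution).
#'
#' @param Omega candidate global frequency (rad/s).
#' @param phi length-N vector of phase offsets (rad).
#' @param params a [model_params()] object.
#' @param topology a [topology()] object.
#' @return length-N vector of residuals (rad/s).
#' @export
global_frequency_residual <- function(Omega, phi, params, topology) {
  n <- topology$n
  stopifnot(length(phi) == n)
  delta <- t(outer(phi, phi, `-`))            # [i,j] = phi_j - phi_i
  tauE <- equilibrium_delay(delta, params)
  s <- rowSums(topology$adjacency * sin(-Omega * tauE + delta))
  params$omega0 - Omega + params$g / n * s
}

#' Characteristic matrix of a locked state
#'
#' The N x N matrix \eqn{M_\lambda} whose singularity condition
#' \eqn{\det M_\lambda = 0} determines the linear stability of a synchronized
#' state \eqn{(\Omega, \phi)} of the plastic-delay network. Its entries are
#' \deqn{M_{ii} = \lambda(\lambda+1) + (g/N)\sum_j a_{ij} C_{ij}
#'       (\lambda + 1 - \Omega\kappa C^0_{ij} H_{ij}),}
#' \deqn{M_{ij} = (g/N) a_{ij} C_{ij}
#'       [\Omega\kappa C^0_{ij} H_{ij} - (\lambda+1) e^{-\lambda \tau^E_{ij}}],}
#' with \eqn{C_{ij} = \cos(-\Omega\tau^E_{ij} + \Delta_{ij})},
#' \eqn{C^0_{ij} = \cos\Delta_{ij}} and \eqn{H_{ij} = H(\tau^E_{ij})} the
#' (hard) Heaviside of the equilibrium delay. The derivation linearizes the
#' delay dynamics at unit homeostatic rate (\code{alpha_tau = 1}).
#'
#' The rotational symmetry of the network guarantees that the vector of ones
#' is in the kernel at \eqn{\lambda = 0} for any offsets \eqn{\phi}.
#'
#' @param lambda complex eigenvalue candidate.
#' @param Omega locked frequency (rad/s).
#' @param phi length-N offsets (rad).
#' @param params a [model_params()] object.
#' @param topology a [topology()] object.
#' @return complex N x N matrix.
#' @export
mlambda_matrix <- function(lambda, Omega, phi, params, topology) {
  n <- topology$n
  a <- topology$adjacency
  delta <- t(outer(phi, phi, `-`))
  tauE <- equilibrium_delay(delta, params)
  Cij <- cos(-Omega * tauE + delta)
  C0 <- cos(delta)
  Hij <- as.numeric(tauE > 0)
  gn <- params$g / n
  off <- gn * a * Cij * (Omega * params$kappa * C0 * Hij -
                           (lambda + 1) * exp(-lambda * tauE))
  diagterm <- lambda * (lambda + 1) +
    gn * rowSums(a * Cij * (lambda + 1 - Omega * params$kappa * C0 * Hij))
  M <- off
  # self-connections (a_ii = 1) contribute their v_j coupling on the diagonal
  diag(M) <- diagterm + diag(off)
  M
}
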