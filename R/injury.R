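#' Random sparse topology (injured connectivity)
#'
#' Samples the binary adjacency \eqn{a_{ij} = 1 \iff p_{ij} \ge \gamma} with
#' \eqn{p_{ij}} i.i.d. uniform on \eqn{[0,1]}, so each connection survives
#' independently with probability \eqn{1 - \gamma}. \eqn{\gamma = 0} gives
#' the all-to-all network, \eqn{\gamma = 1} the uncoupled one.
#'
#' @param n number of oscillators.
#' @param gamma insult index in \eqn{[0, 1]}.
#' @param seed optional RNG seed for reproducibility.
#' @return a [topology()] object.
#' @export
sparse_topology <- function(n, gamma, seed = NULL) {
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(as.integer(stats::runif(n * n) >= gamma), n, n)
  topology(a, gamma = gamma, seed = seed)
}

#' Injury protocol
#'
#' Defines a mid-run connectivity insult and the averaging windows used to
#' summarize synchronization before and after it. Defaults follow the
#' reference protocol: 320 s runs with injury at 160 s, pre-injury averaging
#' over 148-160 s and post-injury over 304-320 s.
#'
#' @param gamma insult index in \eqn{[0, 1]}.
#' @param t_inj injury time (s).
#' @param t_end total duration (s).
#' @param pre_window,post_window numeric \code{c(start, end)} averaging
#'   windows (s), inside the pre-/post-injury phases respectively.
#' @param seed RNG seed governing both the initial offsets and the injury
#'   sample.
#' @return an object of class \code{"injury_protocol"}.
#' @export
injury_protocol <- function(gamma, t_inj = 160, t_end = 320,
                            pre_window = c(148, 160),
                            post_window = c(304, 320), seed = 1L) {
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
  if (t_inj >= t_end) stop("t_inj must precede t_end")
  if (pre_window[2] > t_inj || pre_window[1] >= pre_window[2])
    stop("pre_window must be a proper interval ending by t_inj")
  if (post_window[1] < t_inj || post_window[2] > t_end ||
      post_window[1] >= post_window[2])
    stop("post_window must be a proper interval within [t_inj, t_end]")
  structure(list(gamma = gamma, t_inj = t_inj, t_end = t_end,
                 pre_window = pre_window, post_window = post_window,
                 seed = seed),
            class = "injury_protocol")
}

#' Run one injury trial
#'
#' Integrates the network from a fixed initial condition, severs connections
#' at \code{protocol$t_inj} (each survives with probability
#' \eqn{1-\gamma}; surviving connections keep their delay state), and
#' summarizes frequency and offset dispersion on the pre- and post-injury
#' windows. Offsets are referenced to \eqn{\hat\Omega_{pre}} before the
#' insult and \eqn{\hat\Omega_{post}} after it.
#'
#' @param params a [model_params()] object (\eqn{g/N} convention).
#' @param protocol an [injury_protocol()].
#' @param ic optional [initial_condition()]; by default offsets are drawn
#'   i.i.d. uniform on \eqn{[-\sqrt3\,\delta_0, \sqrt3\,\delta_0]} with
#'   \eqn{(\Omega_0, \delta_0) = (\omega_0, 0.25)} under
#'   \code{protocol$seed}.
#' @param topo pre-injury topology; defaults to all-to-all with \code{n}.
#' @param n number of oscillators when \code{topo} is NULL (default 50).
#' @param cfg optional [sim_config()]; defaults to dt = 0.005 s over
#'   \code{protocol$t_end}.
#' @param keep_trajectory attach the full trajectory to the result.
#' @return an object of class \code{"injury_outcome"}: list with
#'   \code{Omega_pre}, \code{Omega_post}, \code{delta_pre},
#'   \code{delta_post}, \code{surviving_fraction}, \code{plastic},
#'   \code{gamma}, \code{seed} (and \code{trajectory} if requested).
#' @export
run_injury_trial <- function(params, protocol, ic = NULL, topo = NULL,
                             n = 50, cfg = NULL, keep_trajectory = FALSE) {
  if (is.null(topo)) topo <- dense_topology(n)
  n <- topo$n
  if (is.null(ic)) {
    set.seed(protocol$seed)
    phi0 <- stats::runif(n, -sqrt(3) * 0.25, sqrt(3) * 0.25)
    ic <- initial_condition(params$omega0, phi0)
  }
  if (is.null(cfg))
    cfg <- sim_config(dt = 0.005, t_end = protocol$t_end,
                      record_stride = 4L)
  traj <- simulate_network(params, topo, ic, cfg,
                           injury = list(gamma = protocol$gamma,
                                         t_inj = protocol$t_inj,
                                         seed = protocol$seed + 1L))
  pre <- sync_estimate(traj, protocol$pre_window)
  post <- sync_estimate(traj, protocol$post_window)
  surv <- sum(traj$post_topology$adjacency) / max(1, sum(topo$adjacency))
  out <- structure(list(Omega_pre = pre$Omega_hat,
                        Omega_post = post$Omega_hat,
                        delta_pre = pre$delta_hat,
                        delta_post = post$delta_hat,
                        surviving_fraction = surv,
                        plastic = params$kappa > 0,
                        gamma = protocol$gamma, seed = protocol$seed),
                   class = "injury_outcome")
  if (keep_trajectory) out$trajectory <- traj
  out
}

#' @export
print.injury_outcome <- function(x, ...) {
  cat(sprintf("Injury trial (gamma = %g, %s delays, seed %s)\n", x$gamma,
              if (x$plastic) "plastic" else "fixed", format(x$seed)))
  cat(sprintf("  pre:  Omega_hat = %.4f, delta_hat = %.4f\n",
              x$Omega_pre, x$delta_pre))
  cat(sprintf("  post: Omega_hat = %.4f, delta_hat = %.4f  (%.0f%% of connections survive)\n",
              x$Omega_post, x$delta_post, 100 * x$surviving_fraction))
  invisible(x)
}

#' Sweep the insult index
#'
#' Repeats [run_injury_trial()] over a grid of \eqn{\gamma} values, for the
#' plastic network and (optionally) its fixed-delay counterpart
#' (\eqn{\kappa = 0}), reusing the same initial condition across \eqn{\gamma}
#' for a given seed.
#'
#' @param params a [model_params()] object (the plastic variant).
#' @param gammas vector of insult indices.
#' @param protocol an [injury_protocol()] template (its \code{gamma} is
#'   overridden per trial).
#' @param seeds integer vector of seeds; each (gamma, seed) pair is one
#'   trial.
#' @param ... passed to [run_injury_trial()].
#' @param nonplastic also run the \eqn{\kappa = 0} variant (must be given by
#'   full name; placed after \code{...} so that arguments destined for
#'   [run_injury_trial()], like \code{n}, can never partially match it).
#' @return data frame with one row per trial: \code{gamma}, \code{seed},
#'   \code{plastic}, \code{Omega_pre}, \code{Omega_post}, \code{delta_pre},
#'   \code{delta_post}, \code{surviving_fraction}.
#' @export
gamma_sweep <- function(params, gammas, protocol = injury_protocol(0),
                        seeds = 1L, ..., nonplastic = TRUE) {
  variants <- list(params)
  if (nonplastic)
    variants <- c(variants, list(model_params(
      omega0 = params$omega0, g = params$g, kappa = 0,
      tau0 = params$tau0, alpha_tau = params$alpha_tau,
      eps = params$eps)))
  rows <- list()
  for (p in variants) for (gamma in gammas) for (seed in seeds) {
    pr <- injury_protocol(gamma, t_inj = protocol$t_inj,
                          t_end = protocol$t_end,
                          pre_window = protocol$pre_window,
                          post_window = protocol$post_window,
                          seed = seed)
    out <- run_injury_trial(p, pr, ...)
    rows[[length(rows) + 1L]] <-
      data.frame(gamma = gamma, seed = seed, plastic = out$plastic,
                 Omega_pre = out$Omega_pre, Omega_post = out$Omega_post,
                 delta_pre = out$delta_pre, delta_post = out$delta_post,
                 surviving_fraction = out$surviving_fraction)
  }
  do.call(rbind, rows)
}
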