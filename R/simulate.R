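#' Initial condition for a simulation run
#'
#' Before \eqn{t = 0} the phases follow the linear history
#' \eqn{\varphi_i(t) = \Omega_0 t + \phi^0_i}. By default the history is
#' slope-matched near \eqn{t = 0} so that \eqn{\theta_i'} is continuous at the
#' start of the integration (see [make_initial_function()]).
#'
#' @param Omega0 initial common frequency \eqn{\Omega_0} (rad/s).
#' @param phi0 length-N vector of initial offsets \eqn{\phi^0_i} (rad),
#'   each in \eqn{[-\pi, \pi)}.
#' @param slope_matched replace the last stretch of the linear history by a
#'   C1 patch whose slope at \eqn{0^-} equals the model right-hand side
#'   (default \code{TRUE}).
#' @param include_omega0 include the natural-frequency term in the matching
#'   slope (default \code{TRUE}; \code{FALSE} matches only the coupling term).
#' @return an object of class \code{"initial_condition"}.
#' @export
initial_condition <- function(Omega0, phi0, slope_matched = TRUE,
                              include_omega0 = TRUE) {
  stopifnot(is.numeric(Omega0), length(Omega0) == 1L, is.finite(Omega0),
            is.numeric(phi0), all(is.finite(phi0)))
  if (any(phi0 < -pi | phi0 >= pi))
    stop("initial offsets must lie in [-pi, pi)")
  structure(list(Omega0 = Omega0, phi0 = as.numeric(phi0),
                 slope_matched = isTRUE(slope_matched),
                 include_omega0 = isTRUE(include_omega0)),
            class = "initial_condition")
}

#' Integration settings
#'
#' @param dt step size (s). The integrator is a fixed-step RK4 scheme; the
#'   default 0.005 s resolves the fastest phase dynamics
#'   (\eqn{|\theta'| \le \omega_0 + g}) by two to three orders of magnitude.
#' @param t_end duration of the run (s).
#' @param record_stride steps between stored phase/velocity samples.
#' @param tau_stride steps between stored delay snapshots (delays move on the
#'   slow \eqn{\alpha_\tau} time scale, so the default thinning of 100 loses
#'   nothing of interest while keeping N = 50 trajectories small).
#' @param history_margin extra history buffer (s) beyond the analytic delay
#'   bound \eqn{\tau^0 + \kappa}.
#' @param seed optional RNG seed recorded for provenance.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(dt = 0.005, t_end = 200, record_stride = 1L,
                       tau_stride = 100L, history_margin = 1, seed = NULL) {
  stopifnot(dt > 0, t_end > 0, record_stride >= 1, tau_stride >= 1,
            history_margin >= 0)
  structure(list(dt = dt, t_end = t_end,
                 record_stride = as.integer(record_stride),
                 tau_stride = as.integer(tau_stride),
                 history_margin = history_margin, seed = seed),
            class = "sim_config")
}

#' Construct the (slope-matched) initial history
#'
#' Returns the phase history \eqn{\theta_i(t)} for \eqn{t \le 0} as a
#' function. Away from 0 it is the linear function
#' \eqn{\varphi_i(t) = \Omega_0 t + \phi^0_i}; on \eqn{[-T_p, 0]} (with
#' \eqn{T_p =} \code{dt_patch}) a cubic Hermite segment replaces it so that
#' \eqn{\varphi_i(0) = \phi^0_i} and \eqn{\varphi_i'(0^-)} equals the phase
#' right-hand side evaluated on the unpatched linear history,
#' \deqn{\varphi_i'(0^-) = \omega_0 + (g/N) \sum_j a_{ij}
#'       \sin(-\Omega_0 \tau^0 + \phi^0_j - \phi^0_i).}
#' Without the patch, \eqn{\theta_i'} would jump at \eqn{t = 0} because the
#' imposed history slope \eqn{\Omega_0} need not satisfy the model equations.
#'
#' @param ic an [initial_condition()].
#' @param params a [model_params()] object.
#' @param topology a [topology()] object.
#' @param dt_patch length of the patched interval (s).
#' @return a list with elements \code{fun} (vectorized over \code{t}; returns
#'   a \code{length(t)} x N matrix), \code{slope0} (the matched slopes at
#'   \eqn{0^-}) and \code{dt_patch}.
#' @export
make_initial_function <- function(ic, params, topology, dt_patch = 0.05) {
  n <- topology$n
  if (length(ic$phi0) != n)
    stop("initial offsets have length ", length(ic$phi0),
         " but the topology has ", n, " oscillators")
  Omega0 <- ic$Omega0
  phi0 <- ic$phi0

  # target slope at 0-: model rhs on the unpatched linear history
  delayed <- matrix(-Omega0 * params$tau0 + rep(phi0, each = n), n, n)
  slope0 <- phase_rhs(phi0, delayed, params, topology)
  if (!ic$include_omega0) slope0 <- slope0 - params$omega0
  if (!ic$slope_matched) slope0 <- rep(Omega0, n)

  Tp <- dt_patch
  fun <- function(t) {
    t <- as.numeric(t)
    out <- outer(t, rep(Omega0, n)) + rep(phi0, each = length(t))
    inpatch <- which(t > -Tp & t <= 0)
    if (length(inpatch) > 0 && ic$slope_matched) {
      # cubic Hermite on [-Tp, 0]: value/slope (linear, Omega0) at -Tp,
      # value phi0 and slope slope0 at 0
      s <- (t[inpatch] + Tp) / Tp
      h00 <- (1 + 2 * (1 - s)) * s^2
      h10 <- (s - 1) * s^2
      h01 <- (1 + 2 * s) * (1 - s)^2
      h11 <- s * (1 - s)^2
      for (k in seq_along(inpatch)) {
        i <- inpatch[k]
        out[i, ] <- h01[k] * (-Omega0 * Tp + phi0) + h11[k] * (Tp * Omega0) +
          h00[k] * phi0 + h10[k] * (Tp * slope0)
      }
    }
    out
  }
  list(fun = fun, slope0 = slope0, dt_patch = Tp)
}

#' Integrate the adaptive-delay Kuramoto network
#'
#' Fixed-step RK4 integration of the coupled N-phase / N^2-delay system.
#' Delayed phases are obtained by linear interpolation into the accumulated
#' solution history; within a step, each lag is frozen at its start-of-step
#' value (delays move on the slow \eqn{\alpha_\tau} time scale). Delays are
#' clamped at zero after every step to suppress floating-point undershoot
#' below the smoothed-Heaviside floor.
#'
#' @param params a [model_params()] object.
#' @param topology a [topology()] object.
#' @param ic an [initial_condition()] (its offset count must match the
#'   topology).
#' @param cfg a [sim_config()].
#' @param injury optional list with elements \code{gamma}, \code{t_inj} and
#'   optionally \code{seed}: at the first step with \eqn{t \ge t_{inj}} the
#'   adjacency is masked by an i.i.d. Bernoulli(\eqn{1-\gamma}) sample
#'   (connection \eqn{ij} survives iff \eqn{p_{ij} \ge \gamma}); phases and
#'   surviving delays continue unchanged.
#' @return an object of class \code{"kuramoto_trajectory"}: a list with
#'   \code{times}, \code{theta} (T x N, unwrapped), \code{dtheta} (T x N),
#'   \code{tau_times}, \code{tau} (N x N x K array), \code{events},
#'   \code{params}, \code{topology}, \code{post_topology}, \code{ic},
#'   \code{cfg}.
#' @export
simulate_network <- function(params, topology, ic, cfg = sim_config(),
                             injury = NULL) {
  n <- topology$n
  horizon <- params$tau0 + params$kappa + cfg$history_margin
  n_hist <- max(1L, as.integer(ceiling(horizon / cfg$dt)))
  n_steps <- as.integer(round(cfg$t_end / cfg$dt))

  hist <- make_initial_function(ic, params, topology,
                                dt_patch = 10 * cfg$dt)
  tgrid <- seq(-n_hist, 0) * cfg$dt
  theta_hist <- hist$fun(tgrid)

  A_pre <- topology$adjacency
  A_post <- A_pre
  t_inj <- Inf
  events <- list()
  post_topology <- topology
  if (!is.null(injury)) {
    if (is.null(injury$gamma) || injury$gamma < 0 || injury$gamma > 1)
      stop("injury$gamma must lie in [0, 1]")
    if (is.null(injury$t_inj) || injury$t_inj < 0 || injury$t_inj > cfg$t_end)
      stop("injury$t_inj must lie within the simulation window")
    t_inj <- injury$t_inj
    if (!is.null(injury$seed)) set.seed(injury$seed)
    mask <- matrix(as.integer(stats::runif(n * n) >= injury$gamma), n, n)
    A_post <- A_pre * mask
    post_topology <- topology(A_post, gamma = injury$gamma,
                              seed = injury$seed)
    events <- list(list(time = t_inj, label = "injury",
                        gamma = injury$gamma))
  }

  tau_init <- matrix(params$tau0, n, n)
  tau_base <- matrix(params$tau0, n, n)

  res <- integrate_core(theta_hist, tau_init, tau_base,
                        params$omega0, params$g, params$kappa,
                        params$alpha_tau, params$eps,
                        A_pre, A_post, t_inj,
                        cfg$dt, n_steps, cfg$record_stride, cfg$tau_stride)

  tau_arr <- array(t(res$tau), dim = c(n, n, length(res$tau_times)))
  structure(list(times = res$times, theta = res$theta, dtheta = res$dtheta,
                 tau_times = res$tau_times, tau = tau_arr,
                 events = events, params = params, topology = topology,
                 post_topology = post_topology, ic = ic, cfg = cfg),
            class = "kuramoto_trajectory")
}

#' @export
print.kuramoto_trajectory <- function(x, ...) {
  cat(sprintf("Kuramoto trajectory: N = %d oscillators, t in [0, %g] s (%d samples)\n",
              x$topology$n, max(x$times), length(x$times)))
  if (length(x$events) > 0)
    for (e in x$events)
      cat(sprintf("  event: %s at t = %g s (gamma = %g)\n",
                  e$label, e$time, e$gamma))
  invisible(x)
}

#' Tidy long-format export of a trajectory
#'
#' @param x a \code{"kuramoto_trajectory"}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a data frame with columns \code{time}, \code{oscillator},
#'   \code{theta}, \code{dtheta}.
#' @export
as.data.frame.kuramoto_trajectory <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  n <- x$topology$n
  tt <- length(x$times)
  data.frame(time = rep(x$times, n),
             oscillator = rep(seq_len(n), each = tt),
             theta = as.vector(x$theta),
             dtheta = as.vector(x$dtheta))
}

#' Summary of active delays over time
#'
#' Quantiles of the delays on existing connections at each stored delay
#' snapshot, as a data frame (connections removed by an injury event are
#' excluded from snapshots after the event).
#'
#' @param traj a \code{"kuramoto_trajectory"}.
#' @param probs quantile probabilities.
#' @return data frame with one row per snapshot.
#' @export
delay_summary <- function(traj, probs = c(0, 0.25, 0.5, 0.75, 1)) {
  pre <- traj$topology$adjacency == 1L
  post <- traj$post_topology$adjacency == 1L
  t_inj <- if (length(traj$events)) traj$events[[1]]$time else Inf
  out <- lapply(seq_along(traj$tau_times), function(k) {
    act <- if (traj$tau_times[k] >= t_inj) post else pre
    q <- stats::quantile(traj$tau[, , k][act], probs = probs, names = FALSE)
    c(time = traj$tau_times[k], stats::setNames(q, paste0("q", probs)))
  })
  as.data.frame(do.call(rbind, out))
}
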