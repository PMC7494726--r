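#' Wrap angles to [-pi, pi)
#'
#' @param x angles (rad); vectorized.
#' @return wrapped angles.
#' @export
wrap_phase <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Estimate the global synchronization frequency
#'
#' Per-oscillator asymptotic frequencies are the time averages of the phase
#' velocities over a tail window,
#' \eqn{\hat\Omega_i = h^{-1} \int_t^{t+h} \theta_i'(s)\, ds}
#' (trapezoidal rule on the recorded grid), and the global estimate is their
#' sample mean \eqn{\hat\Omega = N^{-1} \sum_i \hat\Omega_i}.
#'
#' @param traj a \code{"kuramoto_trajectory"}.
#' @param window length of the tail window \eqn{h} (s), or a numeric vector
#'   \code{c(t_start, t_end)} giving the window explicitly.
#' @return a list with \code{Omega_hat} (scalar) and \code{Omega_hat_i}
#'   (length-N vector), both in rad/s, plus the \code{window} used.
#' @export
estimate_frequency <- function(traj, window) {
  w <- resolve_window(traj$times, window)
  idx <- which(traj$times >= w[1] - 1e-9 & traj$times <= w[2] + 1e-9)
  if (length(idx) < 2)
    stop("estimation window [", w[1], ", ", w[2],
         "] contains fewer than two samples")
  tt <- traj$times[idx]
  Omega_i <- apply(traj$dtheta[idx, , drop = FALSE], 2, trapz_mean, t = tt)
  list(Omega_hat = mean(Omega_i), Omega_hat_i = Omega_i, window = w)
}

#' Estimate asymptotic phase offsets and their dispersion
#'
#' Offsets are the tail averages of \eqn{\hat\phi_i(t) = \theta_i(t) -
#' \hat\Omega t}, wrapped to \eqn{[-\pi, \pi)}. Because wrapping can split a
#' tight cluster across the \eqn{\pm\pi} seam, the offsets are re-centered by
#' their circular mean before the \eqn{(N-1)}-denominator sample variance
#' \eqn{\hat\delta^2} is computed; the reported offsets and mean offset
#' \eqn{\bar\phi} are mapped back afterwards.
#'
#' @param traj a \code{"kuramoto_trajectory"}.
#' @param Omega_hat estimated global frequency (rad/s).
#' @param window tail window as in [estimate_frequency()].
#' @return an object of class \code{"sync_estimate"}: list with
#'   \code{Omega_hat}, \code{phi_hat} (in \eqn{[-\pi,\pi)}), \code{phi_bar},
#'   \code{delta2_hat}, \code{delta_hat}, \code{window}.
#' @export
estimate_offsets <- function(traj, Omega_hat, window) {
  stopifnot(is.finite(Omega_hat))
  w <- resolve_window(traj$times, window)
  idx <- which(traj$times >= w[1] - 1e-9 & traj$times <= w[2] + 1e-9)
  if (length(idx) < 2)
    stop("estimation window contains fewer than two samples")
  tt <- traj$times[idx]
  resid <- traj$theta[idx, , drop = FALSE] - Omega_hat * tt
  phi_raw <- apply(resid, 2, trapz_mean, t = tt)
  phi_wrapped <- wrap_phase(phi_raw)
  mu <- atan2(mean(sin(phi_wrapped)), mean(cos(phi_wrapped)))
  centered <- wrap_phase(phi_wrapped - mu)
  n <- length(centered)
  delta2 <- if (n > 1) sum((centered - mean(centered))^2) / (n - 1) else 0
  structure(list(Omega_hat = Omega_hat,
                 phi_hat = wrap_phase(centered + mu),
                 phi_bar = wrap_phase(mean(centered) + mu),
                 delta2_hat = delta2, delta_hat = sqrt(delta2),
                 window = w),
            class = "sync_estimate")
}

#' One-call trajectory summary
#'
#' Convenience wrapper running [estimate_frequency()] then
#' [estimate_offsets()] on the same tail window.
#'
#' @param traj a \code{"kuramoto_trajectory"}.
#' @param window tail window (length in s, or \code{c(t_start, t_end)}).
#' @return a \code{"sync_estimate"} (with \code{Omega_hat_i} attached).
#' @export
sync_estimate <- function(traj, window) {
  fr <- estimate_frequency(traj, window)
  est <- estimate_offsets(traj, fr$Omega_hat, window)
  est$Omega_hat_i <- fr$Omega_hat_i
  est
}

#' @export
print.sync_estimate <- function(x, ...) {
  cat(sprintf("Synchronization estimate over t in [%g, %g] s\n",
              x$window[1], x$window[2]))
  cat(sprintf("  Omega_hat = %.4f rad/s, delta_hat = %.4f rad (delta2 = %.3g)\n",
              x$Omega_hat, x$delta_hat, x$delta2_hat))
  if (length(x$phi_hat) == 2)
    cat(sprintf("  Delta12_hat = %.4f rad\n",
                wrap_phase(x$phi_hat[2] - x$phi_hat[1])))
  invisible(x)
}

#' Match an estimated frequency to theoretical candidates
#'
#' Returns the unique candidate frequency within \code{tol} of
#' \eqn{\hat\Omega} (strict inequality), \code{NA} if none matches, and an
#' error if the match is ambiguous.
#'
#' @param estimate a \code{"sync_estimate"} or a numeric \eqn{\hat\Omega}.
#' @param candidates numeric vector of theoretical frequencies (rad/s).
#' @param tol matching tolerance (rad/s); default \code{5e-3}.
#' @return the matched candidate value, or \code{NA_real_}.
#' @export
classify_convergence <- function(estimate, candidates, tol = 5e-3) {
  if (inherits(estimate, "sync_estimate")) estimate <- estimate$Omega_hat
  if (length(candidates) == 0) stop("candidate list is empty")
  hit <- which(abs(estimate - candidates) < tol)
  if (length(hit) == 0) return(NA_real_)
  if (length(hit) > 1)
    stop("ambiguous match: ", length(hit), " candidates within ", tol,
         " of Omega_hat = ", estimate)
  candidates[hit]
}

# --- internal helpers -------------------------------------------------------

# time average by trapezoidal rule
trapz_mean <- function(y, t) {
  h <- diff(t)
  sum(h * (y[-1] + y[-length(y)]) / 2) / (t[length(t)] - t[1])
}

resolve_window <- function(times, window) {
  t_end <- times[length(times)]
  if (length(window) == 1) {
    if (window <= 0) stop("window length must be positive")
    c(t_end - window, t_end)
  } else if (length(window) == 2) {
    if (window[2] <= window[1]) stop("empty estimation window")
    window
  } else stop("'window' must have length 1 or 2")
}
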