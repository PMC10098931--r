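#' @name smoothing
#' @title Trajectory smoothing: EM state-space smoother and zero-phase Butterworth
#'
#' @description
#' Detector output jitters frame to frame; valley finding on jittery
#' trajectories produces spurious cycles. Two smoothers are provided. The
#' EM smoother fits a local-level (random-walk plus observation noise)
#' state-space model per coordinate track, estimating the process and
#' observation variances by expectation-maximization and returning the
#' posterior-mean state path -- the minimal model that separates jitter
#' from motion without assuming a cutoff. The Butterworth smoother is a
#' fixed low-pass design (default third order, 14 Hz cutoff) run
#' forward-backward for zero phase so valley locations are not delayed.
NULL

#' EM smoothing of a scalar track
#'
#' Fits `y_t = mu_t + eps_t`, `mu_t = mu_{t-1} + eta_t` with
#' `eps ~ N(0, r)`, `eta ~ N(0, q)` by EM (Kalman filter/smoother E-step,
#' closed-form variance M-step) and returns the smoothed state means. The
#' log-likelihood is non-decreasing across iterations; the trace is
#' returned so callers can assert it. Constant input is returned
#' unchanged with a warning (the observation variance degenerates).
#'
#' @param track numeric vector, length >= 10, finite.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood improves by less than this.
#' @return list with `smoothed` (posterior state means), `fit` (a list
#'   with `process_var`, `obs_var`, `loglik_trace`, `iterations`).
#' @export
em_smooth <- function(track, max_iter = 50, tol = 1e-6) {
  x <- as.numeric(track)
  n <- length(x)
  if (n < 10) stop("em_smooth needs at least 10 samples")
  if (any(!is.finite(x))) stop("track must be finite")
  if (stats::var(x) == 0) {
    warning("constant input: observation variance degenerate, returning input")
    return(list(smoothed = x,
                fit = list(process_var = 0, obs_var = 0,
                           loglik_trace = numeric(0), iterations = 0L)))
  }
  # crude initial split of the sample variance between the two noises
  d <- diff(x)
  r <- max(stats::var(d) / 2, 1e-10)
  q <- max(stats::var(d) - r, 1e-10)
  m1 <- x[1]
  P1 <- stats::var(x)   # fixed prior spread for the initial level
  trace <- numeric(0)
  sm <- NULL
  for (iter in seq_len(max_iter)) {
    e <- kalman_local_level(x, q, r, m1, P1)
    trace <- c(trace, e$loglik)
    sm <- e
    # M step: closed-form variance updates from smoothed moments
    r_new <- mean((x - e$mu)^2 + e$V)
    dmu <- diff(e$mu)
    q_new <- mean(dmu^2 + e$V[-1] + e$V[-n] - 2 * e$Vlag)
    m1 <- e$mu[1]
    q <- max(q_new, 1e-12)
    r <- max(r_new, 1e-12)
    if (iter > 1 && abs(trace[iter] - trace[iter - 1]) < tol) break
  }
  list(smoothed = sm$mu,
       fit = list(process_var = q, obs_var = r,
                  loglik_trace = trace, iterations = length(trace)))
}

# Kalman filter + RTS smoother for the local-level model, with lag-one
# smoothed covariances and the prediction-error log-likelihood.
kalman_local_level <- function(x, q, r, m1, P1) {
  n <- length(x)
  af <- Pf <- ap <- Pp <- K <- numeric(n)
  ll <- 0
  for (t in seq_len(n)) {
    if (t == 1) { ap[t] <- m1; Pp[t] <- P1 }
    else { ap[t] <- af[t - 1]; Pp[t] <- Pf[t - 1] + q }
    S <- Pp[t] + r
    v <- x[t] - ap[t]
    K[t] <- Pp[t] / S
    af[t] <- ap[t] + K[t] * v
    Pf[t] <- (1 - K[t]) * Pp[t]
    ll <- ll - 0.5 * (log(2 * pi * S) + v^2 / S)
  }
  mu <- af; V <- Pf
  J <- numeric(n)
  for (t in (n - 1):1) {
    J[t] <- Pf[t] / (Pf[t] + q)
    mu[t] <- af[t] + J[t] * (mu[t + 1] - af[t])
    V[t] <- Pf[t] + J[t]^2 * (V[t + 1] - Pp[t + 1])
  }
  # lag-one smoothed covariances Cov(mu_t, mu_{t-1} | y_1..n), t = 2..n,
  # by the standard backward recursion started from the filtered value at n
  Vlag <- numeric(n - 1)
  Vlag[n - 1] <- (1 - K[n]) * Pf[n - 1]
  if (n > 2) {
    for (t in (n - 1):2) {
      Vlag[t - 1] <- J[t - 1] * (Pf[t] + J[t] * (Vlag[t] - Pf[t]))
    }
  }
  list(mu = mu, V = V, Vlag = Vlag, loglik = ll)
}

#' Analog Butterworth squared-magnitude response
#'
#' `|H(w)|^2 = 1 / (1 + (w / wc)^(2n))`: unit gain at DC, exactly 1/2 at
#' the cutoff for every order, monotone non-increasing in frequency.
#'
#' @param w frequency in Hz (vectorized, >= 0).
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order n.
#' @return squared magnitude gain(s) in (0, 1].
#' @export
butterworth_gain <- function(w, cutoff = 14, order = 3) {
  stopifnot(all(w >= 0), cutoff > 0, order >= 1)
  1 / (1 + (w / cutoff)^(2 * order))
}

#' Filter specification
#'
#' @param order filter order (default 3: lower orders leave jitter, higher
#'   ones flatten genuine valleys).
#' @param cutoff cutoff frequency in Hz (default 14).
#' @param fs sampling rate in Hz; must exceed twice the cutoff.
#' @param zero_phase run the filter forward and backward (default), which
#'   removes group delay (valley frames are not shifted) and squares the
#'   magnitude response.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(order = 3, cutoff = 14, fs, zero_phase = TRUE) {
  if (order < 1) stop("order must be >= 1")
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("spec error: cutoff must lie in (0, fs/2)")
  }
  structure(list(order = order, cutoff = cutoff, fs = fs,
                 zero_phase = zero_phase), class = "filter_spec")
}

#' Low-pass Butterworth filtering of a track
#'
#' Digital realization of the analog Butterworth prototype via the
#' bilinear transform with pre-warped cutoff (as designed by
#' `signal::butter`). By default the filter runs forward then backward
#' (zero phase); reflective padding of three filter lengths at each end
#' suppresses edge transients. Output length equals input length; a DC
#' (constant) input passes unchanged.
#'
#' @param track numeric vector.
#' @param spec a [filter_spec()].
#' @return filtered numeric vector.
#' @export
butterworth_filter <- function(track, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  x <- as.numeric(track)
  n <- length(x)
  if (n == 0) return(x)
  bf <- signal::butter(spec$order, spec$cutoff / (spec$fs / 2), type = "low")
  # generous reflective padding: IIR startup transients must decay below
  # double precision before the kept samples begin
  npad <- min(n - 1L, max(30L * (max(length(bf$b), length(bf$a)) - 1L), 90L))
  if (npad < 1L) return(x)
  # odd (point-symmetric) reflection keeps slopes continuous at the ends
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(pre, x, post)
  yp <- as.numeric(signal::filter(bf, xp))
  if (spec$zero_phase) {
    yp <- rev(as.numeric(signal::filter(bf, rev(yp))))
  }
  yp[(npad + 1):(npad + n)]
}
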