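#' Ordinary least-squares quadratic fit to observed trajectory samples
#'
#' Fits \code{x(t) = c0 + c1 t + c2 t^2} to the noisy pre-occluder samples by
#' least squares. The residual variance is \code{s^2 = RSS / (n - 3)}.
#'
#' @param times sample times (seconds, distinct, length >= 4).
#' @param obs_x observed horizontal positions.
#' @return an object of class \code{quad_fit}: coefficients, \code{s2},
#'   normal-equations matrix \code{XtX}, its inverse, and \code{n}.
#' @export
fit_quadratic_ols <- function(times, obs_x) {
  n <- length(times)
  if (n < 4L)
    stop("need at least 4 observed samples for a quadratic fit with residual df",
         call. = FALSE)
  stopifnot(length(obs_x) == n, all(is.finite(times)), all(is.finite(obs_x)))
  X <- cbind(1, times, times^2)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("rank-deficient design: times must contain >= 3 distinct values",
         call. = FALSE)
  coefs <- qr.coef(qx, obs_x)
  resid <- obs_x - X %*% coefs
  rss <- sum(resid^2)
  XtX <- crossprod(X)
  structure(list(coefficients = as.numeric(coefs),
                 s2 = rss / (n - 3),
                 rss = rss,
                 XtX = XtX,
                 XtX_inv = chol2inv(chol(XtX)),
                 n = n),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("quadratic fit (n=%d): x(t) = %.4f + %.4f t + %.5f t^2; s = %.4g\n",
              x$n, x$coefficients[1], x$coefficients[2], x$coefficients[3],
              sqrt(x$s2)))
  invisible(x)
}

#' Dynamic-model endpoint estimate from a quadratic fit
#'
#' Extrapolates the fitted parabola to the occluder exit time and reports the
#' standard error of the fitted value there: \code{sigma_d = sqrt(v * h' (X'X)^-1 h)}
#' with \code{h = (1, t_end, t_end^2)}. This is the SE of the estimated
#' landing point (the true endpoint lies on the smooth curve), not a
#' prediction interval for a new noisy sample. By default \code{v} is the
#' estimated residual variance \code{s^2}; pass \code{noise_sd} to use the
#' known generative noise variance instead (used by the sequential-model
#' equivalence analysis).
#'
#' @param fit a [fit_quadratic_ols()] result.
#' @param t_end extrapolation time (seconds).
#' @param noise_sd optional known noise SD overriding the estimated \code{s}.
#' @return a [gaussian_belief()] with role \code{"dynamic"}.
#' @export
endpoint_estimate <- function(fit, t_end, noise_sd = NULL) {
  stopifnot(inherits(fit, "quad_fit"), is.finite(t_end))
  h <- c(1, t_end, t_end^2)
  v <- if (is.null(noise_sd)) fit$s2 else noise_sd^2
  mu_d <- sum(h * fit$coefficients)
  sigma_d <- sqrt(v * drop(t(h) %*% fit$XtX_inv %*% h))
  gaussian_belief(mu_d, sigma_d, role = "dynamic")
}

#' Sequential trajectory estimation with the statistical belief as a prior
#'
#' Re-expresses prior knowledge of the endpoint distribution as one
#' pseudo-observation of the landing point: weighted least squares on the
#' first \code{k} trajectory samples (weights \code{1/noise_sd^2}) augmented
#' with the datum \code{(t_end, prior$mu)} of SD \code{prior$sigma}. With all
#' samples included, the fitted value at \code{t_end} equals the
#' precision-weighted combination of the prior-free (known-variance) dynamic
#' estimate with the prior — the two routes to a combined prediction agree
#' exactly at the endpoint.
#'
#' @param times,obs_x observed sample times and positions.
#' @param prior a [gaussian_belief()] (statistical prediction).
#' @param noise_sd known observation-noise SD (> 0).
#' @param t_end occluder exit time.
#' @param k number of leading samples to use (default: all; minimum 3).
#' @return a [gaussian_belief()] with role \code{"combined"}: fitted value
#'   and SE at \code{t_end} after \code{k} samples.
#' @export
sequential_estimate_with_prior <- function(times, obs_x, prior, noise_sd,
                                           t_end, k = length(times)) {
  stopifnot(inherits(prior, "gaussian_belief"))
  if (prior$sigma <= 0) stop("prior$sigma must be positive", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (k < 3L) stop("need k >= 3 observed samples", call. = FALSE)
  t_k <- times[seq_len(k)]
  y_k <- obs_x[seq_len(k)]
  X <- rbind(cbind(1, t_k, t_k^2), c(1, t_end, t_end^2))
  y <- c(y_k, prior$mu)
  w <- c(rep(1 / noise_sd^2, k), 1 / prior$sigma^2)
  # solve via QR of the square-root-weighted design; stable even for
  # near-degenerate priors where the normal equations are ill-conditioned
  sw <- sqrt(w)
  qx <- qr(X * sw, tol = 1e-14)
  if (qx$rank < 3L) stop("rank-deficient weighted design", call. = FALSE)
  beta <- qr.coef(qx, y * sw)
  h <- c(1, t_end, t_end^2)
  # weights are exact inverse variances, so cov(beta) = (X'WX)^-1 = (R'R)^-1
  R <- qr.R(qx)
  piv <- qx$pivot
  z <- backsolve(R, h[piv], transpose = TRUE)
  gaussian_belief(drop(sum(h * beta)), sqrt(sum(z^2)), role = "combined")
}

#' Run the dynamic model over a session
#'
#' Fits the quadratic to each trial's observed samples and extrapolates to
#' the occluder exit time (\code{traj_duration_s}, with \code{t = 0} at the
#' first sample). Noise-free warmup trials get \code{sigma_d = 0} exactly.
#'
#' @param session a \code{traj_session}.
#' @param noise_sd_mode \code{"estimated"} (default; SE uses the fitted
#'   residual variance, as available to a participant) or \code{"known"}
#'   (SE uses the generative per-trial noise SD).
#' @return a data.frame with columns \code{trial}, \code{mu_d},
#'   \code{sigma_d}, \code{log_prec_dyn} (\code{Inf} on noise-free trials).
#' @export
run_dynamic <- function(session, noise_sd_mode = c("estimated", "known")) {
  stopifnot(inherits(session, "traj_session"))
  noise_sd_mode <- match.arg(noise_sd_mode)
  tr <- session$trials
  n <- nrow(tr)
  mu_d <- sigma_d <- numeric(n)
  for (i in seq_len(n)) {
    obs <- observed_samples(session, tr$trial[i])
    fit <- fit_quadratic_ols(obs$t, obs$obs_x)
    nz <- tr$sigma_noise[i]
    b <- if (noise_sd_mode == "known")
      endpoint_estimate(fit, session$config$traj_duration_s, noise_sd = nz)
    else
      endpoint_estimate(fit, session$config$traj_duration_s)
    mu_d[i] <- b$mu
    # noise-free trials carry no estimation error: pin the SE at exactly 0
    sigma_d[i] <- if (tr$is_noisefree[i]) 0 else b$sigma
  }
  data.frame(trial = tr$trial, mu_d = mu_d, sigma_d = sigma_d,
             log_prec_dyn = log(1 / sigma_d^2))
}
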