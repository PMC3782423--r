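#' Sample the non-stationary generative environment
#'
#' Draws the per-trial parameters of the Gaussian endpoint distribution. Each
#' parameter (mean, SD) holds its value for a gap drawn uniformly on the
#' integers \code{[jump_gap_min, jump_gap_max]}, then jumps to a fresh value:
#' means are redrawn uniformly on \code{mean_range}, SDs log-uniformly on
#' \code{sd_range}. The two parameters jump independently.
#'
#' Uses the current RNG state; call \code{set.seed()} first for
#' reproducibility.
#'
#' @param config a [task_config()].
#' @return a data.frame with one row per trial and columns \code{trial},
#'   \code{mu_gen}, \code{sigma_gen}, \code{jump_mean}, \code{jump_sd}
#'   (logical flags marking trials on which the parameter took a new value;
#'   trial 1 is the initial draw, not a jump).
#' @export
sample_environment <- function(config) {
  validate_task_config(config)
  n <- config$n_trials
  draw_mean <- function() stats::runif(1, config$mean_range[1], config$mean_range[2])
  draw_sd <- function() runif_log(1, config$sd_range[1], config$sd_range[2])
  piece <- function(draw) {
    val <- numeric(n)
    jump <- logical(n)
    i <- 1L
    current <- draw()
    repeat {
      gap <- sample.int(config$jump_gap_max - config$jump_gap_min + 1L, 1L) +
        config$jump_gap_min - 1L
      j <- min(i + gap - 1L, n)
      val[i:j] <- current
      if (j == n) break
      i <- j + 1L
      current <- draw()
      jump[i] <- TRUE
    }
    list(val = val, jump = jump)
  }
  m <- piece(draw_mean)
  s <- piece(draw_sd)
  data.frame(trial = seq_len(n),
             mu_gen = m$val, sigma_gen = s$val,
             jump_mean = m$jump, jump_sd = s$jump)
}

# log-uniform draw on [lo, hi]; degenerates gracefully when lo == hi
runif_log <- function(n, lo, hi) {
  if (lo == hi) return(rep(lo, n))
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Sample one trial of the trajectory task
#'
#' Draws an endpoint from \code{N(mu_gen, sigma_gen^2)} (resampled, not
#' clipped, if off screen), a horizontal acceleration uniformly on
#' \code{[-accel_max, accel_max]}, and a start point uniformly on the screen;
#' the initial velocity is then solved so the parabola passes through the
#' endpoint at the final sample time. Candidate (start, acceleration) pairs
#' producing any off-screen position are rejected and redrawn, so a given
#' endpoint remains compatible with many trajectories and neither start point
#' nor curvature alone predicts it. Gaussian observation noise of SD
#' \code{sigma_noise} is added to the horizontal coordinate of the observed
#' (pre-occluder) samples only.
#'
#' @param mu_gen,sigma_gen generative endpoint mean and SD for this trial.
#' @param config a [task_config()].
#' @param sigma_noise per-sample observation-noise SD (0 for noise-free
#'   trials).
#' @param noisefree_flag logical; marks a warmup trial (forces
#'   \code{sigma_noise = 0}).
#' @param max_attempts rejection-sampling cap for endpoints and trajectories.
#' @return a list with elements \code{x_end}, \code{accel}, \code{x0},
#'   \code{v0}, \code{times}, \code{true_x}, \code{obs_x} (NA beyond the
#'   occluder), \code{observed} (logical), \code{sigma_noise},
#'   \code{is_noisefree}.
#' @export
sample_trial <- function(mu_gen, sigma_gen, config, sigma_noise = 0,
                         noisefree_flag = FALSE, max_attempts = 1000L) {
  validate_task_config(config)
  stopifnot(is.finite(mu_gen), is.finite(sigma_gen), sigma_gen >= 0)
  if (noisefree_flag) sigma_noise <- 0
  sw <- config$screen_width
  T_end <- config$traj_duration_s
  times <- seq(0, T_end, length.out = config$traj_n_samples)

  x_end <- NA_real_
  for (a in seq_len(max_attempts)) {
    cand <- stats::rnorm(1, mu_gen, sigma_gen)
    if (cand >= 0 && cand <= sw) { x_end <- cand; break }
  }
  if (is.na(x_end))
    stop(sprintf("endpoint rejection failed after %d attempts (mu_gen=%.3f, sigma_gen=%.3f)",
                 max_attempts, mu_gen, sigma_gen), call. = FALSE)

  ok <- FALSE
  for (a in seq_len(max_attempts)) {
    accel <- stats::runif(1, -config$accel_max, config$accel_max)
    x0 <- stats::runif(1, 0, sw)
    v0 <- (x_end - x0 - 0.5 * accel * T_end^2) / T_end
    true_x <- x0 + v0 * times + 0.5 * accel * times^2
    if (all(true_x >= 0 & true_x <= sw)) { ok <- TRUE; break }
  }
  if (!ok)
    stop(sprintf("trajectory rejection failed after %d attempts (x_end=%.3f, accel_max=%.4f)",
                 max_attempts, x_end, config$accel_max), call. = FALSE)

  n_obs <- round(config$observed_fraction * config$traj_n_samples)
  observed <- seq_along(times) <= n_obs
  obs_x <- rep(NA_real_, length(times))
  obs_x[observed] <- true_x[observed] +
    stats::rnorm(n_obs, 0, sigma_noise)

  list(x_end = x_end, accel = accel, x0 = x0, v0 = v0,
       times = times, true_x = true_x, obs_x = obs_x, observed = observed,
       sigma_noise = sigma_noise, is_noisefree = isTRUE(noisefree_flag))
}

#' Generate a full task session
#'
#' Samples the generative environment and one trajectory per trial. The first
#' \code{n_warmup_noisefree} trials are noise-free and flagged as excluded
#' from analysis. Per-trial observation-noise SDs are drawn log-uniformly on
#' \code{noise_sd_range} and then rescaled by a single session-wide factor so
#' that the mean noise SD over analysis trials equals
#' \code{noise_calibration_ratio} times the mean generative endpoint SD over
#' analysis trials.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed; if supplied the session is a
#'   deterministic function of \code{(config, seed)}.
#' @return an object of class \code{traj_session}: a list with \code{config},
#'   \code{environment} (per-trial generative parameters), \code{trials}
#'   (per-trial scalars), \code{samples} (long per-sample table) and
#'   \code{seed}.
#' @export
generate_session <- function(config = task_config(), seed = NULL) {
  validate_task_config(config)
  if (!is.null(seed)) set.seed(seed)
  env <- sample_environment(config)
  n <- config$n_trials
  warm <- seq_len(n) <= config$n_warmup_noisefree
  analysis <- !warm

  sigma_noise <- runif_log(n, config$noise_sd_range[1], config$noise_sd_range[2])
  sigma_noise[warm] <- 0
  if (any(analysis) && mean(sigma_noise[analysis]) > 0) {
    target <- config$noise_calibration_ratio * mean(env$sigma_gen[analysis])
    sigma_noise[analysis] <- sigma_noise[analysis] *
      target / mean(sigma_noise[analysis])
  }

  trials <- vector("list", n)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- sample_trial(env$mu_gen[i], env$sigma_gen[i], config,
                       sigma_noise = sigma_noise[i], noisefree_flag = warm[i])
    trials[[i]] <- data.frame(
      trial = i, x_end = tr$x_end, accel = tr$accel, x0 = tr$x0, v0 = tr$v0,
      sigma_noise = tr$sigma_noise, mu_gen = env$mu_gen[i],
      sigma_gen = env$sigma_gen[i], is_noisefree = tr$is_noisefree,
      is_analysis = analysis[i])
    samples[[i]] <- data.frame(
      trial = i, k = seq_along(tr$times), t = tr$times,
      true_x = tr$true_x, obs_x = tr$obs_x, observed = tr$observed)
  }
  session <- list(config = config,
                  environment = env,
                  trials = do.call(rbind, trials),
                  samples = do.call(rbind, samples),
                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  class(session) <- "traj_session"
  session
}

#' @export
print.traj_session <- function(x, ...) {
  cat(sprintf("traj_session: %d trials (%d analysis), seed %s\n",
              nrow(x$trials), sum(x$trials$is_analysis),
              ifelse(is.na(x$seed), "<none>", x$seed)))
  cat(sprintf("  noise calibration ratio: %.4f\n", noise_calibration_ratio(x)))
  invisible(x)
}

#' Observation-noise calibration ratio of a session
#'
#' Ratio of the mean per-sample observation-noise SD to the mean generative
#' endpoint SD, both taken over the analysis (non-warmup) trials. Sessions
#' built by [generate_session()] are rescaled to hit the configured target
#' (0.67 by default).
#'
#' @param session a \code{traj_session}.
#' @return a single non-negative number.
#' @export
noise_calibration_ratio <- function(session) {
  stopifnot(inherits(session, "traj_session"))
  a <- session$trials$is_analysis
  if (!any(a)) stop("session has no analysis trials", call. = FALSE)
  mean(session$trials$sigma_noise[a]) / mean(session$trials$sigma_gen[a])
}

#' Observed samples of one trial
#'
#' @param session a \code{traj_session}.
#' @param trial trial index.
#' @return a data.frame with columns \code{t} and \code{obs_x} for the
#'   pre-occluder samples of that trial.
#' @export
observed_samples <- function(session, trial) {
  s <- session$samples
  s <- s[s$trial == trial & s$observed, c("t", "obs_x")]
  if (nrow(s) == 0L) stop("no such trial: ", trial, call. = FALSE)
  s
}
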