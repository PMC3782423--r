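#' Configuration for the occluded-trajectory task generator
#'
#' Builds and validates the generative configuration for a session of the
#' trajectory-extrapolation task. All positions are expressed as fractions of
#' the horizontal screen width (so the screen spans \code{[0, 1]}), and times
#' in seconds. A target moves down the screen along a parabolic path (constant
#' horizontal acceleration); the final part of the path is occluded and the
#' observer must predict the horizontal coordinate at which the target lands.
#' Across trials, landing points are drawn from a Gaussian distribution whose
#' mean and standard deviation each jump to fresh values at independent,
#' uniformly distributed intervals of \code{jump_gap_min} to
#' \code{jump_gap_max} trials.
#'
#' @param n_trials number of trials in a session (default 220).
#' @param jump_gap_min,jump_gap_max bounds (in trials) on the gap between
#'   successive jumps of each generative parameter (defaults 20 and 40).
#' @param mean_range interval from which a fresh generative mean is drawn
#'   (uniformly) after a mean jump.
#' @param sd_range interval from which a fresh generative SD is drawn
#'   (log-uniformly) after an SD jump, in screen widths.
#' @param noise_sd_range interval from which the per-trial observation-noise
#'   SD is drawn (log-uniformly) before calibration rescaling.
#' @param noise_calibration_ratio target ratio of the session-mean observation
#'   noise SD to the session-mean generative endpoint SD, computed over
#'   analysis trials (default 0.67).
#' @param traj_duration_s duration of the visible+occluded trajectory
#'   (default 6 s).
#' @param traj_n_samples number of equally spaced samples along the trajectory
#'   (default 40).
#' @param observed_fraction fraction of samples shown before the occluder
#'   (default 0.75).
#' @param accel_max maximum horizontal acceleration magnitude, in screen
#'   widths per second squared. The default is chosen so that a maximal-
#'   curvature trajectory sweeps half the screen width over its duration:
#'   \code{accel_max = screen_width / traj_duration_s^2}.
#' @param n_warmup_noisefree number of initial noise-free trials, excluded
#'   from analysis (default 20).
#' @param screen_width screen width in position units (default 1; changing it
#'   rescales all position quantities).
#'
#' @return an object of class \code{task_config} (a validated list).
#' @seealso [generate_session()]
#' @export
task_config <- function(n_trials = 220L,
                        jump_gap_min = 20L,
                        jump_gap_max = 40L,
                        mean_range = c(0.2, 0.8),
                        sd_range = c(0.02, 0.12),
                        noise_sd_range = c(0.015, 0.09),
                        noise_calibration_ratio = 0.67,
                        traj_duration_s = 6,
                        traj_n_samples = 40L,
                        observed_fraction = 0.75,
                        accel_max = NULL,
                        n_warmup_noisefree = 20L,
                        screen_width = 1.0) {
  if (is.null(accel_max)) {
    # max curvature sweeps 0.5 * screen over the full duration:
    # 0.5 * a * T^2 = 0.5 * screen_width
    accel_max <- screen_width / traj_duration_s^2
  }
  cfg <- list(
    n_trials = as.integer(n_trials),
    jump_gap_min = as.integer(jump_gap_min),
    jump_gap_max = as.integer(jump_gap_max),
    mean_range = as.numeric(mean_range),
    sd_range = as.numeric(sd_range),
    noise_sd_range = as.numeric(noise_sd_range),
    noise_calibration_ratio = as.numeric(noise_calibration_ratio),
    traj_duration_s = as.numeric(traj_duration_s),
    traj_n_samples = as.integer(traj_n_samples),
    observed_fraction = as.numeric(observed_fraction),
    accel_max = as.numeric(accel_max),
    n_warmup_noisefree = as.integer(n_warmup_noisefree),
    screen_width = as.numeric(screen_width)
  )
  validate_task_config(cfg)
  class(cfg) <- "task_config"
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(cfg$n_trials >= 1L)
  if (cfg$jump_gap_min < 1L || cfg$jump_gap_min > cfg$jump_gap_max)
    stop("invalid jump gap range: need 1 <= jump_gap_min <= jump_gap_max",
         call. = FALSE)
  for (nm in c("mean_range", "sd_range", "noise_sd_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || r[1] > r[2])
      stop(sprintf("invalid %s: need c(min, max) with min <= max", nm),
           call. = FALSE)
  }
  if (cfg$mean_range[1] < 0 || cfg$mean_range[2] > cfg$screen_width)
    stop("mean_range must lie within the screen", call. = FALSE)
  if (cfg$sd_range[1] <= 0)
    stop("sd_range must be positive", call. = FALSE)
  if (cfg$noise_sd_range[1] < 0)
    stop("noise_sd_range must be non-negative", call. = FALSE)
  if (cfg$observed_fraction <= 0 || cfg$observed_fraction >= 1)
    stop("observed_fraction must be in (0, 1)", call. = FALSE)
  if (cfg$noise_calibration_ratio <= 0)
    stop("noise_calibration_ratio must be positive", call. = FALSE)
  if (cfg$n_warmup_noisefree < 0L || cfg$n_warmup_noisefree >= cfg$n_trials)
    stop("n_warmup_noisefree must be in [0, n_trials)", call. = FALSE)
  if (cfg$traj_n_samples < 4L)
    stop("traj_n_samples must be at least 4", call. = FALSE)
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Occluded-trajectory task configuration\n")
  cat(sprintf("  %d trials (%d noise-free warmup), jumps every %d-%d trials\n",
              x$n_trials, x$n_warmup_noisefree, x$jump_gap_min, x$jump_gap_max))
  cat(sprintf("  generative means U[%.2f, %.2f], SDs logU[%.3f, %.3f] sw\n",
              x$mean_range[1], x$mean_range[2], x$sd_range[1], x$sd_range[2]))
  cat(sprintf("  noise SD logU[%.3f, %.3f], calibrated to %.2f x mean endpoint SD\n",
              x$noise_sd_range[1], x$noise_sd_range[2],
              x$noise_calibration_ratio))
  cat(sprintf("  trajectory: %d samples over %g s, %.0f%% observed, |accel| <= %.4f sw/s^2\n",
              x$traj_n_samples, x$traj_duration_s,
              100 * x$observed_fraction, x$accel_max))
  invisible(x)
}
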