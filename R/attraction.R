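#' Attraction of responses toward the statistical mean, by trajectory noise
#'
#' Bins analysis trials into terciles (by default) of the dynamic-model SD
#' \code{sigma_d} and, within each bin, regresses the displacement of the
#' response from the true endpoint toward the statistical mean,
#' \code{y = x_end - r}, on the displacement of the endpoint from the
#' statistical mean, \code{x_end - mu_s} (OLS with intercept). A slope of 0
#' means responses track the endpoint (pure dynamic responding); a slope of
#' 1 means responses sit at the statistical mean. For reference, the same
#' slopes are computed for an optimal observer's noiseless responses
#' (precision-weighted combination with \code{M = 1}, \code{b = 0},
#' \code{k -> 0}), whose expected slope in a bin is the mean Bayes weight
#' \code{sigma_d^2 / (sigma_d^2 + sigma_s^2)}.
#'
#' @param beliefs analysis-trial belief table with columns \code{x_end},
#'   \code{mu_s}, \code{sigma_s}, \code{mu_d}, \code{sigma_d}
#'   (see [belief_table()]).
#' @param responses numeric responses aligned with \code{beliefs} rows.
#' @param n_bins number of \code{sigma_d} bins (default 3).
#' @return a data.frame with one row per bin: \code{bin}, \code{n},
#'   \code{mean_sigma_d}, \code{slope}, \code{slope_optimal}.
#' @export
attraction_slopes <- function(beliefs, responses, n_bins = 3L) {
  n <- nrow(beliefs)
  stopifnot(length(responses) == n)
  if (n < n_bins * 10L)
    stop("need at least 10 trials per bin", call. = FALSE)
  qs <- stats::quantile(beliefs$sigma_d, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(beliefs$sigma_d, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  if (length(unique(bin)) != n_bins)
    stop("degenerate sigma_d distribution: empty bin", call. = FALSE)

  r_opt <- combine_prediction(beliefs$mu_s, beliefs$sigma_s,
                              beliefs$mu_d, beliefs$sigma_d,
                              M = 1, b = 0, model = "weighted")$mu_sd
  slope_of <- function(resp, idx) {
    y <- beliefs$x_end[idx] - resp[idx]
    x <- beliefs$x_end[idx] - beliefs$mu_s[idx]
    unname(stats::coef(stats::lm(y ~ x))[2])
  }
  out <- lapply(seq_len(n_bins), function(bi) {
    idx <- which(bin == bi)
    data.frame(bin = bi, n = length(idx),
               mean_sigma_d = mean(beliefs$sigma_d[idx]),
               slope = slope_of(responses, idx),
               slope_optimal = slope_of(r_opt, idx))
  })
  do.call(rbind, out)
}

#' Linear trend of attraction slopes across noise bins, per participant
#'
#' Group-level check that attraction toward the statistical mean grows with
#' trajectory noise: for each participant, the slopes across \code{sigma_d}
#' bins are reduced to a linear contrast (centered bin index weights), and
#' the contrasts are tested against zero with a one-sample t test.
#'
#' @param slope_matrix participants x bins matrix of attraction slopes.
#' @return a list with the per-participant \code{contrasts}, the group
#'   \code{t} statistic and \code{p} value (one-sided, increasing trend).
#' @export
attraction_trend_test <- function(slope_matrix) {
  slope_matrix <- as.matrix(slope_matrix)
  nb <- ncol(slope_matrix)
  stopifnot(nb >= 2L, nrow(slope_matrix) >= 2L)
  w <- seq_len(nb) - mean(seq_len(nb))
  contrasts <- drop(slope_matrix %*% w)
  tt <- stats::t.test(contrasts, alternative = "greater")
  list(contrasts = contrasts,
       t = unname(tt$statistic),
       p = tt$p.value)
}
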