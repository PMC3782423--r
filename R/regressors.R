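#' KL divergence between two univariate Gaussians
#'
#' \deqn{KL(N(\mu_1,\sigma_1^2) \| N(\mu_2,\sigma_2^2)) =
#'   \ln(\sigma_2/\sigma_1) + (\sigma_1^2 + (\mu_1-\mu_2)^2)/(2\sigma_2^2) - 1/2}
#'
#' Vectorized over all arguments.
#'
#' @param mu1,sigma1 parameters of the reference distribution.
#' @param mu2,sigma2 parameters of the comparison distribution.
#' @return non-negative numeric vector.
#' @export
gaussian_kl <- function(mu1, sigma1, mu2, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0))
    stop("sigmas must be positive", call. = FALSE)
  log(sigma2 / sigma1) + (sigma1^2 + (mu1 - mu2)^2) / (2 * sigma2^2) - 0.5
}

#' Build the trial-wise parametric regressors for model-based imaging
#'
#' Computes, per analysis trial, the modulator values used to interrogate
#' neural data (values only; no GLM fitting):
#' \describe{
#'   \item{log_prec_stat, log_prec_dyn}{natural-log precisions
#'     \code{ln(1/sigma^2)} of the statistical and dynamic predictions.}
#'   \item{kl_stat_combined}{KL divergence from the statistical prediction to
#'     the combined (precision-weighted, \code{M = 1}, \code{b = 0} by
#'     default) prediction: how much the statistical model must be updated
#'     with dynamic information.}
#'   \item{kl_stat_update}{KL divergence from the statistical prediction on
#'     trial \code{i} to that on trial \code{i+1} (NA on the last trial).}
#'   \item{mean_change}{unsigned change in the statistical mean between
#'     consecutive trials (NA on the last trial).}
#'   \item{accuracy}{unsigned response error \code{100 * |r - x_end|}, in
#'     percent screen width.}
#'   \item{accuracy_orth}{accuracy orthogonalized with respect to both log
#'     precisions (OLS residual, intercept included).}
#' }
#' Event onsets mark the start of the decision phase (occluder entry): each
#' trial contributes the 6 s trajectory, a response period, 0.5 s feedback
#' and a jittered inter-trial interval (exponential, rate set so the mean of
#' the 2-12 s truncation is 6 s). Event duration is 0.1 s.
#'
#' @param beliefs analysis-trial belief table (see [belief_table()]); the
#'   rows must be consecutive trials so that "next trial" is well defined.
#' @param responses numeric responses aligned with \code{beliefs}.
#' @param M,b combination parameters for the combined prediction used in
#'   \code{kl_stat_combined} (defaults: optimal weighting).
#' @param response_dur_s modeled response-period duration (default 1 s).
#' @return a data.frame of class \code{regressor_table}, one row per
#'   analysis trial.
#' @export
build_regressors <- function(beliefs, responses, M = 1, b = 0,
                             response_dur_s = 1) {
  n <- nrow(beliefs)
  stopifnot(length(responses) == n, n >= 2L)
  if (any(diff(beliefs$trial) != 1L))
    stop("beliefs must cover consecutive trials", call. = FALSE)
  comb <- combine_prediction(beliefs$mu_s, beliefs$sigma_s,
                             beliefs$mu_d, beliefs$sigma_d,
                             M = M, b = b, model = "weighted")
  nxt <- c(seq_len(n - 1) + 1, NA)
  kl_upd <- c(gaussian_kl(beliefs$mu_s[-n], beliefs$sigma_s[-n],
                          beliefs$mu_s[-1], beliefs$sigma_s[-1]), NA)
  iti <- sample_iti(n)
  trial_len <- 6 + response_dur_s + 0.5 + iti
  onset <- 6 + c(0, cumsum(trial_len[-n]))
  out <- data.frame(
    trial = beliefs$trial,
    onset_s = onset,
    duration_s = 0.1,
    log_prec_stat = log(1 / beliefs$sigma_s^2),
    log_prec_dyn = log(1 / beliefs$sigma_d^2),
    kl_stat_combined = gaussian_kl(beliefs$mu_s, beliefs$sigma_s,
                                   comb$mu_sd, comb$sigma_sd),
    kl_stat_update = kl_upd,
    mean_change = c(abs(diff(beliefs$mu_s)), NA),
    accuracy = 100 * abs(responses - beliefs$x_end))
  prec <- out[, c("log_prec_stat", "log_prec_dyn"), drop = FALSE]
  prec <- prec[, vapply(prec, stats::sd, 0) > 0, drop = FALSE]  # drop constants
  out$accuracy_orth <- if (ncol(prec) > 0)
    orthogonalize(out$accuracy, prec)
  else out$accuracy - mean(out$accuracy)
  class(out) <- c("regressor_table", "data.frame")
  out
}

# exponential ITI, rejected outside [lo, hi]; rate solved once so that the
# truncated mean equals mean_s
sample_iti <- function(n, mean_s = 6, lo = 2, hi = 12) {
  trunc_mean <- function(rate) {
    d <- hi - lo
    lo + 1 / rate - d * exp(-rate * d) / (1 - exp(-rate * d))
  }
  rate <- stats::uniroot(function(r) trunc_mean(r) - mean_s,
                         c(1e-4, 5))$root
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    draw <- stats::rexp(2L * (n - got), rate)
    draw <- draw[draw >= lo & draw <= hi]
    take <- min(length(draw), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- draw[seq_len(take)]
    got <- got + take
  }
  out
}

#' Orthogonalize a regressor with respect to others
#'
#' Returns the OLS residual of \code{target} on the \code{others} plus an
#' intercept; the residual has zero correlation with every column of
#' \code{others}.
#'
#' @param target numeric vector.
#' @param others data.frame or matrix of covariates (same number of rows).
#' @return numeric residual vector.
#' @export
orthogonalize <- function(target, others) {
  X <- cbind(1, as.matrix(others))
  if (qr(X)$rank < ncol(X))
    stop("collinear columns in 'others': ",
         paste(colnames(others), collapse = ", "), call. = FALSE)
  drop(stats::lm.fit(X, target)$residuals)
}

#' Pairwise correlations among the main regressors
#'
#' Pearson r and p for every pair of the main modulators
#' (log precisions, the KL terms, mean change, accuracy).
#'
#' @param regs a [build_regressors()] table.
#' @param columns which columns to correlate.
#' @return a list with matrices \code{r} and \code{p}; constant columns give
#'   NA with a warning.
#' @export
correlation_table <- function(regs,
                              columns = c("log_prec_stat", "log_prec_dyn",
                                          "kl_stat_combined", "kl_stat_update",
                                          "mean_change", "accuracy")) {
  stopifnot(nrow(regs) >= 3L)
  X <- regs[, columns, drop = FALSE]
  p <- r <- matrix(NA_real_, ncol(X), ncol(X),
                   dimnames = list(columns, columns))
  for (i in seq_along(columns)) {
    for (j in seq_along(columns)) {
      xi <- X[[i]]; xj <- X[[j]]
      ok <- is.finite(xi) & is.finite(xj)
      if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
        warning(sprintf("constant column: %s or %s", columns[i], columns[j]))
        next
      }
      ct <- stats::cor.test(xi[ok], xj[ok])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Export regressors as a BIDS-style events table
#'
#' Writes a tab-separated file with columns \code{onset}, \code{duration},
#' \code{trial_type} and one modulation column per regressor.
#'
#' @param regs a [build_regressors()] table.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_events_tsv <- function(regs, path) {
  ev <- data.frame(onset = regs$onset_s,
                   duration = regs$duration_s,
                   trial_type = "decision",
                   regs[, c("log_prec_stat", "log_prec_dyn",
                            "kl_stat_combined", "kl_stat_update",
                            "mean_change", "accuracy", "accuracy_orth")])
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}
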