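#' Combine statistical and dynamic predictions into a single response mean
#'
#' The three candidate rules for forming the per-trial combined prediction
#' \code{mu_sd} from the statistical prediction (\code{mu_s}, \code{sigma_s})
#' and the dynamic prediction (\code{mu_d}, \code{sigma_d}), with free
#' parameters \code{M} (mixing factor) and \code{b} (additive spatial bias).
#' Writing \code{P_s = M / sigma_s^2} and \code{P_d = (2 - M) / sigma_d^2}:
#'
#' \describe{
#'   \item{weighted}{precision-weighted average:
#'     \code{mu_sd = b + (P_s mu_s + P_d mu_d) / (P_s + P_d)},
#'     \code{sigma_sd = (P_s + P_d)^(-1/2)}. \code{M} in [0, 2]; \code{M = 1}
#'     is the Bayes-optimal weighting.}
#'   \item{unweighted}{fixed-ratio mixture ignoring trial-wise precisions:
#'     \code{mu_sd = b + M mu_s + (1 - M) mu_d}. \code{M} in [0, 1].}
#'   \item{select}{winner-take-all: the source with the higher (biased)
#'     precision is used alone, \code{mu_sd = b + mu_s} if \code{P_s >= P_d}
#'     else \code{b + mu_d}; \code{sigma_sd} is the chosen source's SD.
#'     \code{M} in [0, 2]. Ties go to the statistical source.}
#' }
#'
#' All arguments are vectorized over trials. \code{sigma_d = 0} (a noise-free
#' trial) is treated as infinite dynamic precision.
#'
#' @param mu_s,sigma_s statistical prediction mean and SD per trial.
#' @param mu_d,sigma_d dynamic prediction mean and SD per trial.
#' @param M mixing factor (range depends on \code{model}).
#' @param b additive bias (screen widths).
#' @param model \code{"weighted"}, \code{"unweighted"} or \code{"select"}.
#' @return a data.frame with columns \code{mu_sd} and \code{sigma_sd}
#'   (\code{sigma_sd} is NA for the unweighted rule, which does not define
#'   a combined variance).
#' @export
combine_prediction <- function(mu_s, sigma_s, mu_d, sigma_d, M, b = 0,
                               model = c("weighted", "unweighted", "select")) {
  model <- match.arg(model)
  check_M(M, model)
  stopifnot(all(sigma_s > 0), all(sigma_d >= 0))
  if (model == "unweighted") {
    return(data.frame(mu_sd = b + M * mu_s + (1 - M) * mu_d,
                      sigma_sd = NA_real_))
  }
  P_s <- M / sigma_s^2
  P_d <- ifelse(sigma_d == 0,
                ifelse(M < 2, Inf, 0),
                (2 - M) / sigma_d^2)
  if (model == "weighted") {
    dyn_dom <- is.infinite(P_d)
    mu_sd <- ifelse(dyn_dom, b + mu_d,
                    b + (P_s * mu_s + P_d * mu_d) / (P_s + P_d))
    sigma_sd <- ifelse(dyn_dom, 0, 1 / sqrt(P_s + P_d))
    return(data.frame(mu_sd = mu_sd, sigma_sd = sigma_sd))
  }
  # select
  take_s <- P_s >= P_d
  data.frame(mu_sd = b + ifelse(take_s, mu_s, mu_d),
             sigma_sd = ifelse(take_s, sigma_s, sigma_d))
}

check_M <- function(M, model) {
  hi <- if (model == "unweighted") 1 else 2
  if (any(M < 0 | M > hi))
    stop(sprintf("M must lie in [0, %d] for the %s model", hi, model),
         call. = FALSE)
  invisible(M)
}

M_bounds <- function(model) c(0, if (model == "unweighted") 1 else 2)
M_default <- function(model) if (model == "unweighted") 0.5 else 1

#' Simulate responses under a combination model
#'
#' Responses are the model's combined prediction plus Gaussian response
#' noise: \code{r ~ N(mu_sd, k^2)}.
#'
#' @param beliefs a data.frame with columns \code{mu_s}, \code{sigma_s},
#'   \code{mu_d}, \code{sigma_d} (one row per trial), e.g. the merge of
#'   [run_filter()] and [run_dynamic()] output.
#' @param M,b,model combination parameters as in [combine_prediction()].
#' @param k response-noise SD (> 0; screen widths).
#' @return a numeric vector of responses, one per row of \code{beliefs}.
#' @export
simulate_responses <- function(beliefs, M = 1, b = 0, k = 0.03,
                               model = "weighted") {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  comb <- combine_prediction(beliefs$mu_s, beliefs$sigma_s,
                             beliefs$mu_d, beliefs$sigma_d,
                             M = M, b = b, model = model)
  stats::rnorm(nrow(beliefs), comb$mu_sd, k)
}

#' Response log likelihood under a combination model
#'
#' \code{sum over trials of log N(r_i; mu_sd(i), k^2)}.
#'
#' @param responses numeric responses, aligned with \code{beliefs} rows.
#' @param beliefs per-trial beliefs as in [simulate_responses()].
#' @param M,b,model,k model parameters.
#' @return a single number.
#' @export
response_loglik <- function(responses, beliefs, M, k, b = 0,
                            model = "weighted") {
  if (any(!is.finite(responses)))
    stop("non-finite response", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  comb <- combine_prediction(beliefs$mu_s, beliefs$sigma_s,
                             beliefs$mu_d, beliefs$sigma_d,
                             M = M, b = b, model = model)
  sum(stats::dnorm(responses, comb$mu_sd, k, log = TRUE))
}

#' Merge statistical and dynamic per-trial outputs into a belief table
#'
#' Convenience constructor for the aligned per-trial table consumed by the
#' fitting and regressor functions, restricted to analysis trials by default.
#'
#' @param session a \code{traj_session}.
#' @param stat output of [run_filter()].
#' @param dyn output of [run_dynamic()].
#' @param analysis_only drop warmup trials (default TRUE).
#' @return a data.frame with columns \code{trial}, \code{x_end}, \code{mu_s},
#'   \code{sigma_s}, \code{mu_d}, \code{sigma_d}.
#' @export
belief_table <- function(session, stat, dyn, analysis_only = TRUE) {
  b <- merge(merge(session$trials[, c("trial", "x_end", "is_analysis",
                                      "sigma_noise")],
                   stat[, c("trial", "mu_s", "sigma_s")], by = "trial"),
             dyn[, c("trial", "mu_d", "sigma_d")], by = "trial")
  b <- b[order(b$trial), ]
  if (analysis_only) b <- b[b$is_analysis, ]
  rownames(b) <- NULL
  b
}
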