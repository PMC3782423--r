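#' Fit a combination model to responses by maximum likelihood
#'
#' Finds the joint maximum-likelihood values of the mixing factor \code{M},
#' the response-noise SD \code{k} and the spatial bias \code{b} for one of
#' the three combination rules (see [combine_prediction()]), given a
#' participant's per-trial responses and the aligned statistical and dynamic
#' predictions. Optimization is a deterministic coarse grid (21 points per
#' free parameter) followed by bounded local refinement (\code{L-BFGS-B})
#' from the best grid cell.
#'
#' Parameter bounds: \code{M} in [0, 2] (weighted, select) or [0, 1]
#' (unweighted); \code{k} in (0, 0.5]; \code{b} in [-0.25, 0.25] screen
#' widths. Any subset of \code{c("M", "k", "b")} may be held fixed (for
#' nested-model BIC comparison); fixed parameters take \code{M = 1}
#' (weighted/select) or \code{0.5} (unweighted), \code{b = 0}, and \code{k}
#' equal to the residual SD at those defaults.
#'
#' @param responses numeric vector of responses, one per row of
#'   \code{beliefs}.
#' @param beliefs per-trial belief table (see [belief_table()]): columns
#'   \code{mu_s}, \code{sigma_s}, \code{mu_d}, \code{sigma_d}.
#' @param model combination rule: \code{"weighted"}, \code{"unweighted"} or
#'   \code{"select"}.
#' @param free character vector naming the free parameters (default all
#'   three).
#' @return an object of class \code{comb_fit} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{logLik} (and hence
#'   \code{stats::BIC}), \code{predict}, \code{residuals}, \code{simulate}
#'   and \code{plot}.
#' @examples
#' set.seed(1)
#' n <- 200
#' beliefs <- data.frame(mu_s = 0.5, sigma_s = 0.05,
#'                       mu_d = runif(n, 0.3, 0.7),
#'                       sigma_d = exp(runif(n, log(0.02), log(0.12))))
#' r <- simulate_responses(beliefs, M = 1, b = 0, k = 0.03)
#' fit <- fit_combination(r, beliefs, model = "weighted")
#' coef(fit)
#' @export
fit_combination <- function(responses, beliefs,
                            model = c("weighted", "unweighted", "select"),
                            free = c("M", "k", "b")) {
  model <- match.arg(model)
  free <- match.arg(free, c("M", "k", "b"), several.ok = TRUE)
  n <- length(responses)
  if (n < 30L)
    stop("need at least 30 trials for a stable fit", call. = FALSE)
  stopifnot(nrow(beliefs) == n, all(is.finite(responses)))

  k_bounds <- c(1e-4, 0.5)
  b_bounds <- c(-0.25, 0.25)
  m_bounds <- M_bounds(model)

  # defaults for fixed parameters
  M0 <- M_default(model)
  b0 <- 0
  mu0 <- combine_prediction(beliefs$mu_s, beliefs$sigma_s,
                            beliefs$mu_d, beliefs$sigma_d,
                            M = M0, b = b0, model = model)$mu_sd
  k0 <- max(stats::sd(responses - mu0), k_bounds[1])

  grid_of <- function(p) {
    switch(p,
      M = seq(m_bounds[1], m_bounds[2], length.out = 21),
      k = exp(seq(log(2e-3), log(k_bounds[2]), length.out = 21)),
      b = seq(b_bounds[1], b_bounds[2], length.out = 21))
  }
  vals <- list(M = if ("M" %in% free) grid_of("M") else M0,
               k = if ("k" %in% free) grid_of("k") else k0,
               b = if ("b" %in% free) grid_of("b") else b0)

  # coarse grid: loop over M (mu_sd depends on it), vectorize over b and k
  best <- list(ll = -Inf)
  for (M in vals$M) {
    mu_sd <- combine_prediction(beliefs$mu_s, beliefs$sigma_s,
                                beliefs$mu_d, beliefs$sigma_d,
                                M = M, b = 0, model = model)$mu_sd
    for (b in vals$b) {
      ssr <- sum((responses - mu_sd - b)^2)
      ll_k <- -n / 2 * log(2 * pi) - n * log(vals$k) - ssr / (2 * vals$k^2)
      j <- which.max(ll_k)
      if (ll_k[j] > best$ll)
        best <- list(ll = ll_k[j], M = M, k = vals$k[j], b = b)
    }
  }

  negll <- function(par) {
    p <- list(M = M0, k = k0, b = b0)
    p[free] <- as.list(par)
    -response_loglik(responses, beliefs, M = p$M, k = p$k, b = p$b,
                     model = model)
  }
  start <- unlist(best[free])
  lower <- c(M = m_bounds[1], k = k_bounds[1], b = b_bounds[1])[free]
  upper <- c(M = m_bounds[2], k = k_bounds[2], b = b_bounds[2])[free]
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
  if (opt$convergence != 0 && opt$value > -best$ll) {
    # refinement failed to improve on the grid: keep the grid optimum
    opt <- list(par = start, value = -best$ll, convergence = opt$convergence)
  }
  pars <- list(M = M0, k = k0, b = b0)
  pars[free] <- as.list(opt$par)
  tol <- 1e-6
  boundary <- any(abs(opt$par - lower) < tol | abs(opt$par - upper) < tol)

  ll <- -opt$value
  p_free <- length(free)
  mu_sd <- combine_prediction(beliefs$mu_s, beliefs$sigma_s,
                              beliefs$mu_d, beliefs$sigma_d,
                              M = pars$M, b = pars$b, model = model)$mu_sd
  structure(list(model = model,
                 coefficients = c(M = pars$M, k = pars$k, b = pars$b),
                 free = free,
                 logLik = ll,
                 BIC = p_free * log(n) - 2 * ll,
                 n = n,
                 boundary = boundary,
                 fitted = mu_sd,
                 responses = responses,
                 beliefs = beliefs),
            class = "comb_fit")
}

#' @export
print.comb_fit <- function(x, ...) {
  cat(sprintf("Combination model fit: %s (free: %s)\n",
              x$model, paste(x$free, collapse = ", ")))
  cat(sprintf("  M = %.4f, k = %.4f, b = %+.4f%s\n",
              x$coefficients["M"], x$coefficients["k"], x$coefficients["b"],
              if (x$boundary) "  [at bound]" else ""))
  cat(sprintf("  logLik = %.2f, BIC = %.2f (n = %d trials)\n",
              x$logLik, x$BIC, x$n))
  invisible(x)
}

#' @export
coef.comb_fit <- function(object, ...) object$coefficients

#' @export
logLik.comb_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$free), nobs = object$n,
            class = "logLik")
}

#' @export
nobs.comb_fit <- function(object, ...) object$n

#' Predicted combined means from a fitted combination model
#'
#' @param object a \code{comb_fit}.
#' @param newdata optional belief table (columns as in [belief_table()]);
#'   defaults to the fitting data.
#' @param ... unused.
#' @return numeric vector of \code{mu_sd} values at the MLE parameters.
#' @export
predict.comb_fit <- function(object, newdata = NULL, ...) {
  b <- if (is.null(newdata)) object$beliefs else newdata
  combine_prediction(b$mu_s, b$sigma_s, b$mu_d, b$sigma_d,
                     M = object$coefficients["M"],
                     b = object$coefficients["b"],
                     model = object$model)$mu_sd
}

#' @export
residuals.comb_fit <- function(object, ...) object$responses - object$fitted

#' Simulate response sets from a fitted combination model
#'
#' @param object a \code{comb_fit}.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return a data.frame of \code{nsim} columns, each a simulated response
#'   vector at the MLE parameters.
#' @export
simulate.comb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- object$coefficients["k"]
  as.data.frame(replicate(nsim, stats::rnorm(object$n, object$fitted, k)))
}

#' @export
summary.comb_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 resid_sd = stats::sd(res),
                 resid_range = range(res)),
            class = "summary.comb_fit")
}

#' @export
print.summary.comb_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SD = %.4f (MLE k = %.4f); residual range [%+.3f, %+.3f]\n",
              x$resid_sd, x$fit$coefficients["k"],
              x$resid_range[1], x$resid_range[2]))
  invisible(x)
}

#' Response vs. prediction plot for a fitted combination model
#'
#' @param x a \code{comb_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.comb_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$responses,
                 xlab = expression(mu[sd]), ylab = "response r",
                 main = sprintf("%s combination model", x$model), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare fitted combination models by logLR and BIC
#'
#' Pairwise log likelihood ratios (first minus second) require fits on the
#' same responses with the same number of free parameters; BIC differences
#' are reported for any set of fits.
#'
#' @param ... two or more \code{comb_fit} objects (optionally named).
#' @return a list with a per-model \code{table} (model, logLik, df, BIC) and
#'   a pairwise \code{logLR} matrix (\code{logLR[i, j] = logLik_i - logLik_j}).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "comb_fit")) fits <- fits[[1]]
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, TRUE, "comb_fit")))
  nms <- names(fits)
  if (is.null(nms) || any(nms == ""))
    nms <- vapply(fits, `[[`, "", "model")
  ns <- vapply(fits, `[[`, 0L, "n")
  if (length(unique(ns)) != 1L)
    stop("fits are on different trial sets", call. = FALSE)
  r0 <- fits[[1]]$responses
  if (!all(vapply(fits, function(f) isTRUE(all.equal(f$responses, r0)), TRUE)))
    stop("fits are on different responses", call. = FALSE)
  ll <- vapply(fits, `[[`, 0, "logLik")
  tab <- data.frame(model = nms,
                    logLik = ll,
                    df = vapply(fits, function(f) length(f$free), 0L),
                    BIC = vapply(fits, `[[`, 0, "BIC"))
  logLR <- outer(ll, ll, `-`)
  dimnames(logLR) <- list(nms, nms)
  list(table = tab, logLR = logLR)
}
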