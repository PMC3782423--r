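#' Grid specification for the Bayesian ideal observer
#'
#' The observer maintains a joint posterior over four parameters of the
#' endpoint distribution: its mean \code{mu}, its standard deviation
#' \code{sigma}, and the per-trial jump probabilities \code{alpha_mu} and
#' \code{alpha_sigma} with which mean and SD independently reset to new
#' values. Defaults: 60 means uniform over the screen, 20 SDs log-spaced over
#' [0.005, 0.3] screen widths, 8 jump rates log-spaced over [0.001, 0.3] per
#' axis.
#'
#' @param mu,sigma,alpha_mu,alpha_sigma strictly increasing numeric axes.
#' @return a validated \code{grid_config} list.
#' @export
grid_config <- function(mu = seq(0, 1, length.out = 60),
                        sigma = exp(seq(log(0.005), log(0.3), length.out = 20)),
                        alpha_mu = exp(seq(log(0.001), log(0.3), length.out = 8)),
                        alpha_sigma = exp(seq(log(0.001), log(0.3), length.out = 8))) {
  axes <- list(mu = mu, sigma = sigma,
               alpha_mu = alpha_mu, alpha_sigma = alpha_sigma)
  for (nm in names(axes)) {
    a <- axes[[nm]]
    if (length(a) < 1L || is.unsorted(a, strictly = TRUE))
      stop(sprintf("axis %s must be strictly increasing", nm), call. = FALSE)
  }
  if (any(axes$sigma <= 0)) stop("sigma axis must be positive", call. = FALSE)
  if (any(axes$alpha_mu < 0 | axes$alpha_mu > 1) ||
      any(axes$alpha_sigma < 0 | axes$alpha_sigma > 1))
    stop("alpha axes must lie in [0, 1]", call. = FALSE)
  class(axes) <- "grid_config"
  axes
}

#' Initialize the observer with a uniform joint prior
#'
#' Before any trial the observer assigns equal probability to every cell of
#' the parameter lattice.
#'
#' @param config a [grid_config()].
#' @return an object of class \code{observer_grid}: the axes plus a 4-D
#'   \code{mass} array (mu x sigma x alpha_mu x alpha_sigma) summing to 1.
#' @export
init_grid <- function(config = grid_config()) {
  stopifnot(inherits(config, "grid_config"))
  dims <- c(length(config$mu), length(config$sigma),
            length(config$alpha_mu), length(config$alpha_sigma))
  grid <- list(mu = config$mu, sigma = config$sigma,
               alpha_mu = config$alpha_mu, alpha_sigma = config$alpha_sigma,
               mass = array(1 / prod(dims), dim = dims))
  class(grid) <- "observer_grid"
  grid
}

#' @export
print.observer_grid <- function(x, ...) {
  b <- predict_endpoint_belief(x)
  cat(sprintf("observer_grid %dx%dx%dx%d; predictive belief N(%.4f, %.4f^2)\n",
              length(x$mu), length(x$sigma), length(x$alpha_mu),
              length(x$alpha_sigma), b$mu, b$sigma))
  invisible(x)
}

#' Bayes update of the observer on one observed endpoint
#'
#' Multiplies the joint mass by the Gaussian likelihood of the observed
#' landing point under each (mu, sigma) cell and renormalizes. Computation is
#' done in log space with max-subtraction to avoid underflow.
#'
#' @param grid an \code{observer_grid}.
#' @param x_i observed endpoint (screen-width units).
#' @return the updated \code{observer_grid}.
#' @export
update_bayes <- function(grid, x_i) {
  stopifnot(inherits(grid, "observer_grid"), is.finite(x_i))
  loglik <- outer(grid$mu, grid$sigma,
                  function(m, s) stats::dnorm(x_i, m, s, log = TRUE))
  lm_ <- log(grid$mass) + as.vector(loglik)  # (mu,sigma) recycle over alphas
  m <- max(lm_)
  if (!is.finite(m))
    stop("posterior underflow: all cells at zero mass; widen the grid",
         call. = FALSE)
  w <- exp(lm_ - m)
  grid$mass <- array(w / sum(w), dim = dim(grid$mass))
  grid
}

#' Leaky propagation of the observer between trials
#'
#' Accounts for the possibility that the generative mean and/or SD jumped
#' since the last trial. Within each (alpha_mu, alpha_sigma) slice, the
#' (mu, sigma) distribution \code{p} becomes the four-way mixture
#' \deqn{(1-a_m)(1-a_s) p + a_m (1-a_s) U(\mu) p(\sigma)
#'       + (1-a_m) a_s p(\mu) U(\sigma) + a_m a_s U(\mu) U(\sigma)}
#' where \code{p(mu)}, \code{p(sigma)} are the slice marginals and U is
#' uniform over the axis. The marginal over the alpha axes is unchanged.
#'
#' @param grid an \code{observer_grid}.
#' @return the propagated \code{observer_grid}.
#' @export
propagate_leaky <- function(grid) {
  stopifnot(inherits(grid, "observer_grid"))
  nm <- length(grid$mu); ns <- length(grid$sigma)
  u_mu <- rep(1 / nm, nm); u_s <- rep(1 / ns, ns)
  mass <- grid$mass
  for (k in seq_along(grid$alpha_mu)) {
    am <- grid$alpha_mu[k]
    for (l in seq_along(grid$alpha_sigma)) {
      as_ <- grid$alpha_sigma[l]
      p <- mass[, , k, l, drop = TRUE]
      dim(p) <- c(nm, ns)
      tot <- sum(p)
      if (tot == 0) next
      pm <- rowSums(p)   # marginal over mu (mass tot)
      ps <- colSums(p)   # marginal over sigma
      mass[, , k, l] <-
        (1 - am) * (1 - as_) * p +
        am * (1 - as_) * outer(u_mu, ps) +
        (1 - am) * as_ * outer(pm, u_s) +
        am * as_ * (tot * outer(u_mu, u_s))
    }
  }
  drift <- abs(sum(mass) - 1)
  if (drift > 1e-10)
    stop(sprintf("mass drift %.2e after propagation", drift), call. = FALSE)
  grid$mass <- mass / sum(mass)
  grid
}

#' Moment-matched Gaussian summary of the observer's endpoint prediction
#'
#' The posterior-predictive distribution over the next endpoint is a mixture
#' of Gaussians (one per grid cell, weighted by posterior mass); this returns
#' the Gaussian with the same mean and variance:
#' \code{mu_s = sum(m * mu)}, \code{sigma_s^2 = sum(m * (sigma^2 + mu^2)) - mu_s^2}.
#'
#' @param grid an \code{observer_grid}.
#' @return a [gaussian_belief()] with role \code{"statistical"}.
#' @export
predict_endpoint_belief <- function(grid) {
  stopifnot(inherits(grid, "observer_grid"))
  mu_cell <- grid$mu                       # recycles along dim 1
  m2_cell <- as.vector(outer(grid$mu^2, grid$sigma^2, `+`))  # dims 1:2
  mu_s <- sum(grid$mass * mu_cell)
  var_s <- sum(grid$mass * m2_cell) - mu_s^2
  if (var_s <= 0)
    stop("degenerate posterior-predictive variance", call. = FALSE)
  gaussian_belief(mu_s, sqrt(var_s), role = "statistical")
}

#' A Gaussian predictive belief over the trajectory endpoint
#'
#' @param mu mean position (screen widths).
#' @param sigma standard deviation (> 0, or 0 for a degenerate noise-free
#'   dynamic estimate).
#' @param role one of \code{"statistical"}, \code{"dynamic"},
#'   \code{"combined"}.
#' @return a \code{gaussian_belief} list.
#' @export
gaussian_belief <- function(mu, sigma, role = c("statistical", "dynamic",
                                                "combined")) {
  role <- match.arg(role)
  stopifnot(is.finite(mu), sigma >= 0)
  structure(list(mu = mu, sigma = sigma, role = role),
            class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("%s belief: N(%.4f, %.4f^2)\n", x$role, x$mu, x$sigma))
  invisible(x)
}

#' Run the ideal observer over a session
#'
#' Processes trials in order. For trial \code{i} it first records the belief
#' in force at the beginning of the trial (i.e. after observing trials
#' \code{1..i-1} only), then updates on the true endpoint \code{x_i}
#' (feedback always showed the true landing point, including on warmup
#' trials) and applies the leaky jump propagation.
#'
#' @param session a \code{traj_session}.
#' @param config a [grid_config()].
#' @param keep_grid logical; if TRUE the final grid is attached as an
#'   attribute \code{"grid"}.
#' @return a data.frame with one row per trial: \code{trial}, \code{mu_s},
#'   \code{sigma_s}, \code{log_prec_stat} (= \code{log(1/sigma_s^2)}).
#' @export
run_filter <- function(session, config = grid_config(), keep_grid = FALSE) {
  stopifnot(inherits(session, "traj_session"))
  grid <- init_grid(config)
  n <- nrow(session$trials)
  mu_s <- sigma_s <- numeric(n)
  for (i in seq_len(n)) {
    b <- predict_endpoint_belief(grid)
    mu_s[i] <- b$mu
    sigma_s[i] <- b$sigma
    grid <- update_bayes(grid, session$trials$x_end[i])
    grid <- propagate_leaky(grid)
  }
  out <- data.frame(trial = session$trials$trial, mu_s = mu_s,
                    sigma_s = sigma_s,
                    log_prec_stat = log(1 / sigma_s^2))
  if (keep_grid) attr(out, "grid") <- grid
  out
}
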