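test_that("the initial grid is uniform with unit mass", {
  g <- init_grid(grid_config())
  expect_equal(dim(g$mass), c(60L, 20L, 8L, 8L))
  expect_equal(sum(g$mass), 1, tolerance = 1e-12)
  expect_true(all(abs(g$mass - 1 / prod(dim(g$mass))) < 1e-15))
  mu_marg <- apply(g$mass, 1, sum)
  expect_true(all(abs(mu_marg - 1 / 60) < 1e-12))
})

test_that("Bayes update matches the hand-computed two-cell posterior", {
  g <- tiny_grid(mu = c(0, 2), sigma = 1)
  g <- update_bayes(g, 0)
  # phi(0) / (phi(0) + phi(2)) with standard-normal densities
  expect_equal(as.numeric(g$mass[1, 1, 1, 1]), 0.8808, tolerance = 1e-4)
  expect_equal(as.numeric(g$mass[2, 1, 1, 1]), 0.1192, tolerance = 1e-4)
  expect_equal(sum(g$mass), 1, tolerance = 1e-12)
})

test_that("an outlying observation favours the widest-sigma cells", {
  sig <- c(0.05, 0.1, 0.3)
  g <- tiny_grid(mu = 0.5, sigma = sig)
  g <- update_bayes(g, 5)
  post <- as.numeric(g$mass[1, , 1, 1])
  # brute-force density comparison on the 3-cell grid
  dens <- dnorm(5, 0.5, sig)
  expect_equal(post, dens / sum(dens), tolerance = 1e-12)
  expect_equal(which.max(post), 3L)
})

test_that("a point-mass prior is unchanged by the update", {
  g <- tiny_grid(mu = c(0.3, 0.7), sigma = 0.1)
  g$mass[] <- 0
  g$mass[2, 1, 1, 1] <- 1
  g2 <- update_bayes(g, 0.1)
  expect_equal(g2$mass, g$mass, tolerance = 1e-12)
})

test_that("leaky propagation has the correct no-jump, certain-jump and mixture limits", {
  g <- init_grid(grid_config(mu = seq(0, 1, length.out = 5),
                             sigma = c(0.05, 0.1),
                             alpha_mu = c(0, 0.5, 1),
                             alpha_sigma = c(0, 1)))
  # one point mass per (alpha_mu, alpha_sigma) slice, at (mu index 2, sigma 1)
  g$mass[] <- 0
  g$mass[2, 1, , ] <- 1 / 6
  g2 <- propagate_leaky(g)
  # alpha = (0, 0): unchanged
  expect_equal(g2$mass[, , 1, 1], g$mass[, , 1, 1], tolerance = 1e-12)
  # alpha = (1, 1): uniform over the slice
  expect_true(all(abs(g2$mass[, , 3, 2] - (1 / 6) / 10) < 1e-12))
  # alpha = (0.5, 0): half stays, half spreads uniformly over mu at sigma*
  sl <- g2$mass[, , 2, 1] * 6
  expect_equal(sl[2, 1], 0.5 + 0.5 / 5, tolerance = 1e-12)
  expect_equal(sl[1, 1], 0.5 / 5, tolerance = 1e-12)
  expect_true(all(sl[, 2] == 0))
  # alpha-marginals untouched
  expect_equal(apply(g2$mass, 3:4, sum), apply(g$mass, 3:4, sum),
               tolerance = 1e-12)
})

test_that("the moment-matched belief reproduces mixture moments", {
  g <- tiny_grid(mu = c(0.4, 0.5), sigma = 0.1)
  g$mass[] <- 0
  g$mass[2, 1, 1, 1] <- 1
  b <- predict_endpoint_belief(g)
  expect_equal(b$mu, 0.5, tolerance = 1e-12)
  expect_equal(b$sigma, 0.1, tolerance = 1e-12)

  g2 <- tiny_grid(mu = c(0.4, 0.6), sigma = 0.05)
  b2 <- predict_endpoint_belief(g2)
  expect_equal(b2$mu, 0.5, tolerance = 1e-12)
  expect_equal(b2$sigma, sqrt(0.05^2 + 0.1^2), tolerance = 1e-12)

  # predictive variance is at least the mean within-cell variance
  g3 <- init_grid(grid_config())
  b3 <- predict_endpoint_belief(g3)
  mean_within <- sum(g3$mass * as.vector(outer(rep(1, 60), g3$sigma^2)))
  expect_gte(b3$sigma^2, mean_within)
})

test_that("mass is conserved through a full filtering run", {
  f <- default_session_fixture()
  out <- run_filter(f$session, keep_grid = TRUE)
  expect_equal(sum(attr(out, "grid")$mass), 1, tolerance = 1e-10)
  expect_true(all(is.finite(out$mu_s)), all(out$sigma_s > 0))
})

test_that("with jump rates pinned at zero the filter matches an independent grid-Bayes oracle", {
  mu_ax <- seq(0, 1, length.out = 121)
  sig_ax <- exp(seq(log(0.01), log(0.3), length.out = 41))
  set.seed(21)
  xs <- rnorm(50, 0.5, 0.08)

  # independent oracle: explicit loop-based joint posterior and predictive
  # moments over the same lattice
  oracle <- function(xs) {
    logp <- matrix(0, length(mu_ax), length(sig_ax))
    out <- matrix(NA_real_, length(xs), 2)
    for (i in seq_along(xs)) {
      p <- exp(logp - max(logp)); p <- p / sum(p)
      m1 <- 0; m2 <- 0
      for (a in seq_along(mu_ax)) for (b in seq_along(sig_ax)) {
        m1 <- m1 + p[a, b] * mu_ax[a]
        m2 <- m2 + p[a, b] * (sig_ax[b]^2 + mu_ax[a]^2)
      }
      out[i, ] <- c(m1, sqrt(m2 - m1^2))
      for (a in seq_along(mu_ax))
        logp[a, ] <- logp[a, ] + dnorm(xs[i], mu_ax[a], sig_ax, log = TRUE)
    }
    out
  }
  expected <- oracle(xs)

  g <- init_grid(grid_config(mu = mu_ax, sigma = sig_ax,
                             alpha_mu = 0, alpha_sigma = 0))
  got <- matrix(NA_real_, length(xs), 2)
  for (i in seq_along(xs)) {
    b <- predict_endpoint_belief(g)
    got[i, ] <- c(b$mu, b$sigma)
    g <- propagate_leaky(update_bayes(g, xs[i]))
  }
  expect_equal(got, expected, tolerance = 1e-8)
  # and the posterior mean homes in on the sample mean
  expect_lt(abs(got[50, 1] - mean(xs[1:49])), 0.02)
})

test_that("a large generative mean jump transiently inflates the statistical SD", {
  set.seed(31)
  xs <- c(rnorm(30, 0.25, 0.04), rnorm(10, 0.75, 0.04))
  g <- init_grid(grid_config())
  sigma_s <- numeric(length(xs))
  for (i in seq_along(xs)) {
    sigma_s[i] <- predict_endpoint_belief(g)$sigma
    g <- propagate_leaky(update_bayes(g, xs[i]))
  }
  expect_gt(sigma_s[32], sigma_s[30])   # jump at trial 31
  expect_lt(sigma_s[40], sigma_s[32])   # and re-converges
})

test_that("on stationary data the statistical SD shrinks across blocks", {
  set.seed(41)
  xs <- rnorm(60, 0.5, 0.06)
  g <- init_grid(grid_config())
  sigma_s <- numeric(length(xs))
  for (i in seq_along(xs)) {
    sigma_s[i] <- predict_endpoint_belief(g)$sigma
    g <- propagate_leaky(update_bayes(g, xs[i]))
  }
  blocks <- split(sigma_s, rep(1:3, each = 20))
  med <- vapply(blocks, median, 0)
  expect_true(all(diff(med) <= 0))
})

test_that("the filter emits the belief in force before each observation", {
  # trial 1 must be the moment match of the uniform prior, unaffected by x_1
  cfg <- task_config(n_trials = 5L, n_warmup_noisefree = 1L)
  s <- generate_session(cfg, seed = 13L)
  out <- run_filter(s)
  prior_belief <- predict_endpoint_belief(init_grid(grid_config()))
  expect_equal(out$mu_s[1], prior_belief$mu, tolerance = 1e-12)
  expect_equal(out$sigma_s[1], prior_belief$sigma, tolerance = 1e-12)
  # trial 2 equals one update+propagation on x_1 alone
  g <- propagate_leaky(update_bayes(init_grid(grid_config()),
                                    s$trials$x_end[1]))
  b2 <- predict_endpoint_belief(g)
  expect_equal(out$mu_s[2], b2$mu, tolerance = 1e-12)
})
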