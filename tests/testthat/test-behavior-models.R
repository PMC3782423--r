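test_that("combination rules reproduce hand-computed cases", {
  w <- combine_prediction(0, 1, 1, 1, M = 1, b = 0, model = "weighted")
  expect_equal(w$mu_sd, 0.5, tolerance = 1e-12)
  expect_equal(w$sigma_sd, 0.70711, tolerance = 1e-4)

  # a hopeless dynamic estimate hands control to the statistical model
  w2 <- combine_prediction(0.3, 0.05, 0.9, 1e9, M = 1, b = 0.01,
                           model = "weighted")
  expect_equal(w2$mu_sd, 0.31, tolerance = 1e-6)

  u <- combine_prediction(0.2, 0.05, 0.6, 0.05, M = 0.25, b = 0,
                          model = "unweighted")
  expect_equal(u$mu_sd, 0.5, tolerance = 1e-12)
  expect_true(is.na(u$sigma_sd))

  s <- combine_prediction(0.2, 0.05, 0.6, 0.1, M = 1, b = 0.02,
                          model = "select")
  expect_equal(s$mu_sd, 0.22, tolerance = 1e-12)
  expect_equal(s$sigma_sd, 0.05, tolerance = 1e-12)
})

test_that("the weighted rule at M = 1 is the Bayes posterior of two Gaussians", {
  set.seed(2)
  for (rep in 1:20) {
    mu_s <- runif(1); sig_s <- runif(1, 0.02, 0.2)
    mu_d <- runif(1); sig_d <- runif(1, 0.02, 0.2)
    w <- combine_prediction(mu_s, sig_s, mu_d, sig_d, M = 1, model = "weighted")
    expect_lte(w$sigma_sd, min(sig_s, sig_d))
    expect_gte(w$mu_sd, min(mu_s, mu_d))
    expect_lte(w$mu_sd, max(mu_s, mu_d))
  }
})

test_that("mixing factors outside the model's range are rejected", {
  expect_error(combine_prediction(0, 1, 1, 1, M = 1.5, model = "unweighted"),
               "\\[0, 1\\]")
  expect_error(combine_prediction(0, 1, 1, 1, M = 2.1, model = "weighted"),
               "\\[0, 2\\]")
})

test_that("simulated responses have the configured noise", {
  beliefs <- synthetic_beliefs(10000, seed = 3)
  mu_sd <- combine_prediction(beliefs$mu_s, beliefs$sigma_s, beliefs$mu_d,
                              beliefs$sigma_d, M = 1, model = "weighted")$mu_sd
  set.seed(4)
  r <- simulate_responses(beliefs, M = 1, b = 0, k = 0.03)
  expect_lt(abs(sd(r - mu_sd) - 0.03), 0.001)
  set.seed(4)
  expect_identical(r, simulate_responses(beliefs, M = 1, b = 0, k = 0.03))
  set.seed(5)
  r0 <- simulate_responses(beliefs[1:50, ], M = 1, b = 0, k = 1e-12)
  expect_equal(r0, mu_sd[1:50], tolerance = 1e-9)
})

test_that("the response log likelihood matches closed-form and brute-force oracles", {
  b1 <- data.frame(mu_s = 0.5, sigma_s = 0.1, mu_d = 0.5, sigma_d = 0.1)
  mu1 <- combine_prediction(0.5, 0.1, 0.5, 0.1, M = 1, model = "weighted")$mu_sd
  expect_equal(response_loglik(mu1, b1, M = 1, k = 1), -0.5 * log(2 * pi),
               tolerance = 1e-9)

  beliefs <- synthetic_beliefs(5, seed = 6)
  set.seed(7)
  r <- runif(5, 0.3, 0.7)
  ll <- response_loglik(r, beliefs, M = 1.2, k = 0.04, b = 0.01)
  mu_sd <- combine_prediction(beliefs$mu_s, beliefs$sigma_s, beliefs$mu_d,
                              beliefs$sigma_d, M = 1.2, b = 0.01,
                              model = "weighted")$mu_sd
  expect_equal(ll, log(prod(dnorm(r, mu_sd, 0.04))), tolerance = 1e-12)
  expect_error(response_loglik(c(r[-1], NA), beliefs, M = 1, k = 0.04),
               "non-finite")
})

test_that("the likelihood is invariant to a common spatial shift", {
  beliefs <- synthetic_beliefs(100, seed = 8)
  set.seed(9)
  r <- simulate_responses(beliefs, M = 1, b = 0.01, k = 0.03)
  ll1 <- response_loglik(r, beliefs, M = 1.1, k = 0.03, b = 0.01)
  shift <- 0.17
  b2 <- beliefs
  b2$mu_s <- b2$mu_s + shift
  b2$mu_d <- b2$mu_d + shift
  ll2 <- response_loglik(r + shift, b2, M = 1.1, k = 0.03, b = 0.01)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("weighted-model parameters are recovered at large n", {
  beliefs <- synthetic_beliefs(2000, seed = 10)
  set.seed(11)
  r <- simulate_responses(beliefs, M = 1, b = 0, k = 0.02)
  fit <- fit_combination(r, beliefs, model = "weighted")
  expect_lt(abs(unname(coef(fit)["M"]) - 1), 0.1)
  expect_lt(abs(unname(coef(fit)["k"]) - 0.02), 0.002)
  expect_lt(abs(unname(coef(fit)["b"])), 0.005)
  expect_equal(fit$BIC, 3 * log(2000) - 2 * fit$logLik, tolerance = 1e-9)
})

test_that("a pure statistical responder drives M toward its upper bound", {
  beliefs <- synthetic_beliefs(300, seed = 12, sigma_s = 0.02)
  set.seed(13)
  r <- beliefs$mu_s + rnorm(300, 0, 0.01)
  fit <- fit_combination(r, beliefs, model = "weighted")
  expect_gt(unname(coef(fit)["M"]), 1.5)
})

test_that("a single-free-parameter profile fit matches a dense-grid oracle", {
  beliefs <- synthetic_beliefs(400, seed = 14)
  set.seed(15)
  r <- simulate_responses(beliefs, M = 1.3, b = 0, k = 0.03)
  fit <- fit_combination(r, beliefs, model = "weighted", free = "M")
  k_fix <- unname(coef(fit)["k"])
  dense <- seq(0, 2, length.out = 2001)
  ll <- vapply(dense, function(M)
    response_loglik(r, beliefs, M = M, k = k_fix, b = 0), 0)
  expect_equal(unname(coef(fit)["M"]), dense[which.max(ll)], tolerance = 5e-3)
  expect_equal(length(fit$free), 1L)
})

test_that("model comparison reports antisymmetric logLRs on a shared trial set", {
  beliefs <- synthetic_beliefs(200, seed = 16)
  set.seed(17)
  r <- simulate_responses(beliefs, M = 1, b = 0, k = 0.03)
  fw <- fit_combination(r, beliefs, model = "weighted")
  fu <- fit_combination(r, beliefs, model = "unweighted")
  cm <- compare_models(weighted = fw, unweighted = fu)
  expect_equal(cm$logLR["weighted", "unweighted"],
               -cm$logLR["unweighted", "weighted"], tolerance = 1e-12)
  expect_equal(cm$logLR["weighted", "weighted"], 0)
  expect_equal(cm$logLR["weighted", "unweighted"], fw$logLik - fu$logLik)
  # mismatched data are refused
  set.seed(18)
  r2 <- simulate_responses(beliefs, M = 1, b = 0, k = 0.03)
  f2 <- fit_combination(r2, beliefs, model = "weighted")
  expect_error(compare_models(fw, f2), "different responses")
})

test_that("the generating model wins the likelihood comparison in most replicates", {
  beliefs <- synthetic_beliefs(200, seed = 19)
  models <- c("weighted", "unweighted", "select")
  gen_pars <- list(weighted = c(M = 1, b = 0),
                   unweighted = c(M = 0.5, b = 0),
                   select = c(M = 1, b = 0))
  for (gen in models) {
    wins <- 0L
    for (rep in 1:10) {
      set.seed(100 * match(gen, models) + rep)
      r <- simulate_responses(beliefs, M = gen_pars[[gen]]["M"],
                              b = gen_pars[[gen]]["b"], k = 0.03, model = gen)
      ll <- vapply(models, function(m)
        fit_combination(r, beliefs, model = m)$logLik, 0)
      if (names(which.max(ll)) == gen) wins <- wins + 1L
    }
    expect_gt(wins, 5, label = sprintf("wins for generator %s", gen))
  }
})

test_that("attraction slopes hit the limiting cases and the optimal weights", {
  f <- default_session_fixture()
  b <- f$beliefs
  # responses glued to the statistical mean: slope 1 in every bin
  s1 <- attraction_slopes(b, b$mu_s)
  expect_equal(s1$slope, rep(1, 3), tolerance = 1e-9)
  # responses glued to the endpoint: slope 0 in every bin
  s0 <- attraction_slopes(b, b$x_end)
  expect_equal(s0$slope, rep(0, 3), tolerance = 1e-9)
  # and grows with trajectory noise, staying inside the meaningful range
  sopt <- attraction_slopes(b, b$x_end)  # responses irrelevant for slope_optimal
  expect_true(all(diff(sopt$slope_optimal) > 0))
  expect_true(all(sopt$slope_optimal > 0 & sopt$slope_optimal < 1))
})

test_that("the optimal-observer slope equals the analytic Bayes weight", {
  # controlled Monte-Carlo: endpoints really drawn from N(mu_s, sigma_s^2)
  # and dynamic estimates unbiased with the stated SD, so the slope in a
  # sigma_d bin converges to the mean dynamic weight sigma_d^2 /
  # (sigma_d^2 + sigma_s^2)
  set.seed(77)
  n <- 6000
  sigma_s <- 0.06
  sigma_d <- exp(runif(n, log(0.02), log(0.15)))
  x <- rnorm(n, 0.5, sigma_s)
  beliefs <- data.frame(trial = 1:n, x_end = x, mu_s = 0.5, sigma_s = sigma_s,
                        mu_d = x + rnorm(n, 0, sigma_d), sigma_d = sigma_d)
  sopt <- attraction_slopes(beliefs, beliefs$x_end)
  qs <- quantile(sigma_d, c(0, 1/3, 2/3, 1))
  bin <- cut(sigma_d, unique(qs), include.lowest = TRUE, labels = FALSE)
  wbar <- as.numeric(tapply(sigma_d^2 / (sigma_d^2 + sigma_s^2), bin, mean))
  expect_equal(sopt$slope_optimal, wbar, tolerance = 0.05)
})

test_that("synthetic precision-weighting participants show rising attraction across noise bins", {
  f <- default_session_fixture()
  b <- f$beliefs
  slopes <- t(vapply(1:6, function(i) {
    set.seed(500 + i)
    r <- simulate_responses(b, M = 1, b = 0, k = 0.03)
    attraction_slopes(b, r)$slope
  }, numeric(3)))
  med <- apply(slopes, 2, median)
  expect_true(all(diff(med) > 0))
  trend <- attraction_trend_test(slopes)
  expect_gt(trend$t, 0)
  expect_lt(trend$p, 0.05)
})
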