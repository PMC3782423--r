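#' Specification of a synthetic participant cohort
#'
#' Defaults mirror the study conditions: 22 participants, 220-trial sessions
#' with 20 noise-free warmup trials, responses generated from the weighted
#' combination rule with per-participant parameters drawn around the optimal
#' values — \code{M} uniform on [0.7, 1.3], response noise \code{k} uniform
#' on [0.02, 0.05] screen widths, bias \code{b} uniform on [-0.02, 0.02].
#'
#' @param n_participants number of synthetic participants (default 22).
#' @param model generating combination rule.
#' @param M_range,k_range,b_range per-participant parameter draw intervals.
#' @param task a [task_config()] used for every participant's session.
#' @param grid a [grid_config()] for the ideal observer.
#' @param seed master seed; participant \code{i} uses \code{seed * 100 + i}.
#' @return a \code{cohort_spec} list.
#' @export
cohort_spec <- function(n_participants = 22L,
                        model = "weighted",
                        M_range = c(0.7, 1.3),
                        k_range = c(0.02, 0.05),
                        b_range = c(-0.02, 0.02),
                        task = task_config(),
                        grid = grid_config(),
                        seed = 1L) {
  stopifnot(n_participants >= 1L)
  hi <- M_bounds(model)[2]
  if (M_range[1] < 0 || M_range[2] > hi)
    stop("M_range outside the generating model's bounds", call. = FALSE)
  if (k_range[1] <= 0) stop("k_range must be positive", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants), model = model,
                 M_range = M_range, k_range = k_range, b_range = b_range,
                 task = task, grid = grid, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate one synthetic participant
#'
#' Generates a session, runs the ideal observer and the dynamic model, draws
#' the participant's \code{(M, k, b)} from the cohort distributions, and
#' simulates responses on the analysis trials under the generating rule.
#'
#' @param spec a [cohort_spec()].
#' @param i participant index (1-based); fixes the participant's seed.
#' @return a list: \code{beliefs} (analysis-trial belief table),
#'   \code{responses}, \code{params} (true \code{M}, \code{k}, \code{b}),
#'   \code{session}.
#' @export
simulate_participant <- function(spec, i) {
  stopifnot(inherits(spec, "cohort_spec"), i >= 1L, i <= spec$n_participants)
  seed_i <- spec$seed * 100L + as.integer(i)
  session <- generate_session(spec$task, seed = seed_i)
  stat <- run_filter(session, spec$grid)
  dyn <- run_dynamic(session)
  beliefs <- belief_table(session, stat, dyn)
  params <- c(M = stats::runif(1, spec$M_range[1], spec$M_range[2]),
              k = stats::runif(1, spec$k_range[1], spec$k_range[2]),
              b = stats::runif(1, spec$b_range[1], spec$b_range[2]))
  responses <- simulate_responses(beliefs, M = params["M"], b = params["b"],
                                  k = params["k"], model = spec$model)
  list(beliefs = beliefs, responses = responses, params = params,
       session = session)
}

#' Model-recovery experiment over a synthetic cohort
#'
#' For each synthetic participant, fits all three combination rules to the
#' simulated responses by maximum likelihood and tabulates the log
#' likelihood ratios of the weighted-combination fit against the other two.
#'
#' @param spec a [cohort_spec()].
#' @param verbose print per-participant progress.
#' @return an object of class \code{model_recovery}: a per-participant
#'   data.frame (true parameters, fitted logLiks, \code{logLR_w_vs_unw},
#'   \code{logLR_w_vs_sel}) with a summary \code{print} method.
#' @export
run_model_recovery <- function(spec = cohort_spec(), verbose = FALSE) {
  rows <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    p <- simulate_participant(spec, i)
    fw <- fit_combination(p$responses, p$beliefs, model = "weighted")
    fu <- fit_combination(p$responses, p$beliefs, model = "unweighted")
    fs <- fit_combination(p$responses, p$beliefs, model = "select")
    rows[[i]] <- data.frame(
      participant = i,
      M_true = p$params["M"], k_true = p$params["k"], b_true = p$params["b"],
      M_hat = coef(fw)["M"], k_hat = coef(fw)["k"], b_hat = coef(fw)["b"],
      logLik_weighted = fw$logLik,
      logLik_unweighted = fu$logLik,
      logLik_select = fs$logLik,
      logLR_w_vs_unw = fw$logLik - fu$logLik,
      logLR_w_vs_sel = fw$logLik - fs$logLik,
      row.names = NULL)
    if (verbose)
      message(sprintf("participant %d: logLR(w,unw) = %.1f, logLR(w,sel) = %.1f",
                      i, rows[[i]]$logLR_w_vs_unw, rows[[i]]$logLR_w_vs_sel))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("model_recovery", "data.frame")
  out
}

#' @export
print.model_recovery <- function(x, ...) {
  cat(sprintf("Model recovery over %d synthetic participants (generator: weighted)\n",
              nrow(x)))
  cat(sprintf("  weighted vs unweighted: summed logLR = %.1f; logLR > 0 for %d/%d\n",
              sum(x$logLR_w_vs_unw), sum(x$logLR_w_vs_unw > 0), nrow(x)))
  cat(sprintf("  weighted vs select:     summed logLR = %.1f; logLR > 0 for %d/%d (min %.1f)\n",
              sum(x$logLR_w_vs_sel), sum(x$logLR_w_vs_sel > 0), nrow(x),
              min(x$logLR_w_vs_sel)))
  invisible(x)
}

#' Parameter-recovery experiment for the weighted combination model
#'
#' Simulates responses at known \code{(M, k, b)} over seeded replicates and
#' summarizes the bias and RMSE of the maximum-likelihood estimates. One
#' session per seed is generated and reused across parameter cells.
#'
#' @param true_params data.frame with columns \code{M}, \code{k}, \code{b}
#'   (one row per cell).
#' @param n_trials analysis trials per replicate (session trials =
#'   \code{n_trials + warmup}).
#' @param seeds integer vector of replicate seeds.
#' @param task,grid configs for session generation and the observer.
#' @return a data.frame: per cell and parameter, the mean estimate, bias and
#'   RMSE across seeds.
#' @export
run_parameter_recovery <- function(true_params = data.frame(M = 1, k = 0.02, b = 0),
                                   n_trials = 200L,
                                   seeds = 1:10,
                                   task = NULL, grid = grid_config()) {
  if (is.null(task))
    task <- task_config(n_trials = n_trials + 20L)
  est <- list()
  for (s in seeds) {
    session <- generate_session(task, seed = s)
    stat <- run_filter(session, grid)
    dyn <- run_dynamic(session)
    beliefs <- belief_table(session, stat, dyn)
    beliefs <- beliefs[seq_len(min(n_trials, nrow(beliefs))), ]
    for (ci in seq_len(nrow(true_params))) {
      set.seed(s * 1000L + ci)
      r <- simulate_responses(beliefs, M = true_params$M[ci],
                              b = true_params$b[ci], k = true_params$k[ci])
      f <- fit_combination(r, beliefs, model = "weighted")
      est[[length(est) + 1L]] <- data.frame(
        cell = ci, seed = s,
        M_true = true_params$M[ci], k_true = true_params$k[ci],
        b_true = true_params$b[ci],
        M_hat = coef(f)["M"], k_hat = coef(f)["k"], b_hat = coef(f)["b"],
        row.names = NULL)
    }
  }
  est <- do.call(rbind, est)
  out <- lapply(split(est, est$cell), function(d) {
    data.frame(cell = d$cell[1],
               M_true = d$M_true[1], k_true = d$k_true[1], b_true = d$b_true[1],
               M_mean = mean(d$M_hat), M_bias = mean(d$M_hat - d$M_true),
               M_rmse = sqrt(mean((d$M_hat - d$M_true)^2)),
               k_mean = mean(d$k_hat), k_bias = mean(d$k_hat - d$k_true),
               k_rmse = sqrt(mean((d$k_hat - d$k_true)^2)),
               b_mean = mean(d$b_hat), b_bias = mean(d$b_hat - d$b_true),
               b_rmse = sqrt(mean((d$b_hat - d$b_true)^2)),
               n_seeds = nrow(d))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Endpoint equivalence of the sequential-prior model and optimal weighting
#'
#' For each analysis trial of a generated session, compares the fitted value
#' at the occluder exit from [sequential_estimate_with_prior()] using all
#' observed samples against the precision-weighted combination
#' (\code{M = 1}, \code{b = 0}) of the known-variance dynamic estimate with
#' the statistical prior. The two are algebraically identical at the
#' endpoint; this reports the maximal numerical discrepancy observed.
#'
#' @param n_trials number of analysis trials to check.
#' @param seed session seed.
#' @param task,grid configs.
#' @return a list: \code{max_mu_diff}, \code{max_sigma_diff}, \code{n}.
#' @export
run_equivalence_check <- function(n_trials = 100L, seed = 1L,
                                  task = task_config(), grid = grid_config()) {
  session <- generate_session(task, seed = seed)
  stat <- run_filter(session, grid)
  dyn <- run_dynamic(session, noise_sd_mode = "known")
  beliefs <- belief_table(session, stat, dyn)
  beliefs <- beliefs[seq_len(min(n_trials, nrow(beliefs))), ]
  dmu <- dsig <- numeric(nrow(beliefs))
  for (j in seq_len(nrow(beliefs))) {
    tr <- beliefs$trial[j]
    obs <- observed_samples(session, tr)
    prior <- gaussian_belief(beliefs$mu_s[j], beliefs$sigma_s[j],
                             role = "statistical")
    seq_b <- sequential_estimate_with_prior(
      obs$t, obs$obs_x, prior,
      noise_sd = beliefs$sigma_noise[j],
      t_end = session$config$traj_duration_s)
    comb <- combine_prediction(beliefs$mu_s[j], beliefs$sigma_s[j],
                               beliefs$mu_d[j], beliefs$sigma_d[j],
                               M = 1, b = 0, model = "weighted")
    dmu[j] <- abs(seq_b$mu - comb$mu_sd)
    dsig[j] <- abs(seq_b$sigma - comb$sigma_sd)
  }
  list(max_mu_diff = max(dmu), max_sigma_diff = max(dsig), n = nrow(beliefs))
}
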