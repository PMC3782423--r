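# Shared fixtures, computed lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# a default-configuration session with observer and dynamic-model runs
default_session_fixture <- function() {
  if (is.null(.fixtures$default)) {
    session <- generate_session(task_config(), seed = 101L)
    stat <- run_filter(session)
    dyn <- run_dynamic(session)
    .fixtures$default <- list(session = session, stat = stat, dyn = dyn,
                              beliefs = belief_table(session, stat, dyn))
  }
  .fixtures$default
}

# a small synthetic belief table not tied to any session (fast fitting tests)
synthetic_beliefs <- function(n, seed = 1L, sigma_s = 0.05) {
  set.seed(seed)
  data.frame(trial = seq_len(n),
             x_end = stats::runif(n, 0.2, 0.8),
             mu_s = stats::runif(n, 0.4, 0.6),
             sigma_s = sigma_s,
             mu_d = stats::runif(n, 0.2, 0.8),
             sigma_d = exp(stats::runif(n, log(0.02), log(0.15))))
}

# tiny observer grid for hand-checkable updates
tiny_grid <- function(mu, sigma, alpha_mu = 0, alpha_sigma = 0) {
  init_grid(grid_config(mu = mu, sigma = sigma,
                        alpha_mu = alpha_mu, alpha_sigma = alpha_sigma))
}
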