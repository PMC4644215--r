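#' Replicated-chain simulation study
#'
#' Reproduces the sampler's canonical operating-characteristics experiment:
#' simulate one dataset (by default 30 items with difficulties uniform on
#' (-2, 2) and 100,000 standard-normal respondents), then run many
#' independent Gibbs chains from uniform(0, 1) starts and record one
#' monitored item parameter and one monitored score parameter at every
#' iteration.  The cross-replication samples estimate the distribution of
#' each parameter at each iteration (for ECDF convergence checks) and the
#' autocorrelation between any two iterations.
#'
#' @param n_chains number of replicated chains.
#' @param n_iter iterations per chain (all retained).
#' @param n_items,m simulated test length and number of respondents.
#' @param monitor_item,monitor_score indices of the monitored item
#'   parameter and score parameter.
#' @param seed master seed: drives the simulated dataset and the
#'   per-chain seeds.
#' @param config_args extra arguments passed to [chain_config()].
#' @return list with matrices `b_trace` and `lambda_trace`
#'   (`n_chains x n_iter`), the true `delta`, and the
#'   [sufficient_statistics()] of the simulated data.
#' @export
replication_study <- function(n_chains = 500L, n_iter = 109L,
                              n_items = 30L, m = 1e5,
                              monitor_item = 2L, monitor_score = 10L,
                              seed = 1L, config_args = list()) {
  set.seed(seed)
  delta <- runif(n_items, -2, 2)
  X <- simulate_latent_rasch(m, delta)
  stats <- sufficient_statistics(X)
  rm(X)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, n_chains)
  tb <- matrix(NA_real_, n_chains, n_iter)
  tl <- matrix(NA_real_, n_chains, n_iter)
  for (r in seq_len(n_chains)) {
    cfg <- do.call(chain_config,
                   c(list(n_iter = n_iter, burn_in = 0L,
                          seed = chain_seeds[r], keep_all = TRUE),
                     config_args))
    d <- gibbs_run(stats, config = cfg)
    tb[r, ] <- d$b[, monitor_item]
    tl[r, ] <- d$lambda[, monitor_score + 1L]
  }
  list(b_trace = tb, lambda_trace = tl, delta = delta, stats = stats,
       monitor_item = monitor_item, monitor_score = monitor_score)
}
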