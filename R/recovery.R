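#' Parameter-recovery simulation study
#'
#' Simulates replicate cohorts from a known coefficient set, refits the
#' model on each, and summarizes how well the posterior recovers the truth:
#' pooled 95% credible-interval coverage, mean absolute error of the
#' posterior means, and the largest split Gelman-Rubin statistic per fit.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param spec A [simulation_spec()] describing each cohort.
#' @param n_iter,burnin,thin,n_chains Chain protocol passed to
#'   [mcmc_sample()].
#' @param seed Base seed; replicate `k` simulates with `seed + k` and fits
#'   with `seed + 1000 + k`.
#' @param prob Credible mass for the coverage check (default 0.95).
#' @return List with `coverage` (pooled proportion of true coefficients
#'   inside their credible interval), `mean_abs_error`, `rhat_max` (vector,
#'   one per replicate), `n_coefficients`, and the per-replicate `details`
#'   data frame.
#' @export
recovery_study <- function(n_replicates, spec, n_iter = 4000, burnin = 1000,
                           thin = 5, n_chains = 2, seed = 1, prob = 0.95) {
  truth <- coef_vector(spec$coefficients)
  a <- (1 - prob) / 2
  covered <- err <- rhat_max <- numeric(0)
  details <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    ch <- simulate_cohort(spec, seed = seed + k)
    fit <- mcmc_sample(ch, n_iter = n_iter, burnin = burnin, thin = thin,
                       n_chains = n_chains, seed = seed + 1000L + k)
    d <- all_draws(fit)
    pm <- colMeans(d)
    lo <- apply(d, 2, quantile, a)
    hi <- apply(d, 2, quantile, 1 - a)
    covered <- c(covered, truth >= lo & truth <= hi)
    err <- c(err, abs(pm - truth))
    rhat_max <- c(rhat_max, max(gelman_rubin(fit)))
    details[[k]] <- data.frame(replicate = k, coefficient = fit$coef_names,
                               truth = truth, mean = pm, lower = lo,
                               upper = hi, row.names = NULL)
  }
  list(coverage = mean(covered), mean_abs_error = mean(err),
       rhat_max = rhat_max, n_coefficients = length(truth),
       details = do.call(rbind, details))
}
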