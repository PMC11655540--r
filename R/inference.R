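mask_levels <- c("free", "present", "absent", "dead")

#' Known-state mask from the observed record
#'
#' Derives, for every individual-year, which latent states are fixed by the
#' data: the registration year is forced present, any year with a positive
#' list indicator is forced present, years from a recorded de-registration
#' up to (exclusive) the next recorded re-registration are forced absent
#' (with the year before the de-registration forced present), and years from
#' a recorded death onward are forced dead (again with the previous year
#' forced present, since only deaths of present individuals are recorded).
#'
#' "Forced absent" is interpreted as known-not-present: the individual is
#' certainly absent (alive) in the de-registration year itself, but may die
#' abroad, unrecorded, later in the span; the likelihood therefore keeps the
#' dead state admissible there while excluding presence.
#'
#' @param data A `cr_cohort`.
#' @param config A [model_config()]; defaults to the cohort's.
#' @return Data frame `id`, `year`, `known` with values
#'   `"free"`, `"present"`, `"absent"`, `"dead"`.
#' @export
known_state_mask <- function(data, config = data$config) {
  ind <- data$individuals
  last <- config$last_year
  ids <- ind$id
  lens <- last - ind$registration_year + 1L
  id_col <- rep(ids, lens)
  year_col <- unlist(lapply(seq_along(ids),
                            function(i) ind$registration_year[i]:last),
                     use.names = FALSE)
  code <- integer(length(id_col))
  key <- paste(id_col, year_col)
  idx_of <- function(id, year) match(paste(id, year), key)

  # registration year and detected years force presence
  code[year_col == rep(ind$registration_year, lens)] <- 1L
  obs <- data$observations
  if (nrow(obs)) code[idx_of(obs$id, obs$year)] <- 1L

  ev <- data$events
  for (id in unique(ev$id)) {
    sub <- ev[ev$id == id, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    mig <- sub[sub$event != "death", , drop = FALSE]
    k <- 1L
    while (k <= nrow(mig)) {
      stopifnot(mig$event[k] == "deregister")
      ye <- mig$year[k]
      yr <- if (k + 1L <= nrow(mig)) mig$year[k + 1L] else last + 1L
      code[idx_of(id, ye:min(yr - 1L, last))] <- 2L
      if (ye - 1L >= min(year_col[id_col == id]))
        code[idx_of(id, ye - 1L)] <- 1L
      if (yr <= last) code[idx_of(id, yr)] <- 1L
      k <- k + 2L
    }
    dth <- sub[sub$event == "death", , drop = FALSE]
    if (nrow(dth)) {
      yd <- dth$year[1]
      code[idx_of(id, yd:last)] <- 3L
      code[idx_of(id, yd - 1L)] <- 1L
    }
  }
  data.frame(id = id_col, year = year_col,
             known = mask_levels[code + 1L], stringsAsFactors = FALSE)
}

# Pack a cohort into the flat arrays consumed by the C++ kernels.
# Rows are individual-years ordered by individual (individuals-table order)
# then year (registration..last).
pack_cohort <- function(data, config = data$config, ids = NULL) {
  ind <- data$individuals
  if (!is.null(ids)) ind <- ind[ind$id %in% ids, , drop = FALSE]
  last <- config$last_year
  lens <- last - ind$registration_year + 1L
  id_col <- rep(ind$id, lens)
  year_col <- unlist(lapply(seq_len(nrow(ind)),
                            function(i) ind$registration_year[i]:last),
                     use.names = FALSE)
  n <- length(id_col)
  key <- paste(id_col, year_col)
  X <- panel_design(data$individuals, id_col, year_col, config)
  O <- matrix(0L, n, config$n_lists)
  obs <- data$observations
  if (!is.null(ids)) obs <- obs[obs$id %in% ind$id, , drop = FALSE]
  if (nrow(obs)) {
    ridx <- match(paste(obs$id, obs$year), key)
    O[cbind(ridx, obs$list_id)] <- 1L
  }
  e <- integer(n); d <- integer(n)
  ev <- data$events
  if (!is.null(ids)) ev <- ev[ev$id %in% ind$id, , drop = FALSE]
  if (nrow(ev)) {
    ridx <- match(paste(ev$id, ev$year), key)
    e[ridx[ev$event == "deregister"]] <- 1L
    d[ridx[ev$event == "death"]] <- 1L
  }
  mask_df <- known_state_mask(
    list(individuals = ind, observations = obs, events = ev, config = config),
    config)
  mask <- match(mask_df$known, mask_levels) - 1L
  list(X = X, O = O, e = e, d = d, anyobs = as.integer(rowSums(O) > 0),
       mask = mask, ptr = c(0L, cumsum(lens)), id = id_col, year = year_col,
       ind_ids = ind$id, L = config$n_lists, p = ncol(X))
}

#' Marginal log-likelihood of a cohort
#'
#' Log-probability of all observed records and events given the regression
#' coefficients, with the latent present/absent/dead trajectories summed out
#' by a forward recursion per individual, respecting the known-state mask.
#'
#' @param data A `cr_cohort`.
#' @param params A [coefficient_set()].
#' @param config A [model_config()]; defaults to the cohort's.
#' @return List with `total` and the per-individual vector `by_individual`
#'   (named by id). Records impossible under the mask give `-Inf` and raise
#'   a data-inconsistency warning.
#' @export
cohort_loglik <- function(data, params, config = data$config) {
  pk <- pack_cohort(data, config)
  res <- cpp_cohort_loglik(pk$X, coef_matrix(params), pk$O, pk$anyobs, pk$e,
                           pk$d, pk$mask, pk$ptr)
  by_ind <- as.numeric(res$by_individual)
  names(by_ind) <- pk$ind_ids
  if (any(!is.finite(by_ind)))
    warning("record inconsistent with known-state mask for individual(s): ",
            paste(pk$ind_ids[!is.finite(by_ind)], collapse = ", "))
  list(total = res$total, by_individual = by_ind)
}

#' Marginal log-likelihood of one individual's record
#'
#' @inheritParams cohort_loglik
#' @param id Individual id.
#' @return Log-probability (`-Inf` for records impossible under the mask).
#' @export
individual_loglik <- function(data, params, id, config = data$config) {
  pk <- pack_cohort(data, config, ids = id)
  res <- cpp_cohort_loglik(pk$X, coef_matrix(params), pk$O, pk$anyobs, pk$e,
                           pk$d, pk$mask, pk$ptr)
  ll <- as.numeric(res$total)
  if (!is.finite(ll))
    warning("record inconsistent with known-state mask for individual ", id)
  ll
}

# ---- low-level probability parameterization -------------------------------
# `probs`: list(phi, psi, eta, lambda: length-Y vectors; theta: Y x L matrix)
# `obs`:   list(o: Y x L 0/1 matrix, e, d: length-Y 0/1 vectors)
# `mask`:  character vector over mask levels (or 0..3 integer codes).

mask_codes <- function(mask) {
  if (is.character(mask)) {
    m <- match(mask, mask_levels) - 1L
    if (anyNA(m)) stop("mask values must be in ", paste(mask_levels, collapse = "/"))
    m
  } else as.integer(mask)
}

pdet_rows <- function(theta, o) {
  apply(ifelse(o == 1, theta, 1 - theta), 1, prod)
}

#' Forward-recursion log-likelihood of one record (probability scale)
#'
#' Low-level entry point taking yearly probabilities directly instead of
#' covariates and coefficients; the first year is the registration year.
#'
#' @param probs List with vectors `phi`, `psi`, `eta`, `lambda` (length `Y`)
#'   and matrix `theta` (`Y x L`).
#' @param obs List with matrix `o` (`Y x L`) and vectors `e`, `d`.
#' @param mask Character or integer known-state mask of length `Y`.
#' @return Log-probability of the record.
#' @export
forward_loglik <- function(probs, obs, mask) {
  o <- as.matrix(obs$o)
  cpp_forward(probs$phi, probs$psi, probs$eta, probs$lambda,
              pdet_rows(as.matrix(probs$theta), o),
              as.integer(rowSums(o) > 0), as.integer(obs$e), as.integer(obs$d),
              mask_codes(mask), FALSE)$loglik
}

#' Forward-backward state posterior of one record (probability scale)
#'
#' @inheritParams forward_loglik
#' @return `Y x 3` matrix of smoothed probabilities over
#'   present/absent/dead, conditioning on the whole record.
#' @export
forward_backward <- function(probs, obs, mask) {
  o <- as.matrix(obs$o)
  res <- cpp_forward(probs$phi, probs$psi, probs$eta, probs$lambda,
                     pdet_rows(as.matrix(probs$theta), o),
                     as.integer(rowSums(o) > 0), as.integer(obs$e),
                     as.integer(obs$d), mask_codes(mask), TRUE)
  g <- res$state_posterior
  colnames(g) <- latent_states()
  g
}

# R-side emission/transition mirror used by the enumeration oracle.
emission_M_r <- function(j, probs, obs, pdet) {
  f <- probs$phi[j]; p <- probs$psi[j]; h <- probs$eta[j]; l <- probs$lambda[j]
  ao <- sum(obs$o[j, ]) > 0; e <- obs$e[j]; d <- obs$d[j]
  emP <- if (e == 0 && d == 0) pdet[j] else 0
  emAP <- if (!ao && d == 0) (if (e == 1) l else 1 - l) else 0
  emAA <- if (!ao && d == 0 && e == 0) 1 else 0
  emDP <- if (!ao && e == 0 && d == 1) 1 else 0
  emDO <- if (!ao && e == 0 && d == 0) 1 else 0
  matrix(c(f * p * emP, f * (1 - p) * emAP, (1 - f) * emDP,
           f * h * emP, f * (1 - h) * emAA, (1 - f) * emDO,
           0,           0,                  emDO),
         3, 3, byrow = TRUE)
}

enumerate_paths_probs <- function(probs, obs, mask) {
  o <- as.matrix(obs$o)
  Y <- nrow(o)
  m <- mask_codes(mask)
  n_free <- sum(m == 0L)
  if (n_free > 12)
    stop("brute-force enumeration is limited to 12 free years (3^12 paths); got ",
         n_free)
  pdet <- pdet_rows(as.matrix(probs$theta), o)
  # "absent" rules out presence only: a de-registered individual may die
  # abroad later in the span without the death being recorded
  allowed <- lapply(m, function(k)
    if (k == 0L) 1:3 else if (k == 2L) 2:3 else k)
  allowed[[1]] <- intersect(allowed[[1]], 1L)  # registration year: present
  if (!length(allowed[[1]])) return(list(paths = NULL, prob = numeric()))
  paths <- as.matrix(expand.grid(rev(allowed)))[, Y:1, drop = FALSE]
  Ms <- if (Y > 1) lapply(2:Y, function(j) emission_M_r(j, probs, obs, pdet))
  init <- if (obs$e[1] == 0 && obs$d[1] == 0) pdet[1] else 0
  pr <- rep(init, nrow(paths))
  if (Y > 1)
    for (j in 2:Y)
      pr <- pr * Ms[[j - 1]][cbind(paths[, j - 1], paths[, j])]
  list(paths = paths, prob = pr)
}

#' Path-enumeration log-likelihood (testing oracle)
#'
#' Computes the same marginal likelihood as [forward_loglik()] by exhaustive
#' enumeration of every admissible latent state sequence. Exponential in the
#' number of free years (refuses beyond 12); intended for verification on
#' small records only.
#'
#' @inheritParams forward_loglik
#' @return Log-probability of the record.
#' @export
enumerate_loglik <- function(probs, obs, mask) {
  en <- enumerate_paths_probs(probs, obs, mask)
  log(sum(en$prob))
}

#' Path-enumeration smoothed state posterior (testing oracle)
#'
#' @inheritParams forward_loglik
#' @return `Y x 3` matrix of conditional state probabilities given the whole
#'   record, by exhaustive path enumeration.
#' @export
enumerate_state_posterior <- function(probs, obs, mask) {
  en <- enumerate_paths_probs(probs, obs, mask)
  Y <- nrow(as.matrix(obs$o))
  tot <- sum(en$prob)
  g <- sapply(1:3, function(s)
    vapply(1:Y, function(j) sum(en$prob[en$paths[, j] == s]) / tot, numeric(1)))
  colnames(g) <- latent_states()
  g
}

#' Brute-force log-likelihood of one individual (testing oracle)
#'
#' Record-level wrapper around [enumerate_loglik()]: builds the yearly
#' probabilities from the cohort's covariates and a coefficient set, then
#' enumerates all admissible latent paths.
#'
#' @inheritParams individual_loglik
#' @return Log-probability of the individual's record.
#' @export
brute_force_loglik <- function(data, params, id, config = data$config) {
  pk <- pack_cohort(data, config, ids = id)
  probs <- list(phi = plogis(drop(pk$X %*% params$phi)),
                psi = plogis(drop(pk$X %*% params$psi)),
                eta = plogis(drop(pk$X %*% params$eta)),
                lambda = plogis(drop(pk$X %*% params$lambda)),
                theta = plogis(pk$X %*% t(params$o)))
  enumerate_loglik(probs, list(o = pk$O, e = pk$e, d = pk$d), pk$mask)
}

#' Log-prior density of the coefficients
#'
#' Independent normal prior with mean zero and common variance `delta` on
#' every regression coefficient of every linear predictor.
#'
#' @param params A [coefficient_set()].
#' @param delta Prior variance (default 2).
#' @return Log-density.
#' @export
log_prior <- function(params, delta = 2) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("`delta` must be a single positive number")
  sum(dnorm(coef_vector(params), mean = 0, sd = sqrt(delta), log = TRUE))
}

# Warm starting values for the sampler: impute the latent trajectory with a
# deterministic register-trace rule (present between detections, absent after
# the last detection, events as recorded) and fit one logistic regression per
# linear predictor on the imputed complete data. Shrunk towards zero and
# capped so separation in sparse predictors cannot produce extreme starts.
warm_init <- function(pk) {
  n <- nrow(pk$X)
  z <- rep(NA_integer_, n)
  z[pk$anyobs == 1L | pk$mask == 1L] <- 1L
  z[pk$mask == 2L] <- 2L
  z[pk$mask == 3L] <- 3L
  first_row <- pk$ptr[-length(pk$ptr)] + 1L
  ind_of <- rep(seq_along(first_row), diff(pk$ptr))
  # free years: present if a detection/forced-present year follows, else absent
  later_present <- stats::ave(z == 1L & !is.na(z), ind_of,
                              FUN = function(v) rev(cummax(rev(v))))
  z[is.na(z)] <- ifelse(later_present[is.na(z)] > 0, 1L, 2L)
  prev_z <- c(NA_integer_, z[-n])
  prev_z[first_row] <- NA_integer_

  fit1 <- function(sel, y) {
    sel <- sel & !is.na(y)
    if (sum(sel) < 2L * pk$p || length(unique(y[sel])) < 2) return(rep(0, pk$p))
    co <- tryCatch(
      suppressWarnings(stats::glm.fit(pk$X[sel, , drop = FALSE], y[sel],
                                      family = stats::binomial())$coefficients),
      error = function(e) rep(0, pk$p))
    co[!is.finite(co)] <- 0
    pmin(pmax(0.8 * co, -3), 3)
  }
  theta <- t(vapply(seq_len(pk$L),
                    function(l) fit1(z == 1L, pk$O[, l]), numeric(pk$p)))
  alive_prev <- !is.na(prev_z) & prev_z != 3L
  rbind(theta,
        fit1(alive_prev, as.numeric(z != 3L)),                      # phi
        fit1(alive_prev & prev_z == 1L & z != 3L, as.numeric(z == 1L)),  # psi
        fit1(alive_prev & prev_z == 2L & z != 3L, as.numeric(z == 1L)),  # eta
        fit1(alive_prev & prev_z == 1L & z == 2L, as.numeric(pk$e)))     # lambda
}

#' Sample the posterior of the regression coefficients
#'
#' Blocked adaptive random-walk Metropolis on the marginalized posterior
#' `log prior + sum_i individual log-likelihood`: one block per linear
#' predictor (each detection list, survival, staying, returning,
#' de-registration). Each block adapts a scalar step size towards the target
#' acceptance rate and an empirical proposal covariance during burn-in only;
#' adaptation is frozen afterwards. Latent trajectories are never sampled --
#' they are summed out exactly by the forward recursion, and smoothed
#' presence probabilities are recovered afterwards with
#' [presence_posterior()].
#'
#' @param data A `cr_cohort`.
#' @param config A [model_config()]; defaults to the cohort's.
#' @param n_iter,burnin,thin Chain protocol; defaults 15000 / 5000 / 10 keep
#'   1000 draws per chain.
#' @param n_chains Number of independent chains (default 2).
#' @param seed Integer seed; chain `c` uses `seed + 7907 * (c - 1)`.
#' @param init_sd Per-chain initialization jitter: chains start from the
#'   warm start plus `N(0, init_sd^2)` noise.
#' @param prior_only If `TRUE` the likelihood is switched off and the
#'   sampler targets the prior (sampler validation).
#' @param target_accept Target block acceptance rate (default 0.234).
#' @param sweeps Metropolis updates of every block per iteration (default 2);
#'   more sweeps raise the effective sample size per retained draw at
#'   proportional cost.
#' @return An object of class `cr_fit`: per-chain draw matrices with columns
#'   named `<predictor>.<covariate>`, acceptance rates, protocol metadata.
#' @export
mcmc_sample <- function(data, config = data$config, n_iter = 15000,
                        burnin = 5000, thin = 10, n_chains = 2, seed = 1,
                        init_sd = 0.1, prior_only = FALSE,
                        target_accept = 0.234, sweeps = 2) {
  stopifnot(n_iter > burnin, burnin >= 1, thin >= 1, n_chains >= 1)
  pk <- pack_cohort(data, config)
  K <- (pk$L + 4L) * pk$p

  # fail fast on data inconsistent with the known-state mask
  zero <- coefficients_from_vector(rep(0, K), pk$L, pk$p)
  chk <- cpp_cohort_loglik(pk$X, coef_matrix(zero), pk$O, pk$anyobs, pk$e,
                           pk$d, pk$mask, pk$ptr)
  if (any(!is.finite(chk$by_individual))) {
    bad <- pk$ind_ids[!is.finite(chk$by_individual)]
    stop("data inconsistent with known-state mask for individual(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }

  nm <- coef_names(pk$L, config)
  chain_seeds <- seed + 7907L * (seq_len(n_chains) - 1L)
  warm <- if (prior_only) matrix(0, pk$L + 4L, pk$p) else warm_init(pk)
  t0 <- proc.time()[["elapsed"]]
  chains <- lapply(seq_len(n_chains), function(ch) {
    set.seed(chain_seeds[ch])
    beta0 <- warm + matrix(rnorm(K, 0, init_sd), nrow = pk$L + 4L,
                           ncol = pk$p, byrow = TRUE)
    res <- cpp_mcmc(pk$X, pk$O, pk$anyobs, pk$e, pk$d, pk$mask, pk$ptr,
                    beta0, config$prior_variance, as.integer(n_iter),
                    as.integer(burnin), as.integer(thin), !prior_only,
                    target_accept, as.integer(sweeps))
    colnames(res$draws) <- nm
    res
  })
  out <- list(
    draws = lapply(chains, `[[`, "draws"),
    acceptance = do.call(rbind, lapply(chains, function(x)
      setNames(as.numeric(x$accept_rate), predictor_labels(pk$L)))),
    loglik = lapply(chains, `[[`, "loglik"),
    coef_names = nm, L = pk$L, p = pk$p, config = config,
    protocol = list(n_iter = n_iter, burnin = burnin, thin = thin,
                    n_chains = n_chains, seed = seed,
                    chain_seeds = chain_seeds, init_sd = init_sd,
                    prior_only = prior_only, target_accept = target_accept,
                    sweeps = sweeps),
    elapsed = proc.time()[["elapsed"]] - t0)
  class(out) <- "cr_fit"
  out
}

#' @export
print.cr_fit <- function(x, ...) {
  cat("Posterior fit:", length(x$draws), "chain(s) x", nrow(x$draws[[1]]),
      "retained draws,", length(x$coef_names), "coefficients\n")
  cat("  protocol:", x$protocol$n_iter, "iterations, burn-in",
      x$protocol$burnin, ", thin", x$protocol$thin, "\n")
  cat("  block acceptance rates (post burn-in):\n")
  print(round(colMeans(x$acceptance), 3))
  invisible(x)
}

#' Posterior means and credible intervals of the coefficients
#'
#' @param object A `cr_fit`.
#' @param prob Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return Data frame with coefficient, posterior mean, sd, lower, upper.
#' @export
summary.cr_fit <- function(object, prob = 0.95, ...) {
  d <- do.call(rbind, object$draws)
  a <- (1 - prob) / 2
  data.frame(coefficient = colnames(d), mean = colMeans(d),
             sd = apply(d, 2, stats::sd),
             lower = apply(d, 2, quantile, a),
             upper = apply(d, 2, quantile, 1 - a), row.names = NULL)
}

all_draws <- function(fit) do.call(rbind, fit$draws)

#' Smoothed yearly presence probabilities
#'
#' For every individual-year, the posterior probability of being present in
#' the country given the individual's whole record, averaged over the
#' retained posterior draws: forward-backward smoothing per draw. Years
#' forced by the data return exactly 1 (registration, detection,
#' re-registration) or 0 (de-registered or dead spans).
#'
#' @param fit A `cr_fit`.
#' @param data The `cr_cohort` that was fitted.
#' @param config A [model_config()]; defaults to the fit's.
#' @return Data frame `id`, `year`, `zhat`.
#' @export
presence_posterior <- function(fit, data, config = fit$config) {
  pk <- pack_cohort(data, config)
  res <- cpp_presence(pk$X, pk$O, pk$anyobs, pk$e, pk$d, pk$mask, pk$ptr,
                      all_draws(fit), rep(-1L, nrow(pk$X)), 0L)
  data.frame(id = pk$id, year = pk$year, zhat = as.numeric(res$zhat))
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential-scale-reduction statistic per coefficient from the
#' between/within-chain variance ratio. With `split = TRUE` (default) each
#' chain is split in half first (split-R-hat).
#'
#' @param x A `cr_fit` or a list of draw matrices (chains x draws x
#'   coefficients as a list of matrices).
#' @param split Split each chain in half before computing the statistic.
#' @return Named vector of R-hat values, one per coefficient.
#' @export
gelman_rubin <- function(x, split = TRUE) {
  chains <- if (inherits(x, "cr_fit")) x$draws else x
  if (!is.list(chains) || length(chains) < 2)
    stop("at least 2 chains are required to compute the Gelman-Rubin statistic")
  if (nrow(chains[[1]]) < 10)
    stop("at least 10 retained draws per chain are required")
  if (split) {
    chains <- unlist(lapply(chains, function(m) {
      n <- nrow(m)
      h <- floor(n / 2)
      list(m[seq_len(h), , drop = FALSE],
           m[(n - h + 1):n, , drop = FALSE])
    }), recursive = FALSE)
  }
  n <- nrow(chains[[1]])
  means <- sapply(chains, colMeans)                     # K x m
  vars <- sapply(chains, function(m) apply(m, 2, var))  # K x m
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, var)
  vhat <- (n - 1) / n * W + B_over_n
  rhat <- sqrt(vhat / W)
  names(rhat) <- colnames(chains[[1]])
  rhat
}

#' Write posterior draws and run metadata to disk
#'
#' One CSV per chain (one row per retained draw, columns
#' `<predictor>.<covariate>`) plus a JSON sidecar with the protocol, seeds,
#' acceptance rates, R-hat values and model configuration.
#'
#' @param fit A `cr_fit`.
#' @param dir Output directory.
#' @return Invisibly the directory.
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in seq_along(fit$draws))
    write.csv(as.data.frame(fit$draws[[ch]]),
              file.path(dir, sprintf("draws_chain%d.csv", ch)),
              row.names = FALSE)
  cfg <- fit$config
  meta <- list(protocol = fit$protocol,
               acceptance = as.data.frame(fit$acceptance),
               rhat = if (length(fit$draws) >= 2) as.list(gelman_rubin(fit)),
               config = list(n_lists = cfg$n_lists, first_year = cfg$first_year,
                             last_year = cfg$last_year,
                             prior_variance = cfg$prior_variance,
                             age_center = cfg$age_center,
                             age_scale = cfg$age_scale,
                             reference_group = cfg$reference_group),
               n_coefficients = length(fit$coef_names))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param dir Directory holding `draws_chain*.csv` and `metadata.json`.
#' @return A `cr_fit` (draws, metadata and rebuilt configuration).
#' @export
read_draws <- function(dir) {
  files <- sort(list.files(dir, pattern = "^draws_chain[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no draws_chain*.csv files in ", dir)
  draws <- lapply(files, function(f) as.matrix(read.csv(f, check.names = FALSE)))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config)
  out <- list(draws = draws, coef_names = colnames(draws[[1]]),
              L = cfg$n_lists, p = length(cfg$covariates), config = cfg,
              protocol = meta$protocol,
              acceptance = as.matrix(meta$acceptance))
  class(out) <- "cr_fit"
  out
}
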