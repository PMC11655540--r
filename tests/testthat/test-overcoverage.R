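toy_tables <- function() {
  cfg <- model_config(n_lists = 2, first_year = 2012, last_year = 2016)
  individuals <- data.frame(
    id = 1:5, sex = c("female", "male", "female", "male", "female"),
    birth_year = 1980, country_group = c("MENA", "MENA", "Eastern Europe",
                                         "Eastern Europe", "Western Europe"),
    registration_year = c(2012, 2012, 2013, 2013, 2014))
  observations <- data.frame(id = c(1, 2, 3), year = c(2015, 2014, 2015),
                             list_id = 1, value = 1)
  events <- data.frame(id = c(2, 4, 4), year = c(2015, 2014, 2016),
                       event = c("death", "deregister", "reregister"))
  cohort(individuals, observations, events, config = cfg)
}

test_that("the registered set applies the death/emigration removal rule", {
  ch <- toy_tables()
  # 2015: id 2 died in 2015 (removed), id 4 de-registered 2014 without
  # return by 2015 (removed), ids 1, 3, 5 remain
  expect_identical(sort(registered_set(ch, 2015)), c(1L, 3L, 5L))
  # 2016: id 4 re-registered in 2016 and is registered again
  expect_identical(sort(registered_set(ch, 2016)), c(1L, 3L, 4L, 5L))
  # before arrival individuals are absent from the set
  expect_identical(sort(registered_set(ch, 2012)), c(1L, 2L))
  # subgroup filters intersect
  expect_identical(registered_set(ch, 2015, sex = "female"), c(1L, 3L, 5L))
  expect_identical(registered_set(ch, 2015, country_group = "MENA"), 1L)
  expect_error(registered_set(ch, 2011), "2012")
})

test_that("the point estimate is one minus the mean presence probability", {
  # OC for presence probabilities (1, 1, 0.5, 0.25) over four registered
  # individuals is 1 - 2.75/4
  expect_equal(1 - mean(c(1, 1, 0.5, 0.25)), 0.3125)
  ch <- tiny_cohort(n = 100, seed = 17)
  fit <- mcmc_sample(ch, n_iter = 400, burnin = 150, thin = 5, n_chains = 2,
                     seed = 3)
  pp <- presence_posterior(fit, ch)
  oc <- oc_estimate(ch, fit)
  for (k in seq_len(nrow(oc))) {
    ids <- registered_set(ch, oc$year[k])
    z <- pp$zhat[pp$year == oc$year[k] & pp$id %in% ids]
    expect_identical(length(z), as.integer(oc$n_registered[k]))
    expect_equal(oc$estimate[k], 1 - mean(z), tolerance = 1e-8)
    expect_lte(oc$lower[k], oc$estimate[k] + 1e-12)
    expect_gte(oc$upper[k], oc$estimate[k] - 1e-12)
  }
})

test_that("register-trace over-coverage is the deterministic unseen fraction", {
  ch <- toy_tables()
  rt <- register_trace_oc(ch)
  # 2015: registered {1, 3, 5}, seen {1, 3} -> 1/3 unseen
  expect_equal(rt$estimate[rt$year == 2015], 1 / 3, tolerance = 1e-12)
  # 2014: registered {1, 2, 3, 5}, seen {2} -> 3/4 unseen
  expect_equal(rt$estimate[rt$year == 2014], 0.75, tolerance = 1e-12)
  expect_false(any(c("lower", "upper") %in% names(rt)))
})

test_that("model-based OC never exceeds register-trace OC", {
  ch <- tiny_cohort(n = 150, seed = 23)
  fit <- mcmc_sample(ch, n_iter = 400, burnin = 150, thin = 5, n_chains = 2,
                     seed = 6)
  tab <- oc_table(ch, fit, by = "sex")
  w <- reshape(tab[, c("year", "subgroup", "method", "estimate")],
               idvar = c("year", "subgroup"), timevar = "method",
               direction = "wide")
  ok <- !is.na(w$estimate.model)
  expect_true(all(w$estimate.model[ok] <= w$estimate.register_trace[ok] + 1e-9))
})

test_that("degenerate certain detection drives both estimators together", {
  cfg <- model_config(n_lists = 2, first_year = 2013, last_year = 2016)
  cf <- const_coefs(0.92, 0.75, 0.25, 0.5, c(1, 1))  # theta = 1
  ch <- simulate_cohort(simulation_spec(120, cfg, coefficients = cf), seed = 2)
  fit <- mcmc_sample(ch, n_iter = 300, burnin = 100, thin = 5, n_chains = 2,
                     seed = 2)
  tab <- oc_table(ch, fit)
  m <- tab[tab$method == "model", ]
  r <- tab[tab$method == "register_trace", ]
  # everyone present is seen: the register trace is exact and the smoothed
  # presence probabilities of unseen (truly absent) years are pushed to zero
  expect_equal(m$estimate, r$estimate, tolerance = 0.02)
})

test_that("OC estimates are invariant to individual ordering", {
  ch <- tiny_cohort(n = 80, seed = 29)
  perm <- sample(nrow(ch$individuals))
  ch2 <- ch
  ch2$individuals <- ch$individuals[perm, ]
  fit <- mcmc_sample(ch, n_iter = 300, burnin = 100, thin = 5, n_chains = 2,
                     seed = 11)
  oc1 <- oc_estimate(ch, fit)
  oc2 <- oc_estimate(ch2, fit)
  expect_equal(oc1, oc2, tolerance = 1e-10)
})

test_that("gap rows count consecutive unseen years and next-year detection", {
  cfg <- model_config(n_lists = 1, first_year = 2012, last_year = 2016)
  individuals <- data.frame(id = 1, sex = "male", birth_year = 1985,
                            country_group = "Rest of World",
                            registration_year = 2012)
  observations <- data.frame(id = 1, year = c(2012, 2015), list_id = 1,
                             value = 1)
  events <- data.frame(id = integer(), year = integer(), event = character())
  ch <- cohort(individuals, observations, events, config = cfg)
  fit <- mcmc_sample(ch, n_iter = 200, burnin = 100, thin = 2, n_chains = 2,
                     seed = 1)
  pp <- presence_posterior(fit, ch)
  gs <- gap_summary(pp, ch, detail = TRUE)
  # unseen 2013 (gap 1), 2014 (gap 2, seen next), 2016 (gap 1, last year)
  expect_identical(gs$year, c(2013L, 2014L, 2016L))
  expect_identical(gs$gap, c(1, 2, 1))
  expect_identical(gs$seen_next, c(FALSE, TRUE, NA))
  expect_identical(gs$tsm, c(1, 2, 4))
  # detected years never appear
  expect_false(2015 %in% gs$year)
  agg <- gap_summary(pp, ch)
  expect_true(all(c("gap", "tsm", "seen_next", "n", "mean") %in% names(agg)))
  expect_identical(sum(agg$n), nrow(gs))
})

test_that("gap-cell smoothed means match the enumeration oracle on a toy cohort", {
  cfg <- model_config(n_lists = 2, first_year = 2012, last_year = 2016)
  pr <- list(phi = 0.95, psi = 0.8, eta = 0.25, lambda = 0.4, theta = 0.55)
  cf <- const_coefs(pr$phi, pr$psi, pr$eta, pr$lambda, rep(pr$theta, 2))
  ch <- simulate_cohort(simulation_spec(250, cfg, coefficients = cf), seed = 41)
  # a single-draw "posterior" fixed at the truth isolates the smoothing step
  truth_draw <- matrix(crcover:::coef_vector(cf), nrow = 1)
  fit <- list(draws = list(truth_draw, truth_draw), config = cfg,
              coef_names = crcover:::coef_names(2, cfg), L = 2L, p = 10L)
  class(fit) <- "cr_fit"
  pp <- presence_posterior(fit, ch)
  gs <- gap_summary(pp, ch, detail = TRUE)
  # oracle: recompute each row's conditional by path enumeration
  pk <- crcover:::pack_cohort(ch, cfg)
  for (k in sample(nrow(gs), min(25, nrow(gs)))) {
    rows <- which(pk$id == gs$id[k])
    Y <- length(rows)
    probs <- list(phi = rep(pr$phi, Y), psi = rep(pr$psi, Y),
                  eta = rep(pr$eta, Y), lambda = rep(pr$lambda, Y),
                  theta = matrix(pr$theta, Y, 2))
    g <- enumerate_state_posterior(
      probs, list(o = pk$O[rows, , drop = FALSE], e = pk$e[rows],
                  d = pk$d[rows]), pk$mask[rows])
    yi <- match(gs$year[k], pk$year[rows])
    expect_equal(gs$zhat[k], unname(g[yi, "present"]), tolerance = 1e-9)
  }
})
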