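test_that("single-year records reduce to the detection product", {
  # registration year only: presence is forced, likelihood is the product of
  # per-list Bernoulli terms
  probs <- list(phi = 0.9, psi = 0.8, eta = 0.2, lambda = 0.5,
                theta = matrix(c(0.7, 0.4), 1))
  obs <- list(o = matrix(c(1, 1), 1), e = 0, d = 0)
  expect_equal(forward_loglik(probs, obs, "present"), log(0.28),
               tolerance = 1e-12)
  expect_equal(enumerate_loglik(probs, obs, "present"), log(0.28),
               tolerance = 1e-12)
})

test_that("impossible observations give -Inf likelihood", {
  probs <- list(phi = c(0.9, 0.9), psi = c(0.8, 0.8), eta = c(0.2, 0.2),
                lambda = c(0.5, 0.5),
                theta = matrix(0, 2, 2))  # theta = 0: detection impossible
  obs <- list(o = matrix(c(0, 1, 0, 0), 2), e = c(0, 0), d = c(0, 0))
  mask <- c("present", "present")
  expect_identical(forward_loglik(probs, obs, mask), -Inf)
})

test_that("forward recursion equals path enumeration on random records", {
  set.seed(2024)
  n_checked <- 0L
  for (rep in 1:250) {
    Y <- sample(2:9, 1)
    L <- sample(1:3, 1)
    rec <- simulate_record(Y, L)
    a <- forward_loglik(rec$probs, rec$obs, rec$mask)
    b <- enumerate_loglik(rec$probs, rec$obs, rec$mask)
    expect_equal(a, b, tolerance = 1e-10)
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 250L)
})

test_that("record-level likelihood agrees with the record-level oracle", {
  ch <- tiny_cohort(n = 60, seed = 14)
  cf <- default_coefficients(ch$config)
  ll <- cohort_loglik(ch, cf)
  for (id in c(1, 7, 23, 44)) {
    a <- individual_loglik(ch, cf, id)
    b <- brute_force_loglik(ch, cf, id)
    expect_equal(a, b, tolerance = 1e-10)
    expect_equal(unname(ll$by_individual[as.character(id)]), a,
                 tolerance = 1e-12)
  }
  expect_equal(ll$total, sum(ll$by_individual), tolerance = 1e-8)
})

test_that("enumeration refuses records with too many free years", {
  probs <- rand_probs(15, 1)
  obs <- list(o = matrix(0L, 15, 1), e = integer(15), d = integer(15))
  expect_error(enumerate_loglik(probs, obs, c("present", rep("free", 14))),
               "12 free years")
})

test_that("log-prior is the independent normal density", {
  cf <- const_coefs(0.5, 0.5, 0.5, 0.5, c(0.5, 0.5))  # all coefficients zero
  K <- 6 * 10
  expect_equal(log_prior(cf, delta = 2), K * (-0.5 * log(4 * pi)),
               tolerance = 1e-12)
  cf1 <- coefficient_set(1, 0, 0, 0, matrix(0, 1, 1))  # single nonzero coef
  expect_equal(log_prior(cf1, delta = 1),
               5 * (-0.5 * log(2 * pi)) - 0.5, tolerance = 1e-12)
  expect_error(log_prior(cf, delta = 0), "positive")
  # a larger prior variance penalizes large coefficients less
  big <- coefficient_set(rep(3, 2), rep(3, 2), rep(3, 2), rep(3, 2),
                         matrix(3, 1, 2))
  expect_gt(log_prior(big, delta = 8), log_prior(big, delta = 2))
})

test_that("smoothing matches enumeration-oracle conditionals", {
  set.seed(99)
  for (rep in 1:60) {
    Y <- sample(2:7, 1)
    L <- sample(1:3, 1)
    rec <- simulate_record(Y, L)
    g <- forward_backward(rec$probs, rec$obs, rec$mask)
    h <- enumerate_state_posterior(rec$probs, rec$obs, rec$mask)
    expect_equal(g, h, tolerance = 1e-10)
    expect_equal(unname(rowSums(g)), rep(1, Y), tolerance = 1e-10)
    # masked years are exact
    expect_true(all(g[rec$mask == "present", "present"] == 1))
    expect_true(all(g[rec$mask == "absent", "present"] == 0))
    expect_true(all(g[rec$mask == "dead", "present"] == 0))
  }
})

test_that("presence probability decays with the length of an unseen gap", {
  # homogeneous record: detected at registration, then unseen to the end
  smoothed_last <- function(gap) {
    Y <- 1 + gap
    probs <- list(phi = rep(0.97, Y), psi = rep(0.8, Y), eta = rep(0.2, Y),
                  lambda = rep(0.3, Y),
                  theta = matrix(0.6, Y, 2))
    o <- matrix(0L, Y, 2); o[1, ] <- 1L
    obs <- list(o = o, e = integer(Y), d = integer(Y))
    mask <- c("present", rep("free", gap))
    g <- forward_backward(probs, obs, mask)
    h <- enumerate_state_posterior(probs, obs, mask)
    expect_equal(g, h, tolerance = 1e-10)
    g[Y, "present"]
  }
  p <- vapply(1:4, smoothed_last, numeric(1))
  expect_true(all(diff(p) < 0))        # monotone decay in gap length
  expect_lt(p[4], 0.25 * p[1])         # 3-4 unseen years: far below a 1-year gap
})

test_that("gelman_rubin follows the between/within variance formula", {
  set.seed(5)
  n <- 400
  m <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  # identical chains, classic (non-split) statistic: B = 0, so
  # R-hat = sqrt((n-1)/n)
  r <- gelman_rubin(list(m, m), split = FALSE)
  expect_equal(unname(r), rep(sqrt((n - 1) / n), 2), tolerance = 1e-9)
  # chains from the same distribution: split R-hat near 1
  r2 <- gelman_rubin(list(matrix(rnorm(2 * n), ncol = 2),
                          matrix(rnorm(2 * n), ncol = 2)))
  expect_lt(max(abs(r2 - 1)), 0.05)
  # disjoint chains: far above 1.1
  r3 <- gelman_rubin(list(matrix(rnorm(n, 0, 0.1), ncol = 1),
                          matrix(rnorm(n, 10, 0.1), ncol = 1)))
  expect_gt(r3, 10)
  expect_error(gelman_rubin(list(m)), "2 chains")
})

test_that("the sampler is reproducible and reports its protocol", {
  ch <- tiny_cohort(n = 80, seed = 31)
  f1 <- mcmc_sample(ch, n_iter = 300, burnin = 100, thin = 2, n_chains = 2,
                    seed = 4)
  f2 <- mcmc_sample(ch, n_iter = 300, burnin = 100, thin = 2, n_chains = 2,
                    seed = 4)
  expect_identical(f1$draws, f2$draws)
  expect_identical(nrow(f1$draws[[1]]), 100L)
  expect_identical(ncol(f1$draws[[1]]), 7L * 10L)
  f3 <- mcmc_sample(ch, n_iter = 300, burnin = 100, thin = 2, n_chains = 2,
                    seed = 5)
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("draws round-trip through the CSV + metadata sidecar", {
  ch <- tiny_cohort(n = 50, seed = 8)
  fit <- mcmc_sample(ch, n_iter = 200, burnin = 100, thin = 5, n_chains = 2,
                     seed = 2)
  dir <- withr::local_tempdir()
  write_draws(fit, dir)
  expect_true(file.exists(file.path(dir, "draws_chain1.csv")))
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- read_draws(dir)
  expect_equal(back$draws[[1]], fit$draws[[1]], tolerance = 1e-12)
  expect_identical(back$coef_names, fit$coef_names)
  expect_identical(back$config$n_lists, ch$config$n_lists)
})

test_that("known-state masks encode registration, detections and events", {
  cfg <- model_config(n_lists = 2, first_year = 2010, last_year = 2016)
  individuals <- data.frame(
    id = 1:3, sex = "female", birth_year = 1985, country_group = "MENA",
    registration_year = c(2010, 2011, 2012))
  observations <- data.frame(id = c(1, 1, 2), year = c(2012, 2015, 2013),
                             list_id = 1, value = 1)
  events <- data.frame(id = c(2, 2, 3), year = c(2014, 2016, 2014),
                       event = c("deregister", "reregister", "death"))
  ch <- cohort(individuals, observations, events, config = cfg)
  m <- known_state_mask(ch)
  get <- function(id, year) m$known[m$id == id & m$year == year]
  expect_identical(get(1, 2010), "present")   # registration
  expect_identical(get(1, 2012), "present")   # detection
  expect_identical(get(1, 2013), "free")
  expect_identical(get(2, 2013), "present")   # year before de-registration
  expect_identical(get(2, 2014), "absent")
  expect_identical(get(2, 2015), "absent")
  expect_identical(get(2, 2016), "present")   # re-registration
  expect_identical(get(3, 2013), "present")   # year before recorded death
  expect_identical(get(3, 2014), "dead")
  expect_identical(get(3, 2016), "dead")
})

test_that("data inconsistent with the mask fails fast with the offender", {
  cfg <- model_config(n_lists = 1, first_year = 2012, last_year = 2015)
  individuals <- data.frame(id = 1:2, sex = "male", birth_year = 1980,
                            country_group = "Eastern Europe",
                            registration_year = 2012)
  # a detection inside the de-registered (forced absent) span
  observations <- data.frame(id = 1, year = 2014, list_id = 1, value = 1)
  events <- data.frame(id = 1, year = c(2013, 2015),
                       event = c("deregister", "reregister"))
  ch <- cohort(individuals, observations, events, config = cfg)
  cf <- default_coefficients(cfg)
  expect_warning(ll <- individual_loglik(ch, cf, 1), "inconsistent.*1")
  expect_identical(ll, -Inf)
  expect_error(suppressWarnings(
    mcmc_sample(ch, n_iter = 100, burnin = 50, thin = 1)), "inconsistent")
})
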