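#' Specification of a synthetic register cohort
#'
#' Describes the generative conditions for a simulated cohort: cohort size,
#' the arrival-year distribution over all years but the last (so every
#' individual is observed for at least one year after arrival), the marginal
#' covariate distributions, and the true coefficient set.
#'
#' Defaults emulate the structure of a migrant register cohort: arrivals
#' uniform over the arrival years, 48% women, age at arrival
#' `18 + Gamma(shape 2.2, scale 6)` years (capped at `age_max`), and
#' country-group proportions dominated by Eastern Europe and MENA.
#'
#' @param n_individuals Cohort size.
#' @param config A [model_config()].
#' @param coefficients True [coefficient_set()]; defaults to
#'   [default_coefficients()].
#' @param arrival_probs Probability vector over arrival years
#'   `first_year..(last_year - 1)`; default uniform.
#' @param sex_prop Proportion of women.
#' @param country_probs Named probability vector over [country_groups()].
#' @param age_shape,age_scale_yrs,age_min,age_max Age-at-arrival Gamma
#'   parameters and bounds.
#' @return An object of class `cr_simspec`.
#' @export
simulation_spec <- function(n_individuals, config,
                            coefficients = default_coefficients(config),
                            arrival_probs = NULL, sex_prop = 0.48,
                            country_probs = NULL, age_shape = 2.2,
                            age_scale_yrs = 6, age_min = 18, age_max = 85) {
  stopifnot(n_individuals >= 1, config$last_year > config$first_year)
  arrival_years <- config$first_year:(config$last_year - 1)
  if (is.null(arrival_probs))
    arrival_probs <- rep(1 / length(arrival_years), length(arrival_years))
  if (length(arrival_probs) != length(arrival_years))
    stop("`arrival_probs` must have one entry per arrival year ",
         min(arrival_years), "..", max(arrival_years))
  if (is.null(country_probs))
    country_probs <- c("Denmark/Norway" = 0.08, "Iceland/Finland" = 0.07,
                       "Eastern Europe" = 0.25, "Western Europe" = 0.12,
                       "MENA" = 0.25, "USA/Canada/Oceania" = 0.08,
                       "Rest of World" = 0.15)
  if (!setequal(names(country_probs), country_groups()))
    stop("`country_probs` must be named by country_groups()")
  country_probs <- country_probs[country_groups()]
  for (nm in c("arrival_probs", "country_probs")) {
    v <- get(nm)
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9)
      stop(sprintf("`%s` must be a probability vector summing to 1 (got %.12f)",
                   nm, sum(v)))
  }
  stopifnot(sex_prop >= 0, sex_prop <= 1)
  out <- list(n_individuals = as.integer(n_individuals), config = config,
              coefficients = coefficients, arrival_years = arrival_years,
              arrival_probs = arrival_probs, sex_prop = sex_prop,
              country_probs = country_probs, age_shape = age_shape,
              age_scale_yrs = age_scale_yrs, age_min = age_min,
              age_max = age_max)
  class(out) <- "cr_simspec"
  out
}

#' Simulate a register cohort from the generative model
#'
#' Forward-simulates every individual from the exact model: presence forced
#' in the registration year, then yearly survival / movement transitions,
#' de-registration notifications on departures (probability `lambda`),
#' re-registration recorded with certainty upon return after a
#' de-registration, recorded deaths when the individual was present the year
#' before, and per-list detections while present. Returns the three observed
#' tables plus the ground-truth latent trajectory of every individual.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed; the cohort is a deterministic function of
#'   `(spec, seed)`.
#' @return An object of class `cr_cohort`: list with data frames
#'   `individuals`, `observations` (positive indicators only), `events`,
#'   `truth` (id, year, state) and the `config`.
#' @export
simulate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cr_simspec"))
  set.seed(seed)
  cfg <- spec$config
  n <- spec$n_individuals
  cf <- spec$coefficients
  if (cf$L != cfg$n_lists)
    stop("coefficient set has ", cf$L, " lists but config expects ", cfg$n_lists)

  r <- sample(spec$arrival_years, n, replace = TRUE, prob = spec$arrival_probs)
  sex <- ifelse(runif(n) < spec$sex_prop, "female", "male")
  cg <- sample(names(spec$country_probs), n, replace = TRUE,
               prob = spec$country_probs)
  age_arr <- pmin(spec$age_max,
                  spec$age_min + floor(rgamma(n, shape = spec$age_shape,
                                              scale = spec$age_scale_yrs)))
  individuals <- data.frame(id = seq_len(n), sex = sex, birth_year = r - age_arr,
                            country_group = cg, registration_year = r,
                            stringsAsFactors = FALSE)

  # state codes: 0 not yet arrived, 1 present, 2 absent, 3 dead
  state <- integer(n)
  dereg_open <- logical(n)
  obs_acc <- list(); ev_acc <- list(); truth_acc <- list()

  for (y in cfg$first_year:cfg$last_year) {
    state[r == y] <- 1L
    movers <- which(state %in% c(1L, 2L) & r < y)
    if (length(movers)) {
      X <- panel_design(individuals, movers, y, cfg)
      phi <- plogis(drop(X %*% cf$phi))
      alive <- runif(length(movers)) < phi
      died <- movers[!alive]
      if (length(died)) {
        recorded <- state[died] == 1L
        state[died] <- 3L
        if (any(recorded))
          ev_acc[[length(ev_acc) + 1L]] <-
            data.frame(id = died[recorded], year = y, event = "death",
                       stringsAsFactors = FALSE)
      }
      keep <- which(alive)
      if (length(keep)) {
        ids <- movers[keep]
        fromP <- state[ids] == 1L
        pmove <- ifelse(fromP, plogis(drop(X[keep, , drop = FALSE] %*% cf$psi)),
                        plogis(drop(X[keep, , drop = FALSE] %*% cf$eta)))
        u <- runif(length(ids))
        # staying from presence, or returning from absence
        leave <- fromP & u >= pmove
        ret <- !fromP & u < pmove
        if (any(leave)) {
          lv <- ids[leave]
          state[lv] <- 2L
          lam <- plogis(drop(X[keep, , drop = FALSE][leave, , drop = FALSE] %*% cf$lambda))
          notify <- runif(length(lv)) < lam
          if (any(notify)) {
            ev_acc[[length(ev_acc) + 1L]] <-
              data.frame(id = lv[notify], year = y, event = "deregister",
                         stringsAsFactors = FALSE)
            dereg_open[lv[notify]] <- TRUE
          }
        }
        if (any(ret)) {
          rt <- ids[ret]
          state[rt] <- 1L
          back <- rt[dereg_open[rt]]
          if (length(back)) {
            ev_acc[[length(ev_acc) + 1L]] <-
              data.frame(id = back, year = y, event = "reregister",
                         stringsAsFactors = FALSE)
            dereg_open[back] <- FALSE
          }
        }
      }
    }
    pres <- which(state == 1L & r <= y)
    if (length(pres)) {
      Xp <- panel_design(individuals, pres, y, cfg)
      for (l in seq_len(cfg$n_lists)) {
        theta <- plogis(drop(Xp %*% cf$o[l, ]))
        hit <- pres[runif(length(pres)) < theta]
        if (length(hit))
          obs_acc[[length(obs_acc) + 1L]] <-
            data.frame(id = hit, year = y, list_id = l, value = 1L)
      }
    }
    arrived <- which(r <= y)
    truth_acc[[length(truth_acc) + 1L]] <-
      data.frame(id = arrived, year = y,
                 state = latent_states()[state[arrived]],
                 stringsAsFactors = FALSE)
  }

  bindrows <- function(acc, proto) {
    if (length(acc)) do.call(rbind, acc) else proto
  }
  observations <- bindrows(obs_acc, data.frame(id = integer(), year = integer(),
                                               list_id = integer(), value = integer()))
  events <- bindrows(ev_acc, data.frame(id = integer(), year = integer(),
                                        event = character(), stringsAsFactors = FALSE))
  truth <- do.call(rbind, truth_acc)
  cohort(individuals = individuals,
         observations = canonical_order(observations, c("id", "year", "list_id")),
         events = canonical_order(events, c("id", "year")),
         truth = canonical_order(truth, c("id", "year")),
         config = cfg)
}

canonical_order <- function(df, keys) {
  if (!nrow(df)) return(df)
  df <- df[do.call(order, df[keys]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Ground-truth over-coverage of a simulated cohort
#'
#' The fraction of individuals administratively registered in `year` --
#' arrived, no recorded death, no unresolved de-registration -- whose true
#' latent state is not "present". This is the quantity the model-based
#' estimator targets.
#'
#' @param cohort A simulated `cr_cohort` (must carry the `truth` table).
#' @param year Year within the observation window.
#' @return Proportion in `[0, 1]`, or `NA` if nobody is registered.
#' @export
true_overcoverage <- function(cohort, year) {
  cfg <- cohort$config
  if (year < cfg$first_year || year > cfg$last_year)
    stop("`year` must lie in ", cfg$first_year, "..", cfg$last_year)
  if (is.null(cohort$truth))
    stop("cohort carries no ground-truth trajectories")
  ids <- registered_set(cohort, year)
  if (!length(ids)) return(NA_real_)
  tr <- cohort$truth
  st <- tr$state[tr$year == year][match(ids, tr$id[tr$year == year])]
  mean(st != "present")
}
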