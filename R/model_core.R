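#' Country-of-birth groups
#'
#' The seven country-of-birth groups used throughout the model. Exactly one
#' group is active per individual; the reference group (by default
#' `"Western Europe"`) is encoded as all-zero indicators in the design matrix.
#'
#' @return Character vector of the seven group labels.
#' @export
country_groups <- function() {
  c("Denmark/Norway", "Iceland/Finland", "Eastern Europe", "Western Europe",
    "MENA", "USA/Canada/Oceania", "Rest of World")
}

#' Latent state labels
#'
#' The yearly latent state of an individual: present in the country, absent
#' (alive but abroad), or dead. Dead is absorbing.
#'
#' @return Character vector `c("present", "absent", "dead")`.
#' @export
latent_states <- function() c("present", "absent", "dead")

cg_slug <- function(x) {
  gsub("_+", "_", gsub("[^a-z0-9]", "_", tolower(x)))
}

#' Model configuration
#'
#' Bundles the structural constants of the model: the number of detection
#' lists, the inclusive calendar-year observation window, the prior variance
#' of the regression coefficients, and the covariate encoding options.
#'
#' Age enters the linear predictors as `(age - age_center) / age_scale` so
#' that coefficients of order one correspond to realistic effects; time since
#' first migration enters in raw years.
#'
#' @param n_lists Number of detection lists `L` (socioeconomic registers),
#'   a positive integer.
#' @param first_year,last_year Inclusive calendar-year range of observation.
#' @param prior_variance Variance `delta` of the independent mean-zero normal
#'   prior on every regression coefficient. Default 2.
#' @param age_center,age_scale Centering/scaling constants for the age
#'   covariate (defaults 40 and 10 years).
#' @param reference_group Country group encoded as the reference level.
#' @return An object of class `cr_config`.
#' @export
model_config <- function(n_lists, first_year, last_year, prior_variance = 2,
                         age_center = 40, age_scale = 10,
                         reference_group = "Western Europe") {
  stopifnot(length(n_lists) == 1, n_lists >= 1,
            length(first_year) == 1, length(last_year) == 1,
            last_year >= first_year)
  if (!is.numeric(prior_variance) || prior_variance <= 0)
    stop("`prior_variance` must be a positive number")
  if (!reference_group %in% country_groups())
    stop("`reference_group` must be one of country_groups()")
  nonref <- setdiff(country_groups(), reference_group)
  cfg <- list(
    n_lists = as.integer(n_lists),
    first_year = as.integer(first_year),
    last_year = as.integer(last_year),
    years = seq.int(first_year, last_year),
    prior_variance = prior_variance,
    age_center = age_center,
    age_scale = age_scale,
    reference_group = reference_group,
    nonref_groups = nonref,
    covariates = c("intercept", "sex_female", "age_std",
                   paste0("cg_", cg_slug(nonref)), "tsm")
  )
  class(cfg) <- "cr_config"
  cfg
}

#' @export
print.cr_config <- function(x, ...) {
  cat("Register capture-recapture model configuration\n")
  cat("  lists:", x$n_lists, " years:", x$first_year, "-", x$last_year,
      " prior variance:", x$prior_variance, "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Build a single covariate vector
#'
#' Encodes one individual-year as the covariate vector entering every linear
#' predictor: intercept 1, female indicator, standardized age, six
#' reference-coded country-group indicators, and time since first migration
#' in years.
#'
#' @param sex `"female"` or `"male"`.
#' @param age Age in years at the year considered.
#' @param country_group One of [country_groups()].
#' @param tsm Time since first migration in years (non-negative).
#' @param config A [model_config()].
#' @return Named numeric vector of length `length(config$covariates)`.
#' @export
covariate_vector <- function(sex, age, country_group, tsm, config) {
  stopifnot(sex %in% c("female", "male"), country_group %in% country_groups(),
            tsm >= 0)
  cg <- as.numeric(config$nonref_groups == country_group)
  x <- c(1, as.numeric(sex == "female"),
         (age - config$age_center) / config$age_scale, cg, tsm)
  names(x) <- config$covariates
  x
}

# Design rows for (id, year) pairs; individuals is the cohort table.
panel_design <- function(individuals, id, year, config) {
  m <- match(id, individuals$id)
  if (anyNA(m)) stop("unknown individual id(s): ",
                     paste(unique(id[is.na(m)]), collapse = ", "))
  age <- year - individuals$birth_year[m]
  tsm <- year - individuals$registration_year[m]
  cg <- outer(individuals$country_group[m], config$nonref_groups, "==")
  X <- cbind(1, as.numeric(individuals$sex[m] == "female"),
             (age - config$age_center) / config$age_scale,
             cg + 0, tsm)
  colnames(X) <- config$covariates
  X
}

#' Regression coefficient set
#'
#' Collects the coefficient vectors of all linear predictors: survival
#' (`phi`), staying conditional on presence (`psi`), returning conditional
#' on absence (`eta`), de-registering upon departure (`lambda`), and one
#' detection vector per list (`theta`). All vectors must share one dimension.
#'
#' @param beta_phi,beta_psi,beta_eta,beta_lambda Numeric coefficient vectors.
#' @param beta_o Detection coefficients: an `L x p` matrix (one row per list)
#'   or a list of `L` numeric vectors.
#' @return An object of class `cr_coefs`.
#' @export
coefficient_set <- function(beta_phi, beta_psi, beta_eta, beta_lambda, beta_o) {
  if (is.list(beta_o)) beta_o <- do.call(rbind, beta_o)
  beta_o <- as.matrix(beta_o)
  p <- length(beta_phi)
  lens <- c(length(beta_psi), length(beta_eta), length(beta_lambda), ncol(beta_o))
  if (any(lens != p))
    stop(sprintf("all coefficient vectors must share one dimension; got %s",
                 paste(c(p, lens), collapse = ", ")))
  out <- list(phi = as.numeric(beta_phi), psi = as.numeric(beta_psi),
              eta = as.numeric(beta_eta), lambda = as.numeric(beta_lambda),
              o = beta_o, L = nrow(beta_o), p = p)
  class(out) <- "cr_coefs"
  out
}

# Stack as the (L+4) x p matrix consumed by the C++ kernels
# (rows theta_1..theta_L, phi, psi, eta, lambda).
coef_matrix <- function(params) {
  unname(rbind(params$o, params$phi, params$psi, params$eta, params$lambda))
}

predictor_labels <- function(L) c(paste0("theta", seq_len(L)),
                                  "phi", "psi", "eta", "lambda")

# Column names "<predictor>.<covariate>" for a flattened coefficient vector.
coef_names <- function(L, config) {
  as.vector(t(outer(predictor_labels(L), config$covariates, paste, sep = ".")))
}

# Flatten (block-major) / rebuild a coefficient set.
coef_vector <- function(params) as.vector(t(coef_matrix(params)))

coefficients_from_vector <- function(v, L, p) {
  m <- matrix(v, nrow = L + 4, ncol = p, byrow = TRUE)
  coefficient_set(beta_phi = m[L + 1, ], beta_psi = m[L + 2, ],
                  beta_eta = m[L + 3, ], beta_lambda = m[L + 4, ],
                  beta_o = m[seq_len(L), , drop = FALSE])
}

#' Logistic link
#'
#' Maps a linear predictor `x . beta` to a probability through the inverse
#' logit, numerically stable for very large magnitudes.
#'
#' @param x Covariate vector.
#' @param beta Coefficient vector of the same length.
#' @return Probability in `(0, 1)` (saturating to 0/1 at machine precision).
#' @examples
#' logistic_link(c(1, 0.5), c(0, 0))  # 0.5
#' @export
logistic_link <- function(x, beta) {
  if (length(x) != length(beta))
    stop(sprintf("length(x) = %d does not match length(beta) = %d",
                 length(x), length(beta)))
  plogis(sum(x * beta))
}

#' Yearly transition distribution of the latent state
#'
#' Distribution of the year-`y` state given the year-`y-1` state, factorized
#' as survival (probability `phi`) followed by movement: staying with
#' probability `psi` from presence, returning with probability `eta` from
#' absence. Dead is absorbing.
#'
#' @param state State at year `y - 1`, one of [latent_states()].
#' @param x Covariate vector for year `y`.
#' @param params A [coefficient_set()].
#' @return Named probability vector over `c("present", "absent", "dead")`,
#'   summing to one.
#' @export
transition_kernel <- function(state, x, params) {
  state <- match.arg(state, latent_states())
  if (state == "dead")
    return(c(present = 0, absent = 0, dead = 1))
  phi <- logistic_link(x, params$phi)
  if (state == "present") {
    psi <- logistic_link(x, params$psi)
    c(present = phi * psi, absent = phi * (1 - psi), dead = 1 - phi)
  } else {
    eta <- logistic_link(x, params$eta)
    c(present = phi * eta, absent = phi * (1 - eta), dead = 1 - phi)
  }
}

#' Probability of a year's observed record given the state pair
#'
#' Emission probability of one individual-year record -- the `L` list
#' indicators, the de-registration flag `e` and the recorded-death flag `d` --
#' conditional on the latent states at years `y - 1` and `y`. Present
#' individuals are detected independently per list with probabilities
#' `theta_l`; an individual leaving the country de-registers with probability
#' `lambda`; absent or dead individuals generate no list records. A death is
#' recorded if and only if the individual was present the year before.
#'
#' @param state_prev,state_now States at years `y - 1` and `y`.
#' @param x Covariate vector for year `y`.
#' @param params A [coefficient_set()].
#' @param obs List with components `o` (0/1 vector of length `L`), `e` (0/1)
#'   and `d` (0/1).
#' @return The probability of the record; 0 for impossible combinations.
#' @export
emission_prob <- function(state_prev, state_now, x, params, obs) {
  state_prev <- match.arg(state_prev, latent_states())
  state_now <- match.arg(state_now, latent_states())
  o <- obs$o
  e <- if (is.null(obs$e)) 0 else obs$e
  d <- if (is.null(obs$d)) 0 else obs$d
  stopifnot(length(o) == params$L, all(o %in% 0:1), e %in% 0:1, d %in% 0:1)
  anyobs <- sum(o) > 0
  if (state_now == "present") {
    if (e != 0 || d != 0) return(0)
    theta <- vapply(seq_len(params$L),
                    function(l) logistic_link(x, params$o[l, ]), numeric(1))
    return(prod(ifelse(o == 1, theta, 1 - theta)))
  }
  if (state_now == "absent") {
    if (anyobs || d != 0) return(0)
    if (state_prev == "present") {
      lam <- logistic_link(x, params$lambda)
      return(if (e == 1) lam else 1 - lam)
    }
    if (state_prev == "absent") return(if (e == 0) 1 else 0)
    return(0)  # dead -> absent impossible
  }
  # state_now == "dead"
  if (anyobs || e != 0) return(0)
  if (state_prev == "present") return(if (d == 1) 1 else 0)
  if (d != 0) return(0)  # deaths from absence are unrecorded
  1
}

#' Reference coefficient values for simulation studies
#'
#' A fixed, documented coefficient set used as the generative truth in the
#' package's parameter-recovery and over-coverage-recovery experiments. The
#' signs follow the qualitative patterns expected for register data: staying
#' and de-registering increase with time since first migration, women
#' de-register and return more than men, migrants from Eastern Europe and
#' MENA are more likely to stay and less likely to de-register, migrants from
#' the Nordic countries and USA/Canada/Oceania the reverse. Detection
#' intercepts span high- to low-detection lists; all values lie in
#' `[-1.5, 1.5]`.
#'
#' @param config A [model_config()].
#' @return A [coefficient_set()].
#' @export
default_coefficients <- function(config) {
  L <- config$n_lists
  p <- length(config$covariates)
  # covariate order: intercept, sex_female, age_std, cg x 6, tsm
  stopifnot(p == 10)
  th_int <- if (L == 1) 0.5 else seq(1.5, -1.5, length.out = L)
  o <- t(vapply(seq_len(L), function(l) {
    cg <- rep_len(c(0.25, -0.25), 6) * (-1)^l
    c(th_int[l], rep_len(c(-0.3, 0.2, -0.2, 0.3), L)[l],
      rep_len(c(-0.1, 0.05, 0.1, -0.05), L)[l], cg, 0.15)
  }, numeric(p)))
  coefficient_set(
    beta_phi    = c(3.0,  0.3, -0.8,  0.1, -0.1,  0.2,  0.15,  0.05,  0.1,  0.05),
    beta_psi    = c(1.5,  0.4,  0.0, -0.7, -0.5,  0.8,  0.9,  -0.6,   0.3,  0.10),
    beta_eta    = c(-1.0, 0.3, -0.1,  0.2, -0.6,  0.5,  0.4,   0.1,   0.2, -0.15),
    beta_lambda = c(0.0,  0.4,  0.1,  1.2,  0.8, -1.0, -1.2,   1.0,  -0.5,  0.12),
    beta_o = o
  )
}
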