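# Shared fixtures: random single-individual records on the probability scale,
# generated by forward simulation from the model itself so that record, events
# and known-state mask are always mutually consistent.

rand_probs <- function(Y, L, lo = 0.05, hi = 0.95) {
  list(phi = runif(Y, 0.7, 0.99), psi = runif(Y, lo, hi),
       eta = runif(Y, lo, hi), lambda = runif(Y, lo, hi),
       theta = matrix(runif(Y * L, lo, hi), Y, L))
}

# Simulate one individual's record (years 1..Y, year 1 = registration).
# Returns probs, obs = list(o, e, d) and the data-derived mask.
simulate_record <- function(Y, L, probs = rand_probs(Y, L)) {
  o <- matrix(0L, Y, L)
  e <- integer(Y); d <- integer(Y)
  state <- integer(Y)  # 1 present, 2 absent, 3 dead
  state[1] <- 1L
  dereg_open <- FALSE
  rereg_year <- integer(0)
  o[1, ] <- as.integer(runif(L) < probs$theta[1, ])
  if (Y > 1) for (y in 2:Y) {
    prev <- state[y - 1]
    if (prev == 3L) { state[y] <- 3L; next }
    if (runif(1) > probs$phi[y]) {
      state[y] <- 3L
      if (prev == 1L) d[y] <- 1L  # deaths recorded only from presence
      next
    }
    if (prev == 1L) {
      if (runif(1) < probs$psi[y]) state[y] <- 1L
      else {
        state[y] <- 2L
        if (runif(1) < probs$lambda[y]) { e[y] <- 1L; dereg_open <- TRUE }
      }
    } else {
      if (runif(1) < probs$eta[y]) {
        state[y] <- 1L
        if (dereg_open) { rereg_year <- c(rereg_year, y); dereg_open <- FALSE }
      } else state[y] <- 2L
    }
    if (state[y] == 1L) o[y, ] <- as.integer(runif(L) < probs$theta[y, ])
  }
  mask <- rep("free", Y)
  mask[1] <- "present"
  mask[rowSums(o) > 0] <- "present"
  for (y in which(e == 1L)) {
    nxt <- rereg_year[rereg_year > y]
    end <- if (length(nxt)) min(nxt) - 1L else Y
    mask[y:end] <- "absent"
    mask[y - 1L] <- "present"
  }
  for (y in rereg_year) mask[y] <- "present"
  if (any(d == 1L)) {
    yd <- which(d == 1L)[1]
    mask[yd:Y] <- "dead"
    mask[yd - 1L] <- "present"
  }
  list(probs = probs, obs = list(o = o, e = e, d = d), mask = mask,
       state = state)
}

# A small simulated cohort reused across tests.
tiny_cohort <- function(n = 120, seed = 11, L = 3, first = 2012, last = 2016) {
  cfg <- model_config(n_lists = L, first_year = first, last_year = last)
  simulate_cohort(simulation_spec(n, cfg), seed = seed)
}

# Coefficient set giving constant probabilities (covariates ignored).
const_coefs <- function(p_phi, p_psi, p_eta, p_lambda, p_theta, ncov = 10) {
  const <- function(p) c(qlogis(p), rep(0, ncov - 1))
  coefficient_set(beta_phi = const(p_phi), beta_psi = const(p_psi),
                  beta_eta = const(p_eta), beta_lambda = const(p_lambda),
                  beta_o = t(vapply(p_theta, const, numeric(ncov))))
}
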