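#' Individuals administratively registered in a year
#'
#' The denominator set `D_y`: individuals who registered in or before `year`
#' and are still administratively counted -- no recorded death up to and
#' including `year` and no unresolved de-registration (a de-registration in
#' or before `year` without a later re-registration in or before `year`).
#' Silent emigrants (absent without de-registering) remain in the set: they
#' are the over-coverage. Optional filters restrict to subgroups.
#'
#' @param data A `cr_cohort`.
#' @param year Calendar year within the observation window.
#' @param sex,country_group,arrival_year Optional subgroup filters (vectors
#'   of admissible values).
#' @return Vector of individual ids (possibly empty).
#' @export
registered_set <- function(data, year, sex = NULL, country_group = NULL,
                           arrival_year = NULL) {
  cfg <- data$config
  if (year < cfg$first_year || year > cfg$last_year)
    stop("`year` must lie in ", cfg$first_year, "..", cfg$last_year)
  ind <- data$individuals
  keep <- ind$registration_year <= year
  if (!is.null(sex)) keep <- keep & ind$sex %in% sex
  if (!is.null(country_group)) keep <- keep & ind$country_group %in% country_group
  if (!is.null(arrival_year)) keep <- keep & ind$registration_year %in% arrival_year
  ids <- ind$id[keep]
  ev <- data$events[data$events$year <= year, , drop = FALSE]
  if (nrow(ev)) {
    dead <- unique(ev$id[ev$event == "death"])
    mig <- ev[ev$event != "death", , drop = FALSE]
    if (nrow(mig)) {
      mig <- mig[order(mig$id, mig$year), , drop = FALSE]
      last_ev <- tapply(mig$event, mig$id, function(x) x[length(x)])
      out <- as.numeric(names(last_ev)[last_ev == "deregister"])
    } else out <- numeric()
    ids <- setdiff(ids, c(dead, out))
  }
  ids
}

subgroup_frame <- function(individuals, by) {
  if (is.null(by)) return(data.frame(subgroup = rep("all", nrow(individuals))))
  cols <- c(sex = "sex", country_group = "country_group",
            arrival_year = "registration_year")
  bad <- setdiff(by, names(cols))
  if (length(bad))
    stop("`by` must be a subset of ", paste(names(cols), collapse = ", "))
  vals <- individuals[, cols[by], drop = FALSE]
  data.frame(subgroup = do.call(paste, c(vals, sep = ":")))
}

# Per-row (individual-year) cell assignment over years x subgroups for rows
# whose individual belongs to D_y that year; returns 0-based cell ids (-1
# excluded), cell labels, and cell sizes.
oc_cells <- function(data, pk, years, by) {
  grp <- subgroup_frame(data$individuals, by)$subgroup
  glev <- sort(unique(grp))
  ncell <- length(years) * length(glev)
  cell <- rep(-1L, length(pk$id))
  gi <- grp[match(pk$id, data$individuals$id)]
  for (k in seq_along(years)) {
    Dy <- registered_set(data, years[k])
    sel <- pk$year == years[k] & pk$id %in% Dy
    cell[sel] <- (k - 1L) * length(glev) + match(gi[sel], glev) - 1L
  }
  list(cell = cell, years = rep(years, each = length(glev)),
       subgroup = rep(glev, length(years)), ncell = ncell,
       n = tabulate(cell + 1L, nbins = ncell))
}

#' Model-based over-coverage estimates with credible intervals
#'
#' For every year (and optional subgroup) computes
#' `OC_y = 1 - sum_{i in D_y} Zhat_iy / |D_y|`, where `Zhat_iy` is 1 for
#' years with a detection and the smoothed posterior presence probability
#' otherwise. The default 95% credible interval comes from the per-draw
#' distribution of `1 - mean` of the per-draw smoothed presence
#' probabilities, and quantifies parameter uncertainty about the expected
#' over-coverage.
#'
#' With `interval = "predictive"` the interval targets the *realized*
#' over-coverage of the cohort instead: each draw additionally receives the
#' conditional Bernoulli variation of the latent presence indicators given
#' the records (normal approximation to the sum), which is the appropriate
#' interval when comparing against the ground truth of a simulated cohort.
#' The predictive interval uses the session RNG; set a seed for
#' reproducibility.
#'
#' @param data A `cr_cohort`.
#' @param fit A `cr_fit` for the same cohort.
#' @param years Years to estimate; default all years after the first.
#' @param by Optional subgroup columns: any of `"sex"`, `"country_group"`,
#'   `"arrival_year"`.
#' @param prob Credible mass (default 0.95).
#' @param interval `"parameter"` (default) or `"predictive"`, see Details.
#' @return Data frame `year`, `subgroup`, `method = "model"`, `estimate`,
#'   `lower`, `upper`, `n_registered`; empty cells get `NA` estimates with
#'   `n_registered = 0`.
#' @export
oc_estimate <- function(data, fit, years = NULL, by = NULL, prob = 0.95,
                        interval = c("parameter", "predictive")) {
  interval <- match.arg(interval)
  cfg <- fit$config
  if (is.null(years)) years <- (cfg$first_year + 1):cfg$last_year
  pk <- pack_cohort(data, cfg)
  cl <- oc_cells(data, pk, years, by)
  res <- cpp_presence(pk$X, pk$O, pk$anyobs, pk$e, pk$d, pk$mask, pk$ptr,
                      all_draws(fit), cl$cell, cl$ncell)
  a <- (1 - prob) / 2
  est <- lower <- upper <- rep(NA_real_, cl$ncell)
  nonempty <- cl$n > 0
  if (any(nonempty)) {
    sums <- res$cell_draws[, nonempty, drop = FALSE]
    if (interval == "predictive")
      sums <- sums + sqrt(res$cell_vars[, nonempty, drop = FALSE]) *
        matrix(rnorm(length(sums)), nrow(sums))
    ocd <- 1 - sweep(sums, 2, cl$n[nonempty], "/")
    est[nonempty] <- 1 - colMeans(res$cell_draws[, nonempty, drop = FALSE]) /
      cl$n[nonempty]
    lower[nonempty] <- apply(ocd, 2, quantile, a)
    upper[nonempty] <- apply(ocd, 2, quantile, 1 - a)
  }
  data.frame(year = cl$years, subgroup = cl$subgroup, method = "model",
             estimate = est, lower = lower, upper = upper,
             n_registered = cl$n, stringsAsFactors = FALSE)
}

#' Register-trace over-coverage
#'
#' The deterministic rule: an individual counts as present in a year if and
#' only if they appear in at least one list that year, so
#' `OC_y = 1 - #seen / |D_y|`. No credible interval is attached.
#'
#' @inheritParams oc_estimate
#' @return Data frame `year`, `subgroup`, `method = "register_trace"`,
#'   `estimate`, `n_registered`.
#' @export
register_trace_oc <- function(data, years = NULL, by = NULL) {
  cfg <- data$config
  if (is.null(years)) years <- (cfg$first_year + 1):cfg$last_year
  grp <- subgroup_frame(data$individuals, by)$subgroup
  glev <- sort(unique(grp))
  rows <- list()
  for (y in years) {
    Dy <- registered_set(data, y)
    seen <- unique(data$observations$id[data$observations$year == y])
    gD <- grp[match(Dy, data$individuals$id)]
    for (g in glev) {
      dg <- Dy[gD == g]
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, subgroup = g, method = "register_trace",
        estimate = if (length(dg)) 1 - mean(dg %in% seen) else NA_real_,
        n_registered = length(dg), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Combined over-coverage table
#'
#' Stacks the model-based and register-trace estimates into one tidy table.
#' For every year and subgroup the model estimate never exceeds the
#' register-trace estimate (smoothed presence probabilities are
#' non-negative and equal one on detected years).
#'
#' @inheritParams oc_estimate
#' @return Data frame with both methods; register-trace rows carry `NA`
#'   interval bounds.
#' @export
oc_table <- function(data, fit, years = NULL, by = NULL, prob = 0.95) {
  m <- oc_estimate(data, fit, years = years, by = by, prob = prob)
  r <- register_trace_oc(data, years = years, by = by)
  r$lower <- NA_real_; r$upper <- NA_real_
  out <- rbind(m, r[, names(m)])
  rownames(out) <- NULL
  out
}

#' Presence-probability summaries by detection gap
#'
#' For every undetected, unresolved individual-year (no list record that
#' year, state not fixed by a de-registration or recorded death), records
#' the number of consecutive undetected years ending at that year, the time
#' since first migration, whether the individual is detected the following
#' year (`NA` in the final observation year), and the smoothed presence
#' probability; then aggregates to per-cell quantiles.
#'
#' @param presence Output of [presence_posterior()].
#' @param data The corresponding `cr_cohort`.
#' @param detail Return the row-level table instead of the aggregate.
#' @return Aggregated data frame `gap`, `tsm`, `seen_next`, `n`, `mean`,
#'   `q25`, `median`, `q75` (or the row-level table when `detail = TRUE`).
#' @export
gap_summary <- function(presence, data, detail = FALSE) {
  cfg <- data$config
  mask <- known_state_mask(data, cfg)
  key <- paste(presence$id, presence$year)
  stopifnot(identical(key, paste(mask$id, mask$year)))
  seen <- unique(paste(data$observations$id, data$observations$year))
  det <- key %in% seen
  reg <- data$individuals$registration_year[match(presence$id, data$individuals$id)]

  # rows arrive ordered by individual then year (presence_posterior order);
  # last detection year at-or-before each row, shifted to strictly-before
  last_seen <- stats::ave(ifelse(det, presence$year, -Inf), presence$id,
                          FUN = cummax)
  prev_seen <- stats::ave(last_seen, presence$id,
                          FUN = function(v) c(-Inf, v[-length(v)]))
  gap_all <- presence$year - pmax(prev_seen, reg - 1)

  keep <- !det & mask$known == "free"
  rows <- presence[keep, , drop = FALSE]
  seen_next <- ifelse(rows$year >= cfg$last_year, NA,
                      paste(rows$id, rows$year + 1L) %in% seen)
  out <- data.frame(id = rows$id, year = rows$year, gap = gap_all[keep],
                    tsm = rows$year - reg[keep], seen_next = seen_next,
                    zhat = rows$zhat)
  if (detail) return(out)
  cells <- split(out$zhat, list(gap = out$gap, tsm = out$tsm,
                                seen_next = addNA(factor(out$seen_next))),
                 drop = TRUE)
  agg <- do.call(rbind, lapply(names(cells), function(nm) {
    z <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(gap = as.numeric(parts[1]), tsm = as.numeric(parts[2]),
               seen_next = parts[3], n = length(z), mean = mean(z),
               q25 = quantile(z, 0.25), median = stats::median(z),
               q75 = quantile(z, 0.75), row.names = NULL)
  }))
  agg[order(agg$gap, agg$tsm, agg$seen_next), , drop = FALSE]
}
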