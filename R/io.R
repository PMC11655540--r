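#' Assemble a cohort object from its tables
#'
#' @param individuals Data frame with columns `id`, `sex`, `birth_year`,
#'   `country_group`, `registration_year`.
#' @param observations Data frame with columns `id`, `year`, `list_id`,
#'   `value` (0/1; zero rows are dropped).
#' @param events Data frame with columns `id`, `year`, `event` (one of
#'   `"death"`, `"deregister"`, `"reregister"`).
#' @param truth Optional ground-truth trajectory table (id, year, state).
#' @param config A [model_config()]; if `NULL` it is inferred from the
#'   tables (year range, number of lists).
#' @param validate Run [validate_cohort()] (default `TRUE`).
#' @return An object of class `cr_cohort`.
#' @export
cohort <- function(individuals, observations, events, truth = NULL,
                   config = NULL, validate = TRUE) {
  observations <- observations[observations$value != 0, , drop = FALSE]
  if (is.null(config)) {
    last <- max(c(individuals$registration_year + 1, observations$year,
                  events$year))
    config <- model_config(n_lists = max(c(1, observations$list_id)),
                           first_year = min(individuals$registration_year),
                           last_year = last)
  }
  out <- list(individuals = individuals,
              observations = canonical_order(observations, c("id", "year", "list_id")),
              events = canonical_order(events, c("id", "year")),
              truth = truth, config = config)
  class(out) <- "cr_cohort"
  if (validate) validate_cohort(out)
  out
}

#' @export
print.cr_cohort <- function(x, ...) {
  cat("Register cohort:", nrow(x$individuals), "individuals,",
      x$config$first_year, "-", x$config$last_year, ",",
      x$config$n_lists, "lists\n")
  cat("  ", nrow(x$observations), "positive list records,",
      nrow(x$events), "events",
      if (!is.null(x$truth)) "(ground truth attached)" else "", "\n")
  invisible(x)
}

fail_rules <- function(msgs) {
  if (length(msgs))
    stop("cohort validation failed:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
}

rule_msg <- function(file, rows, rule, ids) {
  sprintf("%s row %s: %s (id %s)", file, rows, rule, ids)
}

#' Validate cohort tables
#'
#' Checks the structural invariants of the three tables and fails hard --
#' no silent repair -- reporting file, row number and rule name for every
#' violation: known ids, years inside the observation window, no
#' observations before registration, 0/1 values, valid list ids, at most one
#' death per individual, no events after a death, and strict
#' deregister/reregister alternation starting with a deregistration later
#' than the registration year.
#'
#' @param x A `cr_cohort`.
#' @return Invisibly `TRUE`; stops on the first batch of violations.
#' @export
validate_cohort <- function(x) {
  cfg <- x$config
  ind <- x$individuals; obs <- x$observations; ev <- x$events
  msgs <- character()
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      msgs <<- c(msgs, sprintf("%s: missing column(s) %s", file,
                               paste(miss, collapse = ", ")))
  }
  need(ind, c("id", "sex", "birth_year", "country_group", "registration_year"),
       "individuals.csv")
  need(obs, c("id", "year", "list_id", "value"), "observations.csv")
  need(ev, c("id", "year", "event"), "events.csv")
  fail_rules(msgs)

  if (anyDuplicated(ind$id))
    msgs <- c(msgs, sprintf("individuals.csv: duplicate_id (id %s)",
                            paste(unique(ind$id[duplicated(ind$id)]), collapse = ", ")))
  bad <- which(!ind$sex %in% c("female", "male"))
  if (length(bad)) msgs <- c(msgs, rule_msg("individuals.csv", bad, "sex_code", ind$id[bad]))
  bad <- which(!ind$country_group %in% country_groups())
  if (length(bad)) msgs <- c(msgs, rule_msg("individuals.csv", bad, "country_group", ind$id[bad]))
  bad <- which(ind$registration_year < cfg$first_year |
               ind$registration_year > cfg$last_year)
  if (length(bad)) msgs <- c(msgs, rule_msg("individuals.csv", bad, "registration_year_range", ind$id[bad]))

  bad <- which(!obs$id %in% ind$id)
  if (length(bad)) msgs <- c(msgs, rule_msg("observations.csv", bad, "unknown_id", obs$id[bad]))
  bad <- which(obs$year < cfg$first_year | obs$year > cfg$last_year)
  if (length(bad)) msgs <- c(msgs, rule_msg("observations.csv", bad, "year_range", obs$id[bad]))
  bad <- which(!obs$value %in% 0:1)
  if (length(bad)) msgs <- c(msgs, rule_msg("observations.csv", bad, "value_not_binary", obs$id[bad]))
  bad <- which(obs$list_id < 1 | obs$list_id > cfg$n_lists)
  if (length(bad)) msgs <- c(msgs, rule_msg("observations.csv", bad, "list_id_range", obs$id[bad]))
  reg <- ind$registration_year[match(obs$id, ind$id)]
  bad <- which(!is.na(reg) & obs$year < reg)
  if (length(bad)) msgs <- c(msgs, rule_msg("observations.csv", bad, "obs_before_registration", obs$id[bad]))

  bad <- which(!ev$id %in% ind$id)
  if (length(bad)) msgs <- c(msgs, rule_msg("events.csv", bad, "unknown_id", ev$id[bad]))
  bad <- which(ev$year < cfg$first_year | ev$year > cfg$last_year)
  if (length(bad)) msgs <- c(msgs, rule_msg("events.csv", bad, "year_range", ev$id[bad]))
  bad <- which(!ev$event %in% c("death", "deregister", "reregister"))
  if (length(bad)) msgs <- c(msgs, rule_msg("events.csv", bad, "event_code", ev$id[bad]))
  regE <- ind$registration_year[match(ev$id, ind$id)]
  bad <- which(!is.na(regE) & ev$year <= regE)
  if (length(bad)) msgs <- c(msgs, rule_msg("events.csv", bad, "event_not_after_registration", ev$id[bad]))
  fail_rules(msgs)

  for (id in unique(ev$id)) {
    sub <- ev[ev$id == id, , drop = FALSE]
    sub <- sub[order(sub$year), , drop = FALSE]
    dth <- which(sub$event == "death")
    if (length(dth) > 1)
      msgs <- c(msgs, sprintf("events.csv: multiple_death (id %s)", id))
    if (length(dth) && any(sub$year > sub$year[dth[1]]))
      msgs <- c(msgs, sprintf("events.csv: event_after_death (id %s)", id))
    mig <- sub$event[sub$event != "death"]
    expected <- rep_len(c("deregister", "reregister"), length(mig))
    if (length(mig) && !all(mig == expected))
      msgs <- c(msgs, sprintf("events.csv: event_alternation (id %s)", id))
  }
  fail_rules(msgs)
  invisible(TRUE)
}

#' Write cohort tables to CSV
#'
#' Writes `individuals.csv`, `observations.csv`, `events.csv` (and
#' `truth.csv` for simulated cohorts) in canonical row order, so that
#' writing the same cohort twice produces byte-identical files.
#'
#' @param x A `cr_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly the directory path.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) write.csv(df, file.path(dir, name),
                                     row.names = FALSE, quote = FALSE)
  wr(x$individuals, "individuals.csv")
  wr(x$observations, "observations.csv")
  wr(x$events, "events.csv")
  if (!is.null(x$truth)) wr(x$truth, "truth.csv")
  invisible(dir)
}

#' Read cohort tables from CSV
#'
#' Reads the tables written by [write_cohort()] (UTF-8, comma-separated,
#' exact headers) and validates every structural invariant; malformed input
#' fails hard with file, row and rule name.
#'
#' @param dir Directory holding the CSV files.
#' @param config Optional [model_config()]; inferred from the tables when
#'   `NULL`.
#' @return A `cr_cohort` (with `truth` attached when `truth.csv` exists).
#' @export
read_cohort <- function(dir, config = NULL) {
  rd <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing file: ", path)
    read.csv(path, stringsAsFactors = FALSE)
  }
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  cohort(individuals = rd("individuals.csv"),
         observations = rd("observations.csv"),
         events = rd("events.csv"), truth = truth, config = config)
}
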