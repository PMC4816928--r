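#' Trial configuration
#'
#' A `trial_config` bundles everything that distinguishes one country profile
#' from another: the ordered arm tags, phase durations (1-week baseline +
#' 4-week intervention), the run-in threshold (at least 15 barcoded items in
#' week 1), stratification factor definitions, candidate block sizes, the
#' label-scheme tables for every arm, the screening predicate, and the
#' recruitment window.
#'
#' Two profiles ship ready-made: [trial_config_australia()] (5 arms, no
#' stratification) and [trial_config_new_zealand()] (3 arms, stratified by
#' ethnicity and self-reported interest in healthy eating).
#'
#' @param country Profile name.
#' @param arms Ordered character vector of arm tags; each must be one of
#'   `DIG`, `TLL`, `HSR`, `NIP`, `WARNING`.
#' @param baseline_days,intervention_days Phase durations in whole days.
#' @param run_in_min_items Minimum barcoded items recorded during week 1.
#' @param run_in_grace_days Days after the baseline phase during which the
#'   run-in decision stays open (covers late transmission of week-1 lists)
#'   before exclusion.
#' @param strat_factors Named list of factor-level character vectors;
#'   empty list = single unstratified stratum.
#' @param block_sizes Candidate randomization block sizes; default
#'   `length(arms) * c(1, 2)`.
#' @param schemes Label-scheme tables per arm tag; default [default_schemes()].
#' @param screening Predicate `function(answers) -> TRUE/FALSE` applied to
#'   the screening-questionnaire answers (the actual trial criteria live in
#'   the protocols, so this is deliberately opaque and configurable); the
#'   default accepts answers with a truthy `eligible` entry.
#' @param recruitment_days Length of the overall recruitment window, used to
#'   cap the monthly registration reminders ("until 5 weeks before the
#'   overall trial recruitment completion").
#' @return A `trial_config` object.
#' @export
trial_config <- function(country = "custom",
                         arms = c("TLL", "HSR", "NIP"),
                         baseline_days = 7L,
                         intervention_days = 28L,
                         run_in_min_items = 15L,
                         run_in_grace_days = 7L,
                         strat_factors = list(),
                         block_sizes = NULL,
                         schemes = default_schemes(),
                         screening = NULL,
                         recruitment_days = 180L) {
  if (length(arms) == 0) stop_config("`arms` must be non-empty")
  known <- c("DIG", "TLL", "HSR", "NIP", "WARNING")
  if (!all(arms %in% known) || anyDuplicated(arms)) {
    stop_config(paste0("arms must be distinct tags among: ",
                       paste(known, collapse = ", ")))
  }
  if (baseline_days <= 0 || intervention_days <= 0) {
    stop_config("phase durations must be > 0")
  }
  if (run_in_min_items < 0) stop_config("run_in_min_items must be >= 0")
  block_sizes <- as.integer(block_sizes %||% (length(arms) * c(1L, 2L)))
  if (any(block_sizes <= 0) || any(block_sizes %% length(arms) != 0)) {
    stop_config("every block size must be a positive multiple of the number of arms")
  }
  screening <- screening %||% function(answers) isTRUE(answers$eligible)
  structure(
    list(country = country, arms = arms,
         baseline_days = as.integer(baseline_days),
         intervention_days = as.integer(intervention_days),
         run_in_min_items = as.integer(run_in_min_items),
         run_in_grace_days = as.integer(run_in_grace_days),
         strat_factors = strat_factors, block_sizes = block_sizes,
         schemes = schemes, screening = screening,
         recruitment_days = as.integer(recruitment_days)),
    class = "trial_config"
  )
}

#' @rdname trial_config
#' @export
trial_config_australia <- function(...) {
  trial_config(country = "australia",
               arms = c("DIG", "TLL", "HSR", "NIP", "WARNING"),
               strat_factors = list(), ...)
}

#' @rdname trial_config
#' @param ... Overrides passed on to [trial_config()].
#' @export
trial_config_new_zealand <- function(...) {
  trial_config(country = "new_zealand",
               arms = c("TLL", "HSR", "NIP"),
               strat_factors = list(
                 ethnicity = c("maori", "pacific", "other"),
                 interest_healthy_eating = c("low", "high")
               ), ...)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config> ", x$country, ": ", length(x$arms), " arms (",
      paste(x$arms, collapse = ", "), "); baseline ", x$baseline_days,
      " d + intervention ", x$intervention_days, " d; run-in >= ",
      x$run_in_min_items, " items; ",
      if (length(x$strat_factors)) paste0("stratified by ",
        paste(names(x$strat_factors), collapse = " x ")) else "unstratified",
      "\n", sep = "")
  invisible(x)
}

#' Stratum ids defined by a configuration
#'
#' @param config A [trial_config()].
#' @return Character vector of stratum ids: the cross of all factor levels,
#'   or `"(all)"` when unstratified.
#' @export
config_strata <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  if (length(config$strat_factors) == 0) return("(all)")
  grid <- expand.grid(config$strat_factors, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  apply(grid, 1, paste, collapse = ":")
}

#' Stratum id for a participant's factor levels
#'
#' @param config A [trial_config()].
#' @param factors Named list/vector of the participant's factor levels;
#'   ignored when the configuration is unstratified.
#' @return A stratum id string.
#' @export
stratum_id <- function(config, factors = NULL) {
  stopifnot(inherits(config, "trial_config"))
  if (length(config$strat_factors) == 0) return("(all)")
  vals <- map_chr(names(config$strat_factors), function(f) {
    v <- factors[[f]]
    if (is.null(v) || !v %in% config$strat_factors[[f]]) {
      stop_config(paste0("invalid or missing level for stratification factor ", f))
    }
    v
  })
  paste(vals, collapse = ":")
}

#' Read and write trial configurations
#'
#' Configurations serialize to YAML or JSON (by file extension). The
#' screening predicate is code, not data: files store the tag
#' `screening: default` and reading restores the default predicate; supply a
#' custom predicate programmatically after reading if needed.
#'
#' @param config A [trial_config()].
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `write_trial_config()` returns `path` invisibly;
#'   `read_trial_config()` returns a `trial_config`.
#' @export
write_trial_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  x <- list(
    country = config$country, arms = config$arms,
    baseline_days = config$baseline_days,
    intervention_days = config$intervention_days,
    run_in_min_items = config$run_in_min_items,
    run_in_grace_days = config$run_in_grace_days,
    strat_factors = config$strat_factors,
    block_sizes = config$block_sizes,
    recruitment_days = config$recruitment_days,
    screening = "default",
    schemes = schemes_to_list(config$schemes)
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read trial config: ", path))
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  needed <- c("country", "arms", "baseline_days", "intervention_days",
              "run_in_min_items")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop_config(paste0("trial config is missing field(s): ",
                       paste(miss, collapse = ", ")))
  }
  strat <- x$strat_factors
  if (is.null(strat) || length(strat) == 0) strat <- list()
  strat <- lapply(strat, as.character)
  trial_config(
    country = x$country, arms = as.character(x$arms),
    baseline_days = x$baseline_days, intervention_days = x$intervention_days,
    run_in_min_items = x$run_in_min_items,
    run_in_grace_days = x$run_in_grace_days %||% 7L,
    strat_factors = strat,
    block_sizes = x$block_sizes,
    schemes = if (is.null(x$schemes)) default_schemes() else schemes_from_list(x$schemes),
    recruitment_days = x$recruitment_days %||% 180L
  )
}

#' One-way fingerprint of an email address
#'
#' Registration stores only a salted one-way hash of the email, satisfying
#' both the duplicate-registration check (case-insensitive) and the
#' requirement that identifiable information stays out of outcome data.
#'
#' @param email Email address.
#' @return A hex digest string.
#' @export
email_fingerprint <- function(email) {
  if (!is.character(email) || length(email) != 1 || is.na(email) || email == "") {
    stop_arg("`email` must be a non-empty string")
  }
  digest::digest(paste0("labelrct|", tolower(trimws(email))), algo = "sha256")
}
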