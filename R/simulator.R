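#' Synthetic cohort simulation
#'
#' The simulator stands in for real users: it drives n synthetic
#' participants day-by-day through consent, screening, registration, the
#' baseline shopping week, the run-in check, randomization, four
#' intervention weeks of scanning under the allocated label arm, and
#' follow-up -- exercising every module of the engine end-to-end -- and then
#' aggregates the event log into a recruitment-funnel/usage report. It is an
#' engine-exercise model, not a behavioural model of real shoppers.
#'
#' @name simulator
NULL

#' Generate a synthetic food composition database
#'
#' Products are spread across `n_categories` categories with nutrient values
#' drawn from fixed uniform ranges wide enough to exercise every band of the
#' label schemes (energy 100-3600 kJ, sugars 0-60 g, sodium 0-1500 mg, ...).
#' Barcodes are synthetic EAN-13 codes with valid check digits. About 15% of
#' products are beverages.
#'
#' @param n Number of products.
#' @param n_categories Number of categories.
#' @param seed Integer seed.
#' @return A tibble in the food-table column layout (pass to [as_food_db()]
#'   or write as CSV for [read_food_db()]).
#' @export
simulate_food_db <- function(n = 200, n_categories = 8, seed = 1) {
  if (n <= 0) stop_arg("`n` must be positive")
  drawn <- rng_draw(rng_stream(seed), {
    body <- sprintf("930060%06d", sample.int(999999, n))
    barcode <- map_chr(body, function(b) {
      d <- as.integer(strsplit(b, "")[[1]])
      w <- rep(c(1L, 3L), length.out = 12)
      paste0(b, (10L - sum(d * w) %% 10L) %% 10L)
    })
    bev <- runif(n) < 0.15
    tibble(
      barcode = barcode,
      name = sprintf("product-%04d", seq_len(n)),
      category_id = sprintf("cat%02d", sample.int(n_categories, n, replace = TRUE)),
      is_beverage = bev,
      serving_size = round(ifelse(bev, runif(n, 100, 375), runif(n, 20, 150)), 0),
      energy_kj_100 = round(ifelse(bev, runif(n, 0, 250), runif(n, 100, 3600)), 0),
      protein_g_100 = round(runif(n, 0, 25), 1),
      fat_g_100 = round(runif(n, 0, 35), 1),
      satfat_g_100 = round(runif(n, 0, 15), 1),
      carb_g_100 = round(runif(n, 0, 70), 1),
      sugars_g_100 = round(runif(n, 0, 60), 1),
      fibre_g_100 = round(runif(n, 0, 12), 1),
      sodium_mg_100 = round(runif(n, 0, 1500), 0),
      fvnl_pct = round(runif(n, 0, 100), 0)
    )
  })
  drawn$value
}

#' Synthetic participant behaviour model
#'
#' All probabilities are per-event; shopping is a daily Bernoulli trip at
#' rate `trips_per_week / 7` with `items_min + Poisson(items_lambda)` items
#' per trip; dropout is a phase-specific daily Bernoulli hazard.
#'
#' @param consent_prob,screening_pass_prob,registration_prob,baseline_q_prob,followup_q_prob
#'   Stage completion probabilities in `[0, 1]`.
#' @param trips_per_week Mean shopping trips per week (>= 0, at most 7: one
#'   trip per day).
#' @param items_min,items_lambda Items per trip: `items_min + rpois(items_lambda)`.
#' @param receipt_prob Probability a transmitted list gets a receipt photo.
#' @param unmatched_prob Probability a scanned barcode is absent from the
#'   database (feeds the crowdsourcing path).
#' @param crowdsource_prob Probability an unmatched scan is crowdsourced.
#' @param transmit_fail_prob Probability a list transmission fails (the open
#'   list is retained and retried with the next trip).
#' @param dropout_hazard Named daily hazards for phases `baseline`,
#'   `intervention`, `followup`.
#' @return A `behavior_model` object.
#' @export
behavior_model <- function(consent_prob = 0.95, screening_pass_prob = 0.8,
                           registration_prob = 0.95, baseline_q_prob = 0.95,
                           followup_q_prob = 0.8, trips_per_week = 2.5,
                           items_min = 1L, items_lambda = 7,
                           receipt_prob = 0.6, unmatched_prob = 0.05,
                           crowdsource_prob = 0.5, transmit_fail_prob = 0.02,
                           dropout_hazard = c(baseline = 0.01,
                                              intervention = 0.005,
                                              followup = 0.01)) {
  probs <- c(consent_prob, screening_pass_prob, registration_prob,
             baseline_q_prob, followup_q_prob, receipt_prob, unmatched_prob,
             crowdsource_prob, transmit_fail_prob, dropout_hazard)
  if (any(probs < 0 | probs > 1)) stop_arg("probabilities must lie in [0, 1]")
  if (trips_per_week < 0 || trips_per_week > 7 || items_lambda < 0 || items_min < 0) {
    stop_arg("rates must be >= 0 (and trips_per_week at most 7)")
  }
  if (!all(c("baseline", "intervention", "followup") %in% names(dropout_hazard))) {
    stop_arg("dropout_hazard needs baseline, intervention, followup entries")
  }
  structure(list(
    consent_prob = consent_prob, screening_pass_prob = screening_pass_prob,
    registration_prob = registration_prob, baseline_q_prob = baseline_q_prob,
    followup_q_prob = followup_q_prob, trips_per_week = trips_per_week,
    items_min = as.integer(items_min), items_lambda = items_lambda,
    receipt_prob = receipt_prob, unmatched_prob = unmatched_prob,
    crowdsource_prob = crowdsource_prob,
    transmit_fail_prob = transmit_fail_prob,
    dropout_hazard = dropout_hazard
  ), class = "behavior_model")
}

#' @rdname behavior_model
#' @description `behavior_model_compliant()` is the zero-attrition limit:
#'   every stage completes with certainty, a daily trip of exactly five items
#'   guarantees the run-in threshold, and nothing drops out.
#' @export
behavior_model_compliant <- function() {
  behavior_model(consent_prob = 1, screening_pass_prob = 1,
                 registration_prob = 1, baseline_q_prob = 1,
                 followup_q_prob = 1, trips_per_week = 7, items_min = 5L,
                 items_lambda = 0, receipt_prob = 1, unmatched_prob = 0,
                 crowdsource_prob = 0, transmit_fail_prob = 0,
                 dropout_hazard = c(baseline = 0, intervention = 0,
                                    followup = 0))
}

phase_of <- function(p, config, clock) {
  rel <- rel_day(p, clock)
  if (is.na(rel) || rel < config$baseline_days) "baseline"
  else if (rel < config$baseline_days + config$intervention_days) "intervention"
  else "followup"
}

ACTIVE_STATES <- c("REGISTERED", "BASELINE", "RANDOMIZED", "INTERVENTION",
                   "FOLLOW_UP_DUE")

# One participant's whole trajectory. Runs inside the cohort behaviour
# stream; the allocation state (own independent sub-streams) is threaded
# through and returned.
sim_participant <- function(i, config, behavior, db, registry, alloc,
                            related_seed, horizon_days) {
  id <- sprintf("P%04d", i)
  p <- new_participant(id, day = 0L)
  p <- log_event(p, 0L, "installed")
  done <- function() list(participant = p, registry = registry, alloc = alloc)

  ok <- runif(1) < behavior$consent_prob
  p <- consent(p, ok, ok, day = 0L)
  if (p$state != "CONSENTED") return(done())

  answers <- list(eligible = runif(1) < behavior$screening_pass_prob)
  for (f in names(config$strat_factors)) {
    lv <- config$strat_factors[[f]]
    answers[[f]] <- lv[sample.int(length(lv), 1)]
  }
  p <- screen(p, answers, config, day = 0L)

  if (p$state == "SCREENED_ELIGIBLE" && runif(1) < behavior$registration_prob) {
    reg <- register(p, sprintf("p%04d@example.org", i), registry, day = 0L)
    p <- reg$participant
    registry <- reg$registry
    if (reg$ok && runif(1) < behavior$baseline_q_prob) {
      p <- submit_questionnaire(p, "baseline", list(completed = TRUE), day = 0L)
    }
  }

  rs <- rng_stream(related_seed)
  for (day in 0:horizon_days) {
    if (p$state %in% ACTIVE_STATES) {
      adv <- advance_to(p, day, config, alloc)
      p <- adv$participant
      alloc <- adv$alloc
    }
    # deliver today's messages before any terminal break
    msgs <- due_messages(p, day, config)
    for (m in seq_len(nrow(msgs))) {
      p <- mark_sent(p, msgs$rule_id[m], msgs$due_day[m], msgs$channel[m])
    }
    if (!p$state %in% c(ACTIVE_STATES, "CONSENTED", "SCREENED_ELIGIBLE")) break

    # phase-specific daily dropout hazard
    if (p$state %in% c("BASELINE", "INTERVENTION", "FOLLOW_UP_DUE")) {
      if (runif(1) < behavior$dropout_hazard[[phase_of(p, config, day)]]) {
        p <- withdraw(p, day)
        break
      }
    }

    # shopping trip during the 5 data-collection weeks
    rel <- rel_day(p, day)
    shopping <- p$state %in% c("BASELINE", "INTERVENTION") && !is.na(rel) &&
      rel < config$baseline_days + config$intervention_days
    if (shopping && runif(1) < behavior$trips_per_week / 7) {
      k <- behavior$items_min + rpois(1, behavior$items_lambda)
      for (j in seq_len(k)) {
        unmatched <- runif(1) < behavior$unmatched_prob
        code <- if (unmatched) "00000000" else
          db$products$barcode[sample.int(nrow(db$products), 1)]
        sc <- scan(p, code, db, config, day, rng = rs)
        p <- sc$participant
        rs <- sc$stream
        if (sc$crowdsource_offered && runif(1) < behavior$crowdsource_prob) {
          p <- submit_crowdsource(p, code, day)
        }
      }
      if (length(p$open_list$barcode) > 0) {
        sub <- submit_list(p, day, config,
                           transmit_ok = runif(1) >= behavior$transmit_fail_prob)
        p <- sub$participant
        if (sub$ok && runif(1) < behavior$receipt_prob) {
          p <- add_receipt(p, sub$list_id, day)
        }
      }
    }

    if (p$state == "FOLLOW_UP_DUE" && runif(1) < behavior$followup_q_prob) {
      p <- complete_followup(p, list(completed = TRUE), day)
      msgs <- due_messages(p, day, config)
      for (m in seq_len(nrow(msgs))) {
        p <- mark_sent(p, msgs$rule_id[m], msgs$due_day[m], msgs$channel[m])
      }
      break
    }
  }
  list(participant = p, registry = registry, alloc = alloc)
}

#' Simulate a full trial cohort
#'
#' Runs `n` synthetic participants through the engine day-by-day (45 days
#' each by default: the 35-day trial plus a follow-up completion tail) and
#' returns the cohort with its event log, notification log, allocation
#' state, and funnel report. Fully reproducible: the same seed yields the
#' same event log. Randomization uses its own per-stratum sub-streams
#' derived from the seed, so arm sequences are independent of behavioural
#' noise.
#'
#' @param n Number of participants (> 0).
#' @param config A [trial_config()].
#' @param behavior A [behavior_model()].
#' @param db A food database (`food_db`, or a product table).
#' @param seed Integer seed driving all randomness.
#' @param horizon_days Days to simulate per participant.
#' @return A `trial_cohort`: list with `participants`, `events` (tibble),
#'   `notifications` (tibble), `alloc`, `config`, `behavior`, `report`
#'   (a `cohort_report`).
#' @export
simulate_cohort <- function(n, config, behavior = behavior_model(),
                            db = NULL, seed = 1, horizon_days = 45L) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n <= 0) {
    stop_arg("`n` must be a positive participant count")
  }
  stopifnot(inherits(config, "trial_config"), inherits(behavior, "behavior_model"))
  db <- as_food_db(db %||% simulate_food_db(seed = derive_seed(seed, "food_db")))
  n <- as.integer(n)
  alloc <- allocation_state(config$arms, config$block_sizes,
                            config_strata(config),
                            seed = derive_seed(seed, "allocation"))
  stream <- rng_stream(derive_seed(seed, "behavior"))
  registry <- character(0)
  participants <- vector("list", n)

  for (i in seq_len(n)) {
    drawn <- rng_draw(stream, sim_participant(
      i, config, behavior, db, registry, alloc,
      related_seed = derive_seed(seed, paste0("related-", i)),
      horizon_days = horizon_days
    ))
    stream <- drawn$stream
    participants[[i]] <- drawn$value$participant
    registry <- drawn$value$registry
    alloc <- drawn$value$alloc
  }

  events <- bind_rows(map(participants, participant_events))
  notifications <- bind_rows(map(participants, function(p) {
    if (nrow(p$notifications) == 0) return(NULL)
    mutate(p$notifications, participant_id = p$id, .before = 1)
  }))
  if (is.null(notifications) || nrow(notifications) == 0) {
    notifications <- mutate(empty_notifications(),
                            participant_id = character(0), .before = 1)
  }
  structure(
    list(participants = participants, events = events,
         notifications = notifications, alloc = alloc, config = config,
         behavior = behavior, db = db, seed = as.integer(seed),
         report = funnel_report(events)),
    class = "trial_cohort"
  )
}

#' @export
print.trial_cohort <- function(x, ...) {
  cat("<trial_cohort> ", length(x$participants), " participants (",
      x$config$country, ", seed ", x$seed, ")\n", sep = "")
  print(x$report)
  invisible(x)
}

FUNNEL_STAGES <- c(downloads = "installed", consented = "consented",
                   screened_eligible = "screened_eligible",
                   registered = "registered", randomized = "randomized",
                   completed = "completed")

#' Aggregate an event log into a funnel/usage report
#'
#' A deterministic aggregation: funnel stage counts (distinct participants
#' reaching each stage), run-in exclusions, usage totals (lists, items,
#' receipts, label views, crowdsource submissions), and per-stratum per-arm
#' allocation counts.
#'
#' @param events An event tibble (from a `trial_cohort` or
#'   [read_event_log()]), or a path to a JSON-lines event log.
#' @return A `cohort_report`: list with `funnel` (tibble `stage`, `n`),
#'   `excluded_run_in`, `totals` (tibble `metric`, `n`), `arms` (tibble
#'   `stratum`, `arm`, `n`).
#' @export
funnel_report <- function(events) {
  if (is.character(events) && length(events) == 1) {
    events <- read_event_log(events)
  }
  if (!is.data.frame(events)) stop_arg("`events` must be an event tibble or a path")
  stage_n <- map_int(FUNNEL_STAGES, function(ev) {
    length(unique(events$participant_id[events$event == ev]))
  })
  count_ev <- function(ev) sum(events$event == ev)
  rand <- events[events$event == "randomized", , drop = FALSE]
  arms <- if (nrow(rand) == 0) {
    tibble(stratum = character(), arm = character(), n = integer())
  } else {
    summarise(group_by(rand, .data$stratum, .data$arm), n = n(), .groups = "drop")
  }
  structure(
    list(
      funnel = tibble(stage = names(FUNNEL_STAGES), n = as.integer(stage_n)),
      excluded_run_in = count_ev("excluded_run_in"),
      totals = tibble(
        metric = c("lists", "items", "receipts", "label_views", "crowdsource"),
        n = c(count_ev("list_submitted"),
              sum(events$n_items[events$event == "list_submitted"], na.rm = TRUE),
              count_ev("receipt_captured"),
              count_ev("label_view"),
              count_ev("crowdsource_submitted"))
      ),
      arms = arms
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  f <- x$funnel
  cat("<cohort_report>\n  funnel: ",
      paste(sprintf("%s=%d", f$stage, f$n), collapse = " -> "),
      "\n  excluded at run-in: ", x$excluded_run_in,
      "\n  totals: ",
      paste(sprintf("%s=%d", x$totals$metric, x$totals$n), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write and read event logs as JSON lines
#'
#' One event per line. Reading validates each line and names the offending
#' line on failure.
#'
#' @param events An event tibble or `trial_cohort`.
#' @param path File path.
#' @return `write_event_log()` the path, invisibly; `read_event_log()` the
#'   event tibble.
#' @export
write_event_log <- function(events, path) {
  if (inherits(events, "trial_cohort")) events <- events$events
  lines <- map_chr(seq_len(nrow(events)), function(i) {
    row <- as.list(events[i, ])
    jsonlite::toJSON(row[!map_lgl(row, function(v) is.na(v) || is.null(v))],
                     auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read event log: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i]),
                  error = function(e) NULL)
    if (is.null(x) || is.null(x$participant_id) || is.null(x$event) ||
        is.null(x$day)) {
      stop_format(paste0("malformed event at line ", i, " of ", path))
    }
    tibble(participant_id = as.character(x$participant_id),
           day = as.integer(x$day), event = as.character(x$event),
           arm = as.character(x$arm %||% NA), stratum = as.character(x$stratum %||% NA),
           n_items = as.integer(x$n_items %||% NA),
           barcode = as.character(x$barcode %||% NA),
           detail = as.character(x$detail %||% NA))
  })
  bind_rows(rows)
}
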