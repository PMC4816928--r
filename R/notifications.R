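#' Notification and reminder rule engine
#'
#' Ten message rules drive engagement through the trial. Six are
#' clock-triggered and evaluated by [due_messages()]; four are
#' event-triggered and queued by the operation that observes the event
#' (screening failure, list submission, follow-up completion). Every
#' delivered record is unique on (rule, participant, due day) and each rule
#' carries a repeat cap, so no reminder stream can fire unboundedly -- overly
#' frequent reminders were an observed field defect, and the cap is the fix.
#'
#' Day offsets written "day N of a phase" fall N whole days after the
#' phase's anchor day (registration for week 1, randomization for the
#' intervention phase), so "day 3 of week 1" is trial day 3 and "day 28 of
#' the intervention phase" is trial day 35 -- the end of week 5, the same
#' day the follow-up questionnaire becomes due. All other offsets count
#' whole days from their anchor event.
#'
#' @name notifications
NULL

#' The default message-rule table
#'
#' One row per rule: id, trigger description, anchor, 1-based-or-offset
#' schedule, channel, and repeat cap (`Inf` for the per-list rules that fire
#' after every qualifying submission).
#'
#' @return A tibble with columns `rule_id`, `trigger`, `anchor`, `offsets`
#'   (list column), `monthly_after` (extend `offsets` every 28 days until 35
#'   days before recruitment closes), `channel`, `repeat_cap`.
#' @export
default_message_rules <- function() {
  tibble(
    rule_id = c(
      "ineligible_foodswitch_link",
      "registration_reminder",
      "runin_under_threshold",
      "list_sent_success",
      "baseline_recording_reminder",
      "intervention_keep_recording",
      "trial_ending_soon",
      "followup_request",
      "followup_reminder",
      "trial_completed"
    ),
    trigger = c(
      "first eligibility check failed",
      "registration or baseline questionnaire not completed",
      "list submitted in week 1 with running total below the run-in threshold",
      "list transmitted with week-1 total at or above the run-in threshold",
      "no product list sent since the beginning of week 1",
      "no new product list during the intervention phase",
      "day 26 of the intervention phase reached",
      "day 28 of the intervention phase reached",
      "follow-up questionnaire not completed",
      "follow-up questionnaire completed"
    ),
    anchor = c("screening", "consent", "list", "list", "registration",
               "last_list_or_intervention", "intervention", "intervention",
               "intervention_end", "followup"),
    offsets = list(0L, c(2L, 9L, 16L, 23L, 30L), 0L, 0L, c(3L, 5L),
                   c(4L, 6L, 9L, 12L, 18L, 24L), 26L, 28L,
                   c(6L, 12L, 18L, 24L, 30L), 0L),
    monthly_after = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE),
    channel = c("in-app", "push", "in-app", "in-app", "push", "push", "push",
                "in-app", "push", "in-app"),
    # keep-recording can re-arm after every list (its anchor resets), so its
    # cap is one per intervention day rather than one per schedule slot
    repeat_cap = c(1, Inf, Inf, Inf, 2, 28, 1, 1, 5, 1)
  )
}

# Registration-reminder schedule for one participant: 2 days after consent,
# then weekly x4, then every 28 days until 35 days before recruitment closes.
registration_offsets <- function(offs, monthly_after, config, consent_day) {
  if (isTRUE(monthly_after)) {
    horizon <- config$recruitment_days - 35L
    nxt <- max(offs) + 28L
    while (consent_day + nxt <= horizon) {
      offs <- c(offs, nxt)
      nxt <- nxt + 28L
    }
  }
  offs
}

#' Clock-triggered messages due at a given day
#'
#' Returns exactly the notification records whose trigger holds, whose due
#' day equals `clock`, and which have not been sent. Evaluation is pure:
#' calling twice at the same clock returns the same set until the records
#' are marked sent with [mark_sent()]. Event-triggered records previously
#' queued for this day are included while unsent.
#'
#' @param participant A `trial_participant` beyond `INSTALLED`.
#' @param clock Current day index.
#' @param config A [trial_config()].
#' @param rules A message-rule table, default [default_message_rules()].
#' @return A tibble of records: `rule_id`, `participant_id`, `due_day`,
#'   `channel`, `sent` (always `FALSE`).
#' @export
due_messages <- function(participant, clock, config,
                         rules = default_message_rules()) {
  p <- participant
  stopifnot(inherits(config, "trial_config"))
  if (p$state == "INSTALLED") {
    stop_state("notifications require a participant beyond INSTALLED")
  }
  clock <- as.integer(clock)
  r <- p$registration_day
  b <- config$baseline_days
  iv <- config$intervention_days
  due <- character(0)
  chan <- character(0)

  for (i in seq_len(nrow(rules))) {
    id <- rules$rule_id[i]
    offs <- rules$offsets[[i]]
    hit <- switch(id,
      registration_reminder = {
        incomplete <- !state_at_least(p, "REGISTERED") ||
          is.null(p$questionnaires$baseline)
        active <- p$state %in% c("CONSENTED", "SCREENED_ELIGIBLE", "REGISTERED")
        active && incomplete && !is.na(p$consent_day) &&
          (clock - p$consent_day) %in%
            registration_offsets(offs, rules$monthly_after[i], config, p$consent_day)
      },
      baseline_recording_reminder = {
        # "at days 3 and 5 of week 1": phase day N = N days after the
        # anchor (registration closes day 0, so week 1 spans days 1..7)
        p$state %in% c("REGISTERED", "BASELINE") && !is.na(r) &&
          nrow(p$lists) == 0 && (clock - r) %in% offs
      },
      intervention_keep_recording = {
        if (p$state == "INTERVENTION") {
          anchor <- max(r + b, p$last_list_day, na.rm = TRUE)
          (clock - anchor) %in% offs
        } else FALSE
      },
      trial_ending_soon = {
        # "day N of the intervention phase": N days after randomization
        p$state == "INTERVENTION" && (clock - (r + b)) %in% offs
      },
      followup_request = {
        # day 28 of the intervention phase = trial day 35, the same day the
        # engine moves the participant to FOLLOW_UP_DUE
        p$state %in% c("INTERVENTION", "FOLLOW_UP_DUE") &&
          (clock - (r + b)) %in% offs
      },
      followup_reminder = {
        p$state == "FOLLOW_UP_DUE" && (clock - (r + b + iv)) %in% offs
      },
      FALSE  # event-triggered rules never match on the clock
    )
    if (isTRUE(hit)) {
      due <- c(due, id)
      chan <- c(chan, rules$channel[i])
    }
  }

  queued_today <- p$notifications$due_day == clock & !p$notifications$sent
  if (length(due) == 0 && !any(queued_today)) {
    return(quick_tibble(rule_id = character(), participant_id = character(),
                        due_day = integer(), channel = character(),
                        sent = logical()))
  }
  out <- quick_tibble(rule_id = due, participant_id = rep(p$id, length(due)),
                      due_day = rep(clock, length(due)), channel = chan,
                      sent = rep(FALSE, length(due)))
  # event-triggered records queued for today and still unsent
  if (any(queued_today)) {
    q <- p$notifications[queued_today, ]
    out <- bind_rows(out, quick_tibble(
      rule_id = q$rule_id, participant_id = rep(p$id, nrow(q)),
      due_day = q$due_day, channel = q$channel, sent = rep(FALSE, nrow(q))
    ))
  }
  # never re-deliver: drop records already sent, enforce repeat caps
  sent <- p$notifications[p$notifications$sent, ]
  out <- out[!paste(out$rule_id, out$due_day) %in%
               paste(sent$rule_id, sent$due_day), , drop = FALSE]
  if (nrow(out) > 0) {
    caps <- setNames(rules$repeat_cap, rules$rule_id)
    n_sent <- table(sent$rule_id)
    keep <- map_lgl(out$rule_id, function(id) {
      prior <- if (id %in% names(n_sent)) n_sent[[id]] else 0L
      cap <- if (id %in% names(caps)) caps[[id]] else Inf
      prior < cap
    })
    out <- out[keep, , drop = FALSE]
  }
  out[!duplicated(paste(out$rule_id, out$due_day)), , drop = FALSE]
}

#' React to a submitted product list
#'
#' During week 1 a transmitted list with a running item total still under
#' the run-in threshold triggers the keep-going reminder; once the week-1
#' total is at or above the threshold (in any phase) a success message
#' confirms the transmission. Both are in-app, delivered immediately.
#'
#' @param participant A `trial_participant` that just transmitted a list.
#' @param clock Day of the submission.
#' @param config A [trial_config()].
#' @return List with `participant` (message queued) and `rule_id`
#'   (`NA` if no rule matched).
#' @export
on_list_submitted <- function(participant, clock, config) {
  p <- participant
  stopifnot(inherits(config, "trial_config"))
  rel <- rel_day(p, clock)
  rule <- if (!is.na(rel) && rel < config$baseline_days &&
              p$items_week1 < config$run_in_min_items) {
    "runin_under_threshold"
  } else if (p$items_week1 >= config$run_in_min_items) {
    "list_sent_success"
  } else {
    NA_character_
  }
  if (!is.na(rule)) p <- queue_notification(p, rule, clock, "in-app")
  list(participant = p, rule_id = rule)
}

#' Mark a notification record as sent
#'
#' Sent records are never returned by [due_messages()] again; marking twice
#' is an idempotent no-op.
#'
#' @param participant A `trial_participant`.
#' @param rule_id,due_day,channel Record key (as returned by [due_messages()]).
#' @return The updated participant.
#' @export
mark_sent <- function(participant, rule_id, due_day, channel = "in-app") {
  p <- participant
  hit <- p$notifications$rule_id == rule_id & p$notifications$due_day == due_day
  if (any(hit)) {
    p$notifications$sent[hit] <- TRUE
  } else {
    p$notifications <- bind_rows(p$notifications, tibble(
      rule_id = rule_id, due_day = as.integer(due_day),
      channel = channel, sent = TRUE
    ))
  }
  p
}

#' Read and write message-rule tables
#'
#' The rule table round-trips through YAML/JSON so deployments can tune
#' schedules without code changes; a reloaded table is behaviourally
#' identical on any replay trace.
#'
#' @param rules A message-rule table.
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return `write_message_rules()` returns `path` invisibly;
#'   `read_message_rules()` returns the rule tibble.
#' @export
write_message_rules <- function(rules, path) {
  x <- lapply(seq_len(nrow(rules)), function(i) {
    r <- as.list(rules[i, ])
    r$offsets <- as.integer(r$offsets[[1]])
    r$repeat_cap <- if (is.infinite(r$repeat_cap)) "Inf" else r$repeat_cap
    r
  })
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_message_rules
#' @export
read_message_rules <- function(path) {
  if (!file.exists(path)) stop_io(paste0("cannot read message rules: ", path))
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  bind_rows(lapply(x, function(r) {
    tibble(rule_id = r$rule_id, trigger = r$trigger, anchor = r$anchor,
           offsets = list(as.integer(unlist(r$offsets))),
           monthly_after = isTRUE(r$monthly_after), channel = r$channel,
           repeat_cap = as.numeric(r$repeat_cap))
  }))
}
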