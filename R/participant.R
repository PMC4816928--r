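#' Participant lifecycle
#'
#' A participant moves through the automated trial as a state machine:
#'
#' `INSTALLED -> CONSENTED -> SCREENED_ELIGIBLE -> REGISTERED -> BASELINE ->
#' RANDOMIZED -> INTERVENTION -> FOLLOW_UP_DUE -> COMPLETED`
#'
#' with the terminal side-exits `SCREENED_INELIGIBLE` (failed first
#' eligibility check), `EXCLUDED_RUN_IN` (failed the week-1 run-in
#' requirement), and `WITHDRAWN` (allowed from any state). Every transition
#' is logged with its day; all days are whole 0-based day indices on the
#' participant's local calendar, with registration conventionally on day 0 so
#' that trial day indices count from registration.
#'
#' Identifiable information (the salted email fingerprint) is held on the
#' participant but never leaves through outcome exports.
#'
#' @name participant_lifecycle
NULL

PARTICIPANT_STATES <- c(
  "INSTALLED", "CONSENTED", "SCREENED_INELIGIBLE", "SCREENED_ELIGIBLE",
  "REGISTERED", "BASELINE", "EXCLUDED_RUN_IN", "RANDOMIZED", "INTERVENTION",
  "FOLLOW_UP_DUE", "COMPLETED", "WITHDRAWN"
)

# Hot per-scan/per-event stores are kept as parallel atomic vectors and only
# materialized into tibbles through the accessors below.
empty_items <- function() {
  list(barcode = character(), quantity = integer(), matched = logical())
}

empty_events <- function() {
  list(participant_id = character(), day = integer(), event = character(),
       arm = character(), stratum = character(), n_items = integer(),
       barcode = character(), detail = character())
}

empty_notifications <- function() {
  tibble(rule_id = character(), due_day = integer(), channel = character(),
         sent = logical())
}

#' Create a new participant
#'
#' @param id Participant id (the only key allowed into outcome exports).
#' @param day Day the app was first opened (default 0).
#' @return A `trial_participant` in state `INSTALLED`.
#' @export
new_participant <- function(id, day = 0L) {
  structure(
    list(
      id = as.character(id), state = "INSTALLED",
      clock = as.integer(day),
      consent_day = NA_integer_, registration_day = NA_integer_,
      randomization_day = NA_integer_,
      stratum_factors = NULL, stratum = NA_character_, arm = NA_character_,
      email_fp = NA_character_,
      items_week1 = 0L,
      questionnaires = list(),
      open_list = empty_items(),
      next_list_id = 1L,
      lists = tibble(list_id = character(), day = integer(),
                     n_items = integer(), receipt_ids = list()),
      list_items = tibble(list_id = character(), barcode = character(),
                          quantity = integer(), matched = logical()),
      last_list_day = NA_integer_,
      receipts = tibble(receipt_id = character(), day = integer(),
                        list_id = character()),
      label_views = list(barcode = character(), arm = character(),
                         day = integer()),
      crowdsource = tibble(barcode = character(), photos = integer(),
                           day = integer()),
      unmatched_barcodes = character(0),
      notifications = empty_notifications(),
      events = empty_events()
    ),
    class = "trial_participant"
  )
}

#' @export
print.trial_participant <- function(x, ...) {
  cat("<trial_participant> ", x$id, " [", x$state, "]",
      if (!is.na(x$arm)) paste0(" arm=", x$arm), " day=", x$clock,
      " week1_items=", x$items_week1, "\n", sep = "")
  invisible(x)
}

state_rank <- function(state) match(state, PARTICIPANT_STATES)

state_at_least <- function(participant, state) {
  state_rank(participant$state) >= state_rank(state) &&
    !participant$state %in% c("SCREENED_INELIGIBLE", "EXCLUDED_RUN_IN", "WITHDRAWN")
}

log_event <- function(p, day, event, arm = NA_character_,
                      stratum = NA_character_, n_items = NA_integer_,
                      barcode = NA_character_, detail = NA_character_) {
  e <- p$events
  e$participant_id <- c(e$participant_id, p$id)
  e$day <- c(e$day, as.integer(day))
  e$event <- c(e$event, event)
  e$arm <- c(e$arm, arm)
  e$stratum <- c(e$stratum, stratum)
  e$n_items <- c(e$n_items, as.integer(n_items))
  e$barcode <- c(e$barcode, barcode)
  e$detail <- c(e$detail, detail)
  p$events <- e
  p
}

#' Materialize a participant's stores as tibbles
#'
#' Event log, open shopping list, and label-view log accessors.
#'
#' @param participant A `trial_participant`.
#' @return A tibble.
#' @export
participant_events <- function(participant) {
  quick_tibble(
    participant_id = participant$events$participant_id,
    day = participant$events$day, event = participant$events$event,
    arm = participant$events$arm, stratum = participant$events$stratum,
    n_items = participant$events$n_items, barcode = participant$events$barcode,
    detail = participant$events$detail
  )
}

#' @rdname participant_events
#' @export
participant_open_list <- function(participant) {
  quick_tibble(barcode = participant$open_list$barcode,
               quantity = participant$open_list$quantity,
               matched = participant$open_list$matched)
}

#' @rdname participant_events
#' @export
participant_label_views <- function(participant) {
  quick_tibble(barcode = participant$label_views$barcode,
               arm = participant$label_views$arm,
               day = participant$label_views$day)
}

queue_notification <- function(p, rule_id, due_day, channel) {
  dup <- p$notifications$rule_id == rule_id & p$notifications$due_day == due_day
  if (any(dup)) return(p)  # (rule, participant, due day) is unique
  p$notifications <- bind_rows(p$notifications, tibble(
    rule_id = rule_id, due_day = as.integer(due_day),
    channel = channel, sent = FALSE
  ))
  p
}

#' Record informed consent
#'
#' Acceptance of both the consent statement and the terms and conditions is
#' mandatory; refusing either leaves the participant in `INSTALLED` with the
#' refusal logged. Repeated consent is an idempotent no-op.
#'
#' @param participant A `trial_participant` in state `INSTALLED`.
#' @param accepted_consent,accepted_tc Logical flags.
#' @param day Day of the action.
#' @return The updated participant.
#' @export
consent <- function(participant, accepted_consent, accepted_tc, day = 0L) {
  p <- participant
  if (p$state == "CONSENTED") return(p)  # idempotent
  if (p$state != "INSTALLED") {
    stop_state(paste0("consent requires state INSTALLED, not ", p$state))
  }
  if (!is_scalar_flag(accepted_consent) || !is_scalar_flag(accepted_tc)) {
    stop_arg("consent flags must be TRUE or FALSE")
  }
  if (accepted_consent && accepted_tc) {
    p$state <- "CONSENTED"
    p$consent_day <- as.integer(day)
    p <- log_event(p, day, "consented")
  } else {
    p <- log_event(p, day, "consent_refused")
  }
  p
}

#' First eligibility check (screening questionnaire)
#'
#' Applies the configured screening predicate to the questionnaire answers.
#' Eligible participants also have their stratification factor levels read
#' from the answers (for stratified profiles). Ineligible participants get
#' the one-off in-app message offering a link to the FoodSwitch app queued.
#' A re-submitted screening questionnaire is rejected: only one record per
#' kind is ever stored.
#'
#' @param participant A `trial_participant` in state `CONSENTED`.
#' @param answers Named list of screening answers (must include the
#'   stratification factor levels for stratified configurations).
#' @param config A [trial_config()].
#' @param day Day of the action.
#' @return The updated participant.
#' @export
screen <- function(participant, answers, config, day = 0L) {
  p <- participant
  stopifnot(inherits(config, "trial_config"))
  if (!is.null(p$questionnaires$screening)) {
    return(log_event(p, day, "duplicate_questionnaire_rejected",
                     detail = "screening"))
  }
  if (p$state != "CONSENTED") {
    stop_state(paste0("screening requires state CONSENTED, not ", p$state))
  }
  if (!is.list(answers) || length(answers) == 0) {
    stop_labelrct("screening answers are missing or incomplete",
                  "labelrct_screening_error")
  }
  p$questionnaires$screening <- list(answers = answers, day = as.integer(day))
  if (isTRUE(config$screening(answers))) {
    if (length(config$strat_factors) > 0) {
      p$stratum <- stratum_id(config, answers)
      p$stratum_factors <- answers[names(config$strat_factors)]
    } else {
      p$stratum <- "(all)"
    }
    p$state <- "SCREENED_ELIGIBLE"
    p <- log_event(p, day, "screened_eligible", stratum = p$stratum)
  } else {
    p$state <- "SCREENED_INELIGIBLE"
    p <- log_event(p, day, "screened_ineligible")
    p <- queue_notification(p, "ineligible_foodswitch_link", day, "in-app")
  }
  p
}

#' Register with a unique email address
#'
#' Registration requires an email address whose (case-insensitive, salted)
#' fingerprint is not already in the registry -- the duplicate-registration
#' check. On success the fingerprint is added to the registry and the
#' registration day anchors the trial timeline. A rejected attempt leaves
#' the participant in `SCREENED_ELIGIBLE`; retrying with a different email
#' is allowed and the failed attempt stays in the log.
#'
#' @param participant A `trial_participant` in state `SCREENED_ELIGIBLE`.
#' @param email Email address (stored only as a one-way fingerprint).
#' @param registry Character vector of already-registered fingerprints.
#' @param day Day of the action.
#' @return List with `participant`, `registry` (updated), and `ok`.
#' @export
register <- function(participant, email, registry = character(0), day = 0L) {
  p <- participant
  if (p$state != "SCREENED_ELIGIBLE") {
    stop_state(paste0("registration requires state SCREENED_ELIGIBLE, not ", p$state))
  }
  fp <- email_fingerprint(email)
  if (fp %in% registry) {
    p <- log_event(p, day, "registration_rejected_duplicate")
    return(list(participant = p, registry = registry, ok = FALSE))
  }
  p$email_fp <- fp
  p$registration_day <- as.integer(day)
  p$state <- "REGISTERED"
  p <- log_event(p, day, "registered")
  list(participant = p, registry = c(registry, fp), ok = TRUE)
}

#' Store a questionnaire record (screening/baseline/follow-up)
#'
#' At most one record per kind is ever stored; duplicate submissions collapse
#' to the earliest record, with the rejection logged. (Duplicate survey
#' copies were an observed field defect; collapsing at the engine prevents
#' them.)
#'
#' @param participant A `trial_participant`.
#' @param kind One of `"screening"`, `"baseline"`, `"follow_up"`.
#' @param answers Named list of answers.
#' @param day Day of the action.
#' @return The updated participant.
#' @export
submit_questionnaire <- function(participant, kind, answers, day = 0L) {
  p <- participant
  if (!kind %in% c("screening", "baseline", "follow_up")) {
    stop_arg("`kind` must be screening, baseline, or follow_up")
  }
  if (!is.null(p$questionnaires[[kind]])) {
    return(log_event(p, day, "duplicate_questionnaire_rejected", detail = kind))
  }
  p$questionnaires[[kind]] <- list(answers = answers, day = as.integer(day))
  log_event(p, day, "questionnaire_submitted", detail = kind)
}

#' Weeks completed on the trial (progress tracker)
#'
#' @param participant A registered `trial_participant`.
#' @param clock Current day index.
#' @return `floor(days since registration / 7)`, capped at 5.
#' @export
progress <- function(participant, clock) {
  if (!state_at_least(participant, "REGISTERED") || is.na(participant$registration_day)) {
    stop_state("progress tracking requires a registered participant")
  }
  min(5L, max(0L, (as.integer(clock) - participant$registration_day) %/% 7L))
}

#' Withdraw a participant
#'
#' Allowed from any non-terminal state.
#'
#' @param participant A `trial_participant`.
#' @param day Day of withdrawal.
#' @return The updated participant in state `WITHDRAWN`.
#' @export
withdraw <- function(participant, day) {
  p <- participant
  if (p$state %in% c("WITHDRAWN", "COMPLETED")) return(p)
  p$state <- "WITHDRAWN"
  log_event(p, day, "withdrawn")
}
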