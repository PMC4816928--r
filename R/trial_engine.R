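#' Timeline-driven event dispatch
#'
#' The trial timeline is checked from the moment of registration: the
#' baseline phase covers days 0..6 (week 1), randomization is due at the end
#' of week 1 (day 7) conditional on the run-in requirement, the intervention
#' phase covers days 7..34 (weeks 2-5), and the follow-up questionnaire is
#' requested at day 35. [advance_to()] replays every due event exactly once,
#' in order, no matter how coarsely the clock advances, so a participant who
#' reopens the app after a gap catches up deterministically.
#'
#' @name timeline
NULL

rel_day <- function(participant, clock) {
  as.integer(clock) - participant$registration_day
}

#' Second eligibility check: the week-1 run-in requirement
#'
#' Passes when at least `run_in_min_items` barcoded items were recorded on
#' lists submitted during week 1 (item quantities, not distinct barcodes).
#' The counting window is week 1 only; the grace window merely keeps the
#' decision open (e.g. for week-1 lists whose transmission is retried late)
#' before the participant is excluded.
#'
#' @param participant A `trial_participant` in `BASELINE`.
#' @param config A [trial_config()].
#' @param clock Current day index (must be at least `baseline_days` after
#'   registration).
#' @return List with `pass` and the updated `participant` (state
#'   `EXCLUDED_RUN_IN` once the grace window has elapsed without a pass).
#' @export
run_in_check <- function(participant, config, clock) {
  p <- participant
  stopifnot(inherits(config, "trial_config"))
  rel <- rel_day(p, clock)
  if (is.na(rel) || rel < config$baseline_days) {
    stop_state("run-in check is due only at the end of the baseline phase")
  }
  pass <- p$items_week1 >= config$run_in_min_items
  if (!pass && rel > config$baseline_days + config$run_in_grace_days &&
      p$state == "BASELINE") {
    p$state <- "EXCLUDED_RUN_IN"
    p <- log_event(p, p$registration_day + config$baseline_days +
                     config$run_in_grace_days, "excluded_run_in",
                   n_items = p$items_week1)
  }
  list(pass = pass, participant = p)
}

#' Advance a participant's clock, firing every due timeline event
#'
#' Fires, in order and exactly once each: baseline start (day 0, once the
#' baseline questionnaire is in), the run-in check at the end of week 1,
#' randomization (through the allocation state) if the run-in passed,
#' intervention start, and the follow-up request at the end of week 5.
#' Events that were due before `clock` are logged at their due day, not at
#' the observation day (catch-up contract). The clock may never move
#' backwards.
#'
#' @param participant A `trial_participant`, `REGISTERED` or beyond.
#' @param clock Current day index.
#' @param config A [trial_config()].
#' @param alloc An [allocation_state()] (required while randomization can
#'   still fire).
#' @return List with `participant` and `alloc` (both updated).
#' @export
advance_to <- function(participant, clock, config, alloc = NULL) {
  p <- participant
  stopifnot(inherits(config, "trial_config"))
  if (!state_at_least(p, "REGISTERED")) {
    if (p$state %in% c("EXCLUDED_RUN_IN", "WITHDRAWN", "SCREENED_INELIGIBLE")) {
      p$clock <- max(p$clock, as.integer(clock))
      return(list(participant = p, alloc = alloc))
    }
    stop_state("advance_to requires a registered participant")
  }
  clock <- as.integer(clock)
  if (clock < p$clock) {
    stop_state(paste0("clock may not move backwards (", p$clock,
                      " -> ", clock, ")"))
  }
  p$clock <- clock
  r <- p$registration_day
  repeat {
    before <- p$state
    # baseline starts on day 0 once the baseline questionnaire is in
    if (p$state == "REGISTERED" && !is.null(p$questionnaires$baseline) &&
        clock >= r) {
      p$state <- "BASELINE"
      p <- log_event(p, max(r, p$questionnaires$baseline$day),
                     "baseline_started")
    }
    # end of week 1: run-in check, then randomization
    if (p$state == "BASELINE" && clock >= r + config$baseline_days) {
      chk <- run_in_check(p, config, clock)
      p <- chk$participant
      if (chk$pass && p$state == "BASELINE") {
        if (is.null(alloc)) {
          stop_config("an allocation state is required to randomize")
        }
        due <- r + config$baseline_days
        a <- assign_arm(alloc, p$stratum, p$id)
        alloc <- a$state
        p$arm <- a$arm
        p$randomization_day <- due
        p$state <- "RANDOMIZED"
        p <- log_event(p, due, "randomized", arm = a$arm, stratum = p$stratum)
        p$state <- "INTERVENTION"
        p <- log_event(p, due, "intervention_started", arm = a$arm)
      }
    }
    # end of week 5: follow-up questionnaire request
    if (p$state == "INTERVENTION" &&
        clock >= r + config$baseline_days + config$intervention_days) {
      p$state <- "FOLLOW_UP_DUE"
      p <- log_event(p, r + config$baseline_days + config$intervention_days,
                     "followup_due")
    }
    if (p$state == before) break
  }
  list(participant = p, alloc = alloc)
}

#' Complete the follow-up questionnaire
#'
#' Finishes the trial: the participant moves to `COMPLETED` and the
#' completion message plus the end-of-trial FoodSwitch-link event are
#' queued. A second submission collapses to the stored record.
#'
#' @param participant A `trial_participant` in `FOLLOW_UP_DUE` (or already
#'   `COMPLETED`, in which case the duplicate is collapsed).
#' @param answers Named list of follow-up answers.
#' @param day Day of submission.
#' @return The updated participant.
#' @export
complete_followup <- function(participant, answers, day) {
  p <- participant
  if (p$state == "COMPLETED") {
    return(log_event(p, day, "duplicate_questionnaire_rejected",
                     detail = "follow_up"))
  }
  if (p$state != "FOLLOW_UP_DUE") {
    stop_state(paste0("follow-up completion requires state FOLLOW_UP_DUE, not ",
                      p$state))
  }
  p <- submit_questionnaire(p, "follow_up", answers, day)
  p$state <- "COMPLETED"
  p <- log_event(p, day, "completed")
  p <- queue_notification(p, "trial_completed", day, "in-app")
  p <- queue_notification(p, "foodswitch_link", day, "in-app")
  p
}
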