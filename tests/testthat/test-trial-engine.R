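nz <- trial_config_new_zealand()
au <- trial_config_australia()

eligible_answers <- list(eligible = TRUE, ethnicity = "other",
                         interest_healthy_eating = "low")

test_that("consent requires both the consent statement and the T&C", {
  p <- new_participant("P1")
  expect_equal(consent(p, TRUE, FALSE)$state, "INSTALLED")
  expect_equal(consent(p, FALSE, TRUE)$state, "INSTALLED")
  expect_equal(consent(p, TRUE, TRUE)$state, "CONSENTED")
})

test_that("repeated consent is an idempotent no-op", {
  p <- consent(new_participant("P1"), TRUE, TRUE)
  p2 <- consent(p, TRUE, TRUE)
  ev <- participant_events(p2)
  expect_equal(sum(ev$event == "consented"), 1)
  expect_equal(p2$state, "CONSENTED")
})

test_that("screening routes eligible and ineligible participants", {
  p <- consent(new_participant("P1"), TRUE, TRUE)
  ok <- screen(p, eligible_answers, nz)
  expect_equal(ok$state, "SCREENED_ELIGIBLE")
  expect_equal(ok$stratum, "other:low")
  bad <- screen(p, list(eligible = FALSE), au)
  expect_equal(bad$state, "SCREENED_INELIGIBLE")
  # the one-off ineligibility message with the FoodSwitch link is queued
  expect_equal(bad$notifications$rule_id, "ineligible_foodswitch_link")
})

test_that("a re-submitted screening questionnaire is rejected", {
  p <- screen(consent(new_participant("P1"), TRUE, TRUE), eligible_answers, nz)
  p2 <- screen(p, list(eligible = FALSE), nz)
  expect_equal(p2$state, "SCREENED_ELIGIBLE")  # unchanged
  ev <- participant_events(p2)
  expect_true("duplicate_questionnaire_rejected" %in% ev$event)
})

test_that("missing screening answers are a screening error", {
  p <- consent(new_participant("P1"), TRUE, TRUE)
  expect_error(screen(p, list(), nz), class = "labelrct_screening_error")
})

test_that("stratified screening requires valid factor levels", {
  p <- consent(new_participant("P1"), TRUE, TRUE)
  expect_error(screen(p, list(eligible = TRUE, ethnicity = "klingon",
                              interest_healthy_eating = "low"), nz),
               class = "labelrct_config_error")
})

test_that("registration rejects duplicate emails case-insensitively", {
  mk <- function(id) screen(consent(new_participant(id), TRUE, TRUE),
                            eligible_answers, nz)
  r1 <- register(mk("P1"), "User@Example.org", character(0))
  expect_true(r1$ok)
  expect_equal(r1$participant$state, "REGISTERED")
  r2 <- register(mk("P2"), "user@example.ORG", r1$registry)
  expect_false(r2$ok)
  expect_equal(r2$participant$state, "SCREENED_ELIGIBLE")
  # retry with a fresh email succeeds; the failed attempt stays logged
  r3 <- register(r2$participant, "other@example.org", r2$registry)
  expect_true(r3$ok)
  ev <- participant_events(r3$participant)
  expect_true("registration_rejected_duplicate" %in% ev$event)
  expect_length(r3$registry, 2)
})

test_that("a compliant participant fires the trial events in sequence", {
  res <- drive_participant("P1", to_day = 40)
  ev <- participant_events(res$participant)
  key <- ev$event[ev$event %in% c("consented", "screened_eligible",
                                  "registered", "baseline_started",
                                  "randomized", "intervention_started",
                                  "followup_due", "completed")]
  expect_equal(key, c("consented", "screened_eligible", "registered",
                      "baseline_started", "randomized",
                      "intervention_started", "followup_due", "completed"))
  expect_equal(ev$day[ev$event == "randomized"], 7)
  expect_equal(ev$day[ev$event == "followup_due"], 35)
  expect_equal(res$participant$state, "COMPLETED")
})

test_that("a coarse clock jump catches up every event once, in order", {
  cfg <- nz
  alloc <- allocation_state(cfg$arms, cfg$block_sizes, config_strata(cfg),
                            seed = 5)
  p <- new_participant("P1")
  p <- consent(p, TRUE, TRUE, 0)
  p <- screen(p, eligible_answers, cfg, 0)
  p <- register(p, "a@b.org", character(0), 0)$participant
  p <- submit_questionnaire(p, "baseline", list(), 0)
  # week-1 shopping on day 2, then silence until day 40
  p <- advance_to(p, 2, cfg, alloc)$participant
  for (j in 1:15) p <- scan(p, toy_db()$products$barcode[1], toy_db(), cfg, 2)$participant
  p <- submit_list(p, 2, cfg)$participant
  adv <- advance_to(p, 40, cfg, alloc)
  ev <- participant_events(adv$participant)
  expect_equal(sum(ev$event == "randomized"), 1)
  expect_equal(ev$day[ev$event == "randomized"], 7)
  expect_equal(sum(ev$event == "followup_due"), 1)
  expect_equal(ev$day[ev$event == "followup_due"], 35)
  expect_equal(adv$participant$state, "FOLLOW_UP_DUE")
})

test_that("reaching day 35 without the follow-up leaves state FOLLOW_UP_DUE", {
  res <- drive_participant("P1", to_day = 40, complete = FALSE)
  expect_equal(res$participant$state, "FOLLOW_UP_DUE")
})

test_that("the clock may not move backwards", {
  res <- drive_participant("P1", to_day = 10, complete = FALSE)
  expect_error(advance_to(res$participant, 5, nz, res$alloc),
               class = "labelrct_state_error")
})

test_that("the run-in threshold is 'at least 15 items' exactly", {
  mk <- function(items) {
    res <- drive_participant("P1", to_day = 6, items_per_day = 0,
                             complete = FALSE)
    p <- res$participant
    if (items > 0) {
      for (j in seq_len(items)) {
        p <- scan(p, toy_db()$products$barcode[1], toy_db(), nz, 3)$participant
      }
      p <- submit_list(p, 3, nz)$participant
    }
    p
  }
  p14 <- mk(14)
  chk <- run_in_check(p14, nz, 7)
  expect_false(chk$pass)
  expect_equal(chk$participant$state, "BASELINE")  # grace window still open
  p15 <- mk(15)
  expect_true(run_in_check(p15, nz, 7)$pass)
})

test_that("persistent run-in failure past the grace window excludes", {
  res <- drive_participant("P1", to_day = 6, items_per_day = 0, complete = FALSE)
  chk <- run_in_check(res$participant, nz, 7 + nz$run_in_grace_days + 1)
  expect_false(chk$pass)
  expect_equal(chk$participant$state, "EXCLUDED_RUN_IN")
  # and the timeline driver reaches the same outcome
  res2 <- drive_participant("P2", to_day = 20, items_per_day = 0,
                            complete = FALSE)
  expect_equal(res2$participant$state, "EXCLUDED_RUN_IN")
  expect_false("randomized" %in% participant_events(res2$participant)$event)
})

test_that("no participant is randomized below the threshold or before day 7", {
  res <- drive_participant("P1", to_day = 6, complete = FALSE)
  expect_equal(res$participant$state, "BASELINE")  # 35 items but day < 7
  expect_true(is.na(res$participant$arm))
  res2 <- drive_participant("P2", to_day = 7, items_per_day = 2,
                            complete = FALSE)
  expect_equal(res2$participant$items_week1, 14)
  expect_true(is.na(res2$participant$arm))  # under threshold at day 7
})

test_that("arm is set exactly at randomization and matches the allocation log", {
  res <- drive_participant("P1", to_day = 10, complete = FALSE)
  p <- res$participant
  expect_equal(p$state, "INTERVENTION")
  expect_false(is.na(p$arm))
  expect_equal(res$alloc$log$arm[res$alloc$log$participant_id == "P1"], p$arm)
  expect_equal(res$alloc$log$stratum[1], p$stratum)
})

test_that("duplicate follow-up submissions collapse to one record", {
  res <- drive_participant("P1", to_day = 35, complete = FALSE)
  p <- complete_followup(res$participant, list(a = 1), 36)
  expect_equal(p$state, "COMPLETED")
  p2 <- complete_followup(p, list(a = 2), 37)
  expect_equal(p2$questionnaires$follow_up$answers, list(a = 1))
  ev <- participant_events(p2)
  expect_equal(sum(ev$event == "completed"), 1)
  expect_true("duplicate_questionnaire_rejected" %in% ev$event)
})

test_that("follow-up submission before it is due is a state error", {
  res <- drive_participant("P1", to_day = 20, complete = FALSE)
  expect_equal(res$participant$state, "INTERVENTION")
  expect_error(complete_followup(res$participant, list(), 20),
               class = "labelrct_state_error")
})

test_that("the progress tracker floors at weeks and caps at 5", {
  res <- drive_participant("P1", to_day = 3, complete = FALSE)
  p <- res$participant
  expect_equal(progress(p, 0), 0)
  expect_equal(progress(p, 13), 1)
  expect_equal(progress(p, 35), 5)
  expect_equal(progress(p, 70), 5)
})

test_that("every trace is a prefix of the canonical sequence", {
  canonical <- c("INSTALLED", "CONSENTED", "SCREENED_ELIGIBLE", "REGISTERED",
                 "BASELINE", "RANDOMIZED", "INTERVENTION", "FOLLOW_UP_DUE",
                 "COMPLETED")
  co <- simulate_cohort(30, nz, behavior_model(), seed = 21)
  event_to_state <- c(consented = "CONSENTED",
                      screened_eligible = "SCREENED_ELIGIBLE",
                      registered = "REGISTERED", baseline_started = "BASELINE",
                      randomized = "RANDOMIZED",
                      intervention_started = "INTERVENTION",
                      followup_due = "FOLLOW_UP_DUE", completed = "COMPLETED")
  for (p in co$participants) {
    ev <- participant_events(p)
    states <- c("INSTALLED", unname(event_to_state[ev$event]))
    states <- states[!is.na(states)]
    expect_equal(states, canonical[seq_along(states)])
  }
})

test_that("withdrawal is allowed from any active state and is terminal", {
  res <- drive_participant("P1", to_day = 10, complete = FALSE)
  p <- withdraw(res$participant, 11)
  expect_equal(p$state, "WITHDRAWN")
  expect_equal(withdraw(p, 12)$state, "WITHDRAWN")
  expect_equal(sum(participant_events(withdraw(p, 12))$event == "withdrawn"), 1)
})
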