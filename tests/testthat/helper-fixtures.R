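# Small handmade fixtures, built in code at test time.

toy_products <- function() {
  tibble::tibble(
    barcode = c("9300601234561", "9300609876541", "40170725", "9415007701231"),
    name = c("wholegrain crackers", "choc biscuit", "oat bar", "fizzy drink"),
    category_id = c("snacks", "snacks", "snacks", "drinks"),
    is_beverage = c(FALSE, FALSE, FALSE, TRUE),
    serving_size = c(25, 30, 40, 250),
    energy_kj_100 = c(1800, 2200, 1600, 180),
    protein_g_100 = c(9, 5, 8, 0),
    fat_g_100 = c(12, 25, 10, 0),
    satfat_g_100 = c(2, 12, 1.5, 0),
    carb_g_100 = c(60, 62, 55, 10.5),
    sugars_g_100 = c(3, 35, 18, 10.5),
    fibre_g_100 = c(8, 2, 6, 0),
    sodium_mg_100 = c(450, 300, 120, 15),
    fvnl_pct = c(10, 0, 45, 0)
  )
}

toy_db <- function(products = toy_products()) as_food_db(products)

write_toy_csv <- function(products = toy_products(), path = tempfile(fileext = ".csv")) {
  utils::write.csv(products, path, row.names = FALSE, na = "")
  path
}

# A product record as a plain list, for scalar label calls.
flat_product <- function(...) {
  p <- list(
    barcode = "9300601234567", name = "test", category_id = "snacks",
    is_beverage = FALSE, serving_size = 100, energy_kj_100 = 0,
    protein_g_100 = 0, fat_g_100 = 0, satfat_g_100 = 0, carb_g_100 = 0,
    sugars_g_100 = 0, fibre_g_100 = 0, sodium_mg_100 = 0, fvnl_pct = 0
  )
  utils::modifyList(p, list(...))
}

# Scripted trace driver: advances day by day over a day grid, performing
# scripted list submissions, and collects every message the rule engine
# delivers. `lists` maps day -> item count; `followup_day` optionally
# completes the follow-up questionnaire.
run_trace <- function(register_day = 0, baseline_q = TRUE, lists = list(),
                      followup_day = NA, eligible = TRUE, registered = TRUE,
                      days = 0:70, rules = default_message_rules(),
                      cfg = trial_config_new_zealand()) {
  alloc <- allocation_state(cfg$arms, cfg$block_sizes, config_strata(cfg),
                            seed = 17)
  db <- toy_db()
  p <- consent(new_participant("P1"), TRUE, TRUE, day = 0)
  p <- screen(p, list(eligible = eligible, ethnicity = "maori",
                      interest_healthy_eating = "low"), cfg, day = 0)
  if (eligible && registered) {
    p <- register(p, "p1@example.org", character(0), day = register_day)$participant
    if (baseline_q) p <- submit_questionnaire(p, "baseline", list(), register_day)
  }
  got <- list()
  for (day in days) {
    if (p$state %in% c("REGISTERED", "BASELINE", "RANDOMIZED", "INTERVENTION",
                       "FOLLOW_UP_DUE")) {
      adv <- advance_to(p, day, cfg, alloc)
      p <- adv$participant
      alloc <- adv$alloc
    }
    n_items <- lists[[as.character(day)]]
    if (!is.null(n_items) && p$state %in% c("BASELINE", "INTERVENTION")) {
      for (j in seq_len(n_items)) {
        p <- scan(p, db$products$barcode[1], db, cfg, day,
                  rng = rng_stream(day * 10 + j))$participant
      }
      p <- submit_list(p, day, cfg)$participant
    }
    if (!is.na(followup_day) && day == followup_day &&
        p$state == "FOLLOW_UP_DUE") {
      p <- complete_followup(p, list(), day)
    }
    msgs <- due_messages(p, day, cfg, rules)
    for (m in seq_len(nrow(msgs))) {
      p <- mark_sent(p, msgs$rule_id[m], msgs$due_day[m], msgs$channel[m])
      got[[length(got) + 1]] <- list(day = day, rule = msgs$rule_id[m],
                                     channel = msgs$channel[m])
    }
  }
  list(messages = dplyr::bind_rows(got), participant = p)
}

msg_key <- function(tab) {
  if (nrow(tab) == 0) return(character(0))
  sort(paste(tab$day, tab$rule))
}

# Drive one participant from install to any target day with full compliance:
# daily 5-item shopping trips during the data-collection weeks.
drive_participant <- function(id = "P0001", config = trial_config_new_zealand(),
                              db = toy_db(), to_day = 40,
                              alloc = allocation_state(config$arms,
                                                       config$block_sizes,
                                                       config_strata(config),
                                                       seed = 99),
                              items_per_day = 5, complete = TRUE) {
  p <- new_participant(id)
  p <- consent(p, TRUE, TRUE, day = 0)
  answers <- list(eligible = TRUE, ethnicity = "maori",
                  interest_healthy_eating = "high")
  p <- screen(p, answers, config, day = 0)
  reg <- register(p, paste0(id, "@example.org"), character(0), day = 0)
  p <- submit_questionnaire(reg$participant, "baseline", list(ok = TRUE), day = 0)
  for (day in 0:to_day) {
    adv <- advance_to(p, day, config, alloc)
    p <- adv$participant
    alloc <- adv$alloc
    rel <- day - p$registration_day
    if (p$state %in% c("BASELINE", "INTERVENTION") && rel < 35 && items_per_day > 0) {
      for (j in seq_len(items_per_day)) {
        sc <- scan(p, db$products$barcode[1 + (j %% nrow(db$products))],
                   db, config, day, rng = rng_stream(day * 100 + j))
        p <- sc$participant
      }
      p <- submit_list(p, day, config)$participant
    }
    if (complete && p$state == "FOLLOW_UP_DUE") {
      p <- complete_followup(p, list(ok = TRUE), day)
    }
  }
  list(participant = p, alloc = alloc)
}
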