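cfg <- trial_config_new_zealand()

test_that("week-1 scans build the list without delivering a label", {
  res <- drive_participant("P1", to_day = 2, items_per_day = 0, complete = FALSE)
  db <- toy_db()
  sc <- scan(res$participant, db$products$barcode[1], db, cfg, 2)
  expect_true(sc$matched)
  expect_null(sc$label)
  expect_equal(nrow(participant_open_list(sc$participant)), 1)
  expect_equal(length(sc$participant$label_views$barcode), 0)
})

test_that("intervention-phase scans deliver the allocated label plus related products", {
  db <- as_food_db(simulate_food_db(40, n_categories = 2, seed = 8))
  res <- drive_participant("P1", db = db, to_day = 14, complete = FALSE)
  p <- res$participant
  expect_equal(p$state, "INTERVENTION")
  code <- db$products$barcode[7]
  sc <- scan(p, code, db, cfg, 14, rng = rng_stream(5))
  expect_equal(sc$label$arm, p$arm)
  expect_equal(sc$label$barcode, code)
  expect_true(nrow(sc$related) <= 4)
  expect_false(code %in% sc$related$barcode)
  views <- participant_label_views(sc$participant)
  expect_equal(views$barcode[nrow(views)], code)
  expect_equal(views$arm[nrow(views)], p$arm)
})

test_that("an unmatched scan offers crowdsourcing and logs no label view", {
  res <- drive_participant("P1", to_day = 14, complete = FALSE)
  before <- length(res$participant$label_views$barcode)
  sc <- scan(res$participant, "11111111", toy_db(), cfg, 14)
  expect_false(sc$matched)
  expect_true(is_not_found(sc$product))
  expect_true(sc$crowdsource_offered)
  expect_null(sc$label)
  expect_equal(length(sc$participant$label_views$barcode), before)
  p <- submit_crowdsource(sc$participant, "11111111", 14, photos = 2)
  expect_equal(p$crowdsource$barcode, "11111111")
})

test_that("crowdsourcing requires a barcode that failed to match", {
  res <- drive_participant("P1", to_day = 14, complete = FALSE)
  expect_error(submit_crowdsource(res$participant, toy_db()$products$barcode[1], 14),
               class = "labelrct_state_error")
})

test_that("scanning before the baseline phase is a state error", {
  p <- consent(new_participant("P1"), TRUE, TRUE, 0)
  expect_error(scan(p, "12345678", toy_db(), cfg, 0),
               class = "labelrct_state_error")
})

test_that("list submission updates history, counters, and fires the list rules", {
  res <- drive_participant("P1", to_day = 1, items_per_day = 0, complete = FALSE)
  p <- res$participant
  db <- toy_db()
  for (j in 1:5) p <- scan(p, db$products$barcode[1 + j %% 4], db, cfg, 1)$participant
  sub <- submit_list(p, 1, cfg)
  expect_true(sub$ok)
  p <- sub$participant
  expect_equal(nrow(p$lists), 1)
  expect_equal(p$items_week1, 5)
  expect_equal(sub$message_rule, "runin_under_threshold")
  expect_equal(nrow(participant_open_list(p)), 0)
})

test_that("quantities count toward the run-in total, not distinct barcodes", {
  res <- drive_participant("P1", to_day = 1, items_per_day = 0, complete = FALSE)
  p <- res$participant
  db <- toy_db()
  p <- scan(p, db$products$barcode[1], db, cfg, 1, quantity = 15)$participant
  p <- submit_list(p, 1, cfg)$participant
  expect_equal(p$items_week1, 15)
  expect_true(run_in_check(p, cfg, 7)$pass)
})

test_that("a failed transmission keeps the list for a single retried history entry", {
  res <- drive_participant("P1", to_day = 1, items_per_day = 0, complete = FALSE)
  p <- res$participant
  db <- toy_db()
  for (j in 1:3) p <- scan(p, db$products$barcode[1], db, cfg, 1)$participant
  fail <- submit_list(p, 1, cfg, transmit_ok = FALSE)
  expect_false(fail$ok)
  p <- fail$participant
  expect_equal(nrow(p$lists), 0)
  expect_equal(nrow(participant_open_list(p)), 3)
  retry <- submit_list(p, 2, cfg)
  expect_true(retry$ok)
  expect_equal(nrow(retry$participant$lists), 1)
  expect_true("list_transmit_failed" %in% participant_events(retry$participant)$event)
})

test_that("submitting an empty list is rejected", {
  res <- drive_participant("P1", to_day = 1, items_per_day = 0, complete = FALSE)
  expect_error(submit_list(res$participant, 1, cfg),
               class = "labelrct_arg_error")
})

test_that("receipts must link to an existing transmitted list", {
  res <- drive_participant("P1", to_day = 3, complete = FALSE)
  p <- res$participant
  list_id <- p$lists$list_id[1]
  p <- add_receipt(p, list_id, 3)
  expect_equal(p$receipts$list_id, list_id)
  expect_equal(p$lists$receipt_ids[[1]], p$receipts$receipt_id)
  expect_error(add_receipt(p, "nope", 3), class = "labelrct_state_error")
})

test_that("week-1 item counter equals the sum over week-1 submitted lists", {
  co <- simulate_cohort(25, cfg, behavior_model(), seed = 12)
  for (p in co$participants) {
    wk1 <- p$lists$n_items[p$lists$day - p$registration_day < cfg$baseline_days]
    if (!is.na(p$registration_day)) {
      expect_equal(p$items_week1, sum(wk1))
    }
  }
})

test_that("label views occur only post-randomization, matched, in the own arm", {
  co <- simulate_cohort(25, cfg, behavior_model(), seed = 13)
  for (p in co$participants) {
    lv <- participant_label_views(p)
    if (nrow(lv) == 0) next
    expect_true(all(lv$arm == p$arm))
    expect_true(all(lv$day >= p$randomization_day))
    expect_true(all(lv$barcode %in% co$db$products$barcode))
  }
})

test_that("every crowdsource submission corresponds to an unmatched scan", {
  co <- simulate_cohort(25, cfg,
                        behavior_model(unmatched_prob = 0.3,
                                       crowdsource_prob = 1),
                        seed = 14)
  for (p in co$participants) {
    expect_true(all(p$crowdsource$barcode %in% p$unmatched_barcodes))
    expect_true(all(!p$crowdsource$barcode %in% co$db$products$barcode))
  }
})

test_that("outcome exports carry participant ids only and are deterministic", {
  co <- simulate_cohort(15, cfg, behavior_model(), seed = 15)
  out1 <- export_outcomes(co)
  out2 <- export_outcomes(co)
  expect_equal(out1, out2)
  expect_named(out1, c("lists", "items", "receipts", "label_views", "crowdsource"))
  for (tab in out1) {
    expect_false(any(grepl("email|name|address", names(tab))))
    expect_true("participant_id" %in% names(tab))
  }
  # items rows = sum of per-list items rows
  expect_equal(sum(out1$items$quantity),
               sum(out1$lists$n_items))
  # CSV export round-trips byte-identically
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_outcomes(co, "csv", dir = d1)
  export_outcomes(co, "csv", dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("an unknown export format is a format error", {
  co <- simulate_cohort(3, cfg, behavior_model_compliant(), seed = 16)
  expect_error(export_outcomes(co, "parquet"), class = "labelrct_format_error")
})
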