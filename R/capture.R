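#' Shopping-data capture and intervention delivery
#'
#' The app runs two modes over the same barcode scanner. Data collection
#' (weeks 1-5) appends every scan to the participant's open electronic list,
#' which is transmitted to the trial database on submission. Intervention
#' delivery (weeks 2-5, post-randomization) additionally returns the
#' nutrition label for the participant's allocated arm -- plus a random
#' selection of same-category products -- for every recognized barcode, and
#' logs a label-view event. An unrecognized barcode is a normal outcome that
#' offers the crowdsourcing path instead.
#'
#' @name capture
NULL

#' Scan a barcode
#'
#' @param participant A `trial_participant` in `BASELINE` or `INTERVENTION`
#'   (or `FOLLOW_UP_DUE`, still within the 5 data-collection weeks).
#' @param barcode Digit string from the scanner.
#' @param db A [read_food_db()] database.
#' @param config A [trial_config()].
#' @param clock Day of the scan.
#' @param quantity Item quantity recorded with the scan (default 1).
#' @param rng An [rng_stream()] (or seed) for the related-products draw.
#' @return List with `participant` (open list, view log, unmatched register
#'   updated), `matched`, `product` (or not-found marker), `label` (a
#'   `nutrition_label` in intervention mode, else `NULL`), `related` (tibble
#'   or `NULL`), `crowdsource_offered`, and `stream` (advanced rng).
#' @export
scan <- function(participant, barcode, db, config, clock,
                 quantity = 1L, rng = rng_stream(1)) {
  p <- participant
  stopifnot(inherits(db, "food_db"), inherits(config, "trial_config"))
  if (!p$state %in% c("BASELINE", "RANDOMIZED", "INTERVENTION", "FOLLOW_UP_DUE")) {
    stop_state(paste0("scanning requires the baseline or intervention phase, not ",
                      p$state))
  }
  if (quantity < 1) stop_arg("`quantity` must be >= 1")
  if (is.numeric(rng)) rng <- rng_stream(rng)
  hit <- match_barcode(db, barcode)
  matched <- !is_not_found(hit)

  # data collection: every scan appends to the one open list
  p$open_list$barcode <- c(p$open_list$barcode, barcode)
  p$open_list$quantity <- c(p$open_list$quantity, as.integer(quantity))
  p$open_list$matched <- c(p$open_list$matched, matched)

  label <- NULL
  related <- NULL
  crowdsource_offered <- FALSE
  intervention_mode <- p$state == "INTERVENTION" && !is.na(p$arm)
  if (intervention_mode && matched) {
    label <- label_for(hit, p$arm, config)
    related <- related_products(db, hit, n = 4, rng = rng)
    rng <- attr(related, "stream")
    p$label_views$barcode <- c(p$label_views$barcode, barcode)
    p$label_views$arm <- c(p$label_views$arm, p$arm)
    p$label_views$day <- c(p$label_views$day, as.integer(clock))
    p <- log_event(p, clock, "label_view", arm = p$arm, barcode = barcode)
  } else if (!matched) {
    crowdsource_offered <- TRUE
    p$unmatched_barcodes <- union(p$unmatched_barcodes, barcode)
  }
  list(participant = p, matched = matched, product = hit, label = label,
       related = related, crowdsource_offered = crowdsource_offered,
       stream = rng)
}

#' Submit a crowdsource record for an unrecognized product
#'
#' Only barcodes that previously failed to match at scan time can be
#' submitted; photos are stored as a count (metadata only).
#'
#' @param participant A `trial_participant`.
#' @param barcode The unmatched barcode.
#' @param clock Day of submission.
#' @param photos Number of photos attached (>= 1).
#' @return The updated participant.
#' @export
submit_crowdsource <- function(participant, barcode, clock, photos = 1L) {
  p <- participant
  if (!barcode %in% p$unmatched_barcodes) {
    stop_state("crowdsource submissions require a barcode that failed to match at scan time")
  }
  if (photos < 1) stop_arg("`photos` must be >= 1")
  p$crowdsource <- bind_rows(p$crowdsource, tibble(
    barcode = barcode, photos = as.integer(photos), day = as.integer(clock)
  ))
  log_event(p, clock, "crowdsource_submitted", barcode = barcode)
}

#' Transmit the open shopping list
#'
#' On successful transmission the list joins the participant's history, the
#' week-1 item counter is updated (sum of item quantities on lists submitted
#' during week 1 -- the single source of truth for the run-in check), and the
#' list-submission notification rules react. A failed transmission keeps the
#' open list intact for retry, so a retried list lands in the history exactly
#' once.
#'
#' @param participant A `trial_participant` with a non-empty open list.
#' @param clock Day of submission.
#' @param config A [trial_config()].
#' @param transmit_ok Simulated transport success flag.
#' @return List with `participant`, `ok`, `list_id` (`NA` on failure), and
#'   `message_rule` fired by the submission (possibly `NA`).
#' @export
submit_list <- function(participant, clock, config, transmit_ok = TRUE) {
  p <- participant
  stopifnot(inherits(config, "trial_config"))
  if (length(p$open_list$barcode) == 0) {
    stop_arg("the open list is empty; scan items first")
  }
  if (!isTRUE(transmit_ok)) {
    p <- log_event(p, clock, "list_transmit_failed")
    return(list(participant = p, ok = FALSE, list_id = NA_character_,
                message_rule = NA_character_))
  }
  list_id <- sprintf("%s-L%03d", p$id, p$next_list_id)
  p$next_list_id <- p$next_list_id + 1L
  n_items <- sum(p$open_list$quantity)
  p$lists <- bind_rows(p$lists, quick_tibble(
    list_id = list_id, day = as.integer(clock), n_items = as.integer(n_items),
    receipt_ids = list(character(0))
  ))
  p$list_items <- bind_rows(p$list_items, quick_tibble(
    list_id = rep(list_id, length(p$open_list$barcode)),
    barcode = p$open_list$barcode, quantity = p$open_list$quantity,
    matched = p$open_list$matched
  ))
  p$open_list <- empty_items()
  p$last_list_day <- as.integer(clock)
  rel <- rel_day(p, clock)
  if (!is.na(rel) && rel >= 0 && rel < config$baseline_days) {
    p$items_week1 <- p$items_week1 + as.integer(n_items)
  }
  p <- log_event(p, clock, "list_submitted", n_items = n_items, detail = list_id)
  msg <- on_list_submitted(p, clock, config)
  list(participant = msg$participant, ok = TRUE, list_id = list_id,
       message_rule = msg$rule_id)
}

#' Capture a till-receipt photo (metadata only)
#'
#' @param participant A `trial_participant`.
#' @param list_id The transmitted list the receipt belongs to.
#' @param clock Day of capture.
#' @return The updated participant.
#' @export
add_receipt <- function(participant, list_id, clock) {
  p <- participant
  i <- match(list_id, p$lists$list_id)
  if (is.na(i)) stop_state(paste0("receipt links to an unknown list: ", list_id))
  receipt_id <- sprintf("%s-R%03d", p$id, nrow(p$receipts) + 1L)
  p$receipts <- bind_rows(p$receipts, tibble(
    receipt_id = receipt_id, day = as.integer(clock), list_id = list_id
  ))
  p$lists$receipt_ids[[i]] <- c(p$lists$receipt_ids[[i]], receipt_id)
  log_event(p, clock, "receipt_captured", detail = list_id)
}

#' Export the outcome dataset
#'
#' Five per-stream tables -- lists, items, receipts (metadata), label views,
#' crowdsource submissions -- keyed by participant id only. No email
#' fingerprints or free-text identity fields ever reach an export:
#' identifiable information is stored separately from trial outcome data.
#' Row ordering is stable (participant id, then day/list id), so repeated
#' exports are identical.
#'
#' @param cohort A `trial_cohort` (see [simulate_cohort()]) or plain list of
#'   `trial_participant`s.
#' @param format `"tibble"` (return the tables) or `"csv"` (also write
#'   `lists.csv`, `items.csv`, `receipts.csv`, `label_views.csv`,
#'   `crowdsource.csv` under `dir`).
#' @param dir Output directory for `format = "csv"`.
#' @return Named list of tibbles, invisibly for `format = "csv"`.
#' @export
export_outcomes <- function(cohort, format = c("tibble", "csv"), dir = NULL) {
  if (!is.character(format) || !format[1] %in% c("tibble", "csv")) {
    stop_format(paste0("unknown export format: ", format[1]))
  }
  format <- format[1]
  participants <- if (inherits(cohort, "trial_cohort")) cohort$participants else cohort
  pull <- function(get) {
    rows <- lapply(participants, function(p) {
      tab <- get(p)
      if (nrow(tab) == 0) return(NULL)
      mutate(tab, participant_id = p$id, .before = 1)
    })
    bind_rows(rows)
  }
  lists <- pull(function(p) select(p$lists, "list_id", "day", "n_items"))
  items <- pull(function(p) p$list_items)
  receipts <- pull(function(p) p$receipts)
  label_views <- pull(function(p) participant_label_views(p))
  crowdsource <- pull(function(p) p$crowdsource)
  sort_by <- function(tab, cols) {
    if (nrow(tab) == 0) return(tab)
    tab[do.call(order, unname(as.list(tab[, cols]))), , drop = FALSE]
  }
  out <- list(
    lists = sort_by(lists, c("participant_id", "list_id")),
    items = sort_by(items, c("participant_id", "list_id", "barcode")),
    receipts = sort_by(receipts, c("participant_id", "receipt_id")),
    label_views = sort_by(label_views, c("participant_id", "day", "barcode")),
    crowdsource = sort_by(crowdsource, c("participant_id", "day", "barcode"))
  )
  banned <- c("email", "email_fp", "name", "address")
  for (nm in names(out)) {
    if (any(banned %in% names(out[[nm]]))) {
      stop_format("outcome exports must not contain identity fields")
    }
  }
  if (format == "csv") {
    if (is.null(dir)) stop_arg("`dir` is required for CSV export")
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(out))
  }
  out
}
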