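#' Nutrition-label engine
#'
#' Computes the five label formats delivered in the trials from a product
#' record and the configurable scheme tables: Daily Intake Guide (`DIG`),
#' Traffic Lights (`TLL`), Health Star Rating (`HSR`), Nutrition Information
#' Panel (`NIP`, the non-interpretive control), and the Warning Label
#' (`WARNING`, Australian arms only).
#'
#' @name label_engine
NULL

new_label <- function(arm, payload, barcode) {
  structure(list(arm = arm, barcode = barcode, payload = payload),
            class = "nutrition_label")
}

#' @export
print.nutrition_label <- function(x, ...) {
  cat("<nutrition_label> arm=", x$arm, " barcode=", x$barcode, "\n", sep = "")
  print(x$payload)
  invisible(x)
}

require_nutrient <- function(product, col, label) {
  v <- product[[col]]
  if (is.null(v) || is.na(v)) {
    stop_label(paste0(label, " label requires nutrient ", col,
                      " for barcode ", product$barcode))
  }
  as.numeric(v)
}

# round half up to one decimal (display convention; R's round() is half-even)
round1_half_up <- function(x) floor(x * 10 + 0.5) / 10

#' Traffic-light label
#'
#' Colours fat, saturated fat, sugars, and sodium GREEN/AMBER/RED by the
#' per-100 g/mL cutoffs: GREEN at or below `low`, AMBER above `low` up to
#' `high`, RED above `high`. Food or beverage cutoffs are selected by the
#' product's `is_beverage` flag.
#'
#' @param product A product record (one-row tibble or named list).
#' @param thresholds A [tl_thresholds()] object.
#' @return A `nutrition_label` with arm `TLL`; payload is a tibble
#'   `nutrient`, `per_100`, `colour`.
#' @export
traffic_light <- function(product, thresholds = tl_thresholds()) {
  product <- as_product_row(product)
  stopifnot(inherits(thresholds, "tl_thresholds"))
  tab <- if (isTRUE(product$is_beverage)) thresholds$beverage else thresholds$food
  amounts <- map_dbl(names(TL_NUTRIENTS), function(nu) {
    require_nutrient(product, TL_NUTRIENTS[[nu]], "traffic-light")
  })
  i <- match(names(TL_NUTRIENTS), tab$nutrient)
  colour <- ifelse(amounts <= tab$low[i], "GREEN",
                   ifelse(amounts <= tab$high[i], "AMBER", "RED"))
  new_label("TLL", quick_tibble(nutrient = names(TL_NUTRIENTS),
                                per_100 = amounts, colour = colour),
            product$barcode)
}

DI_COMPONENTS <- c(energy_kj = "energy_kj_100", fat_g = "fat_g_100",
                   satfat_g = "satfat_g_100", sugars_g = "sugars_g_100",
                   sodium_mg = "sodium_mg_100")

#' Daily Intake Guide label
#'
#' Expresses the per-serving amount of each labelled component as a
#' percentage of its reference daily intake, rounded half-up to one decimal
#' place. The payload also carries the absolute per-serving amounts.
#'
#' @param product A product record.
#' @param refs A [di_references()] object.
#' @return A `nutrition_label` with arm `DIG`; payload is a tibble
#'   `component`, `per_serving`, `reference`, `pct_di`.
#' @export
daily_intake <- function(product, refs = di_references()) {
  product <- as_product_row(product)
  stopifnot(inherits(refs, "di_references"))
  if (is.null(product$serving_size) || product$serving_size <= 0) {
    stop_label("daily-intake label requires serving_size > 0")
  }
  per100 <- map_dbl(names(DI_COMPONENTS), function(comp) {
    require_nutrient(product, DI_COMPONENTS[[comp]], "daily-intake")
  })
  serv <- per100 * product$serving_size / 100
  ref <- map_dbl(names(DI_COMPONENTS), function(comp) refs[[comp]])
  new_label("DIG", quick_tibble(component = names(DI_COMPONENTS),
                                per_serving = serv, reference = ref,
                                pct_di = round1_half_up(serv / ref * 100)),
            product$barcode)
}

#' Health Star Rating label
#'
#' Scores the product with baseline points (energy, saturated fat, total
#' sugars, sodium; risk-increasing) minus modifying points (fruit/veg/nut/
#' legume content, protein, fibre; risk-decreasing), then maps the final
#' score to a star value in 0.5-5.0 via the configured monotone star map.
#' Missing optional components (`fvnl_pct`, `fibre_g_100`) contribute zero
#' modifying points.
#'
#' @param product A product record.
#' @param tables An [hsr_tables()] object.
#' @return A `nutrition_label` with arm `HSR`; payload carries the star
#'   value, final score, and the per-component point breakdown.
#' @export
health_star <- function(product, tables = hsr_tables()) {
  product <- as_product_row(product)
  stopifnot(inherits(tables, "hsr_tables"))
  bev <- isTRUE(product$is_beverage)
  baseline <- if (bev) tables$baseline_beverage else tables$baseline_food
  star_map <- if (bev) tables$star_map_beverage else tables$star_map_food

  base_vals <- c(
    energy = require_nutrient(product, "energy_kj_100", "health-star"),
    satfat = require_nutrient(product, "satfat_g_100", "health-star"),
    sugars = require_nutrient(product, "sugars_g_100", "health-star"),
    sodium = require_nutrient(product, "sodium_mg_100", "health-star")
  )
  mod_vals <- c(
    fvnl = as.numeric(product$fvnl_pct %||% NA_real_),
    protein = require_nutrient(product, "protein_g_100", "health-star"),
    fibre = as.numeric(product$fibre_g_100 %||% NA_real_)
  )
  base_pts <- map_int(names(base_vals),
                      function(k) band_points(base_vals[[k]], baseline[[k]]))
  mod_pts <- map_int(names(mod_vals),
                     function(k) band_points(mod_vals[[k]], tables$modifying[[k]]))
  score <- sum(base_pts) - sum(mod_pts)
  stars <- star_map$stars[match(TRUE, score <= star_map$max_score)]
  payload <- list(
    stars = stars,
    final_score = score,
    baseline_points = setNames(base_pts, names(base_vals)),
    modifying_points = setNames(mod_pts, names(mod_vals))
  )
  new_label("HSR", payload, product$barcode)
}

NIP_ROWS <- c(energy_kj = "energy_kj_100", protein_g = "protein_g_100",
              fat_g = "fat_g_100", satfat_g = "satfat_g_100",
              carb_g = "carb_g_100", sugars_g = "sugars_g_100",
              sodium_mg = "sodium_mg_100")

#' Nutrition Information Panel (control label)
#'
#' The mandatory back-of-pack declaration: seven nutrient rows, each per
#' 100 g/mL and per serving, with no interpretive element at all (no colours,
#' stars, percentages, or warnings) -- the trials' control arm.
#'
#' @param product A product record.
#' @return A `nutrition_label` with arm `NIP`; payload is a 7-row tibble
#'   `nutrient`, `per_100`, `per_serving`.
#' @export
nip <- function(product) {
  product <- as_product_row(product)
  per100 <- map_dbl(names(NIP_ROWS), function(nu) {
    require_nutrient(product, NIP_ROWS[[nu]], "nutrition-panel")
  })
  new_label("NIP", quick_tibble(nutrient = names(NIP_ROWS), per_100 = per100,
                                per_serving = per100 * product$serving_size / 100),
            product$barcode)
}

#' Warning label
#'
#' Raises a "high in" flag for every configured nutrient whose per-100 g/mL
#' amount strictly exceeds its threshold; the flag set may be empty.
#'
#' @param product A product record.
#' @param rule A [warning_rule()] object.
#' @return A `nutrition_label` with arm `WARNING`; payload is a tibble of
#'   triggered flags `nutrient`, `per_100`, `threshold`, `text`.
#' @export
warning_label <- function(product, rule = warning_rule()) {
  product <- as_product_row(product)
  stopifnot(inherits(rule, "warning_rule"))
  tab <- rule$thresholds
  amounts <- map_dbl(tab$nutrient, function(nu) {
    as.numeric(product[[WARN_NUTRIENTS[[nu]]]] %||% NA_real_)
  })
  hit <- !is.na(amounts) & amounts > tab$threshold
  flags <- quick_tibble(nutrient = tab$nutrient[hit], per_100 = amounts[hit],
                        threshold = tab$threshold[hit], text = tab$text[hit])
  new_label("WARNING", flags, product$barcode)
}

#' Compute the label for a participant's allocated arm
#'
#' Dispatches to the arm's label format using the scheme tables carried by
#' the trial configuration. The label format shown to a participant is
#' determined solely by their randomization allocation.
#'
#' @param product A product record.
#' @param arm One of the configuration's arm tags
#'   (`DIG`, `TLL`, `HSR`, `NIP`, `WARNING`).
#' @param config A [trial_config()] object.
#' @return A `nutrition_label`.
#' @export
label_for <- function(product, arm, config) {
  stopifnot(inherits(config, "trial_config"))
  if (!is.character(arm) || length(arm) != 1 || !arm %in% config$arms) {
    stop_config(paste0("unknown arm for this configuration: ", arm))
  }
  switch(arm,
    DIG = daily_intake(product, config$schemes$DIG),
    TLL = traffic_light(product, config$schemes$TLL),
    HSR = health_star(product, config$schemes$HSR),
    NIP = nip(product),
    WARNING = warning_label(product, config$schemes$WARNING),
    stop_config(paste0("no label format registered for arm ", arm))
  )
}

#' Serialize a label to JSON
#'
#' @param label A `nutrition_label`.
#' @return A JSON string.
#' @export
label_to_json <- function(label) {
  stopifnot(inherits(label, "nutrition_label"))
  jsonlite::toJSON(list(arm = label$arm, barcode = label$barcode,
                        payload = label$payload),
                   dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
}
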