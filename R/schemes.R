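#' Label-scheme tables
#'
#' Every threshold and point table behind the five label formats is
#' configuration data, not code: the engine ships editable defaults laid out
#' like the public front-of-pack style guides (UK FSA traffic-light criteria,
#' the 8700 kJ Australian daily-intake references, Health-Star-Rating-style
#' baseline/modifying point bands) and reads replacements from YAML/JSON.
#'
#' @name label_schemes
NULL

TL_NUTRIENTS <- c(fat = "fat_g_100", satfat = "satfat_g_100",
                  sugars = "sugars_g_100", sodium = "sodium_mg_100")

#' Traffic-light colour thresholds
#'
#' Per-nutrient low/high cutoffs per 100 g (foods) or 100 mL (beverages).
#' A nutrient colours GREEN at or below `low`, AMBER above `low` up to
#' `high`, RED above `high`. Defaults follow the UK FSA 2013 front-of-pack
#' criteria, with salt expressed as sodium (mg).
#'
#' @param food,beverage Data frames with columns `nutrient`
#'   (`fat`, `satfat`, `sugars`, `sodium`), `low`, `high`.
#' @return A `tl_thresholds` object.
#' @export
tl_thresholds <- function(food = NULL, beverage = NULL) {
  food <- food %||% tibble(
    nutrient = c("fat", "satfat", "sugars", "sodium"),
    low = c(3.0, 1.5, 5.0, 120),
    high = c(17.5, 5.0, 22.5, 600)
  )
  beverage <- beverage %||% tibble(
    nutrient = c("fat", "satfat", "sugars", "sodium"),
    low = c(1.5, 0.75, 2.5, 60),
    high = c(8.75, 2.5, 11.25, 300)
  )
  for (tab in list(food, beverage)) {
    tab <- as_tibble(tab)
    if (!all(names(TL_NUTRIENTS) %in% tab$nutrient)) {
      stop_config("traffic-light thresholds must cover fat, satfat, sugars, sodium")
    }
    if (any(tab$low <= 0) || any(tab$high <= tab$low)) {
      stop_config("traffic-light thresholds require 0 < low < high per nutrient")
    }
  }
  structure(list(food = as_tibble(food), beverage = as_tibble(beverage)),
            class = "tl_thresholds")
}

#' Daily-intake reference values
#'
#' Reference daily intakes for the labelled components, used to express a
#' per-serving amount as a percentage. Defaults are the Australian adult
#' reference values (8700 kJ energy).
#'
#' @param energy_kj,fat_g,satfat_g,sugars_g,sodium_mg Positive references.
#' @return A `di_references` object.
#' @export
di_references <- function(energy_kj = 8700, fat_g = 70, satfat_g = 24,
                          sugars_g = 90, sodium_mg = 2300) {
  refs <- c(energy_kj = energy_kj, fat_g = fat_g, satfat_g = satfat_g,
            sugars_g = sugars_g, sodium_mg = sodium_mg)
  if (any(!is.finite(refs)) || any(refs <= 0)) {
    stop_config("daily-intake references must all be > 0")
  }
  structure(as.list(refs), class = "di_references")
}

#' Point band table
#'
#' A band table awards `points` for the highest `threshold` a value strictly
#' exceeds (0 points below the first threshold), so any non-negative value is
#' covered. Thresholds and points must be strictly increasing.
#'
#' @param threshold Increasing numeric cutoffs.
#' @param points Increasing positive integer points.
#' @return A tibble with columns `threshold`, `points`.
#' @export
band_table <- function(threshold, points) {
  tab <- tibble(threshold = as.numeric(threshold), points = as.integer(points))
  if (is.unsorted(tab$threshold, strictly = TRUE) ||
      is.unsorted(tab$points, strictly = TRUE) || any(tab$points < 1)) {
    stop_config("band table thresholds and points must be strictly increasing")
  }
  tab
}

band_points <- function(value, tab) {
  if (is.na(value)) return(0L)
  hit <- which(value > tab$threshold)
  if (length(hit) == 0) 0L else tab$points[max(hit)]
}

#' Health-star point tables
#'
#' Baseline points accrue for energy, saturated fat, total sugars, and sodium;
#' modifying points for fruit/vegetable/nut/legume content, protein, and
#' fibre. `final score = baseline - modifying` maps through a monotone
#' non-increasing score-to-star table onto half-star steps in 0.5-5.0. Food
#' and beverage table variants are selected by the product's `is_beverage`
#' flag. Default bands follow the structure of the public Health Star Rating
#' algorithm; all values are editable configuration.
#'
#' @param baseline_food,baseline_beverage Named lists of band tables for
#'   `energy`, `satfat`, `sugars`, `sodium`.
#' @param modifying Named list of band tables for `fvnl`, `protein`, `fibre`.
#' @param star_map_food,star_map_beverage Data frames `max_score`, `stars`:
#'   a score maps to the first row with `score <= max_score`; the last row
#'   must have `max_score = Inf`; `stars` must be non-increasing half-steps.
#' @return An `hsr_tables` object.
#' @export
hsr_tables <- function(baseline_food = NULL, baseline_beverage = NULL,
                       modifying = NULL, star_map_food = NULL,
                       star_map_beverage = NULL) {
  baseline_food <- baseline_food %||% list(
    energy = band_table(335 * 1:10, 1:10),
    satfat = band_table(1:10, 1:10),
    sugars = band_table(c(5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45), 1:10),
    sodium = band_table(90 * 1:10, 1:10)
  )
  if (is.null(baseline_beverage)) {
    # beverage variant: same bands, rescaled energy (drinks score per 100 mL)
    baseline_beverage <- baseline_food
    baseline_beverage$energy <- band_table(140 * 1:10, 1:10)
  }
  modifying <- modifying %||% list(
    fvnl = band_table(c(40, 60, 67, 80), c(1L, 2L, 5L, 8L)),
    protein = band_table(c(1.6, 3.2, 4.8, 6.4, 8.0, 9.6, 11.6, 13.9, 16.7, 20.0), 1:10),
    fibre = band_table(c(0.9, 1.9, 2.8, 3.7, 4.7, 5.4, 6.3, 7.3, 8.4, 9.7), 1:10)
  )
  default_map <- tibble(
    max_score = c(seq(-6, 18, by = 3), Inf),
    stars = seq(5.0, 0.5, by = -0.5)
  )
  star_map_food <- as_tibble(star_map_food %||% default_map)
  star_map_beverage <- as_tibble(star_map_beverage %||% default_map)

  for (bl in list(baseline_food, baseline_beverage)) {
    if (!all(c("energy", "satfat", "sugars", "sodium") %in% names(bl))) {
      stop_config("baseline tables must cover energy, satfat, sugars, sodium")
    }
  }
  if (!all(c("fvnl", "protein", "fibre") %in% names(modifying))) {
    stop_config("modifying tables must cover fvnl, protein, fibre")
  }
  for (sm in list(star_map_food, star_map_beverage)) {
    if (is.unsorted(sm$max_score, strictly = TRUE) ||
        !is.infinite(sm$max_score[nrow(sm)]) ||
        any(diff(sm$stars) > 0) ||
        !all(sm$stars %in% seq(0.5, 5.0, by = 0.5))) {
      stop_config(paste0("star map must have strictly increasing max_score ",
                         "ending at Inf and non-increasing half-star values"))
    }
  }
  structure(list(baseline_food = baseline_food,
                 baseline_beverage = baseline_beverage,
                 modifying = modifying,
                 star_map_food = star_map_food,
                 star_map_beverage = star_map_beverage),
            class = "hsr_tables")
}

#' Warning-label rule
#'
#' Per-nutrient thresholds per 100 g/mL above which (strictly) a "high in"
#' warning flag is raised. Defaults reuse the traffic-light "high" cutoffs
#' plus an energy cutoff.
#'
#' @param thresholds Data frame with columns `nutrient`
#'   (any of `energy`, `fat`, `satfat`, `sugars`, `sodium`), `threshold`,
#'   `text` (warning text token).
#' @return A `warning_rule` object.
#' @export
warning_rule <- function(thresholds = NULL) {
  thresholds <- as_tibble(thresholds %||% tibble(
    nutrient = c("energy", "satfat", "sugars", "sodium"),
    threshold = c(1700, 5, 22.5, 600),
    text = c("HIGH_IN_ENERGY", "HIGH_IN_SAT_FAT", "HIGH_IN_SUGARS", "HIGH_IN_SODIUM")
  ))
  if (any(thresholds$threshold <= 0)) {
    stop_config("warning thresholds must be > 0")
  }
  structure(list(thresholds = thresholds), class = "warning_rule")
}

WARN_NUTRIENTS <- c(energy = "energy_kj_100", fat = "fat_g_100",
                    satfat = "satfat_g_100", sugars = "sugars_g_100",
                    sodium = "sodium_mg_100")

#' Default scheme tables for every label format
#'
#' @return Named list with elements `DIG`, `TLL`, `HSR`, `WARNING`
#'   (the NIP control needs no scheme table).
#' @export
default_schemes <- function() {
  list(DIG = di_references(), TLL = tl_thresholds(), HSR = hsr_tables(),
       WARNING = warning_rule(), NIP = list())
}

# ---- YAML round-trip ------------------------------------------------------

schemes_to_list <- function(schemes) {
  list(
    DIG = unclass(schemes$DIG),
    TLL = list(food = as.data.frame(schemes$TLL$food),
               beverage = as.data.frame(schemes$TLL$beverage)),
    HSR = list(
      baseline_food = lapply(schemes$HSR$baseline_food, as.data.frame),
      baseline_beverage = lapply(schemes$HSR$baseline_beverage, as.data.frame),
      modifying = lapply(schemes$HSR$modifying, as.data.frame),
      star_map_food = as.data.frame(schemes$HSR$star_map_food),
      star_map_beverage = as.data.frame(schemes$HSR$star_map_beverage)
    ),
    WARNING = list(thresholds = as.data.frame(schemes$WARNING$thresholds))
  )
}

schemes_from_list <- function(x) {
  as_band <- function(df) band_table(as.numeric(df$threshold), as.integer(df$points))
  as_star_map <- function(d) {
    d <- as.data.frame(d)
    # JSON round-trips Inf as the string "Inf"; coerce back
    d$max_score <- as.numeric(d$max_score)
    d$stars <- as.numeric(d$stars)
    d
  }
  list(
    DIG = do.call(di_references, x$DIG),
    TLL = tl_thresholds(food = as_tibble(as.data.frame(x$TLL$food)),
                        beverage = as_tibble(as.data.frame(x$TLL$beverage))),
    HSR = hsr_tables(
      baseline_food = lapply(x$HSR$baseline_food, function(d) as_band(as.data.frame(d))),
      baseline_beverage = lapply(x$HSR$baseline_beverage, function(d) as_band(as.data.frame(d))),
      modifying = lapply(x$HSR$modifying, function(d) as_band(as.data.frame(d))),
      star_map_food = as_star_map(x$HSR$star_map_food),
      star_map_beverage = as_star_map(x$HSR$star_map_beverage)
    ),
    WARNING = warning_rule(as_tibble(as.data.frame(x$WARNING$thresholds))),
    NIP = list()
  )
}
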