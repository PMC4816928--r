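#' Barcode-keyed food composition databases
#'
#' A food database backs both intervention delivery (nutrition labels are
#' computed from its nutrient columns) and data capture (scanned barcodes are
#' matched against it). It is loaded once from a CSV table and is static for
#' the duration of a trial run.
#'
#' Nutrients are stored per 100 g (foods) or per 100 mL (beverages); the
#' `is_beverage` flag selects which convention (and which label-scheme table
#' variant) applies. Per-serving amounts are derived on demand as
#' `per_100 * serving_size / 100`.
#'
#' @name food_db
NULL

FOOD_DB_COLUMNS <- c(
  "barcode", "name", "category_id", "is_beverage", "serving_size",
  "energy_kj_100", "protein_g_100", "fat_g_100", "satfat_g_100",
  "carb_g_100", "sugars_g_100", "fibre_g_100", "sodium_mg_100", "fvnl_pct"
)

# Nutrient columns that must be present (non-missing) for a row to validate.
FOOD_DB_REQUIRED_NUTRIENTS <- c(
  "energy_kj_100", "protein_g_100", "fat_g_100", "satfat_g_100",
  "carb_g_100", "sugars_g_100", "sodium_mg_100"
)

#' Load and validate a food composition database
#'
#' Reads a CSV food table, validates every row against the product invariants,
#' and returns a `food_db` object holding the accepted products plus a
#' rejection report. Invalid rows never abort the load: they are rejected
#' individually with a reason, mirroring how a trial backend must tolerate a
#' partially dirty supplier feed. Duplicate barcodes keep the first occurrence
#' and reject the rest (deterministic, auditable tie-break). Rows whose EAN
#' check digit does not verify are kept but flagged in the `warnings` table:
#' real food databases contain nonconforming codes.
#'
#' @param path Path to a CSV file with header columns
#'   `barcode,name,category_id,is_beverage,serving_size,energy_kj_100,`
#'   `protein_g_100,fat_g_100,satfat_g_100,carb_g_100,sugars_g_100,`
#'   `fibre_g_100,sodium_mg_100,fvnl_pct`.
#' @return A `food_db` object: list with `products` (tibble of valid rows),
#'   `rejected` (tibble: `row`, `barcode`, `reason`), and `warnings` (tibble:
#'   `barcode`, `warning`).
#' @export
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' utils::write.csv(simulate_food_db(5, seed = 1), csv, row.names = FALSE)
#' db <- read_food_db(csv)
#' db$products$barcode
read_food_db <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop_io(paste0("cannot read food database file: ", path))
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  as_food_db(raw)
}

#' Build a food database from an in-memory table
#'
#' Same validation as [read_food_db()], for tables already in R (e.g. from
#' [simulate_food_db()]).
#'
#' @param products A data frame with the food-table columns.
#' @return A `food_db` object.
#' @export
as_food_db <- function(products) {
  if (inherits(products, "food_db")) return(products)
  if (!is.data.frame(products)) stop_arg("`products` must be a data frame")
  missing_cols <- setdiff(FOOD_DB_COLUMNS, names(products))
  if (length(missing_cols) > 0) {
    stop_format(paste0("food table is missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  raw <- as_tibble(products)[FOOD_DB_COLUMNS]
  parsed <- parse_food_rows(raw)
  checks <- validate_food_rows(parsed)

  reason <- checks$reason
  # duplicate tie-break: first occurrence wins, later ones are rejected
  kept_idx <- which(is.na(reason))
  dup_idx <- kept_idx[duplicated(parsed$barcode[kept_idx])]
  reason[dup_idx] <- "duplicate barcode"
  keep <- is.na(reason)

  prods <- parsed[keep, , drop = FALSE]
  rejected <- tibble(
    row = which(!keep),
    barcode = raw$barcode[!keep],
    reason = reason[!keep]
  )
  cs <- checks$checksum
  warn_rows <- keep & !is.na(cs) & !cs
  warnings <- tibble(
    barcode = parsed$barcode[warn_rows],
    warning = rep("EAN check digit does not verify", sum(warn_rows))
  )
  structure(
    list(products = prods, rejected = rejected, warnings = warnings,
         category_index = split(seq_len(nrow(prods)), prods$category_id)),
    class = "food_db"
  )
}

parse_food_rows <- function(raw) {
  num <- function(x) suppressWarnings(as.numeric(x))
  flag <- function(x) {
    x <- tolower(trimws(as.character(x)))
    ifelse(x %in% c("true", "t", "1", "yes"), TRUE,
           ifelse(x %in% c("false", "f", "0", "no"), FALSE, NA))
  }
  tibble(
    barcode = trimws(as.character(raw$barcode)),
    name = as.character(raw$name),
    category_id = trimws(as.character(raw$category_id)),
    is_beverage = flag(raw$is_beverage),
    serving_size = num(raw$serving_size),
    energy_kj_100 = num(raw$energy_kj_100),
    protein_g_100 = num(raw$protein_g_100),
    fat_g_100 = num(raw$fat_g_100),
    satfat_g_100 = num(raw$satfat_g_100),
    carb_g_100 = num(raw$carb_g_100),
    sugars_g_100 = num(raw$sugars_g_100),
    fibre_g_100 = num(raw$fibre_g_100),
    sodium_mg_100 = num(raw$sodium_mg_100),
    fvnl_pct = num(raw$fvnl_pct)
  )
}

# One reason per row (first violation found); checksum validity reported
# separately because it only warns.
validate_food_rows <- function(p) {
  n <- nrow(p)
  reason <- rep(NA_character_, n)
  set <- function(bad, msg) reason <<- ifelse(is.na(reason) & bad, msg, reason)

  set(!grepl("^[0-9]+$", p$barcode), "barcode is not a digit string")
  set(is.na(reason) & !nchar(p$barcode) %in% c(8L, 13L),
      "barcode length is not 8 or 13")
  set(is.na(p$category_id) | p$category_id == "", "missing category_id")
  set(is.na(p$is_beverage), "is_beverage is not a valid flag")
  set(is.na(p$serving_size) | p$serving_size <= 0, "serving_size must be > 0")
  for (col in FOOD_DB_REQUIRED_NUTRIENTS) {
    set(is.na(p[[col]]), paste0("missing required nutrient ", col))
    set(!is.na(p[[col]]) & p[[col]] < 0, paste0("negative nutrient ", col))
  }
  for (col in c("fibre_g_100")) {
    set(!is.na(p[[col]]) & p[[col]] < 0, paste0("negative nutrient ", col))
  }
  set(!is.na(p$fvnl_pct) & (p$fvnl_pct < 0 | p$fvnl_pct > 100),
      "fvnl_pct outside [0, 100]")

  checksum <- map_lgl(p$barcode, function(b) {
    if (!grepl("^[0-9]+$", b) || !nchar(b) %in% c(8L, 13L)) return(NA)
    ean_check_digit_ok(b)
  })
  list(reason = reason, checksum = checksum)
}

#' Verify an EAN-8/EAN-13 check digit
#'
#' @param barcode A digit string of length 8 or 13.
#' @return `TRUE` if the trailing check digit verifies.
#' @export
ean_check_digit_ok <- function(barcode) {
  d <- as.integer(strsplit(barcode, "")[[1]])
  n <- length(d)
  body <- d[-n]
  # weights 3,1,3,... applied from the rightmost body digit
  w <- rep(c(3L, 1L), length.out = n - 1)[(n - 1):1]
  check <- (10L - sum(body * w) %% 10L) %% 10L
  check == d[n]
}

#' @export
print.food_db <- function(x, ...) {
  cat("<food_db> ", nrow(x$products), " products, ",
      length(unique(x$products$category_id)), " categories, ",
      nrow(x$rejected), " rejected rows, ",
      nrow(x$warnings), " check-digit warnings\n", sep = "")
  invisible(x)
}

#' Match a scanned barcode against the database
#'
#' Barcode lookup is the hinge of both app modes: a match feeds label delivery
#' and list building; a miss is a *normal* outcome that feeds the
#' crowdsourcing path, so an absent code returns a not-found marker rather
#' than an error.
#'
#' @param db A `food_db`.
#' @param code A digit string (the scanned barcode).
#' @return The matching product as a one-row tibble, or a not-found marker
#'   (test with [is_not_found()]).
#' @export
match_barcode <- function(db, code) {
  stopifnot(inherits(db, "food_db"))
  if (!is.character(code) || length(code) != 1 || is.na(code)) {
    stop_scan("scanned code must be a single character string")
  }
  if (!grepl("^[0-9]+$", code)) {
    stop_scan(paste0("scanned code is not a digit string: ", code))
  }
  i <- match(code, db$products$barcode)
  if (is.na(i)) return(not_found(code))
  db$products[i, , drop = FALSE]
}

#' Not-found marker for unmatched barcodes
#' @param code The barcode that failed to match.
#' @return An object of class `labelrct_not_found`.
#' @export
not_found <- function(code) {
  structure(list(barcode = code), class = "labelrct_not_found")
}

#' @rdname not_found
#' @param x An object.
#' @export
is_not_found <- function(x) inherits(x, "labelrct_not_found")

#' Random related products from the same category
#'
#' When a label is delivered for a scanned product the app also shows a random
#' selection of other products from the same category. Sampling is without
#' replacement, never includes the scanned product, and is reproducible under
#' a fixed stream.
#'
#' @param db A `food_db`.
#' @param product A product record (one-row tibble or named list) present in `db`.
#' @param n Maximum number of related products.
#' @param rng An [rng_stream()] or an integer seed.
#' @return A tibble of up to `n` related products. The advanced stream is
#'   attached as attribute `"stream"`.
#' @export
related_products <- function(db, product, n = 4, rng = rng_stream(1)) {
  stopifnot(inherits(db, "food_db"))
  product <- as_product_row(product)
  if (!product$barcode %in% db$products$barcode) {
    stop_arg("`product` is not in the database")
  }
  if (is.numeric(rng)) rng <- rng_stream(rng)
  idx <- db$category_index[[product$category_id]]
  idx <- idx[db$products$barcode[idx] != product$barcode]
  k <- min(n, length(idx))
  drawn <- rng_draw(rng, if (k == 0) integer(0) else idx[sample.int(length(idx), k)])
  out <- db$products[drawn$value, , drop = FALSE]
  attr(out, "stream") <- drawn$stream
  out
}

#' Per-serving nutrient amounts
#'
#' @param product A product record.
#' @param fields Nutrient column names (per 100 g/mL) to convert.
#' @return Named numeric vector of per-serving amounts.
#' @export
per_serving <- function(product,
                        fields = c("energy_kj_100", "protein_g_100", "fat_g_100",
                                   "satfat_g_100", "carb_g_100", "sugars_g_100",
                                   "sodium_mg_100")) {
  product <- as_product_row(product)
  vals <- map_dbl(fields, function(f) {
    v <- product[[f]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  })
  setNames(vals * product$serving_size / 100, sub("_100$", "_serv", fields))
}

#' Write a database validation report as JSON
#'
#' @param db A `food_db`.
#' @param path Output file; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
db_validation_report <- function(db, path = NULL) {
  stopifnot(inherits(db, "food_db"))
  rep <- list(
    n_products = nrow(db$products),
    n_rejected = nrow(db$rejected),
    rejected = db$rejected,
    warnings = db$warnings
  )
  js <- jsonlite::toJSON(rep, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
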