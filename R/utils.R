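#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise ungroup left_join n
#' @importFrom purrr map map_chr map_dbl map_int map_lgl keep pmap
#' @importFrom stats rpois runif rbinom setNames
NULL

# Condition helpers: every user-visible failure carries a labelrct_* class so
# callers (and the CLI) can map failures to distinct exit codes.
stop_labelrct <- function(message, class, ...) {
  abort(message, class = c(class, "labelrct_error"), ...)
}

stop_format <- function(message, ...) stop_labelrct(message, "labelrct_format_error", ...)
stop_config <- function(message, ...) stop_labelrct(message, "labelrct_config_error", ...)
stop_state  <- function(message, ...) stop_labelrct(message, "labelrct_state_error", ...)
stop_scan   <- function(message, ...) stop_labelrct(message, "labelrct_scan_error", ...)
stop_label  <- function(message, ...) stop_labelrct(message, "labelrct_label_error", ...)
stop_arg    <- function(message, ...) stop_labelrct(message, "labelrct_arg_error", ...)
stop_io     <- function(message, ...) stop_labelrct(message, "labelrct_io_error", ...)

#' Independent reproducible random streams
#'
#' A tiny wrapper around R's RNG that captures `.Random.seed` so that several
#' logically independent streams (one per randomization stratum, one for the
#' behaviour simulator, ...) can interleave without perturbing each other or
#' the caller's global RNG state.
#'
#' @param seed Integer seed (kept below 2^31).
#' @return An object of class `rng_stream`.
#' @keywords internal
#' @export
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_arg("`seed` must be a single integer")
  }
  st <- rng_eval(NULL, {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    NULL
  })
  structure(list(state = st$state, seed = as.integer(seed)), class = "rng_stream")
}

# Evaluate `expr` under the RNG state `state` (NULL = fresh), restoring the
# caller's global state afterwards. Returns list(value, state).
rng_eval <- function(state, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  value <- force(expr)
  list(value = value, state = get(".Random.seed", envir = globalenv(), inherits = FALSE))
}

# Draw from a stream: returns list(value, stream) with the advanced stream.
rng_draw <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  out <- rng_eval(stream$state, expr)
  stream$state <- out$state
  list(value = out$value, stream = stream)
}

# Deterministically derive a sub-stream seed from a base seed and a string key
# (e.g. a stratum id). Plain 32-bit arithmetic; not cryptographic, just stable.
derive_seed <- function(seed, key) {
  h <- 0
  for (cp in utf8ToInt(paste0("#", key))) h <- (h * 131 + cp) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + h) %% 2147483629)
}

is_scalar_flag <- function(x) is.logical(x) && length(x) == 1 && !is.na(x)

# Fast tibble construction for hot paths (skips tibble()'s quosure machinery).
quick_tibble <- function(...) {
  cols <- list(...)
  tibble::new_tibble(cols, nrow = if (length(cols)) length(cols[[1]]) else 0L)
}

# Accept a Product given as a named list or a one-row data frame.
as_product_row <- function(product) {
  if (is.data.frame(product)) {
    if (nrow(product) != 1) stop_arg("`product` must be a single product (one row)")
    product <- as.list(product)
  }
  if (!is.list(product) || is.null(product$barcode)) {
    stop_arg("`product` must be a product record with at least a `barcode` field")
  }
  product
}
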