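#' Server-style central blocked randomization
#'
#' Allocation happens in shuffled blocks that contain each arm equally often,
#' with the block size drawn uniformly from a configured set of multiples of
#' the arm count ("variable block sizes", which hide the block boundary from
#' anyone watching the sequence). With stratification, each stratum runs its
#' own independent allocation stream, so assignments in one stratum never
#' perturb another and any call order is reproducible from the seed.
#'
#' @name randomization
NULL

#' Generate one randomization block
#'
#' @param arms Character vector of arm tags.
#' @param block_sizes Positive multiples of `length(arms)`; the block size is
#'   drawn uniformly from this set.
#' @param rng An [rng_stream()] or integer seed.
#' @return List with `block` (a uniformly shuffled arm sequence containing
#'   each arm exactly `size/length(arms)` times) and the advanced `stream`.
#' @export
next_block <- function(arms, block_sizes, rng) {
  if (length(arms) == 0) stop_config("at least one arm is required")
  if (any(block_sizes <= 0) || any(block_sizes %% length(arms) != 0)) {
    stop_config("every block size must be a positive multiple of the number of arms")
  }
  if (is.numeric(rng)) rng <- rng_stream(rng)
  drawn <- rng_draw(rng, {
    size <- block_sizes[sample.int(length(block_sizes), 1)]
    sample(rep(arms, each = size / length(arms)))
  })
  list(block = drawn$value, stream = drawn$stream)
}

#' Create an allocation state
#'
#' @param arms Character vector of arm tags (order fixed by the trial
#'   configuration).
#' @param block_sizes Candidate block sizes; default one and two times the
#'   arm count.
#' @param strata Character vector of stratum ids; a single empty-tuple
#'   stratum (`"(all)"`) means no stratification.
#' @param seed Integer seed. Each stratum derives an independent sub-stream
#'   from it, so the full allocation sequence of every stratum is a pure
#'   function of the seed and that stratum's request order.
#' @return An `allocation_state` object.
#' @export
allocation_state <- function(arms, block_sizes = length(arms) * c(1L, 2L),
                             strata = "(all)", seed = 1L) {
  if (length(arms) == 0) stop_config("at least one arm is required")
  if (any(block_sizes <= 0) || any(block_sizes %% length(arms) != 0)) {
    stop_config("every block size must be a positive multiple of the number of arms")
  }
  per_stratum <- lapply(strata, function(s) {
    list(stream = rng_stream(derive_seed(seed, s)),
         pending = character(0),
         counts = setNames(rep(0L, length(arms)), arms),
         block_id = 0L, position = 0L)
  })
  structure(
    list(arms = arms, block_sizes = as.integer(block_sizes),
         strata = setNames(per_stratum, strata), seed = as.integer(seed),
         log = tibble(participant_id = character(), stratum = character(),
                      arm = character(), block_id = integer(),
                      position = integer())),
    class = "allocation_state"
  )
}

#' @export
print.allocation_state <- function(x, ...) {
  cat("<allocation_state> arms: ", paste(x$arms, collapse = ", "),
      "; block sizes {", paste(x$block_sizes, collapse = ", "), "}; ",
      length(x$strata), " stratum/strata; ",
      nrow(x$log), " allocations\n", sep = "")
  invisible(x)
}

#' Allocate the next participant in a stratum
#'
#' Pops the next arm from the stratum's pending sequence, generating a fresh
#' block (via [next_block()]) whenever the sequence is exhausted, and appends
#' to the audit log. Strictly sequential per stratum: replaying the same seed
#' and the same ordered requests reproduces identical allocations.
#'
#' @param state An [allocation_state()].
#' @param stratum Stratum id; must be one of the state's strata.
#' @param participant_id Optional id recorded in the audit log.
#' @return List with `state` (updated), `arm`, `block_id`, `position`.
#' @export
assign_arm <- function(state, stratum = "(all)", participant_id = NA_character_) {
  stopifnot(inherits(state, "allocation_state"))
  if (!stratum %in% names(state$strata)) {
    stop_config(paste0("unknown stratum: ", stratum))
  }
  st <- state$strata[[stratum]]
  if (length(st$pending) == 0) {
    nb <- next_block(state$arms, state$block_sizes, st$stream)
    st$pending <- nb$block
    st$stream <- nb$stream
    st$block_id <- st$block_id + 1L
    st$position <- 0L
  }
  arm <- st$pending[1]
  st$pending <- st$pending[-1]
  st$position <- st$position + 1L
  st$counts[[arm]] <- st$counts[[arm]] + 1L
  state$strata[[stratum]] <- st
  state$log <- bind_rows(state$log, tibble(
    participant_id = participant_id, stratum = stratum, arm = arm,
    block_id = st$block_id, position = st$position
  ))
  list(state = state, arm = arm, block_id = st$block_id, position = st$position)
}

#' Per-stratum arm counts
#'
#' @param state An [allocation_state()].
#' @return A tibble `stratum`, `arm`, `n`. Within any stratum the counts
#'   differ by less than the largest configured block size.
#' @export
allocation_counts <- function(state) {
  stopifnot(inherits(state, "allocation_state"))
  bind_rows(lapply(names(state$strata), function(s) {
    cnt <- state$strata[[s]]$counts
    tibble(stratum = s, arm = names(cnt), n = as.integer(cnt))
  }))
}

#' Write the allocation audit log as JSON lines
#'
#' @param state An [allocation_state()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_allocation_log <- function(state, path) {
  stopifnot(inherits(state, "allocation_state"))
  lines <- map_chr(seq_len(nrow(state$log)), function(i) {
    jsonlite::toJSON(as.list(state$log[i, ]), auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}
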