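#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col coord_flip labs
#'   scale_x_discrete theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a simulated cohort into one row per participant
#'
#' @param x A `trial_cohort`.
#' @param ... Unused.
#' @return A tibble: `participant_id`, `state`, `stratum`, `arm`,
#'   `items_week1`, `n_lists`, `n_items`, `n_receipts`, `n_label_views`,
#'   `n_crowdsource`, `completed`.
#' @export
tidy.trial_cohort <- function(x, ...) {
  bind_rows(map(x$participants, function(p) {
    tibble(
      participant_id = p$id, state = p$state, stratum = p$stratum,
      arm = p$arm, items_week1 = p$items_week1,
      n_lists = nrow(p$lists), n_items = sum(p$lists$n_items),
      n_receipts = nrow(p$receipts),
      n_label_views = length(p$label_views$barcode),
      n_crowdsource = nrow(p$crowdsource),
      completed = p$state == "COMPLETED"
    )
  }))
}

#' One-row summary of a simulated cohort
#'
#' @param x A `trial_cohort`.
#' @param ... Unused.
#' @return A one-row tibble with the funnel counts and usage totals.
#' @export
glance.trial_cohort <- function(x, ...) {
  f <- setNames(as.list(x$report$funnel$n), x$report$funnel$stage)
  t <- setNames(as.list(x$report$totals$n), x$report$totals$metric)
  as_tibble(c(f, list(excluded_run_in = x$report$excluded_run_in), t))
}

#' Plot a recruitment funnel
#'
#' @param object A `cohort_report` (or `trial_cohort`).
#' @param ... Unused.
#' @return A ggplot: funnel stage counts as horizontal bars, in stage order.
#' @export
autoplot.cohort_report <- function(object, ...) {
  f <- object$funnel
  f$stage <- factor(f$stage, levels = rev(f$stage))
  ggplot(f, aes(x = .data$stage, y = .data$n)) +
    geom_col(fill = "#2c7fb8") +
    coord_flip() +
    labs(x = NULL, y = "participants", title = "Recruitment funnel") +
    theme_minimal()
}

#' @rdname autoplot.cohort_report
#' @export
autoplot.trial_cohort <- function(object, ...) {
  autoplot(object$report, ...)
}
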