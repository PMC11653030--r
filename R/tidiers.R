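# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a linkage result
#'
#' One row per vital record with assignment columns for both sides.
#'
#' @param x A `natalink_linkage`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.natalink_linkage <- function(x, ...) {
  as_tibble(x$assignments)
}

#' @rdname tidy.natalink_linkage
#' @export
glance.natalink_linkage <- function(x, ...) {
  a <- x$assignments
  n_m <- sum(!is.na(a$mother_episode_id))
  n_i <- sum(!is.na(a$infant_episode_id))
  n_b <- sum(!is.na(a$mother_episode_id) & !is.na(a$infant_episode_id))
  tibble(
    n_vitals = x$n_vitals,
    n_linked_mother = n_m,
    n_linked_infant = n_i,
    n_linked_both = n_b,
    pct_mother = percent_of(n_m, x$n_vitals),
    pct_infant = percent_of(n_i, x$n_vitals),
    pct_both = percent_of(n_b, x$n_vitals),
    n_tiebreaks = sum(a$mother_tiebreak, a$infant_tiebreak, na.rm = TRUE)
  )
}

#' Tidy linkage metrics
#'
#' `tidy()` returns the per-stratum rate rows; `glance()` the one-row
#' overall summary.
#'
#' @param x A `natalink_metrics` from [linkage_rates()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.natalink_metrics <- function(x, ...) x$strata

#' @rdname tidy.natalink_metrics
#' @export
glance.natalink_metrics <- function(x, ...) x$overall

#' Tidy a score breakdown
#'
#' @param x A `natalink_score`.
#' @param ... Unused.
#' @return The breakdown tibble (variable, level, points).
#' @export
tidy.natalink_score <- function(x, ...) x$breakdown

#' Plot linkage rates by stratum
#'
#' Bar chart of the percentage linked to both episode types per stratum
#' level, faceted by stratum variable.
#'
#' @param object A `natalink_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot natalink_metrics
#' @export
autoplot.natalink_metrics <- function(object, ...) {
  d <- object$strata
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$pct_both)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      yintercept = object$overall$pct_both, linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~stratum, scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "% linked to both sides",
      title = "Linkage rate by stratum",
      subtitle = "dashed line: overall rate"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the distribution of accepted link scores
#'
#' @param object A `natalink_linkage`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot natalink_linkage
#' @export
autoplot.natalink_linkage <- function(object, ...) {
  a <- object$assignments
  d <- bind_rows(
    tibble(side = "mother", score = a$mother_score),
    tibble(side = "infant", score = a$infant_score)
  )
  d <- d[!is.na(d$score), , drop = FALSE]
  cutoffs <- tibble(
    side = c("mother", "infant"),
    cutoff = c(object$config$mother_cutoff, object$config$infant_cutoff)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = 2, fill = "grey40") +
    ggplot2::geom_vline(
      data = cutoffs, ggplot2::aes(xintercept = .data$cutoff),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~side, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "link score", y = "accepted links",
      title = "Accepted link scores by side",
      subtitle = "dashed line: acceptance cutoff"
    ) +
    ggplot2::theme_minimal()
}
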