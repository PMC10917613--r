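#' Plot per-taxon abundance shifts of a profile comparison
#'
#' Horizontal bar chart of signed abundance differences
#' (treated - untreated) per taxon, colored by lost/gained/shared status.
#'
#' @param object A `profile_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profile_comparison
#' @export
autoplot.profile_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$delta,
    y = stats::reorder(.data$taxon, .data$delta),
    fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "abundance change (treated - untreated, % points)",
      y = NULL, fill = NULL,
      title = sprintf("Profile shift, TVI = %.3g", object$tvi)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Gram dose-response
#'
#' Gram-negative and Gram-positive shares of the profile versus saponin
#' concentration, with the fitted Gram-negative trend line.
#'
#' @param object A `dose_response`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dose_response
#' @export
autoplot.dose_response <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(
      cols = c("gram_negative_pct", "gram_positive_pct", "unknown_pct"),
      names_to = "class", values_to = "pct"
    ) |>
    dplyr::mutate(class = sub("_pct$", "", .data$class))
  ggplot2::ggplot(d, ggplot2::aes(.data$concentration, .data$pct,
                                  colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "saponin concentration (% wt/vol)",
      y = "share of profile (%)", colour = NULL,
      title = "Gram-class dose-response"
    ) +
    ggplot2::theme_minimal()
}

#' Stacked Gram-composition bars per sample
#'
#' The familiar two-color composition plot: one stacked bar per sample
#' showing Gram-negative / Gram-positive / unknown shares.
#'
#' @param profiles Named list of normalized profile tibbles (names become
#'   bar labels).
#' @param annotation Gram-annotation tibble.
#' @return A ggplot object.
#' @export
plot_gram_bars <- function(profiles, annotation = NULL) {
  d <- purrr::imap(profiles, function(p, nm) {
    dplyr::mutate(gram_fractions(p, annotation), sample_id = nm)
  }) |>
    purrr::list_rbind() |>
    tidyr::pivot_longer(
      cols = c("gram_negative_pct", "gram_positive_pct", "unknown_pct"),
      names_to = "class", values_to = "pct"
    ) |>
    dplyr::mutate(class = sub("_pct$", "", .data$class))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$pct,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      gram_negative = "#e78ac3", gram_positive = "#66c2a5",
      unknown = "grey70"
    )) +
    ggplot2::labs(x = NULL, y = "share of profile (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
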