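#' Forest-style plot of a drug comparison
#'
#' PRR point estimates with 95% confidence intervals on a log scale, one row
#' per event; undefined rows (zero comparator count) are omitted with a
#' message, since they have no finite estimate to draw.
#'
#' @param object A `prr_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prr_comparison <- function(object, ...) {
  df <- as_tibble(object)
  drop <- is.na(df$prr) | df$prr == 0
  if (any(drop)) {
    message(sprintf("omitting %d event(s) with undefined or zero PRR", sum(drop)))
  }
  df <- df[!drop, ]
  df$event <- factor(df$event, levels = rev(sort(unique(df$event))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prr, y = .data$event)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.25, na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("PRR (%s vs %s, 95%% CI)",
                  attr(object, "drug_a"), attr(object, "drug_b")),
      y = NULL,
      title = sprintf("Adverse-event reporting, %s cases",
                      attr(object, "sex") %||% "")
    ) +
    ggplot2::theme_minimal()
}

#' Log-log diagnostic plot of a power-law fit
#'
#' The fitted points with the least-squares power law overlaid, both axes on
#' the log scale.
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  grid <- tibble(x = exp(seq(log(min(object$data$x)), log(max(object$data$x)),
                             length.out = 100)))
  grid$y <- object$a * grid$x^object$b
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      title = sprintf("y = %.3g x^%.3g, R² = %.3f",
                      object$a, object$b, object$r_squared),
      x = "degree", y = "metric"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of an enrichment result
#'
#' Enrichment ratios of the tested categories, shaded by adjusted p-value.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- as_tibble(object)
  df$category_id <- factor(df$category_id, levels = rev(df$category_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$enrichment_ratio,
                                   y = .data$category_id,
                                   fill = -log10(.data$p_adjusted))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "enrichment ratio (observed / expected overlap)",
                  y = NULL, fill = "-log10 adj. p") +
    ggplot2::theme_minimal()
}
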