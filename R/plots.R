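# ggplot2 visualisations of fitted trends and assessments, mirroring the
# standardized result displays: age-trend scatter with confidence band,
# signed-log feature profiles, and slope forests for follow-up series.

#' Plot a fitted age trend
#'
#' Control values against age with the selected polynomial trend and its
#' pointwise 95% confidence band; rejected outliers are crossed out.
#'
#' @param object A `morph_trend` from [fit_age_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morph_trend <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(age = seq(object$age_range[1], object$age_range[2],
                                   length.out = 100))
  band <- suppressWarnings(evaluate_trend(object, grid$age))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(ymin = .data$fit - .data$ci_halfwidth,
                   ymax = .data$fit + .data$ci_halfwidth),
      fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$fit),
                       linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value, shape = .data$kept),
                        alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 1, `FALSE` = 4),
                                name = "kept") +
    ggplot2::labs(x = "age [years]", y = "value",
                  title = paste0("Age trend (degree ", object$degree, ")"),
                  subtitle = paste0("n = ", object$n_kept, " kept, ",
                                    object$n_rejected_raw + object$n_rejected_residual,
                                    " rejected")) +
    ggplot2::theme_minimal()
}

#' Plot a visit assessment feature profile
#'
#' Signed log10 p-values per key, coloured by highlight level: the at-a-
#' glance anomaly profile of one scan.
#'
#' @param object A `visit_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.visit_assessment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$L,
                                  colour = .data$highlight)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(
      values = c(none = "grey50", yellow = "#e6b800", red = "#cc0000"),
      drop = FALSE) +
    ggplot2::labs(x = "feature (key index)",
                  y = expression(L == -sign(x) %.% log[10] * p),
                  title = "Feature vector of signed log p-values") +
    ggplot2::theme_minimal()
}

#' Plot a series assessment slope forest
#'
#' Fitted annual change rates with +/- 1 slope-uncertainty error bars per
#' key, coloured by highlight level.
#'
#' @param object A `series_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.series_assessment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$slope), ]
  d$key <- factor(d$key, levels = d$key[order(d$slope)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slope, y = .data$key,
                                  colour = .data$highlight)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$slope - .data$delta_a,
                   xmax = .data$slope + .data$delta_a), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(none = "grey50", yellow = "#e6b800", red = "#cc0000"),
      drop = FALSE) +
    ggplot2::labs(x = "annual change rate [units/year]", y = NULL,
                  title = "Follow-up slopes vs cross-sectional aging") +
    ggplot2::theme_minimal()
}

#' Heatmap of a feature-vector correlation matrix
#'
#' @param mat Matrix from [feature_correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_feature_correlation <- function(mat) {
  d <- tibble::as_tibble(as.table(mat), .name_repair = "minimal")
  names(d) <- c("row", "col", "r")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Feature-vector correlation matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
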