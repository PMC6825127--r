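#' Plot Kaplan-Meier curves of the predicted risk groups
#'
#' @param object A `km_result` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot: step curves per group (blue = low risk, red = high
#'   risk) with the log-rank p annotated.
#' @export
autoplot.km_result <- function(object, ...) {
  d <- object$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1),
      .x[, c("time", "surv")]
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv, color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c(low = "#2166AC", high = "#B2182B")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Disease-free survival (months)", y = "Survival probability",
      color = "Risk group",
      subtitle = sprintf("log-rank χ² = %.2f, p = %.2g", object$chi2, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the CSS cutoff-fitting grid
#'
#' @param object A `css_model`.
#' @param ... Unused.
#' @return A ggplot tile map of the grid score over (K_low, K_high), the
#'   selected pair outlined.
#' @export
autoplot.css_model <- function(object, ...) {
  rep_ <- object$fit_report
  ggplot2::ggplot(rep_, ggplot2::aes(.data$K_low, .data$K_high)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$score, alpha = .data$eligible)) +
    ggplot2::geom_tile(
      data = rep_[rep_$K_low == object$K_low & rep_$K_high == object$K_high, ],
      fill = NA, color = "black", linewidth = 0.8
    ) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25), guide = "none") +
    ggplot2::scale_fill_viridis_c(name = "low + high\naccuracy") +
    ggplot2::labs(x = "K_low (max high votes for a low call)",
                  y = "K_high (min high votes for a high call)") +
    ggplot2::theme_minimal()
}

#' Boxplot-style group comparison panel
#'
#' Draws the quartile summaries produced by [compare_groups()] as paired
#' boxes per feature, annotated with the Welch p-value.
#'
#' @param comparisons Output of [compare_groups()].
#' @param max_features Show at most this many features (smallest p first).
#' @return A ggplot.
#' @export
plot_group_comparison <- function(comparisons, max_features = 12) {
  d <- comparisons |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::arrange(.data$p_value) |>
    utils::head(max_features) |>
    tidyr::pivot_longer(
      cols = c("q1_low", "median_low", "q3_low", "q1_high", "median_high", "q3_high"),
      names_to = c("stat", "group"), names_pattern = "(q1|median|q3)_(low|high)"
    ) |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$feature, color = .data$group)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
      position = ggplot2::position_dodge(width = 0.6), width = 0.4
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$median),
      position = ggplot2::position_dodge(width = 0.6), size = 2
    ) +
    ggplot2::scale_color_manual(values = c(low = "#2166AC", high = "#B2182B")) +
    ggplot2::labs(x = NULL, y = "value (IQR around median)", color = "Risk group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Recurrence-score distribution with risk bins
#'
#' @param rs_results Output of [compute_rs()].
#' @param model The [oncotype_model()] providing the bin thresholds.
#' @return A ggplot histogram of RS with the bin boundaries marked.
#' @export
plot_rs_distribution <- function(rs_results, model = oncotype_model()) {
  ggplot2::ggplot(rs_results, ggplot2::aes(.data$rs, fill = .data$bin)) +
    ggplot2::geom_histogram(binwidth = 2, boundary = 0) +
    ggplot2::geom_vline(
      xintercept = model$bin_thresholds, linetype = "dashed",
      color = "grey30"
    ) +
    ggplot2::scale_fill_manual(values = c(
      low = "#2166AC", intermediate = "grey60", high = "#B2182B"
    )) +
    ggplot2::labs(x = "Recurrence score (0-100)", y = "Patients") +
    ggplot2::theme_minimal()
}

#' Heating-score profile of selected genes
#'
#' @param object A `heat_matrix`.
#' @param genes Genes to show (default: the 20 with highest mean heat).
#' @param ... Unused.
#' @return A ggplot tile map (genes x samples) of heating scores.
#' @export
autoplot.heat_matrix <- function(object, genes = NULL, ...) {
  if (is.null(genes)) {
    genes <- names(sort(rowMeans(object$scores), decreasing = TRUE))[1:min(20, nrow(object$scores))]
  }
  d <- tidy(object) |> dplyr::filter(.data$gene %in% genes)
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id, .data$gene, fill = .data$heat)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "Sample", y = NULL, fill = "heating\nscore") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
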