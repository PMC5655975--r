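#' Plot per-position information content of a frequency matrix
#'
#' @param m A `bps_matrix`.
#' @return A ggplot: bars of information content (bits) per heptamer
#'   position, branch site (position 6) highlighted.
#' @export
plot_info_content <- function(m) {
  ic <- info_content(m)
  ic$branch_site <- ic$position == 6L
  ggplot2::ggplot(ic, ggplot2::aes(x = factor(.data$position), y = .data$ic,
                                   fill = .data$branch_site)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "#D55E00")) +
    ggplot2::labs(
      x = "heptamer position", y = "information content (bits)",
      title = sprintf("BPS motif conservation (total %.2f bits)", sum(ic$ic)),
      subtitle = paste("matrix:", attr(m, "source") %||% "custom")
    ) +
    ggplot2::theme_minimal()
}

#' Plot intron regions in 3'ss-relative coordinates
#'
#' @param regions Region tibble from [locate_regions()].
#' @return A ggplot: one horizontal segment per intron and region label.
#' @export
plot_regions <- function(regions) {
  ggplot2::ggplot(regions, ggplot2::aes(y = .data$intron_id)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   yend = .data$intron_id, colour = .data$label),
      linewidth = 3, alpha = 0.75
    ) +
    ggplot2::labs(x = "position relative to the 3'ss", y = NULL,
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' Autoplot a branch-point evaluation
#'
#' Predicted against annotated branch-site positions, one point per intron;
#' correct predictions sit on the diagonal (introns with several annotated
#' sites are drawn against each annotation).
#'
#' @param object A `bps_eval` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bps_eval
#' @export
autoplot.bps_eval <- function(object, ...) {
  d <- tidyr::unnest(object$verdicts, "annotated")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$annotated, y = .data$predicted,
                                  colour = .data$correct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#CC3311", `TRUE` = "#228833")) +
    ggplot2::labs(
      x = "annotated branch site (3'ss-relative)",
      y = "predicted branch site",
      title = sprintf("%d/%d introns correct (%.2f%%)",
                      object$n_correct, object$n_introns, object$accuracy_percent)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
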