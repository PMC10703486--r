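#' Plot the running-sum profile of a GSEA result
#'
#' Enrichment running sum along the ranking with hit positions as a
#' rug and the signed extremum marked.
#'
#' @param object A `gsea_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, ...) {
  df <- tibble(rank = seq_along(object$running_sum),
               running_sum = object$running_sum)
  hit_ranks <- which(object$hits)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(data = tibble(rank = hit_ranks),
                      ggplot2::aes(x = .data$rank), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::annotate("point", x = object$extremum_index, y = object$es,
                      colour = "#d95f02", size = 2) +
    ggplot2::labs(x = "rank in disease signature", y = "running sum",
                  title = sprintf("ES = %.3f, NES = %.3f, p = %.3g",
                                  object$es, object$nes, object$pvalue)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the clustered reversal matrix
#'
#' Drugs (rows, ordered by cluster mean reversal) by contexts, filled
#' by `delta_nes`.
#'
#' @param object A `delta_nes_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delta_nes_matrix
#' @export
autoplot.delta_nes_matrix <- function(object, ...) {
  long <- tidy(object)
  if (!is.null(object$cluster)) {
    row_means <- rowMeans(object$mat)
    cl_mean <- tapply(row_means, object$cluster[names(row_means)], mean)
    key <- row_means + 1e6 * unname(cl_mean[as.character(
      object$cluster[names(row_means)])])
    ord <- names(row_means)[order(key)]
    long$signature_id <- factor(long$signature_id, levels = ord)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$context,
                                     y = .data$signature_id,
                                     fill = .data$delta_nes)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ΔNES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Dot plot of a validation reversal report
#'
#' Treatments by signatures, point size by |median difference|, colour
#' by sign, significance labels overlaid.
#'
#' @param report Tibble from [reversal_report()].
#' @return A ggplot object.
#' @export
plot_reversal_report <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$signature, y = .data$treatment)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$delta_median),
                                     colour = .data$delta_median)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$significance),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_colour_gradient2(low = "#313695", mid = "grey85",
                                    high = "#a50026", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, size = "|Δ median|",
                  colour = "Δ median") +
    ggplot2::theme_minimal()
}
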