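# ggplot2 visualisations of run results.

#' Plot read fate for a demultiplexing run
#'
#' Bar chart of passing reads and every non-zero failure reason.
#'
#' @param object a `demux_metrics` (or `demux_result`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.demux_metrics <- function(object, ...) {
  fates <- tibble(
    fate = c("pass", names(object$reads_fail_by_reason)),
    reads = c(object$reads_pass,
              as.numeric(object$reads_fail_by_reason))) %>%
    filter(.data$reads > 0)
  ggplot2::ggplot(fates,
                  ggplot2::aes(x = stats::reorder(.data$fate, -.data$reads),
                               y = .data$reads)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reads", title = "Read fate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.demux_result <- function(object, ...) {
  autoplot.demux_metrics(object$metrics, ...)
}

#' Barcode rank ("knee") plot
#'
#' Reads per cell barcode against barcode rank, both log-scaled, with
#' the minimum-read threshold marked. The inflection separates genuine
#' cells from low-diversity barcodes.
#'
#' @param x a `demux_result`, or a tibble with columns `cell_label`,
#'   `reads`.
#' @param min_reads threshold to mark (defaults to the run's `-m`).
#' @return a ggplot.
#' @export
plot_barcode_rank <- function(x, min_reads = NULL) {
  if (inherits(x, "demux_result")) {
    min_reads <- min_reads %||% x$metrics$min_reads
    x <- x$barcode_counts
  }
  ranked <- as_tibble(x) %>%
    arrange(desc(.data$reads)) %>%
    mutate(rank = row_number())
  p <- ggplot2::ggplot(ranked, ggplot2::aes(x = .data$rank,
                                            y = .data$reads)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "barcode rank", y = "reads",
                  title = "Barcode rank plot") +
    ggplot2::theme_minimal()
  if (!is.null(min_reads)) {
    p <- p + ggplot2::geom_hline(yintercept = min_reads,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot QC removals
#'
#' @param object a `qc_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$step, y = .data$removed,
                               fill = .data$axis)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "removed", title = "QC filtering") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
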