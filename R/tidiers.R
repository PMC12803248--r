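# broom-style tidiers for the package's result objects.

#' Tidy demultiplexing metrics
#'
#' @param x a `demux_metrics`.
#' @param ... unused.
#' @return long tibble with columns `metric`, `value`: read totals, one
#'   row per failure reason, and per-round exact/corrected counts.
#' @export
tidy.demux_metrics <- function(x, ...) {
  bind_rows(
    tibble(metric = c("reads_total", "reads_pass"),
           value = c(x$reads_total, x$reads_pass)),
    tibble(metric = paste0("fail_", names(x$reads_fail_by_reason)),
           value = as.numeric(x$reads_fail_by_reason)),
    x$per_round %>%
      tidyr::pivot_longer(cols = c("exact_match", "corrected_match"),
                          names_to = "kind", values_to = "value") %>%
      mutate(metric = sprintf("round%d_%s", .data$round, .data$kind)) %>%
      select("metric", "value"),
    tibble(metric = c("barcodes_detected", "barcodes_passing_min_reads",
                      "reads_in_passing_barcodes"),
           value = c(x$barcodes_detected, x$barcodes_passing_min_reads,
                     x$reads_in_passing_barcodes)))
}

#' One-row summary of demultiplexing metrics
#'
#' @inheritParams tidy.demux_metrics
#' @return one-row tibble.
#' @export
glance.demux_metrics <- function(x, ...) {
  tibble(reads_total = x$reads_total,
         reads_pass = x$reads_pass,
         pass_rate = ifelse(x$reads_total > 0,
                            x$reads_pass / x$reads_total, NA_real_),
         barcodes_detected = x$barcodes_detected,
         barcodes_passing_min_reads = x$barcodes_passing_min_reads,
         reads_in_passing_barcodes = x$reads_in_passing_barcodes,
         min_reads = x$min_reads)
}

#' @export
tidy.demux_result <- function(x, ...) tidy(x$metrics, ...)

#' @export
glance.demux_result <- function(x, ...) glance(x$metrics, ...)

#' Tidy a QC report
#'
#' @param x a `qc_report`.
#' @param ... unused.
#' @return tibble with one row per removal step.
#' @export
tidy.qc_report <- function(x, ...) {
  tibble(step = c("cells_removed_low_umi", "genes_removed_low_cells",
                  "cells_removed_high_mito", "cells_removed_high_umi"),
         axis = c("cell", "gene", "cell", "cell"),
         removed = c(x$cells_removed_low_umi, x$genes_removed_low_cells,
                     x$cells_removed_high_mito, x$cells_removed_high_umi))
}

#' One-row summary of a QC report
#'
#' @inheritParams tidy.qc_report
#' @return one-row tibble with input/output dimensions and thresholds.
#' @export
glance.qc_report <- function(x, ...) {
  tibble(genes_in = x$dims_in[1], cells_in = x$dims_in[2],
         genes_out = x$dims_out[1], cells_out = x$dims_out[2],
         min_umis = x$thresholds$min_umis,
         max_umis = x$thresholds$max_umis,
         min_cells_per_gene = x$thresholds$min_cells_per_gene,
         max_mito_frac = x$thresholds$max_mito_frac)
}

#' Tidy an evaluation against simulation truth
#'
#' @param x a `splitpool_evaluation`.
#' @param ... unused.
#' @return long tibble of evaluation metrics.
#' @export
tidy.splitpool_evaluation <- function(x, ...) {
  tibble(metric = c("read_accuracy", "junk_pass_rate", "cell_recovery",
                    "matrix_entry_agreement"),
         value = c(x$read_accuracy, x$junk_pass_rate, x$cell_recovery,
                   x$matrix_entry_agreement))
}

#' @export
glance.splitpool_evaluation <- function(x, ...) {
  tibble(read_accuracy = x$read_accuracy,
         junk_pass_rate = x$junk_pass_rate,
         cell_recovery = x$cell_recovery,
         matrix_identical = x$matrix_identical,
         matrix_entry_agreement = x$matrix_entry_agreement,
         n_genuine = x$n_genuine, n_junk = x$n_junk)
}
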