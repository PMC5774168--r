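#' Contig length distribution plot
#'
#' @param contigs Sequence tibble.
#' @param binwidth Histogram bin width in bases.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(contigs, binwidth = 100) {
  df <- tibble::tibble(length = nchar(contigs$seq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "Contig length (nt)", y = "Contigs",
                  title = "Assembly length distribution") +
    ggplot2::theme_minimal()
}

#' Ortholog-hit-ratio distribution plot
#'
#' @param records OHR tibble from [ohr_table()].
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_ohr_distribution <- function(records, binwidth = 0.05) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$ohr)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::geom_vline(xintercept = c(0.5, 0.7), linetype = "dashed") +
    ggplot2::labs(x = "Ortholog hit ratio", y = "Transcripts",
                  title = "Assembly completeness (OHR)") +
    ggplot2::theme_minimal()
}

#' Plot a family census as per-family minimum gene counts
#'
#' @param object A `family_census` object.
#' @param ... Unused.
#' @return A ggplot object: one bar per family, filled by clan.
#' @export
autoplot.family_census <- function(object, ...) {
  df <- object$families
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$family, -.data$gene_count),
    y = .data$gene_count, fill = .data$clan)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Minimum gene count",
                  title = "Gene-family census",
                  subtitle = "counts are minimum estimates (≥)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 60, hjust = 1))
}
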