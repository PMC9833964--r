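#' Plot the coverage track of a consensus
#'
#' Read-depth profile along the reference, with the sampler's minimum
#' depth drawn as a dashed rule.
#'
#' @param track A `consensus_track`.
#' @param min_depth Depth threshold to annotate (default 3).
#' @param bin Bin width in bp for averaging (default keeps ~1000 points).
#' @return A ggplot object.
#' @export
plot_coverage <- function(track, min_depth = 3,
                          bin = max(1L, nchar(track$seq) %/% 1000L)) {
  L <- length(track$coverage)
  df <- tibble::tibble(pos = seq_len(L) - 1L, depth = track$coverage) |>
    dplyr::mutate(bin = .data$pos %/% bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(pos = min(.data$pos), depth = mean(.data$depth),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = min_depth, linetype = "dashed") +
    ggplot2::labs(x = "position (bp)", y = "read depth",
                  title = track$ref_id) +
    ggplot2::theme_minimal()
}

#' Plot a conservation classification report
#'
#' Stacked per-library fractions of conserved and rejected mate-pairs.
#'
#' @param report Tibble from [classify_report()].
#' @return A ggplot object.
#' @export
plot_classification <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$library, y = .data$fraction,
                               fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "fraction of mate-pairs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the length distribution of simulated ancient-DNA reads
#'
#' @param reads Tibble from [simulate_adna()].
#' @param binwidth Histogram bin width in bp (default 1).
#' @return A ggplot object.
#' @export
plot_read_lengths <- function(reads, binwidth = 1) {
  df <- tibble::tibble(len = nchar(reads$seq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$len)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40",
                            color = "white") +
    ggplot2::labs(x = "read length (bp)", y = "reads") +
    ggplot2::theme_minimal()
}

#' Coverage plot of a consensus track
#'
#' @param object A `consensus_track`.
#' @param ... Passed to [plot_coverage()].
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot consensus_track
#' @export
autoplot.consensus_track <- function(object, ...) {
  plot_coverage(object, ...)
}
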