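#' Nx contiguity statistic
#'
#' Smallest length `l` such that sequences of length `>= l` together
#' cover at least `x` percent of the total assembly length. `nx(len, 50)`
#' is the classic N50.
#'
#' @param lengths Positive sequence lengths in bp.
#' @param x Percent threshold in `(0, 100]`.
#' @return Length in bp.
#' @examples
#' nx(c(10, 9, 8, 7, 6), 50) # 8
#' @export
nx <- function(lengths, x = 50) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  stopifnot(x > 0, x <= 100, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  s[which(cum >= x / 100 * cum[length(cum)])[1]]
}

#' @rdname nx
#' @export
n50 <- function(lengths) nx(lengths, 50)

#' Classify each scaffold join against ground truth
#'
#' For every adjacent contig pair within a scaffold, decides whether the
#' join is consistent with the true coordinates of the contigs. First
#' match wins:
#'
#' * contigs from different truth sequences -> `INTERCHROM`;
#' * effective orientations agree but the downstream contig does not
#'   follow the upstream one in the traversal direction -> `ORDER`;
#' * effective orientations disagree (one contig flipped relative to the
#'   other) -> `ORIENTATION`;
#' * the implied truth gap deviates from the declared scaffold gap by
#'   more than `gap_tolerance` -> `GAP_DEVIANT`;
#' * otherwise `OK`.
#'
#' The effective orientation of a contig is its scaffold orientation
#' composed with its truth strand.
#'
#' @param joins AGP-like tibble: `scaffold`, `idx` (order within the
#'   scaffold), `contig`, `orientation` (`+`/`-`), `gap` (declared gap in
#'   bp before the *next* contig; the last row's value is ignored).
#' @param truth Tibble: `contig`, `truth_seq`, `start` (0-based),
#'   `strand`, `length`.
#' @param gap_tolerance Allowed absolute deviation between implied and
#'   declared gap, in bp (default 1000).
#' @return Tibble with one row per join: `scaffold`, `contig_a`,
#'   `contig_b`, `class`.
#' @export
classify_joins <- function(joins, truth, gap_tolerance = 1000) {
  missing_contigs <- setdiff(joins$contig, truth$contig)
  if (length(missing_contigs) > 0) {
    stop("contig absent from truth: ", missing_contigs[1], call. = FALSE)
  }
  j <- dplyr::left_join(joins, truth, by = "contig") |>
    dplyr::arrange(.data$scaffold, .data$idx) |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::mutate(
      eff = ifelse(.data$orientation == .data$strand, "+", "-"),
      exit_coord = ifelse(.data$eff == "+", .data$start + .data$length,
                          .data$start),
      entry_coord = ifelse(.data$eff == "+", .data$start,
                           .data$start + .data$length)
    ) |>
    dplyr::mutate(
      next_contig = dplyr::lead(.data$contig),
      next_seq = dplyr::lead(.data$truth_seq),
      next_eff = dplyr::lead(.data$eff),
      next_entry = dplyr::lead(.data$entry_coord)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_contig))
  dirn <- ifelse(j$eff == "+", 1, -1)
  gap_truth <- (j$next_entry - j$exit_coord) * dirn
  cls <- dplyr::case_when(
    j$truth_seq != j$next_seq ~ "INTERCHROM",
    j$eff == j$next_eff & gap_truth < 0 ~ "ORDER",
    j$eff != j$next_eff ~ "ORIENTATION",
    abs(gap_truth - j$gap) > gap_tolerance ~ "GAP_DEVIANT",
    TRUE ~ "OK"
  )
  tibble::tibble(scaffold = j$scaffold, contig_a = j$contig,
                 contig_b = j$next_contig,
                 class = factor(cls, levels = c("OK", "INTERCHROM", "ORDER",
                                                "ORIENTATION", "GAP_DEVIANT")))
}

#' Count misjoins in a scaffold set against ground truth
#'
#' A desk-scale, exactly assertable analogue of an assembly-vs-reference
#' misassembly count: joins contradicting the true contig coordinates are
#' tallied by failure class.
#'
#' @inheritParams classify_joins
#' @return A `misjoin_report`: list with `n_joins`, `n_misjoins`, a named
#'   `breakdown` vector over the four failure classes, and the per-join
#'   table. Use [tidy()][generics::tidy] for per-join rows and
#'   [glance()][generics::glance] for the one-row summary.
#' @export
count_misjoins <- function(joins, truth, gap_tolerance = 1000) {
  per_join <- classify_joins(joins, truth, gap_tolerance)
  breakdown <- table(per_join$class)[c("INTERCHROM", "ORDER", "ORIENTATION",
                                       "GAP_DEVIANT")]
  structure(
    list(
      n_joins = nrow(per_join),
      n_misjoins = sum(per_join$class != "OK"),
      breakdown = stats::setNames(as.integer(breakdown),
                                  c("INTERCHROM", "ORDER", "ORIENTATION",
                                    "GAP_DEVIANT")),
      joins = per_join
    ),
    class = "misjoin_report"
  )
}

#' @export
print.misjoin_report <- function(x, ...) {
  cat("<misjoin_report> ", x$n_misjoins, " misjoin(s) in ", x$n_joins,
      " join(s)\n", sep = "")
  if (x$n_misjoins > 0) {
    b <- x$breakdown[x$breakdown > 0]
    cat(" ", paste(names(b), b, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @method tidy misjoin_report
#' @export
tidy.misjoin_report <- function(x, ...) {
  x$joins
}

#' @method glance misjoin_report
#' @export
glance.misjoin_report <- function(x, ...) {
  tibble::tibble(
    n_joins = x$n_joins,
    n_misjoins = x$n_misjoins,
    interchrom = x$breakdown[["INTERCHROM"]],
    order = x$breakdown[["ORDER"]],
    orientation = x$breakdown[["ORIENTATION"]],
    gap_deviant = x$breakdown[["GAP_DEVIANT"]]
  )
}
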