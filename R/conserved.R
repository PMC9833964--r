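#' Pair up primary alignments of a mate-pair library
#'
#' Collapses a SAM tibble into one row per mate-pair, keeping only the
#' primary record of each mate. Mate identity comes from the `/1`/`/2`
#' suffix (or the SAM first/second-mate flag when no suffix is present).
#'
#' @param aln Alignment tibble as from [read_sam()].
#' @return Tibble with one row per pair: `pair_id`, and per mate
#'   `mapped`, `target`, `strand`, `start` (0-based), `end` (0-based
#'   exclusive, `start + reference span of the CIGAR`), suffixed `1`/`2`.
#'   A mate absent from the SAM is treated as unmapped.
#' @export
pair_alignments <- function(aln) {
  aln <- dplyr::filter(aln, !.data$is_secondary_or_supplementary)
  has_suffix <- grepl("/[12]$", aln$qname)
  aln$pair_id <- ifelse(has_suffix, sub("/[12]$", "", aln$qname), aln$qname)
  aln$mate <- ifelse(has_suffix,
                     ifelse(grepl("/1$", aln$qname), 1L, 2L),
                     ifelse(aln$is_first_mate, 1L, 2L))
  span <- rep(0L, nrow(aln))
  mapped <- which(aln$mapped)
  simple <- mapped[grepl("^[0-9]+[M=X]$", aln$cigar[mapped])]
  span[simple] <- as.integer(sub("[M=X]$", "", aln$cigar[simple]))
  complex <- setdiff(mapped, simple)
  span[complex] <- vapply(aln$cigar[complex], cigar_ref_span, numeric(1),
                          USE.NAMES = FALSE)
  aln$end <- aln$pos + span

  one <- function(m, suffix) {
    sub <- dplyr::filter(aln, .data$mate == m) |>
      dplyr::distinct(.data$pair_id, .keep_all = TRUE) |>
      dplyr::select("pair_id", mapped = "mapped", target = "target_id",
                    strand = "strand", start = "pos", end = "end")
    names(sub)[-1] <- paste0(names(sub)[-1], suffix)
    sub
  }
  out <- dplyr::full_join(one(1L, "1"), one(2L, "2"), by = "pair_id")
  out |>
    dplyr::mutate(
      mapped1 = !is.na(.data$mapped1) & .data$mapped1,
      mapped2 = !is.na(.data$mapped2) & .data$mapped2
    )
}

#' Vet mate-pairs for conservation on a second reference
#'
#' The map-method decision: a pair sampled at insert size `Ln` from the
#' generating reference is kept only if its placement on the vetting
#' reference preserves geometry. The cascade (first match wins) is:
#'
#' 1. either mate unmapped -> `UNMAPPED`;
#' 2. mates on different target sequences -> `SPLIT`;
#' 3. orientation not innie-consistent (mates must be on opposite strands
#'    with the `+`-strand mate leftmost; outie order-swaps count here) ->
#'    `INVERTED`;
#' 4. observed insert `Ln'` — the outer distance, rightmost end minus
#'    leftmost start — outside the closed interval
#'    `[(1 - tolerance) * Ln, (1 + tolerance) * Ln]` -> `LENGTH_DEVIANT`;
#' 5. otherwise `CONSERVED`, with `Ln'` recorded.
#'
#' Both interval ends are inclusive: `Ln' = 0.8 Ln` and `Ln' = 1.2 Ln`
#' are conserved at the default tolerance.
#'
#' @param pairs Tibble from [pair_alignments()].
#' @param expected_insert Insert size `Ln` in bp (scalar, or a column name
#'   already present in `pairs`).
#' @param tolerance Allowed fractional deviation of `Ln'` from `Ln`
#'   (default 0.2, i.e. the 20 percent window).
#' @return Verdict tibble: `pair_id`, `status` (factor with levels
#'   `CONSERVED`, `UNMAPPED`, `SPLIT`, `INVERTED`, `LENGTH_DEVIANT`),
#'   `expected_insert`, `observed_insert` (`NA` unless both mates mapped
#'   to the same target).
#' @export
vet_pairs <- function(pairs, expected_insert, tolerance = 0.2) {
  stopifnot(tolerance > 0, tolerance < 1)
  ln <- if (is.numeric(expected_insert)) {
    rep_len(expected_insert, nrow(pairs))
  } else {
    pairs[[expected_insert]]
  }

  both_mapped <- pairs$mapped1 & pairs$mapped2
  same_target <- both_mapped & pairs$target1 == pairs$target2

  # observed outer distance where defined
  lo <- pmin(pairs$start1, pairs$start2)
  hi <- pmax(pairs$end1, pairs$end2)
  obs <- ifelse(same_target, hi - lo, NA_real_)

  plus_first <-
    (pairs$strand1 == "+" & pairs$strand2 == "-" & pairs$start1 <= pairs$start2) |
    (pairs$strand1 == "-" & pairs$strand2 == "+" & pairs$start2 <= pairs$start1)
  innie <- same_target & !is.na(plus_first) & plus_first

  within_tol <- innie & obs >= (1 - tolerance) * ln & obs <= (1 + tolerance) * ln

  status <- dplyr::case_when(
    !both_mapped ~ "UNMAPPED",
    !same_target ~ "SPLIT",
    !innie ~ "INVERTED",
    !within_tol ~ "LENGTH_DEVIANT",
    TRUE ~ "CONSERVED"
  )
  tibble::tibble(
    pair_id = pairs$pair_id,
    status = factor(status, levels = c("CONSERVED", "UNMAPPED", "SPLIT",
                                       "INVERTED", "LENGTH_DEVIANT")),
    expected_insert = as.integer(ln),
    observed_insert = as.integer(obs)
  )
}

#' Filter a mate-pair library to its conserved pairs
#'
#' Applies [vet_pairs()] to the primary alignments of a library against
#' one vetting reference and keeps only `CONSERVED` pairs, preserving
#' pair synchronization. Pairs with a read present in the SAM but missing
#' from the library are an error; a mate missing from the SAM counts as
#' unmapped.
#'
#' @param pairs Library tibble (as from [sample_library()], or any tibble
#'   with `pair_id` and `insert_size`).
#' @param aln SAM tibble (from [read_sam()] or [truth_align()]) of the
#'   library's reads against the vetting reference, or a path to a SAM
#'   file.
#' @param tolerance Fractional insert-size tolerance (default 0.2).
#' @param vet_tag Tag of the vetting reference appended to the library
#'   name per the multi-reference convention (`"tag1-tag2**"`); `NULL`
#'   leaves the name unchanged.
#' @return The kept pairs tibble (same columns as `pairs`, `library`
#'   renamed when `vet_tag` is given), with the full verdict table in
#'   attribute `"verdicts"` (see [verdicts()]).
#' @export
filter_library <- function(pairs, aln, tolerance = 0.2, vet_tag = NULL) {
  if (is.character(aln)) aln <- read_sam(aln)
  pa <- pair_alignments(aln)
  unknown <- setdiff(pa$pair_id, pairs$pair_id)
  if (length(unknown) > 0) {
    stop("read(s) in SAM absent from library: ", unknown[1], call. = FALSE)
  }
  pa <- dplyr::left_join(dplyr::select(pairs, "pair_id", "insert_size"),
                         pa, by = "pair_id") |>
    dplyr::mutate(
      mapped1 = !is.na(.data$mapped1) & .data$mapped1,
      mapped2 = !is.na(.data$mapped2) & .data$mapped2
    )
  v <- vet_pairs(pa, "insert_size", tolerance = tolerance)
  kept <- dplyr::semi_join(
    pairs, dplyr::filter(v, .data$status == "CONSERVED"), by = "pair_id")
  if (!is.null(vet_tag)) {
    nm <- chain_name(pairs$library[1] %||% "lib*", vet_tag)
    if ("library" %in% names(kept)) kept$library <- nm
    v$library <- nm
  }
  attr(kept, "verdicts") <- v
  kept
}

#' Verdict table of a filtered library
#'
#' @param x Result of [filter_library()] or [chain_references()].
#' @return The per-pair verdict tibble.
#' @export
verdicts <- function(x) {
  attr(x, "verdicts")
}

# "mag*" vetted by "mac" -> "mag-mac**"; chaining appends before the stars
chain_name <- function(library_name, vet_tag) {
  stem <- gsub("\\*+$", "", library_name)
  paste0(stem, "-", vet_tag, "**")
}

#' Chain the conserved filter across several vetting references
#'
#' Sequential application of [filter_library()]; the survivor set is the
#' intersection of the per-reference conserved sets, and the library name
#' concatenates the reference tags with the `**` suffix
#' (`"tag1-tag2-tag3**"`). Adding a reference can never increase the kept
#' count.
#'
#' @param pairs Library tibble.
#' @param aln_list Named list of SAM tibbles (or paths), one per vetting
#'   reference, in ranked order; names are the reference tags.
#' @param tolerance Fractional insert-size tolerance (default 0.2).
#' @return Kept pairs tibble; attribute `"verdicts"` holds a list of the
#'   per-reference verdict tables (restricted, at stage k, to the pairs
#'   surviving stages 1..k-1).
#' @export
chain_references <- function(pairs, aln_list, tolerance = 0.2) {
  stopifnot(length(aln_list) >= 1, !is.null(names(aln_list)))
  all_verdicts <- list()
  kept <- pairs
  for (tag in names(aln_list)) {
    aln <- aln_list[[tag]]
    if (is.character(aln)) aln <- read_sam(aln)
    # each SAM covers the full library; restrict to the current survivors
    aln <- aln[sub("/[12]$", "", aln$qname) %in% kept$pair_id, , drop = FALSE]
    kept <- filter_library(kept, aln, tolerance = tolerance, vet_tag = tag)
    all_verdicts[[tag]] <- verdicts(kept)
  }
  attr(kept, "verdicts") <- all_verdicts
  kept
}

#' Summarize conservation verdicts per library
#'
#' @param v A verdict tibble (from [verdicts()]), or a named list of
#'   them; a `library` column, when present, groups the summary.
#' @return Tibble with one row per library and status: `n`, `fraction`
#'   (of the library total), plus per-library `n_total` and
#'   `n_conserved`. Fractions sum to 1 within each library.
#' @export
classify_report <- function(v) {
  if (is.data.frame(v)) v <- list(v)
  tbl <- dplyr::bind_rows(v, .id = "stage")
  if (nrow(tbl) == 0) {
    return(tibble::tibble(library = character(), status = character(),
                          n = integer(), fraction = numeric(),
                          n_total = integer(), n_conserved = integer()))
  }
  if (!"library" %in% names(tbl)) tbl$library <- tbl$stage
  tbl |>
    dplyr::count(.data$library, .data$status, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$library) |>
    dplyr::mutate(
      n_total = sum(.data$n),
      fraction = ifelse(.data$n_total > 0, .data$n / .data$n_total, 0),
      n_conserved = sum(.data$n[.data$status == "CONSERVED"])
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$n_total > 0) |>
    dplyr::select("library", "status", "n", "fraction", "n_total",
                  "n_conserved")
}
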