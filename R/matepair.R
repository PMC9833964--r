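#' Default insert-size ladder
#'
#' The standard ladder of mate-pair insert sizes, 500 bp to 200 kb.
#'
#' @return Integer vector of insert sizes in bp.
#' @export
default_ladder <- function() {
  c(500L, 1000L, 1500L, 2000L, 5000L, 10000L, 20000L, 50000L, 100000L, 200000L)
}

#' Offset step that achieves a target physical coverage
#'
#' With systematic sampling every `step` bases, each accepted fragment
#' contributes `2 * read_len` sequenced bases, so the achieved coverage on
#' a fully usable track is `2 * read_len / step`. Returns the largest step
#' that still meets `target_coverage`, never below 1.
#'
#' @param read_len Read length in bp.
#' @param target_coverage Desired fold coverage (default 30).
#' @return Integer step in bp.
#' @examples
#' step_for_coverage(100, 30) # 6
#' @export
step_for_coverage <- function(read_len, target_coverage = 30) {
  stopifnot(target_coverage > 0)
  max(1L, as.integer(floor(2 * read_len / target_coverage)))
}

#' Sample one in silico mate-pair library from a consensus track
#'
#' Systematic-mode sampling: candidate fragment starts are
#' `0, step, 2*step, ...` with `start + insert_size <= length(track)`. A
#' candidate is emitted iff every base of both read windows
#' `[s, s+r)` and `[s+Ln-r, s+Ln)` has depth `>= min_depth` and is not
#' `N`; the intervening gap is not gated. Read 1 is the forward window,
#' read 2 the reverse complement of the trailing window (innie pair,
#' insert measured outer edge to outer edge). Synthetic reads carry
#' constant quality `I`.
#'
#' @param track A `consensus_track`.
#' @param insert_size Exact insert size `Ln` in bp; must be `>= 2 * read_len`.
#' @param read_len Read length in bp (default 100).
#' @param step Offset step in bp; default derives from
#'   [step_for_coverage()] at `target_coverage`.
#' @param min_depth Minimum read depth for every emitted base (default 3).
#' @param target_coverage Fold coverage used when `step` is `NULL`
#'   (default 30).
#' @param library_name Library tag used in pair ids (single-reference
#'   naming convention `"<tag>*"` by default).
#' @return Tibble with one row per pair: `pair_id`, `library`,
#'   `insert_size`, `start` (fragment start on the track, 0-based),
#'   `seq1`, `qual1`, `seq2`, `qual2`. A track shorter than the insert
#'   yields zero rows.
#' @export
sample_library <- function(track, insert_size, read_len = 100L, step = NULL,
                           min_depth = 3L, target_coverage = 30,
                           library_name = paste0(track$ref_id, "*")) {
  insert_size <- as.integer(insert_size)
  read_len <- as.integer(read_len)
  if (insert_size < 2L * read_len) {
    stop("insert_size (", insert_size, ") must be >= 2 * read_len (",
         2L * read_len, ")", call. = FALSE)
  }
  step <- as.integer(step %||% step_for_coverage(read_len, target_coverage))
  stopifnot(step >= 1L, min_depth >= 0L)
  L <- nchar(track$seq)

  empty <- tibble::tibble(
    pair_id = character(), library = character(), insert_size = integer(),
    start = integer(), seq1 = character(), qual1 = character(),
    seq2 = character(), qual2 = character()
  )
  if (insert_size > L) {
    return(empty)
  }

  ok <- track$coverage >= min_depth & seq_chars(track$seq) != "N"
  # windowed all-ok test via cumulative sums: window [s, s+r) (0-based)
  cs <- c(0L, cumsum(as.integer(ok)))
  win_ok <- function(s0) cs[s0 + read_len + 1L] - cs[s0 + 1L] == read_len
  starts <- seq.int(0L, L - insert_size, by = step)
  keep <- win_ok(starts) & win_ok(starts + insert_size - read_len)
  starts <- starts[keep]
  if (length(starts) == 0) {
    return(empty)
  }

  fwd <- stringr::str_sub(track$seq, starts + 1L, starts + read_len)
  rev_win <- stringr::str_sub(track$seq, starts + insert_size - read_len + 1L,
                              starts + insert_size)
  qual <- strrep("I", read_len)
  tibble::tibble(
    pair_id = sprintf("%s:%s:%d:%d", library_name, track$ref_id,
                      insert_size, starts),
    library = library_name,
    insert_size = insert_size,
    start = starts,
    seq1 = fwd, qual1 = qual,
    seq2 = revcomp(rev_win), qual2 = qual
  )
}

#' Sample a ladder of mate-pair libraries
#'
#' Runs [sample_library()] independently for each insert size of the
#' ladder and returns one row per library with the sampled pairs nested,
#' plus the manifest columns consumed by assembler-config generation.
#'
#' @inheritParams sample_library
#' @param ladder Integer vector of unique insert sizes (default
#'   [default_ladder()]).
#' @return Tibble with columns `library`, `insert_size`, `read_len`,
#'   `step`, `n_pairs` and a list-column `pairs` of per-library tibbles.
#' @export
sample_ladder <- function(track, ladder = default_ladder(), read_len = 100L,
                          step = NULL, min_depth = 3L, target_coverage = 30,
                          library_name = paste0(track$ref_id, "*")) {
  ladder <- as.integer(ladder)
  if (length(ladder) == 0) stop("empty insert-size ladder", call. = FALSE)
  if (anyDuplicated(ladder)) {
    stop("duplicate insert sizes in ladder", call. = FALSE)
  }
  used_step <- as.integer(step %||% step_for_coverage(read_len, target_coverage))
  libs <- purrr::map(ladder, function(ins) {
    sample_library(track, ins, read_len = read_len, step = used_step,
                   min_depth = min_depth, library_name = library_name)
  })
  tibble::tibble(
    library = library_name,
    insert_size = ladder,
    read_len = as.integer(read_len),
    step = used_step,
    n_pairs = vapply(libs, nrow, integer(1)),
    pairs = libs
  )
}

#' Write a sampled ladder to per-library FASTQ pairs plus a manifest
#'
#' Files are named `<library>.<insert>.R1.fq` / `.R2.fq` under `dir`; the
#' manifest TSV (`manifest.tsv`) lists library, insert size, read length,
#' step and pair count. The `*`/`**` suffix of the library tag is dropped
#' from filenames.
#'
#' @param ladder_tbl Output of [sample_ladder()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_ladder <- function(ladder_tbl, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- gsub("\\*+$", "", ladder_tbl$library)
  for (i in seq_len(nrow(ladder_tbl))) {
    write_fastq_pairs(ladder_tbl$pairs[[i]],
                      file.path(dir, paste0(stem[i], ".",
                                            ladder_tbl$insert_size[i])))
  }
  manifest <- dplyr::select(ladder_tbl, -"pairs")
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Convert a pair tibble to per-read rows with source coordinates
#'
#' Each pair becomes two rows (`/1`, `/2`). For pairs sampled by
#' [sample_library()] the source interval of read 1 is `[start, start+r)`
#' on the forward strand and of read 2 `[start+Ln-r, start+Ln)` on the
#' reverse strand — the coordinates [truth_align()] consumes.
#'
#' @param pairs Tibble with `pair_id`, `insert_size`, `start`, `seq1`,
#'   `qual1`, `seq2`, `qual2`.
#' @return Tibble with `id`, `pair_id`, `mate` (1 or 2), `seq`, `qual`,
#'   `src_start`, `src_strand`.
#' @export
pairs_to_reads <- function(pairs) {
  r <- nchar(pairs$seq1)
  dplyr::bind_rows(
    tibble::tibble(id = paste0(pairs$pair_id, "/1"), pair_id = pairs$pair_id,
                   mate = 1L, seq = pairs$seq1, qual = pairs$qual1,
                   src_start = pairs$start, src_strand = "+"),
    tibble::tibble(id = paste0(pairs$pair_id, "/2"), pair_id = pairs$pair_id,
                   mate = 2L, seq = pairs$seq2, qual = pairs$qual2,
                   src_start = pairs$start + pairs$insert_size - nchar(pairs$seq2),
                   src_strand = "-")
  ) |>
    dplyr::arrange(.data$pair_id, .data$mate)
}
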