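#' Summarize one draft-vs-reference PAF alignment
#'
#' Computes the alignment characters used to rank candidate reference
#' genomes: the fraction of draft bases inside alignment blocks (overlaps
#' merged, so nothing is double-counted), the mean identity
#' (total matches over total block length), and the block count.
#'
#' @param paf PAF tibble (from [read_paf()]) of one draft assembly
#'   aligned to one candidate reference.
#' @param draft_len_total Total draft assembly length in bp (> 0).
#' @param ref_tag Tag identifying the candidate reference.
#' @return One-row tibble: `ref_tag`, `aligned_fraction`, `mean_identity`,
#'   `n_blocks`, `total_draft_len`.
#' @export
summarize_paf <- function(paf, draft_len_total, ref_tag = "ref") {
  if (draft_len_total <= 0) {
    stop("draft_len_total must be positive", call. = FALSE)
  }
  if (nrow(paf) == 0) {
    return(tibble::tibble(ref_tag = ref_tag, aligned_fraction = 0,
                          mean_identity = 0, n_blocks = 0L,
                          total_draft_len = as.numeric(draft_len_total)))
  }
  # merge per query sequence: shift each query into its own disjoint frame
  qid <- match(paf$query_id, unique(paf$query_id))
  offset <- (qid - 1) * (max(paf$query_len) + 1)
  merged <- IRanges::reduce(IRanges::IRanges(
    start = paf$query_start + 1 + offset, end = paf$query_end + offset))
  aligned <- sum(IRanges::width(merged))
  tibble::tibble(
    ref_tag = ref_tag,
    aligned_fraction = min(1, aligned / draft_len_total),
    mean_identity = sum(paf$n_matches) / sum(paf$block_len),
    n_blocks = nrow(paf),
    total_draft_len = as.numeric(draft_len_total)
  )
}

#' Rank candidate references by alignment score
#'
#' Score = `aligned_fraction * mean_identity`, so both completeness of
#' the alignment and closeness of the reference matter. Ties break toward
#' fewer blocks (less fragmented alignment), then lexically by tag; the
#' result is invariant to input order.
#'
#' @param summaries Tibble of rows from [summarize_paf()] (one per
#'   candidate), or a list of such rows.
#' @return Tibble ordered by rank: `rank` (dense 1..k), `ref_tag`,
#'   `score`, plus the summary columns.
#' @export
rank_references <- function(summaries) {
  tbl <- dplyr::bind_rows(summaries)
  if (nrow(tbl) == 0) stop("no alignment summaries to rank", call. = FALSE)
  tbl |>
    dplyr::mutate(score = .data$aligned_fraction * .data$mean_identity) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$n_blocks, .data$ref_tag) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "ref_tag", "score", dplyr::everything())
}
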