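#' Simulate ancient-DNA-like single-end reads from forward reads
#'
#' Ancient DNA is highly fragmented (tens to ~170 bp), precluding
#' laboratory mate-pair libraries. This simulator emulates that from
#' modern data: each forward read is cut to a random-length 5'-anchored
#' prefix, the length drawn uniformly from the closed integer interval
#' `[min_len, min(max_len, read length)]`. Reads shorter than `min_len`
#' are dropped and counted. Qualities are cut alongside the bases.
#' Deterministic for a fixed seed and input order.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (e.g. from
#'   [read_fastq()]); conventionally the forward (R1) mates.
#' @param min_len Minimum output length in bp (default 80).
#' @param max_len Maximum output length in bp (default 100).
#' @param seed Integer seed.
#' @return Tibble `id`, `seq`, `qual` of the truncated reads, in input
#'   order, with attribute `"counts"` = named integer vector
#'   `c(n_in, n_out, n_dropped)`.
#' @examples
#' r <- tibble::tibble(id = "r1", seq = strrep("ACGT", 40),
#'                     qual = strrep("I", 160))
#' nchar(simulate_adna(r, seed = 1)$seq)
#' @export
simulate_adna <- function(reads, min_len = 80L, max_len = 100L, seed = 1L) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  stopifnot(min_len > 0, min_len <= max_len)
  keep <- nchar(reads$seq) >= min_len
  out <- reads[keep, , drop = FALSE]
  hi <- pmin(max_len, nchar(out$seq))
  lens <- withr::with_seed(seed, {
    min_len + floor(stats::runif(nrow(out)) * (hi - min_len + 1))
  })
  lens <- as.integer(pmin(lens, hi)) # guard the open upper edge of runif
  out$seq <- substr(out$seq, 1L, lens)
  out$qual <- substr(out$qual, 1L, lens)
  counts <- c(n_in = nrow(reads), n_out = nrow(out),
              n_dropped = sum(!keep))
  message(sprintf("simulate_adna: in=%d out=%d dropped=%d",
                  counts[1], counts[2], counts[3]))
  attr(out, "counts") <- counts
  out
}
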