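#' Build a majority-rule consensus and coverage track from alignments
#'
#' Computes, for one repeat-masked reference sequence, a per-position
#' consensus of the target-species reads aligned to it, plus the read
#' depth at every position. This is the substrate in silico mate-pairs
#' are cut from.
#'
#' Rules, applied column-wise over primary mapped records only:
#' * depth at position *i* counts reads whose `M`/`=`/`X` CIGAR ops cover
#'   *i* (insertions consume query only; deletions leave the reference
#'   base and do not add depth);
#' * the consensus base is the majority base among covering reads, with
#'   ties broken toward the reference base (ties among non-reference
#'   bases fall back to alphabetical order, a documented determinism
#'   choice);
#' * positions with zero depth keep the reference base;
#' * masked reference positions (lowercase or `N`) are forced to `N` in
#'   the consensus while their true depth is still recorded.
#'
#' Base qualities are ignored in the vote and no ambiguity codes are ever
#' emitted.
#'
#' @param reference One-row tibble (or list) with `id` and `seq`, e.g. a
#'   row of [read_fasta()].
#' @param alignments Alignment tibble as from [read_sam()]; records must
#'   carry `seq`. Records not mapped to `reference$id`, unmapped records
#'   and secondary/supplementary records are skipped.
#' @return A `consensus_track`: list with `ref_id`, `seq` (consensus,
#'   alphabet `A,C,G,T,N`), and integer `coverage` of equal length.
#' @examples
#' ref <- tibble::tibble(id = "r", seq = "ACGTACGT")
#' build_consensus(ref, read_sam(character()))
#' @export
build_consensus <- function(reference, alignments) {
  ref_id <- reference$id[[1]]
  ref_seq <- reference$seq[[1]]
  L <- nchar(ref_seq)
  ref_chars <- seq_chars(ref_seq)
  masked <- is_masked_base(ref_chars)
  ref_upper <- toupper(ref_chars)

  aln <- dplyr::filter(alignments, .data$mapped,
                       .data$target_id == ref_id,
                       !.data$is_secondary_or_supplementary)
  coverage <- integer(L)
  counts <- matrix(0L, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))

  if (nrow(aln) > 0) {
    # expand each M/=/X run into (target position, query base) pairs;
    # single-run CIGARs (the overwhelming majority) are vectorized
    simple <- grepl("^[0-9]+[M=X]$", aln$cigar)
    runs_simple <- tibble::tibble(
      t0 = aln$pos[simple],
      q0 = 0L,
      len = as.integer(sub("[M=X]$", "", aln$cigar[simple])),
      read = which(simple)
    )
    runs_complex <- purrr::map_dfr(which(!simple), function(i) {
      ops <- parse_cigar(aln$cigar[i])
      tpos <- aln$pos[i]
      qpos <- 0L
      out <- vector("list", nrow(ops))
      for (j in seq_len(nrow(ops))) {
        op <- ops$op[j]; len <- ops$len[j]
        if (op %in% c("M", "=", "X")) {
          out[[j]] <- list(t0 = tpos, q0 = qpos, len = len, read = i)
          tpos <- tpos + len; qpos <- qpos + len
        } else if (op %in% c("D", "N")) {
          tpos <- tpos + len
        } else if (op %in% c("I", "S")) {
          qpos <- qpos + len
        }
      }
      dplyr::bind_rows(out)
    })
    runs <- dplyr::bind_rows(runs_simple, runs_complex)
    if (nrow(runs) > 0) {
      ends <- runs$t0 + runs$len
      if (any(ends > L)) {
        bad <- runs$read[which(ends > L)[1]]
        stop("alignment for read ", aln$qname[bad],
             " extends beyond reference end", call. = FALSE)
      }
      tpos_all <- sequence(runs$len, from = runs$t0 + 1L) # 1-based
      qbase_all <- unlist(strsplit(toupper(stringr::str_sub(
        aln$seq[runs$read],
        start = runs$q0 + 1L, end = runs$q0 + runs$len)), "", fixed = TRUE))
      coverage <- tabulate(tpos_all, nbins = L)
      for (b in c("A", "C", "G", "T")) {
        sel <- qbase_all == b
        if (any(sel)) counts[b, ] <- tabulate(tpos_all[sel], nbins = L)
      }
    }
  }

  # majority vote with reference tie-break
  cons <- ref_upper
  covered <- coverage > 0
  if (any(covered)) {
    idx <- which(covered)
    sub <- counts[, idx, drop = FALSE]
    best <- pmax(sub[1, ], sub[2, ], sub[3, ], sub[4, ])
    ref_rows <- match(ref_upper[idx], c("A", "C", "G", "T"))
    ref_cnt <- ifelse(is.na(ref_rows), -1L,
                      sub[cbind(ref_rows, seq_along(idx))])
    take_ref <- ref_cnt == best
    # argmax with alphabetical fallback among tied non-reference bases
    arg <- rep("A", length(idx))
    arg[sub[2, ] > sub[1, ]] <- "C"
    arg[sub[3, ] > pmax(sub[1, ], sub[2, ])] <- "G"
    arg[sub[4, ] > pmax(sub[1, ], sub[2, ], sub[3, ])] <- "T"
    cons[idx] <- ifelse(take_ref, ref_upper[idx], arg)
  }
  cons[masked] <- "N"
  cons[!masked & !(cons %in% c("A", "C", "G", "T"))] <- "N"

  structure(
    list(ref_id = ref_id, seq = paste(cons, collapse = ""),
         coverage = coverage),
    class = "consensus_track"
  )
}

#' @export
print.consensus_track <- function(x, ...) {
  cat("<consensus_track> ", x$ref_id, ": ", nchar(x$seq), " bp, ",
      "median depth ", stats::median(x$coverage), ", ",
      sum(seq_chars(x$seq) == "N"), " N positions\n", sep = "")
  invisible(x)
}

#' One-row summary of a consensus track
#'
#' @param x A `consensus_track`.
#' @param ... Unused.
#' @return Tibble with length, depth summaries and the masked fraction.
#' @method glance consensus_track
#' @export
glance.consensus_track <- function(x, ...) {
  tibble::tibble(
    ref_id = x$ref_id,
    length = nchar(x$seq),
    mean_depth = mean(x$coverage),
    median_depth = stats::median(x$coverage),
    frac_n = mean(seq_chars(x$seq) == "N")
  )
}

#' Write the coverage sidecar of a consensus track as BedGraph
#'
#' Intervals are 0-based half-open with integer depth, run-length
#' compressed.
#'
#' @param track A `consensus_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  readr::write_lines(
    sprintf("%s\t%d\t%d\t%d", track$ref_id, starts, ends, r$values), path)
  invisible(path)
}
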