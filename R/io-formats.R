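#' Read a FASTA file into a tibble
#'
#' Sequences are returned one row per record with masking state preserved:
#' soft-masked bases stay lowercase and hard-masked bases stay `N`
#' (parsing goes through [Biostrings::readBStringSet()], which keeps case).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACgtN"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    stop("no sequences in ", path, call. = FALSE)
  }
  ids <- stringr::str_split_i(names(set), "\\s+", 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(id = ids, seq = as.character(unname(set)))
}

#' Write a tibble of sequences to FASTA
#'
#' @param x Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for wrapping sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    body <- x$seq[i]
    starts <- seq(1L, nchar(body), by = width)
    writeLines(substring(body, starts, pmin(starts + width - 1L, nchar(body))), con)
  }
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `id`, `seq`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0) {
    return(tibble::tibble(id = character(), seq = character(), qual = character()))
  }
  if (length(lines) %% 4 != 0) {
    stop("FASTQ line count not a multiple of 4: ", path, call. = FALSE)
  }
  i <- seq(1L, length(lines), by = 4L)
  ids <- sub("^@", "", stringr::str_split_i(lines[i], "\\s+", 1))
  out <- tibble::tibble(id = ids, seq = lines[i + 1L], qual = lines[i + 3L])
  bad <- nchar(out$seq) != nchar(out$qual)
  if (any(bad)) {
    stop("base/quality length mismatch for read ", out$id[which(bad)[1]],
         call. = FALSE)
  }
  out
}

#' Write reads to FASTQ
#'
#' Writes 4-line-per-read FASTQ. Read ids must be unique within the file
#' and base and quality strings must have equal length. Zero reads yield
#' an empty file.
#'
#' @param x Tibble with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(x)))
  if (nrow(x) > 0) {
    if (anyDuplicated(x$id)) {
      stop("duplicate read ids in FASTQ output", call. = FALSE)
    }
    if (any(nchar(x$seq) != nchar(x$qual))) {
      stop("base/quality length mismatch", call. = FALSE)
    }
  }
  out <- character(4L * nrow(x))
  if (nrow(x) > 0) {
    idx <- (seq_len(nrow(x)) - 1L) * 4L
    out[idx + 1L] <- paste0("@", x$id)
    out[idx + 2L] <- x$seq
    out[idx + 3L] <- "+"
    out[idx + 4L] <- x$qual
  }
  readr::write_lines(out, path)
  invisible(path)
}

#' Write a mate-pair library to two synchronized FASTQ files
#'
#' Mate 1 goes to `<prefix>.R1.fq` with id suffix `/1`, mate 2 to
#' `<prefix>.R2.fq` with `/2`, in the same pair order.
#'
#' @param pairs Tibble with columns `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  p1 <- paste0(prefix, ".R1.fq")
  p2 <- paste0(prefix, ".R2.fq")
  write_fastq(tibble::tibble(id = paste0(pairs$pair_id, "/1"),
                             seq = pairs$seq1, qual = pairs$qual1), p1)
  write_fastq(tibble::tibble(id = paste0(pairs$pair_id, "/2"),
                             seq = pairs$seq2, qual = pairs$qual2), p2)
  invisible(c(p1, p2))
}

# SAM FLAG bits used by the package
FLAG_PAIRED <- 0x1L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

#' Read a SAM file into a tibble of alignment records
#'
#' Text SAM only (the pipeline's cross-tool contract); `@` headers are
#' tolerated and optional tags are ignored. SAM's 1-based `POS` is
#' converted to the package-wide 0-based convention, and FLAG bits are
#' decoded into logical columns.
#'
#' @param x Path to a SAM file, or a character vector of SAM lines.
#' @return A tibble with one row per record: `qname`, `flag`, `mapped`,
#'   `strand` (`+`/`-`, `NA` when unmapped), `target_id`, `pos` (0-based
#'   leftmost position, `NA` when unmapped), `mapq`, `cigar`, `mate_mapped`,
#'   `mate_target_id`, `mate_pos` (0-based), `is_first_mate`,
#'   `is_secondary_or_supplementary`, `seq`, `qual`.
#' @export
read_sam <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readr::read_lines(x) else x
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      qname = character(), flag = integer(), mapped = logical(),
      strand = character(), target_id = character(), pos = integer(),
      mapq = integer(), cigar = character(), mate_mapped = logical(),
      mate_target_id = character(), mate_pos = integer(),
      is_first_mate = logical(), is_secondary_or_supplementary = logical(),
      seq = character(), qual = character()
    ))
  }
  f <- stringr::str_split(lines, "\t")
  nf <- lengths(f)
  if (any(nf < 11)) {
    stop("SAM line ", which(nf < 11)[1], " has fewer than 11 fields",
         call. = FALSE)
  }
  col <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(col(2))
  mapped <- bitwAnd(flag, FLAG_UNMAPPED) == 0L
  paired <- bitwAnd(flag, FLAG_PAIRED) != 0L
  rname <- col(3)
  rnext <- col(7)
  rnext <- ifelse(rnext == "=", rname, rnext)
  out <- tibble::tibble(
    qname = col(1),
    flag = flag,
    mapped = mapped,
    strand = ifelse(mapped, ifelse(bitwAnd(flag, FLAG_REVERSE) != 0L, "-", "+"),
                    NA_character_),
    target_id = ifelse(mapped, rname, NA_character_),
    pos = ifelse(mapped, as.integer(col(4)) - 1L, NA_integer_),
    mapq = as.integer(col(5)),
    cigar = col(6),
    mate_mapped = paired & bitwAnd(flag, FLAG_MATE_UNMAPPED) == 0L,
    mate_target_id = ifelse(rnext == "*", NA_character_, rnext),
    mate_pos = ifelse(col(8) == "0", NA_integer_, as.integer(col(8)) - 1L),
    is_first_mate = !paired | bitwAnd(flag, FLAG_FIRST) != 0L,
    is_secondary_or_supplementary =
      bitwAnd(flag, FLAG_SECONDARY + FLAG_SUPPLEMENTARY) != 0L,
    seq = col(10),
    qual = col(11)
  )
  # CIGAR must consume the stored read length when both are present
  has_seq <- out$mapped & out$seq != "*" & out$cigar != "*"
  if (any(has_seq)) {
    qlen <- vapply(out$cigar[has_seq], cigar_query_len, numeric(1))
    bad <- qlen != nchar(out$seq[has_seq])
    if (any(bad)) {
      stop("CIGAR/sequence length mismatch at SAM line ",
           which(has_seq)[which(bad)[1]], call. = FALSE)
    }
  }
  out
}

#' Write alignment records to a SAM file
#'
#' Inverse of [read_sam()]: internal 0-based positions become 1-based SAM
#' `POS`. Reference lengths, when given, are emitted as `@SQ` headers.
#'
#' @param aln Tibble in the layout produced by [read_sam()].
#' @param path Output path.
#' @param ref_lens Optional named integer vector of reference lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, ref_lens = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:unknown"
  if (!is.null(ref_lens)) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lens),
                          as.integer(ref_lens)))
  }
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
    aln$qname, aln$flag,
    ifelse(aln$mapped, aln$target_id, "*"),
    ifelse(aln$mapped, aln$pos + 1L, 0L),
    aln$mapq %||% rep(60L, nrow(aln)),
    ifelse(aln$mapped, aln$cigar, "*"),
    ifelse(is.na(aln$mate_target_id), "*", aln$mate_target_id),
    ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos + 1L),
    aln$seq, aln$qual
  )
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}

#' Read a PAF file into a tibble
#'
#' Only the 12 standard columns are kept (tags dropped); coordinates are
#' already 0-based half-open in PAF and are left untouched.
#'
#' @param path Path to a PAF file.
#' @return Tibble with columns `query_id`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `target_id`, `target_len`, `target_start`,
#'   `target_end`, `n_matches`, `block_len`, `mapq`.
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  cols <- c("query_id", "query_len", "query_start", "query_end", "strand",
            "target_id", "target_len", "target_start", "target_end",
            "n_matches", "block_len", "mapq")
  if (length(lines) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      list(character(), integer(), integer(), integer(), character(),
           character(), integer(), integer(), integer(), integer(),
           integer(), integer()), cols))
    return(out)
  }
  f <- stringr::str_split(lines, "\t")
  if (any(lengths(f) < 12)) {
    stop("PAF line with fewer than 12 columns", call. = FALSE)
  }
  col <- function(i) vapply(f, `[[`, character(1), i)
  out <- tibble::tibble(
    query_id = col(1), query_len = as.integer(col(2)),
    query_start = as.integer(col(3)), query_end = as.integer(col(4)),
    strand = col(5),
    target_id = col(6), target_len = as.integer(col(7)),
    target_start = as.integer(col(8)), target_end = as.integer(col(9)),
    n_matches = as.integer(col(10)), block_len = as.integer(col(11)),
    mapq = as.integer(col(12))
  )
  bad <- with(out, query_start >= query_end | query_end > query_len |
                target_start >= target_end | target_end > target_len)
  if (any(bad)) {
    stop("PAF record with invalid interval at line ", which(bad)[1],
         call. = FALSE)
  }
  out
}
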