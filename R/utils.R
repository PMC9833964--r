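#' Reverse-complement DNA strings
#'
#' Case-preserving reverse complement for a character vector of DNA
#' sequences. `N`/`n` are their own complement; no other IUPAC ambiguity
#' codes are accepted downstream, so none are translated.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N,a,c,g,t,n}`.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' Test whether bases are masked
#'
#' Shared masking predicate: a base counts as masked when it is
#' soft-masked (lowercase) or hard-masked (`N`). Downstream consumers
#' (consensus, mate-pair sampling) treat both states identically.
#'
#' @param bases Character vector of single bases.
#' @return Logical vector.
#' @export
is_masked_base <- function(bases) {
  bases %in% c("a", "c", "g", "t", "n", "N")
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

# parse a CIGAR string into a tibble of (op, len); "*" -> zero rows
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    return(tibble::tibble(op = character(), len = integer()))
  }
  lens <- as.integer(stringr::str_extract_all(cigar, "\\d+")[[1]])
  ops <- stringr::str_extract_all(cigar, "[MIDNSHP=X]")[[1]]
  if (length(lens) != length(ops)) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  tibble::tibble(op = ops, len = lens)
}

# query length consumed by a CIGAR (M, I, S, =, X)
cigar_query_len <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

# reference span consumed by a CIGAR (M, D, N, =, X)
cigar_ref_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
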