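# Independent oracles and tiny fixture builders shared across tests.
# These deliberately re-derive results from first principles (plain loops
# over raw fields) so they cannot share a bug with the implementation.

# construct a consensus_track directly
tiny_track <- function(seq, coverage = rep(100L, nchar(seq)), ref_id = "ref") {
  structure(list(ref_id = ref_id, seq = seq, coverage = as.integer(coverage)),
            class = "consensus_track")
}

# brute-force enumeration of valid systematic-mode fragment starts:
# scan every candidate offset and test both read windows base by base
brute_force_starts <- function(track, insert_size, read_len, step, min_depth) {
  L <- nchar(track$seq)
  ch <- strsplit(track$seq, "")[[1]]
  if (insert_size > L) return(integer())
  starts <- integer()
  s <- 0L
  while (s + insert_size <= L) {
    w1 <- (s + 1L):(s + read_len)
    w2 <- (s + insert_size - read_len + 1L):(s + insert_size)
    ok <- all(track$coverage[w1] >= min_depth) &&
      all(track$coverage[w2] >= min_depth) &&
      all(ch[w1] != "N") && all(ch[w2] != "N")
    if (ok) starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# random track with masked and low-depth patches, for property tests
random_track <- function(seed) {
  set.seed(seed)
  L <- sample(200:5000, 1)
  ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cov <- rep(sample(3:40, 1), L)
  for (k in seq_len(sample(0:4, 1))) { # N patches
    w <- sample(10:200, 1)
    s <- sample(L - w, 1)
    ch[s:(s + w - 1)] <- "N"
  }
  for (k in seq_len(sample(0:4, 1))) { # low-depth patches
    w <- sample(10:200, 1)
    s <- sample(L - w, 1)
    cov[s:(s + w - 1)] <- sample(0:2, 1)
  }
  tiny_track(paste(ch, collapse = ""), cov)
}

# independent conserved-pair verdict recomputed from raw SAM text lines:
# re-parses fields and FLAG bits without read_sam()/pair_alignments()
brute_force_verdict <- function(line1, line2, ln, tol = 0.2) {
  parse <- function(line) {
    f <- strsplit(line, "\t")[[1]]
    flag <- as.integer(f[2])
    cigar <- f[6]
    span <- 0L
    if (cigar != "*") {
      toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
      for (t in toks) {
        op <- substr(t, nchar(t), nchar(t))
        if (op %in% c("M", "D", "N", "=", "X")) {
          span <- span + as.integer(substr(t, 1, nchar(t) - 1))
        }
      }
    }
    list(mapped = bitwAnd(flag, 4L) == 0L,
         rev = bitwAnd(flag, 16L) != 0L,
         rname = f[3],
         pos = as.integer(f[4]) - 1L,
         end = as.integer(f[4]) - 1L + span)
  }
  a <- parse(line1)
  b <- parse(line2)
  if (!a$mapped || !b$mapped) return(list(status = "UNMAPPED", obs = NA))
  if (a$rname != b$rname) return(list(status = "SPLIT", obs = NA))
  obs <- max(a$end, b$end) - min(a$pos, b$pos)
  innie <- (!a$rev && b$rev && a$pos <= b$pos) ||
    (a$rev && !b$rev && b$pos <= a$pos)
  if (!innie) return(list(status = "INVERTED", obs = obs))
  if (obs < (1 - tol) * ln || obs > (1 + tol) * ln) {
    return(list(status = "LENGTH_DEVIANT", obs = obs))
  }
  list(status = "CONSERVED", obs = obs)
}

# build a one-line SAM record (1-based POS) for hand-made fixtures
sam_line <- function(qname, flag, rname, pos1, cigar, seq = "*", qual = "*",
                     rnext = "*", pnext = 0, mapq = 60) {
  paste(qname, flag, rname, pos1, mapq, cigar, rnext, pnext, 0, seq, qual,
        sep = "\t")
}

# small shared two-reference scenario for filter/chain tests (cached)
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- scenario_two_reference(length = 60000L, seed = 7L,
                                       coverage = 20)
    }
    cache
  }
})
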