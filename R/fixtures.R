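#' Generate a random genome with soft-masked repeats
#'
#' Produces an ancestral genome for synthetic experiments: i.i.d. bases
#' at the requested GC content, with planted tandem repeats occupying
#' approximately `repeat_fraction` of the sequence. Repeats are
#' soft-masked (lowercase), emulating a RepeatMasker-style masked
#' reference. Deterministic per seed.
#'
#' @param length Genome length in bp.
#' @param gc GC content in `[0, 1]` (default 0.41, a typical vertebrate
#'   value).
#' @param repeat_fraction Fraction of the genome occupied by planted
#'   repeats, in `[0, 1)` (default 0.05).
#' @param repeat_unit_len Repeat unit length in bp (default 200).
#' @param seed Integer seed.
#' @param id Sequence id.
#' @return A `sim_genome`: list with `id`, `seq` (masked bases lowercase),
#'   `length`, `mask` (tibble of 0-based half-open masked intervals), and
#'   `truth = NULL` (an ancestor maps to itself).
#' @export
make_genome <- function(length, gc = 0.41, repeat_fraction = 0.05,
                        repeat_unit_len = 200L, seed = 1L, id = "anc") {
  stopifnot(gc >= 0, gc <= 1, repeat_fraction >= 0, repeat_fraction < 1)
  length <- as.integer(length)
  withr::with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    target_rep <- floor(repeat_fraction * length)
    intervals <- list()
    occupied <- rep(FALSE, length)
    placed <- 0L
    tries <- 0L
    while (placed < target_rep && target_rep >= repeat_unit_len &&
           tries < 1000L) {
      tries <- tries + 1L
      n_copies <- sample(2:4, 1)
      unit <- sample(c("A", "C", "G", "T"), repeat_unit_len, replace = TRUE,
                     prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      w <- repeat_unit_len * n_copies
      if (w > length) next
      s <- sample.int(length - w + 1L, 1) - 1L # 0-based
      if (any(occupied[(s + 1L):(s + w)])) next
      occupied[(s + 1L):(s + w)] <- TRUE
      bases[(s + 1L):(s + w)] <- tolower(rep(unit, n_copies))
      intervals[[length(intervals) + 1L]] <- c(s, s + w)
      placed <- placed + w
    }
    mask <- if (length(intervals) == 0) {
      tibble::tibble(start = integer(), end = integer())
    } else {
      m <- do.call(rbind, intervals)
      tibble::tibble(start = m[, 1], end = m[, 2]) |> dplyr::arrange(.data$start)
    }
    structure(
      list(id = id, seq = paste(bases, collapse = ""), length = length,
           mask = mask, truth = NULL),
      class = "sim_genome"
    )
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", x$id, ": ", x$length, " bp, ",
      nrow(x$mask), " masked interval(s)",
      if (!is.null(x$truth)) ", derived (truth map attached)", "\n", sep = "")
  invisible(x)
}

# per-base truth arrays of a genome: ancestor position (0-based, NA for
# inserted bases) and strand (+1/-1) for every base
truth_of <- function(genome) {
  if (is.null(genome$truth)) {
    list(anc = 0:(genome$length - 1L), strand = rep(1L, genome$length))
  } else {
    genome$truth
  }
}

check_intervals <- function(iv, L) {
  if (is.null(iv) || nrow(iv) == 0) return(invisible())
  stopifnot(all(iv$start >= 0), all(iv$length > 0),
            all(iv$start + iv$length <= L))
  o <- order(iv$start)
  s <- iv$start[o]; e <- iv$start[o] + iv$length[o]
  if (any(s[-1] < e[-length(e)])) {
    stop("overlapping rearrangement intervals", call. = FALSE)
  }
  invisible()
}

#' Derive a diverged genome from an ancestor
#'
#' Applies structural rearrangements (inversions, then translocations),
#' then point mutations (SNPs and indels) outside rearrangement
#' breakpoint bases, and returns the derived genome together with an
#' exact per-base truth map back to the ancestor. Masking (lowercase)
#' travels with the bases. Deterministic per seed.
#'
#' Divergence presets used in the package's synthetic experiments:
#' a congener-like reference is ~2-4 percent SNPs with a few
#' rearrangements; a family-level reference ~10 percent or more with
#' more rearrangements.
#'
#' @param genome A `sim_genome` (the ancestor).
#' @param snp_rate Per-base substitution probability in `[0, 1)`.
#' @param indel_rate Per-base indel initiation probability in `[0, 1)`.
#' @param indel_max_len Maximum indel length in bp (lengths uniform on
#'   `1..indel_max_len`, insertion or deletion with equal probability).
#' @param inversions Tibble (`start`, `length`), 0-based ancestor
#'   coordinates; intervals must not overlap each other or translocations.
#' @param translocations Tibble (`start`, `length`, `new_start`);
#'   the excised block is reinserted before the ancestor coordinate
#'   `new_start`, which must lie outside every rearranged interval.
#' @param seed Integer seed.
#' @param id Sequence id of the derived genome.
#' @return A `sim_genome` whose `truth` holds per-base `anc` (0-based
#'   ancestor coordinate, `NA` for inserted bases) and `strand`
#'   (`+1`/`-1`); `segments(x)` gives the piecewise-collinear
#'   decomposition.
#' @export
evolve <- function(genome, snp_rate = 0, indel_rate = 0, indel_max_len = 10L,
                   inversions = NULL, translocations = NULL, seed = 1L,
                   id = paste0(genome$id, "_derived")) {
  stopifnot(snp_rate >= 0, snp_rate < 1, indel_rate >= 0, indel_rate < 1)
  L <- genome$length
  both <- dplyr::bind_rows(
    if (!is.null(inversions) && nrow(inversions) > 0)
      dplyr::select(inversions, "start", "length"),
    if (!is.null(translocations) && nrow(translocations) > 0)
      dplyr::select(translocations, "start", "length")
  )
  check_intervals(both, L)
  if (!is.null(translocations) && nrow(translocations) > 0) {
    inside <- vapply(translocations$new_start, function(p) {
      any(p > both$start & p < both$start + both$length)
    }, logical(1))
    if (any(inside)) {
      stop("translocation destination inside a rearranged interval",
           call. = FALSE)
    }
  }

  b <- seq_chars(genome$seq)
  anc <- 0:(L - 1L)
  strand <- rep(1L, L)

  if (!is.null(inversions) && nrow(inversions) > 0) {
    for (i in seq_len(nrow(inversions))) {
      s <- inversions$start[i]; len <- inversions$length[i]
      r <- (s + 1L):(s + len)
      b[r] <- rev(chartr("ACGTNacgtn", "TGCANtgcan", b[r]))
      anc[r] <- rev(anc[r])
      strand[r] <- -rev(strand[r])
    }
  }
  if (!is.null(translocations) && nrow(translocations) > 0) {
    for (i in seq_len(nrow(translocations))) {
      s <- translocations$start[i]; len <- translocations$length[i]
      dest <- translocations$new_start[i]
      cur <- which(anc >= s & anc < s + len & !is.na(anc))
      cur <- cur[order(cur)]
      keep <- setdiff(seq_along(b), cur)
      block <- list(b = b[cur], anc = anc[cur], strand = strand[cur])
      b <- b[keep]; anc <- anc[keep]; strand <- strand[keep]
      ins_at <- sum(anc < dest, na.rm = TRUE) # insert after this many
      b <- append(b, block$b, after = ins_at)
      anc <- append(anc, block$anc, after = ins_at)
      strand <- append(strand, block$strand, after = ins_at)
    }
  }

  withr::with_seed(seed, {
    # breakpoint bases: where adjacency with the next base is not collinear
    n <- length(b)
    adj_ok <- !is.na(anc[-n]) & !is.na(anc[-1]) &
      strand[-n] == strand[-1] & (anc[-1] - anc[-n]) == strand[-n]
    near_break <- rep(FALSE, n)
    near_break[which(!adj_ok)] <- TRUE
    near_break[which(!adj_ok) + 1L] <- TRUE

    if (snp_rate > 0) {
      hit <- which(stats::runif(n) < snp_rate & !near_break)
      if (length(hit) > 0) {
        old <- toupper(b[hit])
        pick <- vapply(old, function(x) {
          sample(setdiff(c("A", "C", "G", "T"), x), 1)
        }, character(1), USE.NAMES = FALSE)
        lower <- b[hit] %in% c("a", "c", "g", "t", "n")
        b[hit] <- ifelse(lower, tolower(pick), pick)
      }
    }
    if (indel_rate > 0) {
      sites <- which(stats::runif(n) < indel_rate & !near_break)
      if (length(sites) > 0) {
        lens <- sample.int(indel_max_len, length(sites), replace = TRUE)
        is_del <- stats::runif(length(sites)) < 0.5
        ins_bases <- lapply(lens, function(k) {
          sample(c("A", "C", "G", "T"), k, replace = TRUE)
        })
        for (j in rev(seq_along(sites))) { # back-to-front keeps indices valid
          p <- sites[j]
          if (is_del[j]) {
            drop_idx <- p:min(length(b), p + lens[j] - 1L)
            b <- b[-drop_idx]; anc <- anc[-drop_idx]; strand <- strand[-drop_idx]
          } else {
            b <- append(b, ins_bases[[j]], after = p)
            anc <- append(anc, rep(NA_integer_, lens[j]), after = p)
            strand <- append(strand, rep(NA_integer_, lens[j]), after = p)
          }
        }
      }
    }
    low <- b %in% c("a", "c", "g", "t", "n")
    r <- rle(low)
    ends <- cumsum(r$lengths)
    mask <- tibble::tibble(start = (ends - r$lengths)[r$values],
                           end = ends[r$values])
    structure(
      list(id = id, seq = paste(b, collapse = ""), length = length(b),
           mask = mask,
           truth = list(anc = as.integer(anc), strand = as.integer(strand))),
      class = "sim_genome"
    )
  })
}

#' Piecewise-collinear segments of a derived genome's truth map
#'
#' Run-length decomposition of the per-base truth map: consecutive bases
#' belong to one segment while the ancestor coordinate advances by the
#' segment strand. Inserted bases form `NA` segments.
#'
#' @param genome A derived `sim_genome` (from [evolve()]).
#' @return Tibble with 0-based half-open `der_start`, `der_end`,
#'   `anc_start`, `anc_end`, and `strand` (`+`/`-`, `NA` for insertions).
#' @export
segments <- function(genome) {
  tr <- truth_of(genome)
  n <- length(tr$anc)
  adj_ok <- !is.na(tr$anc[-n]) & !is.na(tr$anc[-1]) &
    tr$strand[-n] == tr$strand[-1] &
    (tr$anc[-1] - tr$anc[-n]) == tr$strand[-n]
  adj_na <- is.na(tr$anc[-n]) & is.na(tr$anc[-1])
  new_seg <- c(TRUE, !(adj_ok | adj_na))
  seg_id <- cumsum(new_seg)
  starts <- which(new_seg)
  ends <- c(starts[-1] - 1L, n)
  tibble::tibble(
    der_start = starts - 1L,
    der_end = ends,
    anc_start = ifelse(is.na(tr$anc[starts]), NA_integer_,
                       pmin(tr$anc[starts], tr$anc[ends])),
    anc_end = ifelse(is.na(tr$anc[starts]), NA_integer_,
                     pmax(tr$anc[starts], tr$anc[ends]) + 1L),
    strand = ifelse(is.na(tr$strand[starts]), NA_character_,
                    ifelse(tr$strand[starts] > 0, "+", "-"))
  )
}

#' Breakpoint positions of a derived genome on the ancestor
#'
#' Ancestor coordinates at which the derived genome's collinearity with
#' the ancestor breaks (segment boundaries of [segments()], expressed on
#' the ancestor). Useful for deciding which mate-pair fragments straddle
#' a rearrangement.
#'
#' @param genome A derived `sim_genome`.
#' @return Sorted integer vector of 0-based ancestor coordinates.
#' @export
breakpoints_on_ancestor <- function(genome) {
  seg <- dplyr::filter(segments(genome), !is.na(.data$anc_start))
  sort(unique(c(seg$anc_start, seg$anc_end)))
}

#' Simulate paired-end reads from a genome
#'
#' Fragments of fixed `insert` length are drawn uniformly along the
#' genome; each yields an innie pair (read 1 the forward prefix, read 2
#' the reverse complement of the suffix). Per-base substitution errors
#' are applied at `error_rate`. Reads are uppercase (sequencers do not
#' see masking) with constant quality `I`; true fragment starts are kept
#' so reads can be placed by [truth_align()]. Deterministic per seed.
#'
#' @param genome A `sim_genome`.
#' @param insert Fragment (insert) size in bp, `>= read_len` (default 250).
#' @param read_len Read length in bp (default 150).
#' @param coverage Target fold sequence coverage (default 30).
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed Integer seed.
#' @param prefix Read id prefix.
#' @return Pairs tibble in the [sample_library()] layout: `pair_id`,
#'   `library`, `insert_size`, `start`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
make_reads <- function(genome, insert = 250L, read_len = 150L, coverage = 30,
                       error_rate = 0, seed = 1L, prefix = "pe") {
  insert <- as.integer(insert)
  read_len <- as.integer(read_len)
  stopifnot(insert >= read_len, coverage > 0)
  L <- genome$length
  n <- as.integer(ceiling(coverage * L / (2 * read_len)))
  withr::with_seed(seed, {
    starts <- as.integer(floor(stats::runif(n) * (L - insert + 1)))
    up <- toupper(genome$seq)
    s1 <- stringr::str_sub(up, starts + 1L, starts + read_len)
    s2 <- revcomp(stringr::str_sub(up, starts + insert - read_len + 1L,
                                   starts + insert))
    if (error_rate > 0) {
      s1 <- add_read_errors(s1, error_rate)
      s2 <- add_read_errors(s2, error_rate)
    }
    qual <- strrep("I", read_len)
    tibble::tibble(
      pair_id = sprintf("%s:%07d:%d", prefix, seq_len(n) - 1L, starts),
      library = prefix,
      insert_size = insert,
      start = starts,
      seq1 = s1, qual1 = qual, seq2 = s2, qual2 = qual
    )
  })
}

# sprinkle substitution errors over a character vector of reads;
# only reads that draw at least one error are touched
add_read_errors <- function(seqs, rate) {
  rl <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), rl, rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(rl[i], n_err[i])
    ch <- seq_chars(seqs[i])
    ch[pos] <- vapply(ch[pos], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), toupper(x)), 1)
    }, character(1), USE.NAMES = FALSE)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Per-base coordinate map between two genomes sharing an ancestor
#'
#' Composes the truth maps of `src` and `dst` through their common
#' ancestor: for each base of `src`, the 0-based position of the
#' homologous base in `dst` (or `NA` where the base was inserted in `src`
#' or deleted in `dst`) and the composed strand.
#'
#' @param src,dst `sim_genome` objects derived from the same ancestor
#'   (the ancestor itself maps to itself).
#' @return List with integer `pos` and `strand` (`+1`/`-1`) vectors of
#'   length `src$length`.
#' @export
map_coords <- function(src, dst) {
  ts <- truth_of(src)
  td <- truth_of(dst)
  anc_len <- max(c(ts$anc, td$anc), na.rm = TRUE) + 1L
  inv_pos <- rep(NA_integer_, anc_len)
  inv_str <- rep(NA_integer_, anc_len)
  ok <- !is.na(td$anc)
  inv_pos[td$anc[ok] + 1L] <- which(ok) - 1L
  inv_str[td$anc[ok] + 1L] <- td$strand[ok]
  pos <- rep(NA_integer_, length(ts$anc))
  strand <- rep(NA_integer_, length(ts$anc))
  has <- !is.na(ts$anc) & ts$anc < anc_len
  pos[has] <- inv_pos[ts$anc[has] + 1L]
  strand[has] <- ts$strand[has] * inv_str[ts$anc[has] + 1L]
  list(pos = pos, strand = strand)
}

#' Truth-composition alignment of reads onto a genome
#'
#' Emits the alignment each read *would* have on `dst`, computed by
#' composing exact coordinate maps instead of running an aligner: a read
#' whose source interval maps contiguously on one strand of `dst` gets a
#' match-only CIGAR at the composed position; a read whose interval is
#' split by a breakpoint (or partially deleted) on `dst` is emitted
#' unmapped, so the conserved filter must judge the pair from its mate
#' geometry. Substitution differences (SNPs, read errors) do not affect
#' placement.
#'
#' @param reads Tibble with `id`, `seq`, `qual`, `src_start` (0-based on
#'   `src`), `src_strand` (`+`/`-`); e.g. from [pairs_to_reads()].
#' @param src `sim_genome` the read coordinates live on.
#' @param dst `sim_genome` to align onto.
#' @return SAM-layout tibble as from [read_sam()]. Reads named `<stem>/1`
#'   and `<stem>/2` are flagged as mates of one pair.
#' @export
truth_align <- function(reads, src, dst) {
  if (any(is.na(reads$src_start))) {
    stop("read with unknown truth coordinates", call. = FALSE)
  }
  cm <- map_coords(src, dst)
  n_src <- length(cm$pos)
  lens <- nchar(reads$seq)
  if (any(reads$src_start + lens > n_src)) {
    stop("read interval beyond source genome end", call. = FALSE)
  }

  # adjacency indicators between consecutive src bases, then prefix sums:
  # a read maps iff its interval contains no bad adjacency
  d <- diff(cm$pos)
  same <- !is.na(cm$pos[-n_src]) & !is.na(cm$pos[-1]) &
    cm$strand[-n_src] == cm$strand[-1]
  bad_plus <- !(same & cm$strand[-n_src] == 1L & d == 1L)
  bad_minus <- !(same & cm$strand[-n_src] == -1L & d == -1L)
  cp <- c(0L, cumsum(bad_plus))
  cq <- c(0L, cumsum(bad_minus))

  a <- reads$src_start + 1L       # first adjacency index inside the read
  bnd <- reads$src_start + lens - 1L # last adjacency index
  fwd <- cp[bnd + 1L] - cp[a] == 0L
  rev_ <- cq[bnd + 1L] - cq[a] == 0L
  single_ok <- !is.na(cm$pos[reads$src_start + 1L])
  one_base <- lens == 1L
  fwd[one_base] <- single_ok[one_base] & cm$strand[reads$src_start + 1L][one_base] == 1L
  rev_[one_base] <- single_ok[one_base] & cm$strand[reads$src_start + 1L][one_base] == -1L

  mapped <- fwd | rev_
  first_pos <- cm$pos[reads$src_start + 1L]
  last_pos <- cm$pos[reads$src_start + lens]
  dst_pos <- ifelse(fwd, first_pos, ifelse(rev_, last_pos, NA_integer_))
  seg_minus <- rev_
  src_minus <- reads$src_strand == "-"
  dst_strand <- ifelse(mapped, ifelse(xor(seg_minus, src_minus), "-", "+"),
                       NA_character_)

  # SAM stores SEQ/QUAL in reference orientation for minus-strand records
  minus <- mapped & dst_strand == "-"
  out_seq <- ifelse(minus, revcomp(reads$seq), reads$seq)
  out_qual <- ifelse(minus, stringi::stri_reverse(reads$qual), reads$qual)
  out <- tibble::tibble(
    qname = reads$id,
    mapped = mapped,
    strand = dst_strand,
    target_id = ifelse(mapped, dst$id, NA_character_),
    pos = ifelse(mapped, as.integer(dst_pos), NA_integer_),
    mapq = 60L,
    cigar = ifelse(mapped, paste0(lens, "M"), "*"),
    is_secondary_or_supplementary = FALSE,
    seq = out_seq,
    qual = out_qual
  )

  # mate flags for /1-/2 pairs
  paired <- grepl("/[12]$", out$qname)
  stem <- sub("/[12]$", "", out$qname)
  mate1 <- grepl("/1$", out$qname)
  ord <- order(stem, !mate1)
  out <- out[ord, ]
  paired <- paired[ord]; stem <- stem[ord]; mate1 <- mate1[ord]
  # rows are sorted by stem then mate, so complete pairs sit adjacent
  mate_idx <- rep(NA_integer_, nrow(out))
  if (any(paired)) {
    n <- nrow(out)
    adj <- which(paired[-n] & paired[-1] &
                   stem[-n] == stem[-1] & mate1[-n] & !mate1[-1])
    mate_idx[adj] <- adj + 1L
    mate_idx[adj + 1L] <- adj
  }
  out$is_first_mate <- !paired | mate1
  out$mate_mapped <- !is.na(mate_idx) & out$mapped[pmax(mate_idx, 1L)] &
    !is.na(mate_idx)
  out$mate_target_id <- ifelse(out$mate_mapped, out$target_id[pmax(mate_idx, 1L)],
                               NA_character_)
  out$mate_pos <- ifelse(out$mate_mapped, out$pos[pmax(mate_idx, 1L)],
                         NA_integer_)
  self_rev <- out$mapped & !is.na(out$strand) & out$strand == "-"
  mate_rev <- out$mate_mapped & !is.na(mate_idx) &
    out$strand[pmax(mate_idx, 1L)] %in% "-"
  out$flag <- as.integer(
    ifelse(paired, FLAG_PAIRED, 0L) +
      ifelse(out$mapped, 0L, FLAG_UNMAPPED) +
      ifelse(paired & !out$mate_mapped, FLAG_MATE_UNMAPPED, 0L) +
      ifelse(self_rev, FLAG_REVERSE, 0L) +
      ifelse(mate_rev, FLAG_MATE_REVERSE, 0L) +
      ifelse(paired & mate1, FLAG_FIRST, 0L) +
      ifelse(paired & !mate1, FLAG_SECOND, 0L)
  )
  dplyr::select(out, "qname", "flag", "mapped", "strand", "target_id", "pos",
                "mapq", "cigar", "mate_mapped", "mate_target_id", "mate_pos",
                "is_first_mate", "is_secondary_or_supplementary", "seq",
                "qual")
}

#' Convert a `sim_genome` to a one-row sequence tibble
#'
#' @param x A `sim_genome`.
#' @param ... Unused.
#' @return Tibble with `id` and `seq`, as from [read_fasta()].
#' @method as_tibble sim_genome
#' @export
as_tibble.sim_genome <- function(x, ...) {
  tibble::tibble(id = x$id, seq = x$seq)
}
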