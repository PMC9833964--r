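test_that("genome generation honors masking, GC and determinism", {
  g0 <- make_genome(5000, repeat_fraction = 0, seed = 1)
  expect_false(grepl("[acgt]", g0$seq))
  expect_equal(nrow(g0$mask), 0L)

  g1 <- make_genome(5000, repeat_fraction = 0.1, seed = 2)
  g1b <- make_genome(5000, repeat_fraction = 0.1, seed = 2)
  expect_identical(g1$seq, g1b$seq)
  expect_gt(nrow(g1$mask), 0L)
  # mask intervals coincide with lowercase runs
  ch <- strsplit(g1$seq, "")[[1]]
  low <- which(ch %in% c("a", "c", "g", "t"))
  in_mask <- unlist(purrr::map2(g1$mask$start, g1$mask$end,
                                ~ seq(.x + 1, .y)))
  expect_setequal(low, in_mask)

  gbig <- make_genome(100000, gc = 0.5, repeat_fraction = 0, seed = 3)
  gc_real <- mean(strsplit(toupper(gbig$seq), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_real - 0.5), 0.02)
})

test_that("evolve with no mutations is the identity", {
  g <- make_genome(2000, seed = 4)
  d <- evolve(g, seed = 5)
  expect_equal(d$seq, g$seq)
  expect_equal(d$truth$anc, 0:1999)
  expect_equal(unique(d$truth$strand), 1L)
  expect_equal(nrow(segments(d)), 1L)
})

test_that("one inversion yields three segments with a minus middle", {
  g <- make_genome(2000, repeat_fraction = 0, seed = 6)
  d <- evolve(g, inversions = tibble::tibble(start = 500, length = 400),
              seed = 7)
  seg <- segments(d)
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$strand, c("+", "-", "+"))
  expect_equal(seg$der_start, c(0L, 500L, 900L))
  # inverted block is the reverse complement of the ancestral block
  expect_equal(substr(d$seq, 501, 900),
               revcomp(substr(g$seq, 501, 900)))
})

test_that("SNP divergence is realized at the requested rate", {
  g <- make_genome(100000, repeat_fraction = 0, seed = 8)
  d <- evolve(g, snp_rate = 0.02, seed = 9)
  mism <- mean(strsplit(g$seq, "")[[1]] != strsplit(d$seq, "")[[1]])
  expect_lt(abs(mism - 0.02), 0.003)
})

test_that("indels keep the truth map exact", {
  g <- make_genome(10000, repeat_fraction = 0, seed = 10)
  d <- evolve(g, indel_rate = 0.002, indel_max_len = 8, seed = 11)
  expect_false(d$length == g$length && identical(d$seq, g$seq))
  tr <- d$truth
  gch <- strsplit(g$seq, "")[[1]]
  dch <- strsplit(d$seq, "")[[1]]
  has <- !is.na(tr$anc)
  # every mapped derived base equals its ancestor base (no SNPs applied)
  expect_true(all(dch[has] == gch[tr$anc[has] + 1]))
  # ancestor coordinates are strictly increasing along plus-strand segments
  expect_true(all(diff(tr$anc[has]) > 0))
})

test_that("overlapping rearrangements and bad destinations error", {
  g <- make_genome(5000, seed = 12)
  expect_error(
    evolve(g, inversions = tibble::tibble(start = c(100, 300),
                                          length = c(400, 200))),
    "overlap")
  expect_error(
    evolve(g, inversions = tibble::tibble(start = 1000, length = 500),
           translocations = tibble::tibble(start = 3000, length = 200,
                                           new_start = 1200)),
    "destination")
})

test_that("translocated blocks move rigidly with truth preserved", {
  g <- make_genome(5000, repeat_fraction = 0, seed = 13)
  d <- evolve(g, translocations = tibble::tibble(start = 1000, length = 300,
                                                 new_start = 4000),
              seed = 14)
  expect_equal(d$length, g$length)
  tr <- d$truth
  gch <- strsplit(g$seq, "")[[1]]
  dch <- strsplit(d$seq, "")[[1]]
  expect_true(all(dch == gch[tr$anc + 1]))
  # excision splits the backbone around the block: four collinear segments
  seg <- segments(d)
  expect_equal(nrow(seg), 4L)
  expect_true(all(seg$strand == "+"))
  expect_equal(seg$anc_start[3], 1000L) # the moved block
  expect_equal(seg$anc_end[3], 1300L)
})

test_that("read simulation is seeded and hits requested coverage", {
  g <- make_genome(100000, seed = 15)
  a <- make_reads(g, coverage = 10, seed = 16)
  b <- make_reads(g, coverage = 10, seed = 16)
  expect_identical(a, b)
  realized <- sum(nchar(a$seq1) + nchar(a$seq2)) / g$length
  expect_lt(abs(realized - 10) / 10, 0.1)
  expect_false(any(grepl("[acgt]", a$seq1)))
})

test_that("read errors hit approximately error_rate bases", {
  g <- make_genome(20000, repeat_fraction = 0, seed = 17)
  clean <- make_reads(g, coverage = 5, error_rate = 0, seed = 18)
  noisy <- make_reads(g, coverage = 5, error_rate = 0.01, seed = 18)
  mism <- sum(mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, clean$seq1, noisy$seq1))
  rate <- mism / sum(nchar(clean$seq1))
  expect_lt(abs(rate - 0.01), 0.003)
})

test_that("truth alignment to the source genome is the identity placement", {
  g <- make_genome(5000, seed = 19)
  pairs <- make_reads(g, coverage = 5, seed = 20)
  aln <- truth_align(pairs_to_reads(pairs), g, g)
  expect_true(all(aln$mapped))
  reads <- pairs_to_reads(pairs)
  aln <- aln[match(reads$id, aln$qname), ]
  expect_equal(aln$pos, reads$src_start)
  expect_equal(aln$strand, reads$src_strand)
})

test_that("breakpoint-straddling pairs show same-strand geometry downstream", {
  # 3-segment fixture: inversion [1000, 1600) on the target
  g <- make_genome(3000, repeat_fraction = 0, seed = 21)
  d <- evolve(g, inversions = tibble::tibble(start = 1000, length = 600),
              seed = 22)
  # fragment straddling the left breakpoint: read1 [850, 900), read2 window
  # [1150, 1200) (inside the inversion), insert 350
  pairs <- tibble::tibble(
    pair_id = "straddle", library = "x*", insert_size = 350L, start = 850L,
    seq1 = substr(g$seq, 851, 900), qual1 = strrep("I", 50),
    seq2 = revcomp(substr(g$seq, 1151, 1200)), qual2 = strrep("I", 50)
  )
  aln <- truth_align(pairs_to_reads(pairs), g, d)
  expect_true(all(aln$mapped))
  expect_equal(aln$strand[1], aln$strand[2]) # both ended up same strand
  v <- vet_pairs(pair_alignments(aln), 350L)
  expect_equal(as.character(v$status), "INVERTED")
})

test_that("pairs inside a translocated block stay conserved", {
  g <- make_genome(6000, repeat_fraction = 0, seed = 23)
  d <- evolve(g, translocations = tibble::tibble(start = 1000, length = 1000,
                                                 new_start = 5000),
              seed = 24)
  pairs <- tibble::tibble(
    pair_id = "inside", library = "x*", insert_size = 600L, start = 1100L,
    seq1 = substr(g$seq, 1101, 1150), qual1 = strrep("I", 50),
    seq2 = revcomp(substr(g$seq, 1651, 1700)), qual2 = strrep("I", 50)
  )
  aln <- truth_align(pairs_to_reads(pairs), g, d)
  v <- vet_pairs(pair_alignments(aln), 600L)
  expect_equal(as.character(v$status), "CONSERVED")
  expect_equal(v$observed_insert, 600L)
})

test_that("truth-aligned SAM survives a write/read round trip", {
  g <- make_genome(4000, seed = 25)
  d <- evolve(g, inversions = tibble::tibble(start = 1000, length = 800),
              seed = 26)
  pairs <- make_reads(g, coverage = 3, seed = 27)
  aln <- truth_align(pairs_to_reads(pairs), g, d)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, path, ref_lens = stats::setNames(d$length, d$id))
  back <- read_sam(path)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$flag, aln$flag)
  expect_equal(back$strand, aln$strand)
  m <- aln$mapped
  expect_true(all(aln$pos[m] >= 0 & aln$pos[m] + nchar(aln$seq[m]) <= d$length))
})
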