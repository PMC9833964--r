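# hand-made pair-alignment rows for the decision cascade
pa_row <- function(mapped1 = TRUE, target1 = "t", strand1 = "+",
                   start1 = 0L, end1 = start1 + 100L,
                   mapped2 = TRUE, target2 = "t", strand2 = "-",
                   start2 = 9900L, end2 = start2 + 100L,
                   pair_id = "p") {
  tibble::tibble(pair_id = pair_id, mapped1 = mapped1, target1 = target1,
                 strand1 = strand1, start1 = start1, end1 = end1,
                 mapped2 = mapped2, target2 = target2, strand2 = strand2,
                 start2 = start2, end2 = end2)
}

test_that("the verdict cascade matches the worked examples", {
  ln <- 10000L
  conserved <- vet_pairs(pa_row(start1 = 1000L, start2 = 12400L,
                                end2 = 12500L), ln)
  expect_equal(as.character(conserved$status), "CONSERVED")
  expect_equal(conserved$observed_insert, 12500L - 1000L)

  deviant <- vet_pairs(pa_row(start1 = 0L, start2 = 12400L, end2 = 12500L), ln)
  expect_equal(as.character(deviant$status), "LENGTH_DEVIANT")
  expect_equal(deviant$observed_insert, 12500L)

  inverted <- vet_pairs(pa_row(strand2 = "+"), ln)
  expect_equal(as.character(inverted$status), "INVERTED")

  split <- vet_pairs(pa_row(target2 = "chr7"), ln)
  expect_equal(as.character(split$status), "SPLIT")
  expect_true(is.na(split$observed_insert))

  unmapped <- vet_pairs(pa_row(mapped2 = FALSE, target2 = NA,
                               strand2 = NA, start2 = NA, end2 = NA), ln)
  expect_equal(as.character(unmapped$status), "UNMAPPED")
})

test_that("order-swapped (outie) pairs on one sequence count as inverted", {
  # minus-strand mate leftmost: reads point away from each other
  outie <- pa_row(strand1 = "-", start1 = 0L,
                  strand2 = "+", start2 = 9900L)
  expect_equal(as.character(vet_pairs(outie, 10000L)$status), "INVERTED")
})

test_that("both tolerance boundaries are conserved (closed interval)", {
  ln <- 10000L
  at_low <- pa_row(start1 = 0L, start2 = 7900L, end2 = 8000L)   # Ln' = 8000
  at_high <- pa_row(start1 = 0L, start2 = 11900L, end2 = 12000L) # Ln' = 12000
  below <- pa_row(start1 = 0L, start2 = 7898L, end2 = 7999L)    # Ln' = 7999
  above <- pa_row(start1 = 0L, start2 = 11901L, end2 = 12001L)  # Ln' = 12001
  expect_equal(as.character(vet_pairs(at_low, ln)$status), "CONSERVED")
  expect_equal(as.character(vet_pairs(at_high, ln)$status), "CONSERVED")
  expect_equal(as.character(vet_pairs(below, ln)$status), "LENGTH_DEVIANT")
  expect_equal(as.character(vet_pairs(above, ln)$status), "LENGTH_DEVIANT")
})

test_that("vetting against the generating reference keeps everything", {
  sc <- small_scenario()
  reads <- make_reads(sc$target, coverage = 15, seed = 21)
  aln <- truth_align(pairs_to_reads(reads), sc$target, sc$target)
  trk <- build_consensus(as_tibble(sc$target), aln)
  lib <- sample_library(trk, 1000, read_len = 100, step = 40,
                        library_name = "self*")
  self_sam <- truth_align(pairs_to_reads(lib), sc$target, sc$target)
  kept <- filter_library(lib, self_sam)
  expect_equal(nrow(kept), nrow(lib))
  expect_equal(kept$pair_id, lib$pair_id)
  expect_true(all(verdicts(kept)$status == "CONSERVED"))
})

test_that("pairs straddling an inversion breakpoint are rejected, others kept", {
  sc <- small_scenario()
  reads <- make_reads(sc$target, coverage = 15, seed = 22)
  aln1 <- truth_align(pairs_to_reads(reads), sc$target, sc$ref1)
  trk <- build_consensus(as_tibble(sc$ref1), aln1)
  ins <- 2000L
  lib <- sample_library(trk, ins, read_len = 100, step = 25)
  sam2 <- truth_align(pairs_to_reads(lib), sc$ref1, sc$ref2)
  kept <- filter_library(lib, sam2, vet_tag = "ref2")
  v <- verdicts(kept)

  # which fragments straddle a ref2 breakpoint? ref1 coordinates == ancestor
  # coordinates outside ref1's own inversions, so use the truth map
  cm <- map_coords(sc$ref1, sc$ref2)
  frag_status <- vapply(seq_len(nrow(lib)), function(i) {
    s <- lib$start[i]
    w <- cm$pos[(s + 1):(s + ins)]
    if (any(is.na(w))) return("na")
    d <- diff(w)
    # fully inside an inversion is still rigid motion, hence conserved
    if (all(d == 1) || all(d == -1)) "collinear" else "straddler"
  }, character(1))
  v <- v[match(lib$pair_id, v$pair_id), ]
  expect_true(all(v$status[frag_status == "straddler"] != "CONSERVED"))
  expect_true(all(v$status[frag_status == "collinear"] == "CONSERVED"))
  expect_equal(kept$library[1], "ref1-ref2**")
})

test_that("chaining references intersects survivor sets symmetrically", {
  sc <- small_scenario()
  reads <- make_reads(sc$target, coverage = 15, seed = 23)
  aln1 <- truth_align(pairs_to_reads(reads), sc$target, sc$ref1)
  trk <- build_consensus(as_tibble(sc$ref1), aln1)
  lib <- sample_library(trk, 1500, read_len = 100, step = 30)
  sam2 <- truth_align(pairs_to_reads(lib), sc$ref1, sc$ref2)
  sam3 <- truth_align(pairs_to_reads(lib), sc$ref1, sc$ref3)

  k23 <- chain_references(lib, list(ref2 = sam2, ref3 = sam3))
  k32 <- chain_references(lib, list(ref3 = sam3, ref2 = sam2))
  expect_setequal(k23$pair_id, k32$pair_id)
  expect_equal(k23$library[1], "ref1-ref2-ref3**")

  k2 <- filter_library(lib, sam2)
  expect_lte(nrow(k23), nrow(k2))
  expect_lte(nrow(k2), nrow(lib))
  # the chained survivor set is exactly the intersection
  k3 <- filter_library(lib, sam3)
  expect_setequal(k23$pair_id, intersect(k2$pair_id, k3$pair_id))
})

test_that("filter_library rejects SAMs with unknown reads", {
  lib <- tibble::tibble(pair_id = "p1", library = "x*", insert_size = 400L,
                        start = 0L, seq1 = strrep("A", 100),
                        qual1 = strrep("I", 100), seq2 = strrep("T", 100),
                        qual2 = strrep("I", 100))
  rogue <- read_sam(sam_line("zz/1", 0, "t", 1, "100M",
                             strrep("A", 100), strrep("I", 100)))
  expect_error(filter_library(lib, rogue), "absent")
})

test_that("classification report counts and fractions are exact", {
  v <- tibble::tibble(
    pair_id = paste0("p", 1:4),
    status = factor(c("CONSERVED", "CONSERVED", "INVERTED", "SPLIT"),
                    levels = levels(vet_pairs(pa_row(), 10000L)$status)),
    expected_insert = 1000L, observed_insert = NA_integer_,
    library = "lib**"
  )
  rep <- classify_report(v)
  get <- function(s) rep$fraction[rep$status == s]
  expect_equal(get("CONSERVED"), 0.5)
  expect_equal(get("INVERTED"), 0.25)
  expect_equal(get("SPLIT"), 0.25)
  expect_equal(get("LENGTH_DEVIANT"), 0)
  expect_equal(sum(rep$fraction), 1)
  expect_equal(unique(rep$n_conserved), 2L)

  expect_equal(nrow(classify_report(list())), 0L)
})
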