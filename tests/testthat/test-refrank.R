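paf_row <- function(qs, qe, nm, bl = qe - qs, qid = "d1", qlen = 200L) {
  tibble::tibble(query_id = qid, query_len = qlen, query_start = qs,
                 query_end = qe, strand = "+", target_id = "t",
                 target_len = 10000L, target_start = qs, target_end = qe,
                 n_matches = nm, block_len = bl, mapq = 60L)
}

test_that("PAF summaries merge overlapping blocks", {
  full <- paf_row(0L, 200L, 200L)
  s <- summarize_paf(full, 200, "A")
  expect_equal(s$aligned_fraction, 1)
  expect_equal(s$mean_identity, 1)
  expect_equal(s$n_blocks, 1L)

  two <- dplyr::bind_rows(paf_row(0L, 100L, 95L), paf_row(50L, 150L, 90L))
  s2 <- summarize_paf(two, 200, "B")
  expect_equal(s2$aligned_fraction, 0.75) # merged 150 of 200
  expect_equal(s2$mean_identity, (95 + 90) / 200)

  # blocks on different draft sequences never merge
  multi <- dplyr::bind_rows(paf_row(0L, 100L, 100L, qid = "d1"),
                            paf_row(0L, 100L, 100L, qid = "d2"))
  expect_equal(summarize_paf(multi, 400, "C")$aligned_fraction, 0.5)

  empty <- paf_row(0L, 100L, 90L)[0, ]
  s0 <- summarize_paf(empty, 200, "D")
  expect_equal(s0$aligned_fraction, 0)
  expect_equal(s0$n_blocks, 0L)

  expect_error(summarize_paf(full, 0, "E"), "positive")
})

test_that("ranking is by score with block-count and lexical tie-breaks", {
  mk <- function(tag, af, mi, nb) {
    tibble::tibble(ref_tag = tag, aligned_fraction = af, mean_identity = mi,
                   n_blocks = nb, total_draft_len = 1000)
  }
  rk <- rank_references(dplyr::bind_rows(mk("A", 0.9, 0.98, 5),
                                         mk("B", 0.9, 0.90, 5)))
  expect_equal(rk$ref_tag[rk$rank == 1], "A")

  tie <- rank_references(dplyr::bind_rows(mk("A", 0.8, 0.9, 10),
                                          mk("B", 0.8, 0.9, 4)))
  expect_equal(tie$ref_tag[tie$rank == 1], "B")

  lex <- rank_references(dplyr::bind_rows(mk("zeta", 0.8, 0.9, 4),
                                          mk("alpha", 0.8, 0.9, 4)))
  expect_equal(lex$ref_tag[lex$rank == 1], "alpha")
})

test_that("ranking is invariant to input order", {
  set.seed(4)
  base <- tibble::tibble(
    ref_tag = paste0("r", 1:6),
    aligned_fraction = runif(6, 0.5, 1),
    mean_identity = runif(6, 0.8, 1),
    n_blocks = sample(1:20, 6),
    total_draft_len = 1000
  )
  r1 <- rank_references(base)
  for (k in 1:5) {
    r2 <- rank_references(base[sample(6), ])
    expect_equal(r2, r1)
  }
})

test_that("a congener-like reference outranks a distant one", {
  # construct the two candidates from actual divergence: the draft is the
  # target genome, each reference a derived genome; alignment blocks are
  # the syntenic segments with identity measured base by base
  g <- make_genome(40000, repeat_fraction = 0, seed = 31, id = "draft")
  congener <- evolve(g, snp_rate = 0.02, seed = 32, id = "congener")
  distant <- evolve(g, snp_rate = 0.15,
                    inversions = tibble::tibble(start = c(5000, 20000),
                                                length = c(4000, 6000)),
                    seed = 33, id = "distant")
  paf_of <- function(ref) {
    seg <- dplyr::filter(segments(ref), !is.na(anc_start))
    gch <- strsplit(toupper(g$seq), "")[[1]]
    rch <- strsplit(toupper(ref$seq), "")[[1]]
    tr <- ref$truth
    purrr::map_dfr(seq_len(nrow(seg)), function(i) {
      idx <- (seg$der_start[i] + 1):seg$der_end[i]
      matches <- sum(rch[idx] ==
                       chartr("ACGT", ifelse(seg$strand[i] == "-", "TGCA",
                                             "ACGT"),
                              gch[tr$anc[idx] + 1]))
      paf_row(seg$anc_start[i], seg$anc_end[i], as.integer(matches),
              seg$anc_end[i] - seg$anc_start[i], qid = "draft",
              qlen = g$length)
    })
  }
  s_con <- summarize_paf(paf_of(congener), g$length, "congener")
  s_dis <- summarize_paf(paf_of(distant), g$length, "distant")
  rk <- rank_references(dplyr::bind_rows(s_con, s_dis))
  expect_equal(rk$ref_tag[rk$rank == 1], "congener")
  expect_gt(s_con$mean_identity, s_dis$mean_identity)
})
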