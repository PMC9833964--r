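test_that("systematic sampling matches the worked example", {
  set.seed(42)
  seq10k <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  trk <- tiny_track(seq10k, rep(3L, 10000))
  lib <- sample_library(trk, 2000, read_len = 100, step = 500)
  expect_equal(nrow(lib), 17L)
  expect_equal(lib$start, seq(0L, 8000L, by = 500L))
  expect_equal(lib$seq1[1], substr(seq10k, 1, 100))
  expect_equal(lib$seq2[1], revcomp(substr(seq10k, 1901, 2000)))
  expect_equal(unique(nchar(c(lib$seq1, lib$seq2))), 100L)
})

test_that("regions below the depth threshold are skipped entirely", {
  trk <- tiny_track(strrep("A", 5000), rep(2L, 5000))
  expect_equal(nrow(sample_library(trk, 1000, read_len = 100, step = 50)), 0L)
})

test_that("tracks shorter than the insert yield no pairs, bad specs error", {
  trk <- tiny_track(strrep("A", 500))
  expect_equal(nrow(sample_library(trk, 1000, read_len = 100)), 0L)
  expect_error(sample_library(trk, 150, read_len = 100), "2 \\* read_len")
})

test_that("step_for_coverage meets the coverage floor", {
  expect_equal(step_for_coverage(100, 30), 6L)
  expect_equal(step_for_coverage(150, 30), 10L)
  expect_equal(step_for_coverage(100, 200), 1L)
  for (r in c(50, 100, 150)) {
    for (cv in c(10, 30, 60)) {
      expect_gte(2 * r / step_for_coverage(r, cv), cv)
    }
  }
})

test_that("sampler agrees with brute-force enumeration on random tracks", {
  for (seed in 1:25) {
    trk <- random_track(seed)
    L <- nchar(trk$seq)
    ins <- sample(c(200L, 500L, 1000L), 1)
    r <- sample(c(50L, 100L), 1)
    if (ins < 2 * r) ins <- 2L * r
    step <- sample(c(1L, 7L, 50L), 1)
    lib <- sample_library(trk, ins, read_len = r, step = step)
    expect_equal(lib$start,
                 brute_force_starts(trk, ins, r, step, 3L),
                 info = paste("seed", seed))
  }
})

test_that("emitted reads contain no N and no base below min_depth", {
  trk <- random_track(99)
  lib <- sample_library(trk, 400, read_len = 100, step = 3)
  expect_false(any(grepl("N", lib$seq1)))
  expect_false(any(grepl("N", lib$seq2)))
  ch <- strsplit(trk$seq, "")[[1]]
  for (i in seq_len(nrow(lib))) {
    s <- lib$start[i]
    w1 <- (s + 1):(s + 100)
    w2 <- (s + 400 - 100 + 1):(s + 400)
    expect_true(all(trk$coverage[c(w1, w2)] >= 3))
    expect_equal(lib$seq1[i], paste(ch[w1], collapse = ""))
    expect_equal(lib$seq2[i], revcomp(paste(ch[w2], collapse = "")))
  }
})

test_that("achieved physical coverage meets the target on a clean track", {
  set.seed(5)
  trk <- tiny_track(paste(sample(c("A", "C", "G", "T"), 20000, TRUE),
                          collapse = ""))
  lib <- sample_library(trk, 1000, read_len = 100, target_coverage = 30)
  achieved <- sum(2 * 100 * nrow(lib)) / nchar(trk$seq)
  expect_gte(achieved, 30)
})

test_that("ladders compose from single libraries and name per convention", {
  set.seed(6)
  trk <- tiny_track(paste(sample(c("A", "C", "G", "T"), 30000, TRUE),
                          collapse = ""), ref_id = "mag")
  lad <- sample_ladder(trk, ladder = c(2000L), read_len = 100)
  one <- sample_library(trk, 2000, read_len = 100,
                        library_name = "mag*")
  expect_equal(lad$pairs[[1]], one)
  expect_equal(lad$library, "mag*")

  full <- sample_ladder(trk, read_len = 100)
  expect_equal(nrow(full), 10L)
  expect_equal(full$n_pairs[full$insert_size > 30000], rep(0L, 3))
  expect_true(all(full$n_pairs[full$insert_size <= 30000] > 0))

  expect_error(sample_ladder(trk, ladder = c(1000L, 1000L)), "duplicate")
})

test_that("write_ladder emits synchronized files plus a manifest", {
  set.seed(8)
  trk <- tiny_track(paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                          collapse = ""), ref_id = "mag")
  lad <- sample_ladder(trk, ladder = c(500L, 1000L), read_len = 100)
  dir <- withr::local_tempdir()
  manifest <- write_ladder(lad, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "mag.500.R1.fq")))
  n1 <- length(readLines(file.path(dir, "mag.1000.R1.fq")))
  expect_equal(n1, 4L * manifest$n_pairs[manifest$insert_size == 1000])
})
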