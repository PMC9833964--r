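#' Two-reference synthetic scaffolding scenario
#'
#' The package's standard synthetic experiment: one target genome (the
#' "ancestor" all other genomes derive from), three diverged reference
#' genomes, and error-free paired-end reads of the target. The first two
#' references are congener-like (2 and 3 percent SNP divergence), the
#' third slightly more diverged; each carries two planted inversions at
#' loci distinct from every other genome's, all longer than the largest
#' mate-pair insert used, so a fragment can straddle at most one
#' breakpoint. Everything is deterministic per seed.
#'
#' Inversion loci, as fractions of the genome length:
#' ref1 `(0.20, 0.06)` and `(0.60, 0.08)`; ref2 `(0.36, 0.06)` and
#' `(0.76, 0.08)`; ref3 `(0.08, 0.05)` and `(0.48, 0.06)`.
#'
#' @param length Target genome length in bp (default 500 kb).
#' @param seed Integer seed; internal stages use `seed + 1 .. seed + 4`.
#' @param coverage Paired-end read coverage of the target (default 30).
#' @param read_insert,read_len Paired-end fragment and read length
#'   (defaults 250/150 bp).
#' @return List with `target`, `ref1`, `ref2`, `ref3` (`sim_genome`s) and
#'   `reads` (pairs tibble from [make_reads()]).
#' @export
scenario_two_reference <- function(length = 500000L, seed = 1L,
                                   coverage = 30, read_insert = 250L,
                                   read_len = 150L) {
  length <- as.integer(length)
  iv <- function(f, w) {
    tibble::tibble(start = as.integer(f * length),
                   length = as.integer(w * length))
  }
  target <- make_genome(length, gc = 0.41, repeat_fraction = 0.05,
                        repeat_unit_len = 200L, seed = seed, id = "target")
  ref1 <- evolve(target, snp_rate = 0.02,
                 inversions = dplyr::bind_rows(iv(0.20, 0.06), iv(0.60, 0.08)),
                 seed = seed + 1L, id = "ref1")
  ref2 <- evolve(target, snp_rate = 0.03,
                 inversions = dplyr::bind_rows(iv(0.36, 0.06), iv(0.76, 0.08)),
                 seed = seed + 2L, id = "ref2")
  ref3 <- evolve(target, snp_rate = 0.04,
                 inversions = dplyr::bind_rows(iv(0.08, 0.05), iv(0.48, 0.06)),
                 seed = seed + 3L, id = "ref3")
  reads <- make_reads(target, insert = read_insert, read_len = read_len,
                      coverage = coverage, error_rate = 0, seed = seed + 4L)
  list(target = target, ref1 = ref1, ref2 = ref2, ref3 = ref3, reads = reads)
}
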