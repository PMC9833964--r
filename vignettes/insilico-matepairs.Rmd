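---
title: "In silico mate-pairs and conserved-pair filtering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico mate-pairs and conserved-pair filtering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silicomate)
library(dplyr)
```

## The problem

Mate-pair libraries — read pairs cut from the two ends of a kilobase-scale
DNA fragment — are what lets a short-read assembler order and orient
contigs across repeats. Building them in the laboratory requires
high-molecular-weight DNA, which degraded museum samples and ancient DNA
(fragments of roughly 40–170 bp) cannot provide. The in silico alternative
fabricates that long-range information computationally: align the target
species' short reads to a repeat-masked reference genome of a related
species, call a consensus, and cut read-length windows a fixed insert
apart from that consensus. The pairs inherit the *reference's* long-range
geometry, which is the method's power and its danger at once — wherever
the reference's structure differs from the target's (inversions,
translocations, expansions), the fabricated pairs are wrong and the
assembler builds chimeric scaffolds.

The package implements the optimized variant of this idea: generate the
pairs from one reference, then re-map them to a *second* (and optionally
third, fourth, ...) reference and keep only pairs whose placement there
preserves insert size within a tolerance and relative orientation. A pair
that is geometrically consistent across independently evolved references
is very likely to reflect ancestral (and hence target) synteny; a pair
that straddles a lineage-specific rearrangement of the generating
reference is not conserved on the others and is discarded. That is the
entire mechanism by which the filter trades a smaller library for far
fewer misassemblies.

## Pipeline stages and their models

### Consensus (`build_consensus`)

Primary alignments only; depth at a position counts reads whose `M`/`=`/`X`
CIGAR operations cover it. The consensus base is the simple majority among
covering reads, ties resolved toward the reference base; positions without
coverage keep the reference base and masked reference positions (lowercase
or `N`) are forced to `N`. Indels are not realigned: insertions consume
only the query, deletions leave the reference base with no added depth.
Base qualities do not weight the vote — the intended inputs are
k-mer-corrected reads, for which quality weighting is second-order. The
module never emits IUPAC ambiguity codes; at a heterozygous-looking column
the majority (or the reference, on a tie) wins outright. Whether ambiguity
codes would serve the sampler better is deliberately left out: downstream
windows must be concrete sequence.

### Systematic sampling (`sample_library`, `sample_ladder`)

For an insert size $L_n$ and read length $r$, candidate fragments start at
offsets $0, s, 2s, \dots$ and a candidate is emitted iff **both** read
windows $[x, x+r)$ and $[x+L_n-r, x+L_n)$ consist entirely of unmasked
bases with depth at least `min_depth` (default 3). The intervening gap is
*not* gated: only bases that end up in reads must be read-supported, and
requiring 200 kb gaps to be fully covered would emit next to nothing from
real low-coverage data. Pairs are emitted innie (forward window, then
reverse-complemented trailing window), with the insert measured outer edge
to outer edge, and constant quality `I` since consensus bases carry no
calibrated error model.

The offset step is the module's explicit coverage policy: the largest $s$
with $2r/s \ge c$ for a target physical coverage $c$ (default 30-fold),
i.e. $s = \max(1, \lfloor 2r/c \rfloor)$; with $r = 100$ that gives
$s = 6$ and ~33x when nothing is skipped. The default insert ladder is
500 bp, 1 kb, 1.5 kb, 2 kb, 5 kb, 10 kb, 20 kb, 50 kb, 100 kb and 200 kb;
libraries are sampled independently per insert size and never span
sequence boundaries, because an insert distance across different
scaffolds is undefined.

### The conserved-pair filter (`vet_pairs`, `filter_library`, `chain_references`)

After mapping a library to a vetting reference, each pair is judged by a
five-way cascade, first match wins:

1. `UNMAPPED` — either mate has no primary alignment;
2. `SPLIT` — mates on different target sequences;
3. `INVERTED` — orientation is not innie-consistent (mates must sit on
   opposite strands with the plus-strand mate leftmost; outie
   order-swaps are an orientation anomaly and land here too);
4. `LENGTH_DEVIANT` — the observed insert $L_n'$, the outer distance
   from leftmost start to rightmost end, falls outside
   $[(1-t)\,L_n,\ (1+t)\,L_n]$;
5. `CONSERVED` otherwise, with $L_n'$ recorded.

The tolerance $t$ defaults to 0.2 — the 20 % window $0.8\,L_n \le L_n'
\le 1.2\,L_n$ — and the interval is closed on both ends, so a pair at
exactly $0.8\,L_n$ or $1.2\,L_n$ is kept; the boundary behaviour is
pinned by tests. Two conventions had to be fixed where common practice
varies: the insert is measured as outer distance (matching the sampler's
emission convention), and the cascade tests same-sequence placement
*before* the length test, so a cross-scaffold pair is `SPLIT`, never a
length failure. Secondary and supplementary alignments are ignored; one
primary placement vets each mate, and no mapping-quality filter is
applied.

Chaining applies the filter sequentially across references in ranked
order; the survivor set is exactly the intersection of the
per-reference conserved sets (order-independent as a set, verified by
test), so each added reference can only shrink the library. Names follow
the field's convention: `tag*` for a single-reference library,
`tag1-tag2**`, `tag1-tag2-tag3**`, ... for conserved ones.

### Ancient-DNA read simulation (`simulate_adna`)

Each forward read is cut to a 5'-anchored prefix whose length is drawn
uniformly from the closed integer interval $[80, 100]$ (both bounds
configurable). Uniform is the minimal model for "a random length in a
range", and the prefix cut keeps the 5' end where real aDNA fragments
anchor; neither a hard length distribution nor use of the reverse mate is
claimed beyond that. Reads shorter than the minimum are dropped and
counted; reads between the bounds keep their full span available rather
than being discarded. Output is deterministic for a fixed seed and input
order. Deamination damage, adapters and contamination are out of scope.

### Reference ranking (`summarize_paf`, `rank_references`)

Candidates are ranked from PAF alignments of a preliminary (no mate-pair)
assembly to each reference: `aligned_fraction` (draft bases inside
alignment blocks, overlaps merged per draft sequence) times
`mean_identity` (total matches over total block length), ties broken by
fewer blocks, then tag. The product makes both completeness and closeness
of the reference matter — the two drivers that decide reference quality
in practice — and the tie-breaks make the report permutation-invariant.
The combining rule is this package's documented policy; the aligner
itself (minimap2/Unimap class) stays external and only its PAF is
consumed.

### Evaluation (`nx`, `count_misjoins`, `greedy_scaffold`)

`nx(lengths, x)` is the standard Nx statistic (N50 at `x = 50`). Instead
of wrapping an external assembly-evaluation suite, misassemblies are
counted exactly against the synthetic ground truth: each adjacent contig
pair in a scaffold is classified `INTERCHROM`, `ORDER`, `ORIENTATION` or
`GAP_DEVIANT` (first match wins, with the order test applying when the
two effective orientations agree and the orientation test when they do
not). The gap tolerance defaults to 1 kb, the same order of magnitude as
the extensive-misassembly threshold used by standard evaluation tools.
`greedy_scaffold` is a deliberately minimal end-joining scaffolder —
bundle links by contig-end signature, accept bundles in decreasing
support order while ends are free and no cycle forms — included solely so
filtering strategies can be compared by misjoin count inside the package;
it is not a production assembler.

## The synthetic-data generator

`make_genome` draws i.i.d. bases at a requested GC (default 0.41, a
typical vertebrate value) and plants tandem repeats, soft-masked
lowercase, to a requested fraction (default 5 %). `evolve` applies
inversions and translocations first, then SNPs and indels away from the
rearrangement breakpoint bases, and carries an exact per-base coordinate
map back to the ancestor. `make_reads` draws error-free-by-default innie
pairs uniformly (insert 250 bp, read length 150 bp, 30x — the regime of
short-insert paired-end data the method targets). `truth_align` places
reads on any genome of the family by *composing coordinate maps* rather
than running an aligner: a read whose interval maps rigidly gets a
match-only CIGAR at the composed position, a read split by a breakpoint
is emitted unmapped. This makes every expected verdict exactly derivable
and removes external binaries from the tests, while the production path
accepts real BWA-MEM SAM through the same `read_sam` contract.

The standard experiment (`scenario_two_reference`) is a 500 kb target,
two congener-like references at 2 % and 3 % SNP divergence and a third at
4 %, each with two planted inversions (5–8 % of the genome long, loci
distinct across genomes and all longer than the largest insert, so a
fragment straddles at most one breakpoint), plus 30x error-free reads.
Unit tests run the same scenario at 60 kb; the acceptance suite and the
reproduction script run it at the full 500 kb. What the generator does
*not* emulate — sequencing error profiles, diploidy/heterozygosity, real
repeat families, GC bias — bounds what a passing test shows about real
data: the geometry of the method is verified exactly, not its robustness
to noisy alignment, which in production is delegated to the external
mapper.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere inside the package;
  conversion happens only at the SAM boundary (1-based) in
  `read_sam`/`write_sam`.
* Soft-masked (lowercase) and hard-masked (`N`) bases are treated
  identically by consumers, via one shared predicate (`is_masked_base`).
* Consensus ties among non-reference bases fall back to alphabetical
  order — an arbitrary but fixed and documented determinism choice.
* A track shorter than the insert yields an empty library, not an error;
  a duplicate insert in a ladder is an error.
* All generator randomness flows through explicit seeds via scoped RNG
  (`withr::with_seed`), so no call disturbs the caller's RNG state, and
  two pipeline runs from one configuration are byte-identical (no
  timestamps are written).

## Known limitations

* The conserved filter judges geometry only; a pair can be conserved
  across references yet wrong for the target if all references share a
  derived rearrangement the target lacks. More, and more independent,
  references shrink that risk at the cost of library size.
* Majority-rule consensus ignores genotype likelihoods; highly
  heterozygous targets will see reference-biased windows.
* `greedy_scaffold` exists for evaluation; contiguity numbers from it
  should be read comparatively (filtered vs unfiltered), not as
  assembler output.
* Repeat masking is taken from the reference's case/`N` state; the
  package does not run its own repeat annotation.
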