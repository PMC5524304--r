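---
title: "Methods: CNE detection and coding-sequence evolution around WGD paralogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNE detection and coding-sequence evolution around WGD paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohnocne)
```

## The scientific setting

Teleost fishes went through a lineage-specific whole-genome duplication
(WGD) roughly 250-320 Mya, followed by massive duplicate loss during
re-diploidization. Gene families that kept many duplicate pairs — the sox
transcription factors are an extreme case — let us ask how the two copies
(ohnologs, conventionally *a* and *b*) diverged: in their coding sequences,
in the conserved non-coding elements (CNEs) around them (presumed
cis-regulatory), and in their expression. `ohnocne` implements that whole
analysis chain over well-defined inputs, together with a synthetic-data
module that generates every input with controlled ground truth, so the
statistical behaviour of each stage can be verified without genome
downloads.

## Multi-species CNE scanning

`scan_cnes()` runs a seed-and-extend scanner over reference-anchored
alignment blocks (MAF). The primitive is a per-column conservation call:
a column is *conserved* when the fraction of non-gap, non-reference rows
differing from the reference base is strictly below the
`column_substitution_threshold` (default 0.12) and at least
`min_species_in_column` (default 3) rows are informative. Reference-gap
columns are never conserved and do not advance reference coordinates; `N`
never counts as identity. A *seed* is a 10-column window of reference bases
with at least 90% conserved columns (`ceiling(0.9 * 10) = 9`); overlapping
qualifying windows are merged and the merged run trimmed to start and end
on conserved columns. Each seed is then extended outward, accepting at most
3 non-conserved columns per side, and trimmed to conserved ends. Masked
intervals (exons, UTRs, repeats) split the block before scanning, so no
element ever crosses a mask. Finally, elements with no fish row covering at
least half of their columns are dropped — the retention rule that anchors
the elements in ray-finned fish. Elements also supported by a tetrapod row
are flagged (`tetrapod_support`), the deep-conservation class usually
called vCNEs.

Two readings of the written procedure were genuinely open and are worth
recording. First, "90% identity in the seed" is implemented as the fraction
of conserved columns in the window, so seed and extension share a single
column predicate. Second, the per-column substitution fraction is measured
against the reference base, with gapped rows excluded from the denominator;
a consensus-based variant is available behind `scan_params(consensus =
TRUE)` but is not the default. Both choices are deliberately conservative
and are pinned down by an exhaustive oracle: on alignments of up to 60
columns, the scanner's output provably equals the enumeration of all
maximal intervals satisfying the seed + side-budget + end-on-conserved
definition (200 random alignments in the test suite, zero discrepancies
allowed).

The merged-seed trimming deserves one sentence: a 10-column fully conserved
stretch flanked by junk has 9/10-conserved neighbour windows that also
qualify, which would widen the raw merged run by one junk column on each
side; trimming to conserved ends restores the intuitive "exactly those 10
columns" seed, and makes the side budget count junk columns consistently.

## Pairwise (fish-specific) CNE search

`find_hits()` emulates the BLASTN-style search of a masked reference region
against paralog regions at desk scale, with exact rather than heuristic
alignment: full Smith–Waterman dynamic programming under match +1,
mismatch −1, and gap cost `2 + 2k` for a gap of length *k*. `N` mismatches
everything (including `N`), so hard-masked exons cannot anchor or extend
hits. Tie-breaks are deterministic: smaller query start, then smaller
subject start, then shorter alignment. Retained hits must span strictly
more than 50 aligned (match/mismatch) columns at ≥ 60% identity; identity
is matches over match+mismatch columns by default
(`identity_denominator = "with-gaps"` switches to the all-columns
convention). Both subject strands are searched; hits are reported
iteratively, the query footprint of each hard-masked before the next round,
which is the greedy analogue of BLAST's multiple-HSP reporting.

Two stopping rules bound the greedy loop. The score floor is the lowest
score an ungapped retainable hit can achieve
(`ceil(51 × (2×0.6 − 1)) = 11`). On multi-kb random background that floor
alone admits long streaks of score ~11 noise alignments, so the search also
stops after `max_nonretained_streak` (default 5) consecutive best hits that
fail the retention filters — justified because masking only removes
alignment paths, hence best scores are non-increasing across iterations.
The DP core is verified against a brute-force enumeration of all monotone
match chains on short sequences (≤ 8-mers), where the enumeration is
provably equivalent to scoring every local alignment.

One caveat the synthetic data exposed: if two conserved elements sit within
a few hundred bp of each other, the *optimal* local alignment can bridge
them through the unrelated spacer (the bridge costs less than a second
element gains) and report one chained hit. Real CNEs around developmental
genes are typically kilobases apart, and the generator's default spacing
(600 bp at the default element length/scoring) keeps chaining strictly
unprofitable. Users scanning dense regions should be aware that greedy
masking resolves overlaps but does not split chained hits.

## Partitioning ancestral CNEs between paralogs

`build_partition()` marks an ancestral CNE *present* in a species' paralog
environment when at least one retained hit overlaps at least half of the
CNE (the written analysis states no overlap criterion; 50% of the element
is the package's choice and is exposed as `min_overlap`).
`summarize_partition()` then classifies each CNE as a-only / b-only /
both / neither. Because the source reports single per-gene percentages
while its figures show per-species detections, aggregation across species
is explicit: `any_species` (default; a CNE is a-only if seen near *a*
somewhere and never near *b*), `all_species`, or `per_species`.

`count_asymmetry_test()` compares the per-unit CNE counts around the two
paralogs. Whether the original test was paired and what the sampling unit
was is not stated; the default is a paired t-test (counts are naturally
paired per gene or species), with the two-sample equal-variance form
available. Degenerate inputs are handled explicitly: zero-variance
differences give t = 0, p = 1 when the mean difference is zero, and a
machine-floor p with a `degenerate` flag otherwise. Under symmetric
synthetic retention — independent Binomial(N_g, 0.5) counts on both sides,
with N_g = (12, 6, 37, 3, 36) mirroring the five focal genes — the test's
type-I error at α = 0.05 stays within [0.02, 0.09] over 500 datasets
(`calibrate_count_asymmetry()`).

## Branch-partitioned codon models

The coding-sequence side fits Goldman–Yang codon models over the 61 sense
codons of the universal code, with one transition/transversion ratio κ,
codon frequencies either equal or F3x4 (position-specific nucleotide
frequencies, the default for real data), and the rate matrix scaled to one
expected substitution per codon per unit branch length. Branch dN/dS
classes come from newick tags (`#a`, `#b`, `#p`, untagged = `r`), read as:
all branches inside a paralog clade including its stem. Three nested
models are supported: **A** (one ω for all branches), **B** (ω^p for both
paralog clades jointly vs ω^r), and **C** (ω^a, ω^b, ω^r). Model
comparison uses 2ΔlnL against χ² with df = difference in free parameter
counts (one per step in A ⊂ B ⊂ C); the statistic is clipped at zero and
ω estimates sitting on their bounds ([1e-6, 50]) are flagged rather than
corrected.

Likelihoods are computed by Felsenstein pruning with per-branch transition
matrices `exp(Q t)` obtained by eigendecomposition of the reversible
generator's symmetrised form (π^{1/2} Q π^{−1/2}); tiny negative entries
from roundoff are clamped to zero, and site patterns are compressed before
pruning. The pruning core is checked three ways: against a brute-force sum
over all internal-node states on 3-taxon/10-codon instances (agreement to
1e-8, with `Matrix::expm()` as an independent matrix-exponential route);
against the zero-branch closed form Σ log π; and by the nesting identity
that model C with equal ω's reproduces model A exactly.

Fitting maximises κ, the ω classes, and (by default) all branch lengths
jointly with L-BFGS-B on log-transformed parameters, three seeded starting
points by default. Branch lengths can be fixed from the input tree
(`fix_branch_lengths = TRUE`). The simulation studies use a single
warm-started run per fit (`restarts = 1`), which changes nothing about the
distribution of the resulting MLE-based statistics but keeps 500-replicate
experiments to minutes.

Two simulation experiments back the inferential claims, both seeded and
reproducible. `calibrate_branch_lrt()` simulates under model A (6 taxa:
two 2-leaf paralog clades plus two outgroups; 200 codons; κ = 2, ω = 0.2)
and checks that the B-vs-A LRT rejects at ~5%: the acceptance band is
[0.03, 0.08] over 500 replicates. `recover_omega_asymmetry()` simulates
the asymmetric-evolution signature itself (ω^r = 0.05, ω^a = 0.5,
ω^b = 0.1; 300 codons; 8 taxa) and requires the fitted ω̂^a to exceed ω̂^b
in ≥ 90% of 50 replicates — the "one copy constrained, one copy relaxed"
pattern that motivates the whole analysis. The problem sizes (codon counts,
replicate numbers, taxon counts) are the experiments' stated study
conditions. Numerical agreement with published per-gene ω values is *not*
claimed: that would require the real alignments, which are not shipped.

## Retention landscape and expression

`summarize_landscape()` computes the duplicate-retention arithmetic over a
genes × species copy-number matrix: the fraction of genes duplicated in at
least one non-salmonid teleost, its split into duplicated-in-all vs
lineage-specific, the WGD retention rate, and per-salmonid retention
(salmonids are excluded from the teleost denominators throughout, since
their extra WGD inflates copy numbers). The packaged 19-gene sox fixture
is transcribed from the in-text gene lists, not digitised from a figure;
per-gene salmonid copy numbers are synthetic, chosen only to match the
reported totals (51 and 49) and the > 80% salmonid retention statement.
Percentages are reported with standard round-half-up to one decimal. The
source text itself rounds inconsistently (11/19 appears as 57.8, a
truncation, while 3/11 appears as 27.3 and 21/37 as 56.8, both rounded; no
single rule reproduces every printed value), so rounding was chosen as the
convention that matches the most printed figures, and comparisons against
printed values allow a 0.1-point slack where the conventions differ.

`quantify_ddct()` implements Livak ΔΔCt quantification: replicate Cq values
are averaged (arithmetic mean; no aggregation rule was stated), mean
Cq ≥ 34 is a non-detect and propagates, ΔCt = Cq_target − Cq_reference
within each sample, ΔΔCt is taken against a user-chosen calibrator sample
(the original calibrator is unstated, so it is a required input), and
relative expression is 2^−ΔΔCt. The published low-expression rule
"ΔΔCT ≤ 0.10" is internally inconsistent under Livak scaling — a ΔΔCt of
0.10 is *high* expression — and is interpreted as relative expression
2^−ΔΔCt ≤ 0.10, with the literal raw-ΔΔCt threshold available via
`threshold_on = "ddct"`. The bin boundary is closed (≤) and exact; samples
whose reference gene is undetected are flagged, never silently dropped.

## The synthetic-data generators

`make_planted_alignment()` emulates the divergence regime the scanner
faces: every non-reference species copies the reference per column with
match probability 0.60 in background and 0.98 inside planted elements,
mismatches drawn uniformly from the three alternatives, gaps only in
background (so truth intervals stay exact), defaults of nine fish and two
tetrapod rows mirroring the study's taxon classes. The background level
sits below the 60% pairwise identity threshold and the planted level above
every threshold, by construction. What the generator does *not* model:
indels inside elements, rearrangements, local rate variation, or
phylogenetic correlation between species (each row diverges independently).
Passing tests therefore demonstrate correctness of the algorithms under
the stated regime, not scanner performance on real alignments, where
conservation is tree-structured.

`make_paralog_dataset()` plants ancestral elements and retains each
independently near paralog *a* (probability `p_keep_a`) and *b*
(`p_keep_b`) per species, emitting sequences the pairwise search can
rediscover (98% identity copies in unrelated background) plus the truth
partition table. `make_landscape()` and `make_cq_table()` provide
copy-number matrices and noisy Cq tables with known truth. All generators
require a seed and are exactly reproducible; `sub_seeds()` derives
per-replicate seeds below 2^31.

## Numerical and engineering choices

* Coordinates are 0-based half-open everywhere inside the package; MAF and
  BED pass through unchanged, GRanges conversion happens only at the
  boundary.
* The alignment DP and the pruning likelihood are C++ (Rcpp /
  RcppArmadillo); the DP keeps full traceback matrices (uint8 per state)
  with rolling score rows, and refuses inputs beyond ~2.5e8 cells rather
  than paging.
* Optimiser tolerances: `factr = 1e6` by default (~4e-7 relative lnL),
  `1e7` in the 500-replicate experiments; the nesting invariant
  lnL(C) ≥ lnL(B) ≥ lnL(A) is asserted with 1e-4 slack for optimiser
  noise.
* Analysis drivers under `analysis/` are thin narratives over the package
  functions and write everything to `results/`; the full calibration
  experiments run from `scripts/acceptance.R` and the test suite, with
  problem sizes as documented above.

## Known limitations

* The scanner's column predicate ignores the phylogeny (no tree-aware
  conservation score); that is faithful to the original column-counting
  algorithm, not a modelling recommendation.
* The pairwise search is exact DP, not word-seeded; it is meant for
  regions up to a few hundred kb per pair, not genome-wide search, and has
  no E-value statistics.
* Greedy best-hit-and-mask discovery does not enumerate suboptimal
  alignments and can chain elements planted unrealistically close
  together (see above).
* codeml run settings of the original analysis (CodonFreq, initial values,
  cleandata details) are unknown; published per-gene ω values are treated
  as irreproducible without the real data and are not acceptance surfaces.
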