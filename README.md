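# ohnocne

Evolutionary analysis of whole-genome-duplication (WGD) paralogs and the
conserved non-coding elements (CNEs) around them, in the teleost setting:
after the teleost-specific WGD, which duplicate pairs (*ohnologs*, copies
*a* and *b*) were retained, how asymmetrically did their cis-regulatory
neighbourhoods erode, and did one copy's coding sequence evolve under
relaxed constraint? The package is aimed at comparative genomicists who
want the full chain — CNE detection, paralog partition statistics, branch
dN/dS model comparison, retention arithmetic, qPCR quantification — as
tested, reusable functions rather than one-off scripts.

## What it computes

* **Multi-species CNE scanning** (`scan_cnes()`): a seed-and-extend scan
  of reference-anchored alignments (MAF). A column is conserved when the
  substitution fraction among informative rows is < 0.12; seeds are 10-bp
  windows at ≥ 90% conserved columns, extended with up to 3 non-conserved
  columns per side, masked away from exons/repeats, and retained only with
  fish support. Output is BED6 plus a per-element support table.
* **Pairwise fish-specific search** (`find_hits()`): exact Smith–Waterman
  local alignment under BLASTN-style scoring (match +1, mismatch −1, gap
  open 2, extend 2), both strands, iterative best-hit-and-mask reporting;
  hits > 50 aligned columns at ≥ 60% identity are retained.
* **Paralog partition** (`build_partition()`, `summarize_partition()`,
  `count_asymmetry_test()`): classify each ancestral CNE as a-only /
  b-only / both / neither across species and test the per-paralog count
  asymmetry with a (paired) t-test.
* **Branch-partitioned codon models** (`fit_codon_model()`,
  `codon_lrt()`, `simulate_codon_alignment()`): Goldman–Yang models over
  the 61 sense codons with branch ω classes — model A (one ω), B (ω^p for
  paralog branches vs ω^r), C (ω^a, ω^b, ω^r) — fitted by maximum
  likelihood (Felsenstein pruning in C++), compared by 2ΔlnL ~ χ².
* **Retention landscape** (`summarize_landscape()`): duplicate-retention
  percentages over a genes × species copy-number matrix, salmonids
  handled separately.
* **ΔΔCt expression** (`quantify_ddct()`): Livak quantification with a
  34-cycle detection limit and a low-expression bin at relative
  expression ≤ 0.10.
* **Synthetic data** (`make_planted_alignment()`,
  `make_paralog_dataset()`, `make_landscape()`, `make_cq_table()`):
  seeded generators with exact ground truth for every stage.

## Worked example

Scan a simulated alignment with planted elements, summarise the sox
retention landscape, and recover the asymmetric-ω signature:

```r
library(ohnocne)

sim <- make_planted_alignment(length = 2000, cne_lengths = c(25L, 30L), seed = 7)
scan_cnes(sim$block, params = scan_params())[, c(1:3, 5, 7, 10, 11)]
#>        seqid start  end score length fish_support tetrapod_support
#> 1 ref_region   297  322    96     25         TRUE             TRUE
#> 2 ref_region  1466 1496   100     30         TRUE             TRUE
```

Both planted elements (truth: 297–322 and 1466–1496) come back exactly;
the score column is the percent of conserved columns.

```r
summarize_landscape(sox_landscape())
#> <retention_report> 19 genes
#>   duplicated in >=1 teleost: 11 (57.9%)
#>   of these, in all species: 3 (27.3%); lineage-specific: 8 (72.7%)
#>   WGD retention: 10/19 (52.6%); salmonid retention: 84.2%
```

Eleven of the nineteen family members are duplicated in at least one
non-salmonid teleost; ten of those pairs are WGD-derived, a 52.6%
retention rate, far above the genome-wide 12-24% background.

```r
tr <- read_labeled_tree(
  "((A1#a:0.2,A2#a:0.2)#a:0.1,(B1#b:0.2,B2#b:0.2)#b:0.1,(O1:0.2,O2:0.2):0.1);")
aln <- simulate_codon_alignment(tr, model = "C", kappa = 2,
                                omega = c(r = 0.05, a = 0.5, b = 0.1),
                                pi = codon_frequencies(method = "equal"),
                                n_codons = 300, seed = 11)
fb <- fit_codon_model(aln, tr, "B", codon_freq = "equal", restarts = 1)
fc <- fit_codon_model(aln, tr, "C", codon_freq = "equal", restarts = 1,
                      start = list(kappa = fb$kappa,
                                   omega = c(r = unname(fb$omega["r"]),
                                             a = unname(fb$omega["p"]),
                                             b = unname(fb$omega["p"])),
                                   branch_lengths = fb$branch_lengths))
fc
#> <codon_model_fit> model C  lnL = -2938.0052  kappa = 2.027
#>   omega: r=0.0701  a=0.5042  b=0.1514
codon_lrt(fb, fc)[c("statistic", "df", "p")]
#> $statistic
#> [1] 21.12794
#> $df
#> [1] 1
#> $p
#> [1] 4.296186e-06
```

The fitted ω̂ values recover the simulated asymmetry (paralog *a* relaxed
at ω ≈ 0.5, paralog *b* constrained near 0.1), and the C-vs-B likelihood
ratio test rejects the shared-paralog-ω model decisively.

The numbered scripts under `analysis/` run the same machinery as a
narrative workflow (simulate inputs → scan → pairwise + partition → codon
models → landscape + expression), writing tables under `results/`.

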