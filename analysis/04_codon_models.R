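#!/usr/bin/env Rscript

# Branch-partitioned dN/dS analysis on simulated ohnolog codon alignments:
# evolve sequences under asymmetric selection (paralog a relaxed, paralog b
# and orthologs constrained), fit models A (one omega), B (paralogs vs
# rest) and C (a vs b vs rest), and run the nested LRTs -- the same table
# layout a codeml branch-model analysis would produce.

suppressMessages(library(ohnocne))

outdir <- "results/codon"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922L

tree <- read_labeled_tree(paste0(
  "(((A1#a:0.15,A2#a:0.15)#a:0.1,A3#a:0.25)#a:0.1,",
  "((B1#b:0.15,B2#b:0.15)#b:0.1,B3#b:0.25)#b:0.1,",
  "(O1:0.2,O2:0.2):0.1);"))
true_omega <- c(r = 0.05, a = 0.5, b = 0.1)
pi <- codon_frequencies(method = "equal")

rows <- list()
for (rep in 1:3) {
  aln <- simulate_codon_alignment(tree, "C", kappa = 2, omega = true_omega,
                                  pi = pi, n_codons = 300L,
                                  seed = seed + rep)
  write_codon_fasta(aln, file.path(outdir, sprintf("alignment_%d.fa", rep)))
  fa <- fit_codon_model(aln, tree, "A", codon_freq = "equal", restarts = 1)
  fb <- fit_codon_model(aln, tree, "B", codon_freq = "equal", restarts = 1,
                        start = list(kappa = fa$kappa,
                                     omega = c(r = unname(fa$omega[1]),
                                               p = unname(fa$omega[1])),
                                     branch_lengths = fa$branch_lengths))
  fc <- fit_codon_model(aln, tree, "C", codon_freq = "equal", restarts = 1,
                        start = list(kappa = fb$kappa,
                                     omega = c(r = unname(fb$omega["r"]),
                                               a = unname(fb$omega["p"]),
                                               b = unname(fb$omega["p"])),
                                     branch_lengths = fb$branch_lengths))
  ab <- codon_lrt(fa, fb)
  bc <- codon_lrt(fb, fc)
  rows[[rep]] <- data.frame(
    replicate = rep,
    lnL_A = fa$lnL, lnL_B = fb$lnL, lnL_C = fc$lnL,
    omega_all = unname(fa$omega["omega"]),
    omega_r = unname(fc$omega["r"]),
    omega_a = unname(fc$omega["a"]),
    omega_b = unname(fc$omega["b"]),
    lrt_AB_stat = ab$statistic, lrt_AB_p = ab$p,
    lrt_BC_stat = bc$statistic, lrt_BC_p = bc$p)
  cat(sprintf(
    "rep %d: lnL A/B/C = %.2f/%.2f/%.2f; omega_a = %.3f, omega_b = %.3f (truth 0.5/0.1); B-vs-A p = %.3g, C-vs-B p = %.3g\n",
    rep, fa$lnL, fb$lnL, fc$lnL, fc$omega["a"], fc$omega["b"], ab$p, bc$p))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(outdir, "model_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("omega_a > omega_b in %d/3 replicates\n",
            sum(tab$omega_a > tab$omega_b)))
cat("full calibration experiments: calibrate_branch_lrt(), ",
    "recover_omega_asymmetry() (see the methods vignette)\n", sep = "")
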