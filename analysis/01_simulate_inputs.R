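#!/usr/bin/env Rscript

# Generate the synthetic study bundle every downstream step consumes:
# a reference-anchored multi-species alignment with planted conserved
# elements, exon-like masks, paralog-pair regions with asymmetric CNE
# retention, the transcribed sox landscape, and a qPCR Cq table.
# All files land in results/analysis_inputs/.

suppressMessages(library(ohnocne))

seed <- 20260922L
dir <- "results/analysis_inputs"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

## multi-species alignment with planted elements (scanner input)
masks <- genomic_intervals("ref_region", c(900L, 2600L), c(1100L, 2750L))
sim <- make_planted_alignment(length = 6000L,
                              cne_lengths = c(20L, 25L, 30L, 35L, 40L, 30L),
                              mask_intervals = masks, seed = seed)
write_maf(list(sim$block), file.path(dir, "region.maf"))
write_bed(masks, file.path(dir, "exon_mask.bed"))
write_bed(sim$truth, file.path(dir, "planted_truth.bed"))
cat(sprintf("alignment: %d species x %d columns, %d planted elements\n",
            nrow(sim$block$rows), block_ncol(sim$block), nrow(sim$truth)))

## paralog regions with asymmetric retention (pairwise + partition input)
pd <- make_paralog_dataset(n_cnes = 6L, p_keep_a = 0.25, p_keep_b = 0.9,
                           n_species = 3L, seed = seed + 1L)
writeLines(c(">gar_region", pd$query), file.path(dir, "gar_region.fa"))
for (sp in names(pd$subjects)) {
  for (par in c("a", "b")) {
    writeLines(c(sprintf(">%s_paralog_%s", sp, par),
                 pd$subjects[[sp]][[par]]),
               file.path(dir, sprintf("%s_paralog_%s.fa", sp, par)))
  }
}
bed <- pd$query_cnes
bed$seqid <- "gar_region"
write_bed(bed, file.path(dir, "gar_cnes.bed"))
write.table(pd$truth, file.path(dir, "retention_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("paralog bundle: %d ancestral CNEs x %d species (keep a=%.2f, b=%.2f)\n",
            6L, 3L, 0.25, 0.9))

## landscape (transcribed fixture) and a Cq table with known fold changes
write_landscape(sox_landscape(), file.path(dir, "sox_landscape.tsv"))
design <- expand.grid(sample = c("embryo_seg", "embryo_hatch", "brain"),
                      gene = c("sox9a", "sox9b", "rpl7"),
                      stringsAsFactors = FALSE)
design$true_cq <- c(24, 26, 29, 27, 25, 33.5, 20, 20, 20)
cq <- make_cq_table(design, noise_sd = 0.15, seed = seed + 2L)
write.table(cq, file.path(dir, "cq_table.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("landscape and Cq tables written\n")
cat("inputs ready under", dir, "\n")
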