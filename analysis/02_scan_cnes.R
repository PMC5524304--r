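#!/usr/bin/env Rscript

# Scan the simulated multi-species alignment for conserved non-coding
# elements with the study parameters (10-bp seed at 90%, 3 non-conserved
# columns per side, 12% column substitution threshold, fish-presence
# filter), and compare the calls against the planted truth.

suppressMessages(library(ohnocne))

indir <- "results/analysis_inputs"
outdir <- "results/scan"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

blocks <- read_maf(file.path(indir, "region.maf"),
                   species_class = c(
                     setNames(rep("fish", 9), paste0("fish", 1:9)),
                     setNames(rep("tetrapod", 2), paste0("tetrapod", 1:2))))
masks <- read_bed(file.path(indir, "exon_mask.bed"))
truth <- read_bed(file.path(indir, "planted_truth.bed"), merge = FALSE)

calls <- scan_cnes(blocks, masks, scan_params())
write_bed(calls, file.path(outdir, "cnes.bed"))
write.table(calls, file.path(outdir, "cnes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d CNEs called from %d planted elements\n",
            nrow(calls), nrow(truth)))
recovered <- vapply(seq_len(nrow(truth)), function(i) {
  ov <- pmin(calls$end, truth$end[i]) - pmax(calls$start, truth$start[i])
  any(ov >= 0.8 * (truth$end[i] - truth$start[i]) &
        ov >= 0.8 * (calls$end - calls$start))
}, logical(1))
cat(sprintf("recovered at >=80%% reciprocal overlap: %d/%d\n",
            sum(recovered), nrow(truth)))
cat(sprintf("tetrapod-supported (vCNE-like) calls: %d\n",
            sum(calls$tetrapod_support)))
overlaps_mask <- vapply(seq_len(nrow(masks)), function(i) {
  any(calls$start < masks$end[i] & calls$end > masks$start[i])
}, logical(1))
stopifnot(!any(overlaps_mask))
cat("no call overlaps a masked interval\n")
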