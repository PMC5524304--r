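#!/usr/bin/env Rscript

# Duplicate-retention landscape arithmetic on the transcribed 19-gene sox
# matrix, and ddCt expression quantification of the simulated Cq table.

suppressMessages(library(ohnocne))

indir <- "results/analysis_inputs"
outdir <- "results/summary"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ls <- read_landscape(file.path(indir, "sox_landscape.tsv"))
rep <- summarize_landscape(ls)
print(rep)
jsonlite::write_json(unclass(rep), file.path(outdir, "landscape.json"),
                     auto_unbox = TRUE, digits = NA, na = "null")
sal <- salmonid_retention(ls)
cat(sprintf("salmonid retention: %s; pooled %.1f%%\n",
            paste(sprintf("%s %.1f%%", names(sal$per_species_pct),
                          sal$per_species_pct), collapse = ", "),
            sal$pooled_pct))

cq <- read_cq_table(file.path(indir, "cq_table.tsv"))
calls <- quantify_ddct(cq, reference_gene = "rpl7",
                       calibrator_sample = "embryo_seg")
write.table(calls, file.path(outdir, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nexpression calls (reference rpl7, calibrator embryo_seg):\n")
print(calls[, c("gene", "sample", "delta_delta_ct", "relative_expression",
                "bin")])
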