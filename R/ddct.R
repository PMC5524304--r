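#' Read a qPCR Cq table
#'
#' TSV with header `sample<TAB>gene<TAB>cq`; one row per replicate. Empty
#' or `NA` cq fields are non-detects.
#'
#' @param path TSV file path.
#' @return Data frame with columns `sample`, `gene`, `cq`.
#' @export
read_cq_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "gene", "cq") %in% names(df)))
  df$cq <- suppressWarnings(as.numeric(df$cq))
  if (any(!is.na(df$cq) & df$cq <= 0)) {
    stop("Cq values must be positive", call. = FALSE)
  }
  df
}

#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Cq values are averaged per (sample, gene); mean Cq values at or
#' beyond the limit of detection (`lod`, default 34 cycles) become
#' non-detects and propagate. For detected targets,
#' `dCt = Cq_target - Cq_reference` within each sample,
#' `ddCt = dCt_sample - dCt_calibrator`, and relative expression is
#' `2^-ddCt`. Calls with relative expression at or below `low_threshold`
#' (default 0.10) are binned `low`; by construction the boundary is exact.
#' Setting `threshold_on = "ddct"` instead bins on the raw ddCt value.
#'
#' @param cq_table data frame from [read_cq_table()] (or with the same
#'   columns).
#' @param reference_gene normaliser gene id; must be detected in every
#'   sample (samples where it is not are flagged, not dropped).
#' @param calibrator_sample sample id used as the ddCt baseline.
#' @param lod limit of detection in cycles; mean Cq >= lod is a non-detect.
#' @param low_threshold boundary of the `low` expression bin.
#' @param threshold_on `"relative"` (default: bin on `2^-ddCt`) or
#'   `"ddct"` (bin on the raw ddCt).
#' @return Data frame of expression calls: `gene`, `sample`, `cq`,
#'   `delta_ct`, `delta_delta_ct`, `relative_expression`, `bin`
#'   (`nondetect`, `low` or `expressed`), `flag`.
#' @export
quantify_ddct <- function(cq_table, reference_gene, calibrator_sample,
                          lod = 34, low_threshold = 0.10,
                          threshold_on = c("relative", "ddct")) {
  threshold_on <- match.arg(threshold_on)
  stopifnot(all(c("sample", "gene", "cq") %in% names(cq_table)))
  if (!reference_gene %in% cq_table$gene) {
    stop("reference gene ", reference_gene, " not in table", call. = FALSE)
  }
  if (!calibrator_sample %in% cq_table$sample) {
    stop("calibrator sample ", calibrator_sample, " not in table",
         call. = FALSE)
  }
  agg <- stats::aggregate(cq ~ sample + gene, data = cq_table, FUN = mean,
                          na.action = stats::na.pass,
                          na.rm = TRUE)
  agg$cq[!is.finite(agg$cq)] <- NA_real_
  agg$cq[!is.na(agg$cq) & agg$cq >= lod] <- NA_real_   # beyond detection

  ref <- agg[agg$gene == reference_gene, c("sample", "cq")]
  names(ref)[2L] <- "ref_cq"
  calls <- agg[agg$gene != reference_gene, , drop = FALSE]
  calls <- merge(calls, ref, by = "sample", all.x = TRUE)
  calls$flag <- ifelse(is.na(calls$ref_cq), "missing_reference", "")
  calls$delta_ct <- calls$cq - calls$ref_cq

  cal <- calls[calls$sample == calibrator_sample,
               c("gene", "delta_ct")]
  names(cal)[2L] <- "cal_delta_ct"
  calls <- merge(calls, cal, by = "gene", all.x = TRUE)
  calls$flag[is.na(calls$cal_delta_ct) & calls$flag == ""] <-
    "calibrator_nondetect"
  calls$delta_delta_ct <- calls$delta_ct - calls$cal_delta_ct
  calls$relative_expression <- 2^(-calls$delta_delta_ct)

  bin <- rep("expressed", nrow(calls))
  bin[!is.na(calls$relative_expression) &
        (if (threshold_on == "relative") {
          calls$relative_expression <= low_threshold
        } else {
          calls$delta_delta_ct <= low_threshold
        })] <- "low"
  bin[is.na(calls$relative_expression) & !is.na(calls$cq)] <- NA_character_
  bin[is.na(calls$cq)] <- "nondetect"
  calls$bin <- bin
  out <- calls[order(calls$gene, calls$sample),
               c("gene", "sample", "cq", "delta_ct", "delta_delta_ct",
                 "relative_expression", "bin", "flag")]
  rownames(out) <- NULL
  out
}
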