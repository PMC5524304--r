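#' Read / write BED interval files
#'
#' `read_bed()` reads a 3+ column BED file (0-based half-open) into a
#' normalised mask track: intervals sorted and overlapping/bookended runs
#' merged. `write_bed()` writes BED6; for CNE calls the score column carries
#' the percent of conserved columns (0-100).
#'
#' @param path file path.
#' @param merge merge overlapping intervals (default `TRUE`; set `FALSE` to
#'   keep records as-is, e.g. for feature files rather than masks).
#' @return `read_bed()`: a `genomic_intervals` data frame.
#' @export
read_bed <- function(path, merge = TRUE) {
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^(#|track|browser)", first) & nzchar(trimws(first))]
  if (length(first) == 0L) return(genomic_intervals())
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("BED validation error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- granges_to_intervals(gr)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) df$name <- nm
  sc <- S4Vectors::mcols(gr)$score
  if (!is.null(sc)) df$score <- sc
  validate_intervals(df)
  if (merge) merge_intervals(df) else df
}

#' @rdname read_bed
#' @param df data frame with columns `seqid`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @export
write_bed <- function(df, path) {
  validate_intervals(within_strand(df))
  out <- data.frame(
    chrom = df$seqid,
    start = df$start,
    end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) round(df$score, 1) else 0,
    strand = if ("strand" %in% names(df)) ifelse(df$strand == "*", ".", df$strand) else ".",
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# fill in a strand column when absent so validation can run
within_strand <- function(df) {
  if (!"strand" %in% names(df)) df$strand <- "*"
  df
}
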