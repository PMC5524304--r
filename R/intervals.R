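#' Genomic intervals
#'
#' All coordinates in this package are 0-based, half-open `[start, end)`,
#' the convention of BED and MAF. Intervals are carried as plain data frames
#' with columns `seqid`, `start`, `end` and `strand`; converters to and from
#' [GenomicRanges::GRanges] (1-based, closed) live at the boundary so the two
#' conventions never mix inside the package.
#'
#' @param seqid character vector of sequence identifiers.
#' @param start,end integer vectors, 0-based half-open; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded), recycled.
#' @return A data frame with class `c("genomic_intervals", "data.frame")`.
#' @examples
#' genomic_intervals("chr1", 10, 20)
#' @export
genomic_intervals <- function(seqid = character(), start = integer(),
                              end = integer(), strand = "*") {
  n <- max(length(seqid), length(start), length(end))
  if (n == 0L) {
    df <- data.frame(seqid = character(), start = integer(),
                     end = integer(), strand = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("genomic_intervals", "data.frame")
    return(df)
  }
  df <- data.frame(seqid = as.character(seqid),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("seqid", "start", "end", "strand") %in% names(df)))
  if (any(df$start < 0L)) stop("interval start must be >= 0", call. = FALSE)
  if (any(df$start >= df$end)) {
    stop("interval start must be < end (0-based half-open)", call. = FALSE)
  }
  bad <- setdiff(unique(df$strand), c("+", "-", "*"))
  if (length(bad)) {
    stop("invalid strand value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Convert intervals to/from GRanges
#'
#' `intervals_to_granges()` shifts to 1-based closed coordinates;
#' `granges_to_intervals()` is its inverse.
#'
#' @param df a `genomic_intervals` data frame.
#' @param gr a [GenomicRanges::GRanges] object.
#' @return A `GRanges`, or a `genomic_intervals` data frame.
#' @export
intervals_to_granges <- function(df) {
  validate_intervals(df)
  GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand == "*", "*", df$strand)
  )
}

#' @rdname intervals_to_granges
#' @export
granges_to_intervals <- function(gr) {
  genomic_intervals(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Sort and merge overlapping intervals
#'
#' Normalises a mask track: sorts by (seqid, start) and merges overlapping or
#' bookended intervals, dropping strand. Uses [GenomicRanges::reduce()].
#'
#' @param df a `genomic_intervals` data frame.
#' @return A merged `genomic_intervals` data frame.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(genomic_intervals())
  gr <- GenomicRanges::reduce(intervals_to_granges(df), ignore.strand = TRUE)
  out <- granges_to_intervals(gr)
  out[order(out$seqid, out$start), , drop = FALSE]
}
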