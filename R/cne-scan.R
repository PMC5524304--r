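#' Parameters for the multi-species conservation scanner
#'
#' The scanner looks for conserved non-coding elements (CNEs) in a
#' reference-anchored multiple alignment by a seed-and-extend rule: a seed is
#' a window of `seed_length` consecutive reference-base columns in which at
#' least `ceil(seed_identity * seed_length)` columns are conserved; seeds are
#' extended outward, tolerating up to `max_nonconserved_per_side`
#' non-conserved columns on each side, and trimmed to start and end on
#' conserved columns. A column is conserved when the fraction of non-gap,
#' non-reference rows whose base differs from the reference base is strictly
#' below `column_substitution_threshold`, with at least
#' `min_species_in_column` informative rows.
#'
#' @param seed_length seed window width in alignment columns (default 10).
#' @param seed_identity minimum fraction of conserved columns in the seed
#'   window (default 0.90).
#' @param max_nonconserved_per_side non-conserved columns tolerated on each
#'   side during extension (default 3).
#' @param column_substitution_threshold per-column substitution fraction;
#'   strict upper bound (default 0.12).
#' @param min_species_in_column minimum informative (non-gap, non-reference)
#'   rows for a column to be scoreable (default 3).
#' @param window_up,window_down size in bp of the windows flanking a focal
#'   gene within which the scan is meant to run (default 1 Mb each side);
#'   carried as metadata, the scanner processes whatever region it is given.
#' @param fish_presence_min_cover a species supports an element when it has
#'   non-gap bases over at least this fraction of the element's columns
#'   (default 0.50); elements with no supporting fish species are dropped.
#' @param consensus score substitutions against the column consensus base
#'   instead of the reference base (default `FALSE`).
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(seed_length = 10L,
                        seed_identity = 0.90,
                        max_nonconserved_per_side = 3L,
                        column_substitution_threshold = 0.12,
                        min_species_in_column = 3L,
                        window_up = 1e6,
                        window_down = 1e6,
                        fish_presence_min_cover = 0.50,
                        consensus = FALSE) {
  stopifnot(seed_length >= 1L,
            seed_identity > 0, seed_identity <= 1,
            column_substitution_threshold >= 0,
            column_substitution_threshold < 1,
            max_nonconserved_per_side >= 0L,
            min_species_in_column >= 1L,
            fish_presence_min_cover >= 0, fish_presence_min_cover <= 1)
  structure(list(seed_length = as.integer(seed_length),
                 seed_identity = seed_identity,
                 max_nonconserved_per_side = as.integer(max_nonconserved_per_side),
                 column_substitution_threshold = column_substitution_threshold,
                 min_species_in_column = as.integer(min_species_in_column),
                 window_up = window_up, window_down = window_down,
                 fish_presence_min_cover = fish_presence_min_cover,
                 consensus = consensus),
            class = "scan_params")
}

#' Column conservation predicate
#'
#' `conserved_columns()` returns the per-column conservation status of a
#' whole block; `column_conserved()` is the single-column accessor. Gapped
#' rows are excluded from the denominator; `N` never counts as identity
#' (it mismatches every base, including `N`); reference-gap columns are never
#' conserved.
#'
#' @param block an [alignment_block].
#' @param params a [scan_params] list.
#' @return `conserved_columns()`: logical vector, one element per column.
#' @export
conserved_columns <- function(block, params = scan_params()) {
  m <- block_matrix(block)
  ref <- m[1L, ]
  nc <- ncol(m)
  if (nrow(m) == 1L) return(rep(FALSE, nc))
  oth <- m[-1L, , drop = FALSE]
  nongap <- oth != "-"
  informative <- colSums(nongap)
  target <- if (isTRUE(params$consensus)) consensus_base(m) else ref
  tmat <- matrix(target, nrow = nrow(oth), ncol = nc, byrow = TRUE)
  mism <- nongap & (oth != tmat | oth == "N" | tmat == "N")
  frac <- ifelse(informative > 0, colSums(mism) / informative, 1)
  ref != "-" &
    informative >= params$min_species_in_column &
    frac < params$column_substitution_threshold
}

# majority base over all non-gap rows; ties broken A < C < G < T < N
consensus_base <- function(m) {
  apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    tab <- table(factor(col, levels = c("A", "C", "G", "T", "N")))
    names(tab)[which.max(tab)]
  })
}

#' @rdname conserved_columns
#' @param column_index 1-based column index.
#' @export
column_conserved <- function(block, column_index, params = scan_params()) {
  nc <- block_ncol(block)
  if (column_index < 1L || column_index > nc) {
    stop("column index out of range: ", column_index, call. = FALSE)
  }
  conserved_columns(block, params)[column_index]
}

#' Find seed windows
#'
#' Returns maximal merged runs of qualifying seed windows as 1-based column
#' intervals. A window qualifies when all `seed_length` columns carry a
#' reference base and at least `ceil(seed_identity * seed_length)` of them
#' are conserved. Overlapping qualifying windows are merged, and each merged
#' run is trimmed so it starts and ends on a conserved column (a 10-column
#' fully conserved stretch flanked by junk yields exactly those 10 columns,
#' even though its 9/10-conserved neighbour windows also qualify).
#'
#' @inheritParams conserved_columns
#' @param conserved optional precomputed [conserved_columns()] vector.
#' @return Data frame with columns `start_col`, `end_col` (1-based, closed).
#' @export
find_seeds <- function(block, params = scan_params(), conserved = NULL) {
  if (is.null(conserved)) conserved <- conserved_columns(block, params)
  L <- params$seed_length
  nc <- length(conserved)
  if (nc < L) return(data.frame(start_col = integer(), end_col = integer()))
  refbase <- strsplit(toupper(block$rows$text[1L]), "", fixed = TRUE)[[1L]] != "-"
  need <- ceiling(params$seed_identity * L)
  gapcum <- cumsum(!refbase)
  conscum <- cumsum(conserved)
  starts <- seq_len(nc - L + 1L)
  allref <- (gapcum[starts + L - 1L] - c(0, gapcum)[starts]) == 0L
  ncons <- conscum[starts + L - 1L] - c(0, conscum)[starts]
  qual <- allref & ncons >= need
  if (!any(qual)) return(data.frame(start_col = integer(), end_col = integer()))
  covered <- rep(FALSE, nc)
  for (s in starts[qual]) covered[s:(s + L - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  keep <- r$values
  begs <- begs[keep]
  ends <- ends[keep]
  # trim merged runs so seeds start and end on conserved columns
  for (k in seq_along(begs)) {
    cc <- which(conserved[begs[k]:ends[k]]) + begs[k] - 1L
    begs[k] <- cc[1L]
    ends[k] <- cc[length(cc)]
  }
  data.frame(start_col = begs, end_col = ends)
}

#' Extend a seed outward
#'
#' Extends a merged seed interval column by column on each side, including at
#' most `max_nonconserved_per_side` non-conserved columns per side, and trims
#' the result so its first and last columns are conserved.
#'
#' @inheritParams find_seeds
#' @param seed 1-element data frame or list with `start_col`, `end_col`.
#' @return A list with `start_col`, `end_col` of the extended, trimmed element.
#' @export
extend_seed <- function(block, seed, params = scan_params(), conserved = NULL) {
  if (is.null(conserved)) conserved <- conserved_columns(block, params)
  nc <- length(conserved)
  s <- seed$start_col; e <- seed$end_col
  budget <- params$max_nonconserved_per_side
  # rightmost conserved column reachable with <= budget non-conserved after e
  right <- max(which(conserved[s:e])) + s - 1L
  cnt <- 0L
  k <- e + 1L
  while (k <= nc) {
    if (conserved[k]) {
      right <- k
    } else {
      cnt <- cnt + 1L
      if (cnt > budget) break
    }
    k <- k + 1L
  }
  left <- min(which(conserved[s:e])) + s - 1L
  cnt <- 0L
  k <- s - 1L
  while (k >= 1L) {
    if (conserved[k]) {
      left <- k
    } else {
      cnt <- cnt + 1L
      if (cnt > budget) break
    }
    k <- k - 1L
  }
  list(start_col = left, end_col = right)
}

#' Split a block at masked reference positions
#'
#' Columns whose reference coordinate falls inside a mask interval are
#' removed entirely and the block is split into the remaining contiguous
#' pieces, so seeds and extensions can never cross a masked region.
#' Reference-gap columns are never masked (they have no reference
#' coordinate).
#'
#' @param block an [alignment_block].
#' @param masks a `genomic_intervals` data frame (exon/UTR/repeat masks) in
#'   reference coordinates, or `NULL` for no masking.
#' @param warn_outside warn about mask intervals on the block's sequence that
#'   do not overlap it (default `TRUE`).
#' @return A list of `alignment_block` (possibly empty).
#' @export
mask_block <- function(block, masks = NULL, warn_outside = TRUE) {
  if (is.null(masks) || nrow(masks) == 0L) return(list(block))
  refseq <- block$rows$seqid[1L]
  m <- masks[masks$seqid == refseq, , drop = FALSE]
  pos <- block_ref_coordinates(block)
  blk_lo <- block$rows$start[1L]
  blk_hi <- blk_lo + block$rows$size[1L]
  if (warn_outside && nrow(m)) {
    outside <- m$end <= blk_lo | m$start >= blk_hi
    if (any(outside)) {
      warning(sum(outside), " mask interval(s) outside block [",
              blk_lo, ",", blk_hi, ") ignored", call. = FALSE)
    }
  }
  masked <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(m))) {
    masked <- masked | (!is.na(pos) & pos >= m$start[i] & pos < m$end[i])
  }
  if (!any(masked)) return(list(block))
  keep <- !masked
  if (!any(keep)) return(list())
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  pieces <- which(r$values)
  lapply(pieces, function(p) subset_block(block, begs[p]:ends[p]))
}

# contiguous column subset of a block, with per-row coordinates re-anchored
subset_block <- function(block, cols) {
  rows <- block$rows
  charlists <- strsplit(rows$text, "", fixed = TRUE)
  newtext <- vapply(charlists, function(ch) paste(ch[cols], collapse = ""),
                    character(1))
  before <- vapply(charlists, function(ch) {
    sum(ch[seq_len(min(cols) - 1L)] != "-")
  }, integer(1))
  rows$start <- rows$start + before
  rows$size <- nchar(gsub("-", "", newtext, fixed = TRUE))
  rows$text <- newtext
  alignment_block(rows, species_class = block$species_class)
}

#' Scan alignment blocks for conserved non-coding elements
#'
#' Full pipeline over one or more blocks sharing a reference: mask, find
#' seeds, extend, merge overlapping elements, convert to reference
#' coordinates, and drop elements lacking fish support (no fish row with
#' non-gap bases over at least `fish_presence_min_cover` of the element's
#' columns). Output is deterministic, sorted by start then end.
#'
#' @param blocks an [alignment_block] or list of them, sharing one reference
#'   species.
#' @param masks optional `genomic_intervals` mask track.
#' @param params a [scan_params] list.
#' @return A data frame of CNE calls with columns `seqid`, `start`, `end`,
#'   `name`, `score` (percent conserved columns), `strand`, `length`,
#'   `conserved_columns`, `supporting_species` (comma-separated),
#'   `fish_support`, `tetrapod_support`.
#' @export
scan_cnes <- function(blocks, masks = NULL, params = scan_params()) {
  if (inherits(blocks, "alignment_block")) blocks <- list(blocks)
  if (!length(blocks)) return(empty_cne_calls())
  for (b in blocks) {
    if (!any(b$species_class == "fish")) {
      stop("no fish-class species in block; set species_class when reading ",
           "the alignment", call. = FALSE)
    }
  }
  refs <- vapply(blocks, function(b) b$rows$species[1L], character(1))
  if (length(unique(refs)) != 1L) {
    stop("blocks do not share a single reference species", call. = FALSE)
  }
  calls <- list()
  for (b in blocks) {
    for (sub in mask_block(b, masks, warn_outside = FALSE)) {
      calls[[length(calls) + 1L]] <- scan_one_block(sub, params)
    }
  }
  out <- do.call(rbind, c(list(empty_cne_calls()), calls))
  if (nrow(out) == 0L) return(out)
  out <- merge_cne_calls(out)
  keep <- if (params$fish_presence_min_cover > 0) out$fish_support else TRUE
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$seqid, out$start, out$end), , drop = FALSE]
  out$name <- sprintf("cne_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

empty_cne_calls <- function() {
  data.frame(seqid = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             length = integer(), conserved_columns = integer(),
             supporting_species = character(),
             fish_support = logical(), tetrapod_support = logical(),
             stringsAsFactors = FALSE)
}

scan_one_block <- function(block, params) {
  cons <- conserved_columns(block, params)
  seeds <- find_seeds(block, params, conserved = cons)
  if (nrow(seeds) == 0L) return(empty_cne_calls())
  elems <- lapply(seq_len(nrow(seeds)), function(i) {
    extend_seed(block, seeds[i, ], params, conserved = cons)
  })
  iv <- unique(data.frame(
    start = vapply(elems, function(e) as.integer(e$start_col), integer(1)),
    end = vapply(elems, function(e) as.integer(e$end_col), integer(1))))
  ir <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
  pos <- block_ref_coordinates(block)
  m <- block_matrix(block)
  cls <- block$species_class
  refseq <- block$rows$seqid[1L]
  rows <- lapply(seq_along(ir), function(k) {
    i <- IRanges::start(ir)[k]; j <- IRanges::end(ir)[k]
    cols <- i:j
    covers <- rowMeans(m[-1L, cols, drop = FALSE] != "-")
    supporting <- names(covers)[covers >= params$fish_presence_min_cover]
    spcls <- cls[supporting]
    data.frame(
      seqid = refseq, start = pos[i], end = pos[j] + 1L, name = "",
      score = round(100 * sum(cons[cols]) / length(cols), 1), strand = "*",
      length = pos[j] + 1L - pos[i],
      conserved_columns = sum(cons[cols]),
      supporting_species = paste(supporting, collapse = ","),
      fish_support = any(spcls == "fish"),
      tetrapod_support = any(spcls == "tetrapod"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# merge CNE calls with overlapping reference intervals (e.g. across blocks)
merge_cne_calls <- function(df) {
  if (nrow(df) <= 1L) return(df)
  gr <- GenomicRanges::GRanges(df$seqid, IRanges::IRanges(df$start + 1L, df$end))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  rows <- lapply(seq_along(red), function(k) {
    idx <- revmap[[k]]
    g <- df[idx, , drop = FALSE]
    start <- GenomicRanges::start(red)[k] - 1L
    end <- GenomicRanges::end(red)[k]
    spp <- unique(unlist(strsplit(g$supporting_species, ",", fixed = TRUE)))
    spp <- spp[nzchar(spp)]
    cons <- min(max(g$conserved_columns), end - start)
    data.frame(
      seqid = g$seqid[1L], start = start, end = end, name = "",
      score = round(100 * cons / (end - start), 1), strand = "*",
      length = end - start, conserved_columns = cons,
      supporting_species = paste(spp, collapse = ","),
      fish_support = any(g$fish_support),
      tetrapod_support = any(g$tetrapod_support),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
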