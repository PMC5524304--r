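#' Partition ancestral CNEs between WGD paralog environments
#'
#' For every ancestral (reference-species) CNE and every study species, the
#' CNE is marked present in paralog environment `a` and/or `b` when at least
#' one retained pairwise hit overlaps the CNE's query interval by at least
#' `min_overlap` of the CNE length.
#'
#' @param ancestral_cnes data frame of CNE calls in reference coordinates
#'   (columns `name`, `start`, `end`; optional logical `tetrapod_shared`
#'   or `tetrapod_support`).
#' @param hits data frame of pairwise hits with columns `species`, `paralog`
#'   (`"a"` or `"b"`), `q_start`, `q_end` and optionally `retained`
#'   (non-retained hits are ignored).
#' @param species character vector of valid species; defaults to the species
#'   present in `hits`. A hit naming a species outside this set is an error.
#' @param min_overlap minimum hit/CNE overlap as a fraction of CNE length
#'   (default 0.5).
#' @return A `partition_table`: long data frame with one row per CNE x
#'   species, logical columns `in_a`, `in_b`, and per-CNE
#'   `tetrapod_shared`.
#' @export
build_partition <- function(ancestral_cnes, hits, species = NULL,
                            min_overlap = 0.5) {
  stopifnot(all(c("name", "start", "end") %in% names(ancestral_cnes)),
            all(c("species", "paralog", "q_start", "q_end") %in% names(hits)))
  if ("retained" %in% names(hits)) hits <- hits[hits$retained, , drop = FALSE]
  if (is.null(species)) species <- sort(unique(hits$species))
  bad <- setdiff(unique(hits$species), species)
  if (length(bad)) {
    stop("unknown species key(s) in hits: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(hits$paralog %in% c("a", "b"))) {
    stop("paralog must be 'a' or 'b'", call. = FALSE)
  }
  tet <- if ("tetrapod_shared" %in% names(ancestral_cnes)) {
    ancestral_cnes$tetrapod_shared
  } else if ("tetrapod_support" %in% names(ancestral_cnes)) {
    ancestral_cnes$tetrapod_support
  } else {
    rep(FALSE, nrow(ancestral_cnes))
  }
  grid <- expand.grid(cne = ancestral_cnes$name, species = species,
                      stringsAsFactors = FALSE)
  detect <- function(cne_i, sp, par) {
    h <- hits[hits$species == sp & hits$paralog == par, , drop = FALSE]
    if (!nrow(h)) return(FALSE)
    lo <- ancestral_cnes$start[cne_i]; hi <- ancestral_cnes$end[cne_i]
    ov <- pmin(h$q_end, hi) - pmax(h$q_start, lo)
    any(ov >= min_overlap * (hi - lo))
  }
  ci <- match(grid$cne, ancestral_cnes$name)
  grid$in_a <- mapply(detect, ci, grid$species, MoreArgs = list(par = "a"))
  grid$in_b <- mapply(detect, ci, grid$species, MoreArgs = list(par = "b"))
  grid$tetrapod_shared <- tet[ci]
  class(grid) <- c("partition_table", "data.frame")
  grid
}

#' Partition table from explicit presence calls
#'
#' Convenience constructor when detection status is already known (e.g.
#' generator truth or a transcribed fixture).
#'
#' @param df data frame with columns `cne`, `species`, `in_a`, `in_b` and
#'   optionally `tetrapod_shared`.
#' @export
partition_table <- function(df) {
  stopifnot(all(c("cne", "species", "in_a", "in_b") %in% names(df)))
  if (!"tetrapod_shared" %in% names(df)) {
    df$tetrapod_shared <- rep(FALSE, nrow(df))
  }
  df$in_a <- as.logical(df$in_a)
  df$in_b <- as.logical(df$in_b)
  class(df) <- c("partition_table", "data.frame")
  df
}

#' Asymmetry summary of a partition table
#'
#' Classifies each ancestral CNE as retained near paralog a only, paralog b
#' only, both, or neither, and reports the fraction found near only one
#' paralog. Under the default `any_species` aggregation a CNE is a-only when
#' it is detected near `a` in at least one species and never near `b`
#' (paper-style per-gene percentages); `all_species` requires detection in
#' every species; `per_species` returns one summary per species.
#'
#' @param partition a `partition_table`.
#' @param aggregation `"any_species"`, `"all_species"` or `"per_species"`.
#' @return A list of class `asymmetry_summary` (or a data frame of them for
#'   `per_species`) with `total_cnes`, `a_only`, `b_only`, `both`,
#'   `neither`, `one_paralog_fraction` (percent, one decimal),
#'   `dominant_paralog` and `tetrapod_shared_count`.
#' @export
summarize_partition <- function(partition,
                                aggregation = c("any_species", "all_species",
                                                "per_species")) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "per_species") {
    out <- do.call(rbind, lapply(split(partition, partition$species),
                                 function(p) {
      s <- summarize_one(p)
      data.frame(species = p$species[1L], as.data.frame(s),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  agg <- if (aggregation == "any_species") any else all
  by_cne <- split(partition, partition$cne)
  det <- data.frame(
    cne = names(by_cne),
    in_a = vapply(by_cne, function(p) agg(p$in_a), logical(1)),
    in_b = vapply(by_cne, function(p) agg(p$in_b), logical(1)),
    tetrapod_shared = vapply(by_cne, function(p) p$tetrapod_shared[1L],
                             logical(1)))
  summarize_one(det)
}

summarize_one <- function(det) {
  total <- nrow(det)
  if (total == 0L) {
    return(structure(list(total_cnes = 0L, a_only = 0L, b_only = 0L,
                          both = 0L, neither = 0L,
                          one_paralog_fraction = NA_real_,
                          dominant_paralog = NA_character_,
                          tetrapod_shared_count = 0L),
                     class = "asymmetry_summary"))
  }
  a_only <- sum(det$in_a & !det$in_b)
  b_only <- sum(det$in_b & !det$in_a)
  both <- sum(det$in_a & det$in_b)
  neither <- sum(!det$in_a & !det$in_b)
  structure(list(
    total_cnes = total, a_only = a_only, b_only = b_only, both = both,
    neither = neither,
    one_paralog_fraction = round(100 * (a_only + b_only) / total, 1),
    dominant_paralog = if (a_only > b_only) "a" else
      if (b_only > a_only) "b" else "tie",
    tetrapod_shared_count = sum(det$tetrapod_shared)),
    class = "asymmetry_summary")
}

#' @export
print.asymmetry_summary <- function(x, ...) {
  cat(sprintf("<asymmetry_summary> %d CNEs: a-only %d, b-only %d, both %d, neither %d\n",
              x$total_cnes, x$a_only, x$b_only, x$both, x$neither))
  cat(sprintf("  one-paralog fraction %.1f%%; dominant paralog %s; %d shared with tetrapods\n",
              x$one_paralog_fraction, x$dominant_paralog,
              x$tetrapod_shared_count))
  invisible(x)
}

#' @export
as.data.frame.asymmetry_summary <- function(x, ...) {
  data.frame(total_cnes = x$total_cnes, a_only = x$a_only,
             b_only = x$b_only, both = x$both, neither = x$neither,
             one_paralog_fraction = x$one_paralog_fraction,
             dominant_paralog = x$dominant_paralog,
             tetrapod_shared_count = x$tetrapod_shared_count,
             stringsAsFactors = FALSE)
}

#' Paired/two-sample t-test on per-environment CNE counts
#'
#' Tests whether the number of CNEs retained near paralog a differs from the
#' number retained near paralog b (sampling unit: genes or species). The
#' paired version (default; counts are naturally paired per unit) is a
#' one-sample t-test on the differences; the unpaired version is a
#' two-sample equal-variance t-test. Two-sided p-values.
#'
#' @param counts_a,counts_b equal-length numeric vectors of CNE counts.
#' @param paired logical, default `TRUE`.
#' @return A list with `statistic`, `df`, `p`, `method` and `degenerate`
#'   (`TRUE` when the variance is zero and the mean difference is not, in
#'   which case `p` is reported as the machine floor).
#' @export
count_asymmetry_test <- function(counts_a, counts_b, paired = TRUE) {
  stopifnot(length(counts_a) == length(counts_b))
  n <- length(counts_a)
  if (n < 2L) stop("need at least 2 paired counts", call. = FALSE)
  if (paired) {
    d <- counts_a - counts_b
    if (sd(d) == 0) {
      if (mean(d) == 0) {
        return(list(statistic = 0, df = n - 1L, p = 1,
                    method = "paired t", degenerate = FALSE))
      }
      return(list(statistic = sign(mean(d)) * Inf, df = n - 1L,
                  p = .Machine$double.xmin, method = "paired t",
                  degenerate = TRUE))
    }
    tt <- t.test(counts_a, counts_b, paired = TRUE)
    return(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, method = "paired t", degenerate = FALSE))
  }
  if (sd(counts_a) == 0 && sd(counts_b) == 0) {
    d <- mean(counts_a) - mean(counts_b)
    if (d == 0) {
      return(list(statistic = 0, df = 2L * n - 2L, p = 1,
                  method = "two-sample t (equal variance)",
                  degenerate = FALSE))
    }
    return(list(statistic = sign(d) * Inf, df = 2L * n - 2L,
                p = .Machine$double.xmin,
                method = "two-sample t (equal variance)", degenerate = TRUE))
  }
  tt <- t.test(counts_a, counts_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, method = "two-sample t (equal variance)",
       degenerate = FALSE)
}
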