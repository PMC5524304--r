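#' Gene x species copy-number landscape
#'
#' A `landscape_matrix` records, for each gene of the family, how many
#' copies each species carries, the gene's duplication origin
#' (teleost-WGD duplicate, small-scale duplicate, or singleton class) and
#' each species' lineage (non-salmonid teleost, salmonid teleost, or
#' outgroup).
#'
#' @param copy_number integer matrix, genes x species, with dimnames.
#' @param origin named character vector per gene: `"WGD_duplicate"`,
#'   `"SSD_duplicate"` or `"singleton"`.
#' @param lineage named character vector per species: `"teleost"`,
#'   `"salmonid_teleost"` or `"outgroup"`.
#' @return An object of class `landscape_matrix`.
#' @export
landscape_matrix <- function(copy_number, origin, lineage) {
  stopifnot(is.matrix(copy_number), !is.null(rownames(copy_number)),
            !is.null(colnames(copy_number)), all(copy_number >= 0))
  genes <- rownames(copy_number)
  species <- colnames(copy_number)
  stopifnot(all(genes %in% names(origin)), all(species %in% names(lineage)))
  origin <- origin[genes]
  lineage <- lineage[species]
  stopifnot(all(origin %in% c("WGD_duplicate", "SSD_duplicate", "singleton")),
            all(lineage %in% c("teleost", "salmonid_teleost", "outgroup")))
  if (!any(lineage == "teleost")) {
    stop("landscape needs at least one non-salmonid teleost species",
         call. = FALSE)
  }
  storage.mode(copy_number) <- "integer"
  structure(list(copy_number = copy_number, origin = origin,
                 lineage = lineage), class = "landscape_matrix")
}

#' @export
print.landscape_matrix <- function(x, ...) {
  cat(sprintf("<landscape_matrix> %d genes x %d species (%d teleost, %d salmonid, %d outgroup)\n",
              nrow(x$copy_number), ncol(x$copy_number),
              sum(x$lineage == "teleost"),
              sum(x$lineage == "salmonid_teleost"),
              sum(x$lineage == "outgroup")))
  invisible(x)
}

#' Read / write a landscape TSV
#'
#' Format: a comment line `# lineage: sp1=teleost sp2=outgroup ...`
#' followed by a header `gene<TAB>origin<TAB><species...>` and one row per
#' gene with integer copy numbers.
#'
#' @param path TSV file path.
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  lin_line <- grep("^#\\s*lineage:", lines, value = TRUE)
  if (length(lin_line) != 1L) {
    stop("landscape TSV needs exactly one '# lineage:' comment line",
         call. = FALSE)
  }
  pairs <- strsplit(trimws(sub("^#\\s*lineage:", "", lin_line)), "\\s+")[[1L]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  lineage <- setNames(vapply(kv, `[`, character(1), 2L),
                      vapply(kv, `[`, character(1), 1L))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("gene", "origin")), drop = FALSE])
  rownames(m) <- df$gene
  landscape_matrix(m, setNames(df$origin, df$gene), lineage)
}

#' @rdname read_landscape
#' @param x a `landscape_matrix`.
#' @export
write_landscape <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# lineage: ",
                    paste(sprintf("%s=%s", names(x$lineage), x$lineage),
                          collapse = " ")), con)
  df <- data.frame(gene = rownames(x$copy_number),
                   origin = unname(x$origin),
                   x$copy_number, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The sox-gene landscape fixture
#'
#' A 19-gene x 16-species copy-number matrix transcribed from the in-text
#' description of the sox family across vertebrate genomes: ten teleost-WGD
#' duplicate pairs (sox1, 4, 6, 8, 9, 10, 11, 14, 19, 21), the single SSD
#' pair sox17/32 present in all teleosts, sox4 and sox9 duplicated in every
#' non-salmonid teleost, and the documented lineage losses of sox10, sox12
#' and sox30. Salmonid copy numbers are synthetic totals consistent with
#' the reported 51 (salmon) and 49 (trout) sox genes; per-gene salmonid
#' counts are not individually documented in the source text.
#'
#' @return A `landscape_matrix`.
#' @export
sox_landscape <- function() {
  read_landscape(system.file("extdata", "sox_landscape.tsv",
                             package = "ohnocne", mustWork = TRUE))
}

pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round(100 * num / den, 1)
}

#' Duplicate-retention summary of a landscape
#'
#' Computes the retention arithmetic over the non-salmonid teleosts:
#' the fraction of genes duplicated in at least one species, the split of
#' those into duplicated-in-all versus lineage-specific duplicates, the
#' WGD retention rate (WGD-duplicate genes over all genes), and the
#' salmonid retention rate. Percentages are rounded to one decimal.
#'
#' @param x a `landscape_matrix`.
#' @return A list of class `retention_report`.
#' @export
summarize_landscape <- function(x) {
  stopifnot(inherits(x, "landscape_matrix"))
  tel <- x$copy_number[, x$lineage == "teleost", drop = FALSE]
  if (ncol(tel) == 0L) {
    stop("no non-salmonid teleost species", call. = FALSE)
  }
  n_genes <- nrow(tel)
  dup_any <- rowSums(tel >= 2L) >= 1L
  dup_all <- rowSums(tel >= 2L) == ncol(tel)
  n_any <- sum(dup_any)
  n_all <- sum(dup_all)
  wgd <- x$origin == "WGD_duplicate" & dup_any
  sal <- if (any(x$lineage == "salmonid_teleost")) {
    salmonid_retention(x)$pooled_pct
  } else {
    NA_real_
  }
  structure(list(
    n_genes = n_genes,
    n_duplicated_any = n_any,
    pct_duplicated_any = pct1(n_any, n_genes),
    n_duplicated_all = n_all,
    pct_duplicated_all = pct1(n_all, n_any),
    n_lineage_specific = n_any - n_all,
    pct_lineage_specific = pct1(n_any - n_all, n_any),
    n_wgd_duplicates = sum(wgd),
    wgd_retention_pct = pct1(sum(wgd), n_genes),
    salmonid_retention_pct = sal),
    class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf("<retention_report> %d genes\n", x$n_genes))
  cat(sprintf("  duplicated in >=1 teleost: %d (%.1f%%)\n",
              x$n_duplicated_any, x$pct_duplicated_any))
  cat(sprintf("  of these, in all species: %d (%.1f%%); lineage-specific: %d (%.1f%%)\n",
              x$n_duplicated_all, x$pct_duplicated_all,
              x$n_lineage_specific, x$pct_lineage_specific))
  cat(sprintf("  WGD retention: %d/%d (%.1f%%); salmonid retention: %.1f%%\n",
              x$n_wgd_duplicates, x$n_genes, x$wgd_retention_pct,
              x$salmonid_retention_pct))
  invisible(x)
}

#' Salmonid duplicate-retention rate
#'
#' Fraction of assayed genes (copy number >= 1 in that species) retained in
#' two or more copies in each salmonid, plus the pooled rate.
#'
#' @param x a `landscape_matrix` with at least one salmonid species.
#' @return List with `per_species_pct` (named) and `pooled_pct`.
#' @export
salmonid_retention <- function(x) {
  stopifnot(inherits(x, "landscape_matrix"))
  sal <- x$copy_number[, x$lineage == "salmonid_teleost", drop = FALSE]
  if (ncol(sal) == 0L) stop("no salmonid species in landscape", call. = FALSE)
  per <- vapply(seq_len(ncol(sal)), function(j) {
    assayed <- sal[, j] >= 1L
    pct1(sum(sal[assayed, j] >= 2L), sum(assayed))
  }, numeric(1))
  names(per) <- colnames(sal)
  assayed_all <- sal >= 1L
  pooled <- pct1(sum(sal >= 2L), sum(assayed_all))
  list(per_species_pct = per, pooled_pct = pooled)
}
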