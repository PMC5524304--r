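#' Reference-anchored alignment blocks
#'
#' An `alignment_block` is one slice of a reference-anchored multi-species
#' alignment (one MAF `a` paragraph): a set of equal-length gapped rows, the
#' first of which is the reference. Each row records its source interval so
#' alignment columns can be mapped back to reference coordinates.
#'
#' @param rows data frame with columns `species`, `seqid`, `start` (0-based),
#'   `size` (ungapped length), `strand`, `src_size`, `text` (gapped sequence
#'   over `A,C,G,T,N,-`, case-insensitive).
#' @param species_class named character vector mapping species to
#'   `"reference"`, `"fish"`, `"tetrapod"` or `"other"`. Unlisted species
#'   default to `"other"`; the first row is always the reference.
#' @return An object of class `alignment_block`.
#' @export
alignment_block <- function(rows, species_class = NULL) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L,
            all(c("species", "seqid", "start", "size", "strand",
                  "src_size", "text") %in% names(rows)))
  widths <- nchar(rows$text)
  if (length(unique(widths)) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  nongap <- nchar(gsub("-", "", rows$text, fixed = TRUE))
  if (any(nongap != rows$size)) {
    stop("row size does not match its non-gap base count", call. = FALSE)
  }
  cls <- rep("other", nrow(rows))
  names(cls) <- rows$species
  if (!is.null(species_class)) {
    hit <- intersect(rows$species, names(species_class))
    cls[hit] <- unname(species_class[hit])
  }
  cls[1L] <- "reference"
  bad <- setdiff(unique(cls), c("reference", "fish", "tetrapod", "other"))
  if (length(bad)) stop("unknown species class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(rows = rows, species_class = cls), class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %d species x %d columns; reference %s:%s [%d,%d)\n",
              nrow(x$rows), block_ncol(x), x$rows$species[1L], x$rows$seqid[1L],
              x$rows$start[1L], x$rows$start[1L] + x$rows$size[1L]))
  invisible(x)
}

#' @rdname alignment_block
#' @param block an `alignment_block`.
#' @export
block_ncol <- function(block) nchar(block$rows$text[1L])

#' Character matrix view of a block (rows = species, upper case)
#' @rdname alignment_block
#' @export
block_matrix <- function(block) {
  m <- do.call(rbind, strsplit(toupper(block$rows$text), "", fixed = TRUE))
  rownames(m) <- block$rows$species
  m
}

#' Per-column reference coordinate (0-based), NA at reference-gap columns
#' @rdname alignment_block
#' @export
block_ref_coordinates <- function(block) {
  chars <- strsplit(toupper(block$rows$text[1L]), "", fixed = TRUE)[[1L]]
  isbase <- chars != "-"
  pos <- rep(NA_integer_, length(chars))
  pos[isbase] <- block$rows$start[1L] + seq_len(sum(isbase)) - 1L
  pos
}

#' Read / write MAF alignment files
#'
#' Parses the UCSC multiple alignment format: each `a` paragraph becomes one
#' [alignment_block], its first `s` line the reference. MAF coordinates are
#' already 0-based half-open and pass through unchanged. Species names are
#' taken as the `src` field up to the first dot (`hg38.chr17` -> `hg38`).
#'
#' @param path file path.
#' @param species_class optional named vector, see [alignment_block()].
#' @return `read_maf()`: a list of `alignment_block`; `write_maf()`: `path`,
#'   invisibly.
#' @export
read_maf <- function(path, species_class = NULL) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || nrow(cur) == 0L) return(NULL)
    alignment_block(cur, species_class = species_class)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) {
      if (!is.null(cur)) { b <- flush(cur); if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b }
      cur <- NULL
      next
    }
    if (startsWith(ln, "a")) {
      if (!is.null(cur)) { b <- flush(cur); if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b }
      cur <- data.frame(species = character(), seqid = character(),
                        start = integer(), size = integer(), strand = character(),
                        src_size = integer(), text = character(),
                        stringsAsFactors = FALSE)
      next
    }
    if (startsWith(ln, "s")) {
      if (is.null(cur)) {
        stop(sprintf("MAF parse error at line %d: 's' line outside a block", i),
             call. = FALSE)
      }
      f <- strsplit(ln, "[ \t]+")[[1L]]
      if (length(f) != 7L) {
        stop(sprintf("MAF parse error at line %d: expected 7 fields, got %d",
                     i, length(f)), call. = FALSE)
      }
      src <- f[2L]
      sp <- sub("\\..*$", "", src)
      sq <- sub("^[^.]*\\.?", "", src)
      if (sq == "") sq <- src
      cur <- rbind(cur, data.frame(
        species = sp, seqid = sq,
        start = as.integer(f[3L]), size = as.integer(f[4L]),
        strand = f[5L], src_size = as.integer(f[6L]), text = f[7L],
        stringsAsFactors = FALSE))
      next
    }
    # i/e/q lines and anything else are ignored
  }
  if (!is.null(cur)) { b <- flush(cur); if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b }
  blocks
}

#' @rdname read_maf
#' @param blocks list of `alignment_block`.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a score=0", con)
    r <- b$rows
    src <- ifelse(r$seqid == "" | r$seqid == r$species, r$species,
                  paste(r$species, r$seqid, sep = "."))
    writeLines(sprintf("s %s %d %d %s %d %s",
                       src, r$start, r$size, r$strand, r$src_size, r$text), con)
  }
  invisible(path)
}
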