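#' Trees with branch omega-class tags
#'
#' Branch-partitioned codon models need every branch assigned to a dN/dS
#' class: `r` (background/ortholog branches), `p` (both paralog clades
#' jointly), `a` or `b` (the two WGD paralog clades separately). The tag
#' dialect is plain newick in which any leaf or internal node label may end
#' in `#<tag>`; the tag applies to the branch leading to that node.
#' Untagged branches default to class `r`.
#'
#' `"((A#a,B#a)#a,(C#b,D#b)#b,E);"` marks the two cherries (and their stems)
#' as paralog clades `a` and `b`, with `E`'s branch in class `r`.
#'
#' @param text_or_path a newick string, or path to a file containing one.
#' @return A `labeled_tree`: list with `phylo` (an [ape::phylo] with tags
#'   stripped from labels) and `branch_class` (character vector, one entry
#'   per row of `phylo$edge`, values in `r`, `p`, `a`, `b`).
#' @export
read_labeled_tree <- function(text_or_path) {
  txt <- if (file.exists(text_or_path) && !grepl("\\(", text_or_path)) {
    paste(readLines(text_or_path), collapse = "")
  } else {
    text_or_path
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("newick parse error", call. = FALSE)
  labels <- c(tr$tip.label,
              if (!is.null(tr$node.label)) tr$node.label else
                rep("", tr$Nnode))
  tags <- rep(NA_character_, length(labels))
  has <- grepl("#", labels, fixed = TRUE)
  tags[has] <- sub("^.*#", "", labels[has])
  known <- c("r", "p", "a", "b")
  bad <- setdiff(stats::na.omit(unique(tags)), known)
  if (length(bad)) {
    stop("unknown branch tag(s): ", paste(bad, collapse = ", "),
         " (allowed: r, p, a, b)", call. = FALSE)
  }
  clean <- sub("#.*$", "", labels)
  tr$tip.label <- clean[seq_along(tr$tip.label)]
  if (!is.null(tr$node.label)) {
    tr$node.label <- clean[length(tr$tip.label) + seq_len(tr$Nnode)]
  }
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names", call. = FALSE)
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  # the branch leading to node i carries node i's tag
  cls <- tags[tr$edge[, 2L]]
  cls[is.na(cls)] <- "r"
  structure(list(phylo = tr, branch_class = cls), class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat(sprintf("<labeled_tree> %d leaves; branch classes: %s\n",
              length(x$phylo$tip.label),
              paste(sprintf("%s=%d", names(table(x$branch_class)),
                            table(x$branch_class)), collapse = " ")))
  invisible(x)
}

#' @rdname read_labeled_tree
#' @param lt a `labeled_tree`.
#' @param path output file; if `NULL`, the newick string is returned.
#' @export
write_labeled_tree <- function(lt, path = NULL) {
  tr <- lt$phylo
  ntip <- length(tr$tip.label)
  tag_of_node <- rep(NA_character_, ntip + tr$Nnode)
  tag_of_node[tr$edge[, 2L]] <- lt$branch_class
  suffix <- ifelse(is.na(tag_of_node) | tag_of_node == "r", "",
                   paste0("#", tag_of_node))
  tr$tip.label <- paste0(tr$tip.label, suffix[seq_len(ntip)])
  nl <- if (!is.null(tr$node.label)) tr$node.label else rep("", tr$Nnode)
  tr$node.label <- paste0(nl, suffix[ntip + seq_len(tr$Nnode)])
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
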