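#' The 61 sense codons of the universal genetic code
#'
#' State order is fixed (alphabetical over A,C,G,T) and shared by every
#' function in the codon-model module. Stop codons are excluded.
#'
#' @return Character vector of 61 codons.
#' @export
sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  sort(names(code)[code != "*"])
}

# cached codon bookkeeping: codons, amino acids, substitution-type matrix
codon_env <- new.env(parent = emptyenv())

codon_info <- function() {
  if (!is.null(codon_env$info)) return(codon_env$info)
  codons <- sense_codons()
  aa <- Biostrings::GENETIC_CODE[codons]
  n <- length(codons)
  splits <- strsplit(codons, "", fixed = TRUE)
  bases <- do.call(rbind, splits)
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  type <- matrix(0L, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    diffs <- bases != matrix(bases[i, ], n, 3, byrow = TRUE)
    ndiff <- rowSums(diffs)
    one <- which(ndiff == 1L)
    for (j in one) {
      pos <- which(diffs[j, ])
      ti <- is_transition(bases[i, pos], bases[j, pos])
      syn <- aa[i] == aa[j]
      type[i, j] <- if (syn && !ti) 1L else if (syn && ti) 2L else
        if (!syn && !ti) 3L else 4L
    }
  }
  codon_env$info <- list(codons = codons, aa = aa, type = type, bases = bases)
  codon_env$info
}

#' Codon alignments
#'
#' A `codon_alignment` is a gap-free, in-frame alignment over the 61 sense
#' codons: an integer state matrix (taxa x codon sites, states indexed into
#' [sense_codons()]).
#'
#' @param sequences named character vector of nucleotide sequences (equal
#'   lengths, multiples of 3, no gaps or stop codons), or an integer state
#'   matrix with taxa as rownames.
#' @return An object of class `codon_alignment` with elements `taxa`,
#'   `states` and `length` (codon count).
#' @export
codon_alignment <- function(sequences) {
  info <- codon_info()
  if (is.matrix(sequences) && is.numeric(sequences)) {
    states <- sequences
    storage.mode(states) <- "integer"
    stopifnot(!is.null(rownames(states)),
              all(states >= 1L), all(states <= length(info$codons)),
              ncol(states) >= 1L)
  } else {
    stopifnot(is.character(sequences), !is.null(names(sequences)),
              length(sequences) >= 1L)
    widths <- nchar(sequences)
    if (length(unique(widths)) != 1L) stop("sequences of unequal length",
                                           call. = FALSE)
    if (widths[1L] %% 3L != 0L) stop("sequence length not a multiple of 3",
                                     call. = FALSE)
    if (widths[1L] == 0L) stop("empty alignment", call. = FALSE)
    ncod <- widths[1L] %/% 3L
    states <- matrix(NA_integer_, length(sequences), ncod,
                     dimnames = list(names(sequences), NULL))
    for (i in seq_along(sequences)) {
      cods <- substring(toupper(sequences[[i]]),
                        3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
      idx <- match(cods, info$codons)
      if (anyNA(idx)) {
        bad <- unique(cods[is.na(idx)])
        stop("non-sense codon(s) in ", names(sequences)[i], ": ",
             paste(utils::head(bad, 5), collapse = ", "),
             " (gaps and stop codons must be removed first, see ",
             "clean_codon_alignment())", call. = FALSE)
      }
      states[i, ] <- idx
    }
  }
  structure(list(taxa = rownames(states), states = states,
                 length = ncol(states)), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d codons\n",
              length(x$taxa), x$length))
  invisible(x)
}

#' Remove codon columns containing gaps or ambiguity
#'
#' Mirrors the usual cleandata treatment: every codon position at which at
#' least one sequence has a gap, `N`, or a stop codon is removed before
#' model fitting.
#'
#' @param sequences named character vector of aligned nucleotide sequences.
#' @return A `codon_alignment`.
#' @export
clean_codon_alignment <- function(sequences) {
  info <- codon_info()
  widths <- nchar(sequences)
  stopifnot(length(unique(widths)) == 1L, widths[1L] %% 3L == 0L)
  ncod <- widths[1L] %/% 3L
  codmat <- t(vapply(sequences, function(s) {
    substring(toupper(s), 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  }, character(ncod)))
  ok <- apply(codmat, 2L, function(col) all(col %in% info$codons))
  if (!any(ok)) stop("no clean codon columns remain", call. = FALSE)
  seqs <- apply(codmat[, ok, drop = FALSE], 1L, paste, collapse = "")
  names(seqs) <- names(sequences)
  codon_alignment(seqs)
}

#' @rdname codon_alignment
#' @param aln a `codon_alignment`.
#' @export
codon_sequences <- function(aln) {
  info <- codon_info()
  seqs <- apply(aln$states, 1L, function(s) paste(info$codons[s], collapse = ""))
  names(seqs) <- aln$taxa
  seqs
}

#' Read / write codon alignments as FASTA
#' @rdname codon_alignment
#' @param path FASTA file path.
#' @param clean remove gap/stop codon columns on read (default `TRUE`).
#' @export
read_codon_fasta <- function(path, clean = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  if (clean) clean_codon_alignment(seqs) else codon_alignment(seqs)
}

#' @rdname codon_alignment
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- codon_sequences(aln)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Codon equilibrium frequencies
#'
#' `"equal"` gives 1/61 for every sense codon. `"F3x4"` uses the empirical
#' nucleotide composition at each codon position, renormalised over the
#' sense codons.
#'
#' @param aln a `codon_alignment` (only needed for `"F3x4"`).
#' @param method `"F3x4"` or `"equal"`.
#' @return Named numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies <- function(aln = NULL, method = c("F3x4", "equal")) {
  method <- match.arg(method)
  info <- codon_info()
  n <- length(info$codons)
  if (method == "equal") return(setNames(rep(1 / n, n), info$codons))
  stopifnot(inherits(aln, "codon_alignment"))
  cods <- info$codons[as.vector(aln$states)]
  basemat <- do.call(rbind, strsplit(cods, "", fixed = TRUE))
  pos_freq <- lapply(1:3, function(p) {
    tab <- table(factor(basemat[, p], levels = c("A", "C", "G", "T")))
    f <- as.numeric(tab) / sum(tab)
    # guard against absent bases so no sense codon gets frequency zero
    f <- pmax(f, 1e-6) / sum(pmax(f, 1e-6))
    setNames(f, c("A", "C", "G", "T"))
  })
  pi <- pos_freq[[1]][info$bases[, 1]] *
    pos_freq[[2]][info$bases[, 2]] *
    pos_freq[[3]][info$bases[, 3]]
  pi <- pi / sum(pi)
  setNames(as.numeric(pi), info$codons)
}

#' Goldman-Yang instantaneous rate matrix
#'
#' Off-diagonal rates are zero for multi-nucleotide changes and otherwise
#' proportional to the target codon frequency, multiplied by `kappa` for
#' transitions and by `omega` for nonsynonymous changes. Rows sum to zero
#' and the matrix is scaled so the expected number of substitutions per
#' codon per unit branch length is 1.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi codon frequencies (61 values summing to 1).
#' @return A 61 x 61 rate matrix with codon dimnames.
#' @export
build_rate_matrix <- function(kappa, omega,
                              pi = codon_frequencies(method = "equal")) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0)) {
    stop("codon frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  info <- codon_info()
  Q <- .cpp_build_q(kappa, omega, as.numeric(pi), info$type)
  dimnames(Q) <- list(info$codons, info$codons)
  Q
}

#' Transition probability matrix exp(Q t)
#'
#' Computed by eigendecomposition of the reversible generator's symmetrised
#' form; tiny negative entries from roundoff are clamped to zero.
#'
#' @inheritParams build_rate_matrix
#' @param Q rate matrix from [build_rate_matrix()].
#' @param t branch length (expected substitutions per codon).
#' @export
codon_transition_matrix <- function(Q, t,
                                    pi = codon_frequencies(method = "equal")) {
  stopifnot(t >= 0)
  P <- .cpp_pmat(Q, as.numeric(pi), t)
  dimnames(P) <- dimnames(Q)
  P
}

# ---- branch class handling ------------------------------------------------

# map branch tags {r,p,a,b} to the omega classes of model A, B or C
model_branch_classes <- function(model, branch_class) {
  model <- match.arg(model, c("A", "B", "C"))
  if (model == "A") {
    cls <- rep("omega", length(branch_class))
  } else if (model == "B") {
    cls <- ifelse(branch_class %in% c("a", "b", "p"), "p", "r")
  } else {
    if (any(branch_class == "p")) {
      stop("model C needs branches tagged a/b, not the joint tag p",
           call. = FALSE)
    }
    cls <- branch_class
  }
  levels <- switch(model, A = "omega", B = c("r", "p"), C = c("r", "a", "b"))
  factor(cls, levels = levels)
}

# site pattern compression: unique columns + weights
codon_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(states = states[, first, drop = FALSE], weights = as.numeric(tab))
}

# internal: assemble the C++ likelihood inputs for an alignment + tree
codon_lik_data <- function(aln, lt, model) {
  tr <- ape::reorder.phylo(lt$phylo, "postorder")
  # reorder branch classes to match the postorder edge matrix
  key0 <- paste(lt$phylo$edge[, 1], lt$phylo$edge[, 2])
  key1 <- paste(tr$edge[, 1], tr$edge[, 2])
  cls <- lt$branch_class[match(key1, key0)]
  omega_class <- model_branch_classes(model, cls)
  idx <- match(aln$taxa, tr$tip.label)
  if (anyNA(idx) || length(tr$tip.label) != length(aln$taxa)) {
    stop("alignment taxa do not match tree leaves", call. = FALSE)
  }
  states <- aln$states[order(idx), , drop = FALSE]  # row i = tip i
  pat <- codon_patterns(states)
  list(edge = tr$edge - 1L,
       edge_length = if (is.null(tr$edge.length))
         rep(0, nrow(tr$edge)) else tr$edge.length,
       eclass = as.integer(omega_class) - 1L,
       class_levels = levels(omega_class),
       tipstate = pat$states - 1L,
       weights = pat$weights)
}

#' Codon log-likelihood under a branch-partitioned model
#'
#' Felsenstein pruning over the 61 sense codons with a per-branch rate
#' matrix chosen by the branch's omega class (model A: one class for all
#' branches; B: paralog vs rest; C: paralog a, paralog b, rest).
#'
#' @param aln a [codon_alignment].
#' @param tree a `labeled_tree` (see [read_labeled_tree()]); its branch
#'   lengths are used.
#' @param model `"A"`, `"B"` or `"C"`.
#' @param kappa transition/transversion ratio.
#' @param omega named vector of dN/dS values, one per omega class of the
#'   model (`omega` for A; `r`, `p` for B; `r`, `a`, `b` for C). A single
#'   unnamed value is recycled to all classes.
#' @param pi codon frequencies.
#' @return The log-likelihood (numeric scalar).
#' @export
codon_log_likelihood <- function(aln, tree, model = "A", kappa, omega,
                                 pi = codon_frequencies(aln)) {
  dat <- codon_lik_data(aln, tree, model)
  om <- expand_omega(omega, dat$class_levels)
  lnl <- .cpp_codon_lnl(dat$edge, dat$edge_length, dat$eclass, dat$tipstate,
                        dat$weights, kappa, om, as.numeric(pi),
                        codon_info()$type)
  if (!is.finite(lnl)) {
    stop("non-finite log-likelihood (kappa=", kappa, ", omega=",
         paste(signif(om, 4), collapse = "/"), ")", call. = FALSE)
  }
  lnl
}

expand_omega <- function(omega, class_levels) {
  if (length(omega) == 1L && is.null(names(omega))) {
    return(setNames(rep(omega, length(class_levels)), class_levels))
  }
  if (!all(class_levels %in% names(omega))) {
    stop("omega must be named with classes: ",
         paste(class_levels, collapse = ", "), call. = FALSE)
  }
  omega[class_levels]
}

# ---- maximum likelihood fitting -------------------------------------------

#' Fit a branch-partitioned codon model
#'
#' Jointly maximises kappa, the per-class omega values and (by default) all
#' branch lengths by bounded quasi-Newton (`L-BFGS-B` on log-transformed
#' parameters), with random restarts from perturbed starting points under
#' fixed seeds. Omega estimates are bounded to `[1e-6, 50]`; estimates on
#' the bound are flagged.
#'
#' @inheritParams codon_log_likelihood
#' @param codon_freq `"F3x4"` (default) or `"equal"`.
#' @param fix_branch_lengths keep the input tree's branch lengths fixed.
#' @param start optional list with elements `kappa`, `omega` (named per
#'   class) and `branch_lengths` used as the first starting point.
#' @param restarts number of starting points (default 3: the base start plus
#'   two seeded perturbations).
#' @param seed integer seed controlling the restart perturbations.
#' @param control passed to [stats::optim()]; the default `factr` targets a
#'   log-likelihood tolerance well below 1e-4.
#' @return A `codon_model_fit`: list with `model`, `lnL`, `kappa`, `omega`
#'   (named vector), `branch_lengths`, `tree` (branch lengths replaced by
#'   estimates), `free_parameters`, `n_codons`, `boundary` flag and
#'   `convergence` code.
#' @export
fit_codon_model <- function(aln, tree, model = c("A", "B", "C"),
                            codon_freq = c("F3x4", "equal"),
                            fix_branch_lengths = FALSE, start = NULL,
                            restarts = 3L, seed = 1L,
                            control = list(factr = 1e6, maxit = 500L)) {
  model <- match.arg(model)
  codon_freq <- match.arg(codon_freq)
  pi <- codon_frequencies(aln, codon_freq)
  dat <- codon_lik_data(aln, tree, model)
  type <- codon_info()$type
  nclass <- length(dat$class_levels)
  nedge <- nrow(dat$edge)

  bl0 <- pmax(dat$edge_length, 1e-3)
  k0 <- 2
  om0 <- setNames(rep(0.2, nclass), dat$class_levels)
  if (!is.null(start)) {
    if (!is.null(start$kappa)) k0 <- start$kappa
    if (!is.null(start$omega)) om0[] <- expand_omega(start$omega, dat$class_levels)
    if (!is.null(start$branch_lengths)) bl0 <- pmax(start$branch_lengths, 1e-6)
  }

  lb_om <- 1e-6; ub_om <- 50
  nll <- function(par) {
    kappa <- exp(par[1L])
    om <- exp(par[2L:(1L + nclass)])
    bl <- if (fix_branch_lengths) bl0 else exp(par[-seq_len(1L + nclass)])
    lnl <- .cpp_codon_lnl(dat$edge, bl, dat$eclass, dat$tipstate, dat$weights,
                          kappa, om, as.numeric(pi), type)
    if (!is.finite(lnl)) return(1e10)
    -lnl
  }

  base_par <- c(log(k0), log(pmin(pmax(om0, lb_om), ub_om)),
                if (!fix_branch_lengths) log(bl0))
  lower <- c(log(1e-3), rep(log(lb_om), nclass),
             if (!fix_branch_lengths) rep(log(1e-7), nedge))
  upper <- c(log(1e3), rep(log(ub_om), nclass),
             if (!fix_branch_lengths) rep(log(20), nedge))

  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    par0 <- if (r == 1L) base_par else withr::with_seed(seed + r, {
      pmin(pmax(base_par + rnorm(length(base_par), 0, 0.5), lower), upper)
    })
    fit <- tryCatch(
      optim(par0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("codon model fit failed for all starting points",
                          call. = FALSE)

  kappa <- exp(best$par[1L])
  omega <- setNames(exp(best$par[2L:(1L + nclass)]), dat$class_levels)
  bl <- if (fix_branch_lengths) bl0 else exp(best$par[-seq_len(1L + nclass)])
  tr <- ape::reorder.phylo(tree$phylo, "postorder")
  tr$edge.length <- bl
  free <- 1L + nclass + if (fix_branch_lengths) 0L else nedge
  structure(list(model = model, lnL = -best$value, kappa = kappa,
                 omega = omega, branch_lengths = bl,
                 tree = tr, codon_freq = codon_freq,
                 free_parameters = free, n_codons = aln$length,
                 n_taxa = length(aln$taxa),
                 boundary = any(omega <= lb_om * 1.01 | omega >= ub_om * 0.99),
                 convergence = best$convergence),
            class = "codon_model_fit")
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat(sprintf("<codon_model_fit> model %s  lnL = %.4f  kappa = %.3f\n",
              x$model, x$lnL, x$kappa))
  cat("  omega:", paste(sprintf("%s=%.4f", names(x$omega), x$omega),
                        collapse = "  "), "\n")
  if (x$boundary) cat("  note: an omega estimate sits on its bound\n")
  invisible(x)
}

#' Likelihood-ratio test between nested codon models
#'
#' The statistic is twice the log-likelihood difference, clipped at zero;
#' the p-value is the upper tail of a chi-squared distribution with degrees
#' of freedom equal to the difference in free parameter counts
#' (A vs B: 1; B vs C: 1).
#'
#' @param fit_null,fit_alt `codon_model_fit` objects with the null nested in
#'   the alternative (A in B in C), fitted to the same data.
#' @return A list with `statistic`, `df` and `p`.
#' @export
codon_lrt <- function(fit_null, fit_alt) {
  order_ok <- match(fit_null$model, c("A", "B", "C")) <
    match(fit_alt$model, c("A", "B", "C"))
  if (!isTRUE(order_ok)) {
    stop("models not nested: null must precede alternative in A < B < C",
         call. = FALSE)
  }
  if (fit_null$n_codons != fit_alt$n_codons ||
      fit_null$n_taxa != fit_alt$n_taxa) {
    stop("fits come from different datasets", call. = FALSE)
  }
  stat <- max(0, 2 * (fit_alt$lnL - fit_null$lnL))
  df <- fit_alt$free_parameters - fit_null$free_parameters
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Simulate a codon alignment along a labeled tree
#'
#' Root codons are drawn from the equilibrium frequencies and evolved along
#' each branch with the transition matrix of that branch's omega class.
#'
#' @inheritParams codon_log_likelihood
#' @param n_codons number of codon sites (>= 1).
#' @param seed integer seed (mandatory; the draw is fully reproducible).
#' @return A [codon_alignment] over the tree's leaves.
#' @export
simulate_codon_alignment <- function(tree, model = "A", kappa = 2,
                                     omega = 0.2,
                                     pi = codon_frequencies(method = "equal"),
                                     n_codons, seed) {
  stopifnot(n_codons >= 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  tr <- ape::reorder.phylo(tree$phylo, "postorder")
  key0 <- paste(tree$phylo$edge[, 1], tree$phylo$edge[, 2])
  cls <- tree$branch_class[match(paste(tr$edge[, 1], tr$edge[, 2]), key0)]
  omega_class <- model_branch_classes(model, cls)
  om <- expand_omega(omega, levels(omega_class))
  Qs <- lapply(om, function(o) build_rate_matrix(kappa, o, pi))
  if (is.null(tr$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1L]
  nnode <- max(tr$edge)
  withr::with_seed(seed, {
    states <- matrix(NA_integer_, nnode, n_codons)
    states[root, ] <- sample.int(61L, n_codons, replace = TRUE,
                                 prob = as.numeric(pi))
    # preorder: walk edges from last to first so parents precede children
    for (e in rev(seq_len(nrow(tr$edge)))) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      P <- codon_transition_matrix(Qs[[as.integer(omega_class[e])]],
                                   tr$edge.length[e], pi)
      ps <- states[parent, ]
      cs <- integer(n_codons)
      for (s in unique(ps)) {
        idx <- which(ps == s)
        cs[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[child, ] <- cs
    }
    tips <- states[seq_len(ntip), , drop = FALSE]
    rownames(tips) <- tr$tip.label
    codon_alignment(tips)
  })
}
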