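# Independent oracles used to check the implementation on small instances.
# These deliberately use different algorithms / code paths than the package.

# ---- scanner oracle -------------------------------------------------------

# Column conservation by direct rule application (loop form).
oracle_column_conserved <- function(mat, threshold = 0.12, min_rows = 3L) {
  ref <- mat[1L, ]
  vapply(seq_len(ncol(mat)), function(j) {
    if (ref[j] == "-") return(FALSE)
    rows <- mat[-1L, j]
    rows <- rows[rows != "-"]
    if (length(rows) < min_rows) return(FALSE)
    mism <- sum(rows != ref[j] | rows == "N" | ref[j] == "N")
    mism / length(rows) < threshold
  }, logical(1))
}

# Exhaustive enumeration of maximal qualifying element intervals in column
# space: an interval [i, j] qualifies iff its ends are conserved and it
# contains a merged seed [s, e] with at most `budget` non-conserved columns
# on each flank ([i, s) and (e, j]). Maximal qualifying intervals are kept
# and overlapping ones merged.
oracle_scan_columns <- function(conserved, refbase, L = 10L, identity = 0.9,
                                budget = 3L) {
  n <- length(conserved)
  need <- ceiling(identity * L)
  # qualifying seed windows by direct checking
  wins <- list()
  for (s in seq_len(max(0L, n - L + 1L))) {
    cols <- s:(s + L - 1L)
    if (all(refbase[cols]) && sum(conserved[cols]) >= need) {
      wins[[length(wins) + 1L]] <- c(s, s + L - 1L)
    }
  }
  if (!length(wins)) return(data.frame(start = integer(), end = integer()))
  covered <- rep(FALSE, n)
  for (w in wins) covered[w[1L]:w[2L]] <- TRUE
  r <- rle(covered)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  seeds <- cbind(lo[r$values], hi[r$values])
  # merged seeds start and end on conserved columns
  for (k in seq_len(nrow(seeds))) {
    cc <- which(conserved[seeds[k, 1L]:seeds[k, 2L]]) + seeds[k, 1L] - 1L
    seeds[k, 1L] <- cc[1L]
    seeds[k, 2L] <- cc[length(cc)]
  }
  qualifies <- function(i, j) {
    if (!conserved[i] || !conserved[j]) return(FALSE)
    for (k in seq_len(nrow(seeds))) {
      s <- seeds[k, 1L]; e <- seeds[k, 2L]
      if (s < i || e > j) next
      left <- if (s > i) sum(!conserved[i:(s - 1L)]) else 0L
      right <- if (e < j) sum(!conserved[(e + 1L):j]) else 0L
      if (left <= budget && right <= budget) return(TRUE)
    }
    FALSE
  }
  quals <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (qualifies(i, j)) quals[[length(quals) + 1L]] <- c(i, j)
    }
  }
  if (!length(quals)) return(data.frame(start = integer(), end = integer()))
  qm <- do.call(rbind, quals)
  maximal <- vapply(seq_len(nrow(qm)), function(k) {
    !any(qm[, 1L] <= qm[k, 1L] & qm[, 2L] >= qm[k, 2L] &
           (qm[, 1L] < qm[k, 1L] | qm[, 2L] > qm[k, 2L]))
  }, logical(1))
  qm <- qm[maximal, , drop = FALSE]
  ir <- IRanges::reduce(IRanges::IRanges(qm[, 1L], qm[, 2L]))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

# random alignment block for oracle comparisons
random_block <- function(ncol, nspecies = 6L, p_match = 0.75, p_gap = 0.05,
                         n_fish = 3L) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ncol, replace = TRUE)
  species <- c(paste0("f", seq_len(n_fish)),
               paste0("t", seq_len(nspecies - n_fish)))
  texts <- vapply(species, function(sp) {
    s <- ref
    mism <- runif(ncol) > p_match
    s[mism] <- vapply(ref[mism], function(b) sample(setdiff(bases, b), 1L),
                      character(1))
    gap <- runif(ncol) < p_gap
    s[gap] <- "-"
    paste(s, collapse = "")
  }, character(1))
  rows <- data.frame(
    species = c("ref", species), seqid = c("chrT", rep("x", nspecies)),
    start = 0L,
    size = c(ncol, nchar(gsub("-", "", texts, fixed = TRUE))),
    strand = "+", src_size = ncol,
    text = c(paste(ref, collapse = ""), unname(texts)),
    stringsAsFactors = FALSE)
  cls <- setNames(c("reference", rep("fish", n_fish),
                    rep("tetrapod", nspecies - n_fish)), rows$species)
  alignment_block(rows, species_class = cls)
}

# ---- local-alignment oracle ----------------------------------------------

# Brute-force optimal local alignment score: enumerate every monotone chain
# of matched position pairs; gaps between consecutive pairs are charged as
# two consolidated runs (any interleaving costs at least as much, and the
# consolidated form is itself a valid alignment, so the optimum over chains
# equals the optimum over all local alignments).
oracle_local_score <- function(q, s, match = 1, mismatch = -1,
                               gap_open = 2, gap_extend = 2) {
  qc <- strsplit(toupper(q), "")[[1L]]
  sc <- strsplit(toupper(s), "")[[1L]]
  n <- length(qc); m <- length(sc)
  gap_cost <- function(k) if (k > 0L) gap_open + k * gap_extend else 0
  best <- 0
  for (k in seq_len(min(n, m))) {
    qs <- utils::combn(n, k)
    ss <- utils::combn(m, k)
    for (a in seq_len(ncol(qs))) {
      qi <- qs[, a]
      for (b in seq_len(ncol(ss))) {
        si <- ss[, b]
        sub <- sum(ifelse(qc[qi] == sc[si] & qc[qi] != "N" & sc[si] != "N",
                          match, mismatch))
        gaps <- 0
        if (k > 1L) {
          dq <- diff(qi) - 1L
          ds <- diff(si) - 1L
          gaps <- sum(vapply(dq, gap_cost, numeric(1))) +
            sum(vapply(ds, gap_cost, numeric(1)))
        }
        sc_tot <- sub - gaps
        if (sc_tot > best) best <- sc_tot
      }
    }
  }
  best
}

# ---- t-test oracle --------------------------------------------------------

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, df = n - 1,
       p = 2 * pt(abs(t), n - 1, lower.tail = FALSE))
}

oracle_two_sample_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, df = n1 + n2 - 2,
       p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

# ---- codon likelihood oracle ----------------------------------------------

# Brute-force likelihood for a rooted 3-taxon tree ((t1, t2)anc, t3)root by
# summing over both internal nodes' states, with transition matrices from
# Matrix::expm (an independent matrix-exponential route).
oracle_3taxon_lnl <- function(states, bl, kappa, omega, pi) {
  Q <- build_rate_matrix(kappa, omega, pi)
  P <- lapply(bl, function(t) as.matrix(Matrix::expm(Q * t)))
  # bl: t1, t2 (to anc), anc (to root), t3 (to root)
  nsite <- ncol(states)
  lnl <- 0
  for (site in seq_len(nsite)) {
    x1 <- states[1L, site]; x2 <- states[2L, site]; x3 <- states[3L, site]
    like <- 0
    for (r in 1:61) {
      for (aa in 1:61) {
        like <- like + pi[r] * P[[3L]][r, aa] * P[[1L]][aa, x1] *
          P[[2L]][aa, x2] * P[[4L]][r, x3]
      }
    }
    lnl <- lnl + log(like)
  }
  unname(lnl)
}

# the standard 6-taxon study tree used across codon-model tests
study_tree_6taxa <- function() {
  read_labeled_tree(paste0(
    "((A1#a:0.2,A2#a:0.2)#a:0.1,(B1#b:0.2,B2#b:0.2)#b:0.1,",
    "(O1:0.2,O2:0.2):0.1);"))
}

# ---- partition oracle -----------------------------------------------------

oracle_partition <- function(cnes, hits, min_overlap = 0.5) {
  out <- list()
  for (i in seq_len(nrow(cnes))) {
    for (sp in unique(hits$species)) {
      pres <- c(a = FALSE, b = FALSE)
      for (par in c("a", "b")) {
        h <- hits[hits$species == sp & hits$paralog == par &
                    hits$retained, , drop = FALSE]
        for (r in seq_len(nrow(h))) {
          ov <- min(h$q_end[r], cnes$end[i]) - max(h$q_start[r], cnes$start[i])
          if (ov >= min_overlap * (cnes$end[i] - cnes$start[i])) {
            pres[par] <- TRUE
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        cne = cnes$name[i], species = sp, in_a = pres["a"], in_b = pres["b"],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
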