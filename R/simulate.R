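#' Simulate a reference-anchored alignment with planted conserved elements
#'
#' Emulates the divergence regime in which the multi-species scanner
#' operates: a uniform-random reference sequence, with each other species
#' copying it column by column at the background identity (default 0.60 per
#' column per species) except inside planted elements, which are copied at
#' high identity (default 0.98). Gaps are sampled per column per species in
#' the background only, and mismatched bases are drawn uniformly from the
#' three alternatives, so the planted truth intervals are exact. The
#' reference row carries no gaps, so alignment columns map one-to-one onto
#' reference positions. Defaults mirror the study setting: a reference plus
#' two tetrapods and nine fish.
#'
#' @param n_fish,n_tetrapod number of fish / tetrapod rows (besides the
#'   reference).
#' @param length alignment length in columns (= reference bp).
#' @param background_match_prob per-column per-species probability that a
#'   background column matches the reference (default 0.60, below the 60%
#'   pairwise identity threshold so background never qualifies by
#'   construction).
#' @param cne_match_prob identity inside planted elements (default 0.98,
#'   above all scanner and pairwise thresholds).
#' @param cne_lengths lengths of the planted elements; one element is
#'   planted per entry.
#' @param cne_positions optional integer vector of 0-based element starts;
#'   if `NULL`, elements are placed in evenly sized slots with random
#'   offsets, avoiding `mask_intervals`.
#' @param gap_prob per-column per-species gap probability in the background
#'   (default 0.02); planted columns are gap-free.
#' @param mask_intervals optional `genomic_intervals`; planted elements
#'   never overlap masks (a collision is an error).
#' @param seqid reference sequence name.
#' @param seed integer seed (mandatory).
#' @return A list with `block` (an [alignment_block]), `truth`
#'   (`genomic_intervals` of the planted elements) and `params`.
#' @export
make_planted_alignment <- function(n_fish = 9L, n_tetrapod = 2L,
                                   length = 5000L,
                                   background_match_prob = 0.60,
                                   cne_match_prob = 0.98,
                                   cne_lengths = c(20L, 25L, 30L, 35L, 40L),
                                   cne_positions = NULL,
                                   gap_prob = 0.02,
                                   mask_intervals = NULL,
                                   seqid = "ref_region",
                                   seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(background_match_prob >= 0, background_match_prob <= 1,
            cne_match_prob >= 0, cne_match_prob <= 1,
            gap_prob >= 0, gap_prob < 1, length >= 1L)
  bases <- c("A", "C", "G", "T")
  k <- base::length(cne_lengths)
  withr::with_seed(seed, {
    if (is.null(cne_positions) && k > 0L) {
      slot <- length %/% k
      if (any(cne_lengths > slot)) {
        stop("alignment too short for the requested planted elements",
             call. = FALSE)
      }
      cne_positions <- vapply(seq_len(k), function(i) {
        lo <- (i - 1L) * slot
        for (try in 1:50) {
          s <- as.integer(lo + sample.int(slot - cne_lengths[i] + 1L, 1L) - 1L)
          if (!overlaps_mask(s, s + cne_lengths[i], mask_intervals)) return(s)
        }
        stop("could not place a planted element outside the masks",
             call. = FALSE)
      }, integer(1))
    }
    if (k > 0L) {
      ends <- cne_positions + cne_lengths
      if (any(cne_positions < 0L) || any(ends > length)) {
        stop("planted element outside the alignment", call. = FALSE)
      }
      if (k > 1L) {
        o <- order(cne_positions)
        if (any(ends[o][-k] > cne_positions[o][-1L])) {
          stop("planted elements overlap", call. = FALSE)
        }
      }
      if (any(vapply(seq_len(k), function(i) {
        overlaps_mask(cne_positions[i], ends[i], mask_intervals)
      }, logical(1)))) {
        stop("planted element collides with a mask interval", call. = FALSE)
      }
    }
    in_cne <- rep(FALSE, length)
    for (i in seq_len(k)) {
      in_cne[(cne_positions[i] + 1L):(cne_positions[i] + cne_lengths[i])] <- TRUE
    }
    ref <- sample(bases, length, replace = TRUE)
    species <- c(paste0("fish", seq_len(n_fish)),
                 if (n_tetrapod > 0L) paste0("tetrapod", seq_len(n_tetrapod)))
    p_match <- ifelse(in_cne, cne_match_prob, background_match_prob)
    texts <- vapply(species, function(sp) {
      s <- ref
      mism <- runif(length) > p_match
      if (any(mism)) {
        s[mism] <- vapply(ref[mism], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
      }
      gap <- runif(length) < gap_prob & !in_cne
      s[gap] <- "-"
      paste(s, collapse = "")
    }, character(1))
    rows <- data.frame(
      species = c("refsp", species),
      seqid = c(seqid, rep("region", base::length(species))),
      start = 0L,
      size = c(length, nchar(gsub("-", "", texts, fixed = TRUE))),
      strand = "+",
      src_size = length,
      text = c(paste(ref, collapse = ""), unname(texts)),
      stringsAsFactors = FALSE)
    cls <- setNames(c("reference",
                      rep("fish", n_fish),
                      rep("tetrapod", n_tetrapod)),
                    rows$species)
    block <- alignment_block(rows, species_class = cls)
    truth <- if (k > 0L) {
      genomic_intervals(seqid, cne_positions, cne_positions + cne_lengths)
    } else {
      genomic_intervals()
    }
    list(block = block, truth = truth,
         params = list(background_match_prob = background_match_prob,
                       cne_match_prob = cne_match_prob, gap_prob = gap_prob,
                       seed = seed))
  })
}

overlaps_mask <- function(start, end, masks) {
  if (is.null(masks) || nrow(masks) == 0L) return(FALSE)
  any(masks$start < end & masks$end > start)
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# copy a sequence with a given per-base substitution rate
mutate_dna <- function(seq, sub_rate) {
  if (sub_rate <= 0) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mism <- runif(base::length(s)) < sub_rate
  if (any(mism)) {
    s[mism] <- vapply(s[mism], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  paste(s, collapse = "")
}

#' Simulate asymmetric CNE retention around paralog pairs
#'
#' Plants `n_cnes` ancestral elements in a reference query region; for each
#' study species, each element is independently retained near paralog `a`
#' with probability `p_keep_a` and near paralog `b` with probability
#' `p_keep_b`. Retained copies are embedded (with light divergence) in
#' unrelated background sequence, so the pairwise search can rediscover the
#' retention pattern; the generator also returns the truth partition table.
#'
#' @param n_cnes number of ancestral elements.
#' @param p_keep_a,p_keep_b per-element per-species retention
#'   probabilities.
#' @param n_species number of study species.
#' @param p_tetrapod_shared probability that an ancestral element is also
#'   tetrapod-conserved (truth annotation only).
#' @param cne_length element length in bp.
#' @param spacer_length background length between elements (and flanks),
#'   default 600. Keep this comfortably above `cne_length` at the default
#'   scoring: if elements sit too close, the optimal local alignment can
#'   bridge two retained copies through the random spacer and report them
#'   as one chained hit.
#' @param copy_sub_rate substitution rate applied to retained copies
#'   (default 0.02, i.e. ~98% identity).
#' @param emit_sequences also build the query/subject sequences (default
#'   `TRUE`); with `FALSE` only the truth table is generated, which is much
#'   faster for large `n_cnes`.
#' @param seed integer seed (mandatory).
#' @return A list with `truth` (a `partition_table`), `query` (reference
#'   sequence string), `query_cnes` (data frame `name`, `start`, `end`),
#'   and `subjects` (nested list `[[species]][[paralog]]` of sequences).
#' @export
make_paralog_dataset <- function(n_cnes = 10L, p_keep_a = 0.9,
                                 p_keep_b = 0.3, n_species = 3L,
                                 p_tetrapod_shared = 0.2,
                                 cne_length = 100L, spacer_length = 600L,
                                 copy_sub_rate = 0.02,
                                 emit_sequences = TRUE, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(p_keep_a >= 0, p_keep_a <= 1, p_keep_b >= 0, p_keep_b <= 1,
            n_cnes >= 1L, n_species >= 1L)
  species <- paste0("sp", seq_len(n_species))
  withr::with_seed(seed, {
    starts <- spacer_length + (seq_len(n_cnes) - 1L) *
      (cne_length + spacer_length)
    query_cnes <- data.frame(name = sprintf("cne_%d", seq_len(n_cnes)),
                             start = starts, end = starts + cne_length,
                             stringsAsFactors = FALSE)
    tet <- runif(n_cnes) < p_tetrapod_shared
    truth <- expand.grid(cne = query_cnes$name, species = species,
                         stringsAsFactors = FALSE)
    truth$in_a <- runif(nrow(truth)) < p_keep_a
    truth$in_b <- runif(nrow(truth)) < p_keep_b
    truth$tetrapod_shared <- tet[match(truth$cne, query_cnes$name)]
    query <- NULL
    subjects <- NULL
    if (emit_sequences) {
      cnes <- vapply(seq_len(n_cnes), function(i) random_dna(cne_length),
                     character(1))
      query <- character(2L * n_cnes + 1L)
      query[seq(1L, 2L * n_cnes + 1L, by = 2L)] <-
        replicate(n_cnes + 1L, random_dna(spacer_length))
      query[seq(2L, 2L * n_cnes, by = 2L)] <- cnes
      query <- paste(query, collapse = "")
      subjects <- lapply(species, function(sp) {
        lapply(setNames(c("a", "b"), c("a", "b")), function(par) {
          keep <- truth[truth$species == sp,
                        if (par == "a") "in_a" else "in_b"]
          parts <- character(2L * n_cnes + 1L)
          parts[seq(1L, 2L * n_cnes + 1L, by = 2L)] <-
            replicate(n_cnes + 1L, random_dna(spacer_length))
          parts[seq(2L, 2L * n_cnes, by = 2L)] <- ifelse(
            keep, vapply(cnes, mutate_dna, character(1), copy_sub_rate), "")
          paste(parts, collapse = "")
        })
      })
      names(subjects) <- species
    }
    list(truth = partition_table(truth), query = query,
         query_cnes = query_cnes, subjects = subjects,
         params = list(p_keep_a = p_keep_a, p_keep_b = p_keep_b,
                       seed = seed))
  })
}

#' Simulate a gene x species copy-number landscape
#'
#' @param duplication_profile character vector, one entry per gene:
#'   `"singleton"` (one copy everywhere), `"wgd_all"` (WGD duplicate, two
#'   copies in every teleost), `"wgd_some"` (WGD duplicate, two copies in a
#'   random non-empty proper subset of teleosts) or `"ssd_all"` (SSD
#'   duplicate in every teleost).
#' @param n_teleosts,n_salmonids,n_outgroups species counts.
#' @param salmonid_retention_prob probability a salmonid keeps a gene in
#'   >= 2 copies (default 0.85).
#' @param seed integer seed (mandatory).
#' @return A list with `landscape` (a [landscape_matrix]) and
#'   `profile` (the truth vector).
#' @export
make_landscape <- function(duplication_profile, n_teleosts = 9L,
                           n_salmonids = 2L, n_outgroups = 2L,
                           salmonid_retention_prob = 0.85, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(all(duplication_profile %in%
                  c("singleton", "wgd_all", "wgd_some", "ssd_all")),
            n_teleosts >= 1L)
  ng <- base::length(duplication_profile)
  genes <- sprintf("gene%02d", seq_len(ng))
  species <- c(paste0("teleost", seq_len(n_teleosts)),
               if (n_salmonids > 0L) paste0("salmonid", seq_len(n_salmonids)),
               if (n_outgroups > 0L) paste0("outgroup", seq_len(n_outgroups)))
  lineage <- setNames(c(rep("teleost", n_teleosts),
                        rep("salmonid_teleost", n_salmonids),
                        rep("outgroup", n_outgroups)), species)
  withr::with_seed(seed, {
    m <- matrix(1L, ng, base::length(species),
                dimnames = list(genes, species))
    for (i in seq_len(ng)) {
      p <- duplication_profile[i]
      tel <- seq_len(n_teleosts)
      if (p %in% c("wgd_all", "ssd_all")) {
        m[i, tel] <- 2L
      } else if (p == "wgd_some") {
        ndup <- sample.int(max(1L, n_teleosts - 1L), 1L)
        m[i, sample(tel, ndup)] <- 2L
      }
      if (n_salmonids > 0L) {
        sal <- n_teleosts + seq_len(n_salmonids)
        m[i, sal] <- ifelse(runif(n_salmonids) < salmonid_retention_prob,
                            3L, 1L)
      }
    }
    origin <- setNames(ifelse(startsWith(duplication_profile, "wgd"),
                              "WGD_duplicate",
                              ifelse(duplication_profile == "ssd_all",
                                     "SSD_duplicate", "singleton")), genes)
    list(landscape = landscape_matrix(m, origin, lineage),
         profile = setNames(duplication_profile, genes))
  })
}

#' Simulate a qPCR Cq table
#'
#' Adds Gaussian noise to a design of true Cq values; limit-of-detection
#' handling happens downstream in [quantify_ddct()], not here.
#'
#' @param design data frame with columns `sample`, `gene`, `true_cq`.
#' @param noise_sd Gaussian noise standard deviation in cycles.
#' @param n_replicates replicates per (sample, gene), default 3.
#' @param seed integer seed (mandatory).
#' @return A Cq table data frame (`sample`, `gene`, `cq`).
#' @export
make_cq_table <- function(design, noise_sd = 0.2, n_replicates = 3L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(all(c("sample", "gene", "true_cq") %in% names(design)))
  withr::with_seed(seed, {
    reps <- design[rep(seq_len(nrow(design)), each = n_replicates), ]
    reps$cq <- reps$true_cq + rnorm(nrow(reps), 0, noise_sd)
    rownames(reps) <- NULL
    reps[, c("sample", "gene", "cq")]
  })
}
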