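#' Simulation experiments backing the pipeline's statistical guarantees
#'
#' These helpers run the package's standard simulation studies: planted-CNE
#' recovery for the scanner, type-I calibration of the branch-model LRT and
#' of the CNE count-asymmetry t-test, and recovery of the asymmetric-omega
#' signature (one paralog under strict constraint, the other relaxed). They
#' are used by the test suite, the analysis scripts and the acceptance
#' script alike.
#'
#' @name calibration
NULL

# deterministic stream of sub-seeds below 2^31
sub_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Planted-element recovery of the conservation scanner
#'
#' Plants `n_elements` high-identity elements (default lengths 20-40 bp at
#' 98% identity over a 60% background) across several alignments, scans
#' with the given parameters, and scores recovery at >= `min_reciprocal`
#' reciprocal overlap. Calls that touch no planted element are counted as
#' background calls.
#'
#' @param n_elements total planted elements (default 100).
#' @param elements_per_block how many per simulated alignment.
#' @param slot_length reference bp allotted per element (block length =
#'   `elements_per_block * slot_length`).
#' @param params [scan_params()] used for the scan.
#' @param min_reciprocal reciprocal-overlap fraction counting as recovered.
#' @param seed integer seed.
#' @inheritParams make_planted_alignment
#' @return List with `recovered_fraction`, `n_recovered`, `n_elements`,
#'   `background_calls`, `n_calls`.
#' @export
evaluate_scan_recovery <- function(n_elements = 100L,
                                   elements_per_block = 20L,
                                   slot_length = 500L,
                                   background_match_prob = 0.60,
                                   cne_match_prob = 0.98,
                                   cne_lengths = c(20L, 25L, 30L, 35L, 40L),
                                   params = scan_params(),
                                   min_reciprocal = 0.8,
                                   seed = 1L) {
  n_blocks <- ceiling(n_elements / elements_per_block)
  seeds <- sub_seeds(seed, n_blocks)
  n_rec <- 0L; n_tot <- 0L; n_bg <- 0L; n_calls <- 0L
  for (b in seq_len(n_blocks)) {
    k <- min(elements_per_block, n_elements - n_tot)
    lens <- rep_len(cne_lengths, k)
    sim <- make_planted_alignment(
      length = k * slot_length,
      background_match_prob = background_match_prob,
      cne_match_prob = cne_match_prob,
      cne_lengths = lens, seed = seeds[b])
    calls <- scan_cnes(sim$block, params = params)
    tr <- sim$truth
    hit_truth <- rep(FALSE, nrow(calls))
    for (i in seq_len(nrow(tr))) {
      if (nrow(calls)) {
        ov <- pmin(calls$end, tr$end[i]) - pmax(calls$start, tr$start[i])
        rec <- ov >= min_reciprocal * (tr$end[i] - tr$start[i]) &
          ov >= min_reciprocal * (calls$end - calls$start)
        if (any(rec)) n_rec <- n_rec + 1L
        hit_truth <- hit_truth | ov > 0
      }
    }
    n_tot <- n_tot + nrow(tr)
    n_calls <- n_calls + nrow(calls)
    n_bg <- n_bg + sum(!hit_truth)
  }
  list(recovered_fraction = n_rec / n_tot, n_recovered = n_rec,
       n_elements = n_tot, background_calls = n_bg, n_calls = n_calls)
}

# the standard 6-taxon study tree: two 2-leaf paralog clades plus 2 outgroups
default_lrt_tree <- function() {
  read_labeled_tree(paste0(
    "((A1#a:0.2,A2#a:0.2)#a:0.1,(B1#b:0.2,B2#b:0.2)#b:0.1,",
    "(O1:0.2,O2:0.2):0.1);"))
}

# 8-taxon tree with 3-leaf paralog clades, for omega-asymmetry recovery
default_asymmetry_tree <- function() {
  read_labeled_tree(paste0(
    "(((A1#a:0.15,A2#a:0.15)#a:0.1,A3#a:0.25)#a:0.1,",
    "((B1#b:0.15,B2#b:0.15)#b:0.1,B3#b:0.25)#b:0.1,",
    "(O1:0.2,O2:0.2):0.1);"))
}

#' Type-I calibration of the branch-model likelihood-ratio test
#'
#' Simulates codon alignments under the single-ratio model A, fits models A
#' and B (paralog branches vs rest) to each, and reports the fraction of
#' B-vs-A LRTs rejecting at level `alpha`. Under the null this should sit
#' near `alpha`. Model B is warm-started from the model A fit; a single
#' optimisation start per fit keeps the experiment tractable and does not
#' change the null distribution of the statistic.
#'
#' @param n_reps number of replicates (default 500).
#' @param n_codons codons per alignment (default 200).
#' @param tree a `labeled_tree` (default: 6 taxa, two 2-leaf paralog
#'   clades and two outgroups).
#' @param kappa,omega true simulation parameters (default 2 and 0.2).
#' @param alpha test level (default 0.05).
#' @param seed integer seed.
#' @return List with `rejection_rate`, `statistics`, `n_reps`, `alpha`.
#' @export
calibrate_branch_lrt <- function(n_reps = 500L, n_codons = 200L,
                                 tree = default_lrt_tree(), kappa = 2,
                                 omega = 0.2, alpha = 0.05, seed = 1L) {
  seeds <- sub_seeds(seed, n_reps)
  pi <- codon_frequencies(method = "equal")
  ctrl <- list(factr = 1e7, maxit = 300L)
  stats <- vapply(seq_len(n_reps), function(i) {
    aln <- simulate_codon_alignment(tree, model = "A", kappa = kappa,
                                    omega = omega, pi = pi,
                                    n_codons = n_codons, seed = seeds[i])
    fa <- fit_codon_model(aln, tree, "A", codon_freq = "equal",
                          restarts = 1L, control = ctrl,
                          start = list(kappa = kappa, omega = omega))
    fb <- fit_codon_model(aln, tree, "B", codon_freq = "equal",
                          restarts = 1L, control = ctrl,
                          start = list(kappa = fa$kappa,
                                       omega = c(r = unname(fa$omega[1L]),
                                                 p = unname(fa$omega[1L])),
                                       branch_lengths = fa$branch_lengths))
    codon_lrt(fa, fb)$statistic
  }, numeric(1))
  crit <- stats::qchisq(1 - alpha, df = 1)
  list(rejection_rate = mean(stats > crit), statistics = stats,
       n_reps = n_reps, alpha = alpha)
}

#' Recovery of the asymmetric-evolution signature
#'
#' Simulates codon alignments under model C with one paralog clade under
#' strict purifying selection and the other relaxed (defaults:
#' omega_r = 0.05, omega_a = 0.5, omega_b = 0.1), fits model C, and reports
#' how often the fitted omega_a exceeds the fitted omega_b.
#'
#' @inheritParams calibrate_branch_lrt
#' @param omega named true omegas (`r`, `a`, `b`).
#' @param n_codons codons per alignment (default 300).
#' @param n_reps replicates (default 50).
#' @return List with `fraction_a_gt_b`, `omega_a`, `omega_b`, `n_reps`.
#' @export
recover_omega_asymmetry <- function(n_reps = 50L, n_codons = 300L,
                                    tree = default_asymmetry_tree(),
                                    kappa = 2,
                                    omega = c(r = 0.05, a = 0.5, b = 0.1),
                                    seed = 1L) {
  seeds <- sub_seeds(seed, n_reps)
  pi <- codon_frequencies(method = "equal")
  ctrl <- list(factr = 1e7, maxit = 300L)
  om <- t(vapply(seq_len(n_reps), function(i) {
    aln <- simulate_codon_alignment(tree, model = "C", kappa = kappa,
                                    omega = omega, pi = pi,
                                    n_codons = n_codons, seed = seeds[i])
    f <- fit_codon_model(aln, tree, "C", codon_freq = "equal",
                         restarts = 1L, control = ctrl,
                         start = list(kappa = kappa, omega = omega))
    c(a = unname(f$omega["a"]), b = unname(f$omega["b"]))
  }, numeric(2)))
  list(fraction_a_gt_b = mean(om[, "a"] > om[, "b"]),
       omega_a = om[, "a"], omega_b = om[, "b"], n_reps = n_reps)
}

#' Type-I calibration of the CNE count-asymmetry t-test
#'
#' Simulates symmetric retention: for each gene, the CNE counts retained
#' near paralogs a and b are independent Binomial(N_g, p) draws with the
#' same retention probability on both sides, so there is no true asymmetry.
#' The default per-gene ancestral CNE totals (12, 6, 37, 3, 36) mirror the
#' five focal genes of the study.
#'
#' @param n_datasets number of simulated datasets (default 500).
#' @param cne_totals ancestral CNE count per gene.
#' @param p_keep symmetric retention probability (default 0.5).
#' @param paired use the paired test (default `TRUE`).
#' @inheritParams calibrate_branch_lrt
#' @return List with `rejection_rate`, `n_datasets`, `alpha`.
#' @export
calibrate_count_asymmetry <- function(n_datasets = 500L,
                                      cne_totals = c(12L, 6L, 37L, 3L, 36L),
                                      p_keep = 0.5, paired = TRUE,
                                      alpha = 0.05, seed = 1L) {
  rej <- withr::with_seed(seed, {
    vapply(seq_len(n_datasets), function(i) {
      a <- rbinom(length(cne_totals), cne_totals, p_keep)
      b <- rbinom(length(cne_totals), cne_totals, p_keep)
      count_asymmetry_test(a, b, paired = paired)$p < alpha
    }, logical(1))
  })
  list(rejection_rate = mean(rej), n_datasets = n_datasets, alpha = alpha)
}
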