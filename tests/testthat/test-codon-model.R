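eqpi <- codon_frequencies(method = "equal")

test_that("rate matrix has the Goldman-Yang structure", {
  info_type <- local({
    Q1 <- build_rate_matrix(1, 1, eqpi)
    Q1
  })
  # kappa = omega = 1, equal frequencies: all allowed changes share one rate
  offdiag <- info_type[row(info_type) != col(info_type)]
  rates <- unique(round(offdiag[offdiag > 0], 12))
  expect_length(rates, 1L)
  # multi-nucleotide changes are forbidden
  codons <- sense_codons()
  ndiff <- function(x, y) sum(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
  expect_equal(info_type["AAA", "ACC"], 0)
  expect_equal(info_type["AAA", "CCC"], 0)
  # omega = 0 kills every nonsynonymous rate
  Q0 <- build_rate_matrix(2, 0, eqpi)
  aa <- Biostrings::GENETIC_CODE[codons]
  nonsyn <- outer(aa, aa, "!=")
  expect_true(all(Q0[nonsyn & row(Q0) != col(Q0)] == 0))
  # rows sum to zero and -sum(pi * diag) = 1 after scaling
  Q <- build_rate_matrix(2.5, 0.3, eqpi)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(eqpi * diag(Q)), 1, tolerance = 1e-12)
  expect_error(build_rate_matrix(2, 0.3, rep(0.5, 61)), "sum to 1")
})

test_that("zero branch lengths give the equilibrium closed form", {
  lt <- read_labeled_tree("(A:0,B:0);")
  aln <- codon_alignment(c(A = "ATGAAACCC", B = "ATGAAACCC"))
  lnl <- codon_log_likelihood(aln, lt, "A", kappa = 2, omega = 0.2, pi = eqpi)
  expect_equal(lnl, 3 * log(1 / 61), tolerance = 1e-9)
  # differing sequences at zero branch length are (numerically) impossible:
  # the mismatching site's probability collapses to roundoff scale
  aln2 <- codon_alignment(c(A = "ATGAAACCC", B = "ATGAAACCA"))
  lnl2 <- tryCatch(
    codon_log_likelihood(aln2, lt, "A", kappa = 2, omega = 0.2, pi = eqpi),
    error = function(e) -Inf)
  expect_lt(lnl2, 3 * log(1 / 61) - 20)
})

test_that("pruning matches the exhaustive-state oracle on 3 taxa", {
  lt <- read_labeled_tree("((t1:0.2,t2:0.35):0.15,t3:0.4);")
  set.seed(99)
  for (rep in 1:3) {
    kappa <- runif(1, 1, 4)
    omega <- runif(1, 0.05, 1)
    aln <- simulate_codon_alignment(lt, "A", kappa = 2, omega = 0.3,
                                    pi = eqpi, n_codons = 10,
                                    seed = 1000 + rep)
    got <- codon_log_likelihood(aln, lt, "A", kappa = kappa, omega = omega,
                                pi = eqpi)
    states <- aln$states[c("t1", "t2", "t3"), ]
    want <- oracle_3taxon_lnl(states, bl = c(0.2, 0.35, 0.15, 0.4),
                              kappa = kappa, omega = omega, pi = eqpi)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("model C with equal omegas collapses to model A", {
  lt <- read_labeled_tree("((A1#a:0.2,A2#a:0.2)#a:0.1,(B1#b:0.2,B2#b:0.2)#b:0.1,O1:0.3);")
  aln <- simulate_codon_alignment(lt, "C", kappa = 2,
                                  omega = c(r = 0.1, a = 0.4, b = 0.2),
                                  pi = eqpi, n_codons = 50, seed = 77)
  lA <- codon_log_likelihood(aln, lt, "A", kappa = 2, omega = 0.25, pi = eqpi)
  lC <- codon_log_likelihood(aln, lt, "C", kappa = 2,
                             omega = c(r = 0.25, a = 0.25, b = 0.25),
                             pi = eqpi)
  expect_equal(lA, lC, tolerance = 1e-10)
})

test_that("simulation is seed-deterministic and hits equilibrium", {
  lt <- read_labeled_tree("((A:0.2,B:0.2):0.1,C:0.3);")
  a1 <- simulate_codon_alignment(lt, "A", 2, 0.2, eqpi, n_codons = 30,
                                 seed = 5)
  a2 <- simulate_codon_alignment(lt, "A", 2, 0.2, eqpi, n_codons = 30,
                                 seed = 5)
  expect_identical(a1$states, a2$states)
  a3 <- simulate_codon_alignment(lt, "A", 2, 0.2, eqpi, n_codons = 30,
                                 seed = 6)
  expect_false(identical(a1$states, a3$states))
  # zero branch lengths copy the root draw to every tip
  lt0 <- read_labeled_tree("((A:0,B:0):0,C:0);")
  a0 <- simulate_codon_alignment(lt0, "A", 2, 0.2, eqpi, n_codons = 40,
                                 seed = 8)
  expect_equal(a0$states["A", ], a0$states["B", ])
  expect_equal(a0$states["A", ], a0$states["C", ])
  # long simulation approaches the equilibrium codon distribution
  big <- simulate_codon_alignment(lt, "A", 2, 0.2, eqpi, n_codons = 10000,
                                  seed = 9)
  freq <- tabulate(big$states, nbins = 61) / length(big$states)
  expect_lt(max(abs(freq - 1 / 61)), 0.01)
})

test_that("fits recover simulation parameters and respect nesting", {
  lt <- study_tree_6taxa()
  oms <- vapply(1:5, function(i) {
    a <- simulate_codon_alignment(lt, "A", kappa = 2, omega = 0.2, pi = eqpi,
                                  n_codons = 500, seed = 40 + i)
    f <- fit_codon_model(a, lt, "A", codon_freq = "equal", restarts = 1,
                         start = list(kappa = 2, omega = 0.2))
    f$omega[["omega"]]
  }, numeric(1))
  expect_lt(abs(median(oms) - 0.2), 0.05)
  aln <- simulate_codon_alignment(lt, "A", kappa = 2, omega = 0.2, pi = eqpi,
                                  n_codons = 500, seed = 42)
  fit <- fit_codon_model(aln, lt, "A", codon_freq = "equal", restarts = 1,
                         start = list(kappa = 2, omega = 0.2))
  expect_lt(abs(fit$kappa - 2), 0.5)
  fitB <- fit_codon_model(aln, lt, "B", codon_freq = "equal", restarts = 1,
                          start = list(kappa = fit$kappa,
                                       omega = c(r = 0.2, p = 0.2),
                                       branch_lengths = fit$branch_lengths))
  # nesting: the richer model can only improve the likelihood
  expect_gte(fitB$lnL, fit$lnL - 1e-4)
  r <- codon_lrt(fit, fitB)
  expect_gte(r$statistic, 0)
  expect_equal(r$df, 1L)
})

test_that("the LRT machinery follows the chi-squared convention", {
  f0 <- structure(list(model = "A", lnL = -1000, free_parameters = 11L,
                       n_codons = 100L, n_taxa = 6L),
                  class = "codon_model_fit")
  f1 <- structure(list(model = "B", lnL = -998.0795, free_parameters = 12L,
                       n_codons = 100L, n_taxa = 6L),
                  class = "codon_model_fit")
  r <- codon_lrt(f0, f1)
  expect_equal(r$df, 1L)
  expect_equal(r$statistic, 3.841, tolerance = 1e-3)
  expect_equal(r$p, 0.05, tolerance = 1e-3)
  # identical fits -> statistic 0, p 1
  r0 <- codon_lrt(f0, structure(list(model = "B", lnL = -1000,
                                     free_parameters = 12L, n_codons = 100L,
                                     n_taxa = 6L), class = "codon_model_fit"))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(codon_lrt(f1, f0), "nested")
})

test_that("alignment cleaning removes gap and stop codon columns", {
  seqs <- c(A = "ATG---AAATAG", B = "ATGCCCAAATAG")
  aln <- clean_codon_alignment(seqs)
  expect_equal(aln$length, 2L)  # gap codon and stop codon column removed
  expect_error(codon_alignment(c(A = "ATG---")), "non-sense")
  expect_error(codon_alignment(c(A = "ATGC")), "multiple of 3")
  # round trip through FASTA
  f <- withr::local_tempfile(fileext = ".fa")
  write_codon_fasta(aln, f)
  back <- read_codon_fasta(f)
  expect_equal(back$states, aln$states)
})
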