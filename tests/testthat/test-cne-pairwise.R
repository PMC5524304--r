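test_that("identical sequences align end to end", {
  q <- strrep("ACGT", 15)
  h <- local_align(q, q)
  expect_equal(h$score, 60)
  expect_equal(h$identity, 1.0)
  expect_equal(h$aligned_columns, 60L)
  expect_equal(c(h$q_start, h$q_end), c(0L, 60L))
})

test_that("worst-case pair still finds the single best match", {
  h <- local_align("ACGT", "TTTT")
  expect_equal(h$score, 1)
  expect_equal(h$aligned_columns, 1L)
  # tie-break: smallest query start wins -> the T at query position 3
  expect_equal(h$q_start, 3L)
  expect_equal(h$s_start, 0L)
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("alignment scores match the brute-force oracle on short pairs", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:8, 1L)
    m <- sample(2:8, 1L)
    q <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    s <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    want <- oracle_local_score(q, s)
    h <- local_align(q, s)
    got <- if (is.null(h)) 0 else h$score
    expect_equal(got, want, info = paste(q, s))
  }
})

test_that("alignment agrees with Biostrings on gapless high-identity pairs", {
  set.seed(88)
  for (rep in 1:10) {
    core <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    q <- paste0("CCCCCCCC", core, "GGGGGGGG")
    s <- paste0("TTTTTTTT", core, "AAAAAAAA")
    h <- local_align(q, s)
    ref <- Biostrings::pairwiseAlignment(
      q, s, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 2, gapExtension = 2)
    expect_equal(h$score, Biostrings::score(ref))
  }
})

test_that("hit filters read 'longer than 50 bp' strictly", {
  p <- pairwise_params()
  set.seed(5)
  exact50 <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  exact51 <- paste(sample(c("A", "C", "G", "T"), 51, TRUE), collapse = "")
  expect_equal(nrow(find_hits(exact50, exact50, p)), 0L)
  h <- find_hits(exact51, exact51, p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$aligned_columns, 51L)
})

test_that("a planted element inside random flanks is found once", {
  set.seed(31)
  core <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  mutate <- function(s, rate) {
    x <- strsplit(s, "")[[1L]]
    i <- runif(length(x)) < rate
    x[i] <- vapply(x[i], function(b) sample(setdiff(c("A","C","G","T"), b), 1),
                   character(1))
    paste(x, collapse = "")
  }
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  q <- paste0(flank(1000), core, flank(1000))
  s <- paste0(flank(1000), mutate(core, 0.10), flank(1000))
  hits <- find_hits(q, s, pairwise_params())
  expect_equal(nrow(hits), 1L)
  ov <- min(hits$q_end, 1080) - max(hits$q_start, 1000)
  expect_gte(ov, 0.8 * 80)
  expect_gte(hits$identity, 0.6)
})

test_that("reverse-complementing the subject flips strand, not scores", {
  set.seed(41)
  core <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  q <- paste0(strrep("C", 200), core, strrep("G", 200))
  s <- paste0(strrep("T", 150), core, strrep("A", 150))
  fwd <- find_hits(q, s, pairwise_params())
  rev <- find_hits(q, reverse_complement(s), pairwise_params())
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(fwd$score, rev$score)
  expect_equal(fwd$identity, rev$identity)
  expect_setequal(fwd$strand, "+")
  expect_setequal(rev$strand, "-")
  # subject coordinates map back to the same forward-strand interval
  expect_equal(fwd$s_start, rev$s_start)
  expect_equal(fwd$s_end, rev$s_end)
})

test_that("query/subject swap preserves the retained score set", {
  set.seed(51)
  core1 <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
  core2 <- paste(sample(c("A", "C", "G", "T"), 55, TRUE), collapse = "")
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  q <- paste0(rand(300), core1, rand(300), core2, rand(300))
  s <- paste0(rand(200), core2, rand(400), core1, rand(200))
  ab <- find_hits(q, s, pairwise_params())
  ba <- find_hits(s, q, pairwise_params())
  expect_equal(sort(ab$score), sort(ba$score))
  expect_equal(sort(ab$aligned_columns), sort(ba$aligned_columns))
})

test_that("raising min_identity never adds hits", {
  set.seed(61)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  q <- rand(800)
  s <- paste0(substr(q, 100, 400), rand(400))
  lo <- find_hits(q, s, pairwise_params(min_identity = 0.6))
  hi <- find_hits(q, s, pairwise_params(min_identity = 0.9))
  expect_lte(nrow(hi), nrow(lo))
  expect_true(all(hi$score %in% lo$score))
})

test_that("masked query stretches cannot anchor hits", {
  set.seed(71)
  core <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  q <- paste0(strrep("G", 100), core, strrep("C", 100))
  s <- paste0(strrep("T", 50), core, strrep("A", 50))
  masked <- mask_sequence(q, genomic_intervals("q", 100, 200))
  expect_equal(nrow(find_hits(masked, s, pairwise_params())), 0L)
})
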