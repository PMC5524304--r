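test_that("presence needs a retained hit covering half the CNE", {
  cnes <- data.frame(name = "cne_1", start = 100L, end = 200L)
  hits <- data.frame(species = "medaka", paralog = "b",
                     q_start = 120L, q_end = 190L, retained = TRUE)
  p <- build_partition(cnes, hits)
  expect_false(p$in_a)
  expect_true(p$in_b)
  # 40% overlap is below the rule
  hits40 <- data.frame(species = "medaka", paralog = "b",
                       q_start = 160L, q_end = 260L, retained = TRUE)
  expect_false(build_partition(cnes, hits40)$in_b)
  # exactly 50% qualifies
  hits50 <- data.frame(species = "medaka", paralog = "b",
                       q_start = 150L, q_end = 260L, retained = TRUE)
  expect_true(build_partition(cnes, hits50)$in_b)
  # unknown species key
  expect_error(build_partition(cnes, hits, species = "zebrafish"),
               "unknown species")
})

test_that("randomised hit sets match the reclassification oracle", {
  set.seed(12)
  for (rep in 1:20) {
    ncne <- sample(3:8, 1)
    cnes <- data.frame(name = sprintf("c%d", seq_len(ncne)),
                       start = (seq_len(ncne) - 1L) * 200L,
                       end = (seq_len(ncne) - 1L) * 200L + 100L)
    nh <- sample(5:25, 1)
    hits <- data.frame(
      species = sample(c("sp1", "sp2", "sp3"), nh, TRUE),
      paralog = sample(c("a", "b"), nh, TRUE),
      q_start = sample.int(ncne * 200L, nh) - 1L,
      retained = runif(nh) < 0.8)
    hits$q_end <- hits$q_start + sample(20:150, nh, TRUE)
    got <- build_partition(cnes, hits,
                           species = c("sp1", "sp2", "sp3"))
    want <- oracle_partition(cnes, hits)
    key <- function(d) d[order(d$cne, d$species), c("in_a", "in_b")]
    got <- got[order(got$cne, got$species), ]
    want <- want[order(want$cne, want$species), ]
    expect_equal(unname(got$in_a), unname(want$in_a))
    expect_equal(unname(got$in_b), unname(want$in_b))
  }
})

sox_fixture <- function(gene) {
  partition_table(read.delim(system.file(
    "extdata", sprintf("partition_%s.tsv", gene), package = "ohnocne")))
}

test_that("fixture summaries reproduce the per-gene asymmetry fractions", {
  s4 <- summarize_partition(sox_fixture("sox4"))
  expect_equal(s4$total_cnes, 12L)
  expect_equal(s4$b_only, 8L)
  expect_equal(round(100 * s4$b_only / s4$total_cnes, 1), 66.7)
  expect_equal(s4$dominant_paralog, "b")
  expect_equal(s4$tetrapod_shared_count, 2L)

  s10 <- summarize_partition(sox_fixture("sox10"))
  expect_equal(s10$total_cnes, 3L)
  expect_equal(s10$one_paralog_fraction, 100)

  # every CNE near both paralogs -> one-paralog fraction 0
  allboth <- partition_table(data.frame(
    cne = rep(c("c1", "c2"), each = 2), species = rep(c("s1", "s2"), 2),
    in_a = TRUE, in_b = TRUE))
  expect_equal(summarize_partition(allboth)$one_paralog_fraction, 0)

  # empty table
  empty <- partition_table(data.frame(cne = character(),
                                      species = character(),
                                      in_a = logical(), in_b = logical()))
  s0 <- summarize_partition(empty)
  expect_equal(s0$total_cnes, 0L)
  expect_true(is.na(s0$one_paralog_fraction))
})

test_that("category counts always sum to the total", {
  set.seed(23)
  for (rep in 1:20) {
    pt <- partition_table(data.frame(
      cne = rep(sprintf("c%d", 1:6), each = 3),
      species = rep(c("s1", "s2", "s3"), 6),
      in_a = runif(18) < 0.5, in_b = runif(18) < 0.5))
    s <- summarize_partition(pt)
    expect_equal(s$a_only + s$b_only + s$both + s$neither, s$total_cnes)
  }
})

test_that("relabeling paralogs swaps a/b and preserves the fractions", {
  set.seed(34)
  pt <- partition_table(data.frame(
    cne = rep(sprintf("c%d", 1:8), each = 2),
    species = rep(c("s1", "s2"), 8),
    in_a = runif(16) < 0.6, in_b = runif(16) < 0.3))
  sw <- pt
  tmp <- sw$in_a; sw$in_a <- sw$in_b; sw$in_b <- tmp
  s1 <- summarize_partition(pt)
  s2 <- summarize_partition(sw)
  expect_equal(s1$a_only, s2$b_only)
  expect_equal(s1$b_only, s2$a_only)
  expect_equal(s1$one_paralog_fraction, s2$one_paralog_fraction)
  # and the t-test p-value is invariant under the swap
  counts_a <- c(8, 31, 5, 21, 3)
  counts_b <- c(4, 5, 1, 16, 0)
  expect_equal(count_asymmetry_test(counts_a, counts_b)$p,
               count_asymmetry_test(counts_b, counts_a)$p)
})

test_that("the asymmetry t-test matches the closed form", {
  a <- c(8, 31, 5, 21, 3)
  b <- c(4, 5, 1, 16, 0)
  got <- count_asymmetry_test(a, b, paired = TRUE)
  want <- oracle_paired_t(a, b)
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p)

  got2 <- count_asymmetry_test(a, b, paired = FALSE)
  want2 <- oracle_two_sample_t(a, b)
  expect_equal(got2$statistic, want2$statistic)
  expect_equal(got2$p, want2$p)

  # identical counts -> t = 0, p = 1 (paired and unpaired)
  same <- count_asymmetry_test(c(3, 7, 9), c(3, 7, 9))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  flat <- count_asymmetry_test(c(1, 1), c(1, 1), paired = FALSE)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # zero variance with nonzero mean difference -> machine-floor p, flagged
  deg <- count_asymmetry_test(c(5, 6, 7), c(3, 4, 5))
  expect_true(deg$degenerate)
  expect_lt(deg$p, 1e-300)
  expect_error(count_asymmetry_test(1, 2), "at least 2")
})
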