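test_that("the Livak arithmetic is reproduced on a hand-worked table", {
  cq <- data.frame(sample = rep(c("s1", "s2"), each = 2),
                   gene = rep(c("tgt", "ref"), 2),
                   cq = c(25, 20, 28, 20))
  calls <- quantify_ddct(cq, "ref", "s1")
  s1 <- calls[calls$sample == "s1", ]
  s2 <- calls[calls$sample == "s2", ]
  expect_equal(s1$delta_ct, 5)
  expect_equal(s1$delta_delta_ct, 0)
  expect_equal(s1$relative_expression, 1.0)
  expect_equal(s2$delta_ct, 8)
  expect_equal(s2$delta_delta_ct, 3)
  expect_equal(s2$relative_expression, 0.125)
  # 0.125 > 0.10, so this is expressed, not low
  expect_equal(s2$bin, "expressed")
})

test_that("replicates are averaged before the delta steps", {
  cq <- data.frame(sample = "s1", gene = rep(c("tgt", "ref"), each = 3),
                   cq = c(24.8, 25.0, 25.2, 19.9, 20.0, 20.1))
  calls <- quantify_ddct(cq, "ref", "s1")
  expect_equal(calls$delta_ct, 5)
})

test_that("the 34-cycle detection limit is a closed boundary", {
  cq <- data.frame(sample = rep("s1", 4),
                   gene = c("t1", "t2", "t3", "ref"),
                   cq = c(34.2, 34.0, 33.9, 20))
  calls <- quantify_ddct(cq, "ref", "s1")
  expect_equal(calls$bin[calls$gene == "t1"], "nondetect")
  expect_equal(calls$bin[calls$gene == "t2"], "nondetect")  # exactly 34
  expect_false(calls$bin[calls$gene == "t3"] == "nondetect")
  expect_true(is.na(calls$delta_delta_ct[calls$gene == "t1"]))
})

test_that("the low-expression bin boundary is a closed threshold", {
  # exact power-of-two fold changes around a 0.25 threshold: 2^-2 = 0.25
  # lands exactly on the boundary and must be binned low (<=, not <)
  cq <- data.frame(
    sample = rep(c("cal", "s1", "s2", "s3"), each = 2),
    gene = rep(c("tgt", "ref"), 4),
    cq = c(20, 20, 22, 20, 23, 20, 21.5, 20))
  calls <- quantify_ddct(cq, "ref", "cal", low_threshold = 0.25)
  expect_equal(calls$relative_expression[calls$sample == "s1"], 0.25)
  expect_equal(calls$bin[calls$sample == "s1"], "low")       # == threshold
  expect_equal(calls$bin[calls$sample == "s2"], "low")       # 0.125 below
  expect_equal(calls$bin[calls$sample == "s3"], "expressed") # ~0.354 above
  # at the default 0.10 threshold: 0.125 is expressed, 0.0625 is low
  d <- quantify_ddct(cq, "ref", "cal")
  expect_equal(d$bin[d$sample == "s1"], "expressed")  # 0.25
  expect_equal(d$bin[d$sample == "s2"], "expressed")  # 0.125
  cq2 <- data.frame(sample = rep(c("cal", "s4"), each = 2),
                    gene = rep(c("tgt", "ref"), 2), cq = c(20, 20, 24, 20))
  d2 <- quantify_ddct(cq2, "ref", "cal")
  expect_equal(d2$relative_expression[d2$sample == "s4"], 0.0625)
  expect_equal(d2$bin[d2$sample == "s4"], "low")
})

test_that("shifting a sample's Cq values leaves delta-Ct unchanged", {
  set.seed(2)
  base <- data.frame(sample = rep("s1", 4),
                     gene = c("t1", "t2", "t3", "ref"),
                     cq = runif(4, 18, 30))
  shifted <- base
  shifted$cq <- shifted$cq + 1.7
  d1 <- quantify_ddct(base, "ref", "s1")$delta_ct
  d2 <- quantify_ddct(shifted, "ref", "s1")$delta_ct
  expect_equal(d1, d2)
})

test_that("a missing reference flags the sample instead of dropping it", {
  cq <- data.frame(sample = rep(c("s1", "s2"), each = 2),
                   gene = rep(c("tgt", "ref"), 2),
                   cq = c(25, 20, 26, 35))  # reference undetected in s2
  calls <- quantify_ddct(cq, "ref", "s1")
  s2 <- calls[calls$sample == "s2", ]
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$flag, "missing_reference")
  expect_true(is.na(s2$delta_ct))
  expect_error(quantify_ddct(cq, "nope", "s1"), "reference gene")
  expect_error(quantify_ddct(cq, "ref", "nope"), "calibrator")
})

test_that("noise-free synthetic tables recover design fold changes", {
  design <- data.frame(sample = rep(c("cal", "s1"), each = 2),
                       gene = rep(c("tgt", "ref"), 2),
                       true_cq = c(22, 20, 24, 20))
  tab <- make_cq_table(design, noise_sd = 0, seed = 4)
  calls <- quantify_ddct(tab, "ref", "cal")
  expect_equal(calls$delta_delta_ct[calls$sample == "s1"], 2)
  expect_equal(calls$relative_expression[calls$sample == "s1"], 0.25)
  # with noise, the mean recovered ddCt stays near the design value
  reps <- vapply(1:100, function(i) {
    tab <- make_cq_table(design, noise_sd = 0.2, seed = i)
    calls <- quantify_ddct(tab, "ref", "cal")
    calls$delta_delta_ct[calls$sample == "s1"]
  }, numeric(1))
  expect_lt(abs(mean(reps) - 2), 0.1)
})
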