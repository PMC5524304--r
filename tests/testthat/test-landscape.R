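test_that("the transcribed sox landscape reproduces the retention arithmetic", {
  ls <- sox_landscape()
  r <- summarize_landscape(ls)
  expect_equal(r$n_genes, 19L)
  expect_equal(r$n_duplicated_any, 11L)
  expect_equal(r$pct_duplicated_any, round(100 * 11 / 19, 1))
  expect_equal(r$n_duplicated_all, 3L)
  expect_equal(r$pct_duplicated_all, 27.3)
  expect_equal(r$n_lineage_specific, 8L)
  expect_equal(r$pct_lineage_specific, 72.7)
  expect_equal(r$n_wgd_duplicates, 10L)
  expect_equal(r$wgd_retention_pct, 52.6)
  sal <- salmonid_retention(ls)
  expect_true(all(sal$per_species_pct > 80))
  expect_gt(sal$pooled_pct, 80)
})

test_that("degenerate landscapes summarise correctly", {
  m <- matrix(1L, 3, 2, dimnames = list(paste0("g", 1:3), c("t1", "t2")))
  ls <- landscape_matrix(m,
                         setNames(rep("singleton", 3), rownames(m)),
                         setNames(rep("teleost", 2), colnames(m)))
  r <- summarize_landscape(ls)
  expect_equal(r$n_duplicated_any, 0L)
  expect_equal(r$pct_duplicated_any, 0)
  expect_true(is.na(r$pct_duplicated_all))
  # one gene duplicated everywhere
  m2 <- matrix(2L, 1, 2, dimnames = list("g1", c("t1", "t2")))
  ls2 <- landscape_matrix(m2, c(g1 = "WGD_duplicate"),
                          setNames(rep("teleost", 2), c("t1", "t2")))
  r2 <- summarize_landscape(ls2)
  expect_equal(r2$pct_duplicated_any, 100)
  expect_equal(r2$pct_duplicated_all, 100)
  expect_error(salmonid_retention(ls2), "no salmonid")
})

test_that("report values are invariant to row/column permutation", {
  ls <- sox_landscape()
  set.seed(3)
  perm <- landscape_matrix(
    ls$copy_number[sample(nrow(ls$copy_number)),
                   sample(ncol(ls$copy_number))],
    ls$origin, ls$lineage)
  expect_equal(unclass(summarize_landscape(perm)),
               unclass(summarize_landscape(ls)))
})

test_that("an all-absent outgroup species changes nothing", {
  ls <- sox_landscape()
  m <- cbind(ls$copy_number, newsp = 0L)
  ls2 <- landscape_matrix(m, ls$origin, c(ls$lineage, newsp = "outgroup"))
  expect_equal(unclass(summarize_landscape(ls2)),
               unclass(summarize_landscape(ls)))
})

test_that("salmonid retention equals an independent recount", {
  set.seed(8)
  for (rep in 1:10) {
    sim <- make_landscape(sample(c("singleton", "wgd_all", "wgd_some"),
                                 12, TRUE),
                          seed = 100 + rep)
    ls <- sim$landscape
    got <- salmonid_retention(ls)
    sal_cols <- names(ls$lineage)[ls$lineage == "salmonid_teleost"]
    for (sp in sal_cols) {
      v <- ls$copy_number[, sp]
      want <- round(100 * sum(v[v >= 1] >= 2) / sum(v >= 1), 1)
      expect_equal(unname(got$per_species_pct[sp]), want)
    }
  }
})

test_that("landscape TSV round-trips", {
  ls <- sox_landscape()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(ls, f)
  back <- read_landscape(f)
  expect_equal(back$copy_number, ls$copy_number)
  expect_equal(back$origin, ls$origin)
  expect_equal(back$lineage, ls$lineage)
})
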