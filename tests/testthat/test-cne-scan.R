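# small helper: block from explicit row strings (first row = reference)
block_from <- function(..., n_fish = NULL) {
  texts <- c(...)
  n <- length(texts) - 1L
  if (is.null(n_fish)) n_fish <- n
  species <- c("ref",
               if (n_fish > 0L) paste0("f", seq_len(n_fish)),
               if (n > n_fish) paste0("t", seq_len(n - n_fish)))
  rows <- data.frame(
    species = species, seqid = c("chrT", rep("x", n)), start = 0L,
    size = nchar(gsub("-", "", texts, fixed = TRUE)), strand = "+",
    src_size = nchar(texts[1L]), text = texts, stringsAsFactors = FALSE)
  cls <- setNames(c("reference", rep("fish", n_fish),
                    rep("tetrapod", n - n_fish)), species)
  alignment_block(rows, species_class = cls)
}

test_that("column conservation applies the substitution threshold strictly", {
  # 10 identical rows: 0/10 < 0.12 -> conserved
  b <- block_from(rep(strrep("A", 5), 11))
  expect_true(column_conserved(b, 3))
  # 2 of 10 mismatching: 0.20 >= 0.12 -> not conserved
  texts <- c(rep("AAAAA", 9), "CCCCC", "CCCCC")
  expect_false(column_conserved(block_from(texts), 3))
  # 1 of 10 mismatching: 0.10 < 0.12 -> conserved
  texts <- c(rep("AAAAA", 10), "CCCCC")
  expect_true(column_conserved(block_from(texts), 3))
  expect_error(column_conserved(b, 99), "out of range")
})

test_that("gapped rows leave the denominator; sparse columns never conserved", {
  # 8 informative matching rows + 2 gapped rows -> conserved
  texts <- c(rep("AAAAA", 9), "--_--", "-----")
  texts <- gsub("_", "-", texts)
  b <- block_from(texts)
  expect_true(column_conserved(b, 3))
  # fewer than 3 informative rows -> not conserved even if identical
  b2 <- block_from("AAAAA", "AAAAA", "AAAAA", "-----", "-----")
  expect_false(column_conserved(b2, 1))
  # N never counts as identity
  b3 <- block_from("AAAAA", rep("NNNNN", 5))
  expect_false(column_conserved(b3, 1))
})

test_that("column predicate matches the rule oracle on random columns", {
  set.seed(101)
  p <- scan_params()
  for (rep in 1:50) {
    b <- random_block(ncol = 12L, nspecies = sample(4:9, 1), p_match = 0.7)
    got <- conserved_columns(b, p)
    want <- oracle_column_conserved(block_matrix(b))
    expect_equal(got, want)
  }
})

test_that("seeds require 90% conserved columns over reference bases", {
  p <- scan_params()
  # 10 conserved columns flanked by junk -> exactly that window
  ref <- paste0("ACGTA", strrep("A", 10), "ACGTA")
  good <- paste0("TGCAT", strrep("A", 10), "TGCAT")
  b <- block_from(ref, good, good, good)
  s <- find_seeds(b, p)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start_col, s$end_col), c(6L, 15L))
  # 9 of 10 conserved still qualifies (0.9 exactly)
  good9 <- paste0("TGCAT", "AAAACAAAAA", "TGCAT")
  b9 <- block_from(ref, good9, good9, good9)
  s9 <- find_seeds(b9, p)
  expect_equal(nrow(s9), 1L)
  # fully non-conserved alignment -> nothing
  b0 <- block_from(strrep("A", 20), strrep("C", 20), strrep("G", 20),
                   strrep("T", 20))
  expect_equal(nrow(find_seeds(b0, p)), 0L)
})

test_that("extension tolerates up to three non-conserved columns per side", {
  p <- scan_params()
  # seed of 10 then C,C,X,C: right edge should take all four, end conserved
  ref <- paste0(strrep("G", 3), strrep("A", 10), "AATA", strrep("G", 3))
  oth <- paste0(strrep("C", 3), strrep("A", 10), "AACA", strrep("G", 3))
  # careful: make flanks non-conserved via mismatch, tail conserved
  b <- block_from(ref, oth, oth, oth)
  cons <- conserved_columns(b, p)
  seed <- find_seeds(b, p, conserved = cons)[1L, ]
  ext <- extend_seed(b, seed, p, conserved = cons)
  expect_equal(ext$end_col, 20L)  # includes trailing GGG (conserved)
  # seed followed only by non-conserved -> trimmed back to the seed
  ref2 <- paste0(strrep("A", 10), strrep("A", 4))
  oth2 <- paste0(strrep("A", 10), strrep("C", 4))
  b2 <- block_from(ref2, oth2, oth2, oth2)
  cons2 <- conserved_columns(b2, p)
  seed2 <- find_seeds(b2, p, conserved = cons2)[1L, ]
  ext2 <- extend_seed(b2, seed2, p, conserved = cons2)
  expect_equal(c(ext2$start_col, ext2$end_col), c(1L, 10L))
})

test_that("scan equals the exhaustive interval oracle on random blocks", {
  set.seed(202)
  p <- scan_params()
  n_cases <- 60L
  for (case in seq_len(n_cases)) {
    b <- random_block(ncol = sample(20:60, 1L), nspecies = 6L,
                      p_match = runif(1, 0.7, 0.99), p_gap = 0.03)
    cons <- conserved_columns(b, p)
    refbase <- block_matrix(b)[1L, ] != "-"
    want <- oracle_scan_columns(cons, refbase)
    got <- scan_cnes(b, params = scan_params(fish_presence_min_cover = 0))
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      # reference has no gaps in these blocks: columns map 1:1 to coords
      expect_equal(got$start + 1L, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("masking splits blocks and scanning never crosses masks", {
  b <- random_block(ncol = 50L, p_match = 0.95)
  m <- genomic_intervals("chrT", 20, 31)
  pieces <- mask_block(b, m)
  expect_length(pieces, 2L)
  expect_equal(block_ncol(pieces[[1L]]), 20L)
  expect_equal(block_ncol(pieces[[2L]]), 19L)
  expect_equal(pieces[[2L]]$rows$start[1L], 31L)
  # empty mask -> unchanged; full mask -> nothing
  expect_length(mask_block(b, genomic_intervals()), 1L)
  expect_length(mask_block(b, genomic_intervals("chrT", 0, 50)), 0L)
  expect_warning(mask_block(b, genomic_intervals("chrT", 100, 200)),
                 "outside block")
  # no CNE overlaps a masked column
  sim <- make_planted_alignment(length = 1500, cne_lengths = c(25L, 25L),
                                seed = 5)
  masks <- genomic_intervals("ref_region", c(100, 700), c(200, 800))
  calls <- scan_cnes(sim$block, masks, scan_params())
  for (i in seq_len(nrow(calls))) {
    expect_false(any(calls$start[i] < masks$end & calls$end[i] > masks$start))
  }
})

test_that("fish retention rule drops elements without fish support", {
  # planted element carried only by tetrapod rows: all fish rows gapped there
  core <- strrep("A", 30)
  flank <- function() paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                            collapse = "")
  set.seed(9)
  reftxt <- paste0(flank(), core, flank())
  fish <- paste0(flank(), strrep("-", 30), flank())
  tetra <- paste0(flank(), core, flank())
  b <- block_from(reftxt, fish, fish, fish, tetra, tetra, tetra, n_fish = 3L)
  expect_equal(nrow(scan_cnes(b, params = scan_params())), 0L)
  # with the presence filter disabled the element comes back
  relaxed <- scan_params(fish_presence_min_cover = 0)
  expect_gt(nrow(scan_cnes(b, params = relaxed)), 0L)
  # a block with no fish species at all is a configuration error
  b2 <- block_from("AAAA", "AAAA", n_fish = 0L)
  expect_error(scan_cnes(b2, params = scan_params()), "fish")
})

test_that("lowering the column threshold never increases CNE coverage", {
  set.seed(303)
  for (rep in 1:10) {
    b <- random_block(ncol = 60L, nspecies = 8L, p_match = 0.9)
    cover <- vapply(c(0.30, 0.12, 0.05), function(th) {
      calls <- scan_cnes(b, params = scan_params(
        column_substitution_threshold = th, fish_presence_min_cover = 0))
      sum(calls$end - calls$start)
    }, numeric(1))
    expect_true(all(diff(cover) <= 0))
  }
})

test_that("every CNE contains a qualifying seed window", {
  set.seed(404)
  p <- scan_params()
  b <- random_block(ncol = 60L, nspecies = 8L, p_match = 0.92)
  calls <- scan_cnes(b, params = scan_params(fish_presence_min_cover = 0))
  cons <- conserved_columns(b, p)
  for (i in seq_len(nrow(calls))) {
    cols <- (calls$start[i] + 1L):calls$end[i]  # ref ungapped here
    has_seed <- FALSE
    for (s in cols) {
      e <- s + p$seed_length - 1L
      if (e > max(cols)) break
      if (sum(cons[s:e]) >= ceiling(p$seed_identity * p$seed_length)) {
        has_seed <- TRUE
        break
      }
    }
    expect_true(has_seed)
  }
})
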