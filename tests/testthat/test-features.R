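test_that("window extraction returns profile rows -5..+10 and flags edges", {
  seq16 <- "ACDEFGHIKLMNPQRS"
  rec <- onehot_record("w", seq16)
  block <- make_position_window(rec, 5L)
  expect_equal(dim(block), c(16L, 20L))
  expect_equal(rownames(block), as.character(-5:10))
  # one-hot profile: each row is a unit vector at the sequence letter
  chars <- strsplit(seq16, "")[[1]]
  for (r in 1:16) {
    expect_equal(sum(block[r, ]), 1)
    expect_equal(names(which(block[r, ] == 1)), chars[r])
  }
  expect_error(make_position_window(rec, 2L), class = "lrr_edge_position")
  expect_error(make_position_window(rec, 6L), class = "lrr_edge_position")
  expect_true(all(is_edge_position(c(0, 4, 6, 15), 16)))
  expect_false(is_edge_position(5, 16))
})

test_that("feature vectors have documented length and layout", {
  rec <- onehot_record("w", "ACDEFGHIKLMNPQRS")
  block <- make_position_window(rec, 5L)
  v <- assemble_feature_vector(block)
  expect_length(v, 320)
  # position-major: first 20 entries are window position -5 (residue A)
  expect_equal(v[1:20], unname(block[1, ]))
  str_block <- matrix(rep(c(0.2, 0.6, 0.2, 0.5, 0.3, 0.2, 0.1), each = 16),
                      16, 7)
  v2 <- assemble_feature_vector(block, str_block)
  expect_length(v2, 432)
  expect_equal(v2[321:327], str_block[1, ])
  expect_error(assemble_feature_vector(block, str_block[1:6, ]), "16 x 7")
})

test_that("standardizer centers and scales on training statistics only", {
  x <- cbind(a = c(0, 2), b = c(5, 5))
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  expect_equal(unname(z[, 1]), c(-1, 1))  # two-point z-score
  expect_equal(unname(z[, 2]), c(0, 0))   # constant column -> zeros
  # test-set transform reuses training statistics
  z_test <- apply_standardizer(std, cbind(a = c(10, 12), b = c(7, 9)))
  expect_false(isTRUE(all.equal(mean(z_test[, 1]), 0)))
  expect_error(apply_standardizer(list(), x), "not been fitted")
  expect_error(apply_standardizer(std, matrix(0, 2, 3)), "mismatch")
})

test_that("standardizer is invariant to training-sample order", {
  set.seed(7)
  x <- matrix(rnorm(50 * 8), 50, 8)
  s1 <- fit_standardizer(x)
  s2 <- fit_standardizer(x[sample(50), ])
  expect_equal(s1$center, s2$center)
  expect_equal(s1$scale, s2$scale)
})

test_that("standardized training features have zero mean and unit scale", {
  set.seed(8)
  x <- matrix(rnorm(40 * 6, mean = 3, sd = 2), 40, 6)
  z <- apply_standardizer(fit_standardizer(x), x)
  expect_true(all(abs(colMeans(z)) < 1e-6))
  pop_sd <- sqrt(colMeans(sweep(z, 2, colMeans(z), "-")^2))
  expect_true(all(abs(pop_sd - 1) < 1e-6))
})

test_that("pseudo-profiles behave across the temperature range", {
  p <- pseudo_profile_from_sequence("LIV")
  expect_equal(dim(p), c(3L, 20L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  # near-zero temperature concentrates on the residue itself (BLOSUM62 rows
  # peak on the diagonal)
  cold <- pseudo_profile_from_sequence("WLC", temperature = 0.05)
  expect_equal(colnames(cold)[apply(cold, 1, which.max)], c("W", "L", "C"))
  expect_true(all(apply(cold, 1, max) > 0.99))
  hot <- pseudo_profile_from_sequence("WLC", temperature = 1e7)
  expect_true(all(abs(hot - 0.05) < 1e-4))
  # non-standard residues get uniform columns
  px <- pseudo_profile_from_sequence("X")
  expect_true(all(px == 0.05))
  expect_error(pseudo_profile_from_sequence("LIV", temperature = 0),
               "positive")
})

test_that("profile and structural tables read back from disk", {
  std <- amino_alphabet()$standard20
  prof <- matrix(runif(5 * 20), 5, 20, dimnames = list(NULL, std))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", paste(std, collapse = "\t"),
               apply(prof, 1, paste, collapse = "\t")), path)
  got <- read_profile_table(path)
  expect_equal(got, prof, tolerance = 1e-6)
  norm <- read_profile_table(path, normalize = TRUE)
  expect_true(all(abs(rowSums(norm) - 1) < 1e-9))

  str_tab <- cbind(matrix(1 / 3, 4, 3), matrix(1 / 3, 4, 3), 0.2)
  spath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(lrrscan:::STRUCTURAL_COLS, collapse = "\t"),
               apply(str_tab, 1, paste, collapse = "\t")), spath)
  sgot <- read_structural_table(spath)
  expect_equal(unname(sgot), unname(str_tab), tolerance = 1e-6)
})
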