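test_that("alphabet sets partition as documented", {
  a <- amino_alphabet()
  expect_setequal(union(a$strict_leu, a$hydrophobic_nonleu), a$hydrophobic)
  expect_length(intersect(a$strict_leu, a$hydrophobic_nonleu), 0)
  expect_length(a$standard20, 20)
  expect_true(all(a$hydrophobic %in% a$standard20))
})

test_that("FASTA reading handles entries, order, and ambiguity flags", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "LSSLSL", ">b desc", "LSSXSL", "AA"), path)
  recs <- read_fasta(path)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(nchar(recs[[1]]$sequence), 6)
  expect_equal(recs[[2]]$id, "b")
  expect_equal(recs[[2]]$sequence, "LSSXSLAA")
  expect_equal(recs[[2]]$nonstandard, 3L)  # 0-based position of X
  expect_length(recs[[1]]$nonstandard, 0)
})

test_that("FASTA reader rejects empty and malformed input", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("LSSLSL", ">a", "AA"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("repeat annotations validate type, span containment and length", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain_id\tmotif_type\tl0_pos\tstart\tend",
               "c1\tL\t10\t5\t29"), path)
  ann <- read_repeat_annotations(path)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$motif_type, "L")
  expect_equal(ann$l0_pos, 10L)

  bad_type <- data.frame(chain_id = "c1", motif_type = "X", l0_pos = 10L,
                         start = 5L, end = 29L)
  expect_error(validate_annotations(bad_type), "row 1.*not one of N, L, C")
  outside <- data.frame(chain_id = "c1", motif_type = "L", l0_pos = 40L,
                        start = 5L, end = 29L)
  expect_error(validate_annotations(outside), "outside span")

  hdr_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chain_id\tmotif_type\tl0_pos\tstart\tend", hdr_only)
  expect_equal(nrow(read_repeat_annotations(hdr_only)), 0)
})

test_that("prediction output round-trips and GFF3 uses 1-based coordinates", {
  calls <- data.frame(chain_id = "c1", l0 = 9L, probability = 0.75,
                      start = 9L, end = 33L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_motif_predictions(calls, tsv, "tsv")
  expect_equal(read_motif_predictions(tsv, "tsv"), calls)

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_motif_predictions(calls, gff, "gff3")
  lines <- readLines(gff)
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(fields[4]), 10L)   # 0-based 9 -> 1-based 10
  expect_equal(as.integer(fields[5]), 33L)   # half-open end == inclusive end
  expect_true(as.integer(fields[4]) <= as.integer(fields[5]))
  expect_equal(fields[3], "repeat_region")
  expect_true(as.numeric(fields[6]) >= 0 && as.numeric(fields[6]) <= 1)
  expect_equal(read_motif_predictions(gff, "gff3"), calls)

  none <- calls[0, ]
  write_motif_predictions(none, gff, "gff3")
  expect_equal(readLines(gff), "##gff-version 3")
  expect_error(write_motif_predictions(calls, tsv, "bed"))
})

test_that("NCBI-format substitution matrices read back identically", {
  b <- blosum62()
  path <- withr::local_tempfile(fileext = ".mat")
  std <- amino_alphabet()$standard20
  lines <- c("# test matrix", paste(std, collapse = " "),
             vapply(std, function(r) {
               paste(c(r, b$s[r, ]), collapse = " ")
             }, ""))
  writeLines(lines, path)
  m <- read_substitution_matrix(path)
  expect_equal(m$s, b$s)
  expect_equal(m$s["L", "I"], 2)
})

test_that("protein records validate profile and structural dimensions", {
  expect_error(protein_record("a", "LSSLSL", profile = matrix(0, 5, 20)),
               "5 rows")
  bad_str <- matrix(c(rep(c(0.5, 0.5, 0.1), 6)), 6, 3)
  expect_error(protein_record("a", "LSSLSL", structural = bad_str),
               "7 columns")
  ok_str <- cbind(matrix(1 / 3, 6, 3), matrix(1 / 3, 6, 3), 0.1)
  rec <- protein_record("a", "LSSLSL", structural = ok_str)
  expect_equal(dim(rec$structural), c(6L, 7L))
  unnorm <- ok_str; unnorm[1, 1] <- 0.9
  expect_error(protein_record("a", "LSSLSL", structural = unnorm), "sum to 1")
})

test_that("the metric-repaired matrix induces a residue-level metric", {
  d <- lrrscan:::residue_distance_table(metric_blosum62())
  expect_true(all(abs(diag(d)) < 1e-12))
  expect_equal(d, t(d))
  for (k in 1:20) {
    expect_true(all(d <= outer(d[, k], d[k, ], "+") + 1e-9))
  }
})
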