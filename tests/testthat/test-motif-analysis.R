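test_that("motif distance follows the score-difference definition", {
  b <- blosum62()
  # s(L,L)=4, s(I,I)=4, s(L,I)=2 -> d = 4 + 4 - 2*2 = 4
  expect_equal(motif_distance("L", "I", b), 4)
  expect_equal(motif_distance("LL", "II", b), 8)
  set.seed(51)
  for (i in 1:50) {
    a <- random_sequence(16); w <- random_sequence(16)
    expect_equal(motif_distance(a, a), 0)
    expect_equal(motif_distance(a, w), motif_distance(w, a))
  }
  expect_error(motif_distance("LL", "I"), "equal length")
  expect_error(motif_distance("JX", "LL"), "not covered")
})

test_that("distance matrix matches the brute-force oracle exactly", {
  set.seed(52)
  motifs <- random_motifs(25)
  for (mat in list(metric_blosum62(), blosum62())) {
    dm <- motif_distance_matrix(motifs, mat)
    expect_equal(dm$D, t(dm$D))
    expect_true(all(diag(dm$D) == 0))
    for (i in sample(25, 6)) {
      for (j in sample(25, 6)) {
        expect_identical(dm$D[i, j],
                         oracle_motif_distance(motifs[i], motifs[j], mat$s))
      }
    }
  }
})

test_that("silhouettes separate distinct motif populations and not clones", {
  set.seed(53)
  mutate <- function(base, k, subs) {
    vapply(1:k, function(i) {
      ch <- strsplit(base, "")[[1]]
      ch[sample(16, 1)] <- sample(subs, 1)   # conservative single mutation
      paste(ch, collapse = "")
    }, "")
  }
  tight_a <- mutate("LLLLLLLLLLLLLLLL", 20, c("I", "V", "M"))
  tight_b <- mutate("DEDEDEDEDEDEDEDE", 20, c("N", "Q"))
  dm <- motif_distance_matrix(c(tight_a, tight_b))
  sil <- silhouette_between_groups(dm, rep(c("a", "b"), each = 20))
  expect_gte(sil$silhouette, 0.9)

  # one group a relabeled copy of the other: clusters coincide
  same <- random_motifs(60)
  dm2 <- motif_distance_matrix(c(same, same))
  sil2 <- silhouette_between_groups(dm2, rep(c("a", "b"), each = 60))
  expect_lt(abs(sil2$silhouette), 0.1)

  expect_error(silhouette_between_groups(dm, c("a", rep("b", 39))),
               "singleton")
  expect_error(silhouette_between_groups(dm, rep("a", 40)), "two groups")
  # three groups report all pairs
  sil3 <- silhouette_between_groups(dm, rep(c("a", "b"), 20))
  expect_equal(nrow(sil3), 1)
})

test_that("JSD conservation ranks invariant columns above background ones", {
  set.seed(54)
  q <- background_frequencies()
  bg_col <- vapply(1:400, function(i)
    paste0("L", names(q)[sample.int(20, 1, prob = q)]), "")
  motifs <- bg_col   # position 1 invariant L, position 2 background draw
  js <- jsd_conservation(motifs)
  expect_length(js, 2)
  expect_gt(js[1], 0.6)
  expect_lt(js[2], 0.1)
  expect_true(all(js >= 0 & js <= 1))
  expect_error(jsd_conservation(character(0)), "empty")
  expect_error(jsd_conservation(c("LL", "L")), "equal length")
})

test_that("consensus-class matching follows the window definitions", {
  # generic 11-residue consensus: hydrophobic 0/3/5, N or C at 8, hydrophobic
  # at 10 (window string starts at motif position -5)
  w <- "GGGGGLSSLSLSSNSL"
  m <- kk_consensus_match(w)
  expect_true(m[["W6"]])
  expect_true(m[["W11"]])
  expect_true(m[["RI"]])
  expect_true(is.na(m[["PS"]]))     # tail positions beyond the window

  allg <- paste(rep("G", 16), collapse = "")
  expect_false(any(kk_consensus_match(allg)[c("W6", "W11", "RI")]))

  # plant-specific type: N8, (S/T) at 11 and the GxIP tail
  ps <- paste0("GGLGG", "LSSLSL", "SSNSL", "TGAIP", "AA")
  mps <- kk_consensus_match(ps)
  expect_true(mps[["PS"]])
  expect_true(mps[["W11"]])
  expect_false(mps[["CC"]])

  expect_error(kk_consensus_match("LSSLSL"), "at least the 16")
})

test_that("logo frequencies and information content behave at the extremes", {
  same <- rep("LSSLSLSSNSLSGLIP", 30)
  logo <- position_frequency_logo(same)
  expect_equal(dim(logo$freq), c(16L, 20L))
  expect_true(all(abs(logo$bits - log2(20)) < 1e-9))
  expect_equal(unname(logo$freq[1, "L"]), 1)

  set.seed(55)
  rand <- random_motifs(5000, 4)
  logo2 <- position_frequency_logo(rand)
  expect_true(all(logo2$bits < 0.1))
  expect_true(all(abs(rowSums(logo2$freq) - 1) < 1e-9))

  # planted PS-style motifs: the minimal-motif positions carry the signal
  gens <- lapply(1:30, function(i)
    generate_lrr_protein(generator_config(), seed = 700 + i, n_repeats = 8))
  wins <- unlist(lapply(gens, function(g)
    extract_motif_windows(list(g$record), g$annotations)))
  wins <- wins[!is.na(wins)]
  logo3 <- position_frequency_logo(wins)
  top3 <- order(logo3$bits, decreasing = TRUE)[1:3]
  expect_setequal(top3, c(6, 9, 11))   # window indices of L0, L3, L5
  expect_error(position_frequency_logo(character(0)), "empty")
})

test_that("metric MDS embeds exactly-embeddable configurations at ~zero stress", {
  D3 <- matrix(2, 3, 3); diag(D3) <- 0
  em <- mds_embed(D3, seed = 2)
  expect_lt(em$stress1, 1e-4)
  side <- as.matrix(dist(em$coords))
  expect_true(all(abs(side[upper.tri(side)] - 2) < 1e-3))

  line <- as.matrix(dist(cbind(c(0, 1, 3, 7), 0)))
  expect_lt(mds_embed(line, seed = 2)$stress1, 1e-4)

  set.seed(56)
  X <- matrix(rnorm(30 * 20), 30, 20)
  D <- as.matrix(dist(X))
  e1 <- mds_embed(D, seed = 9)
  e2 <- mds_embed(D, seed = 9)
  expect_identical(e1$coords, e2$coords)
  expect_gt(e1$stress1, 0.05)     # 20-dim cloud cannot embed flat in 2D
  expect_lte(e1$stress1, 1)
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
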