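# Small separable problems keep these tests fast; the full-scale benchmark
# behaviour is exercised by the acceptance suite.

make_blob_data <- function(n = 240, d = 8, sep = 3, pos_frac = 0.25,
                           seed = 5) {
  set.seed(seed)
  n1 <- round(n * pos_frac)
  X <- rbind(matrix(rnorm((n - n1) * d), n - n1, d),
             matrix(rnorm(n1 * d, mean = sep), n1, d))
  y <- c(rep(0, n - n1), rep(1, n1))
  list(X = X, y = y)
}

test_that("classifier specifications encode the eight fixed members", {
  c1 <- classifier_spec("C1")
  expect_equal(c1$family, "svc_rbf")
  expect_equal(c1$mode, "seq")
  expect_equal(c1$cost, 1)
  expect_equal(c1$gamma, 0.01)
  expect_equal(c1$imbalance, "class_weight")
  expect_equal(c1$calibration, "sigmoid")
  c4 <- classifier_spec("C4")
  expect_equal(c4$family, "adaboost_stumps")
  expect_equal(c4$n_estimators, 50L)
  expect_equal(c4$calibration, "sigmoid")
  c5 <- classifier_spec("C5")
  expect_equal(c5$gamma, 0.001)
  expect_equal(c5$mode, "seqstr")
  # C1-C4 sequence-only, C5-C8 combined; SMOTETomek members are C3 and C7
  modes <- vapply(paste0("C", 1:8), function(i) classifier_spec(i)$mode, "")
  expect_equal(unname(modes), rep(c("seq", "seqstr"), each = 4))
  imb <- vapply(paste0("C", 1:8), function(i) classifier_spec(i)$imbalance, "")
  expect_equal(names(imb)[imb == "smotetomek"], c("C3", "C7"))
  hidden <- lapply(c("C2", "C3", "C6", "C7"),
                   function(i) classifier_spec(i)$hidden)
  expect_equal(hidden[[1]], c(300L, 250L, 100L))
  expect_equal(hidden[[4]], c(125L, 100L, 10L))
  expect_equal(classifier_spec("C6")$solver, "adam")
  expect_error(classifier_spec("C9"), "unknown classifier")
  expect_error(build_classifier("C0"), "unknown classifier")
})

test_that("MLP members learn a separable problem with both solvers", {
  blob <- make_blob_data()
  for (solver in c("lbfgs", "adam")) {
    m <- lrrscan:::mlp_fit(blob$X, blob$y, hidden = c(16L, 8L),
                           solver = solver,
                           maxit = if (solver == "adam") 300 else 60,
                           seed = 3, early_stopping = solver == "adam")
    p <- lrrscan:::mlp_predict_prob(m, blob$X)
    expect_gt(mean((p > 0.5) == (blob$y == 1)), 0.95)
    expect_true(all(p >= 0 & p <= 1))
  }
  m1 <- lrrscan:::mlp_fit(blob$X, blob$y, c(8L), "lbfgs", maxit = 30, seed = 3)
  m2 <- lrrscan:::mlp_fit(blob$X, blob$y, c(8L), "lbfgs", maxit = 30, seed = 3)
  expect_identical(m1$par, m2$par)   # seeded determinism
})

test_that("SMOTE+Tomek balances classes without touching the RNG state", {
  blob <- make_blob_data(n = 200, pos_frac = 0.1, sep = 4)
  set.seed(123); probe_before <- runif(1)
  rs <- lrrscan:::smote_tomek(blob$X, blob$y, seed = 9)
  expect_gt(mean(rs$y), 0.4)               # minority oversampled to balance
  expect_gte(nrow(rs$X), nrow(blob$X) * 1.5)
  set.seed(123); expect_identical(runif(1), probe_before)
  rs2 <- lrrscan:::smote_tomek(blob$X, blob$y, seed = 9)
  expect_identical(rs$X, rs2$X)
  expect_error(lrrscan:::smote_tomek(blob$X, rep(0, 200)), "both classes")
})

test_that("soft vote equals the member mean and training is reproducible", {
  blob <- make_blob_data(n = 300, d = 432, sep = 1.5, pos_frac = 0.2)
  model <- train_ensemble(blob$X, blob$y, seed = 4, members = c("C1", "C4"))
  pr <- ensemble_probabilities(model, blob$X)
  expect_equal(dim(pr$member), c(300L, 2L))
  expect_true(all(pr$member >= 0 & pr$member <= 1))
  expect_equal(pr$ensemble, rowMeans(pr$member), tolerance = 1e-15)
  model2 <- train_ensemble(blob$X, blob$y, seed = 4, members = c("C1", "C4"))
  pr2 <- ensemble_probabilities(model2, blob$X)
  expect_identical(pr$member, pr2$member)
  expect_error(train_ensemble(blob$X, rep(1, 300)), "both classes")
  expect_error(train_ensemble(blob$X[, 1:320], blob$y, members = "C5"),
               "structural")
})

test_that("prediction demands the inputs each member mode needs", {
  g <- generate_lrr_protein(generator_config(), seed = 21, n_repeats = 6)
  rec <- g$record
  blob <- make_blob_data(n = 250, d = 432, sep = 2, pos_frac = 0.2)
  model <- train_ensemble(blob$X, blob$y, seed = 4, members = c("C1", "C8"))
  expect_error(predict_motif_probabilities(model, rec), "profile")
  rec$profile <- generate_profile(rec, seed = 1, annotations = g$annotations)
  expect_error(predict_motif_probabilities(model, rec), "structural")
  rec$structural <- generate_structural_track(rec, g$annotations, seed = 2)
  track <- predict_motif_probabilities(model, rec)
  n <- nchar(rec$sequence)
  expect_length(track, n)
  expect_true(all(is.na(track[1:5])))            # upstream edge
  expect_true(all(is.na(track[(n - 9):n])))      # downstream edge
  expect_true(all(track[!is.na(track)] >= 0 & track[!is.na(track)] <= 1))
  member <- attr(track, "member")
  expect_equal(rowMeans(member)[!is.na(track)],
               track[!is.na(track)], tolerance = 1e-15)
})

test_that("evaluation report follows the closed-form definitions", {
  perfect <- evaluate_predictions(c(3, 10), c(3, 10))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  none <- evaluate_predictions(integer(0), c(3, 10))
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)

  ev <- evaluate_predictions(c(1:90, 1000 + 1:10), 1:100)
  expect_equal(ev$TP, 90L); expect_equal(ev$FP, 10L); expect_equal(ev$FN, 10L)
  expect_equal(ev$precision, 0.9)
  expect_equal(ev$recall, 0.9)
  expect_equal(ev$f1, 0.9)

  # offset tolerance consumes each truth position once
  tol <- evaluate_predictions(c(11, 12), c(10), tolerance = 2)
  expect_equal(tol$TP, 1L); expect_equal(tol$FP, 1L)
  expect_equal(evaluate_predictions(c(12), c(10), tolerance = 2)$TP, 1L)
  expect_equal(evaluate_predictions(c(14), c(10), tolerance = 2)$TP, 0L)
  expect_error(evaluate_predictions(1, c(3, 3)), "duplicate")

  with_tn <- evaluate_predictions(c(3), c(3), n_positions = 100)
  expect_equal(with_tn$TN, 99L)
})
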