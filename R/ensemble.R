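#' Specification of one ensemble member
#'
#' The ensemble aggregates eight fixed classifier configurations, C1-C8.
#' C1-C4 see sequence-profile features only (320); C5-C8 additionally see the
#' per-residue structural features (432). Families: RBF-kernel support vector
#' classifiers (C1, C5; cost 1, kernel scale 0.01 and 0.001, inverse-frequency
#' class weights, sigmoid-calibrated), three-hidden-layer ReLU perceptrons
#' (C2, C3, C6, C7; C3 and C7 train on SMOTE+Tomek-resampled data; C6 uses
#' Adam with early stopping over a 0.2 validation fraction, the rest L-BFGS)
#' and real (SAMME.R) AdaBoost over 50 depth-1 stumps (C4, C8,
#' sigmoid-calibrated).
#'
#' @param id one of "C1".."C8"
#' @return a \code{classifier_spec} list: id, family, mode ("seq"/"seqstr"),
#'   imbalance treatment, calibration, and family hyperparameters
#' @export
classifier_spec <- function(id) {
  specs <- list(
    C1 = list(family = "svc_rbf", mode = "seq", cost = 1, gamma = 0.01,
              imbalance = "class_weight", calibration = "sigmoid"),
    C2 = list(family = "mlp", mode = "seq", hidden = c(300L, 250L, 100L),
              solver = "lbfgs", imbalance = "none", calibration = "none"),
    C3 = list(family = "mlp", mode = "seq", hidden = c(250L, 150L, 100L),
              solver = "lbfgs", imbalance = "smotetomek", calibration = "none"),
    C4 = list(family = "adaboost_stumps", mode = "seq", n_estimators = 50L,
              imbalance = "none", calibration = "sigmoid"),
    C5 = list(family = "svc_rbf", mode = "seqstr", cost = 1, gamma = 0.001,
              imbalance = "class_weight", calibration = "sigmoid"),
    C6 = list(family = "mlp", mode = "seqstr", hidden = c(250L, 150L, 100L),
              solver = "adam", early_stopping = TRUE,
              validation_fraction = 0.2, imbalance = "none",
              calibration = "none"),
    C7 = list(family = "mlp", mode = "seqstr", hidden = c(125L, 100L, 10L),
              solver = "lbfgs", imbalance = "smotetomek", calibration = "none"),
    C8 = list(family = "adaboost_stumps", mode = "seqstr", n_estimators = 50L,
              imbalance = "none", calibration = "sigmoid"))
  if (!id %in% names(specs)) {
    stop("unknown classifier id '", id, "' (expected C1..C8)")
  }
  c(list(id = id), specs[[id]])
}

#' Build an untrained ensemble member from its specification
#'
#' @param spec a \code{classifier_spec} or classifier id string
#' @return an untrained member (spec plus empty model slot)
#' @export
build_classifier <- function(spec) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  structure(list(spec = spec, model = NULL, calib = NULL),
            class = "lrr_member")
}

# ---- internal member machinery -------------------------------------------

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  rng <- local_rng(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[rng$sample_perm(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

platt_fit <- function(dv, y) {
  fit <- suppressWarnings(
    stats::glm(y ~ dv, family = stats::binomial(),
               control = list(maxit = 100)))
  unname(stats::coef(fit))
}

platt_apply <- function(coefs, dv) {
  1 / (1 + exp(-(coefs[1] + coefs[2] * dv)))
}

svc_fit_raw <- function(X, y, spec, seed) {
  w <- length(y) / (2 * table(factor(y, levels = c(0, 1))))
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), type = "C-classification",
                    kernel = "radial", cost = spec$cost, gamma = spec$gamma,
                    class.weights = stats::setNames(as.numeric(w), names(w)),
                    scale = FALSE)
  dv <- as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                        "decision.values"))
  flip <- mean(dv[y == 1]) < mean(dv[y == 0])
  list(fit = fit, flip = flip)
}

svc_decision <- function(model, X) {
  dv <- as.numeric(attr(stats::predict(model$fit, X, decision.values = TRUE),
                        "decision.values"))
  if (model$flip) -dv else dv
}

adaboost_fit_raw <- function(X, y, spec, seed) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  ypm <- ifelse(y == 1, 1, -1)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  stumps <- vector("list", spec$n_estimators)
  eps <- 1e-10
  for (m in seq_len(spec$n_estimators)) {
    df$.y <- factor(y, levels = c(0, 1))
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, minsplit = 2, minbucket = 1,
                          cp = -1, xval = 0, maxsurrogate = 0,
                          usesurrogate = 0, maxcompete = 0))
    p1 <- pmin(pmax(stats::predict(fit, df)[, "1"], eps), 1 - eps)
    h <- 0.5 * log(p1 / (1 - p1))
    stumps[[m]] <- fit
    w <- w * exp(-ypm * h)
    s <- sum(w)
    if (s <= 0 || !is.finite(s)) break
    w <- w / s
  }
  list(stumps = stumps[!vapply(stumps, is.null, TRUE)])
}

adaboost_decision <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  eps <- 1e-10
  dv <- numeric(nrow(X))
  for (fit in model$stumps) {
    p1 <- pmin(pmax(stats::predict(fit, df)[, "1"], eps), 1 - eps)
    dv <- dv + 0.5 * log(p1 / (1 - p1))
  }
  dv
}

# Fit one member on standardized features (calibration uses 3 internal
# stratified folds of out-of-fold decision values, then a final fit on all
# training data).
fit_member <- function(spec, X, y, seed, mlp_maxit = 150L, calib_folds = 3L) {
  member <- build_classifier(spec)
  spec <- member$spec
  if (spec$imbalance == "smotetomek") {
    rs <- smote_tomek(X, y, seed = seed)
    X <- rs$X; y <- rs$y
  }
  if (spec$family == "mlp") {
    member$model <- mlp_fit(
      X, y, hidden = spec$hidden, solver = spec$solver,
      alpha = spec$alpha %||% 0.5,
      maxit = if (spec$solver == "adam") 60L else mlp_maxit, seed = seed,
      early_stopping = isTRUE(spec$early_stopping),
      validation_fraction = spec$validation_fraction %||% 0.2)
    return(member)
  }
  fit_raw <- switch(spec$family,
                    svc_rbf = svc_fit_raw,
                    adaboost_stumps = adaboost_fit_raw,
                    stop("unknown family ", spec$family))
  decision <- switch(spec$family,
                     svc_rbf = svc_decision,
                     adaboost_stumps = adaboost_decision)
  if (spec$calibration == "sigmoid") {
    fold <- stratified_folds(y, calib_folds, seed + 7L)
    dv_oof <- numeric(length(y))
    for (f in seq_len(calib_folds)) {
      tr <- fold != f
      sub <- fit_raw(X[tr, , drop = FALSE], y[tr], spec, seed + f)
      dv_oof[!tr] <- decision(sub, X[!tr, , drop = FALSE])
    }
    member$calib <- platt_fit(dv_oof, y)
  }
  member$model <- fit_raw(X, y, spec, seed)
  member
}

predict_member <- function(member, X) {
  spec <- member$spec
  if (spec$family == "mlp") return(mlp_predict_prob(member$model, X))
  dv <- switch(spec$family,
               svc_rbf = svc_decision(member$model, X),
               adaboost_stumps = adaboost_decision(member$model, X))
  if (!is.null(member$calib)) platt_apply(member$calib, dv)
  else 1 / (1 + exp(-dv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ensemble ------------------------------------------------------------

#' Train the eight-member soft-voting ensemble
#'
#' Fits the per-mode feature standardizers on the training data, resamples
#' inside the SMOTE+Tomek members, trains all eight members and stores
#' everything needed for prediction. One master seed fans out to the
#' resampler, network initialisation and calibration folds, so two runs with
#' the same data and seed give identical predictions.
#'
#' @param X feature matrix with 432 columns (320 profile + 112 structural
#'   features) — sequence-only members use the first 320 columns
#' @param y 0/1 labels (1 = motif start)
#' @param seed master RNG seed
#' @param members which members to train (default all of C1..C8)
#' @param mlp_maxit L-BFGS iteration cap for the perceptron members
#' @return an \code{lrr_ensemble} model
#' @export
train_ensemble <- function(X, y, seed = 1L, members = paste0("C", 1:8),
                           mlp_maxit = 150L) {
  X <- as.matrix(X); y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training data must contain both classes")
  if (ncol(X) != 432 && ncol(X) != 320) {
    stop("expected 320 or 432 feature columns, got ", ncol(X))
  }
  specs <- lapply(members, classifier_spec)
  if (ncol(X) == 320 &&
      any(vapply(specs, function(s) s$mode, "") == "seqstr")) {
    stop("structural features (columns 321-432) are required for C5-C8")
  }
  mode_cols <- list(seq = seq_len(320), seqstr = seq_len(ncol(X)))
  stds <- lapply(mode_cols, function(cols)
    fit_standardizer(X[, cols, drop = FALSE]))
  fitted <- vector("list", length(specs))
  names(fitted) <- members
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    cols <- mode_cols[[sp$mode]]
    Xs <- apply_standardizer(stds[[sp$mode]], X[, cols, drop = FALSE])
    fitted[[i]] <- fit_member(sp, Xs, y, seed = seed + 100L * i,
                              mlp_maxit = mlp_maxit)
  }
  structure(list(members = fitted, standardizers = stds,
                 mode_cols = mode_cols, seed = seed),
            class = "lrr_ensemble")
}

#' @export
print.lrr_ensemble <- function(x, ...) {
  cat("<lrr_ensemble> soft voter over",
      paste(names(x$members), collapse = ", "), "\n")
  invisible(x)
}

#' Member and soft-vote probabilities for a feature matrix
#'
#' @param model an \code{lrr_ensemble}
#' @param X raw (unstandardized) feature matrix, 432 (or 320) columns as in
#'   training
#' @return list with \code{member} (n x members probability matrix) and
#'   \code{ensemble} (unweighted mean across members)
#' @export
ensemble_probabilities <- function(model, X) {
  X <- as.matrix(X)
  probs <- vapply(model$members, function(mb) {
    cols <- model$mode_cols[[mb$spec$mode]]
    Xs <- apply_standardizer(model$standardizers[[mb$spec$mode]],
                             X[, cols, drop = FALSE])
    predict_member(mb, Xs)
  }, numeric(nrow(X)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  list(member = probs, ensemble = rowMeans(probs))
}

#' Per-position LRR motif probability track for one protein
#'
#' Scores every position with full extended-window context; edge positions
#' (fewer than 5 residues upstream or 10 downstream) are reported as NA.
#' Member probabilities are attached as the \code{"member"} attribute for
#' inspection.
#'
#' @param model an \code{lrr_ensemble}
#' @param record a \code{protein_record} with profile (and structural table
#'   when the ensemble contains combined-feature members)
#' @return numeric track of length \code{nchar(sequence)}
#' @export
predict_motif_probabilities <- function(model, record) {
  needs_str <- any(vapply(model$members,
                          function(mb) mb$spec$mode == "seqstr", TRUE))
  if (is.null(record$profile)) {
    stop("record '", record$id, "' has no sequence profile")
  }
  if (needs_str && is.null(record$structural)) {
    stop("record '", record$id, "' has no structural features, required ",
         "by combined-feature members")
  }
  n <- nchar(record$sequence)
  track <- rep(NA_real_, n)
  pos <- which(!is_edge_position(0:(n - 1L), n)) - 1L
  if (length(pos) == 0) return(track)
  feats <- build_feature_matrix(record, pos, with_structural = needs_str)
  pr <- ensemble_probabilities(model, feats)
  track[pos + 1L] <- pr$ensemble
  member <- matrix(NA_real_, n, ncol(pr$member),
                   dimnames = list(NULL, colnames(pr$member)))
  member[pos + 1L, ] <- pr$member
  attr(track, "member") <- member
  track
}

#' Build the feature matrix for a set of candidate positions
#'
#' @param record \code{protein_record} with profile (and structural features
#'   when \code{with_structural})
#' @param positions 0-based candidate L0 positions, all non-edge
#' @param with_structural append the 112 structural features
#' @return matrix of one feature row per position
#' @export
build_feature_matrix <- function(record, positions, with_structural = TRUE) {
  t(vapply(positions, function(p) {
    block <- make_position_window(record, p)
    str_block <- if (with_structural) {
      record$structural[(p - EXTENDED_OFFSET):(p + 10L) + 1L, , drop = FALSE]
    }
    assemble_feature_vector(block, str_block)
  }, numeric(if (with_structural) 432 else 320)))
}

#' Score motif predictions against truth positions
#'
#' Exact-position matching by default; an optional tolerance of k residues
#' accepts calls offset by up to k from a truth L0 (each truth position is
#' consumed by at most one call), which quantifies the alignment-artefact
#' offsets of 1-3 residues seen in profile-based predictions.
#'
#' @param calls integer vector of predicted L0 positions
#' @param truth integer vector of annotated L0 positions (no duplicates)
#' @param tolerance maximum |call - truth| counted as a hit (default 0)
#' @param n_positions optional number of scored candidate positions, enables
#'   the TN count
#' @return list: TP, FP, FN, TN, precision, recall, f1,
#'   \code{precision_defined} flag (FALSE when there were no calls)
#' @export
evaluate_predictions <- function(calls, truth, tolerance = 0L,
                                 n_positions = NA_integer_) {
  if (anyDuplicated(truth)) stop("duplicate truth positions")
  calls <- sort(unique(as.integer(calls)))
  truth <- sort(as.integer(truth))
  tp <- 0L
  used <- rep(FALSE, length(truth))
  for (cl in calls) {
    cand <- which(!used & abs(truth - cl) <= tolerance)
    if (length(cand)) {
      used[cand[which.min(abs(truth[cand] - cl))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(calls) - tp
  fn <- length(truth) - tp
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if ((tp + fn) > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(TP = tp, FP = fp, FN = fn,
       TN = if (is.na(n_positions)) NA_integer_
            else n_positions - tp - fp - fn,
       precision = precision, recall = recall, f1 = f1,
       precision_defined = precision_defined)
}
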