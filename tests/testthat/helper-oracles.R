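# Independent oracles and fixture builders shared across the suite.

# Brute-force LxxLxL scan: explicit double loop, no vectorized reuse of the
# implementation's machinery.
oracle_scan <- function(sequence) {
  hyd <- c("L", "I", "V", "M", "F", "W", "Y", "C", "A")
  chars <- strsplit(sequence, "")[[1]]
  out <- integer(0)
  n <- length(chars)
  p <- 1L
  while (p + 5L <= n) {
    ok <- TRUE
    for (off in c(0L, 3L, 5L)) {
      if (!(chars[p + off] %in% hyd)) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, p - 1L)
    p <- p + 1L
  }
  out
}

# Per-position brute-force motif distance from raw score lookups.
oracle_motif_distance <- function(a, b, s) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  tot <- 0
  for (i in seq_along(ca)) {
    tot <- tot + s[ca[i], ca[i]] + s[cb[i], cb[i]] - 2 * s[ca[i], cb[i]]
  }
  tot
}

# Exhaustive merge for motif clustering: repeatedly drop the lower-probability
# member (leftmost on ties) of the closest conflicting pair.
oracle_cluster <- function(pos, prob, min_sep = 15L) {
  repeat {
    if (length(pos) < 2) break
    gaps <- diff(pos)
    if (all(gaps >= min_sep)) break
    i <- which(gaps == min(gaps[gaps < min_sep]) & gaps < min_sep)[1]
    drop <- if (prob[i + 1] > prob[i]) i else i + 1
    pos <- pos[-drop]; prob <- prob[-drop]
  }
  list(pos = pos, prob = prob)
}

random_sequence <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

random_motifs <- function(n, len = 16) {
  vapply(seq_len(n), function(i) random_sequence(len), "")
}

# One-hot profile record: profile rows are unit vectors at the sequence
# letters, handy for exact window checks.
onehot_record <- function(id, sequence) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(sequence, "")[[1]]
  prof <- matrix(0, length(chars), 20, dimnames = list(NULL, std))
  prof[cbind(seq_along(chars), match(chars, std))] <- 1
  protein_record(id, sequence, profile = prof)
}

# The synthetic benchmark and trained ensemble are expensive; train once per
# session and share across test files.
.acceptance_cache <- new.env(parent = emptyenv())

cached_benchmark <- function() {
  if (is.null(.acceptance_cache$bench)) {
    .acceptance_cache$bench <- generate_benchmark(generator_config(), seed = 17)
  }
  .acceptance_cache$bench
}

cached_model <- function() {
  if (is.null(.acceptance_cache$model)) {
    bench <- cached_benchmark()
    tr <- bench$split != "test"
    .acceptance_cache$model <- train_ensemble(bench$X[tr, ], bench$y[tr],
                                              seed = 17)
  }
  .acceptance_cache$model
}
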