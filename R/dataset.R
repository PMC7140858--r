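#' Extract 16-residue extended-motif windows for annotated repeats
#'
#' @param records list of \code{protein_record}s
#' @param annotations repeat-annotation data.frame
#' @return character vector of 16-aa windows (NA where the annotated L0 is an
#'   edge position), aligned with annotation rows
#' @export
extract_motif_windows <- function(records, annotations) {
  ids <- vapply(records, function(r) r$id, "")
  vapply(seq_len(nrow(annotations)), function(i) {
    rec <- records[[match(annotations$chain_id[i], ids)]]
    if (is.na(match(annotations$chain_id[i], ids))) {
      stop("annotation chain '", annotations$chain_id[i], "' not in records")
    }
    l0 <- annotations$l0_pos[i]
    n <- nchar(rec$sequence)
    if (is_edge_position(l0, n)) return(NA_character_)
    substr(rec$sequence, l0 - EXTENDED_OFFSET + 1L, l0 + 10L + 1L)
  }, "")
}

#' Positional identity between two equal-length windows
#'
#' @param a,b residue strings of equal length
#' @return number of positions with identical residues
#' @export
window_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("windows must have equal length")
  sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Greedy repeat-level redundancy filter (ID50)
#'
#' Walks the repeats in input order and keeps one only if its 16-residue
#' extended window shares fewer than 8 identical positions (strictly) with
#' every previously kept window — i.e., below 50% identity over the window.
#' The pass is order-dependent but idempotent: re-filtering its own output
#' changes nothing.
#'
#' @param windows character vector of 16-aa extended windows, in input order
#' @param max_identical windows with this many or more matching positions to a
#'   kept window are dropped (default 8)
#' @return integer vector of kept indices into \code{windows}
#' @export
filter_id50 <- function(windows, max_identical = 8L) {
  bad_len <- which(nchar(windows) != EXTENDED_LEN)
  if (length(bad_len)) {
    stop("window ", bad_len[1], " has length ", nchar(windows[bad_len[1]]),
         ", expected 16")
  }
  mat <- do.call(rbind, strsplit(windows, ""))
  kept <- integer(0)
  for (i in seq_along(windows)) {
    if (length(kept) == 0) { kept <- i; next }
    ident <- rowSums(mat[kept, , drop = FALSE] ==
                       matrix(mat[i, ], nrow = length(kept),
                              ncol = EXTENDED_LEN, byrow = TRUE))
    if (all(ident < max_identical)) kept <- c(kept, i)
  }
  kept
}

#' Cross-set redundancy filter over full sequences and repeat windows
#'
#' Removes the later member of every pair that fails any of three bounds,
#' computed from local pairwise alignments (BLOSUM62, gap open 11 / extend 1):
#' (a) alignment length > 100 with identity > 20%; (b) alignment length in
#' \[40, 100\] with identity > 20% and overlap > 60% of both sequences;
#' (c) for repeat-window entries, alignment length >= 16 with identity >= 50%.
#' Identity is identities / alignment length (gap columns included); overlap
#' is the aligned span divided by the sequence length, per sequence.
#'
#' @param sequences character vector of sequences, in input order
#' @param is_repeat_window logical vector: TRUE entries are 16-aa repeat
#'   windows subject to bound (c) rather than (a)/(b)
#' @return integer vector of kept indices
#' @export
cross_redundancy_filter <- function(sequences,
                                    is_repeat_window =
                                      rep(FALSE, length(sequences))) {
  stopifnot(length(is_repeat_window) == length(sequences))
  n <- length(sequences)
  if (n <= 1) return(seq_len(n))
  kept <- integer(0)
  for (i in seq_len(n)) {
    redundant <- FALSE
    for (j in kept) {
      both_windows <- is_repeat_window[i] && is_repeat_window[j]
      # windows are compared over their full span (global alignment), full
      # sequences by local alignment
      st <- alignment_stats(sequences[j], sequences[i],
                            type = if (both_windows) "global" else "local")
      if (both_windows) {
        if (st$length >= 16 && st$identity >= 0.5) { redundant <- TRUE; break }
      } else {
        if (st$length > 100 && st$identity > 0.2) { redundant <- TRUE; break }
        if (st$length >= 40 && st$length <= 100 && st$identity > 0.2 &&
            st$overlap1 > 0.6 && st$overlap2 > 0.6) { redundant <- TRUE; break }
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  kept
}

# Local alignment statistics for the redundancy filter: alignment length
# (gapped columns included), fractional identity, and per-sequence overlap of
# the aligned span.
alignment_stats <- function(a, b, type = "local") {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = type, substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  pat_rng <- aln@pattern@range
  sub_rng <- aln@subject@range
  list(length = len,
       identity = if (len > 0) Biostrings::nmatch(aln) / len else 0,
       overlap1 = BiocGenerics::width(pat_rng) / nchar(a),
       overlap2 = BiocGenerics::width(sub_rng) / nchar(b))
}

#' Stratified 5-way split into test and cross-validation folds
#'
#' Partitions sample indices into five parts of near-equal size within each
#' class, preserving the class ratio. Part 1 is the held-out test set; parts
#' 2-5 are the cross-validation folds. Deterministic under a fixed seed.
#'
#' @param labels 0/1 class labels
#' @param n_parts number of parts (default 5)
#' @param seed RNG seed
#' @return factor of length \code{length(labels)} with levels "test",
#'   "cv1".."cv4" (or "cv(n_parts-1)")
#' @export
make_splits <- function(labels, n_parts = 5L, seed = 1L) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  small <- classes[vapply(classes, function(cl) sum(labels == cl), 0L) < n_parts]
  if (length(small)) {
    stop("class ", small[1], " has fewer than ", n_parts, " members")
  }
  part <- integer(length(labels))
  rng <- local_rng(seed)
  for (cl in classes) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample_perm(length(idx))]
    part[idx] <- rep_len(seq_len(n_parts), length(idx))
  }
  lv <- c("test", paste0("cv", seq_len(n_parts - 1L)))
  factor(lv[part], levels = lv)
}

# Seeded RNG scoped to a closure so callers' RNG state is untouched.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample_perm = function(n) with_state(function() sample.int(n)),
    runif = function(n) with_state(function() stats::runif(n)),
    draw = function(f) with_state(f)
  )
}
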