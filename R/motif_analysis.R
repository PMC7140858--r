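# Per-residue distance table induced by a substitution matrix:
# d(i,j) = s(i,i) + s(j,j) - 2 s(i,j). Zero on the diagonal, symmetric; for
# suitably built score matrices it is also a metric across residues.
residue_distance_table <- function(matrix) {
  s <- matrix$s
  outer(diag(s), diag(s), "+") - 2 * s
}

#' BLOSUM-metric distance between two equal-length motifs
#'
#' Sums the per-residue distances d(a_i, b_i) = s(a_i,a_i) + s(b_i,b_i) -
#' 2 s(a_i,b_i) over the motif span. With a score matrix whose induced
#' per-residue distance is a metric (see [metric_blosum62()]), the motif
#' distance is a metric on sequence space.
#'
#' @param a,b residue strings of equal length
#' @param matrix a \code{substitution_matrix} (default the metric surrogate)
#' @return nonnegative numeric distance
#' @export
motif_distance <- function(a, b, matrix = metric_blosum62()) {
  if (nchar(a) != nchar(b)) stop("motifs must have equal length")
  d <- residue_distance_table(matrix)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (!all(c(ca, cb) %in% rownames(d))) {
    stop("motifs contain residues not covered by the substitution matrix")
  }
  sum(d[cbind(ca, cb)])
}

#' Pairwise motif distance matrix
#'
#' @param motifs character vector of equal-length motifs
#' @param matrix a \code{substitution_matrix}
#' @return an object of class \code{motif_distance_matrix}: list(motifs, D,
#'   matrix_name) with D symmetric, zero-diagonal
#' @export
motif_distance_matrix <- function(motifs, matrix = metric_blosum62()) {
  if (length(unique(nchar(motifs))) > 1) {
    stop("all motifs must have equal length")
  }
  d <- residue_distance_table(matrix)
  idx <- do.call(rbind, lapply(strsplit(motifs, ""),
                               function(ch) match(ch, rownames(d))))
  if (any(is.na(idx))) {
    stop("motifs contain residues not covered by the substitution matrix")
  }
  n <- length(motifs)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d[idx[i, ], , drop = FALSE]
    # row i vs all: sum over positions of d(a_p, b_p)
    D[i, ] <- vapply(seq_len(n), function(j)
      sum(di[cbind(seq_len(ncol(idx)), idx[j, ])]), 0)
  }
  structure(list(motifs = motifs, D = D, matrix_name = matrix$name),
            class = "motif_distance_matrix")
}

#' Silhouette coefficients between motif groups
#'
#' For every pair of groups, computes the mean silhouette width over the two
#' groups' members using the precomputed motif distances. Values near 1 mean
#' cleanly separated motif populations; near 0, coincident ones; negative,
#' motifs that sit closer to the opposite group.
#'
#' @param dmat a \code{motif_distance_matrix} (or plain symmetric matrix)
#' @param groups group label per motif
#' @return data.frame with columns group1, group2, silhouette
#' @export
silhouette_between_groups <- function(dmat, groups) {
  D <- if (inherits(dmat, "motif_distance_matrix")) dmat$D else as.matrix(dmat)
  groups <- as.character(groups)
  stopifnot(nrow(D) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) stop("at least two groups are required")
  if (any(tab < 2)) {
    stop("singleton group: ", names(tab)[tab < 2][1])
  }
  gs <- names(tab)
  pairs <- utils::combn(gs, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    silhouette = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    sel <- groups %in% pairs[, k]
    sil <- cluster::silhouette(as.integer(factor(groups[sel])),
                               dmatrix = D[sel, sel])
    out$silhouette[k] <- mean(sil[, "sil_width"])
  }
  out
}

#' Per-position Jensen-Shannon conservation of aligned motifs
#'
#' For each column of an aligned motif set, the Jensen-Shannon divergence
#' (base-2 logs, hence in [0,1]) between the observed residue distribution
#' and a background distribution — by default the BLOSUM62-derived
#' background. Higher scores mean stronger conservation.
#'
#' @param motifs character vector of equal-length aligned motifs
#' @param background named probability vector over the 20 residues
#' @return numeric vector of one score per motif position
#' @export
jsd_conservation <- function(motifs, background = background_frequencies()) {
  if (length(motifs) == 0) stop("empty motif set")
  if (length(unique(nchar(motifs))) > 1) {
    stop("all motifs must have equal length")
  }
  std <- amino_alphabet()$standard20
  q <- background[std]
  q <- q / sum(q)
  mat <- do.call(rbind, strsplit(motifs, ""))
  apply(mat, 2, function(col) {
    col <- col[col %in% std]
    if (length(col) == 0) return(0)
    p <- as.numeric(table(factor(col, levels = std))) / length(col)
    r <- (p + q) / 2
    kl <- function(x, y) {
      nz <- x > 0
      sum(x[nz] * log2(x[nz] / y[nz]))
    }
    0.5 * kl(p, r) + 0.5 * kl(q, r)
  })
}

# ---- Kobe-Kajava consensus classes ---------------------------------------

# Constraint tables, positions relative to L0. "h" = hydrophobic set,
# "o" = nonpolar (hydrophobic plus glycine, proline excluded), otherwise a
# literal residue set. Constraints beyond +10 describe the consensus tails
# and are only evaluated when the supplied window reaches them.
kk_class_constraints <- function() {
  h <- amino_alphabet()$hydrophobic
  o <- union(h, "G")
  list(
    W6  = list("0" = h, "3" = h, "5" = h),
    W11 = list("0" = h, "3" = h, "5" = h, "8" = c("N", "C"), "10" = h),
    RI  = list("0" = h, "3" = h, "5" = h, "8" = c("N", "C"), "10" = h),
    T   = list("-3" = h, "0" = h, "3" = h, "5" = h, "8" = "N", "10" = h,
               "13" = h, "18" = c("F", "L"), "21" = h),
    S   = list("-3" = h, "0" = h, "3" = h, "5" = h, "8" = "N", "10" = h,
               "13" = h, "14" = "P"),
    PS  = list("-3" = h, "0" = h, "3" = h, "5" = h, "8" = "N", "10" = h,
               "11" = c("S", "T"), "12" = "G", "14" = "I", "15" = "P"),
    CC  = list("-3" = union(h, "C"), "0" = h, "3" = h, "5" = h, "8" = "C",
               "11" = "I", "12" = "T", "13" = "D", "16" = o))
}

#' Match a motif window against the Kobe-Kajava consensus classes
#'
#' The window string must be aligned so that L0 sits at (0-based) string
#' index 5, i.e., it starts at motif position -5; it may extend beyond +10,
#' in which case the longer class consensus tails (T, S, PS, CC) are also
#' checked. \code{W6} and \code{W11} are the generic minimal
#' (\code{LxxLxL}) and 11-residue (\code{LxxLxLxx(N/C)xL}) consensuses; RI,
#' T, S, PS and CC are the published class consensuses (ribosomal-inhibitor,
#' typical, short, plant-specific and cysteine-containing types).
#'
#' @param window residue string of length >= 16, L0 at string index 5
#' @param classes which classes to evaluate (default all)
#' @return named logical vector: TRUE/FALSE match, NA where the window is too
#'   short to evaluate that class's constraints
#' @export
kk_consensus_match <- function(window, classes = names(kk_class_constraints())) {
  if (nchar(window) < EXTENDED_LEN) {
    stop("window must cover at least the 16-residue extended motif")
  }
  chars <- strsplit(window, "")[[1]]
  cons <- kk_class_constraints()[classes]
  vapply(cons, function(con) {
    pos <- as.integer(names(con))
    idx <- pos + EXTENDED_OFFSET + 1L          # string indices
    if (any(idx > length(chars))) return(NA)
    all(mapply(function(i, allowed) chars[i] %in% allowed, idx, con))
  }, NA)
}

#' Position frequency and information-content table for a motif set
#'
#' Per-position residue frequencies plus information content in bits
#' (log2(20) minus the Shannon entropy of the observed distribution, i.e.,
#' relative entropy against a uniform background) — the quantities a sequence
#' logo displays.
#'
#' @param motifs character vector of equal-length aligned motifs
#' @return list with \code{freq} (positions x 20 matrix) and \code{bits}
#'   (numeric per position)
#' @export
position_frequency_logo <- function(motifs) {
  if (length(motifs) == 0) stop("empty motif set")
  if (length(unique(nchar(motifs))) > 1) {
    stop("all motifs must have equal length")
  }
  std <- amino_alphabet()$standard20
  mat <- do.call(rbind, strsplit(motifs, ""))
  freq <- t(apply(mat, 2, function(col) {
    col <- col[col %in% std]
    as.numeric(table(factor(col, levels = std))) / max(1, length(col))
  }))
  colnames(freq) <- std
  bits <- apply(freq, 1, function(p) {
    nz <- p > 0
    log2(20) + sum(p[nz] * log2(p[nz]))
  })
  list(freq = freq, bits = bits)
}

#' Metric multidimensional scaling of a motif distance matrix
#'
#' Embeds the motifs in two dimensions by SMACOF stress majorization,
#' initialised from the classical (Torgerson) solution with a small seeded
#' jitter, and reports the normalized stress-1 of the embedding
#' (sqrt(sum (d - dhat)^2 / sum d^2)).
#'
#' @param dmat a \code{motif_distance_matrix} or symmetric distance matrix
#' @param seed RNG seed for the jittered initialisation
#' @param max_iter majorization iteration cap
#' @return list with \code{coords} (n x 2) and \code{stress1}
#' @export
mds_embed <- function(dmat, seed = 1L, max_iter = 300L) {
  D <- if (inherits(dmat, "motif_distance_matrix")) dmat$D else as.matrix(dmat)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(D)
  rng <- local_rng(seed)
  X <- suppressWarnings(stats::cmdscale(D, k = 2))
  if (ncol(X) < 2) X <- cbind(X, 0)[, 1:2, drop = FALSE]
  X <- X + matrix(rng$draw(function() stats::rnorm(2 * n, sd = 1e-4)), n, 2)
  denom <- sum(D^2)
  if (denom == 0) {
    return(list(coords = X * 0, stress1 = 0))
  }
  edist <- function(X) {
    as.matrix(stats::dist(X))
  }
  stress_of <- function(E) sqrt(sum((D - E)^2) / denom)
  E <- edist(X)
  prev <- stress_of(E)
  for (it in seq_len(max_iter)) {
    B <- ifelse(E > 0, -D / pmax(E, 1e-12), 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    E <- edist(X)
    cur <- stress_of(E)
    if (prev - cur < 1e-9) { prev <- cur; break }
    prev <- cur
  }
  list(coords = X, stress1 = prev)
}
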