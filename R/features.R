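#' Extract the 16 x 20 profile block around a candidate L0 position
#'
#' The extended motif window spans 5 residues upstream to 10 downstream of
#' L0. Positions too close to either terminus cannot provide the full window
#' and are "edge positions": they are never scored, mirroring the exclusion
#' of incomplete repeats from the training data.
#'
#' @param record a \code{protein_record} with a profile
#' @param l0 candidate motif start, 0-based
#' @return 16 x 20 numeric matrix, rows ordered -5..+10
#' @seealso [is_edge_position()]
#' @export
make_position_window <- function(record, l0) {
  if (is.null(record$profile)) stop("record '", record$id, "' has no profile")
  n <- nchar(record$sequence)
  if (is_edge_position(l0, n)) {
    stop(structure(class = c("lrr_edge_position", "error", "condition"),
                   list(message = paste0("position ", l0, " lacks full ",
                                         "window context in '", record$id, "'"),
                        call = sys.call(-1))))
  }
  idx <- (l0 - EXTENDED_OFFSET):(l0 + 10L) + 1L  # 1-based rows
  block <- record$profile[idx, , drop = FALSE]
  rownames(block) <- as.character(-5:10)
  block
}

#' Does a candidate position lack full extended-window context?
#'
#' @param l0 0-based position(s)
#' @param seq_len sequence length
#' @return logical vector: TRUE where fewer than 5 residues upstream or 10
#'   downstream exist
#' @export
is_edge_position <- function(l0, seq_len) {
  l0 - EXTENDED_OFFSET < 0L | l0 + 10L >= seq_len
}

#' Assemble the feature vector for one candidate position
#'
#' Sequence-only mode flattens the 16 x 20 profile block position-major
#' (20 residue values for window position -5 first) into 320 features. The
#' combined mode appends the 16 x 7 structural block (order H, E, C, B, M,
#' Eexp, disorder per position), for 432 features.
#'
#' @param block 16 x 20 profile block from [make_position_window()]
#' @param structural optional 16 x 7 structural block for the same window
#' @return numeric feature vector of length 320 or 432
#' @export
assemble_feature_vector <- function(block, structural = NULL) {
  stopifnot(nrow(block) == EXTENDED_LEN, ncol(block) == 20)
  v <- as.vector(t(block))
  if (!is.null(structural)) {
    structural <- as.matrix(structural)
    if (nrow(structural) != EXTENDED_LEN || ncol(structural) != 7) {
      stop("structural block must be 16 x 7, got ",
           nrow(structural), " x ", ncol(structural))
    }
    v <- c(v, as.vector(t(structural)))
  }
  if (any(!is.finite(v))) stop("feature vector contains non-finite values")
  v
}

#' Fit a feature standardizer on training vectors
#'
#' Learns per-feature mean and standard deviation; constant features are given
#' unit scale so they transform to exact zeros. The standardizer must be
#' fitted on the training split only and then applied unchanged to validation
#' and test data.
#'
#' @param x numeric matrix, rows = training samples
#' @return object of class \code{lrr_standardizer}
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("standardizer needs at least 2 training vectors")
  center <- colMeans(x)
  # population standard deviation, so two points map to exactly -1 / +1
  scale <- sqrt(colMeans(sweep(x, 2, center, "-")^2))
  scale[scale < 1e-12] <- 1
  structure(list(center = center, scale = scale), class = "lrr_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std an \code{lrr_standardizer} from [fit_standardizer()]
#' @param x numeric matrix or vector with matching feature count
#' @return standardized matrix
#' @export
apply_standardizer <- function(std, x) {
  if (!inherits(std, "lrr_standardizer")) {
    stop("standardizer has not been fitted (expected an 'lrr_standardizer')")
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(std$center)) {
    stop("feature count mismatch: standardizer was fitted on ",
         length(std$center), " features, got ", ncol(x))
  }
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

#' Build a pseudo-profile from the bare sequence
#'
#' A fallback when no alignment-derived profile is available: the column for
#' residue r is the softmax of the substitution-matrix row s(r, .) divided by
#' a temperature. Low temperatures concentrate mass on the residue itself;
#' high temperatures approach the uniform distribution. Non-standard residues
#' receive uniform columns.
#'
#' @param sequence residue string or \code{protein_record}
#' @param matrix a \code{substitution_matrix} (default BLOSUM62)
#' @param temperature softmax temperature, must be positive (default 2)
#' @return L x 20 probability matrix, rows summing to 1
#' @export
pseudo_profile_from_sequence <- function(sequence, matrix = blosum62(),
                                         temperature = 2) {
  if (inherits(sequence, "protein_record")) sequence <- sequence$sequence
  if (temperature <= 0) stop("temperature must be positive")
  std <- amino_alphabet()$standard20
  chars <- strsplit(toupper(sequence), "")[[1]]
  cols <- matrix(1 / 20, nrow = length(chars), ncol = 20,
                 dimnames = list(NULL, std))
  known <- chars %in% std
  if (any(known)) {
    sm <- matrix$s / temperature
    soft <- exp(sm - apply(sm, 1, max))
    soft <- soft / rowSums(soft)
    cols[known, ] <- soft[chars[known], , drop = FALSE]
  }
  cols
}

#' Read a whitespace-separated per-residue profile table
#'
#' Accepts HHblits/PSI-BLAST style ASCII output reduced to 20 numeric columns
#' per residue ('#' comment lines ignored; an optional header row of residue
#' letters is honoured for column ordering). Values can be kept as scores or
#' renormalized to per-row probabilities.
#'
#' @param path path to the profile table
#' @param normalize renormalize each row to sum to 1 (shifting rows to be
#'   non-negative first if needed)
#' @return L x 20 numeric matrix with standard-residue column order
#' @export
read_profile_table <- function(path, normalize = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  std <- amino_alphabet()$standard20
  fields1 <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  has_header <- all(fields1 %in% std) && length(fields1) == 20
  order20 <- if (has_header) fields1 else std
  body <- if (has_header) lines[-1] else lines
  vals <- do.call(rbind, lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (ncol(vals) != 20) stop("profile table must have 20 numeric columns")
  colnames(vals) <- order20
  vals <- vals[, std, drop = FALSE]
  if (normalize) {
    vals <- vals - pmin(apply(vals, 1, min), 0)
    rs <- rowSums(vals)
    rs[rs == 0] <- 1
    vals <- vals / rs
  }
  vals
}

#' Read a per-residue structural feature table
#'
#' Seven tab/whitespace-separated columns per residue: H, E, C secondary
#' structure probabilities; B, M, Eexp relative solvent accessibility
#' probabilities; disorder probability.
#'
#' @param path path to the table
#' @return L x 7 numeric matrix
#' @export
read_structural_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (all(is.na(suppressWarnings(as.numeric(first))))) lines <- lines[-1]
  vals <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (ncol(vals) != 7) stop("structural table must have 7 columns")
  colnames(vals) <- STRUCTURAL_COLS
  vals
}
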