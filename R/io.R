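#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased. Non-standard residues (B, Z, X, U, O, *) are kept
#' in place but their positions are recorded per record in the
#' \code{nonstandard} attribute (0-based indices).
#'
#' @param path path to a FASTA file
#' @return a list of \code{protein_record} objects (see [protein_record()])
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty FASTA file: ", path)
  }
  first_content <- which(nzchar(trimws(lines)))[1]
  if (!startsWith(trimws(lines[first_content]), ">")) {
    stop("malformed FASTA header: sequence data before first '>' at line ",
         first_content)
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    protein_record(id = ids[i], sequence = toupper(as.character(set[[i]])))
  })
}

#' Construct a protein record
#'
#' The central carrier for one chain: sequence, optional per-residue sequence
#' profile (L x 20, rows follow the sequence) and optional per-residue
#' structural feature matrix (L x 7: helix/extended/coil probabilities,
#' buried/medium/exposed relative solvent accessibility, disorder).
#'
#' @param id chain identifier
#' @param sequence residue string (uppercase)
#' @param profile optional L x 20 numeric matrix, columns named by residue
#' @param structural optional L x 7 numeric matrix (columns H,E,C,B,M,Eexp,dis)
#' @return an object of class \code{protein_record}
#' @export
protein_record <- function(id, sequence, profile = NULL, structural = NULL) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id),
            is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  std <- amino_alphabet()$standard20
  bad <- which(!chars %in% std) - 1L   # 0-based flagged positions
  if (length(bad) && any(!chars[bad + 1L] %in% NONSTANDARD_RESIDUES)) {
    stop("record '", id, "' contains characters that are neither standard ",
         "residues nor recognised ambiguity codes")
  }
  if (!is.null(profile)) {
    profile <- as.matrix(profile)
    if (nrow(profile) != n) {
      stop("profile has ", nrow(profile), " rows but sequence length is ", n)
    }
    if (ncol(profile) != 20) stop("profile must have 20 columns")
    if (is.null(colnames(profile))) colnames(profile) <- std
    profile <- profile[, std, drop = FALSE]
    if (any(!is.finite(profile))) stop("profile contains non-finite values")
  }
  if (!is.null(structural)) {
    structural <- as.matrix(structural)
    if (nrow(structural) != n) {
      stop("structural table has ", nrow(structural),
           " rows but sequence length is ", n)
    }
    if (ncol(structural) != 7) {
      stop("structural table must have 7 columns (H,E,C,B,M,Eexp,disorder)")
    }
    colnames(structural) <- STRUCTURAL_COLS
    ss_sum <- rowSums(structural[, 1:3, drop = FALSE])
    rsa_sum <- rowSums(structural[, 4:6, drop = FALSE])
    if (any(abs(ss_sum - 1) > 1e-6) || any(abs(rsa_sum - 1) > 1e-6)) {
      stop("secondary-structure and solvent-accessibility probability ",
           "triples must each sum to 1")
    }
  }
  structure(list(id = id, sequence = sequence, profile = profile,
                 structural = structural, nonstandard = bad),
            class = "protein_record")
}

STRUCTURAL_COLS <- c("H", "E", "C", "B", "M", "Eexp", "disorder")

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", nchar(x$sequence), " aa",
      if (!is.null(x$profile)) ", profile" else "",
      if (!is.null(x$structural)) ", structural" else "", "\n", sep = "")
  invisible(x)
}

#' Read structural repeat annotations from a TSV table
#'
#' Expected columns: \code{chain_id}, \code{motif_type} (N, L or C),
#' \code{l0_pos} (0-based), \code{start}, \code{end} (0-based, half-open).
#' Lines starting with \code{#} are comments.
#'
#' @param path path to the TSV file
#' @return a data.frame of validated annotations (possibly zero rows)
#' @export
read_repeat_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "integer", "integer", "integer"))
  if (nrow(df) == 0) return(empty_annotations())
  names(df) <- c("chain_id", "motif_type", "l0_pos", "start", "end")
  validate_annotations(df)
}

empty_annotations <- function() {
  data.frame(chain_id = character(), motif_type = character(),
             l0_pos = integer(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Validate a repeat-annotation table
#'
#' Checks the motif-type vocabulary (N/L/C), that each L0 lies inside its
#' half-open span and that spans are at least 6 residues long.
#'
#' @param df data.frame with columns chain_id, motif_type, l0_pos, start, end
#' @return the validated data.frame
#' @export
validate_annotations <- function(df) {
  bad_type <- which(!df$motif_type %in% c("N", "L", "C"))
  if (length(bad_type)) {
    stop("row ", bad_type[1], ": motif_type '", df$motif_type[bad_type[1]],
         "' is not one of N, L, C")
  }
  outside <- which(df$l0_pos < df$start | df$l0_pos >= df$end)
  if (length(outside)) {
    stop("row ", outside[1], ": l0_pos ", df$l0_pos[outside[1]],
         " lies outside span [", df$start[outside[1]], ",",
         df$end[outside[1]], ")")
  }
  short <- which(df$end - df$start < 6)
  if (length(short)) {
    stop("row ", short[1], ": repeat span shorter than 6 residues")
  }
  df
}

#' Write motif predictions to TSV or GFF3
#'
#' The TSV format keeps the package's internal convention (0-based L0,
#' half-open spans); GFF3 uses 1-based inclusive coordinates with feature type
#' \code{repeat_region} and the call probability as score.
#'
#' @param calls data.frame with columns chain_id, l0 (0-based), probability,
#'   start, end (0-based half-open span)
#' @param path output path
#' @param format "tsv" or "gff3"
#' @return the path, invisibly
#' @export
write_motif_predictions <- function(calls, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  need <- c("chain_id", "l0", "probability", "start", "end")
  if (!all(need %in% names(calls))) {
    stop("calls must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(calls) > 0 && (any(calls$probability < 0) ||
                          any(calls$probability > 1))) {
    stop("probabilities must lie in [0,1]")
  }
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(need, collapse = "\t"), con)
    if (nrow(calls) > 0) {
      utils::write.table(calls[, need], con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  } else {
    lines <- "##gff-version 3"
    if (nrow(calls) > 0) {
      lines <- c(lines, sprintf(
        "%s\tlrrscan\trepeat_region\t%d\t%d\t%.6g\t.\t.\tl0=%d",
        calls$chain_id, calls$start + 1L, calls$end, calls$probability,
        calls$l0 + 1L))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read motif predictions written by [write_motif_predictions()]
#'
#' @param path input path
#' @param format "tsv" or "gff3"
#' @return data.frame with columns chain_id, l0, probability, start, end
#'   (0-based half-open, regardless of on-disk format)
#' @export
read_motif_predictions <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    return(df)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(
    data.frame(chain_id = character(), l0 = integer(), probability = numeric(),
               start = integer(), end = integer(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    chain_id = vapply(parts, `[`, "", 1),
    l0 = as.integer(sub("^l0=", "", vapply(parts, `[`, "", 9))) - 1L,
    probability = as.numeric(vapply(parts, `[`, "", 6)),
    start = as.integer(vapply(parts, `[`, "", 4)) - 1L,
    end = as.integer(vapply(parts, `[`, "", 5)),
    stringsAsFactors = FALSE)
}

#' Read a substitution matrix in NCBI text format
#'
#' Accepts the usual BLAST-style matrix layout: '#' comments, a header row of
#' residue letters and one row per residue. The matrix must be symmetric and
#' cover the 20 standard residues.
#'
#' @param path path to the matrix file
#' @param name optional display name (defaults to the file name)
#' @return a \code{substitution_matrix}: list(name, s = 20x20 numeric matrix)
#' @export
read_substitution_matrix <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, "", 1)
  vals <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(vals) <- labels
  colnames(vals) <- header
  substitution_matrix(vals, name = name)
}

#' Construct a substitution matrix object
#'
#' @param s square numeric matrix with residue dimnames; restricted to the 20
#'   standard residues and checked for symmetry
#' @param name display name
#' @return a \code{substitution_matrix}
#' @export
substitution_matrix <- function(s, name = "custom") {
  std <- amino_alphabet()$standard20
  if (!all(std %in% rownames(s)) || !all(std %in% colnames(s))) {
    stop("substitution matrix must cover all 20 standard residues")
  }
  s <- s[std, std]
  if (!isSymmetric(unname(s), tol = 1e-9)) {
    stop("substitution matrix must be symmetric")
  }
  structure(list(name = name, s = s), class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix> ", x$name, " (20 x 20)\n", sep = "")
  invisible(x)
}

#' The BLOSUM62 substitution matrix
#'
#' @return a \code{substitution_matrix} wrapping the BLOSUM62 scores shipped
#'   with Biostrings
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  substitution_matrix(e$BLOSUM62, name = "BLOSUM62")
}

#' A metric-repaired BLOSUM62 (synthetic surrogate)
#'
#' The motif distance of [motif_distance()] is built from per-residue
#' distances d(i,j) = s(i,i) + s(j,j) - 2 s(i,j). Under plain BLOSUM62 this
#' quantity violates the triangle inequality for a few residue triples, so
#' for metric analyses (silhouettes, MDS) a matrix whose induced d *is* a
#' metric is preferable. This function builds one synthetically: it takes the
#' BLOSUM62-induced distances, replaces them by their shortest-path (metric)
#' closure over the 20-residue graph, and re-derives scores with the original
#' diagonal so that the closure is reproduced exactly. The result is a
#' deterministic, in-code stand-in for recalculated BLOSUM variants with the
#' metric property; it is not a published matrix.
#'
#' @return a \code{substitution_matrix} named "metric_blosum62_synthetic"
#' @export
metric_blosum62 <- function() {
  b <- blosum62()$s
  n <- nrow(b)
  d <- outer(diag(b), diag(b), "+") - 2 * b
  # Floyd-Warshall closure: largest metric dominated by d
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  s <- (outer(diag(b), diag(b), "+") - d) / 2
  substitution_matrix(s, name = "metric_blosum62_synthetic")
}
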