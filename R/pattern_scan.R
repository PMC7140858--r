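#' Classify a 6-residue window against the minimal LRR pattern
#'
#' A window matches the minimal motif \code{LxxLxL} when positions 0, 3 and 5
#' are all hydrophobic (L, I, V, M, F, W, Y, C, A). Matching windows are
#' partitioned by how many of those three positions are strict leucine:
#' \code{"3L"} (all), \code{"2L"}, \code{"1L"} or \code{"0L"} (hydrophobic but
#' leucine-free). Non-matching windows classify as \code{"none"}.
#'
#' @param window6 a 6-character residue string
#' @return one of "3L", "2L", "1L", "0L", "none"
#' @examples
#' classify_minimal_window("LSSLSL")  # "3L"
#' classify_minimal_window("PSSLSL")  # "none"
#' @export
classify_minimal_window <- function(window6) {
  stopifnot(is.character(window6), length(window6) == 1)
  if (nchar(window6) != MINIMAL_LEN) {
    stop("minimal-motif window must be exactly 6 residues, got ",
         nchar(window6))
  }
  chars <- strsplit(window6, "")[[1]][c(1, 4, 6)]
  if (!all(is_hydrophobic(chars))) return("none")
  paste0(sum(chars == "L"), "L")
}

#' Scan a sequence for potential LRR motifs
#'
#' Enumerates every position whose 6-residue window matches \code{LxxLxL} and
#' annotates the extended-pattern flags: asparagine or cysteine at relative
#' position +8 and a hydrophobic residue at +10 (only evaluated when those
#' positions exist). Overlapping matches are all reported; clustering of
#' nearby calls is the delineation stage's job, not the scanner's.
#'
#' @param sequence residue string (or a \code{protein_record})
#' @return data.frame with columns \code{pos} (0-based match start),
#'   \code{class} (leucine-count class), \code{n8}, \code{c8}, \code{l10}
#'   (logical extended flags, NA when out of range)
#' @export
scan_potential_motifs <- function(sequence) {
  if (inherits(sequence, "protein_record")) sequence <- sequence$sequence
  stopifnot(is.character(sequence), length(sequence) == 1)
  n <- nchar(sequence)
  empty <- data.frame(pos = integer(), class = character(),
                      n8 = logical(), c8 = logical(), l10 = logical(),
                      stringsAsFactors = FALSE)
  if (n < MINIMAL_LEN) return(empty)
  chars <- strsplit(sequence, "")[[1]]
  hyd <- is_hydrophobic(chars)
  leu <- chars == "L"
  starts <- seq_len(n - MINIMAL_LEN + 1L)          # 1-based window starts
  hit <- hyd[starts] & hyd[starts + 3L] & hyd[starts + 5L]
  p1 <- starts[hit]                                # 1-based L0 positions
  if (length(p1) == 0) return(empty)
  nleu <- leu[p1] + leu[p1 + 3L] + leu[p1 + 5L]
  at <- function(off) ifelse(p1 + off <= n, chars[pmin(p1 + off, n)], NA)
  r8 <- at(8L)
  r10 <- at(10L)
  data.frame(
    pos = p1 - 1L,
    class = paste0(nleu, "L"),
    n8 = r8 == "N",
    c8 = r8 == "C",
    l10 = ifelse(is.na(r10), NA, r10 %in% amino_alphabet()$hydrophobic),
    stringsAsFactors = FALSE)
}

PATTERN_ROWS <- c("3L", "2L", "1L", "0L", "LxxLxL",
                  "LxxLxLxxN", "LxxLxLxxC", "LxxLxLxx(N/C)xL")

#' Tabulate LRR sequence-pattern occurrences over a dataset
#'
#' For every pattern row (the leucine-count classes of the minimal motif, the
#' minimal motif itself and the extended variants) counts potential motifs,
#' split by whether the hosting protein carries any repeat annotation
#' (LRR vs non-LRR protein) and whether the motif start coincides with an
#' annotated L0 (true vs false motif). Each pattern row is counted
#' independently, so extended rows are subsets of the \code{LxxLxL} row.
#'
#' @param records list of \code{protein_record}s
#' @param annotations repeat-annotation data.frame (may have zero rows)
#' @return data.frame with one row per pattern and columns \code{total},
#'   \code{nonlrr_false}, \code{nonlrr_true}, \code{lrr_false},
#'   \code{lrr_true}
#' @export
tabulate_pattern_counts <- function(records, annotations = empty_annotations()) {
  ids <- vapply(records, function(r) r$id, "")
  missing <- setdiff(unique(annotations$chain_id), ids)
  if (length(missing)) {
    stop("annotations reference chains absent from records: ",
         paste(missing, collapse = ", "))
  }
  tab <- matrix(0L, nrow = length(PATTERN_ROWS), ncol = 4,
                dimnames = list(PATTERN_ROWS,
                                c("nonlrr_false", "nonlrr_true",
                                  "lrr_false", "lrr_true")))
  for (rec in records) {
    hits <- scan_potential_motifs(rec)
    if (nrow(hits) == 0) next
    ann <- annotations[annotations$chain_id == rec$id, , drop = FALSE]
    is_lrr <- nrow(ann) > 0
    truth <- hits$pos %in% ann$l0_pos
    col_of <- function(is_true) {
      if (is_lrr) ifelse(is_true, "lrr_true", "lrr_false")
      else ifelse(is_true, "nonlrr_true", "nonlrr_false")
    }
    add <- function(row, sel) {
      if (!any(sel)) return()
      cols <- col_of(truth[sel])
      for (cn in unique(cols)) {
        tab[row, cn] <<- tab[row, cn] + sum(cols == cn)
      }
    }
    add("LxxLxL", rep(TRUE, nrow(hits)))
    for (cl in c("3L", "2L", "1L", "0L")) add(cl, hits$class == cl)
    add("LxxLxLxxN", !is.na(hits$n8) & hits$n8)
    add("LxxLxLxxC", !is.na(hits$c8) & hits$c8)
    add("LxxLxLxx(N/C)xL",
        !is.na(hits$n8) & (hits$n8 | hits$c8) & !is.na(hits$l10) & hits$l10)
  }
  out <- as.data.frame(tab)
  out$total <- rowSums(tab)
  out$pattern <- rownames(out)
  rownames(out) <- NULL
  out[, c("pattern", "total", "nonlrr_false", "nonlrr_true",
          "lrr_false", "lrr_true")]
}
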