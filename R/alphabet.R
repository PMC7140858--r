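#' Amino acid alphabet and hydrophobicity sets used by the LRR pattern scanner
#'
#' The LRR minimal motif \code{LxxLxL} places hydrophobic residues at relative
#' positions 0, 3 and 5 of a repeat. "Hydrophobic" here is the nine-residue set
#' L, I, V, M, F, W, Y, C, A; the pattern classes additionally distinguish
#' strict leucine from the other eight hydrophobics.
#'
#' @return A list with components:
#'   \item{standard20}{the 20 standard residues, alphabetical}
#'   \item{hydrophobic}{the hydrophobic set \{L,I,V,M,F,W,Y,C,A\}}
#'   \item{strict_leu}{\code{"L"} alone}
#'   \item{hydrophobic_nonleu}{the hydrophobic set without leucine}
#' @examples
#' a <- amino_alphabet()
#' setdiff(a$hydrophobic, c(a$strict_leu, a$hydrophobic_nonleu))  # empty
#' @export
amino_alphabet <- function() {
  hyd <- c("L", "I", "V", "M", "F", "W", "Y", "C", "A")
  list(
    standard20 = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    hydrophobic = hyd,
    strict_leu = "L",
    hydrophobic_nonleu = setdiff(hyd, "L")
  )
}

# Residues that occur in real-world FASTA but are not one of the standard 20.
# They are retained in sequences, flagged on input, treated as non-hydrophobic
# by the pattern scanner and given uniform background profile columns.
NONSTANDARD_RESIDUES <- c("B", "Z", "X", "U", "O", "*")

#' Is each residue hydrophobic in the LRR-motif sense?
#'
#' Non-standard residues (B, Z, X, U, O, *) are conservatively non-hydrophobic.
#'
#' @param residues character vector of single-letter residues
#' @return logical vector
#' @export
is_hydrophobic <- function(residues) {
  residues %in% amino_alphabet()$hydrophobic
}

# Window geometry of the 16-residue extended motif: indices 0..15 carry motif
# position labels -5..+10, so L0 sits at window index 5 (0-based), L3 at 8,
# L5 at 10, the N/C position (+8) at 13 and L10 at 15.
EXTENDED_OFFSET <- 5L   # residues upstream of L0 in the extended window
EXTENDED_LEN    <- 16L
MINIMAL_LEN     <- 6L

#' Background amino acid frequencies
#'
#' The BLOSUM62-derived background distribution commonly used for
#' Jensen-Shannon conservation scoring; also used by the synthetic generator
#' to draw unconstrained ("x") positions.
#'
#' @return named numeric vector over the 20 standard residues, summing to 1
#' @export
background_frequencies <- function() {
  # order A R N D C Q E G H I L K M F P S T W Y V
  f <- c(A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024, Q = 0.034,
         E = 0.059, G = 0.083, H = 0.025, I = 0.062, L = 0.092, K = 0.056,
         M = 0.024, F = 0.044, P = 0.043, S = 0.059, T = 0.055, W = 0.014,
         Y = 0.034, V = 0.072)
  f <- f / sum(f)
  f[amino_alphabet()$standard20]
}
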