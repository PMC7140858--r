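#' Call motifs from a per-position probability track
#'
#' Positions whose probability meets the threshold become candidate calls;
#' candidates closer than 15 residues are then greedily clustered — the
#' closest conflicting pair is merged first, keeping the higher-probability
#' member (leftmost on ties) — until no two calls lie within 15 residues.
#' One structural repeat can host several overlapping sequence signatures, so
#' collapsing sub-repeat-distance calls to a single motif is what turns a
#' probability track into a repeat skeleton.
#'
#' @param track numeric probability track (NA at unscored edge positions)
#' @param threshold calling threshold in (0,1), default 0.5
#' @param min_separation minimum spacing between surviving calls (default 15)
#' @return data.frame with columns \code{l0} (0-based) and \code{probability},
#'   sorted by position
#' @export
call_motifs <- function(track, threshold = 0.5, min_separation = 15L) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1")
  }
  pos <- which(!is.na(track) & track >= threshold) - 1L
  prob <- track[pos + 1L]
  while (length(pos) > 1) {
    gaps <- diff(pos)
    close <- which(gaps < min_separation)
    if (length(close) == 0) break
    i <- close[which.min(gaps[close])]   # closest pair, leftmost on ties
    drop <- if (prob[i + 1L] > prob[i]) i else i + 1L  # keep higher, leftmost tie
    pos <- pos[-drop]
    prob <- prob[-drop]
  }
  data.frame(l0 = pos, probability = prob)
}

#' Delineate repeats from called motifs
#'
#' Consecutive motifs 15-35 residues apart bound a normal repeat
#' \code{[m_i, m_(i+1))}. When the gap exceeds 35 residues the stretch is
#' taken to start a terminal repeat or contain a break, and exactly the first
#' 24 residues (the most frequent repeat length in structural data) are
#' assigned; gaps beyond 100 residues additionally flag a probable inserted
#' domain. The final motif receives a terminal span of up to 24 residues,
#' clipped at the sequence end.
#'
#' @param motifs data.frame from [call_motifs()] (or integer positions),
#'   sorted, no two entries within 15 residues
#' @param seq_len sequence length
#' @return data.frame with columns l0, probability, start, end (0-based
#'   half-open) and status in \{normal, gap_assigned_24, domain_break_flag,
#'   terminal\}
#' @export
delineate_repeats <- function(motifs, seq_len) {
  if (is.data.frame(motifs)) {
    l0 <- as.integer(motifs$l0)
    prob <- if ("probability" %in% names(motifs)) motifs$probability
            else rep(NA_real_, length(l0))
  } else {
    l0 <- as.integer(motifs)
    prob <- rep(NA_real_, length(l0))
  }
  if (is.unsorted(l0, strictly = TRUE)) {
    stop("motifs must be sorted by position without duplicates")
  }
  if (length(l0) > 1 && any(diff(l0) < 15L)) {
    stop("motifs closer than 15 residues must be clustered before ",
         "delineation (see call_motifs)")
  }
  n <- length(l0)
  if (n == 0) {
    return(data.frame(l0 = integer(), probability = numeric(),
                      start = integer(), end = integer(),
                      status = character(), stringsAsFactors = FALSE))
  }
  status <- character(n)
  start <- l0
  end <- integer(n)
  for (i in seq_len(n)) {
    if (i == n) {
      end[i] <- min(l0[i] + 24L, seq_len)
      status[i] <- "terminal"
    } else {
      gap <- l0[i + 1L] - l0[i]
      if (gap <= 35L) {
        end[i] <- l0[i + 1L]
        status[i] <- "normal"
      } else {
        end[i] <- l0[i] + 24L
        status[i] <- if (gap > 100L) "domain_break_flag" else "gap_assigned_24"
      }
    }
  }
  data.frame(l0 = l0, probability = prob, start = start, end = end,
             status = status, stringsAsFactors = FALSE)
}

#' Coverage of an LRR domain by repeats
#'
#' The coverage percentage (CP) is 100 times the summed repeat length,
#' clipped to the domain, divided by the domain length.
#'
#' @param repeats data.frame with \code{start}/\code{end} columns (0-based
#'   half-open spans)
#' @param domain length-2 vector: domain span \code{c(start, end)}, half-open
#' @return list with \code{cp}, the domain span, and per-repeat clipped
#'   contributions
#' @export
coverage_percent <- function(repeats, domain) {
  if (length(domain) != 2 || domain[2] <= domain[1]) {
    stop("domain must be a non-empty half-open interval c(start, end)")
  }
  contrib <- if (nrow(repeats) == 0) numeric(0) else {
    pmax(0L, pmin(repeats$end, domain[2]) - pmax(repeats$start, domain[1]))
  }
  list(cp = 100 * sum(contrib) / (domain[2] - domain[1]),
       domain = domain, contributions = contrib)
}

#' Distribution of repeat lengths from consecutive motif spacings
#'
#' Reports the spacing between consecutive called motifs, excluding the
#' terminal repeat (no downstream motif) and gaps over 100 residues
#' (probable inserted domains). Spacings outside the 19-35 residue range seen
#' in structural repeats are flagged as ambiguous: too short suggests a false
#' positive, too long a missed motif or protruding insertion.
#'
#' @param motifs sorted motif positions (data.frame with \code{l0} or vector)
#' @param range_ok inclusive length range considered unambiguous
#'   (default c(19, 35))
#' @return data.frame with columns \code{length}, \code{count},
#'   \code{ambiguous}
#' @export
repeat_length_distribution <- function(motifs, range_ok = c(19L, 35L)) {
  l0 <- if (is.data.frame(motifs)) as.integer(motifs$l0) else as.integer(motifs)
  if (length(l0) < 2) {
    return(data.frame(length = integer(), count = integer(),
                      ambiguous = logical()))
  }
  gaps <- diff(sort(l0))
  gaps <- gaps[gaps <= 100L]
  if (length(gaps) == 0) {
    return(data.frame(length = integer(), count = integer(),
                      ambiguous = logical()))
  }
  tab <- table(gaps)
  len <- as.integer(names(tab))
  data.frame(length = len, count = as.integer(tab),
             ambiguous = len < range_ok[1] | len > range_ok[2])
}
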