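#' Configuration for the synthetic solenoid-protein generator
#'
#' Defaults emulate the statistics of structurally delineated LRR domains:
#' 5-30 repeats per protein, repeat lengths supported on 19-35 residues with
#' a sharp peak at 24, hydrophobic minimal-motif positions that are strict
#' leucine about half the time, asparagine at motif position +8 in ~45% of
#' repeats (cysteine ~10%), a hydrophobic +10 in ~70% and a hydrophobic -3 in
#' ~50%; unconstrained positions draw from the background residue
#' frequencies. Profiles are Dirichlet draws concentrated on the true
#' residue. Decoys are repetitive non-LRR solenoids (helical ankyrin-like,
#' 33-residue period; beta pectate-lyase-like, 22-residue period) or
#' composition-matched shuffles.
#'
#' @param n_proteins number of LRR proteins in a benchmark
#' @param n_decoys number of decoy proteins in a benchmark
#' @param repeats_range min/max repeats per protein
#' @param repeat_lengths support of the repeat-length distribution
#' @param repeat_length_peak mode of the repeat-length distribution
#' @param p_leu probability that a minimal-motif hydrophobic is leucine
#' @param p_n8,p_c8 probabilities of N / C at motif position +8
#' @param p_hyd10 probability of a hydrophobic at +10
#' @param p_hyd_m3 probability of a hydrophobic at -3
#' @param profile_concentration Dirichlet concentration on the true residue
#' @param decoy_types decoy classes cycled over when generating decoy sets
#' @param max_windows benchmark window budget after subsampling
#' @param max_positive_fraction positive share of the benchmark windows
#' @return a validated \code{generator_config} list
#' @export
generator_config <- function(n_proteins = 40L, n_decoys = 10L,
                             repeats_range = c(5L, 30L),
                             repeat_lengths = 19:35,
                             repeat_length_peak = 24L,
                             p_leu = 0.5, p_n8 = 0.45, p_c8 = 0.10,
                             p_hyd10 = 0.7, p_hyd_m3 = 0.5,
                             profile_concentration = 30,
                             decoy_types = c("ankyrin_like", "pel_like",
                                             "shuffled"),
                             max_windows = 5000L,
                             max_positive_fraction = 0.02) {
  probs <- c(p_leu, p_n8, p_c8, p_hyd10, p_hyd_m3, max_positive_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (p_n8 + p_c8 > 1) stop("p_n8 + p_c8 must not exceed 1")
  if (length(repeat_lengths) == 0 || min(repeat_lengths) < 15) {
    stop("repeat lengths below 15 residues are structurally impossible ",
         "(motifs would overlap)")
  }
  if (repeats_range[1] < 1 || repeats_range[2] < repeats_range[1]) {
    stop("invalid repeats_range")
  }
  w <- exp(-abs(repeat_lengths - repeat_length_peak) / 2.5)
  list(n_proteins = as.integer(n_proteins), n_decoys = as.integer(n_decoys),
       repeats_range = as.integer(repeats_range),
       repeat_lengths = as.integer(repeat_lengths),
       repeat_length_weights = w / sum(w),
       p_leu = p_leu, p_n8 = p_n8, p_c8 = p_c8, p_hyd10 = p_hyd10,
       p_hyd_m3 = p_hyd_m3, profile_concentration = profile_concentration,
       decoy_types = decoy_types, max_windows = as.integer(max_windows),
       max_positive_fraction = max_positive_fraction)
}

draw_background <- function(n, rng) {
  q <- background_frequencies()
  names(q)[rng$draw(function()
    sample.int(20, n, replace = TRUE, prob = q))]
}

draw_hydrophobic <- function(n, p_leu, rng) {
  a <- amino_alphabet()
  leu <- rng$runif(n) < p_leu
  other <- a$hydrophobic_nonleu[rng$draw(function()
    sample.int(length(a$hydrophobic_nonleu), n, replace = TRUE))]
  ifelse(leu, "L", other)
}

#' Generate one synthetic LRR protein with planted ground truth
#'
#' Plants \code{n_repeats} extended motifs separated by repeat-length
#' distribution draws, with background linkers of at least 5 residues at both
#' termini so every planted L0 has full window context. The first and last
#' repeats are labelled N and C, interior ones L.
#'
#' @param config a \code{generator_config}
#' @param seed RNG seed
#' @param n_repeats optional repeat count (default drawn from
#'   \code{repeats_range})
#' @param id chain id
#' @return list with \code{record} (a \code{protein_record}) and
#'   \code{annotations} (repeat-annotation data.frame)
#' @export
generate_lrr_protein <- function(config = generator_config(), seed = 1L,
                                 n_repeats = NULL, id = paste0("synth_", seed)) {
  rng <- local_rng(seed)
  if (is.null(n_repeats)) {
    n_repeats <- rng$draw(function()
      sample(seq(config$repeats_range[1], config$repeats_range[2]), 1))
  }
  lens <- config$repeat_lengths[rng$draw(function()
    sample.int(length(config$repeat_lengths), n_repeats, replace = TRUE,
               prob = config$repeat_length_weights))]
  linker <- 5L + rng$draw(function() sample(0:10, 1))
  l0 <- linker + c(0L, cumsum(lens[-n_repeats]))
  total <- l0[n_repeats] + lens[n_repeats] + 5L
  chars <- draw_background(total, rng)
  for (i in seq_len(n_repeats)) {
    p <- l0[i] + 1L                       # 1-based L0 index
    chars[p + c(0L, 3L, 5L)] <- draw_hydrophobic(3, config$p_leu, rng)
    u <- rng$runif(1)
    if (u < config$p_n8) chars[p + 8L] <- "N"
    else if (u < config$p_n8 + config$p_c8) chars[p + 8L] <- "C"
    if (rng$runif(1) < config$p_hyd10) {
      chars[p + 10L] <- draw_hydrophobic(1, config$p_leu, rng)
    }
    if (rng$runif(1) < config$p_hyd_m3) {
      chars[p - 3L] <- draw_hydrophobic(1, config$p_leu, rng)
    }
  }
  spans_end <- c(l0[-1], min(l0[n_repeats] + 24L, total))
  ann <- data.frame(
    chain_id = id,
    motif_type = c("N", rep("L", max(0, n_repeats - 2)), "C")[seq_len(n_repeats)],
    l0_pos = l0, start = l0, end = spans_end, stringsAsFactors = FALSE)
  if (n_repeats == 1) ann$motif_type <- "N"
  list(record = protein_record(id, paste(chars, collapse = "")),
       annotations = validate_annotations(ann))
}

# Column targets that emulate what a homolog alignment shows at conserved
# motif positions: hydrophobic positions carry the hydrophobic-set mass
# (leucine about half), the +8 position carries asparagine/cysteine mass.
conservation_target <- function(role, residue) {
  std <- amino_alphabet()$standard20
  hyd <- amino_alphabet()$hydrophobic
  t <- stats::setNames(rep(0.1 / 11, 20), std)
  if (role == "hyd") {
    t[hyd] <- 0.4 / 8
    t["L"] <- 0.5
  } else if (role == "nc8") {
    t[] <- 0.2 / 15
    t[c("D", "S", "T", "C")] <- c(0.08, 0.07, 0.05, 0.05)
    t[residue] <- 0.55
  }
  t / sum(t)
}

#' Generate a noisy per-residue profile for a record
#'
#' Without annotations, each row is a Dirichlet draw whose concentration
#' piles on the true residue; as the concentration grows the columns
#' approach one-hot. When repeat annotations are supplied the profile
#' emulates what an alignment of homologous repeats produces: columns at
#' conserved motif positions (L0, L3, L5, a hydrophobic -3/+10, an N or C at
#' +8) are sharply concentrated on the conserved residue class, while
#' unconserved positions get flatter, noisier columns blending the realized
#' residue with the background — the contrast that makes profile-based motif
#' detection work on real proteins. A zero-row annotation table selects the
#' alignment-emulating mode with no conserved positions (used for decoys, so
#' every chain's profile comes from the same emulated process).
#' Non-standard residues receive symmetric draws.
#'
#' @param record a \code{protein_record}
#' @param config a \code{generator_config}
#' @param seed RNG seed
#' @param annotations optional repeat annotations marking true motifs
#' @return L x 20 probability matrix, rows summing to 1
#' @export
generate_profile <- function(record, config = generator_config(), seed = 1L,
                             annotations = NULL) {
  rng <- local_rng(seed)
  std <- amino_alphabet()$standard20
  hyd <- amino_alphabet()$hydrophobic
  chars <- strsplit(record$sequence, "")[[1]]
  n <- length(chars)
  conc <- config$profile_concentration
  onehot <- function(res) stats::setNames(as.numeric(std == res), std)
  alpha <- matrix(0, n, 20, dimnames = list(NULL, std))
  known <- chars %in% std
  if (is.null(annotations)) {
    for (i in which(known)) alpha[i, ] <- conc * onehot(chars[i]) + 0.1
  } else {
    q <- background_frequencies()
    role <- rep("", n)
    for (l0 in if (nrow(annotations)) annotations$l0_pos else integer(0)) {
      p <- l0 + 1L
      for (off in c(0L, 3L, 5L)) role[p + off] <- "hyd"
      for (off in c(-3L, 10L)) {
        if (p + off >= 1 && p + off <= n && chars[p + off] %in% hyd) {
          role[p + off] <- "hyd"
        }
      }
      if (p + 8L <= n && chars[p + 8L] %in% c("N", "C")) role[p + 8L] <- "nc8"
    }
    for (i in which(known)) {
      if (nzchar(role[i])) {
        t <- 0.7 * conservation_target(role[i], chars[i]) +
          0.3 * onehot(chars[i])
        alpha[i, ] <- conc * t + 0.02
      } else {
        t <- 0.65 * onehot(chars[i]) + 0.35 * q
        alpha[i, ] <- 0.25 * conc * t + 0.02
      }
    }
  }
  alpha[!known, ] <- 1
  g <- matrix(rng$draw(function()
    stats::rgamma(n * 20, shape = as.vector(alpha))), n, 20)
  prof <- g / rowSums(g)
  colnames(prof) <- std
  prof
}

# Dirichlet helper for probability triples with position-dependent emphasis.
draw_triples <- function(alpha_rows, rng) {
  g <- matrix(rng$draw(function()
    stats::rgamma(length(alpha_rows), shape = as.vector(alpha_rows))),
    nrow(alpha_rows), ncol(alpha_rows))
  g / rowSums(g)
}

#' Generate per-residue structural feature tracks
#'
#' Emulates predicted 3-state secondary structure, 3-class relative solvent
#' accessibility and disorder: extended-state probabilities run high across
#' planted minimal motifs (the ventral beta strand) and motif hydrophobics
#' read as buried; ankyrin-like decoys instead show 33-residue-period
#' helix-high tracks, pectate-lyase-like decoys 22-residue-period
#' extended-high tracks.
#'
#' @param record a \code{protein_record}
#' @param annotations repeat annotations (empty for decoys)
#' @param config a \code{generator_config}
#' @param seed RNG seed
#' @param decoy_type NULL for LRR proteins, else the decoy class
#' @return L x 7 matrix (H,E,C,B,M,Eexp,disorder)
#' @export
generate_structural_track <- function(record, annotations,
                                      config = generator_config(), seed = 1L,
                                      decoy_type = NULL) {
  rng <- local_rng(seed)
  n <- nchar(record$sequence)
  ss_alpha <- matrix(rep(c(1.5, 1.5, 6), each = n), n, 3)   # coil baseline
  rsa_alpha <- matrix(rep(c(2, 3, 4), each = n), n, 3)      # exposed-ish
  mark_ss <- function(pos, state, strength = 9) {
    pos <- pos[pos >= 1 & pos <= n]
    ss_alpha[pos, ] <<- matrix(rep(c(1, 1, 1), each = length(pos)),
                               length(pos), 3)
    ss_alpha[pos, state] <<- strength
  }
  if (is.null(decoy_type)) {
    for (l0 in annotations$l0_pos) {
      mark_ss(l0 + 1L + 0:5, 2)                       # E over minimal motif
      bur <- l0 + 1L + c(0L, 3L, 5L)
      rsa_alpha[bur[bur <= n], ] <-
        matrix(rep(c(8, 2, 1), each = sum(bur <= n)), sum(bur <= n), 3)
    }
  } else if (decoy_type == "ankyrin_like") {
    helix <- which(((seq_len(n) - 1L) %% 33L) %in% c(3:12, 18:27))
    mark_ss(helix, 1)
  } else if (decoy_type == "pel_like") {
    strand <- which(((seq_len(n) - 1L) %% 22L) %in% c(0:4, 9:13, 16:19))
    mark_ss(strand, 2)
  }
  ss <- draw_triples(ss_alpha, rng)
  rsa <- draw_triples(rsa_alpha, rng)
  disorder <- rng$draw(function() stats::rbeta(n, 1, 12))
  out <- cbind(ss, rsa, disorder)
  colnames(out) <- STRUCTURAL_COLS
  out
}

#' Generate one non-LRR decoy protein
#'
#' Decoys carry no true motifs: \code{"shuffled"} permutes a generated LRR
#' protein's residues (matched composition, destroyed motif geometry);
#' \code{"ankyrin_like"} and \code{"pel_like"} build repetitive solenoid
#' sequences with 33- and 22-residue periods whose hydrophobic phase avoids
#' the LRR spacing. Profiles and structural tracks are attached.
#'
#' @param config a \code{generator_config}
#' @param seed RNG seed
#' @param type decoy class
#' @param id chain id
#' @return a \code{protein_record} with profile and structural features
#' @export
generate_decoy <- function(config = generator_config(), seed = 1L,
                           type = c("ankyrin_like", "pel_like", "shuffled"),
                           id = paste0("decoy_", type[1], "_", seed)) {
  type <- match.arg(type)
  rng <- local_rng(seed * 31L + 5L)
  if (type == "shuffled") {
    base <- generate_lrr_protein(config, seed * 31L + 6L, id = id)
    chars <- strsplit(base$record$sequence, "")[[1]]
    chars <- chars[rng$sample_perm(length(chars))]
  } else {
    period <- if (type == "ankyrin_like") 33L else 22L
    hyd_phase <- if (type == "ankyrin_like") c(4L, 8L, 12L, 19L, 23L, 27L)
                 else c(1L, 3L, 10L, 12L, 17L)
    n_units <- rng$draw(function() sample(8:15, 1))
    n <- period * n_units + 10L
    chars <- draw_background(n, rng)
    units <- rep(seq_len(n) - 1L, 1) %% period
    sel <- which(units %in% hyd_phase)
    chars[sel] <- draw_hydrophobic(length(sel), 0.25, rng)
  }
  rec <- protein_record(id, paste(chars, collapse = ""))
  rec$profile <- generate_profile(rec, config, seed * 31L + 7L,
                                  annotations = empty_annotations())
  rec$structural <- generate_structural_track(
    rec, empty_annotations(), config, seed * 31L + 8L,
    decoy_type = if (type == "shuffled") "ankyrin_like" else type)
  rec
}

#' Generate a labelled benchmark with decoys
#'
#' Builds \code{n_proteins} LRR proteins (with profiles and structural
#' tracks) and \code{n_decoys} decoys; assembles candidate windows —
#' positives at planted L0 positions, negatives at other non-edge positions
#' of LRR proteins and decoys — and stratified-subsamples them to the window
#' budget so positives make up about \code{max_positive_fraction} of the
#' samples, echoing the extreme class imbalance of real repeat-level data.
#' A stratified 5-way split (test + 4 CV folds) is attached.
#'
#' @param config a \code{generator_config}
#' @param seed RNG seed
#' @return an \code{lrr_benchmark}: records, decoys, annotations, feature
#'   matrix X (432 columns), labels y, origin table, split factor
#' @export
generate_benchmark <- function(config = generator_config(), seed = 17L) {
  rng <- local_rng(seed + 991L)
  proteins <- lapply(seq_len(config$n_proteins), function(i) {
    g <- generate_lrr_protein(config, seed + i, id = paste0("synth_", i))
    g$record$profile <- generate_profile(g$record, config, seed + 10000L + i,
                                         annotations = g$annotations)
    g$record$structural <- generate_structural_track(
      g$record, g$annotations, config, seed + 20000L + i)
    g
  })
  decoys <- lapply(seq_len(config$n_decoys), function(i) {
    type <- config$decoy_types[(i - 1L) %% length(config$decoy_types) + 1L]
    generate_decoy(config, seed + 30000L + i, type,
                   id = paste0("decoy_", type, "_", i))
  })
  annotations <- do.call(rbind, lapply(proteins, `[[`, "annotations"))
  records <- lapply(proteins, `[[`, "record")
  pool <- do.call(rbind, c(
    lapply(records, function(rec) {
      n <- nchar(rec$sequence)
      pos <- which(!is_edge_position(0:(n - 1L), n)) - 1L
      truth <- annotations$l0_pos[annotations$chain_id == rec$id]
      data.frame(chain_id = rec$id, pos = pos,
                 label = as.integer(pos %in% truth),
                 stringsAsFactors = FALSE)
    }),
    lapply(decoys, function(rec) {
      n <- nchar(rec$sequence)
      pos <- which(!is_edge_position(0:(n - 1L), n)) - 1L
      data.frame(chain_id = rec$id, pos = pos, label = 0L,
                 stringsAsFactors = FALSE)
    })))
  n_pos_target <- min(sum(pool$label == 1),
                      max(10L, round(config$max_positive_fraction *
                                       config$max_windows)))
  n_neg_target <- min(sum(pool$label == 0),
                      config$max_windows - n_pos_target)
  take <- function(idx, k) idx[rng$draw(function()
    sample.int(length(idx), k))]
  sel <- sort(c(take(which(pool$label == 1), n_pos_target),
                take(which(pool$label == 0), n_neg_target)))
  origin <- pool[sel, , drop = FALSE]
  rownames(origin) <- NULL
  all_recs <- c(records, decoys)
  rec_ids <- vapply(all_recs, function(r) r$id, "")
  X <- do.call(rbind, lapply(split(seq_len(nrow(origin)), origin$chain_id),
                             function(rows) {
    rec <- all_recs[[match(origin$chain_id[rows[1]], rec_ids)]]
    build_feature_matrix(rec, origin$pos[rows], with_structural = TRUE)
  }))
  ord <- order(unlist(split(seq_len(nrow(origin)), origin$chain_id),
               use.names = FALSE))
  X <- X[ord, , drop = FALSE]
  y <- origin$label
  split <- make_splits(y, 5L, seed + 77L)
  structure(list(records = records, decoys = decoys,
                 annotations = annotations, X = X, y = y, origin = origin,
                 split = split, config = config, seed = seed),
            class = "lrr_benchmark")
}

#' @export
print.lrr_benchmark <- function(x, ...) {
  cat("<lrr_benchmark> ", length(x$records), " LRR proteins, ",
      length(x$decoys), " decoys, ", nrow(x$X), " windows (",
      sum(x$y), " positive)\n", sep = "")
  invisible(x)
}
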