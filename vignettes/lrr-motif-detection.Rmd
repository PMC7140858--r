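---
title: "Detecting leucine-rich repeat motifs with a classifier ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting leucine-rich repeat motifs with a classifier ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Leucine-rich repeat (LRR) domains are solenoids of ~19–35-residue coils.
Each coil contributes one short beta strand to a ventral sheet, and that
strand carries the sequence signature `LxxLxL`: hydrophobic residues
(L, I, V, M, F, W, Y, C, A) at relative positions 0, 3 and 5, with position
0 (**L0**) marking the canonical repeat start. The pattern is trivially
common — any protein of realistic composition matches it every few dozen
residues — so the true repeat starts cannot be read off the sequence alone.
Structural superposition shows that similarity extends about five residues
upstream and ten downstream of L0; this 16-residue *extended motif* is the
context `lrrscan` classifies. The problem is acute in irregular LRR
domains, such as those of plant NOD-like immune receptors, where candidate
signatures overlap within less than one repeat length.

## The classifier ensemble

Every non-edge position of a chain (≥ 5 residues upstream, ≥ 10
downstream) is a candidate L0. Its feature vector is the 16 × 20 block of
the per-residue sequence profile (PSSM-style; HHblits or PSI-BLAST tabular
output, or the package's softmax pseudo-profile fallback), flattened
position-major to 320 features. When per-residue structural predictions are
available — 3-state secondary structure, 3-class relative solvent
accessibility, disorder — their 16 × 7 block is appended, for 432 features.
Features are standardized (centered, scaled by the population standard
deviation) with statistics learned on the training split only; constant
features map to zero.

Eight fixed members vote:

| id | family | features | imbalance | notes |
|----|--------|----------|-----------|-------|
| C1 | RBF SVC, cost 1, γ = 0.01 | 320 | inverse-frequency class weights | sigmoid-calibrated |
| C2 | MLP 300-250-100, L-BFGS | 320 | — | |
| C3 | MLP 250-150-100, L-BFGS | 320 | SMOTE+Tomek | |
| C4 | AdaBoost, 50 depth-1 stumps | 320 | — | real (SAMME.R) boosting, sigmoid-calibrated |
| C5 | RBF SVC, cost 1, γ = 0.001 | 432 | class weights | sigmoid-calibrated |
| C6 | MLP 250-150-100, Adam | 432 | — | early stopping, validation fraction 0.2 |
| C7 | MLP 125-100-10, L-BFGS | 432 | SMOTE+Tomek | |
| C8 | AdaBoost, 50 depth-1 stumps | 432 | — | sigmoid-calibrated |

All repeat types (N-terminal entry, core, C-terminal exit) are one positive
class; multiclass variants discriminate worse at these sample sizes. The
ensemble output is the unweighted arithmetic mean of the eight member
probabilities (soft voting) — an identity the test suite checks to
machine precision. A position is *called* at probability ≥ 0.5 by default;
0.4 is a useful reporting threshold when screening non-LRR folds.

Numerical choices worth recording:

* **Calibration.** SVC and boosting members emit decision values, not
  probabilities; a Platt sigmoid is fitted by logistic regression on
  out-of-fold decision values from 3 internal stratified folds. Three folds
  keep ~27 positives per calibration fit at benchmark scale; more folds add
  cost without visibly changing the curves.
* **MLP.** Three ReLU hidden layers, sigmoid output, cross-entropy with an
  L2 penalty of 0.5, written directly in R (no installed package provides
  multi-hidden-layer perceptrons). With ~10²–10³ positives against 10³–10⁵
  negatives and ~2 × 10⁵ weights, that penalty level is what keeps the
  L-BFGS members from memorizing the minority class; the iteration cap
  (150 L-BFGS iterations, 60 Adam epochs) is the fitted default.
* **SMOTE+Tomek.** Synthetic minority samples are interpolated between a
  minority point and one of its 5 nearest minority neighbours until classes
  balance; Tomek links (cross-class mutual nearest neighbours) are then
  removed, both members of each link.
* **Boosting.** Depth-1 `rpart` stumps under case weights; leaf
  probabilities are clipped at 10⁻¹⁰ before the half-log-ratio vote.
* **Determinism.** One master seed fans out to splits, resampling,
  network initialisation and calibration folds; identical data + seed gives
  identical predictions.

## From probability tracks to repeats

Delineation turns a per-position track into repeat calls:

1. positions at or above the threshold become candidates;
2. candidates closer than 15 residues are greedily merged — closest pair
   first, keeping the higher-probability member, leftmost on ties — because
   one structural repeat can host several overlapping signatures;
3. consecutive motifs 15–35 residues apart bound a *normal* repeat
   `[m_i, m_{i+1})`; a gap above 35 assigns exactly the first 24 residues
   (the modal repeat length in structural data) and, above 100 residues,
   additionally flags a probable inserted domain; the final motif takes a
   terminal span of up to 24 residues, clipped at the chain end.

For a gap in (35, 100] the remainder after the 24-residue assignment is
left unassigned rather than rescanned; rescanning would manufacture
repeats the track itself never supported. Coverage percentage is
100 × (summed repeat length clipped to the domain) / domain length. The
repeat-length histogram uses consecutive motif spacings, excludes terminal
repeats and >100-residue gaps, and flags spacings outside 19–35 residues
as ambiguous (too short: likely false positive; too long: likely missed
motif or protruding insertion).

## Motif analytics

The per-residue distance `d(i,j) = s(i,i) + s(j,j) − 2·s(i,j)` turns a
substitution matrix into a dissimilarity; summing over the 16 positions
gives the motif distance. For silhouette and embedding work a matrix whose
induced `d` is a metric is preferable. The recalculated BLOSUM variants
published with that property are not redistributable here, so the package
constructs a surrogate in code (`metric_blosum62()`): the BLOSUM62-induced
distances are replaced by their Floyd–Warshall shortest-path closure and
scores re-derived so the closure is exact. Over the 20 standard residues
BLOSUM62's induced distances already satisfy the triangle inequality, so
the surrogate coincides with BLOSUM62 there — the construction matters for
extended alphabets and for making the metric property hold by construction
rather than by accident. The test suite verifies the metric on 10,000
random triples.

Group separation uses the mean silhouette width per group pair on the
precomputed distances. Two-dimensional maps come from SMACOF metric MDS
(initialised from the classical solution with seeded jitter), reporting
stress-1 = √(Σ(d−d̂)²/Σd²). Column conservation uses Jensen–Shannon
divergence (base-2, window 0) against the BLOSUM62-derived background
distribution, while sequence-logo heights use relative entropy against a
uniform background — two distinct conventions, kept distinct on purpose.

Published LRR consensus classes (ribosomal-inhibitor, typical, short,
plant-specific, cysteine-containing) are matched as positional constraint
sets over windows W6 (motif positions 0–5), W11 (0–10) and W16 (−5..+10).
The published consensus strings extend beyond +10; constraints outside the
supplied window yield `NA` rather than a guess. Two mapping decisions were
genuinely open and are fixed as follows: W11 is `LxxLxLxx(N/C)xL`; and the
"nonpolar" symbol in the cysteine-containing consensus is read as the
hydrophobic set plus glycine, excluding proline.

## The synthetic benchmark

Real training data for this method requires curated structure-derived
repeat tables plus per-chain HHblits profiles and RaptorX structural
predictions — none of which can be bundled or regenerated offline. The
package therefore ships a generator whose defaults encode the structural
statistics the method rests on: 5–30 repeats per protein; repeat lengths
19–35 with a sharp mode at 24; minimal-motif hydrophobics that are strict
leucine with probability 0.5; asparagine at +8 in 45% of repeats (cysteine
10%); hydrophobic +10 in 70% and −3 in 50%; background positions drawn
from BLOSUM-style background frequencies. Profiles are Dirichlet draws:
conserved motif positions get sharply peaked columns over the conserved
residue class, unconserved positions flatter, noisier columns — the
contrast an alignment of homologous repeats actually produces, applied
identically to LRR chains and decoys. Structural tracks run extended-high
across minimal motifs with buried hydrophobics; decoys are repetitive
non-LRR solenoids (33-residue helical ankyrin-like, 22-residue beta
pectate-lyase-like periods, phases chosen off the LRR spacing) or
composition-matched shuffles, carrying no truth motifs.

The benchmark assembles all planted L0 windows as positives and other
non-edge windows as negatives, then stratified-subsamples to 5,000 windows
at ~2% positives (4,000 train / 1,000 held-out test), echoing the extreme
imbalance of repeat-level data; 50 decoys feed the specificity check.
These sizes are the package's benchmark conditions and are what the
acceptance checks run.

What passing these checks shows — and does not. The generator plants
motifs whose signal lives exactly where the method looks, with conditional
independence between positions given the motif; real repeats have
correlated irregularities, alignment artefacts that shift profile columns
by 1–3 residues (the dominant error mode on real chains, which is why
`evaluate_predictions()` supports an offset tolerance), phylogenetic
dependence between chains, and insertion "islands" that no generator
parameter reproduces. Recovery and specificity on the benchmark validate
the machinery end to end; they do not certify real-data accuracy.

## Known limitations

* Scoring every position of every chain with eight members is deliberate
  but slow; the method is not meant for database-scale scans.
* Edge positions (first 5, last 10 residues) are never scored, so repeats
  starting hard against a terminus are reported as `NA`, not called.
* The ID50/cross-redundancy filters reproduce published retained counts
  only up to the aligner; a different local aligner or gap model shifts
  borderline pairs.
* The Kobe–Kajava class matcher evaluates published consensus strings
  literally; it does not learn class boundaries from data.
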