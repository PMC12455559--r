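---
title: "petscreen: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petscreen: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petscreen)
```

`petscreen` implements the computational side of an iterative,
machine-learning-guided screen for PET hydrolases: profile-HMM homology
scoring with condition-specific tuning, supervised activity prediction
under pooled cross-validation, multi-objective candidate selection,
plate-assay and melt-curve processing, and per-residue statistics that
contrast acid-tolerant with neutral-only-active enzymes.  This vignette
documents the models, the tunable parameters, what the synthetic world does
and does not emulate, and the choices made where the design was genuinely
open.

## 1. Profile HMMs

A profile HMM with `L` match states is built from an alignment of active
enzymes.  Columns with gap fraction at most `match_gap_threshold` (default
0.5) become match states; all other columns feed insert states.  Emissions
are residue counts plus a Laplace pseudocount `alpha` (default 1) over the
20-letter alphabet; a background-weighted pseudocount is not needed because
the default background is uniform (1/20), which also makes closed-form
checks exact (a single match state emitting one residue with probability 1
scores exactly `log2(20)` bits on that residue).  Transitions are counted
from each row's implied state path with a pseudocount of 1 on every allowed
transition (`M->{M,I,D}`, `I->{M,I}`, `D->{M,D}`); the rare implied `I->D`
and `D->I` moves, which this transition family excludes, are folded into
`I->M` and an uncounted emission respectively.  Sequence weighting is not
applied; rows contribute equally.

Scoring is log-odds against the background, by the forward algorithm in log
space; bit scores are `log2 P(seq|model)/P(seq|background)`.  Two modes
exist:

* **global** — the entire sequence is emitted by the model.  All closed-form
  and path-enumeration tests run in this mode.
* **uni-local** (default) — entry is uniform over match states (weight
  `1/L`), exit is free from any match state, and flanking residues are
  emitted at background (zero log-odds).  This is the mode used for real
  scoring because library enzymes carry accessory domains that should not
  be penalized.  The score is a log-odds sum over subsequence alignments,
  not a normalized probability; it is used for ranking and for locating the
  catalytic span (Viterbi), never as a probability.

`X` emits with background probability everywhere, so it is score-neutral.
Viterbi ties break deterministically `M > D > I`.

**Tuning.** `tune_hmm(base, new)` re-aligns the union from scratch by
default and rebuilds the profile; with `method = "map"` new sequences are
instead Viterbi-aligned onto the existing architecture and appended as
rows.  Re-alignment is the default because the tuned set is small (tens of
sequences) and a fresh alignment avoids freezing early architecture
mistakes; mapping is provided for large bases where the architecture should
stay fixed.

## 2. Alignment and trees

Pairwise alignment is global Needleman–Wunsch–Gotoh with affine gaps
(BLOSUM62, gap open −11, extend −1, the community-standard parameters); a
gap of length *k* costs `open + (k-1) * extend`.  Multiple alignment is
progressive: a UPGMA guide tree on MUSCLE-style shared-k-mer distances
(k = 3), then profile–profile merges with occupancy-weighted expected
BLOSUM62 column scores.  There is no iterative refinement; the recovery
test (≥ 90 % of true residue pairs at 0.1 substitutions/site) bounds what
the aligner is trusted for.

Pairwise identity divides identical aligned positions by the length of the
**shorter** sequence (standard for redundancy filtering, and insensitive to
accessory-domain length differences); `'X'` never counts as identical.  The
alignment-length denominator is available via an argument.  The greedy
redundancy filter scans candidates in input order — deterministic, and the
order-dependence is intentional (earlier candidates have priority).

Distance trees use `1 − identity` on the gap-stripped alignment (columns
with > 50 % gaps removed, so accessory domains do not distort distances)
and neighbor joining — the standard greedy heuristic for minimum evolution —
with leaf labels sorted before joining so ties resolve deterministically.

## 3. Assay processing

Product quantification inverts Beer–Lambert at 260 nm:
`umol = max(0, A260 − blank) * dilution / (epsilon * path) * volume`, with
defaults ε = 17 mM⁻¹cm⁻¹, path 1 cm, volume 0.5 mL, dilution 10.  These
constants are configuration, not assertions: with them, the 0.05-absorbance
activity call corresponds to ≈ 3 µmol product per mg enzyme at the 5 µg
loading.

The activity call is `A260 ≥ blank + 0.05`, inclusive at the boundary (a
small numeric tolerance keeps the inclusive boundary exact under floating
point).  Replicate wells are **averaged before** the call and the
quantification; the "either replicate" rule is a configuration away but is
not default because averaging is the usual plate-reader convention.  Blanks
are matched per (substrate, pH, temperature).

pH optimum is the pH of the maximum specific activity, ties broken toward
lower pH (the screen targets low-pH performance, so a tie should not be
reported as neutral).  Contingency tables exclude enzymes not tested at
both values of the contrasted axis and marginalize activity over the other
axes; the three cells therefore sum to at most the co-tested count.

**Tm extraction.** The DSF trace is smoothed with a centered moving average
(window 11 points ≈ 5.5 °C on the 0.5 °C grid), differentiated, and the
derivative smoothed again (window 5).  Local maxima qualify if they reach
25 % of the tallest peak *and* five times the median absolute derivative
(the noise floor); the **highest-temperature** qualifying maximum is the
reported Tm, matching the convention of reporting the highest unfolding
transition.  Flat or featureless curves return `NA` rather than an error.
The windows were chosen so that a two-state sigmoid with 2 % amplitude
noise is recovered within 1 °C in ≥ 95 % of draws, and a pure-noise trace
triggers the floor.

## 4. Predictors and evaluation

Cross-validation uses 5 random folds.  All metrics are computed over
**pooled out-of-fold predictions** rather than averaged per-fold metrics,
because some conditions have very few actives and a per-fold AUROC would
often be undefined; no example is ever predicted by a model that saw it in
training.  AUROC is the rank-based Mann–Whitney statistic with half credit
for ties, so `auroc(s, y) + auroc(s, 1−y) = 1` holds identically.
Precision uses the 0.5 decision boundary (strictly above = positive) and is
`NA` when no positive predictions exist.

Two model specifications ship with the package: a bagged ensemble of 100
CART trees (Gini splits, `sqrt(p)` features per node, probability = the
fraction of trees voting active) and an L2-penalized logistic regression
(glmnet, fixed lambda).  Any object with `fit`/`predict` members can be
plugged in.  Built-in features are k-mer composition blocks (explicit, each
block summing to one), sequence length, profile-HMM bit scores, and
optionally an external embedding table (id → vector), which stands in for
language-model embeddings that are out of scope here.

`condition_predictor_experiment()` packages the three-way comparison at one
assay condition: a base HMM built from a held-out "known hydrolase" set;
per-fold tuned HMMs (base + condition-active training enzymes), with each
fold's scores normalized by a reference enzyme's bit score so they pool
across folds; and a supervised model trained per fold on length plus the
base and fold-tuned bit scores.  The compact feature set is the default
here because at screen scale (~150 training examples) wide k-mer blocks
dilute the informative score features; the k-mer blocks can be switched on
with `kmer_k`.

## 5. Selection rules

Round-2 style selection keeps candidates that are the argmax of any single
score **or** at or above the 50th percentile in all three (activity, Tm,
acid tolerance), then applies the greedy identity filter at 90 % against
known sequences and already-retained candidates.  Percentiles are computed
over the candidate pool itself with linear interpolation — the only
self-contained reading.  "Maximized any individual score" is read as the
global argmax per score (a top-N variant would be a trivial extension).
Round-3 style selection keeps `activity ≥ 10` (in the assay's µmol/mg
unit; the threshold is fully configurable and the unit is a convention, not
a law) and `Tm > 55 °C` **strictly**, then filters identity at 95 %.

## 6. Group analysis

Active enzymes are split into an acid group (positive call at pH 4.5) and a
neutral group (active, tested at 4.5, not active there); actives never
tested at 4.5 are excluded — they cannot be classified either way, which is
why a screen's grouped count is smaller than its total active count.

Per-position property tests are two-sided Mann–Whitney U: exact p by full
enumeration of group assignments for combined n ≤ 12 (enumeration handles
ties naturally), tie-corrected normal approximation with continuity
correction otherwise; all-tied data give p = 1.  **No multiple-testing
correction is applied by default** — this mirrors the screening practice of
treating p < 0.05 positions as candidate factors and validating them
downstream; a Benjamini–Hochberg option exists.  The permutation-null
calibration test keeps the realized false-positive rate at the nominal 5 %.

Differential conservation flags (column, class) pairs with class frequency
≥ 0.9 in one group and ≤ 0.5 in the other, over a fixed residue-class
taxonomy (hydrophobic, aromatic, aliphatic, polar, positive, negative,
charged, small, proline/glycine); gaps count as not-in-class.

An enzyme *exhibits* a factor when its value is strictly closer to the
acid-group mean than to the neutral-group mean; equidistant or missing
values do not count, so factor counts are conservative.  The factor-count
versus activity correlation (Spearman, average ranks) is computed over
enzymes with measurable activity — including never-active enzymes would mix
the "has the determinants" question with the unrelated "expressed and
folded" one.

Accessory (non-catalytic) domains are the residues outside the uni-local
Viterbi span against the catalytic-domain HMM, kept if at least 40 residues
(shorter flanks are linkers/tags), and clustered by single linkage at 35 %
identity — permissive thresholds chosen because accessory modules diverge
faster than catalytic domains; both are configurable.

## 7. The synthetic world

The generator emulates the *structure* of a modern high-throughput PET
hydrolase screen so that every downstream stage has a recoverable answer:

* ~212 enzymes with round-labelled ids (`DP`, `TEP`, `ESM`); round 1 (`DP`)
  is tested at pH 5.5–8.5, later rounds at 4.5–7.5, which exercises the
  "not tested at both conditions" exclusion rules downstream.
* A 250-residue catalytic domain evolved from a random root along a star
  phylogeny (per-site substitution probability `1 − exp(−rate)`, default
  rate 0.35; sparse indels).  Acid-prone enzymes descend from a shared
  subfamily root carrying 0.04 substitutions/site of common divergence —
  condition-specific actives cluster phylogenetically, which is what gives
  HMM tuning something real to learn.
* Acid propensity is the logistic of the accessory-domain indicator plus
  standard-normal noise, thresholded at zero (intercept −0.6, accessory
  log-odds 2.5).  Nine planted alignment columns are then written with
  their configured residue class at conditional probability 0.95 given acid
  propensity versus 0.30 otherwise, so the configured enrichments are
  realized exactly in the sequences.  The acid-tolerant *flag* is the
  conjunction of being active and acid-prone.
* Overall activity is a coin with log-odds raised by 1.5 for accessory
  carriers (a binding module helps measurable activity), by default
  *decoupled* from the planted acid columns: generic activity and
  condition-specific tolerance are separate axes, as in a real screen where
  the base HMM of known actives is uninformative about the acid condition.
* Latent activity at a condition is
  `active * Amax * phresp * tempfac * subfac` with `Amax` lognormal
  (median 30 µmol/mg), a Gaussian pH response of width 1.0 around the
  optimum (5.0 for acid-prone, 7.5 otherwise, spread 0.15) **zeroed beyond
  2.5 pH units** — activity collapses once catalytic protonation states are
  lost, and without the hard cutoff lognormal outliers at 3 pH units from
  their optimum would smear the group boundary; a soft exponential penalty
  above `Tm − 5 °C`; and substrate factors (crystalline powder 1.0,
  amorphous film 0.3, reproducing the powder-dominant contingency
  pattern).
* Wells: `A260 = blank + c * specific_activity * mg + N(0, 0.005)`, with
  `c` the inverse of the quantification formula; 0.005 AU is typical
  replicate precision of a UV plate reader (the replicate-noise
  distribution is not specified by any source; this is the package's
  choice, made once).  Yield tiers (lognormal, thresholds 200/100 µg) give
  32-condition duplicate coverage, 8-condition, or 4-condition coverage.
  Melt curves are two-state sigmoids at the true Tm (occasionally with a
  lower secondary transition) plus 2 % noise.
* Property tables (pKa, hydrophobicity, electrostatics, stickiness) carry
  planted acid-vs-neutral shifts at specific columns — including −0.37 pKa
  at the catalytic-histidine column, +0.26 at the catalytic aspartate, and
  +1.5 at the serine-adjacent histidine — plus unshifted decoy columns for
  false-positive accounting.

**What a green test does not establish.**  The world is a statistical
caricature: there is no interfacial kinetics, no polymer physics, no
correlated property structure along the chain, no expression biology (yield
is independent of sequence), and residue substitution is uniform rather
than BLOSUM-biased.  Recovery tests validate the *pipeline's logic* —
calls, splits, tests, tuning, pooling — not any claim about real PET
hydrolase biochemistry.

## 8. Numerical choices and degenerate inputs

* Forward/Viterbi run in natural-log space with exact `-Inf` handling;
  emission and transition logs are precomputed once per call.
* Alignment DPs store explicit backpointers (no traceback-by-recomputation).
* Empty sequences, absent reference rows, zero-match-column alignments,
  `k > n` folds, single-class AUROC inputs, and monotone-flat melt curves
  raise errors or `NA` exactly as documented in each function.
* Identical seeds give byte-identical worlds, assays and pipeline reports;
  model fitting seeds derive from the master seed plus the fold index.

## 9. Known limitations

* The uni-local HMM score is a ranking score, not a calibrated probability;
  no E-values are computed.
* The progressive aligner has no refinement pass and will not match MAFFT
  or MUSCLE on hard alignments; its guarantees are only those in its tests.
* `cross_split_identity` is quadratic in library size (exact pairwise
  alignments); use it diagnostically, not in loops.
* The bagged-tree classifier is a minimal CART forest (no OOB estimates,
  no importance measures).
* Pipeline orchestration currently requires synthetic mode; the stage
  functions themselves accept external data through the documented file
  formats.
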