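---
title: "Predicting MoRFs from relative local conservation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MoRFs from relative local conservation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morfscan)
```

## The problem

Molecular recognition features (MoRFs) are short segments — roughly 5
to 25 residues — inside intrinsically disordered protein regions that
fold upon binding a partner molecule.  They are functionally critical
(signalling, regulation, disease-associated interactions) yet hard to
spot: a disordered region evolves quickly, so the absolute conservation
signal that identifies functional sites in ordered proteins is diluted.
What survives is *relative local* conservation: a MoRF tends to be more
conserved than the residues immediately around it, while mixing highly
conserved and highly variable positions internally.

`morfscan` classifies every residue of a protein as MoRF or non-MoRF
using only the protein's position-specific scoring matrix (PSSM) — the
N x 20 integer log-odds matrix produced by an iterative profile search
(e.g. PSI-BLAST against a large sequence database).  No predicted
disorder, secondary structure, accessibility or B-factors enter the
feature set.

## The transformation chain

Let $C_i$ denote a PSSM score at position $i$ (each of the 20 columns
is processed independently).

**Masking** converts absolute into relative local conservation by
subtracting the windowed local mean,

$$\mathrm{Masking}\_C_i \;=\; C_i - \frac{1}{2n+1}\sum_{j=i-n}^{i+n} C_j ,$$

with masking-window size $2n+1 = 25$ by default.  At the termini the
window is truncated to existing positions and the mean divides by the
actual count; a fixed $2n+1$ denominator is only meaningful for full
windows, and zero-padding here would bias the local mean toward zero
exactly where coverage is thinnest.

**Filtering** zeroes everything at or below the local average,

$$\mathrm{Filtering}\_C_i = \max(\mathrm{Masking}\_C_i,\, 0),$$

so only above-local-average (strongly locally conserved) signal
survives.

**Smoothing** propagates each retained score to its neighbours by a
windowed *sum* (not mean) over $2m+1 = 13$ rows,

$$\mathrm{Smoothing}\_C_i \;=\; \sum_{j=i-m}^{i+m} \mathrm{Filtering}\_C_j ,$$

with $m$ all-zero rows appended conceptually at each end so the output
keeps N rows.  Because MoRF residues occur in runs, summation
concentrates mass where conserved positions are dense and suppresses
isolated noise.  Smoothing operates on the *filtered* matrix in the
full chain; the smoothing-only ablation encoder applies it directly to
the raw matrix, which is why smoothed matrices carry no sign
constraint.

**Scaling** divides by a single global constant and clips into
$[-1, 1]$.  The constant is the maximum absolute value observed across
all *training* matrices after the encoder's transformation chain, and
it is stored in the model artifact and reused verbatim at prediction
time.  A per-protein ratio would make train and test feature spaces
incomparable, which is why a global divisor was chosen; clipping (rather
than re-normalising) keeps a test-time outlier from rescaling everyone
else.

Four encoder modes support ablation: `raw` (scaled standard PSSM),
`mask_only`, `smooth_only` and `mfs` (mask, filter, smooth — the full
chain and the default).

## Classification

Each residue is encoded by concatenating the $2h+1 = 25$ transformed
matrix rows centred on it (500 features), zero rows standing in beyond
the termini — consistent with the zero-padding of smoothing, and neutral
in the scaled space.  An RBF-kernel C-SVM (via `e1071`, i.e. libsvm)
is trained on all MoRF residues plus an equal number of uniformly
down-sampled non-MoRF residues (the down-sampling ratio is a parameter;
1:1 is the default).  `grid_search()` offers the standard
powers-of-two grid over cost and kernel width with stratified, seeded
k-fold cross-validation scored by balanced accuracy.  Binary calls use
threshold 0 on the signed decision value; the threshold is stored in
the model so calls are always `score > threshold`, never a second code
path.

Window defaults (masking 25, smoothing 13, outside window 25) follow
the sizes at which cross-validated accuracy plateaus in this design;
all are exposed as parameters and must be odd so windows are centred.
The smoothing window size itself must be odd; no oddness is imposed on
$m$.

## Evaluation

Per-residue evaluation pools all residues of a test set (it does not
average per protein): sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, FPR, plain accuracy, and the balanced accuracy
$ACC = (\text{sensitivity} + \text{specificity})/2$.  Metrics with a
zero denominator are reported as `NA` with a warning rather than forced
to zero.  ROC curves sweep every distinct score (ties grouped into one
vertex), are anchored at (0,0) and (1,1), and AUC is the trapezoidal
integral — equal to the probability that a random positive residue
outscores a random negative one, ties counting one half.  The test
suite checks this equivalence against a pair-counting oracle and
against an independent ROC implementation.

## Region composition analysis

For a flank length $W$, every residue is tagged MoRF (inside an
annotated interval), flank (within $W$ of an interval boundary but
inside none), or general non-MoRF (everything else — deliberately
*excluding* the flanks, so flank enrichment is measured against a
clean background).  Compositions are pooled across proteins;
physicochemical composition uses ten overlapping property groups
(hydrophobic, polar, small, proline, tiny, aliphatic, aromatic,
positive, negative, charged) with Taylor-classification memberships by
default, configurable via TSV.  `difference_curve()` tracks
composition(flank) − composition(non-MoRF) across $W$ (default sweep
1–30), and `flank_correlation()` reports the Pearson correlation of
each feature's difference with $W$, with its two-sided t-based
p-value, via `stats::cor.test`.

## The synthetic generator

Real MoRF benchmarks require externally distributed datasets and
PSI-BLAST profiles computed against a large sequence database, so the
package ships a seeded generator that plants the *mechanism* the
predictor exploits and nothing else:

- chains of 60–200 residues with one or two MoRFs of 5–25 residues
  (the short-MoRF length class); real benchmark chains average several
  hundred residues, but desk-scale chains keep the full train/test
  cycle in seconds without changing the local structure of the signal;
- each position is "conserved" with probability 0.7 inside MoRFs
  versus 0.15 outside — conservation *density*, not uniform
  conservation, is the planted contrast, so MoRFs still contain
  variable residues;
- a conserved position scores ~N(7, 1) in its own residue's column and
  ~N(−2±1, 1) elsewhere; a variable position is i.i.d. ~N(−1, 1); all
  scores are rounded to integers and clipped to [−10, 12] so fixtures
  and genuinely parsed PSSMs exercise identical code paths.  The
  variable-position spread of 1 was chosen analytically: the noise
  mass that survives mask+filter grows as $20\,\sigma\,\varphi(0)$ per
  background row, and spreads much above 1 would bury the conserved
  columns' retained signal, destroying the very contrast the generator
  exists to plant;
- every protein receives a random integer baseline offset (~N(0, 2))
  added to all its scores, emulating between-protein differences in
  absolute conservation level (alignment depth, evolutionary rate).
  Relative local conservation is exactly invariant to this offset;
  absolute scores are not.  This is the nuisance masking is designed
  to remove, and without it synthetic data would be unrealistically
  kind to the raw-PSSM encoder;
- optionally (`flank_bias`), flank letters are biased toward the
  disorder-promoting set A, G, E, S, T to emulate the composition
  contrast of real flanking regions; this is off by default because
  the predictor consumes matrix values only.

Because conserved rows carry one high score against nineteen low ones,
their *row sums* are lower than variable rows' — so on raw matrices
MoRF residues sit at an absolute-conservation disadvantage, and after
mask → filter → smooth their summed local conservation clearly exceeds
the background's.  The generator therefore reproduces the qualitative
distribution shift across the transformation chain, and a model
trained on 60 simulated proteins recovers planted MoRFs on 20 held-out
proteins with pooled AUC well above chance, the full chain beating the
raw encoding.

What passing these tests does **not** show: performance on real
proteins.  The generator has i.i.d. conservation within regions, no
real evolutionary correlation structure, no immune-response or
binding-partner biases, and its composition signal is optional and
crude.  Synthetic results validate the machinery, not the biology.

## Numerical and degenerate-input choices

- Masking/smoothing are O(N) per column via cumulative sums; the test
  suite checks them against explicit double-loop oracles including
  termini.
- Stage tags travel with every matrix; each operation validates its
  input stage, so the chain cannot be silently mis-ordered.  Raw
  matrices must be integer; filtered matrices non-negative; scaled
  matrices within $[-1, 1]$.
- Residues outside the 20-letter alphabet are rejected or mapped to X
  per configuration; X rows simply carry whatever scores the PSSM
  provides (all zeros when absent) and X is excluded from composition
  denominators.
- An all-zero training set resolves the auto scale divisor to 1 rather
  than dividing by zero.
- Empty regions, constant correlation series and single-class label
  vectors produce explicit `NA`s or errors, never silent zeros.

## A worked run

```{r example, eval = FALSE}
library(morfscan)

train <- simulate_proteins(simulation_config(n_proteins = 60, seed = 101))
test  <- simulate_proteins(simulation_config(n_proteins = 20, seed = 202))

model <- fit_morf_predictor(train, transform_config(encoder_mode = "mfs"),
                            seed = 7)
preds <- do.call(rbind, lapply(test, function(p) predict(model, p)))
truth <- unlist(lapply(test, morf_labels))
evaluate_predictions(preds, truth)
```

## Limitations

- The PSSM must be supplied (or simulated); running the profile search
  itself is out of scope, though any PSI-BLAST ASCII matrix parses
  directly.
- No alternative conservation measures (entropy, Jensen–Shannon), no
  per-column normalisation schemes, and no features beyond the matrix.
- The decision threshold is the SVM's natural 0; operating points at
  other FPR levels should be read off the ROC curve rather than by
  re-thresholding calls.
- Training at genuine benchmark scale (hundreds of chains, ~250k
  residues) is supported by the code but not exercised by the tests,
  which run at desk scale.
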