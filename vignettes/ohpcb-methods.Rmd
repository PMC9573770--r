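---
title: "Methods: structure-based identification and quantification of OH-PCB metabolites"
author: "ohpcb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based identification and quantification of OH-PCB metabolites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

PCBs are metabolized to hydroxylated congeners (OH-PCBs), measured by
GC-MS/MS as methylated derivatives (MeO-PCBs). There are 837 possible
mono-hydroxylated congeners but only a few dozen authentic standards, so
most metabolite peaks cannot be matched against a standard. This package
predicts, from structure alone, the two observables the instrument
measures for every peak — the relative retention time (RRT) and the
relative intensities of five MRM transitions (the MS/MS profile) — and
uses them to rank candidate structures for unknown peaks and to convert
peak areas into concentrations.

## Structures and symmetry

The substitutable biphenyl positions are 2-6 and 2'-6'. The numbering
symmetry group has order eight: flip either ring about the inter-ring
axis (2<->6, 3<->5) and exchange the rings. Every structure is stored in
a canonical orientation: the chlorine pattern takes the representative
with most chlorines on the unprimed ring and the lexicographically
smallest locant sequence under the order 2 < 2' < 3 < 3' < ... < 6',
which reproduces the Ballschmiter-Zell (BZ) congener representatives.
Congeners sorted by chlorine count and then by locant sequence receive
BZ numbers 1-209; a three-entry exception table fixes the historical
numbering irregularity at PCB 107-109, where the accepted list deviates
from the strict ordering rule. The enumeration is regression-tested
against twenty accepted congener assignments and an independent
brute-force canonicalization oracle.

Metabolite candidates for a parent congener come in three classes:
direct OH insertion at free positions, NIH 1,2-shift products (a
chlorine moves to an adjacent free position on the same ring and the
hydroxyl takes the vacated position, changing the congener number), and
di-hydroxylation. By default the di-OH class is limited to pairs that
are ortho (catechol) or para (hydroquinone-like) to each other, the
metabolically plausible products; `fullDiOh = TRUE` enumerates all free
pairs. When the same structure arises from two classes, the
first-listed class (direct < shift < di-OH) is recorded as provenance.

## Descriptor registry

The predictor matrix concatenates two families and is frozen under a
registry version:

* *Chemoinformatic* (77 descriptors, computed from the molecular graph
  parsed out of the SMILES by OpenBabel): constitutional counts,
  molecular weight (monoisotopic), topological indices (Wiener, Harary,
  Zagreb, Platt, Balaban J, Schultz, eccentric connectivity, radius /
  diameter / Petitjean, simple and valence connectivity chi 0-3, Kier
  kappa 1-3 and flexibility), Moreau-Broto autocorrelations (lags 0-5)
  and Moran autocorrelations (lags 1-3) over atomic mass,
  electronegativity, polarizability and van der Waals radius, and
  additive sums (topological polar surface area, an additive
  hydrophobicity score, molar refractivity). All values depend only on
  the molecular graph, so symmetry-equivalent SMILES give identical
  vectors.
* *Substitution-pattern* (31 descriptors, computed from the canonical
  structure record): per-position chlorine indicators, chlorine counts
  total / per ring / per ortho-meta-para class, counts of chlorines
  ortho, meta and para to the methoxy groups on the same ring,
  class-resolved counts on the opposite ring, substituent class
  indicators, flanking-chlorine count, chlorine-chlorine adjacency,
  longest chlorine run, and the ortho-ortho' chlorine pair count that
  controls the biphenyl twist.

Cleaning is deterministic and logged: drop columns with missing values,
zero variance (skipped with a warning for a single row), or exact
duplication of an earlier column. Missing values are never imputed; a
column either survives intact or is dropped.

## Retention-time model (MLR)

The protocol runs in a fixed order: clean the matrix, select predictors
by bidirectional stepwise AIC starting from the full cleaned set, screen
outliers by Cook's distance on the selected-predictor fit (an
observation is removed when CD >= 10 x mean CD), then refit with
repeated 10-fold cross-validation (5 repeats; a single integer seed
controls fold assignment). The reported coefficient set is the one from
the fold fit with the least held-out RMSE; across-fold standard
deviations are kept as coefficient deviations, and that same fold fit
backs the 95% prediction intervals through the linear-model predictive
distribution.

Two numerical guards matter in practice. First, when the descriptor pool
is not smaller than the observation count, the stepwise start is
pre-screened to the floor(n/2) descriptors most correlated with the
response so the full starting model has residual degrees of freedom.
Second, the Cook's-distance screen should be run on a compact fit:
heavily overparameterized screening fits push leverages toward one,
which inflates the mean Cook's distance and desensitizes the 10 x mean
cutoff. The pipeline applies the screen after AIC selection for exactly
this reason; the order of selection and screening is a design choice of
this package, fixed and documented rather than inherited.

Response factors are modelled on the log10 scale (`logTransformRrf`),
which normalizes their right-skewed distribution; all RRF errors are
reported in log10 units.

## Response-factor models (RFR)

Per transition, descriptors are selected by an importance vote: 100
random 2/3 splits, a forest fitted on each, the top six descriptors by
permutation importance recorded, and descriptors with strictly more than
50 votes kept. Permutation importance (decrease in accuracy) is used
rather than impurity importance because it is more stable on correlated
descriptors. The vote-threshold semantics are strict (> minVotes), and
the null behaviour is calibrated by the pool width: with top-6 votes
over p descriptors the expected null vote count is 6/p x iterations, so
thresholds near iterations/2 are only meaningful for pools comfortably
wider than a dozen descriptors.

ntree (100-1000 by 100) and mtry (1 to the number of predictors) are
tuned by exhaustive grid search on out-of-bag RMSE; one forest per mtry
at the maximal tree count supplies the exact out-of-bag error at every
smaller tree count, so the full grid costs p forest fits rather than
10p. Ties go to the smaller ntree, then the smaller mtry. The final
forest is grown from a stored seed, making the ensemble and all its
predictions exactly reproducible; intervals come from the 2.5% and
97.5% quantiles of per-tree predictions.

## Transitions, similarity and ranking

The MRM precursor is the nominal m/z of the most abundant chlorine
isotopologue of the methylated molecular ion: formula
C(12+k)H(10-n+2k)Cl(n)O(k) for n chlorines and k methoxy groups, with
the isotopologue taken from the binomial 35Cl/37Cl distribution
(0.7576/0.2424; ties to the lower m/z). Products are the precursor minus
the neutral losses 15, 30, 43, 50 and 66. Profile similarity is the
cosine between five-vectors; values within 1e-12 of the exact limits 0
and 1 are snapped to those limits so the identity and orthogonality
properties hold exactly.

Candidates are ranked by the weighted rank score
`w_rrt * rank(|dRRT|) + w_msms * rank(1 - cos theta)` with default
weights (1, 1). Rank-based combination was chosen over raw-value
combination for scale freeness: retention deviations (dimensionless RRT)
and cosine distances live on incommensurate scales. Ties in the score
break towards the higher cosine, then the smaller retention deviation.
Position classification from a profile compares the loss-50 and loss-43
responses (ortho when loss-50 dominates); an exact tie classifies as
meta/para with a warning — an arbitrary, documented rule.

## Quantification

RRT and RRF follow the standard internal-standard conventions
(`rt / rt_IS` and `(area/area_IS) / (conc/conc_IS)`); the reference
compound and its record (name, retention time, response, concentration,
units) are configuration, since screening studies use
laboratory-specific internal standards. Quantification inverts the RRF
definition exactly, using the loss-50 transition for all-ortho and
loss-43 for all-meta/para methoxylation; di-methoxy structures mixing
the two classes are excluded and flagged. Concentration units pass
through from the internal-standard record (ng/mL or ng/g).

## The synthetic-data generator

The generator stands in for a measured standard set and defines the
package's study conditions; its defaults are fixed:

* 124 standards, about one fifth dihydroxylated — the size of a
  realistic MeO-PCB standard library.
* RRT rule: linear in registry descriptors with intercept 0.15 and
  coefficients on chlorine count (0.05), the Wiener index (0.001 — the
  classic QSRR topological term; it also separates close isomers that
  tie on positional counts), and positional features (ortho chlorines
  -0.06, ortho-ortho' pairs -0.05, para/meta substituent class
  +0.15/+0.08, flanking chlorines -0.08, para-related same-ring
  chlorines +0.06, opposite-ring chlorines +0.025, substituent count
  +0.05). The coefficient scale yields a within-homolog isomer spread of
  several minutes at the 25-minute reference — the spread that makes
  isomer ranking by retention informative on apolar columns.
* RRF rules: per-loss log10-linear with an ortho contrast of 1 log10
  unit (loss 50 up, loss 43 down for ortho methoxy), an
  ortho-by-chlorination interaction and flanking-chlorine terms for the
  chlorine-involving losses. The interaction is deliberately absent from
  the descriptor registry so that forests outperform linear models on
  response factors while the linear retention rule favours MLR — the
  asymmetry the package's model comparison is designed around.
* Noise: sigma 0.02 RRT units on retention (about half a minute at the
  reference — the scale of model lack-of-fit for retention
  prediction), 0.2 log10 units on training response factors, and 0.05
  log10 units of replicate-level area noise in simulated sample runs.
  An optional outlier fraction shifts retention responses by ten noise
  standard deviations for influence-screen testing.
* A generation-time normality screen (Shapiro test on the injected
  noise) warns if the residual structure ever stops matching the
  models' assumptions.

Identical specs generate byte-identical data; all randomness flows from
the single integer seed.

What the generator does *not* emulate: coelution and peak-integration
error, isotope-pattern noise, detector saturation, matrix effects,
between-batch retention drift, and any systematic chemistry the
descriptor registry cannot express. Synthetic tests therefore
demonstrate that the machinery is correct and well-calibrated under its
own assumptions — recovery of generating coefficients in the noiseless
limit, nominal interval coverage, signal-descriptor recovery, top-3
identification and 2-fold quantification at the stated noise levels —
not that those accuracies transfer to any particular instrument. For
measured data, `reproduceValidation()` re-runs the full training
protocol on a user-supplied standards table and reports the same metric
blocks (cross-validated retention metrics, per-transition RRF MAEs in
log10 units, the cosine-similarity distribution, and fold-difference
statistics); those numbers are data- and split-dependent.

## Problem sizes and seeds used by the test suite

The suite trains one shared fixture (124 synthetic standards, seed 1;
30 voting iterations with a strict threshold of 15; tree grid
{200, 500}, seed 2) and reuses it across model, ranking and
quantification tests; identification uses sample-run seed 11 and
quantification seed 12 with 40 standards spanning 9-1048 ng/mL, three
orders of magnitude. Interval coverage is estimated on 1000 fresh
points. These sizes keep the suite's full run around a minute while
leaving every statistical check comfortably powered; the
reduced-iteration vote keeps the same selection behaviour as the
100-iteration default on the fixture's strong contrasts (the
100-iteration default is itself exercised in the planted-signal vote
test).

## Known limitations

* BZ numbering relies on the strict ordering rule plus the documented
  107-109 exception; any further historical quirks of the accepted list
  would need additional exception entries.
* The descriptor registry is this package's own frozen list. It is a
  reasonable superset of common QSRR practice for halogenated
  biphenyls, but models trained on it are not numerically comparable to
  models trained on other descriptor software.
* The di-OH candidate default (ortho/para pairs only) may include
  structures a specific metabolic system does not produce, and excludes
  meta-related pairs by design.
* Mixed ortho + meta/para di-methoxy structures cannot be quantified by
  the transition-selection rule and are flagged, not estimated.
* The weighted rank score is one defensible choice among several; the
  weights are configurable and the default (1, 1) treats retention and
  fragmentation evidence as equally informative.
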