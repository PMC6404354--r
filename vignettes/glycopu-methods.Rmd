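---
title: "Positive-unlabelled Bayesian prediction of glycosylation sites: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive-unlabelled Bayesian prediction of glycosylation sites: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycopu)
```

## The problem

Protein glycosylation attaches glycans to specific side chains: tryptophan
(C-linked), asparagine (N-linked), or serine/threonine (O-linked).
Experimentally verified sites give *positive* examples, but there are no
verified negatives: a residue not annotated today may simply not have been
assayed yet, and successive database releases reveal that a substantial
fraction of yesterday's "negatives" become positives. `glycopu` therefore
treats site prediction as a positive-unlabelled (PU) learning problem: each
candidate site carries an observed indicator $s \in \{1, 0\}$ (labelled
positive vs unlabelled), linked to the unobserved truth $y$ by the
*selected completely at random* (SCAR) assumption

$$P(s = 1 \mid x, y = 1) = c, \qquad P(s = 1 \mid x, y = 0) = 0,$$

with a constant labelling frequency $c$. Two consequences drive everything
in the package: the *nontraditional* classifier $g(x) = P(s=1 \mid x)$ is a
constant multiple of $P(y = 1 \mid x)$, and any marginal distribution is
the mixture $P(v) = \alpha P(v \mid y{=}1) + (1 - \alpha) P(v \mid y{=}0)$
with class prior $\alpha = P(y = 1)$, so negative-class quantities can be
recovered by mixture inversion without ever observing a negative.

## Feature extraction

Each candidate site is represented by a 15-residue window (seven residues
either side of the site); windows crossing a terminus are padded with the
unknown symbol `X`. Six descriptor groups are computed per window:

| group | features | notes |
|---|---|---|
| amino acid composition (AAC) | 20 | frequencies over non-`X` symbols |
| dipeptide composition (DPC) | 400 | ordered adjacent pairs |
| autocorrelation (normalized Moreau–Broto, Moran, Geary) | 3 × 240 | 8 z-scored property scales × 30 lags |
| composition–transition–distribution (CTD) | 147 | 7 three-class partitions |
| sequence-order (coupling numbers + quasi-sequence-order) | 60 + 100 | 2 distance matrices × 30 lags |
| pseudo amino acid composition (type I & II) | 50 + 50 | $\lambda_1 = 30$, $\lambda_2 = 15$ |
| AAindex positional encoding | 15 per index | z-scored property per window position |

Numerical conventions for degenerate inputs: `X` is excluded from all
composition counts, maps to 0 (the mean) in z-scored property encodings and
to distance 0 in the distance-matrix features; lags or tiers that meet or
exceed the window length emit 0, so every group's dimensionality is fixed
regardless of content; Moran/Geary denominators of zero (a property
constant over the window) emit 0 with a warning.

The lag bounds deserve a comment: with a 15-mer, lags above 14 are
infeasible, yet the conventional feature counts for these encodings (240
per autocorrelation kind, 60 + 100 sequence-order, 50 + 50
pseudo-composition) imply 30 lags. We keep the conventional
dimensionalities and emit structural zeros for infeasible lags rather than
silently shrinking the vectors. The same spirit applies to the descriptor
total: the commonly cited total of 9927 for this encoding set does not
equal the sum of its constituent group sizes (9947 with 560 AAindex
tables); this package reports its own exact total and documents the
discrepancy rather than fudging either number.

Two sourcing limitations are explicit design choices. First, a full
AAindex1 snapshot cannot be shipped here; the package vendors a 10-index
AAindex1-format subset (standard hydropathy, hydrophilicity, Grantham
composition/polarity/volume, molecular weight, isoelectric point,
polarizability, residue volume, side-chain mass) and accepts any full
AAindex1 file via `descriptor_config(aaindex_path = ...)`, which restores
the 8400-feature block (560 complete indices × 15 positions). Second, the
sequence-order descriptors require two amino-acid distance matrices; the
Grantham matrix is computed from Grantham's published composition/polarity/
volume table and quadratic form (it reproduces the published anchors
D(Leu, Ile) = 5 and D(Cys, Trp) = 215), while the second matrix is a
clearly labelled **synthetic stand-in** (`physchem_synthetic_distance()`):
Euclidean distance in the z-scored hydrophobicity/hydrophilicity/side-chain
mass space, scaled to [0, 1]. It plays the same structural role as the
Schneider–Wrede physicochemical distance, whose exact values are not
redistributable here.

## Preprocessing

The Bayesian learners are discrete, so continuous features are discretized
by equal-frequency binning (default 5 bins) with edges placed at midpoints
between order statistics; edges are fit on training rows only and applied
unchanged downstream ("value ≤ edge" falls in the lower bin). Feature
selection uses greedy mRMR in the MID (difference) form: the first feature
maximizes the plug-in mutual information $I(f; s)$ (natural log,
$0 \log 0 = 0$) and each next feature maximizes
$I(f; s) - \operatorname{mean}_{g \in \text{selected}} I(f; g)$, with ties
broken by ascending feature name. The labelling indicator $s$ serves as the
selection target, as it must in a PU setting. The number of bins, the MI
base and the mRMR variant are not fixed by the source method description;
these defaults are the conventional choices and are exposed in the
configuration.

## Class-prior estimation

Both estimators consume scores from a held-out validation split produced by
the nontraditional scorer (a naive Bayes model of $s$; self-contained and
deterministic).

**Elkan–Noto (e1).** $\hat c$ = mean validation score over labelled
positives; $\hat\alpha = \widehat{P}(s{=}1) / \hat c$, clipped to (0, 1].
Under SCAR with a calibrated scorer one can show
$\hat\alpha \to \alpha / E[P(y{=}1 \mid x) \mid y{=}1]$: the estimator is
exact for separable classes and *overestimates* in proportion to class
overlap. This bias is visible in the package's simulations and mirrors the
behaviour reported for this estimator elsewhere.

**AlphaMax (score-space).** Validation scores are histogrammed on 25 fixed
bins of [0, 1]. The unlabelled-score distribution is modelled as
$\alpha^* f_1 + (1 - \alpha^*) f_0$ with $f_1$ the labelled-positive
histogram (unsmoothed — see below) and $f_0$ a free nonnegative normalized
per-bin density. For each $\alpha^*$ on a grid (0.01–0.99, step 0.01) the
profile log-likelihood is maximized over $f_0$ in closed form by KKT
water-filling. The resulting curve is flat while the mixture is feasible
and bends downward beyond the true proportion; the estimate is the largest
$\alpha^*$ before the normalized curve's local slope exceeds 10% of its
mean decline rate (a knee rule fixed a priori). Two numerical choices
matter and were made deliberately:

* *No pseudo-count smoothing of $f_1$.* Smoothing leaks positive mass into
  bins where the unlabelled histogram is empty; that mass can never be
  matched, so the likelihood decreases from the very first grid point and
  the plateau that carries the signal disappears. The free $f_0$ already
  keeps the likelihood finite wherever unlabelled mass exists.
* *Slope-threshold knee rather than maximum second difference.* On these
  histogram profiles the curvature grows monotonically toward
  $\alpha^* = 1$, so a max-curvature rule degenerates to the grid boundary;
  the slope-departure rule recovers the plateau edge.

The in-mixture proportion is rescaled to the full dataset,
$\hat\alpha = (n_L + \alpha^* n_U) / n$. In the packaged simulations the
AlphaMax estimate is uniformly closer to the truth than Elkan–Noto
(median absolute error 0.02–0.06 vs 0.05–0.19 across
$\alpha \in \{0.1, 0.2, 0.3\}$, $c \in \{0.3, 0.5, 1\}$), reproducing the
qualitative ordering reported for the two estimators on real glycosylation
data. Pipelines clamp a collapsing prior at a floor of $10^{-4}$ with a
warning, making the "keep the prior estimate fairly low" regime of heavily
imbalanced pools operational.

## The PU Bayes family

For discrete attributes $x_1, \dots, x_k$ the averaged $n$-dependence
estimator scores

$$\text{score}(y) \;=\; \sum_{S \in \binom{A}{n}} \delta(x_S)\,
P(y, x_S) \prod_{m \notin S} P(x_m \mid y, x_S),$$

where $\delta(x_S) = 1$ iff the parent tuple $x_S$ occurs in training; if
every $\delta(x_S) = 0$ the model falls back to order $n - 1$, bottoming
out at naive Bayes ($n = 0$). PNB, PAODE and PAnDE are the $n = 0, 1, n$
members; "PA2DE (V2.0)" is PAnDE with $n = 2$ whose prior comes from
AlphaMax, plain PA2DE uses Elkan–Noto — that is the only difference. PTAN
replaces the parent sets with a Chow–Liu tree over conditional mutual
information $I(X_i; X_j \mid Y)$ computed from the derived class
conditionals (Kruskal, deterministic tie-breaks, root at attribute 1).

Estimation under PU proceeds per conditioning context: positive-class
tables come from labelled rows (SCAR makes them a random sample of
positives), marginal tables from all rows, and negative-class tables by
mixture inversion $P(v \mid 0) = (P(v) - a\,P(v \mid 1))/(1 - a)$ at the
raw-frequency level, where $a$ is the context-specific positive fraction
$\alpha P(\text{ctx} \mid 1) / P(\text{ctx})$. Sampling noise can push raw
inverted entries negative; they are clipped to $\varepsilon = 10^{-6}$ and
the context renormalized, with clip events counted. m-estimate smoothing
($m = 1$, uniform base) is applied *after* inversion, on derived pseudo
counts with effective sample size $n_{\text{ctx}}(1 - a)$. Ordering the
steps this way has a useful exact consequence: when the data are fully
labelled and $\alpha$ equals the empirical positive fraction, the inverted
negative counts equal the true negative counts and PNB reproduces a
standard supervised naive Bayes to floating-point precision — a property
the test suite asserts at $10^{-9}$.

The joint $P(y, x_S)$ under PU is not spelled out in the source
description; it is implemented as $\alpha P(x_S \mid y{=}1)$ and
$(1-\alpha) P(x_S \mid y{=}0)$ with the negative factor derived by the same
inversion. Ties at the 0.5 decision threshold predict positive
(the PU setting privileges recovering positives); smoothing constants and
tie-breaks are deterministic throughout.

Two properties discovered during development are worth recording. First,
posteriors cannot be exactly invariant to duplicating the training set
while $m > 0$ (the smoothing effect is $O(m/n)$); invariance is exact at
$m = 0$ and the suite asserts monotone convergence to the unsmoothed limit
as counts scale. Second, the test AUC of this family is nearly invariant to
the supplied prior: a ±50% misspecification of $\alpha$ moves the median
AUC by $\sim 10^{-3}$ at moderate separation, and an *overestimate* can
rank marginally better. The corresponding property test therefore asserts
the "true prior is not worse" comparison with a 0.002 noise margin.

The averaged-family scorer is implemented in C++ (the per-parent-set
counting and scoring is $O(\binom{k}{2} n k)$ at $n{=}2$, infeasible in
pure R at the default 100 selected features) and is validated against an
independent pure-R brute-force transcription of the score on 200 random
small models to $10^{-12}$.

## Evaluation protocols

Metrics are F1, accuracy and midrank Mann–Whitney AUC. The benchmark
protocol draws, per repeat, as many unlabelled rows as there are positives,
splits 50/20/30 into train/validation/test *stratified by* $s$
(stratification is a package decision: it prevents positive-free validation
sets that would break prior estimation), fits the discretizer, mRMR and the
scorer on the training split, estimates the prior on validation, merges
train+validation ("trainingV") and refits before evaluating on test;
means ± SD are reported over repeats (100 in the reference protocol;
examples in this package use fewer and say so). Five-fold cross-validation
stratifies folds by $s$ and estimates the prior on an internal 75/25 split
of each training part. A paired two-sided Student's t-test over repeats is
provided for learner comparisons (conventional threshold $p \le 0.01$).
Baseline adapters for RF, SVM and one-class SVM exist as thin wrappers and
fail with a clear message when their backing packages are absent — the PU
pipeline has no dependency on them.

## Synthetic data: what a green test establishes

`generate_scar()` draws $y \sim \text{Bernoulli}(\alpha)$, attributes
independently per class (uniform negatives; positives exponentially tilted
with alternating direction), and labels positives with probability $c$ —
SCAR holds by construction. The default separation 0.73 was calibrated
once, by simulating the Bayes-optimal AUC of the log-likelihood-ratio at
$k = 10$ ternary attributes, to give Bayes AUC ≈ 0.90: hard enough that
prior-recovery and learner tests are informative, not saturated. A
`dependence` switch makes even-indexed attributes copy their predecessor
with probability ½, giving the $n \ge 1$ learners structure to find.

`generate_proteins()` emits i.i.d. background-frequency sequences with
N-linked sequons (`N[!P][ST][!P]`) written in, annotates a fraction of
sequon occurrences positive and enriches the flanking window positions of
positives from a fixed residue set — a deliberately separable construction
so the end-to-end pipeline has recoverable signal. What these generators do
**not** emulate: real glycosylation data have no such clean positional
enrichment, exhibit homology between substrates (the reference pipeline
deduplicates at 30% identity before training), correlated sites within
proteins, and annotation dynamics that violate SCAR in unknown ways. A
green end-to-end test therefore establishes that the machinery is wired
correctly and can recover planted signal — not that comparable accuracy
will transfer to proteome data.

## Known limitations

* The Elkan–Noto estimator's overestimation under class overlap is
  intrinsic (see above); on the default synthetic world its median absolute
  error exceeds the 0.05 aspiration that holds only for near-separable
  data. The AlphaMax route is the recommended default for exactly this
  reason.
* The vendored AAindex subset (10 indices) stands in for the full database;
  totals and selections will differ from a run with a complete AAindex1
  file.
* PFBC (a full Bayesian network classifier with decision-tree conditional
  tables) is out of scope, as are the supervised/one-class baselines'
  internals.
* Model JSON serialization stores the discrete training matrix (the
  sufficient statistics) rather than expanded probability tables; at
  $n = 2$ and $k = 100$ the materialized conditional tables would be
  ~10^8 entries, while refitting from counts is deterministic and
  bit-stable.
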