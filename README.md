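# glycopu

Positive-unlabelled (PU) Bayesian classifiers for protein glycosylation
site prediction.

## The problem

Glycosylation attaches glycans to specific residues — tryptophan
(C-linked), asparagine (N-linked), serine/threonine (O-linked). Databases
record experimentally *verified* sites, but there are no verified
negatives: unannotated residues are merely unexplored, and a substantial
fraction of them turn positive in later database releases. Training a
conventional supervised classifier on "negatives" sampled from unannotated
residues therefore bakes label noise into the model. `glycopu` instead
learns from positives and unlabelled candidates only, under the *selected
completely at random* (SCAR) assumption: a true site is labelled with a
constant probability `c` independent of its features, so
`P(s=1|x) = c · P(y=1|x)` and every negative-class quantity can be
recovered by inverting the mixture
`P(v) = α P(v|y=1) + (1−α) P(v|y=0)`, where `α` is the class prior.

## What is inside

* **seqio** — FASTA and site-table I/O, 15-residue window extraction
  (`p1…p15`, site at `p8`, `X`-padded termini), `N[!P][ST][!P]` sequon
  classification, and annotation-snapshot comparison (`compare_snapshots`)
  that quantifies previously mislabelled negatives and the hindsight class
  prior.
* **descriptors** — AAC (20), DPC (400), normalized Moreau–Broto / Moran /
  Geary autocorrelation (3 × 240), CTD (147), sequence-order coupling +
  quasi-sequence-order (60 + 100), pseudo amino acid composition type I/II
  (50 + 50) and positional AAindex encodings (15 per index; AAindex1 reader
  included, small snapshot vendored).
* **preprocess** — equal-frequency discretization, plug-in mutual
  information, greedy mRMR (MID scheme, default top 100), and the
  20-per-protein / 10,000-cap unlabelled sampling protocol.
* **prior** — Elkan–Noto (e1) and a score-space AlphaMax estimator of the
  class prior `α` and labelling frequency `c`.
* **pubayes** — PNB, PAODE (=PA1DE), PAnDE (default n = 2 → PA2DE) with
  the order-reduction fallback for unseen parent tuples, and PTAN
  (Chow–Liu tree over conditional mutual information). "PA2DE (V2.0)" is
  PA2DE with the AlphaMax prior. The averaged-family scorer is implemented
  in C++ and validated against a brute-force transcription of the score.
* **evaluate** — F1/ACC/midrank AUC, the repeated 50/20/30
  randomization protocol with trainingV retraining, stratified k-fold CV,
  paired t-tests, and optional RF/SVM/one-class adapters.
* **synthetic** — SCAR generators with known ground truth and
  motif-bearing synthetic proteins, so everything above is testable
  offline.
* **cli** — `inst/cli/glycopu` with `simulate`, `extract-features`,
  `select-features`, `estimate-prior`, `train`, `predict`, `benchmark`.

## Worked example

Generate a synthetic world with motif-embedded positive sites, extract the
full descriptor set, and benchmark PA2DE (V2.0) under the randomized
50/20/30 protocol:

```r
library(glycopu)

sim <- generate_proteins(sequence_spec(n_proteins = 200, seed = 11))
unl <- sample_unlabelled(sim$proteins, sim$sites, "N",
                         per_protein = 20, cap = 10000, seed = 12)
sites <- rbind(sim$sites[, c("protein_id", "position")],
               unl[, c("protein_id", "position")])
feats <- extract_features(sim$proteins, sites)      # 1108 x 1697
s <- c(rep(1L, nrow(sim$sites)), rep(0L, nrow(unl)))

report <- randomization_protocol(
  feats, s, list(`PA2DE(V2.0)` = learner_spec()),
  n_repeats = 10, seed = 5, mrmr_k = 100)
print(report)
#> Evaluation report (randomization 50/20/30, 10 repeat(s))
#>   PA2DE(V2.0)  F1 0.921 ± 0.027  ACC 0.919 ± 0.028  AUC 0.977 ± 0.011
```

Per repeat, the protocol draws as many unlabelled sites as positives,
splits 50/20/30, discretizes (5 equal-frequency bins) and selects 100 mRMR
features on the training split, estimates `α` on the validation split with
AlphaMax, retrains PA2DE on train+validation and scores the test split.
F1/ACC treat the posterior ≥ 0.5 as a positive call against the observed
labelling indicator; AUC ranks the posteriors. The high values reflect the
deliberately separable synthetic world — see the methods vignette
(`vignettes/glycopu-methods.Rmd`) for what a green synthetic benchmark
does and does not establish.

The same flow from the shell:

```sh
inst/cli/glycopu simulate --mode proteins --n 200 --seed 11 --out-prefix sim
inst/cli/glycopu extract-features --fasta sim.fasta --sites sim_sites.tsv \
    --type N --seed 12 --out features.tsv
inst/cli/glycopu select-features --features features.tsv --k 100 --out ranking.tsv
inst/cli/glycopu train --features features.tsv --selected ranking.tsv \
    --prior-method alphamax --seed 5 --out model.json
inst/cli/glycopu predict --model model.json --features features.tsv --out pred.tsv
```

`pred.tsv` has one row per candidate site:
`protein_id  position  glyco_type  posterior  label`.

## Snapshot comparison

The PU motivation can be quantified directly from two annotation
snapshots of the same glycosylation type:

```r
cmp <- compare_snapshots(earlier, later)  # data.frames of annotations
cmp$pct_mislabelled   # fraction of newly added positives that were
                      # previously "negatives"
cmp$actual_prior      # hindsight class prior of the earlier snapshot
```

For example, with 1208 earlier positives, 41,526 earlier unlabelled sites
and 2118 later positives of which 237 were previously unlabelled, the
mislabelling share is 237/(2118−1208) = 26.04% and the hindsight prior is
(237+1208)/(41,526+1208) = 3.38% — the arithmetic the test suite pins down.

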