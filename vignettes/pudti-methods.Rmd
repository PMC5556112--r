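---
title: "Screening drug-target interactions from positives and unlabeled pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug-target interactions from positives and unlabeled pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pudti)
```

## The problem

Interaction databases record which drug-compound/protein pairs are known to
interact; they almost never record validated *non*-interactions. A
classifier trained on "known positives vs everything else" therefore learns
from a negative class salted with undiscovered positives, and the common
shortcut of sampling negatives uniformly from the unlabeled pairs inherits
that contamination. `pudti` implements a positive-unlabeled (PU) screening
pipeline that (i) extracts *reliable negatives* from the unlabeled pool by
consensus of two PU classifiers, (ii) assigns the remaining *ambiguous*
pairs soft class-membership weights from local and global cosine
similarity, and (iii) trains a support vector machine whose slack penalties
are scaled by those weights (SVM-SW).

## Feature representation

A drug-target pair is the concatenation of four blocks, in fixed order:

* `G` — drug descriptors, ingested as-is (e.g. 1444 PaDEL columns;
  computing them needs an external tool and is out of scope),
* `O` — binary domain indicators over a fixed vocabulary (1331 human PFAM
  domains at reference settings),
* `A` — type-I pseudo amino acid composition: 20 residue frequencies plus
  `lambda = 30` sequence-order correlation factors over hydrophobicity,
  hydrophilicity and side-chain mass (each standardized over the 20
  residues), weighted by `w = 0.05` and jointly normalized to sum to 1.
  The weight and the property set are package defaults (the canonical
  published ones); they are not prescribed by the interaction-screening
  method itself,
* `B` — bi-gram features of the PSI-BLAST position-specific scoring
  matrix: `B[i, j] = sum_k T[k, i] * T[k + 1, j]` over consecutive
  positions, flattened row-major to 400 values. `T` is the elementwise
  logistic transform `1 / (1 + exp(-s))` of the log-odds scores; raw
  log-odds would make `B` unbounded in profile depth, and the bi-gram
  construction assumes scores in (0, 1). `transform = "none"` exposes the
  raw bilinear map.

At reference dimensions the protein part has 1331 + 50 + 400 = 1781
coordinates and the full vector 3225.

## Feature selection

For every feature, presence is counted in the positive set `P` and the
unlabeled set `U`; the discriminant ability is

```
da(f) = (as(f, P) + as(f, U)) * log(|P| / as(f, P) + |U| / as(f, U))
```

with natural log (the base only rescales scores) and a 0.5 continuity
correction replacing a zero count inside its ratio. Features frequent in
one set but rare in the other score high; the top `k` (default 300) are
kept. Continuous descriptors are binarized for counting by "strictly above
the column median over P and U" (policy `median`; `nonzero` is available).
The median policy is a package decision: the counting rule presumes binary
presence and no binarization is prescribed for continuous descriptors.

## Reliable-negative extraction

Two PU classifiers label every unlabeled sample:

* **Spy classifier.** A fraction (`spy_ratio = 0.15`) of the positives is
  hidden in the unlabeled pool. A Gaussian naive Bayes model (the original
  spy technique used multinomial text counts; the features here are
  continuous after selection) is fitted with the remaining positives
  against the augmented pool, and EM re-estimates the pool-side class
  responsibilities (at most 50 iterations, tolerance 1e-4, per-feature
  variance floor 1e-6). The negative decision threshold is the 5th
  percentile of the spies' positive scores: anything scoring below almost
  every known-positive spy is called negative. Scores are thresholded on
  the log-odds scale — identical decisions in exact arithmetic, but
  posteriors underflow to exactly 0 in double precision for well-separated
  samples, which would make the strict `<` comparison vacuous.
* **Rocchio classifier.** Class prototypes
  `c+ = 16 * mean(P / ||P||) - 4 * mean(U / ||U||)` (and mirrored `c-`);
  a sample is positive when its cosine to `c+` exceeds its cosine to `c-`.

A sample is a **reliable negative (RN)** when both classifiers reject it.
A sample is an **extracted positive (EP)** when the Rocchio vote is
positive *and* its spy log-odds exceed the maximum spy log-odds, i.e. it
looks more positive than every genuine positive planted as a spy. The high
bar is deliberate and asymmetric to the RN rule: unlabeled pools are
dominated by negatives (a few percent hidden positives is typical), so a
merely "not negative" consensus floods the positive class with false
positives — in pilot experiments a symmetric AND rule admitted hundreds of
~10%-precision "positives" against a dozen true ones and destroyed
downstream accuracy. Everything else is **ambiguous (A)**. EP joins the
positive set for all later stages. An empty RN is an error (downstream
training needs a negative class), with a hint to relax the thresholds.

## Prototypes and similarity weights

The reliable negatives are partitioned by k-means into
`a = round(t * |RN| / (|A| + |RN|))` clusters and the ambiguous set into
`n = round(t * |A| / (|A| + |RN|))` clusters, so the budget `t = 30` is
shared and `a + n ≈ t`. k-means uses k-means++ seeding with 10 restarts
and Lloyd iterations; `k` is capped at the number of distinct points, and
counts that round to zero are lifted to one with a warning. Each negative
cluster `N_i` yields a Rocchio prototype pair
(`n_i = 16 * mean(N_i-hat) - 4 * mean(P-hat)`, mirrored `p_i`).

Every ambiguous sample receives three weight pairs, each summing to 1:

* **Local** — samples are temporarily tagged by which side of the Rocchio
  decision hyperplane they fall on (cosine to the positive vs the negative
  class prototype built from the current P and RN; ties tag negative), and
  every member of an ambiguous cluster receives the cluster's tag
  fractions `(LocP, LocN)`. An alternative rule
  (`tag_rule = "prototype"`) compares the best cosine over the
  per-cluster positive prototypes with the best over the negative ones;
  it is not the default because the maximum over near-duplicate positive
  prototypes is optimistically biased — on synthetic pools that are ~90%
  true negatives it tagged roughly half the samples positive (tag accuracy
  near chance), while the hyperplane rule reached 0.76-0.91.
* **Global** — `GloP(x) = sum_i sim(x, p_i) / sum_i (sim(x, p_i) +
  sim(x, n_i))`, cosines clamped at 0 first so the weights stay in [0, 1];
  a sample with no positive similarity to any prototype carries no
  direction information and gets (0.5, 0.5) with a warning. A zero-norm
  vector has cosine 0 against anything.
* **Combined** — `W^P = (1 - alpha) * LocP + alpha * GloP` with
  `alpha = 0.6`, and likewise `W^N`. Samples in one cluster share local
  weights but differ globally, which is the point of mixing the two.

## The similarity-weighted SVM

The training objective keeps positives and reliable negatives as ordinary
soft-margin samples (penalties `C1`, `C4`) and constrains every ambiguous
sample toward *both* classes, with slack penalties `C2 * W^P(x)` on the
positive side and `C3 * W^N(x)` on the negative side. This maps exactly
onto a per-sample-penalty C-SVM on an augmented set in which each
ambiguous sample appears twice with opposite labels; rows whose penalty
falls below 1e-12 are dropped (unpenalized slack makes the constraint
vacuous). The dual — box constraints `0 <= a_i <= c_i`, one equality —
is solved by sequential minimal optimization with second-order working-set
selection (stopping tolerance 1e-6 on the maximal KKT violation; bias from
the mean over free support vectors, midpoint of the violation interval if
none). The solver is verified in the test suite against an independent
interior-point QP solution of the same dual to 1e-5, and against a
standard C-SVM in the degenerate case (no ambiguous rows, equal
penalties).

Kernel: RBF with `gamma` defaulting to 1 / (number of selected features).
All four penalties default to 1; the method as published selects them by
grid search, and `svm_sw_grid_search` provides that (exhaustive, maximal
mean CV AUC on the labeled rows, ties resolved toward the smallest
penalties then the smallest gamma). The published grid phrase — a step of
2^-4 over [2^-5, 2^5] — is internally inconsistent (161 points per
parameter, four parameters), so the grid is left configurable rather than
guessing one reading. A decision score of exactly 0 classifies as
negative: positivity requires a strictly positive margin.

## Evaluation protocol

`pairwise_cv` implements repeated pairwise cross-validation with a PU
split: all drug-target pairs are partitioned into `folds = 5` subsets of
near-equal size; each subset in turn is masked and scored; within the
training pairs, `r = 30` percent of the known interactions form `P` and
everything else — including the remaining known interactions — forms `U`.
The whole pipeline (selection, extraction, weighting, training) reruns
from scratch inside every fold; a disjointness assertion between training
and test indices runs on every fold. Masked pairs that were unlabeled
count as negatives at scoring time, the usual convention for
interaction-matrix benchmarks. Precision/recall at zero denominators are
0 with a warning; AUC is the rank (Mann-Whitney) statistic on decision
scores, ties counted one half. The size-matched random-negative baseline
(`negatives = "random"`) replaces extraction and weighting by a uniform
draw from `U` of the same size as the consensus RN and trains only P vs
those negatives.

## The synthetic generator

`generate_dti_data` emulates what makes PU screening hard: interactions
are rare (`positive_rate`), only a fraction are recorded
(`label_rate`), and the rest hide in the unlabeled pool. Drugs and targets
carry latent vectors; with `affinity = TRUE` the truly interacting pairs
are those with the highest logistic latent affinity (hit exactly at
`positive_rate`), concentrating interactions on promiscuous drugs and hub
targets the way real interactomes do; `affinity = FALSE` draws truth
uniformly over pairs. Pair features concatenate per-drug and per-target
blocks mixing Bernoulli (domain-like) and continuous (descriptor-like)
coordinates; continuous coordinates sit around a positive baseline
(mean 2, unit variance, plus pair-level noise `noise_sd`) because every
cosine-based stage of the method assumes directions carry information, as
they do for nonnegative descriptor magnitudes — zero-centred features
would make cosine similarity structurally uninformative and would test the
geometry, not the method. True interactions shift the informative
continuous coordinates by `effect_size` and the informative binary
coordinates by `effect_size` in log-odds.

What it does *not* emulate: real chemistry, descriptor correlation
structure, PaDEL marginals, or cold-start structure (new drugs/targets).
Passing tests show the machinery behaves as designed under a controllable
geometry, not that it reproduces benchmark accuracy on curated corpora.

### Study conditions used by the tests

* Default spec (200 drugs x 50 targets, `positive_rate` 0.03,
  `label_rate` 0.3, `effect_size` 1): the reliable-negative recovery
  experiment — RN precision against ground truth beats a size-matched
  random draw, paired over 20 seeds with a one-sided sign test.
* Contaminated-pool conditions (50 x 20, `positive_rate` 0.25,
  `label_rate` 0.2, `effect_size` 2, ≈27% of the unlabeled pool hidden
  positives): the pipeline-level comparisons. The contamination level is
  the point: when the unlabeled pool is nearly clean (≤10% hidden
  positives) a uniform negative draw is already almost noise-free and both
  arms coincide; reliable-negative extraction earns its keep exactly when
  contamination is heavy. At these conditions the full pipeline beats the
  random-negative baseline consistently, and the ambiguous-sample
  weighting itself adds accuracy over discarding the ambiguous set.
* Null conditions (same sizes, `effect_size` 0, `affinity = FALSE`):
  cross-validated AUC should sit at chance; the band checked is
  [0.45, 0.55] on the mean over 10 seeds. Truth is i.i.d. here because hub
  concentration would let the classifier memorize entity identity through
  the per-drug feature blocks — a real property of pairwise
  cross-validation, but a confound for the question this experiment asks
  (whether the PU machinery invents signal that is not in the features).
  Problem sizes throughout are chosen so the whole suite runs at desk
  scale; they are stated here so the experiments are reproducible as
  specified.

## Known limitations

* The extracted-positive stage is conservative by design; on pools where
  hidden positives are plentiful and well separated it will still admit
  only samples that outscore every spy.
* Spy thresholds rest on few spies when `|P|` is small (the classifier
  refuses to run below 10 positives); fold-level positive sets in
  cross-validation should be sized accordingly (`r`, `folds`).
* The solver materializes the kernel matrix; training is comfortable to a
  few thousand augmented rows and not intended beyond.
* Weights are computed in the selected-feature space (selection precedes
  extraction in the pipeline), so re-running with different `top_k`
  changes all downstream stages.
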