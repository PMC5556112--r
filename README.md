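# pudti

Screening drug-target interactions (DTIs) with positive-unlabeled
learning.

Interaction databases store known drug-target interactions and nothing
else: there is no curated set of pairs known *not* to interact. Training a
classifier with "everything unlabeled" as the negative class — or with a
uniform random sample of it — contaminates the negatives with undiscovered
interactions. `pudti` is for computational drug-repositioning work that
needs a principled negative class and a classifier aware of what remains
uncertain:

1. **Reliable-negative extraction.** Two positive-unlabeled classifiers
   label the unlabeled pool: a spy-based Gaussian naive Bayes / EM model
   (a fraction of positives is hidden among the unlabeled samples and
   calibrates a rejection threshold from their scores) and a Rocchio
   prototype classifier (cosine to weighted class centroids,
   `c+ = 16 * mean(P-hat) - 4 * mean(U-hat)` and its mirror). Pairs both
   classifiers reject form the reliable negatives `RN`; pairs that look
   more positive than every spy, with a positive Rocchio vote, join the
   positives; the rest are *ambiguous* `A`.
2. **Similarity weights.** Reliable negatives are k-means-partitioned into
   `a = round(t |RN| / (|A| + |RN|))` clusters with one Rocchio prototype
   pair `(p_i, n_i)` each. Every ambiguous sample gets local weights
   (its micro-cluster's fraction of temporarily positive-tagged members),
   global weights `GloP(x) = Σ_i sim(x, p_i) / Σ_i (sim(x, p_i) +
   sim(x, n_i))`, and the blend `W^P = (1 - α) LocP + α GloP` (α = 0.6).
3. **Similarity-weighted SVM (SVM-SW).** An RBF soft-margin SVM in which
   each ambiguous sample is constrained toward both classes with slack
   penalties `C2 W^P(x)` and `C3 W^N(x)` (positives: `C1`, reliable
   negatives: `C4`):

   ```
   min  ½‖w‖² + C1 Σ_{i∈P} ε_i + C2 Σ_{j∈A} W^P(x_j) ε_j
              + C3 Σ_{m∈A} W^N(x_m) ε_m + C4 Σ_{n∈RN} ε_n
   ```

   solved as a per-sample-penalty C-SVM dual by sequential minimal
   optimization.

The package also provides the protein descriptor blocks (type-I pseudo
amino acid composition, bi-gram PSSM features, domain indicator vectors),
the discriminant-ability feature filter
`da(f) = (as(f,P) + as(f,U)) · log(|P|/as(f,P) + |U|/as(f,U))`,
pairwise cross-validation with positive-unlabeled splits, and a seeded
synthetic generator with known ground truth. See the methods vignette
(`vignettes/pudti-methods.Rmd`) for the full model description and every
numerical decision.

## Worked example

```r
library(pudti)

# 1000 drug-target pairs; 250 interact, only 50 are recorded as known,
# 200 hide in the unlabeled pool (~27% contamination).
spec <- synthetic_spec(n_drugs = 50, n_targets = 20, positive_rate = 0.25,
                       label_rate = 0.2, effect_size = 2, seed = 42)
d <- generate_dti_data(spec)

fit <- pudti_fit(d$x, which(d$known), which(!d$known),
                 pudti_config(svm_tol = 1e-3), seed = 1)
fit$split
#> sample_split: |P| = 50, |EP| = 6, |RN| = 713, |A| = 231

head(round(fit$weights[, -1], 3), 3)
#>   LocP LocN  GloP  GloN    WP    WN
#> 1    1    0 0.550 0.450 0.730 0.270
#> 2    1    0 0.561 0.439 0.737 0.263
#> 3    1    0 0.561 0.439 0.736 0.264

pred <- predict(fit, d$x)
auc_score(pred$score, d$truth)   # against the generator's ground truth
#> 0.997

pairwise_cv(d$x, d$known, pudti_config(svm_tol = 1e-3, trials = 1), seed = 1)
#> pairwise cross-validation report
#>     metric      mean         sd
#>  precision 0.1771199 0.09191921
#>     recall 0.6033333 0.17810733
#>          F 0.2675834 0.12681786
#>        auc 0.8688005 0.05494205
```

The extractor keeps 713 of 950 unlabeled pairs as reliable negatives and
promotes only 6 to the positive side; the 231 ambiguous pairs carry soft
weights instead of hard labels. Cross-validated precision looks low
because masked *unlabeled* test pairs count as negatives even when they
are hidden true interactions — the standard convention for this protocol —
while the AUC of 0.87 measures ranking quality against the revealed
labels.

A command-line wrapper over the same functions ships in
`inst/cli/pudti` (subcommands `simulate`, `select-features`,
`extract-negatives`, `weight`, `train`, `predict`, `evaluate`).

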