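---
title: "Judging classifier applicability from dataset characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judging classifier applicability from dataset characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algsel)
```

## The problem

Given a tabular classification dataset — typically a medical one: modest
sample size, mixed variable kinds, skewed class frequencies — which of the
classic learning algorithms should be tried first? `algsel` implements a
meta-learning answer: describe the dataset with a fixed vector of
characteristic indicators, relate those indicators to how eight base
algorithms (LR, C4.5-style trees, SVM, AdaBoost, kNN, naive Bayes, random
forest, and a single-hidden-layer perceptron) actually perform, and distill
the relation into explicit, human-readable applicability knowledge:
recommendation labels, domain-difference tests, magnitude-prediction
formulas and induced decision rules.

## Preprocessing model

Two rules, in a fixed order. An attribute whose missing fraction strictly
exceeds 30% is dropped first; remaining incomplete rows are dropped second.
The order matters: a single badly collected variable must not trigger mass
row deletion under the complete-case filter. Imputation is deliberately
absent — filled-in values would distort the very indicators the package
measures. The threshold is configurable; the boundary is read strictly, so
a column at exactly 30% missing survives. The missing-value ratio indicator
(`R_missing`) is recorded at load time, before these rules run, since
afterwards it is identically zero.

## The 26 indicators

Three families, plus the domain tag (`field_label`) as a 27th meta-attribute:

* **Simple** — attribute count `P`, sample size `N`, class count `N_class`,
  largest/least class ratios, kind ratios and `R_missing`. Binary is
  treated as a sub-kind of discrete, so `R_discrete + R_continuous = 1` and
  `R_binary <= R_discrete`.
* **Statistical** — per continuous attribute: geometric and harmonic means,
  trimmed mean, upper percentile, mean absolute deviation, variance (n−1),
  standard deviation, IQR, index of dispersion (variance/mean), skewness
  (biased g1) and non-excess kurtosis (normal = 3); aggregated by the
  arithmetic mean across eligible attributes, plus `MAr`, the mean absolute
  pairwise Pearson correlation. Attributes with non-positive values are
  excluded from the two product-type means, attributes with zero mean from
  the dispersion index; such exclusions are flags, not errors, and an
  all-discrete dataset reports zeros with a flag.
* **Information-theoretic** — class entropy `E_C`, mean attribute entropy
  `ME_V`, mean attribute–class mutual information `MME_CV`, the equivalent
  number of variables `ENV = E_C / MME_CV` and the noise–signal ratio
  `NSR = (ME_V − MME_CV) / MME_CV`.

Open choices settled here (each configurable): entropies in bits;
continuous attributes discretized by equal-width histograms with Sturges'
rule `max(2, ceil(log2 N) + 1)` bins; 10% trim per tail for the trimmed
mean; the 90th percentile (linear interpolation) for `Prctile`. Under the
histogram estimator all entropies are nonnegative, which forces `ENV >= 1`
and `NSR >= 0` — properties the test suite checks on randomized data. One
published rule references a *negative* NSR threshold (−38.7407), which is
unreachable under histogram entropies; the rule is stored exactly as
printed, and an optional `estimator = "differential"` mode (Gaussian
differential entropy for continuous attributes) is provided because it is
the one standard estimator that legitimately produces negative `ME_V`. No
further intent is guessed.

## Benchmarking and the failure taxonomy

Each algorithm is fitted on a stratified 70/30 holdout with a fixed seed.
Beyond train/test accuracy, two per-class recalls are kept: `S_largest` and
`S_least`, the multiclass analogues of sensitivity and specificity —
`S_least` is what matters when the rare class is the clinically interesting
one. Modeling time (wall-clock fit seconds, floored at 0.1 ms against timer
resolution) and model memory (serialized fitted-model bytes, a reproducible
proxy chosen because an external measurement method would be
hardware-specific) are kept raw and on the log10 scale, where magnitude
comparisons live.

Failures are data, not crashes. Every non-completed record carries exactly
one reason: `dimension_limit` (one-hot design too wide for the weight-based
learners LR/BP), `category_limit` (a discrete attribute with more levels
than the random-forest implementation accepts), `memory_limit`, `timeout`,
or `numeric_error`. The numeric limits are configurable with documented
defaults, the original study's thresholds not being published. Timeouts are
enforced both in-flight (interrupting the fit where R can) and after the
fact, because compiled fitting code cannot always be interrupted; either
way the record is a `timeout`.

Base learners are standard implementations with fixed hyperparameters
(k = 5 for kNN, RBF SVM, 100 trees for RF, one hidden layer of 8 units for
BP, 30 SAMME boosting rounds over depth-2 trees for AB). Ranking uses
test-partition accuracy — the generalization-relevant choice; the tie chain
(accuracy, then `S_least`, then time, then a fixed algorithm order) is a
documented invention, since ties must break somehow and reproducibly.

## Labels, contingency tables and the chi-square

Per dataset, ranks 1–3 are recommended (`Y`), 4–5 medium (`M`), 6–8 and all
failures not recommended (`No`); with eight completions and no ties that is
exactly 3/2/3. When fewer than three algorithms complete, all completed
ones are `Y`. Cross-tabulating one algorithm's labels against dataset
domains (medical/biology/general) gives a 3×3 table tested with the
marginal-products form of the independence statistic,

$$\chi^2 = n\left(\sum_{i,j} \frac{A_{ij}^2}{n_{Ri}\, n_{Cj}} - 1\right),$$

which is algebraically the classical Pearson $\sum (O-E)^2/E$ — the test
suite verifies the identity to 1e-9 on a thousand random tables. Zero
marginals raise an error (the statistic divides by them) rather than
silently collapsing categories; expected counts below 5 produce a logged
caveat, not a correction, because the published analysis applied none. The
verdict compares against the upper-0.05 quantile at $(R-1)(C-1)$ degrees of
freedom — the published analysis reports only binary verdicts, and this
α/df pair is the unique standard choice that reproduces all eight of them.

## The formula bank and rule engine

Forty-eight transcribed linear formulas — 8 algorithms × 3 dataset
categories (mixed/discrete/continuous) × 2 targets — predict log10 runtime
seconds and log10 model memory on the source study's hardware. They are
exposed as *relative magnitude estimates* for ranking, never absolute
guarantees. The bank ships as a human-readable CSV; loading verifies the
48 keys and a checksum test freezes every coefficient. Ratio thresholds
printed as percentages (77.78%) are stored as fractions (0.7778) to match
the metafeature scale. Rules with no numeric predicate (naive Bayes on
biomedical discrete datasets) are encoded as domain-scoped advisories.

## Re-inducing applicability knowledge

Two meta-learners, mirroring how the published knowledge was produced:

* **Bidirectional stepwise regression** with partial-F entry/removal
  p-values (defaults 0.05/0.10 — unstated in the source, these are the
  textbook pair), run after a marginal correlation pre-filter (|r| > 0.3)
  for magnitude targets. The binary "recommend or not" framing uses a
  linear probability model by default; a logistic mode sits behind a flag.
  Least squares was chosen as the default because the procedure is
  specified as regression with no link function. Lexicographic candidate
  order makes every run deterministic.
* **A gain-ratio decision tree** with pessimistic pruning: binary midpoint
  splits for continuous features, multiway splits for categorical ones,
  growth to purity or a `min_leaf` floor, then bottom-up collapse of any
  subtree whose pessimistic error (exact binomial upper-confidence bound at
  cf = 0.25, the classic default) is no better than its root as a leaf.
  Subtree grafting is not implemented — collapse-only pruning keeps the
  estimate conservative and the implementation auditable. Gain-ratio
  computation is cross-checked against an exhaustive split-enumeration
  oracle in the tests.

Cross-validation is stratified k-fold (default 10) with seeded shuffling;
folds that lose a class in training are skipped with a warning.

## What the synthetic generators do and do not show

`generate_base_dataset()` emulates UCI-style tables: Dirichlet class
priors, per-class Gaussian continuous attributes with a compound-symmetry
correlation target, discrete attributes mixing a class-determined level
with a uniform one at a controllable rate (chosen because mutual
information is then provably monotone in the rate), and MCAR missingness.
`generate_meta_dataset()` samples indicator vectors from realistic ranges
and plants a known applicability rule, optionally flipping labels.

These generators make ground truth available, which real data never does —
passing tests show the machinery is correct *given its assumptions*
(Gaussian within-class attributes, MCAR missingness, axis-aligned planted
rules), not that real medical datasets satisfy them. In particular the
desk-scale validation — a 10-fold cross-validated gain-ratio tree reaching
at least 75% accuracy on a planted rule with 10% label noise at n = 400 —
is the analogue of the original study's above-75% claim, whose exact value
depends on its 293-dataset metadata and cannot be recomputed from the
publication alone. Likewise the stepwise recovery experiment draws its
features *independently* over ranges sized so that each coefficient of the
target formula is identifiable at n = 500 under noise σ = 0.1; a recovery
experiment with confounded features would measure the sampler, not the
selector.

Problem sizes throughout the test suite (dataset rows in the hundreds to a
few thousand, 200-dataset invariant sweeps, 20-seed recovery loops) are the
package's chosen desk scale: large enough for the statistical claims being
checked, small enough to run anywhere.

## Known limitations

* The failure-taxonomy thresholds and all base-learner hyperparameters are
  stand-ins; absolute times/memory are hardware-dependent by construction.
* The stepwise false-entry rate is the per-candidate α by design: with p
  pure-noise candidates, expect a spurious entry in roughly
  $1-(1-\alpha)^p$ of runs. The procedure is faithful to its definition
  rather than multiplicity-corrected.
* The rule engine stores published thresholds verbatim; it does not try to
  reconcile the negative-NSR rule with the nonnegative histogram estimator.
* Data integration beyond row-wise concatenation of same-schema tables,
  imputation, and landmarking-style metafeatures are out of scope.
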