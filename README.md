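# algsel

Which classification algorithm should you try first on *this* dataset?
`algsel` is a meta-learning toolkit for that question, aimed at biomedical
tabular data: it quantifies a dataset with 26 characteristic indicators,
benchmarks eight classic learners — logistic regression (LR), a decision
tree (C45), SVM, AdaBoost (AB), k-nearest neighbours (kNN), naive Bayes
(NB), random forest (RF) and a single-hidden-layer perceptron (BP) — for
accuracy, runtime and memory with an explicit failure taxonomy, discretizes
per-dataset accuracy rankings into recommendation labels (Y/M/No), tests
domain differences with an R×C chi-square, evaluates a bank of 48 published
linear formulas predicting log10 runtime/memory magnitudes together with
domain-scoped applicability rules, and re-induces such knowledge from
metadata with bidirectional stepwise regression and a gain-ratio decision
tree with pessimistic pruning.

## The statistics at the core

**Characteristic indicators.** Simple counts and ratios (`P`, `N`,
`N_class`, `R_largest`, `R_least`, kind and missingness ratios), statistical
aggregates over continuous attributes (geometric/harmonic/trimmed means,
percentile, MAD, variance, SD, IQR, dispersion index, skewness, kurtosis,
mean absolute correlation `MAr`), and information-theoretic quantities:
class entropy `E_C`, mean attribute entropy `ME_V`, mean attribute–class
mutual information `MME_CV`, the equivalent number of variables
`ENV = E_C / MME_CV`, and the noise–signal ratio
`NSR = (ME_V − MME_CV) / MME_CV`.

**Per-class recall.** `S_largest` and `S_least` — the recall of the most
and least frequent class (×100) — are the multiclass analogues of
sensitivity and specificity; `S_least` is the number to watch for
rare-disease screening.

**Domain-difference test.** For a label-by-domain count table
(rows medical/biology/general, columns Y/M/No):

    chi^2 = n * ( sum_ij A_ij^2 / (n_Ri * n_Cj) - 1 )

the marginal-products form of the Pearson independence statistic, compared
against the chi-square upper-0.05 quantile at (R−1)(C−1) df.

**Meta-learning.** A gain-ratio (C4.5-style) decision tree with
pessimistic confidence-bound pruning, and p-value-driven bidirectional
stepwise least squares after a |r| > 0.3 correlation pre-filter, with
stratified k-fold cross-validation.

## Worked example

```r
library(algsel)

spec <- base_dataset_spec(n_rows = 300, n_continuous = 3, n_discrete = 2,
                          n_binary = 1, n_classes = 3, class_separation = 2,
                          missing_rate = 0.05, domain = "medical", seed = 11)
d <- preprocess(generate_base_dataset(spec, name = "clinic"))
d
#> <algsel_dataset 'clinic'> 212 x 6 attributes, class 'class' (3 levels),
#>   domain medical, raw missing 5.7%
```

300 rows went in; the 5% MCAR mask left 212 complete rows (no attribute
crossed the 30% missingness bar, so no column was dropped). Characterize
and read off the indicators:

```r
mf <- characterize(d)
round(mf[, c("P","N","N_class","R_largest","R_least","E_C","MME_CV","ENV","NSR")], 3)
#>   P   N N_class R_largest R_least   E_C MME_CV   ENV   NSR
#> 1 6 212       3     0.472   0.179 1.486  0.562 2.643 2.761
```

`ENV = 2.64`: the class variable carries about 1.49 bits and an average
attribute shares 0.56 of them, so roughly three informative attributes'
worth of signal is needed. Benchmark all eight learners and label the
ranking:

```r
rec <- benchmark_suite(list(d), seed = 2)
label_benchmark(rec)[, c("algorithm", "rank", "label")]
#>   algorithm rank label
#> 1       SVM    1     Y
#> 2        NB    2     Y
#> 3        BP    3     Y
#> 4        LR    4     M
#> 5        AB    5     M
#> 6       C45    6    No
#> 7        RF    7    No
#> 8       kNN    8    No
```

The published formula bank predicts resource magnitudes for a dataset of
this category from the indicators alone (log10 seconds / log10 bytes on
the source study's hardware — relative magnitudes, useful for ranking):

```r
predict_resource_magnitudes(mf, dataset_category(d))
#>   algorithm category  log10_time log10_memory
#> 1        LR    mixed -0.71           5.21
#> 2       C45    mixed -0.90           5.47
#> 3       SVM    mixed -0.40           6.02
#> 4        AB    mixed -0.04           8.74
#> 5       kNN    mixed -2.92           5.43
#> 6        NB    mixed -4.40           4.57
#> 7        RF    mixed -1.44           6.66
#> 8        BP    mixed -0.92           7.89
```

(NB is predicted fastest and lightest; the ensemble AB the heaviest —
about four orders of magnitude more memory.) Finally, the stored
applicability rules that fire for this medical mixed-kind dataset:

```r
applicable_rules(mf, dataset_category(d))
#>   algorithm     verdict rule
#> 1        AB recommended suitable for medical mixed datasets with
#>                         discrete-variable ratio below 77.78%
#> 2        NB recommended suitable when the noise-signal ratio exceeds -38.7407
```

`run_pipeline()` chains all stages over a dataset collection and writes
per-stage CSV artifacts plus a JSON summary; `inst/cli/algsel.R` is a thin
command-line wrapper (`simulate`, `characterize`, `predict`, `run-all`).

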