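# hullshift

Quantify heterogeneity between tabular patient cohorts of different origin —
for example ICU feature tables from different hospitals — and assess whether
a model trained at one site can be trusted at another, *before* deploying it.

A data-driven model is only reliable inside its validity domain, the region
densely covered by its training data; the convex hull (CH) of the training
set bounds that region from above. `hullshift` implements a two-step
pipeline:

1. **Convex-hull coverage.** For every ordered site pair (query A, hull B)
   and every pair of numeric features (i, j), compute the bootstrap-averaged
   fraction of A's patients inside B's 2D convex hull,

   CHcov(fⁱ, fʲ) = (1/|A|) · Σₖ∈A 1[(fⁱₖ, fʲₖ) ∈ CH_ij(B)],

   after DBSCAN denoising of the hull-forming sample. Per feature, coverage
   is the median over all pairs containing it; per site pair, the summary is
   the mean over features (rows of the coverage matrix are the query site).
   Features below Q1 − 1.5·IQR of the per-feature distribution are flagged
   as low-coverage: they carry the support shift, and they point in the
   *direction* of impaired generalization.
2. **Dataset-origin discrimination.** Hull overlap is necessary but not
   sufficient for homogeneity, so four classifiers (ridge logistic
   regression, random forest, RBF SVM, AdaBoost; stratified 80/20 split,
   grid search with stratified 5-fold CV, balanced class weights except
   AdaBoost) are trained to predict which site a record came from — with and
   without the flagged features. High ROC AUC exposes diverging underlying
   distributions even where hulls coincide.

A cross-site generalization harness closes the loop on a concrete endpoint:
first-day ARDS labels from diagnosis codes plus a sustained (≥ 24 h)
Horowitz-index (PaO2/FiO2 < 300) drop, one random-forest model per site,
evaluated on every site (cross-prediction ROC AUC matrix). A seeded
synthetic multi-site generator (`generate_scenario()`) makes every stage
testable without clinical data.

## Worked example

```r
library(hullshift)

# two synthetic sites, 6 features; site B's feature f1 is shifted by 4 sd
cohorts <- generate_scenario("single-feature-shift", p = 6, n = 1000,
                             magnitude = 4, seed = 1)
cohorts <- prepare_cohorts(cohorts)   # sparsity filter, intersect, impute

cm <- coverage_matrix(cohorts, n_boot = 20, seed = 1)
cm
#> <hs_coverage_matrix> 2 sites, 6 features, n_boot = 20
#>       A     B
#> A 1.000 0.776
#> B 0.775 1.000
#> 2 low-coverage feature flags; see $flagged

dplyr::filter(cm$per_feature, flagged)
#> # A tibble: 2 × 6
#>   query_site hull_site feature coverage threshold flagged
#> 1 A          B         f1        0.0506     0.9   TRUE
#> 2 B          A         f1        0.0486     0.898  TRUE

rep <- discriminate_sites(cohorts$A, cohorts$B,
                          flagged = flagged_union(cm, "A", "B"), seed = 1)
dplyr::select(rep, model_family, feature_variant, test_auc)
#> 1 logistic-regression    all                  0.999
#> 2 random-forest          all                  0.999
#> 3 support-vector-machine all                  0.998
#> 4 adaboost               all                  0.998
#> 5 logistic-regression    excluding-flagged    0.519
#> 6 random-forest          excluding-flagged    0.483
#> 7 support-vector-machine excluding-flagged    0.531
#> 8 adaboost               excluding-flagged    0.527
```

Reading the numbers: mean coverage 0.78 in both directions looks moderate,
but the per-feature table shows the entire deficit concentrated in `f1`
(coverage ≈ 0.05, far below the 0.90 flagging threshold) — the shifted
feature. Origin classifiers separate the sites almost perfectly (AUC ≈ 1.0)
with all features, and collapse to chance (≈ 0.5) once `f1` is removed: the
two sites differ *only* through that feature's support shift.

Results are tidy objects: `tidy()`, `glance()` and `autoplot()` methods
exist for coverage matrices and cross-prediction matrices, and everything
chains with the pipe.

`run_pipeline(config)` orchestrates the full analysis (prepare → coverage →
flag → discriminate → optional cross-prediction) and writes CSV reports plus
a JSON summary; reruns with the same configuration are byte-identical. A
thin command-line wrapper lives in `exec/hullshift`:

```sh
exec/hullshift synth --scenario nested-support --n 2000 --p 10 \
    --magnitude 1.5 --seed 1 --out cohorts/
exec/hullshift coverage --cohorts cohorts/cohort_A.csv,cohorts/cohort_D.csv \
    --n-boot 100 --seed 1 --out results/
exec/hullshift run --config run.yaml
```

## Documentation

The methods vignette (`vignettes/hullshift-methods.Rmd`) documents the
model and its assumptions, all tunable parameters with defaults and
rationale, what the synthetic generator does and does not emulate, numerical
conventions, and known limitations.
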