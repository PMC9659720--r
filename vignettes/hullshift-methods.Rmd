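---
title: "Detecting dataset shift between multi-site cohorts with convex-hull coverage and origin classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dataset shift between multi-site cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullshift)
```

## The problem

A prediction model trained on one hospital's ICU cohort is routinely asked to
score patients from another hospital. Data-driven models are only trustworthy
inside their *validity domain* — the region densely covered by training
samples — and the convex hull (CH) of the training set is an upper bound for
that region. When a deployment site's patients fall outside the training
site's hull, the model extrapolates, and its performance there is
unknowable from internal validation alone. hullshift quantifies this risk
before any endpoint model is deployed, using a two-step pipeline:

1. **Convex-hull coverage analysis.** For every ordered pair of sites and
   every pair of numeric features, measure the fraction of the query site's
   patients inside the 2D convex hull of the other site's patients. Aggregate
   to per-feature medians and a site-by-site mean-coverage matrix, and flag
   features with anomalously low coverage.
2. **Dataset-origin discrimination.** Train classifiers to predict which site
   a patient record came from. Hull overlap is *necessary but not sufficient*
   for homogeneity: two cohorts can share a hull while concentrating their
   density in different regions (the cluster-gap construction below), and a
   site classifier with high ROC AUC exposes exactly that.

A third component, the cross-prediction harness, closes the loop on a
concrete endpoint: label first-day ARDS per patient, train one random-forest
model per site, evaluate every model on every site, and compare the
internal-to-external AUC drops with the coverage matrix.

## Step 1: coverage analysis

For a feature pair $(i, j)$ and ordered site pair (query $A$, hull $B$), the
pair coverage is

$$\mathrm{CHcov}(f^i, f^j) = \frac{1}{|A|}\sum_{k \in A}
  \mathbf{1}\left[(f^i_k, f^j_k) \in \mathrm{CH}_{ij}(B)\right],$$

the fraction of $A$'s points inside or on $B$'s 2D hull. Working in all
$\binom{p}{2}$ two-dimensional projections rather than the full $p$-space is
deliberate: full-dimensional hulls of clinically sized samples shrink to
nothing as dimension grows, so their intersections are uninformative even for
identically distributed data. 2D projections remain estimable at hospital
sample sizes; if the full hulls overlap, every projection overlaps too, so
low projection coverage is a sound alarm.

Per feature, coverage is the **median** over the $p-1$ pairs containing it;
per site pair, the summary is the **mean** over features. Features whose
median coverage falls strictly below $Q_1 - 1.5\,\mathrm{IQR}$ of the
per-feature distribution (quartiles by linear interpolation, R type 7) are
flagged as low-coverage: these carry the support shift.

Three robustness devices surround the raw geometry:

* **DBSCAN denoising** of the hull-forming sample only. Convex hulls are
  extremely sensitive to single outliers; density-based noise removal strips
  them before hull construction. Query points are never removed — removing
  them would silently inflate coverage. A point is retained when it is a core
  point or within `eps` of one; `min_samples = 5` and
  `eps` = the 90th percentile of 5-nearest-neighbour distances on the
  z-scored projection are the defaults (both configurable). The percentile
  rule makes the radius scale-free across heterogeneously scaled clinical
  features; it is computed once per feature pair on the original sample and
  reused across bootstrap replicates so that the denoising operating point is
  stable and runs stay fast.
* **Bootstrap averaging** (default 100 replicates): both cohorts are
  resampled with replacement at original size each replicate; the reported
  coverage is the replicate mean (the sd is reported alongside). A flag
  allows hull-side-only resampling for sensitivity analysis.
* **Degenerate-projection handling.** A protocol-constant feature (all values
  equal, or collinear after denoising) has no 2D hull. Such pairs are
  skipped, logged in a QC table, and the per-feature medians are taken over
  surviving pairs. Crashing the run on a constant ventilator setting would be
  wrong; silently imputing a coverage would be worse.

All geometry runs on standardized (z-scored per feature, pooled over the two
sites) coordinates. Membership is a half-plane sign test against the
counterclockwise hull edges with an absolute tolerance of `1e-9` on the
signed point-to-edge distance, so boundary points count as inside and
self-coverage is exactly 1.

Direction semantics are fixed throughout: `coverage(A by B)` is the fraction
of A's points inside B's hull, and every output labels entries explicitly as
(query site, hull site). Rows of the coverage matrix are the query site. The
matrix diagonal is 1 by convention and excluded from summaries.

## Step 2: origin discrimination

Patients from two sites are stacked with labels 0/1 and the pair is treated
as a binary classification problem. Four families are trained — ridge
logistic regression, random forest, RBF support vector machine, and discrete
AdaBoost over depth-1 decision stumps — with a stratified 80/20 train/test
split and grid search maximizing ROC AUC under stratified 5-fold
cross-validation on the training split. Because the stacked labels are
usually imbalanced, logistic regression, random forest and the SVM use
balanced class weights ($w_c = n / (2 n_c)$); AdaBoost is trained unweighted,
matching the reference protocol. Features are standardized with train-split
statistics for the two scale-sensitive families (logistic regression, SVM);
tree ensembles consume raw values. Default grids are deliberately small and
desk-scale (regularization $C \in \{0.01, 0.1, 1, 10\}$, forest size
$\{100, 300\} \times$ depth $\{\infty, 10\}$, SVM cost $\{0.1, 1, 10\}$,
boosting rounds $\{50, 200\}$) and fully configurable.

Each pair is trained twice: on all features, and excluding the union of
features flagged low-coverage in either direction of the pair. If
discrimination collapses to chance after the exclusion, the detectable shift
lived entirely in the flagged support-shifted features; if it persists, the
sites differ in their underlying densities beyond support.

Reports carry CV AUC, test AUC, precision, recall and F1 (threshold 0.5 on
probabilities, 0 on margins; precision is defined as 0 when no positives are
predicted), the chosen hyperparameters, and the seed. The best family per
variant is marked; all families are always reported.

## The ARDS cross-prediction harness

The endpoint use case labels *first-day ARDS* from two ingredients: a
qualifying diagnosis code (ICD-10 `J80`, or the ICD-9 respiratory-failure
list `5185, 51851, 51852, 51853, 51882` where ICD-10 is unavailable), and the
oxygenation criterion of the Berlin definition — the Horowitz index
(PaO2/FiO2, mmHg over inspired fraction) dropping below 300 and staying below
for at least 24 hours, with onset during the first ICU day. Only the
oxygenation component is evaluated; PEEP ≥ 5 and imaging criteria are out of
scope. Patients lacking PaO2, FiO2 or PEEP measurements in the first 24 h
cannot be assessed and are excluded (and counted). Coded patients with later
onset are controls, as are uncoded patients; the label-count report separates
the two control subtypes so either composition can be audited.

Concrete conventions, all configurable:

* FiO2 values above 1 are percentages and divided by 100; values in (0, 1]
  are fractions. Both conventions occur in ICU charting.
* The Horowitz series is evaluated at PaO2 measurement times using the most
  recent FiO2 (last observation carried forward).
* Between measurements the below/above-threshold state is carried forward; a
  below-threshold run is broken by the first measurement at or above 300. If
  the record ends while still below threshold, the run qualifies only if its
  *observed* span reaches 24 h — an unobserved continuation is not assumed.

One random forest per site is trained on the labeled first-day features
(stratified 80/20 internal split, balanced class weights, the same CV grid
search). The cross-prediction matrix reports the internal held-out test AUC
on the diagonal and, off-diagonal, the AUC of each site's model on the
*whole* external cohort — the external site contributes no training data, so
no split is taken there. The drop from diagonal to off-diagonal measures
transportability, and its alignment with low directional coverage is the
pipeline's headline synthesis.

## Synthetic study conditions

Real multi-hospital ICU tables cannot be redistributed, so the package ships
a seeded generator of multi-site cohorts; every generator is a pure function
of its specification and seed. A site is a Gaussian mixture over $p$
features with optional per-feature support scaling about the grand mean,
missing-completely-at-random masking, and a logistic endpoint model applied
to the complete (pre-masking) features. Endpoint prevalence is set through
the intercept and defaults to about 7%, the middle of typical day-1 ARDS
prevalence in ICU cohorts. MCAR is the only missingness mechanism on offer:
the pipeline's imputation is univariate (site-median), so richer mechanisms
would add nothing testable here.

Four named scenarios encode the study conditions used by the tests and the
acceptance script:

* **identical** — two i.i.d. sites; the null case. Coverage should be high
  and origin AUC near 0.5.
* **single-feature-shift** — site B's first feature mean is shifted by a
  chosen number of pooled standard deviations. The shifted feature should be
  flagged by the Q1 − 1.5 IQR rule and drive origin discrimination; removing
  it should return the classifiers to chance.
* **cluster-gap** — site A is bimodal in feature 1 (modes a chosen gap
  apart), site B unimodal in the gap centre. B lies almost entirely inside
  A's hulls, yet the two densities barely overlap: high coverage with high
  origin AUC, the constructed proof that hull overlap is necessary but not
  sufficient.
* **nested-support** — three narrow sites plus one wide site (support scale
  $1 + m$) strictly containing them, with endpoints attached: the
  cross-site generalization stress case.

### Why the nested-support endpoint is non-monotone

The nested-support endpoint uses a single-index model
$\Pr(y = 1 \mid x) = \sigma(\beta_0 + s(\beta^\top x))$ with a *tent* link:
$s(u) = u$ up to a peak at $u_0 = 5$ (2.5 reference sd of the index) and
declining beyond it. The outcome process is identical across sites; only the
feature support differs.

This choice is load-bearing, and we record why. With a plain monotone-linear
endpoint, a random forest trained on a narrow site extrapolates each tree
flat beyond its support; a flat extension of a monotone score preserves the
*ranking* of external patients almost perfectly, so the narrow-site model
barely degrades on the wide site no matter how little of the wide site it
covered — the coverage warning would look like a false alarm by
construction. Measured on three seeds, the narrow-on-wide AUC drop under a
linear endpoint was 0.03–0.06 while the wide model lost up to 0.15 on narrow
sites (a resolution artefact of fitting on a 3× coarser scale), the exact
opposite of the clinically observed pattern. Real dose-response relations
are not globally monotone (both hypoxia and hyperoxia are adverse; both
hypo- and hypertension are), and a model that never saw the downturn will
confidently misrank patients beyond it. Placing the tent's turning point
just outside the narrow sites' support reproduces the realistic failure
mode: narrow-site models learn a monotone relation, extrapolate it into the
wide site's tail, and lose 0.08–0.13 AUC there, while the wide-site model —
which saw the full dose-response — transfers to the narrow sites without
loss. The wide site also shows a somewhat higher raw prevalence, which is
consistent with heterogeneous case mixes across real hospitals. The other
scenarios keep the plain linear endpoint.

The time-series generator emits PaO2/FiO2/PEEP records on a regular grid
(default every 4 h for 72 h): cases cross P/F 300 within the first day and
stay below; controls either never cross, cross after hour 24, or dip once
without sustaining. It exists to exercise the labeler end to end, not to
simulate physiology.

## Data preparation conventions

* First-day aggregation uses the half-open window $[0, 24)$ h: a
  measurement at exactly 24 h belongs to day 2. Medians; for even counts,
  the mean of the two middle values.
* Features missing in **more than** 30% of a site's patients are dropped —
  strictly more, so an exactly-30% feature is retained.
* The sparsity filter is applied per site first, then features are
  intersected across sites (the order is configurable via
  `intersect_first`), then missing entries are imputed with the site-wide
  feature median. Imputation is strictly per-site — pooling across sites
  would leak exactly the between-site signal the pipeline is trying to
  measure — and univariate, a known limitation.
* Only numeric features enter the pipeline; categorical columns are rejected
  at load time. Unit harmonization across sites is assumed done upstream.

## Numerical and reproducibility choices

* Quartiles and percentiles use linear interpolation (R type 7), recorded in
  the run metadata.
* Hull membership tolerance: 1e-9 absolute on standardized coordinates;
  boundary points are inside. Self-coverage of any point set by its own hull
  is exactly 1 with denoising and resampling disabled, and adding points to
  a hull-forming set can never decrease coverage.
* Every stochastic step takes an explicit integer seed; sub-seeds are
  derived by hashing the site pair and feature pair, not from loop order, so
  permuting the input cohorts permutes the outputs consistently. Random
  forests run single-threaded with a fixed seed. Rerunning the pipeline with
  an identical configuration produces byte-identical report files.
* AUC is the Mann-Whitney statistic with midrank ties (cross-checked against
  pROC in the tests).

## Problem sizes used by the shipped checks

The test suite and acceptance script run entirely on synthetic data at sizes
chosen to give stable statistics on a single CPU in minutes: geometry oracles
on 100 instances of 50–300 points; the area-ratio check at n = 1000 and 100
bootstrap replicates; flagging recovery over 20 seeds at p = 10, n = 2000,
10 bootstrap replicates; null calibration of the origin classifiers over 20
seeds at n = 600 per site (assertions on seed-averaged AUC, whose
uncertainty is a few thousandths); the separable-shift and feature-removal
checks at n = 1200 averaged over 3 seeds; the nested-support harness at
p = 6, n = 1500 over 3 seeds. Statements about calibration are made on seed
averages because a single held-out split's null AUC has a standard error of
several hundredths at these sizes.

## What passing tests do and do not show

The generator produces independent Gaussian-mixture features, MCAR
missingness and a known outcome model. Real ICU tables have correlated,
skewed, heavy-tailed features, informative missingness, label noise from
coding practice, and temporal drift. Passing the shipped checks shows the
machinery is correct and the advertised geometries are recovered under
controlled conditions; it does not certify performance claims on clinical
data. In particular, coverage benchmarks depend on sample size (hull
coverage of a small query set by a large training set is optimistic), so
what counts as "good" coverage should be calibrated per dataset — for
example by measuring train/test self-coverage within one site.

## Known limitations

* 2D projections bound, but do not equal, full-dimensional overlap; the
  approximation is sound only when densities are reasonably homogeneous
  within the box spanned by the projection intersections.
* DBSCAN parameters are heuristics; pathological densities may need manual
  `eps`/`min_samples`.
* Site-median imputation ignores multivariate structure.
* The origin classifiers detect *that* distributions diverge, not *where*;
  the coverage analysis supplies direction, the classifiers supply breadth.
* No probability calibration, model persistence, or feature attribution.
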