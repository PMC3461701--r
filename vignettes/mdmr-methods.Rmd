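---
title: "Distance matrix regression: model, tests, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance matrix regression: model, tests, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmreg)
```

## The model

Multivariate distance matrix regression (MDMR) treats the P variables
measured on each of N samples as a *profile*, summarizes all profiles by an
N×N distance matrix D, and asks whether M ancillary predictors explain
variation in those distances. Write A = −½ D∘D and

$$G = \left(I - \tfrac{1}{N}\mathbf{1}\mathbf{1}'\right) A
      \left(I - \tfrac{1}{N}\mathbf{1}\mathbf{1}'\right),$$

the Gower-centered inner-product matrix. With H the hat matrix of the design
(intercept plus regressors), the test statistic is the trace ratio

$$F = \frac{\mathrm{tr}(HGH)}{\mathrm{tr}\big((I-H)\,G\,(I-H)\big)}.$$

Because H is idempotent the cross terms vanish and
tr(HGH) + tr((I−H)G(I−H)) = tr(G): the statistic partitions the total
distance-based variation, and tr(HGH)/tr(G) is reported as the variance
fraction (the distance-space analogue of R²). For Euclidean distances on
complete data, G is the Gram matrix of the column-centered data, so with
P = 1 and a two-group predictor the two traces are literally the
between-group and within-group sums of squares and the procedure collapses
to one-way ANOVA. This equivalence is enforced to 1e-8 in the test suite.

### Degrees of freedom

Two different degree-of-freedom scales matter, and conflating them is the
one place where a plausible implementation goes badly wrong:

* the *statistic* is scaled in sample space,
  $F^* = F \cdot (N - M - 1)/M$, the analogue of the classical
  mean-square ratio;
* the *reference distribution* for the analytic p-value is
  $F(P \cdot M,\; P N - M - 1)$: the numerator and denominator degrees of
  freedom grow with the number of variables behind the distance matrix.

For M = 1 the reference pair is (P, P·N − 2). Under iid normal nulls the
exact distribution of F\* is F(P, P(N−2)); the reference pair overstates the
denominator df by P·2 − 1, which is negligible at N = 100 but makes the
analytic test visibly anticonservative at N = 4 (about 8% rejection at the
5% level — a property the acceptance suite checks, since it discriminates
this df convention from the alternative of scaling the statistic itself by
the variable-scaled df, which would reject ~40% of the time at N = 4).
For M > 1 the rule (P·M, P·N − M − 1) is our documented extrapolation — it
reduces to the single-regressor rule and to classical regression df at
P = 1 — and the permutation test is authoritative in that regime
(`extrapolated_df` is flagged in every result).

### Permutation test

The null distribution is built by relabeling the samples of the regressor
block while D (hence G) stays fixed. Since
tr(H G[π,π]) determines the permuted statistic and
tr(G[π,π]) = tr(G), only the model trace is recomputed per permutation; for
a single regressor H = 11′/N + uu′ with u the unit vector spanning the
centered predictor, so all permuted statistics come from one matrix
product — this is what keeps thousand-simulation × hundreds-of-permutations
experiments inside a minute on one CPU.

Conventions, chosen once:

* Sampled mode uses the add-one estimator p = (1 + b)/(B + 1), which cannot
  return zero and has valid level.
* When the number of *distinct* relabelings (the multiset permutations of
  the design rows, e.g. `choose(N, N/2)` for a balanced dichotomy) is at
  most `n_perm`, the test switches to exhaustive enumeration with
  p = #{F ≥ F_obs}/#arrangements, identity included. At N = 4 with a 2/2
  split there are only 6 arrangements, so the smallest attainable p is 1/6 —
  which is why permutation tests at tiny N are severely conservative at the
  1–5% levels while the analytic p-value is anticonservative there.
* Ties count toward the numerator (conservative), with a 1e-8 relative
  tolerance so that exact ties arising from symmetric relabelings are not
  broken by floating-point summation order.

### Collinearity

H is formed from a column-pivoted QR factorization of [1, X]; columns whose
pivot falls below 1e-10 (relative) are dropped and reported in
`dropped_columns`, never silently absorbed. The intercept is always
included: with G doubly centered the intercept direction contributes zero
to tr(HGH), but omitting it breaks the ANOVA correspondence for 0/1 coded
groups.

## Distances and missing data

Euclidean and Manhattan distances are computed over pairwise-complete
coordinates and rescaled by `sqrt(P/P_shared)` (Euclidean) or `P/P_shared`
(Manhattan), so that the expected distance is comparable across pairs with
different missingness; `min_shared_fraction` (default 0.5) bounds how much
missingness a pair may have before the distance is refused. The
correlation distance is d = 1 − r (range [0, 2]); zero-variance profiles
are an error rather than an NA. The similarity transform for display is
s = 1 − d/d_max with an empirical or theoretical maximum.

## What the generators emulate

The synthetic-data module reproduces the simulation conditions under which
the method's level accuracy and power were characterized:

* **Null level accuracy** — N ∈ {100, 50, 20, 10, 4} samples, P = 10 iid
  standard-normal variables, a dichotomous 50/50 (or continuous standard
  normal) predictor independent of the data, 1000 simulations; empirical
  rejection rates are tabulated at nominal levels 1–75%.
* **Power versus effect** — N = 30 split 15/15, P = 100, a common mean
  shift added to all (or a fraction of) variables of the experimental
  group. The default shift grid has step 0.02: with 500–1000 simulations
  per point, Monte-Carlo error (binomial SE ≈ 1.8% near 80% power) already
  makes a finer grid meaningless. MDMR reaches 80% power near a 0.24 SD
  shift; the Bonferroni t comparator (reject if any of the P per-variable
  pooled t-tests has p ≤ 0.05/P) reaches it near 0.56 — the value implied
  by its exact noncentral-t closed form
  $1 - (1 - \pi_1)^P$, $\pi_1 = P(|T_{N-2,\delta\sqrt{n_0 n_1/N}}| >
  t_{1-\alpha/2P})$, against which the simulation is verified within
  Monte-Carlo error.
* **Power versus N and versus regressor correlation** — the same designs
  with the sample size or the regressor-variable correlation varied.
* **Distribution families** — besides iid normal: a bimodal equal mixture
  of N(−1, 0.5²) and N(1, 0.5²), a log-normal exp(N(0,1)), and an
  equicorrelated multivariate normal; all standardized to unit variance so
  shifts stay in SD units. The bimodal and log-normal parameters are this
  package's choices (the qualitative claim is robustness of level and
  power across shapes, not specific numbers).

What the generators do *not* emulate: heteroscedasticity across variables,
heavy-tailed outliers, block correlation structure beyond equicorrelation,
and missing data; passing simulations therefore show calibration and power
under clean exchangeable nulls, not robustness to those features of real
assays.

Every experiment driver takes a single integer seed and is exactly
reproducible from it; reported rates carry binomial standard errors.

## Choosing the number of clusters

`select_k()` scans k = 2..k_max: cluster (UPGMA cut of the distance matrix,
or k-means with 10 restarts on the raw data), dummy-code membership into
k−1 indicators (reference coding, labels canonicalized by first occurrence
so the design is deterministic), and run MDMR. "Adding clusters does not
add significantly" is operationalized as a permutation test of the
*marginal gain*: the (k+1)-clustering's indicators are added to the
k-clustering's design, the gain in tr(HGH) is recorded, and the added block
is permuted while the base block stays fixed; the scan stops at the first
k whose k→k+1 gain has p > 0.05. A scan whose k = 2 test is already
nonsignificant reports one cluster; if every increment is significant the
rule is indeterminate and the k with the largest scaled F is reported,
labelled `argmax_f`. Both the per-k trace and the increment trace are
returned, because the "highest F" and "first nonsignificant increment"
readings can disagree and the honest output is the full scan.

Two caveats are worth stating. Testing cluster labels that were themselves
derived from D against D is circular; under pure noise the nominal p-values
of the per-k fits are optimistic, which is why the increment rule rather
than the raw per-k significance drives the selection. And over-splitting a
true two-group structure into five clusters still explains slightly *more*
raw variation — it is the sample-space df penalty in F\* that makes the
true grouping win, a tendency (not a certainty) checked over hundreds of
replicates in the acceptance suite.

## Numerical choices

* Symmetry/diagonal tolerance for input distance matrices: 1e-8 relative;
  matrices within tolerance are symmetrized as (D + D′)/2.
* Gower centering is computed as a_ij − ā_i· − ā_·j + ā_··, equal to the
  explicit C A C product to machine precision (enforced against a
  brute-force oracle in the tests).
* QR pivot threshold 1e-10 relative; permutation-tie tolerance 1e-8
  relative; CSV round-trips preserve entries to 1e-12 (17 significant
  digits on write).
* Monte-Carlo problem sizes in the shipped tests and acceptance script:
  1000 simulations × 200–500 permutations for level/agreement studies,
  500 simulations per grid point for power curves — sizes at which binomial
  error, not the grid, limits precision, and a full run stays around a
  minute on one CPU.

## Limitations

The analytic p-value is trustworthy for N well above ~10 and Euclidean
distances; for tiny N, non-Euclidean distances (where G need not be PSD and
the raw trace ratio can in principle be negative), or M > 1, rely on the
permutation test. The missing-data rescaling keeps distances comparable in
expectation but no claim is made about the critical level of missingness a
study can tolerate. k-means operates on the raw data matrix only;
clustering arbitrary distance matrices by k-medoids is out of scope, as are
heatmap/dendrogram rendering and ordination embeddings.
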