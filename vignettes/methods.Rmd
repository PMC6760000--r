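---
title: "Exhaustive subset selection for neonatal DTI gait prognosis: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive subset selection for neonatal DTI gait prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdti)
```

## The problem and the procedure

Very-low-birth-weight preterm infants carry a substantially elevated risk of
motor impairment. Regional diffusion-tensor imaging (DTI) at near-term age
summarizes white-matter microstructure as four scalar metrics per region —
fractional anisotropy (FA, dimensionless in [0, 1]) and mean, axial and
radial diffusivity (MD, AD, RD, in mm²/s) — over a 99-region vocabulary
(48 bilateral regions on each side plus the genu, splenium and body of the
corpus callosum), giving up to 396 candidate features per infant. The
question this package operationalizes: which *set of three* regional
metrics, taken together, best predicts a toddler-age gait outcome
(walking velocity, step length, step width, single-limb support, or a
composite temporal-spatial deviation index), either as a continuous value
or as a binary high-risk classification?

The procedure is deliberately simple and fully linear:

1. **Preprocessing.** Every feature column is adjusted for postmenstrual
   age (PMA) at scan by ordinary least-squares residualization on
   (intercept, PMA), then standardized to zero mean and unit variance.
2. **Exhaustive search.** Every $\binom{m}{3}$ subset of features is
   scored. There is no greedy shortcut: with 396 features this is
   10,271,580 subsets, which is why the search is chunked, logged and
   checkpointable.
3. **Penalized linear models.** Each subset is fit with L2
   (ridge/logistic) regression at regularization strength
   $\lambda = 1$, intercept unpenalized.
4. **Leave-one-out cross-validation (LOOCV).** Each subset's score is
   computed from $n$ refits, each excluding one subject, pooling the
   held-out predictions: adjusted $R^2$ for the continuous task, ROC-AUC
   for the classification task.
5. **Operating point.** For classification, one
   (sensitivity, specificity) pair is selected from the cross-validated
   ROC by maximizing $\mathrm{sens}^2 + \mathrm{spec}^2$.
6. **Impairment labels.** A subject is "impaired" on an outcome when the
   score is strictly worse than one standard deviation from a
   typically-developing cohort mean, in the outcome's declared direction.

## Model conventions (and why they must be pinned down)

Several conventions are underdetermined in any prose description of this
kind of analysis; the package fixes each one explicitly and exposes the
alternatives as switches.

**Penalty convention.** "Regularization strength 1.0" can mean the
penalty multiplier $\lambda$ or an inverse penalty (as in
`C`-parameterized logistic implementations, where the documented objective
is $-\ell + \tfrac{1}{2C}\lVert\beta\rVert^2$). The defaults are: ridge
objective $\sum_i (y_i - \beta_0 - x_i\beta)^2 + \lambda\lVert\beta\rVert^2$
and logistic objective $-\ell(\beta) + \tfrac{\lambda}{2}\lVert\beta\rVert^2$,
both with $\lambda = 1$ and the intercept never penalized (standard
practice). `penalty_spec(convention = "inverse_strength")` reproduces the
inverse parameterization, and `scale_by_n`/`penalize_intercept` cover the
remaining ambiguities. Because every feature is standardized and $k = 3$
is tiny, the selected subsets are insensitive to these switches; the
coefficients are not, which is why the convention is printed with every
serialized fit.

**Preprocessing scope.** Residualization and standardization are applied
once on the full sample by default (`scope = "global"`), matching a single
whole-cohort preprocessing pass. This leaks distributional information
into LOOCV: the held-out subject's value participated in the means,
variances and PMA slopes. The alternative
(`scope = "per_training_fold"`) recomputes standardization on each
training fold and applies it to the held-out row. The default follows the
most literal reading of a single preprocessing pass; the leakage-free
variant exists because the optimism it removes is real, if small at
$n = 52$.

**Scores.** The CV $R^2$ pools all $n$ held-out residuals into one
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ rather than averaging per-fold
scores (a per-fold $R^2$ is undefined for single-observation folds), and
the adjustment is $1 - (1 - R^2)(n-1)/(n-p-1)$ with $p = k = 3$, not
counting the intercept. There is no unique "cross-validated adjusted
R²" in the literature, so the formula is stated here and in every report.
AUC is the Mann–Whitney statistic with midrank ties, identical to
trapezoidal integration of the ROC as constructed.

**ROC and operating point.** The positive rule is score ≥ threshold;
thresholds are the unique observed scores plus a $+\infty$ sentinel, so
(0, 1) and (1, 0) are always on the curve. Ties on
$\mathrm{sens}^2+\mathrm{spec}^2$ break toward higher sensitivity first:
in a screening context a missed impaired infant costs more than a false
referral.

**Impairment strictness.** "Worse than one SD" is a strict inequality: a
score exactly at mean ± SD is not impaired. The direction is a required
input for every outcome — low velocity is impaired but *high* step width
is impaired, and for the composite deviation index no default is safe.

**Degenerate cases.** A logistic training fold that loses its minority
class entirely predicts the training prevalence and is flagged, rather
than aborting a 10-million-subset run; a subset whose evaluation fails
outright is scored $-\infty$ with the reason logged. A collinear design
at $\lambda = 0$ falls back to the minimum-norm pseudo-inverse solution
with a warning. Logistic fits use Newton iterations from zero with
step-halving, converged when the gradient max-norm is below $10^{-8}$;
ridge fits are closed-form. For the linear task with global preprocessing
the LOOCV predictions use the exact leave-one-out identity for penalized
linear smoothers, $\hat y_{-i} = (\hat y_i - h_{ii} y_i)/(1 - h_{ii})$;
this is algebra, not approximation, and the test suite verifies equality
with naive per-fold refitting at $10^{-10}$.

**Determinism.** Subsets are enumerated in lexicographic order by a
combinatorial unranking function, score ties break lexicographically, and
scores are kept at full double precision until report time (tables round
half-up to two decimals, rates to whole percents). A checkpoint file
(chunk index, best-so-far buffer, input fingerprint) makes an interrupted
search resumable with a byte-identical final ranking.

## What the synthetic cohort emulates

No subject-level data ships with the package, so a generator produces
cohorts with the statistical structure the analysis assumes, and the
validation suite runs against *planted truth*.

**Tensor coherence.** Features are not drawn independently: each region
gets per-subject eigenvalue triples
$\lambda_1 \ge \lambda_2 \ge \lambda_3 > 0$ (baseline + per-week
maturation slope × PMA deviation + noise, re-sorted and floored at
$10^{-9}$), and FA/MD/AD/RD are derived from them. The identities
$AD = \lambda_1$, $RD = (\lambda_2+\lambda_3)/2$, $MD = (AD + 2RD)/3$
hold exactly (MD is computed *from* AD and RD, so the identity is exact in
floating point), and FA is the usual normalized eigenvalue dispersion in
[0, 1]. Default maturation slopes shrink the radial eigenvalues faster
than the axial one, so FA rises and MD/RD fall with scan age — the
directionality regional DTI shows in the neonatal period — and PMA is
drawn from a normal with mean 36.5, SD 1.2 weeks (truncated at ±3 SD),
matching the scan-age distribution of the cohort the defaults emulate.

**Within-region dependence and identifiability.** Because all four
metrics of a region derive from three eigenvalues, they are intrinsically
dependent; MD in particular is an *exact* linear combination of
same-region AD and RD. Two design choices follow. First, the default
planted features are FA, AD and RD in three distinct regions — planting
MD would make the "true" subset unidentifiable by construction, since
other pool columns span it. Second, the default eigenvalue noise SDs,
(4.5, 5, 2.5) × 10⁻⁵ mm²/s, spread subject-level variation unevenly so
the worst within-region correlations sit near 0.75–0.8: strong enough to
be a real obstacle (as in regional DTI, where sibling metrics correlate
highly), short of the near-singular regime in which no finite sample
could distinguish a planted feature from its sibling. With this
structure, the exhaustive linear search recovers the exact planted triple
in about 19 of 20 cohorts at $n = 150$ — the regime the recovery tests
assert — and the misses substitute a same-region sibling, never an
unrelated feature.

**Outcome and labels.** The latent outcome is
$\sum_j w_j z_j + \varepsilon$ over the scan-age-adjusted, standardized
planted features — the toddler outcome depends on microstructure, not on
when the scan happened, so the PMA component of a feature carries no
outcome signal and the planted effect lies exactly in the space the
pipeline searches after residualization —
with default weights $(1, -0.9, 0.8)$ and noise set so the planted signal
explains half the latent variance (population $R^2 = 0.5$). Thresholding
a latent variable of which the features explain only half the variance
caps classification performance well below perfection, so the
cross-validated AUCs the validation suite measures for the winning
subsets sit in the low-to-mid 0.8s by design, not by deficiency. The latent scale is mapped
affinely to a clinical scale — defaults emulate a velocity-like outcome
with a typical-cohort reference of mean 95, SD 16 cm/s ($n = 42$), a
preterm cohort SD 15% wider, and the offset placed so the one-SD
impairment threshold cuts the latent distribution at a target prevalence
of 14/52. Realized prevalence then varies binomially around the target.
Binary MRI findings for the comparison arm are drawn with configurable
base rates (defaults ~5–16%) and a mild odds-ratio association (2) with
impairment — deliberately weak, since the comparison arm's point is that
a handful of coarse binary findings carries little cross-validated
signal.

**Streams.** One seed fully determines a cohort; internally it is split
into independent sub-streams (scan ages, tensors, outcome noise,
findings), so enlarging the region pool appends tensor draws without
perturbing the outcome noise, and a cohort with more regions still has
the same outcome realization.

**What passing does not show.** The generator produces Gaussian,
linearly-confounded, linearly-predictive features with exactly three
relevant columns. Real regional DTI has registration error, non-Gaussian
artifact tails, spatially correlated *between*-region structure, and no
guarantee that any 3-feature linear model is well specified. Recovery of
planted signals validates the machinery — enumeration, fitting, CV
accounting, operating-point selection — not the clinical claim.

## A pooled-LOOCV caveat: null models score *below* chance

Pooling leave-one-out probabilities has a known artifact: when the model
is close to intercept-only, each held-out positive was predicted by a
model trained at a slightly *lower* prevalence (its own positive label
was removed), so held-out probabilities are weakly anti-correlated with
the truth and the null CV AUC falls below 0.5 rather than centering on
it. For continuous features the coefficient noise dominates and the
effect is mild (null medians around 0.43–0.45 at the emulated cohort
size); for a handful of near-uninformative binary findings — the
structural-MRI comparison arm under the null — the fit *is* essentially
intercept-only and the pooled CV AUC collapses toward 0. This is worth
knowing when reading the comparison table: a very low MRI-arm CV AUC
means "no usable cross-validated signal", not "informatively wrong". The
apparent (same-data) AUC of the same null models stays near 0.5, which
is why both are reported.

## Selection optimism, honestly reported

The reported CV score of the *winning* subset is a maximum over up to
~10⁷ candidates and is therefore optimistically biased even though each
individual score is cross-validated; with 396 features there is no inner
loop that corrects this without nesting the entire search. The package
does not silently adjust for it. Instead every report shows apparent and
cross-validated scores side by side (the within-subset optimism gap), and
`permutation_null()` re-runs the full search on outcome-permuted copies
to show the distribution of the best CV score under no association — on
null cohorts the best-of-many CV AUC sits visibly above 0.5, which is the
selection effect made tangible. The one-sided permutation p-value uses
the standard $(1 + \text{exceedances})/(1 + B)$ form.

## Problem sizes used in the validation suite

The test and acceptance suites run at desk scale, chosen so the full
suite exercises every code path in minutes: oracle-equivalence suites at
$n \le 15$ against naive per-fold refits and exhaustive threshold scans;
recovery suites at $n = 150$ over a 20-feature pool (1,140 subsets per
search; 20 seeds linear, 5 logistic); null calibration over 50 cohorts at
the emulated study size $n = 52$; and an end-to-end run on a 10-feature,
$n = 30$ cohort through the delimited-text round trip. The full
396-feature grid is available (`cohort_config(n_features = 396)`, or real
data of that width) and runs the identical code path with chunked
progress and checkpointing; it is hours-scale and not part of the test
suite.

## Known limitations

- LOOCV only; no k-fold or repeated CV, and no nested CV around the
  selection step (see above for how optimism is surfaced instead).
- Linear models only: no interactions, no elastic-net/L1, no probability
  calibration, no class weighting for the imbalanced outcomes.
- No confidence intervals on sensitivity/specificity at the operating
  point.
- The generator does not emulate images, registration error, or
  between-region correlation beyond the shared scan-age confound.
- Global preprocessing (the default) leaks fold information as discussed;
  switch to `per_training_fold` when leakage-free estimates matter more
  than matching the single-pass convention.
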