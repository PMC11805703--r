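---
title: "Variance decomposition of longitudinal BMI trajectories in twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition of longitudinal BMI trajectories in twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twintraj)
```

## The problem

Body mass index (BMI) measured repeatedly from early adolescence into
midlife carries two distinct signals per person: a *level* (BMI at some
reference age) and a *rate of change* (annual BMI gain). In twin cohorts,
contrasting monozygotic (MZ) pairs — who share essentially all segregating
genetic variation — with dizygotic (DZ) pairs — who share half on average —
identifies how much of the variation in each signal, and of the covariation
between them, is attributable to additive genetic factors. `twintraj`
implements that full analysis chain: trajectory extraction, univariate and
multivariate twin variance decomposition, and polygenic-score correlation,
together with a synthetic-cohort generator whose architecture is known
exactly, so that every stage can be validated by parameter recovery rather
than by fiat.

## The growth model

Adult-wave observations (three waves at mean ages roughly 17.5, 24 and 37
years) enter a linear mixed-effects model

$$\mathrm{bmi}_{ij} = \beta_0 + \beta_1 (a_{ij} - 17.5) + u_{0i} + u_{1i}(a_{ij} - 17.5) + \varepsilon_{ij},$$

with correlated random intercepts and slopes per individual and REML
fitting (`lme4`; ML is available for likelihood comparisons). Each
individual's trajectory estimate is the fixed effect plus the
empirical-Bayes (BLUP) deviation, so the intercept is the model-implied
BMI at the centering age (17.5 years by default, configurable) and the
slope is in kg/m² per year. BLUPs shrink toward the fixed line relative to
per-individual least squares; this is intentional and is verified by a
test. Only individuals observed at all three adult waves are used
(`select_complete_individuals`), and at least three observations per
individual are required — with fewer, a per-individual line plus residual
is not identified.

Two choices here were genuinely open. First, fits are stratified by sex by
default, because male and female levels and trajectories differ
substantially and all downstream analyses are sex-specific. Second, the
growth model contains no family-level random effect: twin non-independence
inflates nothing downstream, because the trajectory estimates are
subsequently analysed by models that represent the pair covariance
explicitly.

## The twin model

For a trait with per-pair observations $(y_1, y_2)$, the expected
within-group covariance is assembled from path coefficients $a, c, e$ (or
$d$) as

$$\Sigma_g = \begin{pmatrix} \sigma^2 & \kappa\,\mathrm{cov} \\ \kappa\,\mathrm{cov} & \sigma^2 \end{pmatrix},\qquad
\sigma^2 = a^2 + c^2 + e^2,$$

with cross-twin constants $\kappa_A = 1$ (MZ) and $0.5$ (DZ),
$\kappa_C = 1/1$, $\kappa_D = 1/0.25$, $\kappa_E = 0/0$. Five groups enter
the likelihood: MZ male, MZ female, DZ male, DZ female, and opposite-sex DZ
(male twin listed first; the genetic correlation of opposite-sex pairs is
fixed at 0.5). The likelihood is full-information maximum likelihood
(FIML): rows are grouped by missingness pattern and each pattern
contributes its own Gaussian term, so partially observed pairs are used
without imputation. With no missing data this is identical to the
complete-data likelihood, which a test asserts exactly.

Shared environment and dominance are not jointly identifiable with twins
reared together, so `twin_model_spec` refuses `C` together with `D`. Path
coefficients are sign-unidentified; the package reports absolute paths and
standardized variance shares ($a^2 + c^2 + e^2 = 1$) only.

Three sex-limitation variants are provided, and their definitions are a
design decision of this package (the field uses these names without a
single canonical definition): `"full"` (separate paths and means per sex),
`"no_sex_difference"` (everything equated), and `"no_sex_genetic"`
(genetic paths equated, environmental paths and means free). Model choice
proceeds by likelihood-ratio tests against a reference, selecting the most
parsimonious model not significantly worse at $\alpha = 0.05$, with AIC as
tie-break.

The saturated model estimates each group's two means, two variances and
covariance freely; for complete data its maximum is the closed-form
sample-moment value, which is used directly. Comparing it against the
birth-order-constrained variant tests the classical equal-means/equal-
variances assumption. Violations are flagged, not fatal: with large
samples these tests reject for differences too small to distort variance
shares, and the analysis chain mirrors the field's practice of reporting
and proceeding.

### Numerical choices

Optimization is quasi-Newton (BFGS) on the unconstrained path scale with
Falconer moment estimates as starting values, a Nelder-Mead polish, up to
five jittered restarts, and `parscale` set from the start values — the
latter matters because BMI-level paths (units of kg/m²) and slope paths
(kg/m² per year) differ by two orders of magnitude, which would otherwise
break finite-difference gradients. Any non-positive-definite candidate
covariance returns `Inf` rather than an error, so optimizers back away
from the boundary. Likelihood equality checks in tests use tolerances of
1e-6 to 1e-12; nested-model deviances are allowed to go negative by at
most 1e-4 (optimizer tolerance).

Profile-likelihood confidence intervals for a standardized share $s$
re-optimize all nuisance parameters at each candidate value — the
constrained sex's paths are reparameterized as a total variance plus a
split of the remaining share — and locate the bounds where the profiled
$-2\ell$ rises by $\chi^2_1(0.95) = 3.841$, by bisection. Shares of exactly
0 or 1 can make a group covariance singular, so the profile is evaluated
just inside the boundary (at $10^{-6}$), and unbracketed bounds are
reported at the boundary with a flag.

Likelihood-ratio tests of a variance component against zero sit on the
boundary of the parameter space; the naive $\chi^2_1$ p-value is the
default (mirroring common practice), with the conservative 50:50 mixture
available via `boundary = TRUE` in `compare_models`. The calibration test
accepts the resulting conservatism: under a true AE model the ACE-vs-AE
rejection rate at nominal 0.05 is expected near 0.025.

## The multivariate Cholesky decomposition

For $k$ traits, each component covariance is parameterized as
$\Sigma_X = T_X T_X^\top$ with $T_X$ lower-triangular, which keeps
$\Sigma_A$ and $\Sigma_E$ positive semi-definite by construction. The
expected $2k \times 2k$ pair covariance has the phenotypic
$\Sigma = \Sigma_A + \Sigma_E$ on the diagonal blocks and
$\kappa_A \Sigma_A$ off-diagonal. Standardizing gives the genetic and
environmental correlations

$$r_X[i,j] = \frac{\Sigma_X[i,j]}{\sqrt{\Sigma_X[i,i]\,\Sigma_X[j,j]}},$$

and the share of a phenotypic covariance carried by each component is
$\Sigma_X[i,j] / \Sigma[i,j]$ (the shares sum to one by construction).
Trait order affects the triangular paths but not the implied covariances;
a test asserts order invariance of $\Sigma_A$ and $\Sigma_E$. The default
trait set and order is (BMI at the first wave, BMI at the second wave,
intercept, slope); the AE Cholesky is the default, with an ACE variant
available.

By-sex multivariate fits use the same-sex MZ and DZ groups of that sex;
opposite-sex pairs are excluded from per-sex fits (a decision — with
per-sex parameters an OS pair's cross-block would mix both sexes' paths
and contributes little at these sizes). Confidence intervals for the
correlation matrices use the delta method on the Fisher-z scale (numeric
Jacobian against the inverse $-2\ell$ Hessian) and are labeled
`ci_method = "delta"`; profiling every correlation of a $k=4$ fit was
judged not worth its cost given that the univariate module provides
profile CIs where the headline shares live.

## The polygenic-score module

A precomputed score is regressed on the top ten genetic principal
components with a family random intercept (population-stratification
correction); the conditional (within-family) residuals are standardized to
mean 0, variance 1. Conditional rather than marginal residuals are the
default because the family effect is a nuisance stratification term —
a `conditional = FALSE` switch provides the marginal variant. Correlations
with traits are Pearson with Fisher-z intervals; twin non-independence is
ignored by default (matching common reporting), with an effective-sample-
size cluster adjustment available and labeled. Strength labels use the
bins weak $[0, 0.40)$, moderate $[0.40, 0.60)$, strong $[0.60, 1]$ — the
half-open intervals close the gaps the verbal convention leaves at 0.395
and 0.595. The two-sample Kolmogorov-Smirnov statistic is the supremum
distance between right-continuous empirical CDFs; the p-value is exact for
small tie-free samples ($n_1 n_2 \le 10^4$) and asymptotic otherwise.

## The synthetic cohort

The generator draws, per pair, latent additive-genetic vectors that are
identical within MZ pairs and correlated 0.5 within DZ pairs via the
$\sqrt{0.5}$-shared/$\sqrt{0.5}$-unique construction (distributionally
identical to a joint multivariate-normal draw, with simpler code), shared-
environment vectors identical within pairs, and independent unique-
environment vectors. Trait values are sex-specific means plus triangular
loadings times the latents, so the implied covariances are known exactly
and are echoed in a truth manifest (implied $a^2$, $r_A$, $r_E$, and MZ/DZ
cross-twin covariances, whose 2:1 genetic ratio is asserted by a test).

The default architecture emulates a five-wave Finnish-style BMI follow-up:

* group sizes 100 pairs per zygosity-by-sex group (on the order of the
  ~500 complete pairs such cohorts retain);
* trait means per sex (e.g. male/female intercept 21.77/20.99 kg/m², slope
  0.24/0.22 kg/m² per year) and SDs around 2.6 kg/m² for levels and 0.10
  kg/m² per year for the slope;
* heritabilities 0.84 (adolescent levels), 0.80 (intercept), 0.635
  (slope), with genetic correlations 0.44–0.85 and small environmental
  correlations — values in the range such cohorts report;
* wave ages jittered around 11.4, 14.0, 17.6, 24.2 and 37.2 years with the
  observed age SDs, truncated at ±3 SD, identical for co-twins (twins
  share a birth date and survey occasion);
* adult-wave observations generated from each individual's intercept and
  slope as $\mathrm{bmi}(a) = \mathrm{int} + \mathrm{slope}(a - 17.5) +
  N(0, 0.5)$; the first two waves observe the adolescent traits directly;
* a polygenic score $\lambda A_1 + \sqrt{1-\lambda^2}\,\epsilon$ with
  $\lambda = 0.35$ on the first genetic factor, standardized — giving
  score-trait correlations near 0.3 for the first trait
  ($\lambda \cdot a$), the range reported for BMI scores.

Trajectory traits are generated directly (intercept and slope are latent
traits; waves are derived from them) rather than induced by simulating all
five waves and letting the growth model define them; the direct route
makes the twin-model truth exact. The generator emulates the *structure*
of a real cohort, not its full texture: BMI is generated Gaussian (real
BMI is right-skewed), missingness is independent per observation (real
attrition is correlated with BMI and within person), zygosity is known
without error, and the score is generated at the score level, not from
genotypes. Recovery tests on this cohort therefore validate the
estimators, not the robustness of the design to those real-data features.
Dominance generation is not implemented (the analysis models here select
AE throughout); the configuration schema reserves a slot for it.

## Problem sizes in the validation suite

The test suite checks recovery at 2000 pairs/group (grid of
heritabilities, mean absolute error ≤ 0.03), CI coverage over 500
replicates of 500-pair cohorts, LRT calibration over 200 null replicates
of 300-pair cohorts, and the ML-vs-Falconer oracle equivalence at 50,000
pairs/group — the last because the two estimators, while both consistent,
differ by a sampling term with SD ≈ 0.046·√(2000/n), so the 0.03
agreement band is only a sound check when n makes that term small. The
Falconer oracle uses ANOVA intraclass correlations (the classical twin
rMZ/rDZ), not column-wise Pearson correlations, as the moment analogue of
the equal-means/equal-variances likelihood.

## Known limitations

Linear trajectories only; three adult observations per individual cannot
support curvature. The growth model ignores twin clustering (see above).
Sex-limitation variants do not include a qualitative-sex-limitation model
with a free opposite-sex genetic correlation. The multivariate CIs are
delta-method, not profile. Assumption-test violations are reported, never
enforced. None of the package's outputs on simulated data estimate any
real cohort's parameters; they demonstrate that the machinery recovers
known truths under the stated generating conditions.
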