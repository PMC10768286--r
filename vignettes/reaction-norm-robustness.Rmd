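---
title: "Reaction-norm models for robustness of growth: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-norm models for robustness of growth: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robustnorm)
```

## The problem

Livestock populations are managed across locations and years that differ
widely in growth conditions. When the relative genetic merit of animals
changes with the environment (genotype-by-environment interaction, G×E),
a single environment-free breeding value is an incomplete description of a
sire. A linear *reaction norm* describes each animal's merit as a straight
line over an environmental gradient: an intercept `a0` (overall merit at
the average environment) and a slope `a1` (how merit changes per unit of
environment). A *robust* animal combines a high intercept with a flat
slope. This package implements the full pipeline for estimating and — more
importantly — *validating* such robustness breeding values in sheep-like
body-weight data:

1. derive the environmental covariable (EC) from the data themselves,
2. fit linear reaction-norm mixed models by REML,
3. compute intercept, slope and scale-corrected-slope EBV with prediction
   error variances,
4. validate slope EBV against the realized performance of progeny by
   cross-validation, forward prediction, and between-dataset comparison,
5. generate synthetic populations with the same variance structure so that
   every stage can be exercised end to end.

## The environmental covariable

The EC of a contemporary group (CG; flock × year × management group) is the
best linear unbiased estimate (BLUE) of the group's post-weaning growth
rate (PWGR, g/day), from a mixed model with fixed sex, birth-by-rear type,
post-weaning age (linear and quadratic) and CG, plus random additive
genetic effects and optionally random genetic-group effects and a dam
permanent-environment effect (`derive_ec()`). CG effects are estimable only
up to a reference; we drop the first CG level and re-centre the solutions
afterwards, which leaves all downstream quantities invariant. The centred
values are standardized to mean 0 and variance 1 across CGs — unweighted by
CG size by default, because the EC is a property of the *environment*, not
of how many lambs happened to be recorded in it (a size-weighted option is
provided). Slopes are therefore expressed per SD of EC; `slope_per_gday()`
converts to g/day units using the EC standard deviation.

The EC is derived once on the full data and treated as known downstream.
Cross-validation folds split progeny, not contemporary groups, so no EC
re-estimation happens within training folds — deliberately mirroring how
such analyses are run in practice.

Record eligibility before EC derivation (`filter_records()`): known sire,
dam, birth- and rear-type; at least 40 days between weaning and
post-weaning weighing; CGs with at least 15 animals from at least 3 sires;
PWGR within 4 SD of the mean. The 4-SD screen is applied once, globally
(not per CG) — the rule is a single outlier screen, and re-estimating the
SD after each removal could cascade. CG-level rules are re-checked after
record-level removals until stable. For reaction-norm fitting on a wide
gradient, `trim_by_ec()` optionally removes CGs beyond a limit (e.g.
±75 g/day or ±120 g/day of the mean), because sparse data at the extremes
of an EC produce unreliable slope estimates.

## The reaction-norm model

For phenotype vector `y` (post-weaning weight, kg):

    y = X b + Z1 a0 + Z2 a1 + Z3 c + Q g + Z4 m + e

with fixed effects `b` (sex, birth×rear, age linear+quadratic, CG, and
optionally dam age), additive genetic intercept `a0` and slope `a1` (`Z2`
carries each record's EC value), dam permanent environment `c` (identity
covariance — relationships between dams ignored), random genetic-group
effects `g` with common variance through the group-proportion matrix `Q`,
and optionally an additive maternal genetic effect `m` with pedigree
covariance and zero covariance with all other terms. The genetic
(co)variance is

    [a0; a1] ~ N(0, K ⊗ R),   K = [σ²a0  σa0a1; σa0a1  σ²a1]

where `R` is the pedigree relationship matrix `A`, a genomic matrix, the
single-step blend `H`, or an identity (sire model). The residual is either
a *continuous* function of the EC — intercept and slope residual
coefficients with 2×2 covariance `E`, so `var(e_i) = [1, x_i] E [1, x_i]'`
— or *discrete classes* along the EC. Genetic groups are fitted as random
with a common variance (they are reported as a variance component, not as
fixed regressions), which also keeps the equations full-rank with many
small groups.

`Q` rows are built by the standard recursion (average of parent rows;
unknown-parent slots contribute the animal's own group label) and always
sum to one. `A` uses the tabular method (`build_A()`), its sparse inverse
Henderson's rules with Meuwissen–Luo inbreeding (`build_Ainv()`); `G` is
VanRaden's first method with observed allele frequencies (`build_G()`,
missing codes imputed to twice the allele frequency); `blend_H()` forms
`G* = λG + (1-λ)A22` with λ = 0.95 by default — the weight is *on the
genomic information*, a convention that is configurable because software
implementations differ — and propagates the genotyped-block update to
relatives through the standard partitioned identity.

### REML

Variance components maximise the restricted likelihood, evaluated through
Henderson's mixed-model equations with sparse Cholesky factorisations:

    -2 logL = (n-p) log 2π + log|R| + log|G| + log|C| + y'Py.

The 2×2 covariances (K, E) are parameterised by their log-Cholesky factors
and scalar variances by their logs, so every iterate is automatically
positive definite — no projection onto the PSD cone is needed, and a
continuous residual can never go negative inside the fitted range. The
optimiser is Nelder–Mead (with restarts accepted once the likelihood
improves by less than 1e-6), which we chose over average-information
updates for robustness near boundaries (e.g. intercept–slope correlations
approaching ±1 on small data) at the cost of more likelihood evaluations;
each evaluation reuses the symbolic Cholesky analysis, so fits with tens of
thousands of equations remain tractable. Standard errors, when requested,
come from the numerically differentiated observed information on the
natural (covariance) scale; at boundary optima they are reported as
unavailable rather than fabricated.

### EBV, PEV, accuracy and the scale-corrected slope

`solve_blup()` solves the MME at given components. Because the equations
carry `R⁻¹` explicitly, the diagonal of the inverse coefficient matrix *is*
the PEV in trait units squared — the convention is stated here because
λ-ratio formulations of the MME scale it differently. Accuracy is
`r = sqrt(1 - PEV/σ²)` with the prior variance of the corresponding
component (K[1,1] for intercepts, K[2,2] for slopes).

Part of the slope variance merely reflects *scale-type* G×E: if the genetic
variance grows along the EC, high-intercept animals get steeper slopes
without re-ranking. The scale-corrected slope removes the genetic
regression on the intercept:

    a1* = a1 - (σa0a1 / σ²a0) a0,

leaving rank-type robustness (`scale_correct()`). Its PEV is not derived —
the `a1` accuracy serves as its approximation, a stated limitation. With
intercept–slope correlation `r`, the share of slope variance due to
scale-type G×E is `r²` (`scale_type_share()`), e.g. 0.16 % at r = 0.04.

`variance_profile()` evaluates `ΛKΛ'` on an EC grid (genetic variance
`σ²a0 + 2xσa0a1 + x²σ²a1`) and heritability with denominator genetic +
maternal genetic (if fitted) + dam permanent environment + residual at that
EC level; it refuses grid points outside the fitted EC range.

## Validation designs

**Threefold cross-validation** (`assign_cv_folds()`): within each sire,
progeny are ordered by EC and each consecutive triplet is randomly permuted
over the three folds, so every fold spans close to the sire's full
environmental range. Leftover one or two progeny are assigned by a random
partial permutation, making expected fold sizes equal (the leftover rule is
our choice; any fixed rule biases fold sizes). Sires qualify with ≥ 25
progeny and an EC range ≥ 60 g/day overall *and within every fold*;
progeny of non-qualifying sires remain permanently in the training data.
All randomness flows from one integer seed, and an identical seed gives a
bitwise-identical assignment.

**Pre-correction** (`precorrect_phenotypes()`): realized performance must
be measured on phenotypes free of fixed-effect, dam and group signal, so
`y* = y - Xb - Zc - Qg` with solutions from a full-data animal-model fit.
Note that the full-data fit deliberately includes the test records — that
is how the procedure is defined in practice, and the leak affects only the
nuisance corrections, not the genetic signal being validated.

**Realized regression** (`fit_realized_regression()`): within each test
fold, `y*` is regressed on the EC with a random intercept `p0` and slope
`p1` per sire, *identity* sire covariance (relationships deliberately
ignored so the realized values are not themselves smoothed by the
pedigree), the continuous residual model, and components re-estimated by
REML within the fold. The only fixed effect here is an overall mean:
phenotypes are already pre-corrected, and re-fitting the full fixed
structure would correct twice. Pearson correlations between training EBV
and realized (p0, p1) quantify predictive ability
(`correlate_validation()`); fold averages are arithmetic means.

**Forward prediction** (`forward_split()`): train on earlier birth years,
test on the following year's progeny of sires meeting the same
progeny-count and EC-range rules. The pre-correction, realized-regression
and correlation code paths are shared with the cross-validation design.

**Between-dataset comparison** (`compare_between_datasets()`): sires with
progeny in two independently analysed datasets get two sets of EBV; their
Pearson correlation is compared with the *expected* correlation — the
product of the two datasets' mean EBV accuracies over the common sires,
averaged on the Fisher-Z scale because accuracies are not normally
distributed (`fisher_z_mean()`, `expected_correlation()`). A realised
correlation below the expectation by a factor ρ is evidence of a
between-dataset genetic correlation of about ρ.

## The synthetic-population generator

`simulate_population()` builds the forward model exactly as the analysis
assumes it: unrelated founder sires (optionally paternal half-sib groups)
randomly mated to founder dams; progeny assigned uniformly to contemporary
groups whose ECs are equally spaced; true (a0, a1) drawn from K with
progeny values as parent average plus Mendelian sampling; dam
permanent-environment effects; residuals from the continuous model
`e = e1 + x e2` with `(e1, e2) ~ N(0, E)`. Every record's components are
stored so the phenotype identity `y = μ + fixed + a0 + a1 x + c + e`
reconstructs exactly. Optional unlinked biallelic markers are gene-dropped
so that `build_G()` approximates the pedigree relationships. What the
generator does *not* emulate: linkage and LD structure, selection over
generations, heterogeneous CG sizes, non-normal residuals, and breed
mixtures — passing tests therefore say nothing about those features of
real data.

Numerical defaults and why:

* **EC grid span ±√3 SD.** The EC is standardized to unit variance, so the
  progeny EC spread should have variance ≈ 1; an equally spaced grid over
  ±√3 has exactly that (a ±2 SD grid, by contrast, has variance 4/3).
  With the default EC SD of 38 g/day the implied span of ~131 g/day matches
  the bulk of a real EC distribution and keeps per-fold ranges comfortably
  above the 60 g/day eligibility rule.
* **Genetic components** of the cross-validation experiment
  (`cv_experiment_config()`): σ²a0 = 7.88 kg², σ²a1 = 0.64 kg²/SD-EC,
  r = 0.04, σ²c = 2.13 kg² — the full-data reaction-norm estimates for this
  trait. Genetic-group variance is omitted: the simulated population is a
  single breed and the experiment's analysis model carries no group term.
* **Residual covariance** E = [[10, 0.35], [0.35, 0.8]] kg². The residual
  intercept variance puts the within-CG phenotypic variance at the mean EC
  near 20 kg² (h²(0) ≈ 0.39, at the upper end of post-weaning-weight
  estimates, as expected after CG effects are absorbed); the residual scale
  increase mirrors the genetic one (E22/E11 ≈ K22/K11 ≈ 0.08) with a small
  positive residual intercept–slope correlation.
* One progeny per dam in the experiment ("random mating"), so the dam
  permanent environment is unidentifiable there and the analysis is a sire
  model; the parameter-recovery simulations use three progeny per dam so
  σ²c is estimable in the animal model.

## The simulated cross-validation experiment

`run_cv_experiment()` repeats, per replicate: simulate 337 sires ×
43 progeny; assign triplet folds; fit the sire-model reaction norm
(identity sire covariance, continuous residual) on two folds by REML;
pre-correct all phenotypes (the generator's only fixed effect is the
overall mean, so the Eq-4-style correction reduces to a GLS mean); estimate
each sire's realized regression in the held-out fold; correlate. With 20
replicates (the package's default; the experiment stabilises well before
that) the run-averaged correlations land near 0.68 for the intercept and
0.12 for the slope and scale-corrected slope, the values
`scripts/acceptance.R` recomputes. Successive fits are warm-started from
the previous estimates, which changes nothing about the optimum and roughly
halves the runtime (~6 minutes on one CPU at 20 runs).

## Problem sizes used in the checks

The test suite exercises: exact identities and hand-computable toys (≤ 60
records) against dense-matrix oracles; a full-scale parameter recovery (10
populations of 300 sires × 50 progeny, n = 15,000 records, animal model
with pedigree and dam permanent environment); the 20-run cross-validation
experiment above; and paired-dataset attenuation at between-dataset genetic
correlations 0.7, 0.9 and 1.0 (350 common sires × 60 progeny per dataset).
These sizes were chosen as the smallest at which the stochastic checks have
comfortable Monte-Carlo margins.

## Known limitations

* Linear reaction norms only; no quadratic or spline norms.
* Single-trait analyses; no multi-trait or maternal-direct covariances
  (the maternal term is constrained uncorrelated with all else).
* The PEV of the scale-corrected slope is approximated by the slope PEV.
* `build_A()` is dense and intended for up to a few thousand animals;
  large-pedigree work should stay on the sparse `build_Ainv()` path.
* Whether MTG2-style blending weights λ on G or on A22 is not documented
  in the field's software manuals; the convention here (weight on G) is
  explicit and switchable via the `lambda` argument.
* REML standard errors are asymptotic and unavailable at boundary optima.
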