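---
title: "Mapping general production and environmental sensitivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping general production and environmental sensitivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Dairy sires are progeny-tested: a bull's genetic merit is estimated from the
milk records of hundreds or thousands of half-sib daughters, milked across a
wide range of herd environments.  When genotype-by-environment interaction
(GxE) is present, a sire's merit is not one number — it is a *reaction norm*,
a function of the environment.  With a continuous environmental descriptor
$E$, a first-order reaction norm summarizes each sire $j$ by an intercept
$s_{j0}$ and a slope $s_{j1}$:

* the intercept, evaluated in the *average* environment ($E = 0$), is the
  sire's **general production (GP)**;
* the slope is the sire's **environmental sensitivity (ES)**; genetic
  variance in ES *is* GxE.

`reactnorm` implements a three-step mapping pipeline for SNPs affecting GP
and ES:

1. a random-regression **sire model** fitted by REML, yielding BLUP sire
   estimates of GP and ES;
2. a per-SNP **mixed linear model** association scan on those estimates,
   with a pedigree (numerator-relationship) polygenic term, Storey
   *q*-values, and a discovery/validation replication protocol;
3. a **log-transform decomposition**: repeating both steps on
   $\ln(y)$ separates *scaling* GxE (removable by a monotone
   transformation; no re-ranking of sires across environments) from
   *persistent* GxE.

Because progeny-test daughter records are not publicly deposited, the
package ships a first-class synthetic-data module that generates data with
exactly the statistical structure the model assumes, with full ground truth
retained, so every stage is verifiable end to end.

# The reaction-norm sire model

For daughter $i$ of sire $j$ with a record at herd-test-day $k$:

$$
y_{ijk} = \mu + b\,E_k + \sum_{m=0}^{1} s_{jm} E_k^m
        + \sum_{m=0}^{1} d_{ijm} E_k^m + e_{ijk},
$$

with

* $E_k$ the standardized environmental descriptor of herd-test-day $k$
  (mean 0, SD 1 across herd-test-days);
* $(s_{j0}, s_{j1})$ i.i.d. across sires with unstructured $2\times 2$
  covariance $G_s$ — intercept variance $\sigma^2_{s0}$, slope variance
  $\sigma^2_{s1}$, correlation $\rho_{s0s1}$;
* $(d_{ij0}, d_{ij1})$ i.i.d. across daughters with covariance $G_d$ (the
  daughter term absorbs the three quarters of additive variance a sire
  model does not assign to sires, plus permanent environment);
* $e_{ijk}$ independent with one variance per environment decile: records
  are ranked by $E$ and split into 10 equal classes, and a separate
  $\sigma^2_{e,c}$ is fitted per class with zero covariance across classes.

Since $E$ is centred, the BLUP of $s_{j0}$ is the GP estimate and the BLUP
of $s_{j1}$ the ES estimate.

Sire effects are i.i.d. in this model — the pedigree is deliberately
ignored.  With large daughter groups the estimates are driven almost
entirely by progeny records, and the fit with pedigree-correlated sire
effects (covariance $A \otimes G_s$) gives practically the same intercept
estimates; the test suite and the acceptance script verify this on
synthetic data by computing the correlation between the two sets of
estimates, which must exceed 0.98.  The pedigree *is* used in step 2, where
it matters: sire estimates are shrunken, family-structured quantities, and
the association scan must control for that structure.

## The log-scale variant

For log-transformed yields the daughter regression on the environment is
dropped (daughter intercept only) and a single homogeneous residual
variance is fitted.  The full model on the log scale is poorly conditioned
— the transformation compresses exactly the variance heterogeneity those
terms describe.  `fit_reaction_norm(mode = "homogeneous")` implements this
variant as a restriction of the same likelihood, not a separate code path.

# REML implementation

The restricted likelihood is computed exactly, in time linear in the number
of records.  Daughters are nested in sires and carry few records each, so
the daughter effects and residual are absorbed daughter-by-daughter
(Woodbury identity; at most a $2\times2$ solve per daughter), leaving
mixed-model equations over the fixed effects and the $2q$ sire effects
only.  With i.i.d. sires these decouple into $q$ closed-form $2\times2$
blocks; with pedigree-correlated sires a dense $(2q+2)$ Cholesky is used.
The kernel is written in C++ (RcppArmadillo), as is usual for REML software
in this field; one likelihood evaluation on 300,000 records costs a few
milliseconds.

Numerical choices:

* **Parameterization.** Each covariance block is optimized through its
  log-Cholesky factor (log-diagonal, free off-diagonal), residual variances
  through their logs, so every parameter vector maps to a valid model and
  the optimization is unconstrained.
* **Optimizer.** Quasi-Newton (`nlminb`, PORT) with finite-difference
  gradients; relative-tolerance convergence at $10^{-8}$, iteration cap
  200; Nelder-Mead fallback if the quasi-Newton path fails.  Bounds are
  deliberately *not* imposed — they switch PORT to a slower projected
  algorithm; invalid evaluations are instead mapped to a large penalty.
* **Boundary components.** In the log-Cholesky parameterization a variance
  can approach but never reach zero, and the likelihood flattens as the
  log-SD heads to $-\infty$.  A converged slope variance below 0.1% of its
  own intercept variance (or any variance at the absolute floor,
  $10^{-10}\,\mathrm{var}(y)$) is therefore reported as 0 with a boundary
  flag, and — because positive semidefiniteness then forces the
  covariance to 0 too — the corresponding BLUPs are reported as exactly 0.
  Without this rule, near-boundary slope BLUPs degenerate into a tiny
  scaled copy of the intercepts and would spuriously replicate every
  intercept QTL as an ES hit.
* **Standard errors.** Asymptotic SEs of the sire components come from the
  finite-difference observed information on the working scale, delta-method
  transformed; a singular information matrix (possible on a likelihood
  ridge, see below) is handled by an eigenvalue pseudo-inverse.
* **Starting values.** Method of moments from per-sire ordinary
  least-squares regressions of yield on environment.
* **Oracle.** Every fast path is checked against a naive dense
  implementation that builds the full $n \times n$ covariance; the test
  suite asserts agreement of likelihood values and BLUPs to $10^{-6}$ and
  $10^{-8}$ on dozens of random instances, and that the fitted optimum is
  at least as good as a derivative-free search of the dense likelihood.

## An identifiability subtlety

If every daughter has exactly **one** record, the daughter intercept
variance is exactly aliased with a constant shift of the ten residual-class
variances (a constant lies in the span of the decile step functions), and
the daughter slope components are identified only by weak within-decile
variance curvature.  The likelihood then has a flat ridge; sire components
are unaffected, the optimizer stops on it harmlessly, and SEs fall back to
the pseudo-inverse.  With two or more records per daughter the
within-daughter covariances identify all of $G_d$.  Real test-day data has
roughly ten records per daughter; the simulator's default does too.

# The synthetic progeny-test generator

`sim_config()` + `simulate_dataset()` generate, in order: genotypes,
pedigree, sire effects, and daughter records — each from its own
deterministic sub-stream of the master seed, so one stage's output is
stable when another stage's parameters change.

What it emulates, and the defaults:

* **Population structure.** Two generations: ~1 grandsire per 10 sires,
  paternal half-sib families, dams unknown.  Daughters nested in sires,
  assigned uniformly to herd-test-days.
* **Environments.** One standard-normal value per herd-test-day (the
  descriptor of real data is approximately normal after standardization);
  no herd time-series structure.
* **Records.** Default 150 daughters per sire is desk scale (real
  progeny-test daughter groups are larger); default 10 records per
  daughter mirrors first-lactation test-day recording and makes all
  components identifiable (see above).
* **Sire components** default to a protein-yield scale:
  $\sigma^2_{s0} = 2379.37$, $\sigma^2_{s1} = 17.02$, $\rho = 0.79$
  (grams-per-day units).
* **Daughter and residual components** are not reported for the real data
  and were chosen once, on quantitative-genetic grounds: daughter
  (co)variances about three times the sire values
  ($\sigma^2_{d0} = 7200$, $\sigma^2_{d1} = 51$, $\rho_d = 0.6$), residual
  class variances ramping from 20,000 to 33,000 across environment deciles
  (absolute variance grows with production level).  This puts phenotypic
  variance near 36,000 and sire-model heritability near 0.26 — realistic
  for protein yield — and at national-progeny-test sizes it reproduces the
  order of magnitude of the standard errors typically reported for sire
  reaction-norm components.
* **QTL architecture.** `n_qtl` SNPs receive effects from a two-component
  scale mixture (many small, a few `qtl_large_ratio`-fold larger),
  directions drawn within the column space of $G_s$; the realized QTL
  covariance is recolored to exactly `qtl_var_fraction` of $G_s$ and the
  polygenic remainder carries the rest, so total sire (co)variances are
  calibrated regardless of QTL sampling.
* **Multiplicative mode** (`sim_config_multiplicative()`) generates
  $y = \exp(\mu' + b'E + s'_{j0} + d'_{ij0} + e')$ — *no* slope variance on
  the log scale, so all observed-scale GxE is pure scaling and is removable
  by the log transform.  Log-scale defaults ($\sigma^2_{s0} = 0.01$,
  $b' = 0.15$, daughter 0.008, residual 0.012) give desk-scale studies
  usable ES reliability.

What it does **not** emulate: linkage disequilibrium between SNPs,
selection, overlapping generations, lactation-curve shapes, herd
time-series structure, or the fixed-effect corrections of the routine
evaluation (records are emitted pre-corrected).  Passing tests therefore
demonstrate correctness of the estimation machinery under the model's
assumptions — not robustness to the many ways real data violate them.

# Environment descriptor

The descriptor of a herd-test-day is its mean performance.  Where records
carry the three component yields, the package combines them into milk
energy yield, $0.802\,\text{milk} + 38.4\,\text{fat} +
23.6\,\text{protein}$ (kg), and averages within herd-test-day; with a
single trait column the mean yield is used directly.  Raw levels are
standardized over herd-test-day units (each environment weighted equally,
sample SD) to mean 0, SD 1.  Constant levels across herd-test-days are an
error, not a silent zero.  Residual classes: records sorted by descriptor,
split into 10 contiguous groups differing in size by at most one, remainder
to the lowest classes, ties broken by stable record order.

# Genotype quality control

The editing rules, applied in this order with strict inequalities:

1. individuals with more than 10% missing genotypes removed;
2. SNPs removed for minor allele frequency below 3%, call rate below 90%,
   Hardy-Weinberg deviation at $P < 0.001$ (1-df chi-square, no continuity
   correction), unknown position, or a sex-chromosome label — each failure
   reason recorded;
3. sporadic missing calls imputed by the modal genotype class (ties toward
   the expected dosage $2f$, then the smaller class) — a deliberate,
   documented simplification of haplotype-based imputation, low-impact
   because post-QC missingness is sporadic;
4. dosages recoded to count the **major** allele, with frequencies computed
   on the full post-QC matrix *before* the discovery/validation split so
   effect signs are comparable across sets.

# Association and replication

Sires are split at random into a discovery set and a validation set (the
defaults, 1797 and 500, are at the scale of a national progeny-tested bull
population).  For each SNP $k$ and each component
$m \in \{GP, ES\}$:

$$\hat s_{jm} = \mu_m + b_{km} x_{jk} + u_j + \epsilon_j,\qquad
u \sim N(0, A\,\sigma^2_{sm}),\ \epsilon \sim N(0, I\,\sigma^2_{em}),$$

with $x_{jk} \in \{0,1,2\}$ counting major-allele copies and $A$ the
pedigree numerator relationship matrix (tabular method).  One
eigendecomposition of $A$ per sire set rotates the model to independent
errors; each SNP then needs only a one-dimensional REML profile over the
variance ratio and a weighted regression.  The ratio is re-profiled per SNP
by default (exact; affordable at these sizes), with an approximate mode
that estimates it once under the null.  The $p$-value is a normal-reference
Wald test on $b_{km}$ — the conventional choice for mixed-model GWAS, and
its calibration is itself tested (permutation type-I error within the exact
binomial band at $\alpha = 0.001$).

Discovery significance is $P < 0.001$ pointwise.  FDR is estimated by
Storey *q*-values ($\hat\pi_0$ from the 0.05–0.95 lambda grid, cubic
smoothing spline evaluated at the largest lambda; degenerate grids fall
back to $\hat\pi_0 = 1$, which makes the procedure exactly
Benjamini-Hochberg); the *q*-value of the significant SNP with the largest
$p$ estimates the false-positive proportion among the significant set.  A
SNP is **validated** when its validation-set $p$ is below 0.01 *and* the
effect has the same strictly nonzero sign in both sets; validation-set
estimates are the reporting estimates because they are free of the
winner's-curse (Beavis) bias of the discovery set.

# Scaling versus persistent GxE

`run_scale_comparison()` runs the observed-scale pipeline
(heterogeneous mode) and the log-scale pipeline (homogeneous mode on
$\ln y$) with the *same* split — so a SNP's classification is not
confounded by split randomness — and classifies every SNP by its
ES-validation pattern: `observed_only` (scaling-removable), `both`
(persistent), `log_only`, `neither`.  Only the natural log is implemented;
Box-Cox alternatives are a known extension point and the transformation is
injectable through `log_transform_records()`.  Effects are reported both
raw and in units of the fitted sire slope SD of each scale, since the raw
scales are not comparable.

In multiplicative-mode simulations the expected pattern, verified by the
acceptance tests, is: an intercept QTL validates for ES on the observed
scale (higher-intercept sires have proportionally steeper observed-scale
norms), the log-scale slope variance is a boundary estimate, and the QTL
does not validate for ES on the log scale.

# Problem sizes

The test suite runs everything at desk scale, chosen as the smallest sizes
at which each property is statistically decidable: oracle equivalence on
instances of up to ~50 records; component recovery on 20 replicates of 500
sires × 60 daughters × 10 records; the pedigree-ignorability check on 200
sires × 150 daughters; type-I calibration on 10,000 null SNPs × 1797
sires; the scaling decomposition on 10 replicates of 150 sires.  The same
sizes are used by `scripts/acceptance.R`.

# Known limitations

* First-order reaction norms only; no quadratic terms, no repeated-records
  permanent-environment modelling beyond the daughter intercept.
* The association scan is single-marker; no LD-aware clumping of validated
  SNPs into loci, no multi-marker or Bayesian alternatives.
* The simulator's independence assumptions (no LD, i.i.d. environments)
  mean power and FDR results transfer to real data only qualitatively.
* With very small validation sets the sign-agreement rule is conservative;
  validated-SNP counts are then downward-biased relative to a larger
  replication sample.
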