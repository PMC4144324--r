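---
title: "Two-stage hierarchical modeling of longitudinal pedigree phenotypes"
author: "hlmkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage hierarchical modeling of longitudinal pedigree phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlmkin)
```

## The problem

Longitudinal cohorts collected in extended pedigrees carry two nested layers
of correlation: repeated measurements within an individual, and genetic
relatedness between individuals of the same family.  Standard kinship mixed
models handle the second layer when testing SNP effects on the *mean level*
of a phenotype, but they do not directly address genetic effects on the
*rate of change* over age.  `hlmkin` implements a two-stage hierarchical
linear model that separates the two questions while keeping the kinship
correction in both.

## The model

**Level 1 (within individual).** For individual $i$ observed at ages
$x_{ij}$:

$$Y_{ij} = \beta_{0,i} + \beta_{1,i}\,(x_{ij} - x_{\mathrm{ref}}) + e_{ij},
\qquad e_{ij} \sim N(0, \sigma^2).$$

Ages are centered at a reference age $x_{\mathrm{ref}}$ (default 42 years,
chosen as a typical mean examination age for adult blood-pressure cohorts),
so $\beta_{0,i}$ is the individual's expected phenotype *at* the reference
age — for systolic blood pressure, "SBP(42)" — and $\beta_{1,i}$ is the
individual's rate of change in units of the phenotype per year.

Before fitting, time-varying covariates (current smoking, antihypertensive
medication) are removed by a single pooled regression of the raw values on
those covariates; the estimated covariate contributions are subtracted,
leaving intercept plus residual (`adjust_covariates()`).  Pooling is
deliberate: with at most four visits per person, per-individual adjustment
is not estimable.

**Level 2 (between individuals).** Each level-1 coefficient is regressed on
the SNP dosage $G_i \in \{0, 1, 2\}$ with a kinship-structured random
effect:

$$\beta_{0,i} = \gamma_{00} + \gamma_{01} G_i + U_{0,i}, \qquad
  \beta_{1,i} = \gamma_{10} + \gamma_{11} G_i + U_{1,i},$$

$$U_{0,i} = u_{0,i} + \epsilon_{0,i},\quad
  \mathrm{Var}(u_0) = \sigma^2_{0,g} A,\quad
  \mathrm{Var}(\epsilon_0) = \sigma^2_{0,e} I$$

(and identically for the slope).  $\gamma_{01}$ and $\gamma_{11}$ — the SNP
effects on the level and on the rate of change — are the parameters of
interest; both are tested by a two-sided Wald $\chi^2_1$ on
$(\hat\gamma / \mathrm{se})^2$.  Sex enters level 2 as an additional fixed
covariate (it is constant over visits, so it belongs to the
between-individual model, not the pre-adjustment).

The two level-2 models are fitted as separate univariate mixed models, each
with its own genetic variance; no cross-covariance between intercepts and
slopes is modeled.  A joint one-step fit of the combined model is out of
scope by design: the two-stage decomposition is what makes the kinship
adjustment of the slope phenotype straightforward.

## Kinship

$A$ is the *relationship matrix* $2\Phi$, where $\Phi$ holds pedigree
kinship coefficients computed by the classical recursion over a
topologically sorted pedigree (`kinship_from_pedigree()`):
$\phi_{ii} = (1 + \phi_{fm})/2$, $\phi_{ij} = (\phi_{fj} + \phi_{mj})/2$.
On the relationship scale $\sigma^2_g$ is the additive genetic variance and
the diagonal is 1 for non-inbred individuals; raw kinship scale is available
via `kinship_matrix(..., scale = "kinship")` for compatibility with tools
that expect $\Phi$.  Individuals with one known and one unknown parent are
treated as having an unrelated non-inbred unknown parent; kinship between
pedigrees is fixed at zero, so the cohort matrix is block-diagonal.

## REML by eigendecomposition

`reml_fit()` estimates $(\gamma, \sigma^2_g, \sigma^2_e)$ by restricted
maximum likelihood using the single-decomposition strategy familiar from
EMMA-class mixed-model association methods: eigendecompose $A = U D U'$
once, rotate $y$ and $X$ by $U'$, and profile the restricted likelihood
over the variance ratio $\delta = \sigma^2_e / \sigma^2_g$, where the
covariance is diagonal, $\sigma^2_g (D + \delta I)$.  The profile is
evaluated on a 100-point log grid over $\delta \in [10^{-5}, 10^5]$ and the
best bracket is refined by Brent's method (tolerance $10^{-9}$ in
$\log_{10}\delta$); the $\sigma^2_g = 0$ boundary is evaluated explicitly
and reported when it is the optimum.  The restricted log-likelihood
includes the $+\tfrac12\log|X'X|$ term so its value is invariant to the
rotation.  Because the decomposition depends only on $A$, one
decomposition per phenotype serves every SNP in a scan; only SNPs with
missing dosages (dropped individuals, complete-case by default) trigger a
subset decomposition.

Degenerate cases behave as expected: with $A = I$ only the total variance
is identifiable and the fixed effects equal ordinary least squares; with
$\delta$ fixed at $\infty$ the fit *is* OLS, to numerical precision.  ML
estimation is available behind `method = "ml"`; the Wald test is the
default with the likelihood machinery available for comparisons.

## Scan diagnostics

`run_scan()` orchestrates stage 1, outlier screening and the per-SNP stage-2
fits for both phenotypes and reports, per phenotype: the genomic-control
inflation factor $\lambda$ (median of the $\chi^2_1$ quantiles implied by
the p-values over the null median 0.4549), a Bonferroni threshold
$\alpha / n_{\mathrm{tested}}$, Q-Q coordinates, and top hits.  SNPs
monomorphic in the analyzed subset or below `maf_min` (default 0.01) are
excluded from $\lambda$ and the Bonferroni count.  Alternative
random-effect modes — `"pedigree"` (a shared random intercept per family)
and `"none"` (OLS) — are provided as comparison models; on heritable data
they leave relatedness partially or wholly unmodeled and inflate
$\lambda$, which is the expected diagnostic contrast.

## Outlier screening

Level-1 summaries double as outlier diagnostics.  Two rules, applied once
on the full sample (no iterative re-screening): values of the level or the
slope beyond 3 SD of their mean, and levels below 60 mmHg (physiologically
implausible for SBP).  Flagged individuals are excluded from both level-2
analyses.  The SD rule uses a single pass because repeated re-computation
after removal would change the estimand; with an all-constant metric
(SD = 0) only the floor rule can fire.

One caveat worth stating explicitly: the 3-SD screen assumes outliers are
artifacts.  If a rare variant of very large effect is real — a MAF 0.03
allele shifting the level by ~2 SD, say — its carriers live exactly where
the screen trims, and trimming them attenuates the estimated effect.
Screening is therefore part of the *scan* (where it protects the null
distribution), while effect-size estimation under a known causal model
should be run without it; the shipped recovery checks do exactly that.

Singleton individuals (one visit) cannot contribute a slope; their one
value is carried to the reference age along the population mean slope so
they still enter the level analysis.  This carry-forward is an assumption,
not an estimate — it keeps the level analysis at full sample size at the
cost of shrinking singleton variability toward the mean trajectory.

## The synthetic cohort generator

`simulate_cohort()` draws pedigrees, gene-drops genotypes and generates
phenotypes from the combined model

$$Y_{ij} = \gamma_{00} + \gamma_{10} t_{ij} + \gamma_{01} G_i +
\gamma_{11} G_i t_{ij} + U_{0,i} + U_{1,i} t_{ij} + \beta' z_{ij} + r_{ij}$$

with known truth stored alongside.  Its defaults emulate a
blood-pressure family study at realistic scale, and they are the study
conditions under which the package's calibration and power claims are
tested:

* 20 pedigrees of 27–107 members, built generation-wise (founder couple,
  offspring counts 1 + Poisson(1.6), spouses marry in with probability
  0.75 for three generations) to an exactly drawn target size;
* 1–4 exams per individual with probabilities 246/183/309/194 out of 932;
  entry ages on 16–94 years drawn as a scaled Beta(1.5, 3.46) with mean
  ≈ 39.6 — family cohorts enroll mostly younger adults with a long elderly
  tail, which puts the mean exam age near the reference age of 42 (a
  uniform age distribution would instead concentrate a third of the sample
  above 60, where back-extrapolated levels at 42 are very noisy); exam
  gaps 3.9, 3.0, 3.0 years (the
  first two gaps reproduce the 3.9 y and cumulative 6.9 y spacing typical
  of the emulated study; the third is kept at 3.0 y);
* grand intercept $\gamma_{00} = 118$ mmHg and mean slope
  $\gamma_{10} = 0.303$ mmHg/yr (typical adult SBP medians);
* variance components $\sigma^2_{0,g} = 40$, $\sigma^2_{0,e} = 40$,
  $\sigma^2 = 50$ mmHg² — intercept heritability 0.5 among its random
  part; slope variances $\sigma^2_{1,g} = \sigma^2_{1,e} = 0.02$
  (mmHg/yr)², i.e. a slope SD of 0.2 around a 0.3 mean, chosen once as a
  realistic magnitude since slope variance decompositions are rarely
  reported;
* time-varying smoking and medication as two-state Markov chains
  (prevalences 0.2 / 0.25, persistence 0.85 between exams) with additive
  effects +4 / −10 / +3 mmHg for smoking, medication and male sex.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (markers are independent given transmission), ascertainment, genotype
error, medication assignment that responds to current blood pressure, and
non-linear age trajectories.  Calibration and recovery results on this
generator therefore demonstrate correctness of the estimator under its own
assumptions, not robustness to those real-data features — in particular,
off-target effect estimates at markers correlated with causal variants
through LD cannot be studied here.

## Numerical choices

* Kinship matrices are checked for positive semidefiniteness; eigenvalues
  in $(-10^{-8}, 0)$ are clipped to zero with a warning, anything lower is
  an error.
* Monomorphic SNPs return a missing effect with $p = 1$ rather than being
  silently dropped, so result tables stay aligned with the input map.
* The MAF filter is applied to the analyzed subset's recomputed allele
  frequency, not the cohort-wide one.
* Duplicate (individual, age) measurement pairs are an error naming the
  individual, not a silent average.
* Power counts two-sided significance regardless of sign, and replicates
  redraw phenotypes on fixed pedigrees and genotypes by default, matching
  the replicate design of workshop-style simulated data.

## Problem sizes used in the shipped checks

The test-suite calibration runs use 20 pedigrees of 55–65 members with 500
null SNPs; effect-recovery runs use 100 phenotype replicates over ~750
individuals with a MAF 0.03 causal variant of −18.6 mmHg/allele on the
level and 0.3 mmHg/yr/allele on the slope; the Monte-Carlo kinship
cross-check uses 200,000 gene drops per pedigree.  These sizes were chosen
as the smallest at which the sampling error of each check is well inside
the tolerance being asserted.

## Known limitations

Single-chromosome scale orchestration only; no genomic (marker-based)
relationship matrices; no shrinkage of level-1 estimates (each trajectory
is an independent OLS fit, so individuals with two visits get a noisy,
unregularized slope); no joint bivariate level/slope model; no score or
mixed-model LRT alternatives to the Wald test beyond the likelihood values
reported by `reml_fit()`.
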