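---
title: "Variance decomposition of DNA methylation in longitudinal twin cohorts"
author: "twinmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition of DNA methylation in longitudinal twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

## The problem

DNA methylation at a CpG site, measured in a population, varies between
individuals. The classical twin design decomposes that variation into
additive genetic (A), dominant genetic (D), common/shared environmental (C)
and unique environmental (E) components by exploiting the known difference
in genetic sharing between monozygotic (MZ) and dizygotic (DZ) co-twins: MZ
pairs correlate 1 for both A and D, DZ pairs correlate 0.5 for A and 0.25
for D, both correlate 1 for C, and E is uncorrelated within pairs. With
twin data alone C and D are confounded and cannot be estimated jointly, so
the model families are ACE and ADE.

`twinmeth` implements this decomposition per CpG on array-style methylation
data measured at one or two time points ("waves"), together with the
surrounding pipeline a practitioner needs: beta/M-value handling,
detection-P quality control, blood-cell-composition adjustment, intraclass
correlations with a Fisher z test for the MZ/DZ difference, a two-wave
bivariate model for the persistence of genetic control, and a synthetic
cohort generator with known ground truth that makes every stage testable by
parameter recovery.

## Value scales

Array intensities give the beta value `meth / (meth + unmeth + 100)` in
[0, 1); all modelling is done on the M value, the base-2 logit of beta,
which is closer to homoscedastic. Beta values of exactly 0 or 1 cannot
occur from the intensity formula, but can occur in imported tables; the
logit clamps them to `[1e-6, 1 - 1e-6]` with a warning rather than
propagating infinities.

## Univariate model and fitting

For a pair with phenotypes \(y = (y_1, y_2)\), the model is a bivariate
normal with member means \(\mu_i = \beta_0 + \beta_{age} age_i +
\beta_{sex} sex_i\) and covariance

\[
\begin{pmatrix} V & c_z \\ c_z & V \end{pmatrix}, \qquad
V = A + C + D + E, \qquad
c_{MZ} = A + C + D, \quad c_{DZ} = \tfrac12 A + C + \tfrac14 D .
\]

Age and sex enter the mean model only (shared coefficients across
zygosities); cell-composition adjustment happens upstream as a per-CpG OLS
residualisation on the six blood cell proportions, so the twin model sees
residuals. Covariate columns that are constant in a given data set are
dropped automatically.

Numerical choices:

* **Path-coefficient parameterization.** Each free variance is the square
  of an unconstrained real, so non-negativity is structural and no bounded
  optimiser is needed. Signs are fixed non-negative at reporting.
* **Profiled mean model.** At every variance point the mean coefficients
  are solved by generalised least squares from precomputed cross-moments,
  so one likelihood evaluation costs O(1) in the number of pairs and the
  optimiser works in at most three dimensions.
* **Internal unit scaling.** Data are divided by their pooled standard
  deviation before optimisation and results are mapped back. The profile
  likelihood is then an identical function of the parameters for any affine
  transform of the input, which makes standardized estimates exactly
  invariant to rescaling or shifting the M values.
* **Multi-start.** Nelder-Mead runs from a documented grid: equal variance
  split, each component dominant, and a method-of-moments start from the
  observed MZ/DZ correlations; a quasi-Newton polish follows. During model
  selection each full model is additionally seeded with the solutions of
  its nested models, which enforces the likelihood monotonicity
  loglik(full) >= loglik(nested) by construction.
* **Minimum data rule.** A fit requires 5 complete pairs per zygosity;
  twin-model stages use only pairs where both members are observed.

## Model selection

Six models are fitted: ACE, ADE, AE, CE, DE, E. The best full model (BFM)
is the AIC-minimal of {ACE, ADE}; the best nested model (BNM) is the
AIC-minimal of the BFM's nested set ({AE, CE, E} or {AE, DE, E}). A
likelihood-ratio test compares BNM to BFM with degrees of freedom equal to
the difference in free parameter counts, using the plain chi-squared
reference. Because the null values lie on the boundary of the parameter
space this reference is conservative; the boundary 50:50 mixture is
deliberately not used, matching common practice in this literature. If the
LRT p value exceeds 0.05 the BNM is kept by parsimony; otherwise the
AIC-minimal of {BFM, BNM} wins. AIC ties are broken by the fixed order ACE,
ADE, AE, CE, DE, E.

Heritability is narrow sense \(h^2 = A/(A+C+E)\) for ACE-family finals and
broad sense \(h^2 = (A+D)/(A+D+E)\) for ADE-family finals.

## Confidence intervals

Intervals on the standardized components (a2, c2, d2, e2, h2) are
2.5–97.5% Wald intervals by the delta method on the proportion functions of
the path coefficients, using the observed information of the profile
likelihood. They are reported untruncated, so lower bounds can be negative
and upper bounds can exceed 1. Two boundary behaviours are intentional:

* A component estimated at exactly zero has zero gradient for its
  proportion, so its interval degenerates to `0 (0–0)`; similarly an E-only
  fit reports `e2 = 1 (1–1)`. Zero-information directions are handled with
  a spectral pseudo-inverse.
* If the observed information has genuinely negative curvature directions
  the variance is undefined and the bounds are reported as `NaN`.

"Significant" in all scan outputs means 0 is excluded from the 2.5–97.5%
interval of the standardized component; the proportion interval (not the
raw-variance interval) is used, and no multiple-testing adjustment is
applied. Whether Wald, profile or bootstrap intervals are preferable for
tiny cohorts is an open question; Wald was chosen for speed and because
degenerate/untruncated behaviour is then analytically transparent.

## Bivariate (two-wave) model

For pairs measured at two waves the vector (twin1-wave1, twin1-wave2,
twin2-wave1, twin2-wave2) is quadrivariate normal. The correlated-factors
parameterization is used because the quantities of interest are the
cross-wave factor correlations themselves: per-wave components plus
\(r_g, r_c, r_d, r_e\), the correlations of the A, C, D, E factors across
waves. Within-twin cross-wave covariance is
\(r_g\sqrt{A_1A_2} + r_c\sqrt{C_1C_2} + r_d\sqrt{D_1D_2} +
r_e\sqrt{E_1E_2}\); the cross-twin cross-wave covariance drops the E term
and scales A/D by the zygosity coefficients. Correlations are mapped
through `tanh` of an unconstrained real so they stay inside [-1, 1]; a
consequence is that \(\hat r_g\) can approach but never exactly equal 1,
and its delta-method interval shrinks as the estimate saturates. The
default family is AE (the common final family for strongly heritable
sites); ACE and ADE are selectable. Pairs missing any of the four
measurements are excluded (complete-quadruple rule). The mean model is
wave-specific (intercept + age + sex per wave) and profiled out as in the
univariate fit.

## Intraclass correlations

The ICC estimator is the one-way random-effects ANOVA ICC(1,1),
\(r = (MSB - MSW)/(MSB + MSW)\) for pair size 2 — the canonical
definition, property-tested against the double-entry Pearson correlation.
Negative estimates are reported, not truncated. Confidence intervals use
the Fisher transform with standard error \(1/\sqrt{n - 3/2}\), the
large-sample value for an intraclass correlation from n pairs. The
MZ-vs-DZ comparison uses Fisher's z test with n = number of pairs, since
the pair is the sampling unit. For an MZ-only replication cohort, where
heritability cannot be estimated, CpGs are ranked by MZ ICC: sites under
strong genetic control must rank at the top.

## The synthetic cohort generator

`simulate_cohort()` is the generative inverse of the models above: per CpG
and pair it draws from the multivariate normal whose covariance is exactly
the twin-model covariance implied by the configured A/C/D/E (per wave) and
cross-wave correlations, then adds mean structure. Defaults emulate an
aging-twin longitudinal design: wave-1 ages uniform on 73–82 years with a
10-year wave gap, like-sex pairs with an even sex ratio, typical
whole-blood mean cell fractions (Gran 0.60, CD4T 0.15, CD8T 0.10, Mono
0.07, Bcell 0.05, NK 0.03) drawn from a Dirichlet distribution
(concentration 200, so only their role as regression covariates matters),
and small age/sex mean effects (0.005 M/year, 0.05 M) so the covariate
adjustment path is exercised. Simulation is on the M scale — the modelling
scale — and beta outputs come from the inverse base-2 logit, which keeps
them strictly inside (0, 1).

CpG-SNP sites (a polymorphism at the interrogated dinucleotide) get a
genotype-dependent mean instead of a genetic variance component: pair
genotypes are drawn under Hardy-Weinberg by explicit parental-allele
transmission — exact sibling identity-by-descent for DZ pairs, a shared
genotype for MZ pairs — so trimodal beta histograms and the DZ genotype
correlation of 0.5 are reproduced exactly rather than via a Gaussian
shortcut. Detection-P missingness is injected uniformly at random: a
configured fraction of entries receives P > 0.01 (the default QC
threshold), the rest P <= 0.01.

The generator does **not** emulate probe chemistry (Type I/II bias, SWAN
normalisation), batch/chip effects, genome-scale probe counts, or
beta-scale heteroscedasticity; passing recovery tests therefore validates
the inference machinery, not robustness to those artefacts. The wave-1 vs
wave-2 marginal variance relationship is unconstrained (per-wave components
are configurable) because the design itself does not fix it.

## The scan pipeline

`run_scan()` chains QC (detection-P masking at 0.01, SNP-probe and listed
exclusions, > 5% missingness exclusion — the conventional array
thresholds), cell adjustment, per-wave ICC tables, per-wave univariate
selection with standardized components, cross-wave significance overlap,
the bivariate model on the discovery set (all CpGs with
`bivariate_all = TRUE`), and an optional MZ-only replication ranking.
Three significance flags are recorded per wave — a2, heritability (h2;
equal to a2 for ACE-family finals, a2 + d2 for ADE-family finals) and c2 —
with their cross-wave overlaps. The h2 overlap is the discovery notion for
"genetic" sites and triggers the bivariate stage: a strongly heritable
site can express its genetic variance through D rather than A at one wave
when the sampled DZ correlation falls below half the MZ correlation, and
the heritability interval is what identifies it either way.
SNP-probe exclusion takes an explicit id list rather than keying off the
CpG-SNP annotation flag, because genotype-driven sites can be the most
interesting hits rather than artefacts. Failures are isolated per CpG. The
scan draws no random numbers, sorts stably, and writes byte-identical
tables on identical inputs; `write_scan()` emits the CSV tables and a JSON
manifest.

## A worked example

```{r example, eval = FALSE}
ids <- sprintf("cg%03d", 1:30)
truth <- cpg_truth(ids,
                   A = c(rep(0.9, 2), rep(0, 28)),
                   C = c(rep(0, 4), rep(0.65, 2), rep(0, 24)),
                   E = 1 - c(rep(0.9, 2), rep(0, 2), rep(0.65, 2), rep(0, 24)))
cfg <- simulation_config(n_mz_pairs = 120, n_dz_pairs = 180, truth = truth,
                         n_waves = 2, seed = 42)
cohort <- simulate_cohort(cfg)
scan <- run_scan(cohort$dataset, cohort$sheet)
scan$counts
heritability_heatmap_matrix(scan)[1:6, ]
```

## Problem sizes used in validation

The test suite validates the pipeline by simulation at sizes chosen to make
Monte-Carlo error small relative to the tolerance being asserted:
closed-form twin correlations at 20,000 pairs per zygosity; univariate
recovery and CI calibration over 100 replicates of 1,000 + 1,000 pairs;
selection consistency over 200 replicates; bivariate recovery over 50
replicates; and the end-to-end planted-signal scan over 20 seeds of a
170-CpG cohort at 160 MZ + 250 DZ pairs (ten times a typical aging-twin
discovery cohort), with 6 planted high-heritability sites and 11 planted
shared-environment sites.

## Known limitations

* Wald intervals can behave erratically at severe boundary cases in tiny
  samples (the `NaN` convention makes this visible rather than hiding it).
* The LRT chi-squared reference is conservative at boundary nulls, so the
  parsimony rule slightly favours nested models.
* No ACDE model (not identifiable with twins only), no sex-limitation or
  heterogeneity models, no Bayesian estimation, no cross-trait bivariate
  models, and no more than two waves.
* Cell-composition proportions are consumed, not estimated; reference-based
  deconvolution and array normalisation are assumed to have happened
  upstream.
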