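---
title: "Models and methods: infant plasma exmiRNA biomarkers of prenatal alcohol exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmirpae)
```

# The problem

Prenatal alcohol exposure (PAE) produces growth restriction and cognitive
impairment that is hard to predict from exposure history alone. Circulating
extracellular miRNAs (exmiRNAs) in infant plasma, profiled on qPCR panels,
are candidate biomarkers: if exposure reorganizes miRNA expression in ways
that track later outcomes, a small plasma draw could identify infants who
need early intervention. This package implements the statistical pipeline
for such a study end to end — panel quality control and normalization,
covariate-adjusted effect-size screening, co-expression network analysis,
confirmatory factor analysis (CFA) of the exposure-responsive miRNAs,
mediation of exposure effects on growth and cognition through the factor
scores, and Monte Carlo power studies — and pairs it with a synthetic-cohort
generator so every step is exercisable and testable without access to the
original cohort data.

# The measurement scale

qPCR reports a cycle threshold (CT) per assay: the cycle at which
amplification crosses a fixed fluorescence level. CT falls by one cycle for
each doubling of input, so *lower CT means higher expression* and a unit
difference is a twofold change. Normalization is global-mean delta-CT: per
sample, the mean CT over the expressed miRNA set is subtracted from each
CT, making every sample's delta-CT profile mean-zero and removing
per-sample input/efficiency offsets (an additive per-sample constant
cancels exactly). Group contrasts are delta-delta-CT (exposed minus
control), so negative values mean upregulation under exposure.

Three QC rules precede normalization:

* **Hemolysis.** Erythrocyte lysis contaminates plasma miRNA content. A
  sample is excluded iff absorbance at 414 nm exceeds 0.3 **and**
  delta-CT(miR-23a-3p − miR-451a) exceeds 7 (miR-451a is
  erythrocyte-enriched). Both inequalities are strict: boundary values
  pass. Detection of the erythrocyte transcript SLC4A1 is surfaced as a
  warning flag only.
* **Expressed set.** A miRNA enters the analysis iff detected in at least
  80 % of samples in at least one group × age cell (`>=` at the boundary).
  Samples whose half-panel failed amplification QC are excluded from both
  numerator and denominator for that half's assays.
* **Non-detects.** Remaining non-detects are imputed at one cycle above
  the miRNA's highest detected CT — just beyond the observed detection
  range — per miRNA within a timepoint, groups pooled. The operation is
  idempotent. Imputation compresses group differences slightly (imputed
  values are group-blind), a bias documented below.

# Effect-size screening

Because the panel tests 148 expressed miRNAs in a cohort of tens of
infants, screening is by effect size rather than adjusted p-values. Per
miRNA, an ANCOVA `delta_ct ~ group + cigarettes/day` adjusts the group
contrast for maternal smoking; adjusted means are model predictions at the
covariate grand mean. Cohen's d divides the adjusted-mean difference by the
pooled *raw* within-group SD (the adjustment enters the numerator only);
Hedges' g applies the small-sample factor `J = 1 − 3/(4(n−2)−1)`; the 95 %
CI uses the normal approximation `d ± 1.96·SE` with
`SE = sqrt((n_c+n_e)/(n_c n_e) + d²/(2(n_c+n_e)))`. The screen keeps
`|d| >= 0.40`, a cutoff chosen for its clinical interpretation: U3 — the
share of exposed infants above the control mean — is `pnorm(0.40)` ≈ 66 %,
the logistic-equivalent odds ratio `exp(0.40·π/√3)` ≈ 2.07, and the
binomial effect size display `0.40/sqrt(0.40²+4)` ≈ a 20 % rate
difference:

```{r}
str(effect_interpretations(0.40))
```

No multiple-testing correction is applied anywhere in the screen; the
design screens on magnitude and reports which CIs exclude zero.

Sex specificity uses a stratified bootstrap: subjects are resampled with
replacement within exposure group (preserving the design) for the combined
sample and for each sex alone; each resample is re-tested by the smoking-
adjusted ANCOVA at p < 0.05; a miRNA is called sex-specific iff that sex's
significant fraction exceeds 0.5 *and* exceeds the combined fraction. Note
the bootstrap recenters at the observed effect, so a "null" miRNA whose
sample effect happens to be moderate can show elevated proportions — the
classification rule, not the raw proportion, is the inferential surface.

# Co-expression networks

Within each group and age, pairwise Pearson correlations over subjects are
tested with the t-transform (`df = m − 2`); correlations with `p >= 0.05`
are masked. Matrices are ordered by complete-linkage clustering on
`1 − r` (the distance the usual correlation-plot tooling defaults to; the
choice affects display order only — counts are permutation-invariant).
Stability of the significant-pair count is assessed by subject-level
bootstrap with a percentile 99 % CI. Resampling with replacement
duplicates subjects, which mechanically inflates `|r|` in a resample, so
the bootstrap distribution sits above the observed count; it is read as a
stability band for *comparing* groups, not as an estimator of the count.

Chromosome annotation comes from a miRBase-dialect GFF3 (parsed with
`rtracklayer`); duplicated MIMAT accessions get incrementing copy indices.
A locus is "clustered" if another miRNA locus on the same chromosome lies
within 10 kb. Cross-chromosome enrichment counts significant pairs with
members on two different chromosomes — once per chromosome-pair
combination of their loci — normalized by the product of expressed-miRNA
counts per chromosome, and reports the exposed/control fold change
(division by zero is flagged, not silently dropped).

# Confirmatory factor analysis

The exposure-responsive miRNAs are modeled as indicators of a small number
of latent factors. The engine fits, by maximum likelihood on the sample
covariance `S`, the discrepancy

`F(θ) = log|Σ(θ)| + tr(S Σ(θ)^{-1}) − log|S| − p`,

with `Σ = Λ Φ Λ' + Θ`. Identification fixes factor variances at 1 (all
loadings free); correlated-factor models free the off-diagonal of `Φ`;
bifactor models add a general factor loading on every item with all
factors mutually orthogonal; declared residual covariances enter `Θ`.
Optimization is BFGS with the analytic gradient
`dF = tr[(Σ^{-1} − Σ^{-1} S Σ^{-1}) dΣ]`, principal-axis-style starting
values, and up to five restarts with inflated residual-variance starts
when the search hits a non-PD `Σ` (handled by a smooth ridge penalty so
the optimizer can retreat). `chi2 = (n−1)·F_min`. Heywood cases (negative
residual variances) and improper factor correlations (`|φ| > 1`) are
flagged, never silently truncated.

Standard errors invert the **expected (Fisher) information**
`I_ab = (n−1)/2 · tr(Σ^{-1} dΣ_a Σ^{-1} dΣ_b)`, evaluated analytically at
the solution. This is the standard complete-data ML choice in SEM
software; it is exact (no finite-difference noise) and in simulation
matches the sampling SD of the estimates, which a numerically
differentiated observed Hessian only approximates here.

Fit indices follow the conventional definitions (CFI, TLI, RMSEA with a
90 % CI from noncentral-χ² inversion, SRMR from standardized residuals),
with `df = 0` conventions RMSEA = 0 and CFI = 1. Information criteria are
`AIC = −2LL + 2q`, `BIC = −2LL + q·ln n`, `SABIC = −2LL + q·ln((n+2)/24)`;
the package counts covariance-structure parameters only (no mean
structure), so `q` differs by `p` (the item means) from software that
models saturated means — Δχ², ΔAIC and ΔBIC between models are unaffected.

The small-sample (Bartlett) correction multiplies the chi-square by
`1 − (4k + 2p + 5)/(6n)` with `k` factors, `p` items and `n` the sample
size plus one; the omnibus p-value and, on request, CFI/TLI/RMSEA are
recomputed from the corrected value. The corrective factor is strictly
below 1, so the corrected p-value can only move up.

Reliability per factor: omega
`(Σλ)² / ((Σλ)² + ΣVar(ε) + 2·Σ residual covariances)` (collinearity-
adjusted composite reliability) and maximal reliability
`H = Σ(l²/(1−l²)) / (1 + Σ(l²/(1−l²)))` on standardized loadings — sign-
invariant and never below the best single item's `l²`. Factor scores for
downstream use are unweighted means of each factor's item delta-CTs, so a
*lower* score means *higher* expression of the factor's miRNAs; signs of
downstream regression paths must be read against this convention.

# Mediation

Whether exposure effects on growth (WHO weight/length/head-circumference
z-scores) and visual recognition memory (Fagan Test of Infant
Intelligence novelty preference) travel through the miRNA factors is
tested by the product of coefficients: `a` from `mediator ~ exposure`
(exposure = oz absolute alcohol/day), `b` and the direct path `c'` from
`outcome ~ exposure + mediator`, all variables z-scored so coefficients
are standardized. The indirect effect `a·b` gets a Sobel z-test
(delta-method SE) and a bias-corrected (BC, not accelerated) case-
resampling bootstrap CI; for least squares on one sample the decomposition
`total = c' + a·b` is exact. Maternal smoking is modeled as an exogenous
correlate of exposure — which leaves the OLS path estimates unchanged — with
a sensitivity switch to enter it as a covariate in both equations instead.
Missing outcomes are handled complete-case per model. The battery runs
three single-factor models per outcome plus a joint model with all three
factors entered together (their residual correlations free, which for OLS
means each mediator keeps its own exposure equation while the outcome
equation includes all mediators). Mediation is classified *partial* when
direct and indirect effects are both significant, *full* when only the
indirect is.

# Monte Carlo power studies

The CFA study generates multivariate-normal data from a population
3-factor model — loadings 0.50, factor correlations 0.50, residual
variances 0.75, factor variances 1 (so items have unit variance) — at
n = 59, fits each replicate with the package's ML engine, and aggregates
per-parameter power (`|est/SE| > 1.96`), coverage of nominal 95 %
intervals, and percentage bias `100·(mean estimate − truth)/truth`.
Replicates where the optimizer fails, a residual variance goes below
−1e−6, or the factor correlation matrix is improper are counted as
non-converged and excluded from aggregates; at n = 59 this removes a few
percent of replicates and prevents rare degenerate solutions from
dominating the spread.

The item → factor allocation of the original 2-week model is not published
in-text, so the study ships a default 8/5/5 split of 18 items and a
sensitivity sweep. This matters for one quantity: asymptotic
(Fisher-information) power for a factor correlation of 0.50 at n = 59 is
0.78–0.85 for any 18-item 3-factor allocation, reaching ~0.90 only with
~7–8 items per factor (a 22-item model, the scale of the 6.5-month
structure). Loading power (high 80s to mid 90s), coverage (low-to-mid
90s) and bias (< 5 %) are allocation-robust. The mediation study draws the
standardized trivariate system with all paths 0.40 at n = 58 and fits
replicates on the raw scale — the population is already standardized, and
re-z-scoring every replicate would distort the SEs and the coverage.
Power for the component paths lands near 90 %, the Sobel test of the
indirect effect near 75 % (the Sobel z is conservative at this n), and
coverage and absolute bias sit at nominal levels.

Simulation sizes: the analysis scripts, tests and acceptance checks run
1000 replications per condition, the package's choice for routine
verification; `n_reps = 10000` reproduces the full-scale study.

# The synthetic cohort generator

`cohort_config()` defaults encode the study conditions: 31 control and 37
exposed infants at two ages; 752 assays with 148 expressed; 18 responsive
miRNAs with target Cohen's d between 0.40 and 0.88, about 80 %
upregulated under exposure; a 3-factor latent structure (loadings 0.5,
correlations 0.5) over the responsive set; alcohol dose near zero for
controls and gamma-distributed (mean ≈ 0.7 oz/day) for exposed; smoking
as zero-inflated Poisson with higher prevalence among exposed mothers (so
the ANCOVA adjustment is non-trivial); and outcomes generated from the
linear structural chain `factor = a·exposure + noise`,
`outcome = c'·exposure + b·factor + noise` with defaults a = b = c' = 0.4.
Each generation block (subjects, panel, hemolysis, loci) draws from its
own seed-derived RNG stream, so adding one block never perturbs another
and equal seeds give byte-identical outputs.

CT values are built as `baseline − loading·factor − shift·exposed +
noise` with baselines uniform in [18, 34] and noise SD 1; non-detects
arise when the latent CT exceeds the assay ceiling (37) or by random
dropout. Two calibration details make the *configured* d the *realized*
post-normalization d: the exposure shift is reduced by the factor-mediated
component of the group difference (computed against the realized factor
scores), and inflated to offset the bleed of all responsive shifts into
the per-sample global mean. The second correction necessarily pushes a
small opposite-sign offset (≈ Σshift/130 of a CT cycle) onto the
non-responsive expressed miRNAs — a real property of global-mean
normalization, visible in the screen as a mild excess of small
opposite-direction effects.

What the generator does **not** emulate: plate-position and batch
effects, amplification-curve artifacts, inter-plate calibration drift,
heavy-tailed or miRNA-specific noise, group differences in correlation
structure beyond the shared factors, and attrition. Passing tests on
synthetic cohorts therefore demonstrate that the *statistics* are
implemented correctly under the generating model, not that the biology of
any real cohort will reproduce; with default non-detect settings the
imputation rule attenuates realized effect sizes by a few hundredths of a
cycle, exactly as it would in real data.

# Numerical and design choices

* CFA convergence: relative tolerance 1e−12 on the discrepancy, max 1000
  BFGS iterations, 5 ridge restarts; saturated models recover `Σ = S` to
  numerical precision and `chi2 = 0`.
* RMSEA CI: noncentral-χ² inversion by root-finding on the ncp, bounds
  clamped at 0 when the target tail probability is unattainable.
* Bootstrap CIs: percentile (correlation counts, 99 %) and BC percentile
  (mediation, 95 %); BC's `z0` is clamped away from 0/1 by one bootstrap
  unit to keep `qnorm` finite.
* Degenerate inputs: constant miRNAs correlate as non-significant with a
  warning; zero-variance ANCOVA covariates fall back to unadjusted means
  with a warning; miRNAs with zero detections cannot be imputed and error;
  strata with fewer than 4 subjects make the sex classification
  "indeterminate".
* The hemolysis rule, detection threshold, effect cutoff, correlation
  alpha and bootstrap sizes are surfaced in `pipeline_config()` with the
  reference-analysis values as defaults.

# Known limitations

* The CFA engine covers ML on complete data; no FIML for missingness, no
  ordinal/WLSMV estimation, no exploratory rotation.
* The Sobel z and the BC bootstrap can disagree near the significance
  boundary at small n; both are reported.
* Cross-chromosome totals depend on the duplicated-locus bookkeeping; the
  partition invariant (within + cross = total) is the tested surface.
* The correlation-count bootstrap band is a comparative, not calibrated,
  uncertainty statement (see above).
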