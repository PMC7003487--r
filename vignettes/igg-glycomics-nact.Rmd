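---
title: "Methods: serum IgG N-glycomics for NACT response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum IgG N-glycomics for NACT response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyconact)
```

## The problem

Neoadjuvant chemotherapy (NACT) downstages locally advanced gastric cancer
before surgery, but fewer than half of patients respond histologically, and
there is no accepted pre-treatment biomarker of response. Serum IgG carries
a conserved N-glycan at Asn-297 of its Fc region, and the composition of
that glycan pool (galactosylation, sialylation, core fucosylation,
bisecting GlcNAc) modulates IgG effector function and shifts with
inflammatory state. `glyconact` implements a complete analysis chain for
testing whether the pre-treatment serum IgG N-glycome predicts NACT
response: peak quantification, trait algebra, univariate screening, and
logistic prediction models, plus a calibrated cohort simulator so that the
entire chain is testable without access to patient-level data.

Throughout, the outcome is the Becker histopathological regression grade:
grades 1a/1b/2 (at most 50% residual tumor) define responders, grade 3
non-responders (`becker_responder()`).

## The 24-peak panel and structural classification

HILIC-UPLC of 2-AB-labelled IgG N-glycans resolves 24 peaks (GP1-GP24),
each annotated with a dominant composition written `H<i>N<j>F<k>S<l>`
(hexose, HexNAc, fucose, NeuAc; a parenthesised 6/3 marks arm isomers).
Structural features are a pure function of the composition, under the
standard biantennary-IgG reading:

* **oligomannose**: N = 2 (only GP5, H5N2);
* **galactose count**: H − 3 clipped to 0..2 — the three core mannoses are
  not galactoses;
* **bisecting GlcNAc**: N ≥ 5 (the fifth GlcNAc on the core mannose).
  GP1 (H3N3F1, N = 3) is treated as truncated/monoantennary, not
  bisecting;
* **fucosylated**: F ≥ 1 (difucosylation, GP20, carries no extra feature:
  no downstream trait distinguishes fucose counts beyond presence);
* **neutral** ⇔ no NeuAc.

Arm annotations are metadata only; positional isomers (GP8/GP9, GP10/GP11)
always land in the same trait groups. These rules reproduce exactly the
structural groupings implied by the reference study's trait sums (e.g. the
neutral agalactosylated set {GP1, GP2, GP3, GP4, GP6} whose group means add
to the printed G0 totals in both outcome groups).

## Normalization

Each peak area is divided by the total area of its chromatogram and
expressed in percent, so every `SampleProfile` sums to 100. For trace-level
input, `integrate_fixed_windows()` applies the shared-window convention
(identical integration intervals for all samples) with trapezoidal
integration and linearly interpolated window boundaries. Baseline
subtraction is off by default: manual baseline correction is operator
dependent and irreproducible, and the default keeps the stage
deterministic; a linear per-window baseline is available by flag. Zero
areas are allowed (a peak may be absent); an all-zero sample is an error,
and missing peak columns are an error rather than imputed, because the
trait algebra requires the complete panel.

## The 17 summarized traits

Linear-sum traits are sums of member-peak percentages: GPN (neutral,
GP1-15), S1/S2/S totals, G0/G1/G2 totals, F total, B total. Ratio traits
normalize within a structural stratum: F and B within neutral glycans (per
GPN) and within sialylated glycans (GP16-24); FG0/FG1/FG2, the
galactosylation distribution of fucosylated glycans (fractions of total
fucosylated, summing to 1); and the Gal-ratio

$$\mathrm{Gal\text{-}ratio} = \frac{FG0}{FG1 + 2\,FG2},$$

which weights digalactosylated structures twice and rises with
agalactosylation of the fucosylated pool.

Three conventions deserve comment, all fixed by requiring agreement with
the reference study's printed arithmetic where it is checkable:

* **GP20 is excluded from S1/S2/S totals** even though it is
  monosialylated: the printed sialylation sums demand it. It stays in the
  sialylated denominator of F-sialo/B-sialo and in FG2, where the printed
  values are not decisive and the structural feature should govern.
* **F total is a plain linear sum** of fucosylated peaks. The reference
  study's printed F-total group means are not reproducible as any linear
  combination of its printed peak means, so its exact denominator is
  unknowable from the summaries; the linear sum is the documented choice
  here.
* **FG0/FG1/FG2 use total fucosylated glycans as denominator**, so they sum
  to 1 per sample. Published group means of such per-patient ratios need
  not sum to 1 (a mean of ratios is not a ratio of means), which is
  consistent with what the reference summaries show.

Trait definitions are data, not code: the default set ships as JSON
(`inst/extdata/trait_definitions.json`) and users may load alternatives
with `read_trait_definitions()`.

Because linear traits commute with averaging, applying the calculator to a
published group-mean profile must reproduce the published group-mean trait
exactly; this identity anchors the package's exact worked examples
(G0 total 29.941/36.040, G1 total 37.920, S1 total 10.929/9.489).

## Univariate statistics

Continuous features use the two-sample t-test, pooled-variance by default
(the era-typical default of clinical statistics software; Welch by
option). Categorical baseline variables use the chi-squared test with
Yates continuity correction for 2×2 tables — validated because it, and not
the uncorrected Pearson test, reproduces the reference baseline-table
p-values (age 0.884, sex 0.924) — Pearson for larger tables, and Fisher's
exact test whenever any expected cell count is below 5. Two-sided p < 0.05
is "significant", with no multiple-testing correction by default,
mirroring the reference analysis across its 24 + 17 features
(Benjamini-Hochberg by option).

Per-feature discrimination is the Mann-Whitney AUC (ties 0.5) with a
DeLong 95% CI truncated to [0, 1]. The default orientation is *as-is*
(higher value scores toward responder), so AUCs below 0.5 mark features
that fall in responders; a *directional* option reflects such features.
The reference table mixes both conventions, so orientation is
configurable rather than inferred.

## The three prediction models

`build_paper_models()` fits, in-sample on the pre-treatment cohort:

* **clinical**: age (dichotomized at 60, the baseline-table encoding;
  continuous age by option), histology and regimen, dummy-coded with the
  most frequent level as reference (Other, XELOX);
* **glyco**: GP4 (H3N4F1), GP6 (H3N5F1), GP18 (H5N4F1S1);
* **combined**: the union of both term sets.

In *discovery* mode the glycan terms are instead chosen by stepwise
selection over all 24 peaks with clinical terms forced. The default
stepwise flavour is bidirectional with AIC — a conventional default where
the goal is predictive screening — with BIC and p-value enter/remove
(0.05/0.10) as options. For selection-recovery experiments the package's
own tests use BIC: AIC's asymptotic false-entry rate per pure-noise
candidate is ≈ 16%, so with ~20 null candidates AIC *by design* admits
several noise terms, whereas BIC's penalty grows with n and gives
consistent support recovery. That is a property of the criteria, not of
the implementation, and is why the recovery suite (600 samples, 100
replicates) selects with BIC.

ROC analysis is empirical over all thresholds; the operating point
maximizes the Youden index, with ties resolved toward higher specificity
(consistent with reporting a 100%-specificity operating point). At n ≈ 49
with near-perfect operating points, logistic separation is a real
possibility; it is detected (fitted probabilities pinned at 0/1 with
runaway coefficients) and flagged, and a ridge-stabilized IRLS refit
supplies finite scores, never silently.

In-sample ROC reproduces the reference procedure; `cv_model_auc()`
provides stratified k-fold cross-validation for honest evaluation and is
what the null-cohort tests use (cross-validated AUC ≈ 0.5 when no signal
exists, while in-sample AUC is optimistically inflated — at this cohort
size, substantially).

## The cohort simulator

`simulate_cohort()` draws two-group compositional profiles by a
logistic-normal model: for group mean profile $m$ (percent) and per-peak
log-scale sigmas $\sigma$, a sample is
$100\cdot\mathrm{softmax}(\mu + \varepsilon)$, $\varepsilon_k \sim
N(0,\sigma_k^2)$. A logistic-normal rather than Dirichlet default because
IgG peak abundances span three orders of magnitude (GP22 ≈ 0.003% vs GP4 ≈
22.6%) and need strictly positive, peak-specific multiplicative noise;
Dirichlet is available by option. Because
$E[\mathrm{softmax}(\mu+\varepsilon)] \ne \mathrm{softmax}(\mu)$, the
centre $\mu$ is calibrated by a fixed-point iteration against a large
common-random-numbers Monte Carlo sample (deterministic, cached), so the
configured group means are the *actual* means of the generator; the
large-n mean-recovery test verifies this within Monte-Carlo error.

Defaults are the reference study's conditions: group sizes 24/25; group
mean profiles equal to the published group means renormalized to 100;
covariate frequencies and the responder Becker-grade mix (0/10/15 across
1a/1b/2; non-responders all grade 3) as published. The study publishes no
variances, so the default dispersion is *derived* from its printed
arithmetic: each peak's pooled SD is backed out of its printed group means
and t-test p-value at n = 24/25, expressed as a CV, and used as that
peak's log-scale sigma (capped at 2.5 for the near-zero peaks, where the
implied CVs are enormous and the cap is a numerical guard). This makes the
six reference-significant peaks the most frequently flagged in simulated
cohorts by construction — a qualitative calibration; no claim of
reproducing the real covariance structure is made. Raw totals are
log-normal (meanlog log 1e6, sdlog 0.2) purely so total-area normalization
is exercised.

`simulate_pre_post()` adds a post-NACT timepoint per patient: the pre
profile perturbed in log space by within-subject noise (default sigma
0.05, the scale of UPLC analytical repeatability plus short-term
biological variation — IgG glycomes are stable over weeks) plus a
configurable treatment effect, default zero (the null treatment effect:
the reference study saw no significant pre/post glycan changes). Two
caveats the tests make explicit: (i) compositional closure spreads any
single-peak effect onto all peaks as a renormalization factor, so under a
large targeted effect the "unaffected" peaks shift too (by a far smaller
amount — the power spot-check asserts the ratio, not a nominal rejection
rate); and (ii) for the near-zero peaks with huge between-subject sigma,
paired differences are heavy-tailed and the paired t-test runs slightly
conservative, which is why the null rejection rate sits near 4-4.5% rather
than exactly 5%.

What the simulator does **not** emulate: between-peak biological
correlation beyond closure, covariate-glycome association (age and sex do
shift real IgG galactosylation), batch/drift effects, and measurement
error distinct from biological variation. Passing tests therefore
demonstrate the pipeline's statistical behaviour under a plausible
generative model, not performance on real cohorts.

## Numerical choices and degenerate inputs

* Profile sums are validated to 1e-9; trait identities (GPN = G0+G1+G2+GP5;
  S = S1+S2; GPN+S1+S2+GP20 = 100; FG0+FG1+FG2 = 1) hold to 1e-9 and are
  property-tested on random simplex draws.
* Ratio traits with zero denominator yield `NA` plus a classed warning,
  never a silent 0.
* Zero-variance equal-mean group comparisons report t = 0, p = 1.
* Integration windows are half-open by convention; boundary points are
  interpolated, so a peak straddling two windows partitions exactly.
* All simulation randomness flows from a single seed via scoped RNG
  (`withr::with_seed`); nothing touches the global RNG state.

## Problem sizes used by the test-suite experiments

Chosen as the package's own balance of statistical resolution and runtime:
DeLong coverage at n = 24/25 over 1000 simulations (tolerance ±2 points);
t-test type-I error over 10,000 null simulations (±1 point); stepwise
recovery over 100 replicates of 300 + 300 samples; paired-null calibration
over 1000 replicate 40-pair cohorts; mean recovery at 10,000 samples per
group.

## Limitations

The headline metrics of the reference study (clinical/glyco/combined AUC
0.650/0.770/0.840, sensitivity 64%, specificity 100%) require its
unpublished patient-level data and are not reproducible from summaries;
this package reproduces the *procedure* and every desk-checkable number
(trait sums, responder arithmetic, baseline-table p-values). Simulated
cohorts calibrated to the published effect sizes yield in-sample AUCs of
the same order, but they are draws from a model, not a validation. Ratio
traits whose exact published denominators are unknowable (F total,
F/B-neutral, F/B-sialo, FG0/1/2, Gal-ratio) follow the documented
reconstructions above.
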