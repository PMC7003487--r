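# glyconact

Serum IgG N-glycomics analysis for predicting neoadjuvant chemotherapy
(NACT) response in locally advanced gastric cancer.

Fewer than half of gastric-cancer patients respond histologically to
NACT, and there is no accepted pre-treatment biomarker of response. The
IgG Fc N-glycan pool shifts with inflammatory state, and its composition
— measured as 24 HILIC-UPLC peaks (GP1–GP24, compositions `H<i>N<j>F<k>S<l>`)
— is a candidate serum biomarker. This package is for analysts working
with such IgG glycome panels: it implements the full chain from raw peak
areas (or chromatogram traces) to prediction models, plus a calibrated
cohort simulator so every stage is testable without patient-level data.

The core quantities:

* **Total-area normalization**: peak percentage
  `p_i = 100 · area_i / Σ_j area_j`, so each profile sums to 100.
* **17 summarized traits** built from structural features (galactose count
  `H − 3` clipped to 0..2; bisecting GlcNAc `N ≥ 5`; fucosylation `F ≥ 1`;
  sialylation `S`), e.g. `G0 total = GP1+GP2+GP3+GP4+GP6` and the
  **Gal-ratio** `FG0 / (FG1 + 2·FG2)`, the agalactosylated-to-galactosylated
  distribution of fucosylated glycans.
* **Univariate screening**: pooled t-tests, Yates/Pearson/Fisher
  contingency tests, per-feature Mann–Whitney AUC with DeLong 95% CI.
* **Three logistic models** of the Becker-grade responder outcome
  (grades 1a/1b/2 vs 3): clinical (age ≤60/>60, histology, regimen), glyco
  (GP4, GP6, GP18), combined — with empirical ROC, Youden operating point,
  optional stepwise term discovery and cross-validated AUC.
* **Cohort simulation**: logistic-normal draws on the percent simplex,
  mean-calibrated to the reference group-mean profiles, with per-peak
  dispersion backed out of the reference t-statistics.

## Worked example

Trait algebra on the reference non-response group-mean profile (linear
traits commute with averaging, so these reproduce the published group
trait means exactly):

```r
library(glyconact)
ref <- reference_group_profiles()
nrg <- setNames(ref$mean_nrg, ref$peak_id)
round(compute_traits(nrg)[c("G0_total","G1_total","G2_total","S1_total","Gal_ratio")], 3)
#>  G0_total  G1_total  G2_total  S1_total Gal_ratio
#>    29.941    37.920    18.661    10.929     0.309
```

29.941% of total IgG glycans are agalactosylated in non-responders (vs
36.040 if you repeat this on `mean_rg`): responders-to-be carry more
agalactosylated, pro-inflammatory IgG before treatment.

An end-to-end run on a simulated cohort calibrated to the reference
conditions (24 non-responders, 25 responders):

```r
sim <- simulate_cohort(simulation_config(seed = 1))
cohort <- merge(sim$clinical, normalize_areas(sim$areas), by = "sample_id")
models <- build_paper_models(cohort)
for (nm in names(models)) print(models[[nm]]$roc)
#> ROC: AUC 0.673 (95% CI 0.523-0.823), sens 68.0% / spec 58.3% at 0.522
#> ROC: AUC 0.855 (95% CI 0.754-0.956), sens 84.0% / spec 70.8% at 0.463
#> ROC: AUC 0.902 (95% CI 0.821-0.982), sens 84.0% / spec 79.2% at 0.412
```

Clinical covariates alone discriminate poorly (AUC 0.67); the three-peak
glyco model does most of the work (0.86) and combining both helps (0.90).
These are in-sample AUCs on one simulated draw — optimistic at n = 49, as
`cv_model_auc()` will show.

Univariate screening of the same cohort puts the calibrated signal peaks
on top:

```r
cmp <- compare_features(normalize_areas(sim$areas), sim$clinical$responder)
head(cmp[order(cmp$p_value), c("feature","mean_nrg","mean_rg","p_value","auc")], 5)
#>    feature mean_nrg mean_rg p_value   auc
#> 6      GP6    6.084   7.932 0.00039 0.778
#> 14    GP14   15.689  13.497 0.00791 0.267
#> 18    GP18    7.131   5.623 0.00934 0.315
#> 4      GP4   23.176  26.329 0.01026 0.688
#> 2      GP2    0.588   0.932 0.02759 0.655
```

(AUCs below 0.5 mark features that *decrease* in responders; orientation
is configurable.)

A thin command-line front end covers the same stages
(`simulate | integrate | normalize | traits | compare | model | report`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "glyconact.R", package = "glyconact"))')
Rscript $CLI simulate --outdir out --seed 5
Rscript $CLI normalize --areas out/areas.csv --out out/profiles.csv
Rscript $CLI model --profiles out/profiles.csv --clinical out/clinical.csv --out out/models.json
```

See the methods vignette (`vignettes/igg-glycomics-nact.Rmd`) for the
model assumptions, trait-definition conventions, simulator calibration and
known limitations.

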