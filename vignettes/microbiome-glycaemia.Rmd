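---
title: "Methods: gut microbiota, glycaemic traits and the Healthy Microbiome Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gut microbiota, glycaemic traits and the Healthy Microbiome Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycobiome)
```

This vignette is the package's account of its statistical methods: what is
modelled, which choices were open and how they were resolved, what the
synthetic cohorts do and do not emulate, and what the test suite can and
cannot establish about real data.

## The analysis problem

The setting is a longitudinal cohort spanning provinces nested in two broad
regions (North and South), with a genus-level 16S relative-abundance table
at baseline and a glycaemic panel (fasting glucose, fasting insulin, HbA1c,
and derived HOMA-IR) at baseline and follow-up. The questions are: which
genera are prospectively associated with glycaemic traits; does a simple
carriage-based index built from those genera predict incident type 2
diabetes; how strongly does geography structure the microbiome; and do
dietary habits line up with the trait-related genera.

## Preprocessing

* **Exclusions** are applied sequentially (antibiotics, intestinal disease,
  prevalent diabetes); a participant meeting several criteria is counted at
  the first, so the report's counts are disjoint and sum exactly.
* **Prevalence filter**: a genus is retained iff detected (abundance
  strictly > 0) in at least 10% of participants. The boundary is inclusive;
  "present" is strict positivity. Both are deliberate readings of a filter
  whose edge cases are usually left unstated.
* **Imputation** replaces missing continuous covariates by the mean of the
  observed values *within the participant's region*, and missing
  categorical covariates by the regional mode, with ties broken by
  lexicographic order of the category labels (a deterministic,
  documentable rule). Outcome columns are never imputed; a region with no
  observed value for a column is an error, not a silent fallback.
* **HOMA-IR** is glucose [mmol/l] × insulin [μU/ml] / 22.5. The cohort
  stores insulin in pmol/l, and the conversion 6.945 pmol/l per μU/ml is
  applied inside the formula. This constant is a judgement call: the
  classic formula is stated in μU/ml while the assay panel is reported in
  pmol/l, and only the converted version reproduces the published
  cohort-mean HOMA-IR of 1.7 from mean glucose 5.2 and mean insulin 50.7.
  It is exposed as `insulin_conversion` in `run_config()` for cohorts that
  store insulin differently.
* **HbA1c units** interconvert by the NGSP master equation
  (% − 2.15) × 10.929, reported to one decimal, anchoring 6.5% = 47.5
  mmol/mol.
* **Incident diabetes** at follow-up: fasting glucose ≥ 7.0 mmol/l or
  HbA1c ≥ 47.5 mmol/mol or current diabetes medication, thresholds
  inclusive, evaluated only after imputation so inputs are complete.

## Genus–trait association

Within each region, for genus *g* and trait *y*:

\[
z(y_1) = \beta\, z(g) + \gamma\, y_0 + \mathbf{x}'\boldsymbol\delta +
u_{0,\text{prov}} + u_{1,\text{prov}} z(g) + \varepsilon
\]

fitted by REML (`lme4::lmer`), where z(·) standardizes within the region's
analysis sample, \(y_0\) is the raw baseline trait, and **x** collects age,
sex, household income, marital status, education, residence, urbanisation
index, total energy intake, alcohol, smoking and physical activity, plus
BMI in the primary variant. Random province intercepts and genus slopes
absorb between-province heterogeneity of the microbiome.

Design choices worth recording:

* **Abundance transformation.** Effects are reported per SD of *relative
  abundance* because that is the per-SD estimand the association records
  are defined on; no log or CLR transform by default. A CLR option
  (`clr_transform` in `run_config()`) exists for sensitivity analysis.
  Standardization makes the estimates invariant to affine rescaling of the
  raw abundances.
* **Baseline adjustment** uses the raw baseline value; with a linear model
  this is equivalent up to scaling to adjusting for the standardized value.
* **Convergence fallback.** Random slopes over a handful of provinces are
  frequently singular. The fit hierarchy is explicit: full model → random
  intercept only, and the fallback taken is recorded per record
  (`fallback_north`/`fallback_south`), never hidden. Fewer than 30 usable
  observations is a refusal, not a fit.
* **Pooling** of the two regional estimates uses DerSimonian–Laird
  random-effects meta-analysis exactly as the closed form in
  `meta_combine()`. With only two strata τ² is unstable; it is reported in
  every record so users can audit it rather than being smoothed over.
* **FDR family**: all genus × trait tests of one scan variant, adjusted by
  Benjamini–Hochberg. The family choice is a convention the package fixes
  explicitly, since nothing in the estimand forces it.
* **Panel admission** uses the raw pooled p < 0.05, not the q-value: the
  signed panel is a screening construction, and q-values are carried
  alongside for reporting. A genus whose minimum-p admitting associations
  disagree in sign is excluded with a warning — a conservative rule for a
  case the index definition leaves open.

## The Healthy Microbiome Index and its risk model

HMI counts satisfied panel conditions: carrying a favourable genus, or not
carrying a harmful one. "Carrying" defaults to strictly positive abundance;
a detection threshold (`carriage_threshold`) is exposed because 16S
pipelines differ in their noise floor. The index is integer, bounded by the
panel size, monotone in each satisfied condition, and maps to its
complement when all panel directions are reversed — properties the test
suite asserts directly.

The risk model is a modified Poisson regression: log-link Poisson on the
binary incident-diabetes outcome with robust (HC0 sandwich) standard
errors, which yields consistent risk ratios with valid Wald intervals for
binary outcomes, where a log-binomial model would often fail to converge.
Model-based standard errors are available behind `robust = FALSE`. The HMI
is standardized on the follow-up analysis sample, since that is the
modelled population. Subgroup analyses stratify by region, age group
(< / ≥ 50 years), sex, BMI level (< / ≥ 24 kg/m², the Chinese overweight
threshold) and residence; the cut-points are package choices, documented
and configurable, and each stratum drops its own stratifier from the
covariates. Strata with fewer than 10 events are skipped with a recorded
reason.

## Community comparison

Bray–Curtis dissimilarity (`vegan::vegdist`) feeds classical PCoA and a
PERMANOVA permutation test (`vegan::adonis2`, whole-label permutations,
add-one p-value so the floor is 1/(1 + n_perm); 1000 permutations by
default). The test statistic is the PERMANOVA pseudo-F — the conventional
companion of Bray–Curtis ordination; the permutation count, not the
statistic, is the anchored quantity, and this choice is recorded here
rather than assumed silently. PCoA axes are ordered by eigenvalue; negative
eigenvalues (inevitable for Bray–Curtis) are excluded from the
explained-variance denominator rather than corrected (no Lingoes/Cailliez),
and each axis's sign is fixed by making its largest-magnitude loading
positive so coordinates are reproducible.

## Region classification and diet prediction

A gradient-boosted tree classifier (xgboost) predicts the probability of
Southern membership under leave-one-province-out cross-validation: every
participant is scored by a model that never saw their province, which is
the point — genus signatures must generalize across geography, not memorize
it. The cycle is repeated (default 10 times) with derived seeds
(`seed + repeat − 1`) and probabilities averaged; "repeated ten times" is
read as reseeded repetitions of the whole cycle, one of several defensible
readings, fixed here.

Two implementation details matter for calibration:

* **Per-fold class balancing.** Holding out an entire province skews the
  training base rate toward the other region, which shifts that fold's
  probabilities wholesale and *inverts* the pooled AUC under the null. Each
  training fold therefore reweights classes to parity
  (`scale_pos_weight`).
* **Regularization.** Pooling probabilities from models fit on different
  folds makes the null AUC sensitive to per-fold overfitting noise. The
  frozen defaults (depth 3, η 0.1, 60 rounds, `min_child_weight` 25,
  subsample and column subsample 0.8) are deliberately conservative so that
  a cohort with no regional signal scores AUC ≈ 0.5. They are recorded in
  the classifier report.

Feature attribution uses xgboost's native SHAP values on each fold's
held-out participants, averaged as mean |attribution| across all folds and
repeats; genera above 1e-12 (zero up to floating-point dust) count as
region-discriminating. SHAP local accuracy — attributions plus bias
reconstruct the model margin — is asserted in tests.

Diet prediction runs ten-fold cross-validation, stratified by region so
that folds are regionally balanced and the evaluation does not reduce to
region recognition. Performance is Pearson r for intakes and ROC AUC (with
95% CI, `pROC`) for the wheat-vs-rice staple preference, defined as
wheat/rice intake ratio ≥ 1 (infinite ratio counts as wheat preference;
zero intake of both leaves the label undefined and flagged).

## Diet–microbiota associations

Linear regressions estimate the difference in each panel genus (and the
HMI), in SD units, per SD of each continuous dietary/lifestyle factor (per
category for smoking and alcohol), mutually adjusted for the other factors
and for the confounder set (age, sex, BMI, energy, income, marital status,
education, residence, urbanisation index, animal and vegetable oil). Wheat,
rice and the wheat/rice ratio are functionally dependent, so the ratio's
models exclude the two components and vice versa; any factor pair with
|r| > 0.99 drops the later factor with a log entry. BH FDR runs over the
whole factor × outcome grid. Fibre is tested separately as a sole exposure
with the same confounders. Finally, food-group-to-trait regressions are
fitted with and without the HMI term; attenuation of a food coefficient
when the HMI enters is the mediation signal of interest.

## The synthetic cohort generator

`generate_cohort()` draws: provinces nested in the two regions (default 15,
6 North, weighted so ~36% of participants are Northern); covariates
calibrated region-wise to the emulated cohort's published means and SDs
(age 50.8 ± 12.7 years overall, BMI 24.8/23.7 kg/m² North/South, the 12
food-group intakes as moment-matched log-normals, and so on); zero-inflated
log-normal genus compositions with per-genus occupancy probabilities,
a log-scale North/South shift on selected genera, and diet effects on the
log scale, closed to sum 1; follow-up traits driven by the planted per-SD
betas plus baseline tracking, age and BMI effects, and province intercepts,
with the residual variance chosen so the standardized trait has unit
variance; and incident diabetes as a log-link Bernoulli,
\( \log p = \log(\text{baseline incidence}) + \log RR \times HMI_z +
0.15 \times \text{age}_z \), with HMI computed from the planted signed
panel over the followed subsample — so the Poisson regression estimand
equals the planted parameter exactly. Default sizes mirror the emulated
study: 2772 participants, 66% retained at follow-up, baseline incidence
0.067, planted risk ratio 0.69 per SD.

Choices and caveats:

* **Zero-inflated log-normal rather than Dirichlet**, so occupancy
  (prevalence, which the filter and the carriage logic act on) and
  abundance are controlled independently.
* **Planted trait effects** live on fasting glucose, log fasting insulin
  and HbA1c. HOMA-IR is a deterministic function of glucose and insulin and
  therefore inherits effects rather than receiving its own; insulin effects
  are planted on the log scale because insulin is generated log-normally,
  so their raw-scale per-SD magnitude is attenuated (sign preserved).
* **Ascertainment consistency.** Drawn cases are reconciled with the
  follow-up panel: half are marked as medicated, the rest elevated above
  the glucose or HbA1c diagnostic threshold; non-cases are capped just
  below threshold (affecting well under 1% of draws at the calibrated
  means). `ascertain_t2d()` therefore reproduces the drawn incidence
  exactly. The elevation step slightly inflates follow-up trait variance —
  a realistic feature of diagnostic data that mildly attenuates per-SD
  effects on the raw scale.
* **Loss to follow-up is MCAR** — an assumption, since no attrition
  mechanism is available to emulate; informative dropout is out of scope.
* **Not emulated**: phylogenetic correlation between genera, sequencing
  noise, batch effects, and within-province clustering of diet beyond the
  regional means. Passing tests therefore demonstrate statistical
  correctness of the estimators under the generator's assumptions, not
  robustness to everything real 16S data can do.

## Numerical conventions and test scales

Row closure is validated to 1e-9; round-trip I/O to 1e-12; abundance row
sums may fall below 1 (pipelines that drop unclassified reads) but exceed
1 only within 1e-6. Degenerate inputs fail loudly: constant columns cannot
be standardized, all-zero abundance rows cannot enter Bray–Curtis, a
constant outcome cannot be cross-validated, fewer than 10 events cannot
support the risk model.

The test suite runs its simulations at sizes chosen to keep the full suite
in the low minutes while leaving comfortable statistical margins: cohorts
of 1200–2772 for scan calibration (type-I error and p-uniformity on
all-null cohorts, power for |β| = 0.15 at n = 2000), 20,000 × 30 seeds for
risk-ratio recovery (mean within ±0.03 of the planted 0.69 with ≥ 90% CI
coverage), 100–150 replicate datasets for permutation-test uniformity, and
brute-force oracle comparisons (BH step-up, Bray–Curtis double loop,
DerSimonian–Laird closed forms, Mann–Whitney AUC identity) at small n where
enumeration is exact.

## Known limitations

Two-stratum DerSimonian–Laird τ² is noisy by construction; the package
reports it rather than pretending otherwise. The signed panel inherits
screening noise (chance admissions at α = 0.05), which attenuates the
estimated HMI risk ratio relative to an oracle panel — visible in the
README example. Boosted-tree hyperparameters are frozen defaults, not
tuned; AUCs should be read as achievable-with-defaults, not optimal. The
CLR sensitivity path shares the prevalence filter with the primary path
and does not address compositional bias beyond that.
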