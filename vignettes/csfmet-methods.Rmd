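---
title: "csfmet: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{csfmet: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Untargeted LC-HRMS metabolomics of cerebrospinal fluid produces a
feature-by-injection intensity table contaminated by solvent/carry-over
signals, instrument drift over the injection sequence, features that do
not respond linearly to analyte amount, blood-derived compounds leaking
through the blood–brain barrier, and missingness. After cleaning, the
scientific question is discriminative: which identified metabolites
separate a progressive disease phenotype (SPMS) from a relapsing one
(RRMS) and from controls, which biochemical pathways do they implicate,
and how do they track disability (EDSS), disease duration and MRI
measures. `csfmet` implements that full path and a synthetic-cohort
generator that makes every stage testable.

# Preprocessing model and assumptions

All filters operate on the `injection_table` container and emit a
`filter_report` (removed ids and reasons); the `provenance` field records
step order, which the pipeline fixes as: blank filter → dilution filter →
log2 → TIC outliers → coverage → identification → LOESS → QC CV →
replicate merge → albumin filter → imputation.

**Blank filter.** A feature is a contaminant when its mean blank
intensity reaches `blank_ratio` (default 0.5) of its mean pooled-QC
intensity, missing values counted as zero. The 50% default is
deliberately conservative and exposed as a parameter, since published
blank-ratio conventions vary; it is reported in the filter report.

**Dilution filter.** Features must show |Pearson r| ≥ 0.7 between raw
intensity and injection volume over the terminal QC dilution series
(0.5–32 µL, 2-fold). Missing dilution values count as zero intensity —
absence at low volume is informative. A feature with zero variance across
the series has an undefined correlation and is removed: a flat feature
cannot demonstrate dilution linearity.

**TIC rule.** The total ion count is computed on raw (never log2)
intensities — a "total ion count" of logs is not a count — and only study
injections are ever removed (QC/blank/dilution injections are structural).
Threshold: TIC < 60% of the mean study TIC.

**LOESS drift normalization.** Fitted per feature on pooled-QC log2
intensity versus injection order with `limma::loessFit` at span 0.3
(tricube weights, locally linear). The fitted curve is evaluated at every
injection's order by linear interpolation between QC fits, with linear
extrapolation beyond the QC range; the fit is subtracted and the QC mean
added back, so the QC-predicted level is flat and centered. Anchoring on
QCs rather than all samples is essential: fitting on study samples would
absorb genuine group differences into the "drift". Fewer than 5 QCs is an
error (a median-centering fallback is suggested in the message rather than
silently applied). Because the local fits are linear, a pure linear drift
is removed exactly (to numerical precision), which the tests assert.

**Albumin filter.** Spearman ρ between each feature and the CSF/serum
albumin ratio over all study samples; removal requires jointly p < 0.05
and |ρ| > 0.5. Whether the original analysis used all samples or MS
patients only is ambiguous; all study samples is the default because the
albumin ratio is a technical covariate, not a phenotype.

**Replicates and imputation.** Replicate log2 profiles are averaged
missing-aware after reporting the minimum pairwise Pearson correlation
across subjects. Remaining missing values become the feature mean; this
runs after the 75% coverage filter, so an all-missing feature cannot
occur.

# Identification

Features match library entries within 15 ppm and 20 s; ties break by
smallest ppm error, then smallest RT error. MS/MS spectra are compared by
greedy nearest-m/z peak pairing within a fragment tolerance of 0.01 Th
(the source conventions state none; greedy pairing is unambiguous and
testable, optimal assignment would change results only for pathological
spectra). Coverage is shared/|reference| and the dot product is the cosine
of paired raw intensities, unpaired peaks contributing only to the norms;
a match needs (coverage ≥ 0.5 or ≥ 5 shared peaks) and dot > 0.5. A
library match without acquired MS/MS is validation level 1, with a
matching MS/MS level 2, and with a contradicting MS/MS the identity is
rejected and the feature excluded. Multiple features matching one entry
are all retained (adduct-resolved rows are reported separately and merged
only by name canonicalization in set operations).

# Age adjustment

Per feature, ordinary least squares of log2 level on age over RRMS +
controls only; SPMS is excluded because including it would risk removing
disease-driven alterations that correlate with the older SPMS age
distribution. Features with slope p < 0.05 are corrected in **all**
subjects by subtracting `slope × (age − mean reference age)`. Centering at
the reference mean age is a deliberate choice (the uncentered form is
equally consistent with a bare "correct the levels"): it preserves the
reference-group mean of each feature and makes the correction idempotent —
refitting on the reference set after correction returns a slope of zero by
the OLS residual property, which the tests check to 1e-9.

# PLS-DA, VIP and validation

Predictors are autoscaled; zero-variance variables are dropped with a
warning. Classes are coded −1/+1 (first factor level negative, i.e. the
contrast "SPMS:RRMS" codes SPMS = +1) and the coded response centered.
Components come from NIPALS, which for one response is: w ∝ Xᵀy
(normalized), t = Xw, p = Xᵀt/tᵀt, c = yᵀt/tᵀt, then deflation. Scores are
mutually orthogonal and T = X_s W(PᵀW)⁻¹; both identities are asserted at
1e-8–1e-10 in the tests, as are mean(VIP²) = 1 and the one-component
closed form VIP = √p·|w₁|.

Numerical/validation choices, all configurable:

* **Component count**: chosen automatically by adding components while the
  inner cross-validated Q² improves by ≥ 0.01 (min 1, max 10). Inside
  `repeated_cv` the count is chosen once on the full data and reused for
  all fold-models; per-fold reselection would multiply runtime roughly
  tenfold without changing what the aggregate VIPs estimate.
* **Q²**: 1 − PRESS/TSS over stratified inner folds (default 7,
  independent of the outer 5-fold loop), refitting scaling and centering
  per training fold. Negative Q² = no predictivity; the pipeline reports
  such contrasts as "no significant difference" and excludes them from
  downstream tables.
* **Permutation test**: `p = (1 + #{perm ≥ obs})/(n_perm + 1)` for both
  R²Y and Q²; default 100 permutations (the original count is unstated).
* **Repeated CV**: stratified 5-fold × 10 repeats = 50 fold-models.
  Per-variable VIP mean with a normal-approximation 95% CI
  (±1.96·sd/√50); AUROC as the tie-corrected Mann–Whitney statistic; ROC
  curves vertically averaged on a fixed 101-point 1−specificity grid with
  the SEM of sensitivity.
* **Projection**: held-out samples (e.g. transitioning patients) are
  scaled with training parameters and projected; the predicted class uses
  the midpoint of the class-mean fitted scores as threshold. Never refits.

# Differential statistics and pathways

Variables with mean VIP ≥ 1.0 (boundary inclusive) are altered. Welch's
t-test is used for the per-metabolite comparison; BH FDR is applied with
m = the number of VIP-selected metabolites — the convention that
reproduces the printed FDR columns of the motivating report tables, which
the acceptance tests verify from the printed p-values alone. Change
direction is purely the sign of the log2 fold change (difference of group
means on log2 data).

Pathway over-representation is the hypergeometric upper tail P(X ≥ k)
with the universe defaulting to the union of all library compounds (a
configurable alternative is "all identified metabolites"; the original
web tool's background is unstated). FDR is computed across the whole
library with zero-hit pathways retained in the denominator. The topology
impact is Σ betweenness(hits) / Σ betweenness(all pathway compounds),
with fractional credit over tied shortest paths; normalization constants
cancel in the ratio, and a zero denominator (complete graphs, ≤ 2 nodes)
defines impact 0. Betweenness is computed with igraph and cross-checked
in the tests against a brute-force all-pairs shortest-path counting
oracle on small graphs.

# Associations

Spearman ρ uses average ranks; p-values use the exact small-sample null
distribution for n ≤ 9 without ties (via `stats::cor.test`) and the
t-approximation otherwise. Correlations run over MS patients only —
controls have no EDSS/duration and their inclusion in MRI correlations
would mix phenotype with severity. Cells are marked significant at
p < 0.05 without multiplicity adjustment, matching the per-cell
convention of the association table this mirrors (a BH option exists).
Rows are clustered on ρ vectors with Euclidean distance and complete
linkage (the distance is the only stated choice; complete linkage is the
package's documented default and configurable).

# The synthetic cohort: what it emulates, and what it does not

Defaults are fixed to the emulated study design: 10 controls / 30 RRMS /
16 SPMS; ages normal with (39, 13.1), (39, 10.6), (58, 9.3) years
truncated at 18; EDSS on the half-point scale and log-normal disease
durations with SPMS medians above RRMS; a QC + blank pair at the start of
the run and after every 8th study injection; a terminal 2-fold dilution
series 0.5–32 µL; ~15% age-dependent features (slopes 0.02–0.05
log2/year); blank-borne contaminants at 10% of features; 5%
albumin-linked features; SPMS-only group effects with |log2 FC| spaced
over 0.1–1.2 on a quarter of the features (so RRMS vs control is a true
null, as reported for the emulated study); technical noise SD 0.3 log2;
5% MCAR missingness.

Choices the generator makes where the emulated design is silent:

* **Drift**: smooth monotone decay plus a mild sinusoid (10% of the
  amplitude), recoverable by LOESS at span 0.3. The default amplitude is
  0.5 log2 units over the run: large enough that drift correction is
  consequential, small enough that no study injection violates the 60%
  TIC rule — consistent with the emulated study, which removed no sample
  outliers. The dilution series is exempt from drift so its volume
  linearity is exact by construction.
* **Missingness** is MCAR only; intensity-dependent dropout is out of
  scope because no mechanism is stated.
* **Replicates**: one injection per sample by default; a replicate count
  option produces correlated copies to exercise replicate merging (the
  emulated study reports a minimum replicate correlation of 0.99 but not
  the replicate count).
* **Clinical coupling**: a latent progression score per MS subject drives
  EDSS, duration and MRI measures through a Gaussian copula (target rank
  correlation 0.7) and feeds designated "progression" features, so the
  association module has recoverable signal.
* **Pooled QC** levels are the raw-scale mean of the expected study
  levels, as a pooled aliquot would be.

A green test on this generator establishes that the pipeline recovers the
structure the generator injects — linear-in-volume dilution behavior,
additive smooth drift, linear age trends, monotone albumin links, MCAR
gaps. It does **not** establish performance on real data with
correlated features, adduct/isotope redundancy, retention-time warping,
intensity-dependent missingness, or batch structure, none of which are
simulated; feature-level simulation also says nothing about peak picking,
which is upstream of this package's scope.

# Known limitations

* PLS-DA is strictly two-class; multi-group contrasts are fit pairwise.
* No OPLS, no nonlinear age models, no longitudinal modelling of
  follow-up EDSS.
* The m/z–RT match ignores adduct networks; rows for different adducts of
  one compound are merged only by name canonicalization.
* The pathway analysis ships only synthetic libraries plus GMT/edge-list
  parsers; no KEGG data is redistributed and no API is queried.
* With small cohorts (n = 16 vs 30) the VIP CI from 50 fold-models
  understates between-cohort variability; it quantifies resampling noise,
  not replication uncertainty.
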