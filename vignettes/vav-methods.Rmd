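---
title: "Volumetric vascularization analysis and prognostic modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric vascularization analysis and prognostic modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vavmri)
```

## The problem

Dynamic contrast-enhanced (DCE) breast MRI samples the signal intensity of
every voxel once before and repeatedly after contrast injection. How a
tumor voxel enhances — how fast the contrast washes in, and whether the
signal keeps rising, plateaus, or washes out over the delayed phase —
reflects the quality of its neovascularization and is therefore prognostic.
`vavmri` implements a fully automated volumetric analysis of this
vascularization and couples it to survival modelling: can imaging features
improve the risk prediction of the Nottingham Prognostic Index (NPI), the
standard clinicopathological score for primary breast cancer?

The package works on an 8-frame series (one pre-contrast frame, seven
post-contrast frames at one-minute spacing) with 1.1 x 0.9 mm in-plane
voxels and 3 mm slices by default, and the only user input the method
requires is a rectangular volume of interest (VOI) enclosing the index
tumor.

## Voxel kinetics and the nine enhancement patterns

For a curve $SI_0, SI_1, \dots, SI_7$ the package computes

* **wash-in** $= 100\,(SI_1 - SI_0)/SI_0$ — initial uptake relative to the
  pre-contrast baseline;
* **delayed change** $= 100\,(SI_7 - SI_1)/SI_1$ — late behaviour relative
  to the *first post-contrast* frame, not the baseline;
* **peak enhancement** $= \max_t 100\,(SI_t - SI_0)/SI_0$ over the
  post-contrast frames, and **time to peak (TTP)**, the earliest minute
  attaining that maximum.

Wash-in is binned weak / intermediate / strong and the delayed phase
persistent / plateau / wash-out; the cross of the two gives nine patterns
A–I (A = weak + persistent, I = strong + wash-out):

| | persistent (> +10%) | plateau (±10%) | wash-out (< −10%) |
|---|---|---|---|
| **weak** [30, 50) | A | B | C |
| **intermediate** [50, 100] | D | E | F |
| **strong** (100, ∞) | G | H | I |

The published bin edges are stated as overlapping ranges ("30% to 50%",
"50% to 100%", ">100%"), so a convention was needed: the weak bin is
right-open, the intermediate bin closed, and the enhancement threshold is
*inclusive* — a voxel at exactly 30% wash-in enhances, so the printed
threshold value itself is classifiable. Signal changes are computed signed;
a voxel whose signal falls below baseline simply has negative wash-in and
is excluded by the threshold. All edges are configurable in
`kinetic_config()`.

Three whole-volume reductions follow:

1. **Total enhancing tumor volume (TTV)** — VOI voxels with wash-in at or
   above the 30% threshold, converted to cm³. Necrotic tumor and perifocal
   tissue fall below the threshold and are excluded automatically; voxels
   with non-positive baseline (air) are excluded silently with a logged
   count, since a percentage change is undefined there.
2. **Heterogeneity of vascularization** — the percentage of TTV voxels in
   each of the nine patterns; the nine cells always sum to 100%.
3. **The most suspect compartment** (next section).

## The most suspect compartment

The TTV is scanned with 3×3-voxel in-plane clusters. The published
description ("clusters, size 3×3 voxels") with 3 mm slices is read as
in-plane; the default is a stride-1 sliding window rather than a disjoint
tiling, because a sliding search cannot miss the optimum through grid
phase. A disjoint tiling is available via
`kinetic_config(cluster_mode = "tiled")`. Clusters never span slices, and a
cluster's curve is the mean over its *enhancing* member voxels only —
the cluster is scored as one unit (mean curve first, percentages second).

Each cluster receives a **wash-out score**. The published "ratio of wash-in
and wash-out" is not given as a formula, so two forms are provided:

* `difference` (default): wash-in − delayed change, in percentage points.
  It increases with wash-in and with wash-out magnitude and is stable when
  the delayed change is near zero, where a literal quotient is not.
* `quotient`: wash-in / max(ε, −delayed), ε = 1 percentage point. Note the
  floor makes this form explode for persistent curves (positive delayed
  change); it is retained for comparability, not recommended.

The cluster maximizing the score is the most suspect compartment; ties
resolve to the first cluster in deterministic slice/row/col order. Its mean
curve yields the four compartment features: wash-out ratio, wash-in, peak
enhancement, and TTP.

Together with the TTV and the nine heterogeneity percentages these are the
14 features returned by `extract_vav_features()`.

## The phantom generator

`make_phantom()` builds a fully known test object: an ellipsoidal tumor in
a flat background, each tumor voxel following the canonical curve of its
assigned pattern. Templates sit at the *center* of each classification cell
(wash-in +40 / +75 / +170%; delayed +20 / 0 / −30%), so every template is at
least 5 percentage points — in practice 10 or more — from every bin edge
and small noise cannot flip a label. Post-contrast frames interpolate
linearly between $SI_1$ and $SI_7$, which puts the peak at minute 1 for
plateau and wash-out patterns (earliest-maximum tie rule) and minute 7 for
persistent ones. A configurable fraction of tumor voxels forms a
sub-threshold necrotic core (+10% wash-in), emulating the non-enhancing
center of larger carcinomas.

Voxels are allocated to patterns by largest-remainder apportionment, so a
noiseless phantom realizes its mix *exactly* (to the voxel) and the
downstream classifier must recover it to machine precision — the basis of
the recovery tests. The default mix places just over half of the enhancing
volume in the weak/intermediate persistent cells and 10.3% in the strong
wash-out pattern, mimicking a heterogeneous invasive carcinoma whose most
suspect compartment shows the textbook malignant curve: +170% wash-in
peaking at minute 1 and washing out thereafter.

Noise is additive Gaussian on signal intensity (default SD 2 at baseline
100), clipped at zero. This is a simplification — magnitude MR noise is
Rician — which is acceptable at the SNR of a clinical breast protocol,
where the Gaussian approximation to the Rician is close; the generator
makes no claim about low-SNR behaviour. What the phantoms do *not* emulate:
pharmacokinetics (no Tofts model), partial-volume mixing at tumor
boundaries, motion, B1/coil inhomogeneity, and spatial noise correlation.
Tests passing on phantoms therefore validate the *feature-extraction
algebra*, not robustness to real acquisition artifacts.

## The cohort generator

`make_cohort()` draws subjects from an explicit proportional-hazards model:
event times are exponential with hazard
$\lambda_0 \exp\{\beta^\top (x - \mu)\}$, censoring is uniform on an
administrative window of 27–93 months, and the observed time is the
minimum of the two. The default $\beta$ is the published four-covariate
model (TTV 0.01 per cm³, heterogeneity-A −0.05 per %, TTP 0.61 per minute,
NPI 0.70 per unit); centering at the covariate means $\mu$ keeps
$\lambda_0$ interpretable as an average subject's hazard.

The covariate distributions approximate the published cohort summaries and
are configuration, not estimates: TTV is lognormal (median 3.2 cm³, mean
~9, SD ~25 — volumes are strongly right-skewed), heterogeneity-A is
truncated normal (29 ± 14%, within 0–100), TTP is discrete on 1..7 minutes
with mean ~1.5 (most tumors peak in the first minute or two), and NPI is
truncated normal (4.4 ± 1.1 on its 2.2–7.4 range). The default
$\lambda_0 = 1.13 \times 10^{-3}$ per month was calibrated once by Monte
Carlo so that about 11% of subjects experience the event under this
censoring window — the censoring regime the pipeline is designed for
(roughly 35 events per 314 subjects).

## The prognostic pipeline

`prognostic_report()` chains the published analysis:

1. **NPI**: $0.2 S + N + G$ with the nodal map 0 → 1, 1–4 → 2, >4 → 3.
   Reported to one decimal; the raw value is retained.
2. **Univariate screen** of the imaging features: one Cox model per
   feature, likelihood-ratio P, retained when P < 0.007 (a Bonferroni
   correction of a 10% error level across 14 features). Non-convergent fits
   are dropped with a warning.
3. **Backward selection** from the screened features (plus NPI for the
   compound model): repeatedly remove the covariate with the largest
   drop-one likelihood-ratio P at or above 0.05. The entry threshold 0.001
   is part of the interface but idle — pure backward elimination never
   re-enters. Ties in event times use the Efron approximation (follow-up is
   recorded in months, so ties are expected); Wald statistics are used only
   for confidence intervals, likelihood ratios for all selection decisions.
4. **Harrell's C** of each model's linear predictor: a vectorized
   enumeration of all ordered pairs. A pair is usable when the earlier time
   is an event (a tied event/censored pair counts, the event taken as
   earlier; tied event times do not); tied predictors count one half.
5. **Youden cutoff**: every observed predictor value is a candidate
   threshold, J = sensitivity + specificity − 1 against the observed event
   indicator, smallest maximizer on ties. The published phrase "on the
   time-dependent data" names no horizon, so the default operationalizes
   Youden on the event indicator over observed follow-up; a fixed-horizon
   variant (e.g. 60 months, censored-before-horizon subjects excluded) is
   available via `run_config(youden_horizon =)`.
6. **Kaplan–Meier comparison** of the resulting low/high risk groups:
   survfit curves, logrank P, and the between-group hazard ratio from a
   one-covariate Cox model with Wald CI.

Model comparison is reported as the difference in Harrell's C with a
subject-resampling bootstrap CI (the models are refit without re-running
selection on each resample). Age is supported as an optional covariate but
excluded from defaults; the heterogeneity covariate entering the models is
the category-A percentage (weak wash-in, persistent), the cell retained in
the published model.

## Numerical conventions and degenerate inputs

* TTP ties: earliest minute attaining the maximum; peak ≥ wash-in always,
  since minute 1 is part of the scanned range.
* $SI_0 \le 0$ (or $SI_1 \le 0$): voxel flagged invalid and excluded, never
  an exception in whole-volume calls; a single-curve call returns the
  invalid flag. NaN input is an error.
* Empty TTV: allowed by segmentation (0 cm³), but the heterogeneity matrix
  and cluster search refuse an empty mask with an instructive error.
* Multiple disjoint enhancing components inside the VOI all count toward
  TTV; choosing the VOI around the index lesion is the caller's
  responsibility.
* The VOI is specified as half-open, 0-based voxel index ranges per axis —
  unambiguous cuboid arithmetic regardless of R's 1-based indexing.
* All generator randomness flows from the spec seed through an isolated RNG
  scope that restores the caller's `.Random.seed`.

## Problem sizes used in the test suite

The shipped tests run the classifier against a brute-force lookup on a
dense kinetic grid including all bin boundaries; heterogeneity
normalization on 100 random phantoms (grids around 5×14×14); exact
composition recovery on noiseless phantoms (12×40×40, ~2,500 tumor
voxels); the cluster search against exhaustive window enumeration on grids
up to 3×10×10; concordance against naive pair enumeration on 50 instances
of up to 40 subjects; coefficient recovery on 20 cohorts of 1,000 subjects;
screen calibration on 400 null cohorts of 300 subjects; and the
NPI-vs-compound comparison on 20 cohorts of 314 subjects. These sizes give
stable statistical checks at interactive runtimes and are the package's
chosen defaults for its own validation.

## Known limitations

* The kinetic templates and the additive-Gaussian noise model make phantom
  classification intentionally easy; margins shrink with real
  partial-volume voxels and the package has no partial-volume model.
* The wash-out-ratio formula and the cluster tiling of the original
  commercial implementation are unknown; both are config axes and results
  can shift between conventions.
* Harrell's C is O(n²) in memory; fine to a few thousand subjects, not for
  biobank scale.
* The bootstrap CI on ΔC resamples subjects but keeps the selected feature
  set fixed, so it understates selection uncertainty.
* In-sample concordance of a model fitted and evaluated on the same cohort
  is optimistic; the package compares models under identical conditions but
  does not cross-validate.
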