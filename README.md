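# vavmri

Volumetric analysis of breast-tumor vascularization from dynamic
contrast-enhanced (DCE) MRI, coupled to survival modelling.

## What it does, and for whom

In DCE breast MRI every tumor voxel traces an enhancement curve — one
pre-contrast and seven post-contrast frames at one-minute spacing. The
shape of that curve (fast or slow wash-in; persistent, plateau or wash-out
delayed phase) reflects tumor neovascularization and carries prognostic
information. `vavmri` is for imaging scientists and biostatisticians who
want a fully automated, reproducible implementation of this analysis and of
the survival pipeline built on top of it:

* **Voxel kinetics** — wash-in `100·(SI₁−SI₀)/SI₀`, delayed change
  `100·(SI₇−SI₁)/SI₁`, peak enhancement, time to peak (TTP);
* **TTV** — total enhancing tumor volume: voxels with wash-in ≥ 30%, in cm³
  (necrosis and perifocal tissue fall below the threshold);
* **Heterogeneity of vascularization** — the percentage of the TTV in each
  of nine patterns A–I, the cross of wash-in bins (weak 30–50%,
  intermediate 50–100%, strong >100%) with delayed-phase bins (persistent
  >+10%, plateau ±10%, wash-out <−10%);
* **Most suspect compartment** — the 3×3-voxel cluster maximizing a
  wash-out score, characterized by wash-in, peak, TTP and the score itself
  (14 imaging features in total);
* **Prognosis** — the Nottingham Prognostic Index `NPI = 0.2·S + N + G`,
  univariate Cox screening (likelihood-ratio P < 0.007), backward-selected
  Cox models (removal at P ≥ 0.05, Efron ties), Harrell's concordance
  index, Youden-optimal risk cutoffs, and Kaplan–Meier comparison with
  logrank test and hazard ratio;
* **Generators** — DCE phantoms with exactly known kinetic composition and
  survival cohorts drawn from a known proportional-hazards model, so the
  whole chain is testable without patient data.

Volumes are read and written as NIfTI (4D series, 3D label maps), cohorts
as CSV, derived results as JSON, configuration as YAML.

## Worked example

```r
library(vavmri)

# a heterogeneous tumor phantom: ~2500 voxels, 15% necrotic core,
# 10.3% of the enhancing volume in the strong wash-out pattern I
ph  <- make_phantom(phantom_spec(noise_sd = 0, seed = 42))
seg <- segment_ttv(ph$series)
f   <- extract_vav_features(ph$series)
f
#> Vascularization features (14 parameters)
#>   TTV: 6.201 cm^3 (2088 voxels)
#>   Heterogeneity (% of TTV):
#>              persistent plateau wash-out
#> weak               30.6       6      4.0
#> intermediate       25.3       8      5.0
#> strong              5.8       5     10.3
#>   Most suspect compartment: wash-in 170.0%, peak 170.0% at 1 min, washout ratio 200.0

compute_npi(size_cm = 5.8, n_positive_nodes = 5, grade = 2)$npi_1dp
#> [1] 6.2
```

The TTV is the enhancing voxel count times the voxel volume
(2088 × 2.97 mm³ = 6.20 cm³; the 368 necrotic voxels enhance below the 30%
threshold and are excluded). The heterogeneity cells recover the generated
mix exactly because the phantom is noiseless, and the most suspect
compartment lands on a strong wash-out cluster: +170% wash-in, peak at
minute 1, wash-out score 200 (difference form: 170 − (−30), the category-I
template's delayed change). The NPI of a
5.8 cm, grade-2 tumor with 5 positive nodes is 0.2·5.8 + 3 + 2 = 6.2.

On the survival side:

```r
co  <- make_cohort(cohort_spec(n_subjects = 314, seed = 2))
rep <- prognostic_report(co$table, run_config(seed = 3))
#> 314 subjects, 35 events; screen retained: het_A_pct, ttp_min;
#> C(npi)=0.673 C(npi_vav)=0.831
```

Adding the imaging features to the NPI raises in-sample concordance from
67.3% to 83.1% on this simulated cohort, and Youden-cutoff stratification
of the compound model separates the risk groups at a hazard ratio of ~12
(`rep$stratification$npi_vav`).

## Analysis workflow

The `analysis/` directory runs the complete study as numbered drivers, each
a thin narrative over the package functions (optional argument: a seed):

```sh
Rscript analysis/01_simulate_phantoms.R 1   # phantoms -> scratch/, truth -> results/
Rscript analysis/02_extract_features.R 1    # 14 features + recovery check
Rscript analysis/03_simulate_cohort.R 1     # 314-subject cohort -> results/cohort.csv
Rscript analysis/04_fit_models.R 1          # screen, Cox models, Harrell's C
Rscript analysis/05_stratify.R 1            # Youden cutoff, KM, logrank, HR
```

Tables and JSON land in `results/`, volumes in `scratch/`.

## Documentation

The methods vignette (`vignettes/vav-methods.Rmd`) documents the
classification conventions, the two wash-out-score forms, the generator
design (what the phantoms emulate and what they deliberately do not), the
statistical pipeline, and known limitations.
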