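# magnetoadrenal

Modeling and analysis toolkit for **magnetothermal adrenal stimulation**:
remotely triggering adrenal hormone release by heating injected iron-oxide
magnetic nanoparticles (MNPs) with an alternating magnetic field (AMF)
until heat-sensitive TRPV1 channels (threshold ≈ 42 °C) open.

It is written for two audiences. Experimenters designing a stimulation
protocol can ask the *forward* question — will this injection volume,
concentration and specific loss power actually heat the gland past 42 °C?
Analysts with stimulation data can run the *inverse* side — the heart-rate,
serum-hormone, freezing-behavior and histology pipeline that quantifies
what the stimulation did. A seeded synthetic-cohort generator reproduces
every input modality, so the entire pipeline is testable end to end with
no animal data.

## What's inside

**Thermal design core.** A finite-difference solver for the Pennes
bio-heat equation on an ellipsoidal adrenal gland (5.5 × 2.2 × 2.2 mm)
with a fat shell:

ρᵢCᵢ ∂T/∂t = ∇·(Kᵢ∇T) − ρ_b C_b ω_b (T − T_b) + P(x)

with the blood-perfusion term acting as a heat sink and injections rendered
as uniform spheres of power density SLP × c_Fe (2.4 × 10⁷ W/m³ at the
default 600 W/g, 40 mg/ml). The explicit C++ kernel solves a 60 s epoch at
0.1 mm resolution in seconds and is verified against closed-form
conduction solutions.

**Calorimetric SLP estimation** (initial-slope method with baseline-drift
correction) and linear-response f·H₀² extrapolation across AMF conditions.

**Analysis stages.** Kalman-smoothing gap imputation, baseline scaling and
gamma-GLM (identity link) comparison of stimulation-window heart-rate AUCs;
4PL ELISA calibration with beta-tail outlier screening (p < 0.0005) and
pooled t tests on log post/pre hormone ratios; the min-max /
baseline-scaling / moving-average freezing normalization chain with an
in-package beta-regression MLE (trial × phase × treatment); moment-based
ellipse fitting of adrenal sections with medulla/ZR/ZF/ZG zone coverage.

## Worked example

Does the standard two-injection protocol reach the TRPV1 threshold?

```r
library(magnetoadrenal)
sim <- simulate_adrenal_heating(spacing = 0.15)   # Table defaults, 60 s
sim$report
#> peak 48.61 C at 60 s; crossing times 1.64 / 1.64 s (per injection site);
#> volume >= 42 C at 60 s: 16.30 mm3 of 34.80 mm3 tissue
```

Both 1 µl sites cross 42 °C less than two seconds after field onset and
nearly half of the gland+shell volume is above threshold by 60 s — the
protocol has a comfortable design margin.

A full synthetic run (28 rats, seed 11) through every analysis stage:

```r
m <- run_all(cohort_config(seed = 11))
#> CORT: t = -5.40, df = 26, p < 0.001 (pooled)        # active ratios suppressed
#> HR pre-conditioning condition effect: t = 11.42     # active rats respond
#> HR post-conditioning (day 4): t = -0.73, p = 0.47   # response blunted
#> behavior: 24 retained / 4 excluded (non-conditioners);
#> endpoint t = -0.16 (df 21.3)                        # no extinction effect
m$stages$histology$aggregate
#>      zone particle_px zone_px coverage_pct
#> 1 medulla        3951   68180     5.79
#> 2      ZF        2216  136248     1.63
#> 3      ZG           0   80864     0.00
#> 4      ZR        4249  139664     3.04
```

The generator encodes post-conditioning suppression (hormone ratios < 1 in
active rats, day-4 heart-rate rise blunted to zero, no behavioral effect,
no particles in the zona glomerulosa), and each stage recovers exactly that
pattern; per-stage exclusion bookkeeping (retained + excluded = input,
machine-readable reasons) is part of the returned manifest.

A thin CLI mirrors the API for shell use:

```sh
exec/magnetoadrenal simulate-cohort --seed 4 --out cohort/
exec/magnetoadrenal analyze-hr --traces cohort/hr --out hr.json
exec/magnetoadrenal simulate-heat --spacing-mm 0.1 --out heat/
```

## Layout

- `R/`, `src/` — API and the C++ bio-heat kernel
- `tests/testthat/` — oracle-based unit, property and acceptance suites
- `vignettes/magnetoadrenal-methods.Rmd` — models, conventions, caveats
- `exec/magnetoadrenal` — CLI dispatcher
- `scripts/acceptance.R` — headline-result reproduction
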