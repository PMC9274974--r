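---
title: "Models and methods behind magnetoadrenal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magnetoadrenal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetoadrenal)
```

`magnetoadrenal` models and analyzes remote magnetothermal stimulation of
the adrenal gland. Iron-oxide magnetic nanoparticles (MNPs) injected into
the gland dissipate heat under an alternating magnetic field (AMF); once
local tissue temperature crosses the ~42 °C activation threshold of the
TRPV1 ion channel, calcium influx triggers release of epinephrine and
corticosterone. The package covers the design side (does a given injection
configuration actually reach 42 °C?) and the measurement side (heart-rate,
serum-hormone, freezing-behavior and histology analyses of a stimulated rat
cohort), plus a seeded synthetic-cohort generator so the full pipeline runs
and can be validated without animal data.

# The bio-heat model

## Governing equation

Tissue temperature follows the Pennes bio-heat equation, per compartment
$i \in \{\text{adrenal}, \text{fat}, \text{outside}\}$:

$$\rho_i C_i \frac{\partial T}{\partial t}
  = \nabla \cdot (K_i \nabla T)
  - \rho_b C_b \omega_b \,(T - T_b) + P(\mathbf{x})$$

The perfusion term is implemented as a heat *sink*: blood at arterial
temperature $T_b$ carries heat away from tissue warmer than $T_b$ at rate
$\rho_b C_b \omega_b$ per kelvin. (Written with the opposite sign the term
would be self-amplifying and the equation would have no bounded steady
state; the sink convention is the physically standard one and is what this
package solves.) Perfusion acts in every compartment.

## Parameters

| Parameter | Symbol | Default | Units |
|---|---|---|---|
| MNP specific loss power | SLP | 600 | W/g(Fe) |
| MNP iron concentration | — | 40 | mg/ml |
| Blood density | $\rho_b$ | 1000 | kg/m³ |
| Blood heat capacity | $C_b$ | 4180 | J/(kg·K) |
| Blood perfusion rate | $\omega_b$ | 0.0064 | 1/s |
| Arterial / initial / boundary temperature | $T_b$, $T_o$ | 37 | °C |
| Adrenal density / heat capacity / conductivity | $\rho_A$, $C_A$, $K_A$ | 1020 / 3540 / 0.52 | kg/m³, J/(kg·K), W/(m·K) |
| Fat density / heat capacity / conductivity | $\rho_F$, $C_F$, $K_F$ | 911 / 2348 / 0.21 | kg/m³, J/(kg·K), W/(m·K) |

The gland is an ellipsoid with full axis lengths 5.5 × 2.2 × 2.2 mm
(semi-axes 2.75 / 1.1 / 1.1 mm; `gland_geometry()` accepts semi-axes
directly if preferred) wrapped in a concentric fat shell. The shell
thickness is not a well-constrained anatomical number; the default is
0.5 mm and is configurable. The medium between the fat shell and the
simulation box ("outside") must conduct heat for the Dirichlet boundary to
be meaningful; it defaults to perfused fat, the tissue that actually
surrounds the retroperitoneal gland.

## Injection sources

Each injection of volume $V$ µl is rendered as a uniform sphere of radius
$(3V/4\pi)^{1/3}$ mm — the bolus a slow (0.1 µl/min) infusion plausibly
forms — with volumetric power density $\mathrm{SLP} \times c_{Fe}$
(2.4 × 10⁷ W/m³ at the defaults). Boundary voxels get partial-volume
weights so the integrated power matches $\mathrm{SLP} \times m_{Fe}$
essentially exactly; a Gaussian source of the same total power (σ = half
the bolus radius) is available as an alternative. The default placement is
two sites at ±1 mm on the long axis, mirroring the two-injection surgical
protocol targeting medulla and cortex.

## Numerics

The solver (`simulate_bioheat()`, C++ core) uses explicit forward-time
central-space finite differences on a cell-centered isotropic grid with
harmonic-mean face conductivities, which keeps the scheme flux-conservative
across the adrenal/fat interface. The time step is checked against the
stability limit $h^2 / (6\,\alpha_{\max})$ and defaults to 0.8 of it; a
violating user-supplied `dt` is rejected before stepping. Temperatures are
in °C throughout (the PDE is offset-invariant). The outer box, placed
≥ 1 mm beyond the fat shell, is Dirichlet at $T_o$ by default; an insulated
(zero-flux) option exists mainly for energy-balance verification. No
implicit scheme is provided: at the design resolution (0.1 mm, ~2.4 × 10⁵
voxels, ~8 × 10³ steps for a 60 s epoch) the explicit solve takes seconds,
so the extra machinery would buy nothing.

Verification rests on closed forms: (i) zero source at equilibrium is
preserved exactly; (ii) uniform heating of an insulated box raises the mean
temperature at exactly $P/\rho C$; (iii) a uniformly heated sphere in an
infinite medium has center rise $P a^2 / 2K$ at steady state
(`sphere_steady_rise()`) and, at finite time,
$\tfrac{P}{K}\int_0^a r\,\mathrm{erfc}\!\big(r/2\sqrt{\alpha t}\big)\,dr$
(`sphere_transient_rise()`). At 60 s the transient solution sits ~8 %
below steady state — that physical deficit, not discretization error,
dominates the comparison against the steady value, which is why grid
refinement is judged against the transient form. The test suite runs the
sphere configuration at 0.2 and 0.1 mm (errors vs. the transient oracle
~0.6 % and ~0.05 %) and checks that the full gland peak moves < 3 % when
the spacing is halved.

With Table defaults the model predicts a peak around 48.6 °C after 60 s,
crossing 42 °C within a few seconds of field onset — comfortably past the
TRPV1 threshold, which is the design claim the acceptance script recomputes.

# SLP calorimetry

`estimate_slope()` fits an ordinary least-squares line to the first 10 s
(configurable) after field-on and subtracts the drift slope fitted to the
10 s before field-on. `slp_from_slope()` converts via
$\mathrm{SLP} = C_{sol} m_{sol} \dot T / m_{Fe}$. Extrapolation between
AMF conditions uses linear-response scaling
$\mathrm{SLP} \propto f H_0^2$ (`extrapolate_lrt()`); this is an explicit
modeling substitute for a full dynamic-hysteresis treatment and is flagged
as an extrapolation in its output — it is only trustworthy while the
particles remain in the linear regime, which holds for the 13–15 kA/m,
515–624 kHz conditions of interest. At those conditions an 880 W/g bench
measurement extrapolates to ~800 W/g in vivo, clearing the 600 W/g design
bound the thermal model assumes.

# Statistical machinery

* **Gamma GLM, identity link** (`fit_gamma_glm_identity()`): used to compare
  stimulation-window heart-rate AUCs, which are sums of positive
  baseline-scaled samples and empirically gamma-shaped. Fitting delegates
  to base R's IRLS (`glm.fit`); dispersion is the Pearson estimate and
  coefficient tests are Wald t tests. On a saturated group design the
  score equations reduce to group sample means, which the tests exploit as
  an exact oracle.
* **Beta regression** (`fit_beta_regression()`): joint MLE of logit-link
  mean coefficients and a common precision φ, written in-package. The
  optimizer is a damped Newton ascent (ridged-Cholesky Hessian repair,
  step halving) with an analytic gradient, started deterministically from
  least squares on the logit-transformed response; the log-likelihood
  trace is therefore monotone and is stored on the fit. Standard errors
  come from the observed information. Convergence tolerance is 1e-9 on
  the log-likelihood with a gradient-norm check, max 200 iterations.
* **Beta MLE and tail rule** (`fit_beta_mle()`, `tail_prob()`): shape
  parameters via `fitdistrplus`; the outlier rule excludes a sample when
  `min(F(x), 1 - F(x))` under the fitted distribution falls below 0.0005
  ("extremely unlikely" in either direction; one-sided variants are a
  flag away).
* **t tests** (`t_test()`): wraps `stats::t.test`, recording the variant.
  The serum log-ratio comparison defaults to the pooled variant
  (df $n_1 + n_2 - 2$); the behavioral endpoint comparison defaults to
  Welch. Published df in this literature do not always pin the variant
  down, so every result carries its variant explicitly.
* **Cullen–Frey summary** (`cullen_frey()`): unbiased sample skewness and
  kurtosis (matching `fitdistrplus::descdist`, against which the tests
  cross-check), a bootstrap cloud of the pair, and distances to the
  normal/uniform/exponential/logistic points and the gamma and lognormal
  loci — the standard pre-fitting diagnostic for choosing gamma, beta and
  lognormal models in this pipeline.

# Pipeline conventions

**Heart rate.** Sessions are laid out 0–300 s pre-stimulation, 300–360 s
stimulation, ≥ 60 s post, sampled at 1 Hz (both configurable). Pulse-ox
dropouts are imputed by the fixed-interval smoother of a maximum-likelihood
local-level state-space model (`StructTS` + `tsSmooth`); traces with > 50 %
missing or no observation in the first/last 10 s are rejected rather than
imputed. Each trace is divided by its mean pre-stimulation rate, day-1/2
sessions are averaged pointwise, and the AUC is the plain sum over
300 ≤ t ≤ 360 **inclusive** — 61 samples at 1 Hz; the inclusive convention
is fixed so the statistic is bit-stable.

**Serum hormones.** Each plate is calibrated with a four-parameter
logistic curve $y = d + (a - d)/(1 + (x/c)^b)$ (the ELISA standard) fitted
by Levenberg–Marquardt; inversion is algebraic and ODs at or beyond an
asymptote are flagged, never clipped. Baseline screening fits a beta
distribution per hormone to pre-stimulation values mapped into (0,1) by
dividing by 1.05 × the observed maximum (the mapping is recorded in the
output). Hormone values are averaged across the two collection days
*before* the post/pre ratio is formed, and conditions are compared by a
two-sample t test on log ratios.

**Freezing behavior.** Trials per phase: habituation 5, conditioning 7,
extinction 20, recall 3; freezing is the fraction of the 30 s tone spent
immobile. The normalization chain per rat and phase is: min–max
normalization; division by the rat's baseline (mean of normalized
habituation trials 3–5, floored at 0.05 to keep the scaling bounded);
re-clipping into [0,1] (clip counts reported); centered moving average of
window 3 with shrunk end windows; and boundary compression
$(y(n-1) + 0.5)/n$ so beta regression sees the open interval. A flat phase
(max = min) maps to constant 0.5 and is flagged. Non-conditioners are
flagged automatically: a rat conditioned iff its mean raw freezing on the
last 3 conditioning trials exceeds its habituation mean by ≥ 0.10 (the
threshold is configurable; ties count as conditioned). The regression
design is trial (numeric, restarting at 1 per phase, uncentered), phase
(categorical, habituation reference), treatment (control reference), with
all 2- and 3-way interactions. The endpoint analysis averages extinction
trials 18–20 per rat and compares conditions with a Welch t test.

# The synthetic cohort

`gen_cohort()` draws a full cohort (default 14 rats per condition, a
28-animal study) from one seed; identical seeds give byte-identical files.
The generative families are the ones the analyses assume:

* heart rate: Gaussian baseline (380 ± 20 bpm) plus, in active rats, a
  logistic rise during stimulation (mean fraction 0.10, per-rat SD 0.04)
  that decays after field-off; on post-conditioning day 4 the rise is
  multiplied by a blunting factor (default 0 — fully blunted, matching the
  observed near-zero post-conditioning condition effect); white noise
  (5 bpm), a slow random-walk wander (0.4 bpm/√s) emulating real
  physiologic drift, and 10 % missing samples;
* hormones: log-normal baselines (meanlog log 100, sdlog 0.4) with
  multiplicative post/pre effects (active 0.7, control 1.0) and log-normal
  ratio noise (sdlog 0.3) — post-conditioning suppression in active rats;
* freezing: acquisition $f_{max}(1 - e^{-k t})$ ($k = 0.6$,
  $f_{max} = 0.8$), extinction $f_{end} + (f_{start} - f_{end}) e^{-\lambda t}$
  ($\lambda = 0.15$, treatment modifier 1.0 = no behavioral effect, the
  observed outcome), beta observations with precision 20; non-acquirers
  (fraction 0.15) are generated *flat at habituation level* so the
  exclusion rule has unambiguous ground truth;
* histology: elliptical sections with particle blobs placed by per-zone
  probabilities (medulla 0.35 / ZR 0.35 / ZF 0.30 / ZG 0 — the observed
  deposition pattern) and clipped to their zone's elliptical annulus, again
  for unambiguous ground truth;
* calorimetry: drift-free baseline plus linear heating at the slope implied
  by a true SLP of 880 W/g, with 0.05 K sensor noise.

What the generator does *not* emulate: within-trial autocorrelation or
rat-level random effects in freezing beyond the curve family; circadian or
assay-plate structure in hormones; heart-rate artifacts other than missing
samples; realistic histology staining. Passing tests therefore demonstrate
that the pipeline recovers what it assumes, not that real data satisfy
those assumptions.

# Statistical caveats and known limitations

* **Normalization-induced dependence.** Min–max normalization, baseline
  scaling and smoothing are all *per-rat* transformations: they couple
  observations within a rat, while the beta-regression Wald tests treat
  rows as independent. Treatment-effect p-values computed after the full
  chain are therefore anticonservative (smoothing alone correlates
  neighboring trials by construction). The package's calibration checks
  run the estimator on independent observations, where its type-I error is
  nominal; p-values from chained data should be read as descriptive. A
  mixed model would be the principled fix but is out of scope.
* **Outlier-filter power.** Because the beta distribution is fitted to
  *all* baseline values including a prospective outlier, the fit adapts to
  moderate outliers (MLE contamination) and the 0.0005 tail rule has low
  power against a single sample that is merely "very unlikely" at n ≈ 20.
  Only far-tail values are reliably removed; the tests plant accordingly.
* **Linear trial-slope summaries of exponential decay.** The
  trial × treatment interaction measures a *linear* slope difference. When
  extinction curves floor out inside the 20-trial window, a faster-decaying
  group spends most of the window flat and the linear summary can reverse
  sign. Interaction signs are informative only in the non-floored regime.
* **Design-check scope.** The thermal model verifies a design bound, not a
  patient-specific prediction: injection coordinates, shell thickness and
  the outside medium are idealized, and MNP-scale heating physics is
  intentionally out of scope (sources are bulk power densities).
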