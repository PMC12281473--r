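---
title: "Quantitative TOLD oximetry: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative TOLD oximetry: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toldmri)
```

## The measurement

Molecular O2 carries two unpaired electrons and acts as a weak
paramagnetic contrast agent: raising the dissolved O2 concentration in
a tissue shortens its longitudinal relaxation time T1. Two consequences
are exploited here. First, the relaxation *rate* R1 = 1/T1 grows
linearly with pO2, with a phase-specific slope r1 (the relaxivity), so
R1 shifts measured between two breathing gases can be converted into
oxygen shifts. Second, on a T1-weighted sequence the signal intensity
rises as T1 shortens, so a time series recorded across a gas switch
traces the wash-in and wash-out of tissue oxygen in real time — the
tissue oxygen level-dependent (TOLD) signal. Unlike the T2\*-based BOLD
effect, which reflects the deoxy-/oxyhemoglobin balance of the blood
pool, the TOLD response reports dissolved O2 in the tissue itself; in
brain parenchyma, which is essentially free of heme iron, it is
positive and approximately linear in pO2.

`toldmri` implements the full chain from raw acquisitions to
quantitative oxygenation and O2 consumption measures, with a synthetic
scanner stand-in so that every stage can be validated against known
ground truth.

## Signal models

### Saturation-recovery T1 mapping

A variable-TR spin-echo series samples the recovery curve

$$M(\mathrm{TR}) = M_0\,\bigl(1 - e^{-\mathrm{TR}/T_1}\bigr),$$

by default at the 12 repetition times 15000, 8000, 5500, 4000, 3000,
2000, 1600, 1200, 800, 500, 200, 100 ms (`default_tr_s()`). Echo-time
and flip-angle attenuation are constant across TRs and are absorbed
into $M_0$. `fit_t1()` fits the two parameters per pixel by variable
projection: for any candidate $T_1$ the optimal $M_0$ is a linear
least-squares solve, so the problem reduces to a one-dimensional search
over $T_1$, handled by a coarse log-spaced scan (80 points over
0.01–20 s) followed by golden-section refinement. This is robust — no
starting-value failures, no divergence — and recovers noiseless inputs
to better than $10^{-6}$ relative error.

Two modelling switches deserve note:

- **Additive offset.** Whether magnitude data should carry a constant
  offset term is not determinable from the protocol alone; with a
  longest TR of 15 s (far above any brain T1) the offset is barely
  identifiable and both variants reproduce the tabulated phantom T1
  values at realistic SNR. The two-parameter model is therefore the
  default and a three-parameter `offset = TRUE` variant is available.
- **Invalid-pixel policy.** Degenerate pixels (constant signal, fewer
  than three distinct TRs, non-convergence) are *flagged*, not raised:
  `fit_t1_map()` returns a `scalar_map` with a validity mask, and all
  ROI statistics use valid pixels only. This avoids NaN-poisoning of
  downstream means while keeping the failure count visible.

### Relaxivity calibration

`fit_relaxivity()` is an ordinary least-squares regression of phantom
R1 on the pO2 of the equilibrating gas. pO2 follows the dry-gas
convention `gas_po2(fraction, 760)` — N2 0, air 159.6, carbogen 722,
100% O2 760 mmHg — with no water-vapour correction, because that
convention reproduces the published corn-oil slope from the tabulated
R1 means. The packaged calibration table (`phantom_calibration()`)
gives, at 7 T and ~30 °C:

```{r}
oil <- phantom_calibration("corn_oil")
coef(fit_relaxivity(oil$r1_mean, gas_po2(oil$o2_fraction)))["slope"]
water <- phantom_calibration("water")
coef(fit_relaxivity(water$r1_mean, gas_po2(water$o2_fraction)))["slope"]
```

The corn-oil slope agrees with the published 8.20 × 10⁻⁴ mmHg⁻¹s⁻¹ to
0.3%. The water slope computed from the *rounded* tabulated means is
1.65 × 10⁻⁴, about 3.5% below the published 1.71 × 10⁻⁴, which was
evidently computed from unrounded triplicate data; tests and default
constants treat the published value as authoritative and allow a 5%
band on the rounded-input recomputation. The same limitation applies to
the water line evaluated at 40 mmHg (0.224 from rounded inputs versus
the published 0.220), which is why the two-compartment defaults below
are the published constants rather than on-the-fly regression outputs.

### Henry's-law unit conversion

Relaxivities are used in two unit systems: per mmHg of O2 partial
pressure and per mM of dissolved O2. `henry_constant()` holds the
proportionality between the two; its default, **690 mmHg per mM at
30 °C**, is the factor implied by the published water pair
(0.118 / 1.71 × 10⁻⁴). EPR oximetry showed O2 solubility in water and
corn oil to be equivalent, so one factor serves both phases (the
corn-oil pair implies 694, a 0.6% difference that bounds the error of
this choice). The constant is configurable; no temperature-dependent
solubility model is attempted.

### Two-compartment oximetry

Tissue relaxation in a voxel is a sum of components. The model adopted
here keeps the two dominant ones — an aqueous phase (proxy: water) and
a lipidic phase (proxy: corn oil) —

$$R_{1T} = V_A R_{1A} + V_L R_{1L}, \qquad V_A + V_L = 1,$$

with the phase rates evaluated at a physiological reference pO2 of
40 mmHg: $R_{1A} = 0.220$ and $R_{1L} = 1.546\ \mathrm{s^{-1}}$ by
default. `solve_fractions()` inverts this to
$V_A = (R_{1L} - R_{1T})/(R_{1L} - R_{1A})$; in strict mode (default) a
tissue rate outside the reference interval is an error (per-pixel maps
downgrade the failure to an invalid pixel), and a clamping mode exists
for exploratory use. A gas-challenge rate shift then converts to an
oxygen shift through the fraction-weighted sum of per-phase quotients:

$$\Delta O_2 = V_A\,\frac{\Delta R_1}{r_{1A}} + V_L\,\frac{\Delta R_1}{r_{1L}}.$$

This reading of the conversion — apportioning the measured ΔR1 to each
phase by volume and converting each part with its own relaxivity — is
a genuine choice: the alternative reading
$\Delta R_1 / (V_A r_{1A} + V_L r_{1L})$ is also dimensionally valid
but does not reproduce the published regional oxygen shifts (it gives
~0.18 rather than 0.28 mmol/L for the cortex under carbogen), so the
weighted-quotient form is implemented. `estimate_delta_o2()` evaluates
it twice, with per-mM and per-mmHg relaxivities, and returns both; the
ratio of the two outputs is always bracketed by the per-phase Henry
factors (690–694), a property the test suite checks.

Worked end-to-end with the published tissue constants:

```{r}
fr <- solve_fractions(c(cortex = 0.54, ventricles = 0.38, caudate = 0.59))
round(fr$va, 2)
s <- estimate_delta_o2(0.041, solve_fractions(0.54))
c(mM = round(s$delta_o2_mM, 2), mmHg = round(s$delta_o2_mmHg))
```

One rounding subtlety: published results tables carry the *rounded*
fractions (e.g. caudate $V_A = 0.72$) into the ΔO2 arithmetic. At the
printed precision this matters only for the caudate mmHg figure
(168 with $V_A = 0.72$, 169 with the unrounded 0.721);
`as_fractions()` exists so a printed ratio can be reused exactly.

### TOLD kinetics

The time series is reduced to the percent enhancement

$$\Delta M\% = 100\,\frac{M - \bar M_{\mathrm{base}}}{\bar M_{\mathrm{base}}},$$

with $\bar M_{\mathrm{base}}$ the mean over the baseline window —
by default every frame of the initial air period. For ROI curves the
ROI-mean intensity is formed per frame *first* and the enhancement
computed from it, matching time-course plots whose error bars show the
per-frame spread within the ROI; the per-pixel spread is returned
alongside as `sd`. The curve is exactly invariant under global
intensity scaling, and its baseline mean is zero by construction.

The rising phase is fitted (`fit_oxygenation()`) with the wash-in model

$$S(t) = S_{\max}\,\bigl(1 - e^{-(t-t_{\mathrm{on}})/T_{\mathrm{ox}}}\bigr),$$

where $T_{\mathrm{ox}}$ is the time to reach $63.2\%$
($1 - e^{-1}$) of the plateau and $k_{\mathrm{ox}} = 1/T_{\mathrm{ox}}$
is the oxygenation rate. The fit is bounded nonlinear least squares
(`nls`, port algorithm; $S_{\max} \in (-100, 1000)\%$,
$T_{\mathrm{ox}} \in (0.01, 100)$ min), initialised from the window
extremum and the first 63.2% crossing; negative-going challenges
(e.g. a switch to N2) initialise from the minimum and fit a negative
plateau. The fit window defaults to the full challenge interval — the
published protocol does not state whether the fit stopped at gas-off,
and for a wash-in that has plateaued the distinction is immaterial.
Non-convergent or flat windows return `converged = FALSE` with
parameters flagged rather than erroring.

The decaying phase after gas-off is summarised (`fit_consumption()`)
by the O2 consumption rate $k_{\mathrm{oc}}$: the negative
least-squares slope of $\ln \Delta M\%$ versus time over the first
`n_points = 5` frames strictly after the switch (matching the
published five-point practice; configurable). The decay is fitted on
raw ΔM% — the signal is taken to return to the pre-challenge baseline,
so no final-offset subtraction is applied. Non-positive values inside
the window have no logarithm; they are excluded with a message, and
fewer than two usable points is an error. Frame timestamps follow the
frame-start convention, gas-switch times come from the schedule (never
inferred from the data), and the frame containing a switch belongs to
the incoming gas (left-closed intervals).

## The synthetic generator

`simulate_variable_tr()` and `simulate_told()` generate data from the
exact forward models above, plus noise, for any `phantom_scene`. The
stated world of the defaults:

- **Brain phantom** (`brain_phantom()`): 64 × 64 single slice, three
  disc ROIs with the measured 7 T per-gas T1 group means (cortex
  1.85/1.72/1.73 s under air/carbogen/O2; ventricles 2.84/2.75/2.79 s;
  caudate 1.70/1.60/1.62 s), M0 = 100, and the carbogen-challenge
  kinetic group means (S_max 5.08/4.05/3.08%, T_ox 0.60/0.97/0.66 min).
  The consumption rate was published only for the cortex
  (1.55 min⁻¹); the phantom uses that value for all three regions.
- **Tube phantom** (`tube_phantom()`): water and corn-oil discs with
  the tabulated per-gas T1 means.
- **Gas paradigms**: the calibration/imaging sessions used 5 min air
  followed by 16 min of challenge gas; the kinetic session used
  5 min air / 5 min carbogen / 5 min air at 20-s frames (45 frames).
  Both are expressible as `gas_schedule` objects; the pipeline default
  is the kinetic paradigm.
- **TOLD trajectory**: rise per the wash-in model from each challenge
  onset; after each offset, exponential decay at $k_{\mathrm{oc}}$
  toward the pre-challenge baseline (asymptote 0%). The published
  curves return to baseline but do not state the asymptote; 0 is the
  natural reading and is what the generator implements. Multi-cycle
  schedules are supported by continuity (each interval starts from the
  level reached at its boundary), but no published data constrains
  repeated challenges.
- **Noise**: additive zero-mean Gaussian on the magnitude images with
  sd expressed as a fraction of M0, defaulting to 0 and typically
  exercised at 0.01–0.05. This is justified operationally — the
  experiments run far above the noise floor, where Rician noise is
  indistinguishable from Gaussian — and a Rician mode
  (`rician = TRUE`) exists for low-SNR exploration. No B0/B1
  inhomogeneity, no physiological noise, no sequence-level (Bloch)
  simulation: flip-angle and TE effects are constants absorbed in M0.

A green round-trip test therefore establishes that the estimators
invert the stated forward models at the stated noise levels — not that
they are robust to motion, partial-volume mixtures, B1 shading, or
physiological drift, none of which the generator emulates. Group means
from living animals (the in vivo tables) are measurements; they enter
the package only as fixture ground truths and worked-example constants
and are not claimed to be derivable from simulation.

## Numerical and interface choices

- Determinism: every stochastic generator takes a `seed`; identical
  scene + seed gives bit-identical arrays, and the pipeline writes
  byte-identical CSVs for identical configs.
- `t1_to_r1()` is its own inverse (unit-tagged reciprocal), so R1→T1
  conversion needs no second function; zero-valued pixels become
  invalid rather than infinite.
- Results CSVs print doubles with `%.17g` so they re-read exactly.
- NIfTI-1 I/O is implemented minimally in-package (float64 storage,
  gzip supported, scl_slope/inter honoured on read); acquisition
  metadata that the NIfTI header cannot carry — TR lists, frame
  intervals, gas schedules, ground truth — lives in a JSON sidecar,
  and a missing sidecar key is a schema error naming the key.
- The kinetic estimators are S3 model objects (`t1_fit`,
  `relaxivity_fit`, `kinetic_fit`) with `print`, `coef`, `predict`,
  `residuals`, and `plot` methods, so they compose with the usual R
  modelling workflow.

## Limitations

- Only the two-term specialisation of the multi-component relaxation
  sum is implemented; per-pixel multi-exponential fitting is out of
  scope.
- ΔO2 in mmHg is an *equivalent* (the shift the calibration lines
  translate the ΔR1 into), not a claim about physiological pO2; the
  package reports both unit forms without interpretation.
- $k_{\mathrm{oc}}$ is the operational semi-log decay slope, not a
  metabolic CMRO2 model; no hemodynamic modelling of the decay is
  attempted.
- Absolute pO2 maps are not produced — only challenge-induced shifts,
  as in the underlying experiments.
- Motion correction and DICOM conversion are assumed done upstream.
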