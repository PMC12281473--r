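# toldmri

Quantitative analysis of tissue oxygen level-dependent (TOLD) MRI for
gas-challenge experiments.

Dissolved molecular O2 is paramagnetic: raising tissue pO2 shortens T1,
increases the longitudinal relaxation rate R1 = 1/T1, and enhances the
T1-weighted signal. Unlike the blood-volume-confounded BOLD effect, this
TOLD response reports tissue oxygen directly, which makes it attractive
for planning radiotherapy of hypoxic tumours and for studying brain
oxygen metabolism in small animals. `toldmri` turns the raw acquisitions
of such an experiment — variable-TR image stacks and T1-weighted time
series recorded while the breathing gas is switched between air and a
hyperoxic gas (carbogen, 95% O2 + 5% CO2, or 100% O2) — into
quantitative oxygenation measures:

- **T1/R1 mapping.** Per-pixel least-squares fits of the
  saturation-recovery model `M(TR) = M0 (1 − e^(−TR/T1))` to a
  variable-TR series (default protocol: 12 TRs from 15 s down to
  100 ms), converted to R1 maps and gas-challenge shifts
  ΔR1 = R1(hyperoxia) − R1(air).
- **O2 relaxivity calibration.** Ordinary least squares of phantom R1 on
  dry-gas pO2 gives the relaxivity r1 (slope) of dissolved O2 in water
  and corn oil — proxies for the aqueous and lipidic phases of tissue —
  in mmHg⁻¹s⁻¹ and, through a Henry's-law factor, mM⁻¹s⁻¹.
- **Two-compartment oximetry.** Tissue relaxation is modelled as
  `R1T = VA·R1A + VL·R1L` with `VA + VL = 1`; solving at a reference
  pO2 of 40 mmHg yields the aqueous volume fraction
  `VA = (R1L − R1T)/(R1L − R1A)`, and the measured ΔR1 converts to a
  tissue O2 shift `ΔO2 = VA·(ΔR1/r1A) + VL·(ΔR1/r1L)` in both mmol/L
  and mmHg-equivalent units.
- **TOLD kinetics.** Time series reduce to percent-enhancement curves
  `ΔM% = 100 (M − M̄_base)/M̄_base`; the rising phase is fitted with
  `S(t) = S_max (1 − e^(−t/T_ox))` giving the oxygenation rate
  `k_ox = 1/T_ox` and plateau `S_max`, and the post-challenge decay
  gives the O2 consumption rate `k_oc` as the negative semi-log slope
  over (by default) five points.
- **Synthetic phantoms.** A generator with known ground truth (tube
  phantoms, a three-ROI mouse-brain scene, full TOLD time series under
  any gas schedule) stands in for the scanner, so every stage is
  testable offline.

Images are exchanged as NIfTI-1 (`.nii`/`.nii.gz`) with JSON sidecars
carrying TR lists, frame intervals, and gas schedules; tables are CSV.

## Worked example

The end-to-end pipeline on the noiseless synthetic brain phantom
(64 × 64, cortex / ventricles / caudate nucleus, with the measured 7 T
per-gas T1 means as ground truth):

```r
library(toldmri)
report <- run_pipeline(told_config(seed = 1))
report
#> <run_report> toldmri 0.1.0, seed 1, noise sigma 0
#>
#> Oximetry (per ROI):
#>         roi r1_baseline delta_r1     va      vl delta_o2_mM delta_o2_mmHg
#>      cortex      0.5405  0.04085 0.7583 0.24173     0.27989        193.21
#>  ventricles      0.3521  0.01152 0.9004 0.09963     0.08995         62.08
#>     caudate      0.5882  0.03676 0.7223 0.27770     0.24299        167.74
#>
#> TOLD kinetics (per ROI):
#>         roi s_max t_ox  k_ox k_oc converged
#>      cortex  5.08 0.60 1.667 1.55      TRUE
#>  ventricles  4.05 0.97 1.031 1.55      TRUE
#>     caudate  3.08 0.66 1.515 1.55      TRUE
```

Reading the cortex row: fitting T1 maps under air and carbogen gives a
baseline R1 of 0.54 s⁻¹ and a challenge-induced shift of 0.041 s⁻¹; the
two-compartment solve puts the cortical aqueous fraction at 0.76, and
the relaxivity conversion translates the ΔR1 into an oxygen increase of
about 0.28 mmol/L (≈ 193 mmHg equivalent). The kinetics table recovers
the generator's wash-in plateau (5.08%), rise time (0.60 min), and
consumption rate (1.55 min⁻¹) for the cortex.

Individual stages are available as plain functions returning classed
objects with the usual `print`/`coef`/`predict`/`residuals`/`plot`
methods:

```r
cal <- phantom_calibration("corn_oil")
fit <- fit_relaxivity(cal$r1_mean, gas_po2(cal$o2_fraction))
coef(fit)["slope"]      # 8.22e-4 mmHg^-1 s^-1
fr  <- solve_fractions(0.54)           # cortex under air -> VA = 0.76
estimate_delta_o2(0.041, fr)           # -> 0.28 mM, 194 mmHg
```

A thin command-line wrapper with `simulate`, `t1map`, `deltar1`,
`relaxivity`, `fractions`, `deltao2`, `toldfit`, and `run` subcommands
is installed at `inst/cli/toldmri.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the pipeline's headline quantities
from scratch — the three regional aqueous volume fractions, the five
tissue ΔO2 conversions, the corn-oil relaxivity regression, and the
kinetic parameters recovered from a freshly simulated noiseless
challenge — and writes them to a JSON file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/told-oximetry.Rmd` documents the signal models, the
two-compartment assumptions, the defaults and their provenance, what
the synthetic generator does and does not emulate, and known
limitations.
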