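# admittr

Admittance-based sensing of mixed electrolyte concentrations: a
simulation and estimation toolkit in R.

Electrolyte levels (Na⁺, K⁺, Cl⁻) in body fluids are a core vital sign
for point-of-care diagnostics and athlete monitoring. A cheap way to
measure them is an insulated coplanar electrode pair driven by a small AC
voltage: dissolved ions change the electrode–sample *admittance*
`Y = G + jB`, and a comparator-based differential amplifier with coherent
I/Q detection resolves even minute admittance changes. `admittr` models
this sensing chain end to end and implements the calibration/inversion
mathematics that turns measured responses back into the concentrations of
a two-salt (NaCl + KCl) mixture.

## What is inside

* **Equivalent circuit** — electrode polarization (series `Rp`, `Cp` per
  electrode) in series with the bulk sample (`Rs ∥ Cs`), reduced to the
  one-port admittance `Y_T = 1/(2 Z_p + Z_s)`:
  `circuit_params()`, `total_admittance()`, `admittance_to_GC()`.
* **Analog front end** — all-pass phase-shift trim
  `(jωR₂C − 1)/(jωR₂C + 1)`, differential amplifier
  `U_out = −[ΔY + Y₀(θ²/2 + jθ)]·U/Y_f`, waveform synthesis at 1 MHz and
  coherent I/Q demodulation: `ps_gain()`, `amplifier_output()`,
  `synthesize_waveform()`, `coherent_detect()`.
* **Calibration** — per frequency (5, 10 kHz) and channel
  (in-phase, quadrature), the response surface
  `V = α₀ + α₁x₁ + α₂x₁² + α₃x₂ + α₄x₂²` (`x₁` = NaCl mM, `x₂` = KCl mM),
  fitted by OLS with a Pearson-`R` diagnostic: `fit_response_surface()`,
  `fit_calibration()`, plus a shipped reference coefficient set
  (`reference_calibration()`).
* **Inversion** — closed-form linear initialization from the quadrature
  channels, then Gauss–Newton/Levenberg–Marquardt refinement of
  `(x₁, x₂)` against all four quadratic surfaces, with conditioning
  diagnostics and a global lattice safeguard:
  `estimate_concentrations()`, `linear_init()`, `newton_refine()`,
  `single_channel_roots()`.
* **Synthetic data** — measurement campaigns with the structure of the
  0.5–4 mM mixed-solution experiments (grid × 2 frequencies × 2 channels
  × replicates, deionized-water reference, Gaussian noise), both at the
  phasor level and through the full waveform chain:
  `generator_config()`, `simulate_measurements()`, `simulate_waveforms()`.
* **Workflows** — `run_simulate()` / `run_fit()` / `run_estimate()` with
  CSV/JSON round-tripping and provenance logging, plus a thin CLI at
  `inst/cli/admittr` (`simulate`, `fit`, `estimate` subcommands).

## Worked example

Simulate a calibration campaign, fit the surfaces, and estimate an
unknown mixture from a single noisy measurement:

```r
library(admittr)

cfg <- generator_config(seed = 1)        # 0-4 mM grid, 5 replicates, sigma = 0.02
df  <- simulate_measurements(cfg)        # 720 records
cal <- fit_calibration(df)
print(cal)
#> Admittance calibration: 5000, 10000 Hz x {in_phase, quadrature}
#>   quadratic   5000 Hz in_phase   [0.683, 1.609, -0.121, 1.817, -0.117]  R = 1.000
#>   quadratic  10000 Hz in_phase   [0.369, 1.274, -0.083, 1.501, -0.089]  R = 1.000
#>   quadratic   5000 Hz quadrature [-0.166, 0.429, 0.018, 0.518, 0.026]  R = 1.000
#>   quadratic  10000 Hz quadrature [-0.079, 0.239, 0.019, 0.309, 0.023]  R = 1.000
#>   linear      5000 Hz in_phase   [1.139, 1.127, 0.000, 1.351, 0.000]  R = 0.995
#>   linear     10000 Hz in_phase   [0.697, 0.944, 0.000, 1.149, 0.000]  R = 0.996
#>   linear      5000 Hz quadrature [-0.249, 0.500, 0.000, 0.621, 0.000]  R = 0.999
#>   linear     10000 Hz quadrature [-0.159, 0.314, 0.000, 0.400, 0.000]  R = 0.998

# a fresh noisy measurement of a 2 mM NaCl + 2 mM KCl mixture
yy  <- simulate_measurements(generator_config(grid = 2, replicates = 1, seed = 7))
obs <- yy[yy$x1_mM == 2 & yy$x2_mM == 2, c("freq_hz", "channel", "response_v")]
estimate_concentrations(cal, obs)
#> Mixed-electrolyte concentration estimate
#>   NaCl: 1.941 mM   KCl: 2.043 mM
#>   init (8, 0) mM -> 38 iteration(s), converged, residual 0.03
#>   warning: ill-conditioned linear initialization (augmented solve used)
#>   refinement mode: quadratic
```

Reading the output: the fitted coefficient table mirrors the shipped
reference surfaces (each row is `[α₀, α₁, α₂, α₃, α₄]` with its fit
correlation `R`); the estimate recovers the 2 + 2 mM mixture to within a
few hundredths of a mM here, while the audit line shows the closed-form
initialization was ill-conditioned (the quadrature surfaces respond
almost identically to Na⁺ and K⁺ — see the vignette's identifiability
section) and the refined solution is what carries the accuracy. The
residual 0.03 is the expected noise floor for four channels at
σ = 0.02.

The same workflow from a shell:

```sh
Rscript inst/cli/admittr simulate --seed 1 --out data.csv
Rscript inst/cli/admittr fit --data data.csv --out calibration.json
Rscript inst/cli/admittr estimate --calibration calibration.json \
        --data data.csv --out estimates.json
```

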