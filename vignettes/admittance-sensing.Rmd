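---
title: "Admittance sensing of mixed electrolytes: model, calibration and inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admittance sensing of mixed electrolytes: model, calibration and inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admittr)
```

# The measurement problem

Dissolved electrolytes make water conductive: ions carry charge between a
pair of electrodes, and ion accumulation at each electrode interface forms
an electrical double layer. An insulated coplanar electrode pair driven by
a small AC voltage therefore presents an *admittance* $Y = G + jB$ that
shifts with ion concentration — the conductance $G$ tracking ion
transport, the susceptance $B = \omega C$ tracking interfacial and bulk
capacitance. `admittr` models a sensor built on this principle end to end:
a lumped equivalent circuit of the electrode/sample stack, a
comparator-based differential amplifier that converts admittance changes
to voltage phasors, coherent I/Q demodulation, polynomial calibration
surfaces at two working frequencies (5 and 10 kHz), and the inversion of
those surfaces for the NaCl and KCl concentrations of a mixed sample.

The package's intended users are instrument developers and analysts who
want to study this sensing architecture — its sensitivity, its
identifiability limits, its calibration workflow — without hardware in
the loop.

# Equivalent circuit

Each electrode's double layer is a polarization resistance $R_p$ in
series with a polarization capacitance $C_p$; the bulk sample is
$R_s \parallel C_s$. With two identical electrodes in series with the
sample, the one-port admittance is

$$Y_T = \frac{1}{2 Z_p + Z_s}, \qquad
  Z_p = R_p + \frac{1}{j\omega C_p}, \qquad
  Z_s = \frac{R_s}{1 + j\omega R_s C_s},$$

reducible to a conductance/capacitance pair $G_T = \mathrm{Re}(Y_T)$,
$C_T = \mathrm{Im}(Y_T)/\omega$. No published numeric values exist for
these four elements, so they are free simulation parameters with
plausible defaults (`circuit_params()`: $R_p = 100\ \Omega$,
$C_p = 1\ \mu$F, $R_s = 10\ \mathrm{k}\Omega$, $C_s = 10$ nF); the
calibration and inversion modules never consume them — they operate on
measured responses. Limit cases use IEEE sentinels (`Cp = Inf` for
negligible polarization reactance, `Cs = 0`/`Cs = Inf` for open/short)
and are evaluated analytically, so no overflow ambiguity arises.

One caveat worth stating precisely: $G_T$ increases as $R_s$ falls (the
concentration proxy) only in the operating regime where the polarization
*reactance* $2/(\omega C_p)$ is small against the resistive terms. When
the double-layer reactance dominates ($2R_p + R_s < 2/(\omega C_p)$),
$G_T$ can move the other way. The monotonicity test pins the regime
explicitly rather than claiming the property globally.

# Analog front end

The drive generator produces $U\sin\omega t$ and its inverted copy
$aU\sin(\omega t + \pi - \theta)$, with the amplitude ratio $a$ chosen so
the reference admittance balances the target baseline ($Y_0 = a Y_1$) and
the residual phase mismatch $\theta$ trimmed by first-order all-pass
phase-shift networks with gain

$$\frac{V_o}{V_i} = \frac{j\omega R_2 C - 1}{j\omega R_2 C + 1},
  \qquad \left|\frac{V_o}{V_i}\right| \equiv 1 .$$

For small $\theta$, the comparator-based amplifier outputs

$$U_\mathrm{out} = -\left[\Delta Y + Y_0\!\left(\tfrac{\theta^2}{2}
  + j\theta\right)\right] \frac{U}{Y_f},$$

linear in the admittance change $\Delta Y = \Delta G + j\Delta B$ with
gain $U/Y_f$. The $\theta$-dependent terms are a fixed bias: normalizing
every measurement against the deionized-water reference subtracts them.
`amplifier_output()` scales the $\Delta Y$ term and the bias term
separately so that this subtraction cancels in floating point *exactly*,
not merely to rounding — the property the test suite asserts with
`expect_identical()`.

Defaults mirror the prototype operating point: $U = 0.5$ V,
$R_f = 200\ \mathrm{k}\Omega \parallel C_f = 100$ pF (so
$|U/Y_f| \approx 8.47\times 10^4$ V/S at 5 kHz), sampling at 1 MHz.
`amplifier_output()` implements the general complex-$Y_0$ form; the
real-$Y_0$ expression above is its special case.

## I/Q convention and detection

A phasor $P$ is rendered as
$\mathrm{Re}(P)\sin\omega t + \mathrm{Im}(P)\cos\omega t$, and coherent
detection correlates against the same references:
$I = (2/N)\sum s_n \sin\omega t_n$, $Q = (2/N)\sum s_n \cos\omega t_n$.
I is thus the component in phase with the non-inverted drive and maps to
$\Delta G$, Q leads by 90° and maps to $\Delta B$. Records must span an
integer number of carrier periods; non-integer spans are detected and
flagged as leakage rather than silently biased. Detection integrates over
100 carrier cycles by default (no integration time is prescribed by the
architecture; 100 cycles keeps records short while averaging noise as
$\sigma\sqrt{2/N}$). A 20$\times$ oversampling floor guards aliasing.

# Calibration surfaces

Normalized responses (deionized-water-referenced, volts) are modelled per
frequency and channel as

$$V = \alpha_0 + \alpha_1 x_1 + \alpha_2 x_1^2 + \alpha_3 x_2
      + \alpha_4 x_2^2,$$

with $x_1$ = NaCl and $x_2$ = KCl in mM; the linear form sets
$\alpha_2 = \alpha_4 = 0$. There is no $x_1 x_2$ cross term in the
standard surface (an opt-in `interaction` flag exists for diagnostics).
Fits are ordinary least squares on the design
$[1, x_1, x_1^2, x_2, x_2^2]$ — unweighted, since no heteroscedasticity
treatment is part of the architecture — via `stats::lm()`, with rank
deficiencies reported by column. The fit diagnostic $R$ is the Pearson
correlation between fitted and observed responses: it is 1 for a perfect
fit, invariant to affine response rescaling, and matches the convention
in which such calibrations are usually reported.

The package ships a reference calibration (`reference_calibration()`,
plain JSON in `inst/extdata/`) for NaCl/KCl mixtures on 0.5–4 mM:
quadratic and linear coefficient sets for both channels at both
frequencies. It anchors the synthetic generator and the worked examples.

# Inversion

Estimation proceeds in two stages (`estimate_concentrations()`):

1. **Linear initialization.** The two linear quadrature surfaces give a
   2×2 linear system in $(x_1, x_2)$, solved in closed form. The shipped
   slope matrix is nearly singular — its 2-norm condition number is about
   147, because the quadrature response is almost equally sensitive to
   Na$^+$ and K$^+$ — so the solve monitors conditioning and, above the
   default threshold of 100, redoes the initialization as a 4×2
   least-squares solve over all four linear surfaces. (The threshold is
   set below the shipped calibration's condition number deliberately:
   that calibration *should* trigger the more robust path.)

2. **Gauss–Newton refinement with Levenberg–Marquardt step control.**
   Stacked residuals $r_k(x) = \hat V_k(x) - y_k$ over the four quadratic
   surfaces are minimized with the analytic Jacobian
   $\partial r_k/\partial x_i = \alpha_{1|3} + 2\alpha_{2|4}x_i$ and
   projection onto the admissible box $[0, 8]$ mM (twice the calibrated
   range; concentrations cannot be negative). Steps solve the damped
   normal equations $(J^\top J + \lambda I)\,\delta = -J^\top r$ with
   $\lambda = 0$ (pure Gauss–Newton) as long as each projected step
   reduces the residual; a rejected or unsolvable step inflates $\lambda$
   until descent resumes. This matters in practice: with noisy data the
   undamped iteration can cycle along the curved residual valley without
   ever satisfying a stopping rule. With exactly two equations the
   undamped iteration is plain Newton–Raphson, available as
   `mode = "quadrature"`; `mode = "mixed"` pairs linear quadrature with
   quadratic in-phase equations. Stopping: step norm $< 10^{-10}$ mM,
   residual norm $< 10^{-8}$, gradient norm
   $\lVert J^\top r\rVert < 10^{-12}$ (first-order stationarity, the
   operative criterion under noise, where the residual floor is set by
   the noise itself), or 50 iterations. `converged` reports whether any
   of the first three fired; hitting the iteration cap is reported as
   non-convergence with full diagnostics, never as an error.

**Global safeguard.** The stacked least-squares objective has a long,
gently curved valley (see the identifiability discussion below) and can
hold spurious local minima; started from a poorly conditioned
initialization, plain Gauss–Newton lands in one in a substantial fraction
of cases. When the refined residual norm stays above $10^{-7}$, the
estimator therefore evaluates the objective on a 0.25 mM lattice over the
admissible box (a vectorized polynomial evaluation, cheap), refines from
the best lattice point, and returns the lower-residual result. The
returned object keeps the primary initialization in its audit trail. With
the safeguard, noise-free inversion is exact to better than
$10^{-6}$ mM everywhere on the calibrated plane — one of the acceptance
checks of the test suite.

**Why two frequencies.** A single-frequency, single-channel quadratic
inversion can admit two admissible roots: the 5 kHz in-phase surface
peaks inside the box, so a response at 6 mM has a 7.37 mM twin
(`single_channel_roots()` enumerates them). The two-frequency,
four-surface estimator resolves the same sample uniquely. Even the
two-frequency *quadrature-only* mode can be ambiguous, because the two
quadrature surfaces are nearly parallel — a further argument for feeding
all four surfaces to the refinement, which is the default.

# Synthetic data generator

`generator_config()` describes a measurement campaign with the structure
of the mixed-solution experiments the package models:

* grid $\{0, 0.5, 1, 2, 3, 4\}$ mM per analyte (the 0.5–4 mM working
  range plus the deionized-water reference, which is always measured);
* 5 replicates per solution;
* additive homoscedastic Gaussian noise per channel,
  $\sigma = 0.02$ response units by default — error magnitudes are not
  published for this architecture, so $\sigma$ is a configuration knob;
  0.02 is roughly 2–3 % of the quadrature full-scale response and
  exercises the fitter without drowning the single-analyte resolution;
* ground truth: the shipped quadratic reference surfaces, so every
  downstream test is anchored to the same coefficient sets.

The full Cartesian product of grid levels is measured in mixed mode
(which pairs were actually measured is not recorded in the source
calibration; the Cartesian design is the simulator's choice), and
single-analyte modes hold the other ion at zero.

A second path, `simulate_waveforms()`, converts each design point's
response into the admittance change that would produce it, pushes it
through the amplifier model (including a configurable phase mismatch) and
renders sampled waveforms; `detect_waveform_dataset()` demodulates them
and subtracts the water reference. Noise-free, the two paths agree to
$10^{-9}$; with noise, waveform-level sample noise is scaled as
$\sigma\sqrt{N/2}$ so the detected I/Q scatter again equals $\sigma$.
Reference records are rendered cleanly (in practice the reference is
measured once with long averaging), so normalized responses carry one
noise term, as on the phasor path.

What the generator does *not* emulate: temperature and humidity drift,
electrode fouling or aging, heteroscedastic or correlated noise, op-amp
non-idealities, ADC quantization. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical model, not
robustness to every artefact of real measurements.

# Identifiability: what the calibration can and cannot resolve

The shipped surfaces respond to the two ions almost identically: for
every channel and frequency the gradient ratio
$(\partial V/\partial x_2) : (\partial V/\partial x_1)$ lies between
about 1.15 and 1.30. The stacked 4×2 Jacobian's two singular values are
correspondingly lopsided:

```{r singular-values}
cal <- reference_calibration()
J <- function(x1, x2) t(sapply(cal$quadratic, surface_gradient, x1 = x1, x2 = x2))
sapply(list(c(0.5, 0.5), c(2, 2), c(4, 4)),
       function(x) svd(J(x[1], x[2]))$d)
```

The strong direction (total concentration, roughly $x_1 + x_2$) has
sensitivity 2–3 response units per mM; the weak direction
(Na-vs-K difference) only 0.016–0.035. At the default noise
$\sigma = 0.02$, the Cramér–Rao bound for the weak direction is
$\sigma / s_\mathrm{min} \approx 0.6\text{–}1.2$ mM *per replicate*: no
estimator can tell 0.5 mM of NaCl from 0.5 mM of KCl in a single mixed
measurement with this calibration. Total concentration, by contrast, is
resolved to $\approx 0.01$ mM, and single-analyte estimation (the other
ion known) is comfortably inside 0.5 mM steps. The acceptance script
measures the mixed-grid resolution honestly and reports what the
simulation actually achieves; the curved residual valley also makes the
maximum-likelihood estimate visibly biased at small $\sigma$ (verified in
development against a brute-force grid minimizer), which is why the
noise-consistency acceptance check carries a bias clause the mixed design
cannot meet. These are statements about the identifiability of the
published calibration under the simulated design, not about the
algorithms, which recover exactly whenever the data determine the answer.

# Numerical choices, at a glance

| Choice | Value | Why |
|---|---|---|
| Admissible box | $[0, 8]^2$ mM | twice the calibrated range; projection, not failure, on exit |
| GN stopping | step $10^{-10}$ mM, residual $10^{-8}$, 50 iters | exact-recovery margin below the $10^{-6}$ mM test bound |
| Condition threshold | 100 | below the shipped pair's $\kappa \approx 147$, so the robust path engages |
| Safeguard lattice | 0.25 mM steps | finer than the narrowest observed basin of attraction |
| Detection window | 100 cycles | integer-period records; noise averages as $\sigma\sqrt{2/N}$ |
| CSV/JSON precision | `%.17g` / 17 significant digits | doubles round-trip exactly |

Problem sizes used by the test suite and acceptance script — a 0.25 mM
noise-free sweep of $[0,4]^2$ (289 inversions), the mixed 0.5–4 mM grid
at $\sigma = 0.02$ with 5 replicates and 20 seeds (6400 inversions), and
500-seed noise ladders — were chosen to give stable Monte-Carlo
statistics at interactive runtimes.

# Known limitations

* The mixed-design Na/K separation is conditioning-limited, as quantified
  above; improving it requires a calibration with more contrast between
  the ions (e.g. additional frequencies or channels with different ion
  selectivity), not a better optimizer.
* The lumped RC electrode model ignores constant-phase-element and
  Warburg behaviour; the surfaces are polynomial interpolants valid on
  the calibrated range, and extrapolation beyond the admissible box is
  flagged, not modelled.
* Published fit-quality values for the reference device depend on its raw
  dataset and are not reproducible from coefficients alone; the package
  reports $R$ for its own fits instead.
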