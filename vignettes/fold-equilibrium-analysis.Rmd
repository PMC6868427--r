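---
title: "Quantifying a two-state RNA fold equilibrium: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a two-state RNA fold equilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnafoldeq)
```

This vignette explains the models behind each stage of the package, the
assumptions they rest on, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where more than one defensible option existed.

## The two-site longitudinal exchange model

An RNA that slowly interconverts between two secondary structures — here a
1nt-bulge fold (1B, state A) and a 2nt-bulge fold (2B, state B) — shows two
resolved resonances per reporter nucleus. During a mixing period the
longitudinal magnetization of the two states evolves under relaxation and
exchange:

$$\frac{d}{dt}\begin{pmatrix}M_A\\M_B\end{pmatrix} =
-\begin{pmatrix}k_f + R_1^A & -k_b\\ -k_f & k_b + R_1^B\end{pmatrix}
\begin{pmatrix}M_A\\M_B\end{pmatrix}$$

with forward/backward refolding rate constants $k_f$ ($A\to B$), $k_b$
($B\to A$) and per-fold longitudinal relaxation rates. Writing
$a_{11}=k_f+R_1^A$, $a_{22}=k_b+R_1^B$, $a_{12}=-k_b$, $a_{21}=-k_f$, the
eigenvalues of $-A$ are

$$\lambda_{1,2}=\tfrac12\!\left[-(a_{11}+a_{22})\pm
\sqrt{(a_{11}-a_{22})^2+4a_{12}a_{21}}\right],$$

both non-positive for any physical parameter set. All four observable decay
channels are the same biexponential kernel
$f_c(t) = [(c+\lambda_1)e^{\lambda_1 t}-(c+\lambda_2)e^{\lambda_2 t}]
/(\lambda_1-\lambda_2)$ with channel constants $c = a_{22}$ (ZZ auto-peak
AA, initial magnetization confined to fold A), $c=a_{11}$ (BB), and
$c = a_{22}-a_{21}$, $a_{11}-a_{12}$ for the T1 channels A and B.

Two model commitments deserve emphasis:

* **Initial conditions.** The AA/BB forms are the diagonal elements of
  $\exp(-At)$ — one fold selected at $t=0$. The T1 forms correspond to
  propagating the *equilibrium-weighted* initial vector
  $(p_A, p_B) = (k_b, k_f)/k_{ex}$ and normalizing each component by its own
  zero-time value. This is adopted as the model contract and is enforced in
  the test suite by comparison against a generic matrix-exponential
  propagator (`exchange_propagator()`), which makes no use of the closed
  forms. Every closed-form curve must agree with that oracle to $10^{-9}$;
  the published algebra for this family of experiments is easy to mistype
  (coefficient pairings differ between channels), so the oracle — not any
  transcription — is the source of truth here.
* **Two states only.** No third species, no transverse pathways, no
  cross-relaxation. Cross-peak (AB/BA) build-up curves are deliberately not
  fitted; auto-peaks plus T1 channels already determine all four parameters.

Degenerate eigenvalues (possible only when $k_f k_b = 0$ and
$a_{11}=a_{22}$) switch to the limiting form
$e^{\lambda t}(1 + (c+\lambda)t)$ when
$|\lambda_1-\lambda_2| < 10^{-10}\,\mathrm{s^{-1}}$. At $t=0$ every curve is
set to exactly 1 rather than trusting floating-point cancellation.

### Fitting

`fit_exchange()` minimizes the joint sum of squared residuals of all
supplied channels (AA/BB alone, or all four) over the four shared
parameters, with box constraints (rates $\ge 0$) under Levenberg-Marquardt.
When per-point uncertainties are given, residuals are weighted $1/\sigma$;
the residual standard deviation reported for Monte-Carlo seeding is always
computed on the raw intensity scale. Starting values are data-driven — $R_1$
from log-linear decays of the T1 (or auto-peak) channels, the exchange rate
from the excess decay of AA over A — with up to five bounded multi-start
perturbations before failure is declared. Convergence uses relative
tolerances of $10^{-12}$ with a 500-iteration cap. Sharing the two $R_1$
values across the ZZ and T1 experiments is a deliberate choice: both
experiments monitor the same spins under the same conditions, and the joint
fit is what makes $R_1$ and $k$ separable at all.

### Monte-Carlo uncertainties

`monte_carlo_errors()` implements a parametric bootstrap: synthetic data are
drawn as best-fit curves plus i.i.d. Gaussian noise (sd defaulting to the
fit's residual sd), refit from the best-fit starting point, and the
per-parameter standard deviations across runs are reported. The noise model
is additive on normalized intensities, which matches how intensities arrive
(peak sums normalized by the zero-mixing-time volume). More than 20% of
runs failing to refit aborts with diagnostics. A nominal-coverage property
(±1 sd intervals covering truth in roughly the Gaussian 68% of repeated
simulations) is part of the test suite.

## Sugar-pucker analysis

The quantitative-J experiment yields
$S_\mathrm{cross}/S_\mathrm{diag} = -\tan^2(2\pi J \zeta)$ with evolution
delay $\zeta$ (default 13.05 ms, giving a usable range
$J < 1/(4\zeta) = 19.16$ Hz). Inversion uses the principal arctangent
branch and round-trips to machine precision. The two-state north/south
conversion is linear in $J$ between limiting couplings:

* `j_north = 1.0 Hz`, `j_south = 8.8 Hz` by default. These are calibration
  choices of this package, not literature constants: 8.8 Hz is the observed
  coupling of a reference uridine known to sit almost fully C2′-endo, and
  1.0 Hz is a typical pure-north value; with these limits a 4.6 Hz coupling
  converts to 46% C2′-endo. Both are arguments everywhere they are used.
* A cross peak whose |ratio| falls below `detection_threshold` (default
  0.01) is reported as *pure C3′-endo, no detectable cross peak* with an
  undefined $J$, rather than $J = 0$: in practice the noise floor, not a
  true zero coupling, drives non-detection.

## Fold populations

Peak-volume ratios give populations directly,
$p_{1B} = V_{1B}/(V_{1B}+V_{2B})$, invariant under any uniform volume
scaling, with first-order error propagation when volume uncertainties are
supplied. For 1D slices where the two folds' resonances are resolved,
`fit_two_lorentzians()` fits $I(x) = \sum_i A_i/(1+((x-x_{0i})/(w_i/2))^2)
+ c$ and converts amplitudes and widths to areas via the closed form
$A_i\pi w_i/2$. A constant baseline is co-fitted by default (linear
optionally); fits whose centres end up closer than a quarter of the wider
linewidth carry a merged-peak flag, since area partitioning becomes
unreliable there. `titration_summary()` orders conditions as given (no
parsing of "eq." amounts is attempted) and reports the direction of change
of $p_{2B}$.

## Melting thermodynamics

Absorbance-versus-temperature curves are reduced to the association degree
with linear folded/unfolded baselines fitted in two windows (defaults: the
lowest and highest 15% of the temperature range),
$\alpha(T) = (A_\mathrm{high}(T)-A(T))/(A_\mathrm{high}(T)-A_\mathrm{low}(T))$,
then fitted to the monomolecular two-state van't Hoff form

$$\alpha = \frac{1}{1+e^{(\Delta H^0 - T\Delta S^0)/(RT)}},$$

yielding $\Delta H^0$, $\Delta S^0$ (association; both negative for a
folding transition, $\Delta S^0 \ge 0$ at the optimum is an error) and
$T_m = \Delta H^0/\Delta S^0$, at which $\alpha = 1/2$ identically.
Temperatures are converted to Kelvin on read; $R = 8.314\times10^{-3}$
kJ mol⁻¹ K⁻¹. Errors come from residual resampling (200 refits, seeded).
`cycle_average()` fits heating-cooling cycles independently and reports
mean ± sd of $T_m$, excluding (with a warning) cycles that fail.

One transformation property is worth knowing: because the baselines are
*estimated*, noise in the baseline windows propagates into the α
denominator and biases $|\Delta H^0|$ slightly upward — about 2–3% at
0.002 AU noise on a 0.15 AU transition. $T_m$, a ratio, is far more robust
(better than 0.1%). The recovery tests encode exactly this behaviour;
a maximum-likelihood joint fit of baselines and thermodynamics would reduce
the bias but departs from the standard windowed treatment implemented here.
Monomolecularity (concentration-independence of $T_m$) is treated as a
reporting matter, not a fitted constraint.

## The synthetic-data generator

`scenario_config()` fixes the study conditions; all generators are
deterministic given its seed.

* **Exchange:** 11 mixing times (5, 10, 20, …, 100 ms), SNR 100 (Gaussian
  sd $1/\mathrm{SNR}$ on normalized intensities), and a four-residue preset
  with $k_{ex}$ = 20.89, 15.24, 10.11, 7.88 s⁻¹ split by detailed balance at
  60/40 populations. $R_1 = 2.5$ s⁻¹ in both folds — a typical ribose C1′
  value at 14.1 T — because fitted per-fold $R_1$ values are not separately
  tabulated anywhere to copy.
* **Conditions:** apo 0.60, Mg²⁺-saturated 0.30, EDTA 0.75, branched 0.25,
  branched+Mg²⁺ 0.10 (as $p_{1B}$), with a five-step Mg²⁺ titration preset.
  Volumes are drawn lognormally around $p\cdot V_\mathrm{tot}$ with CV 5% —
  multiplicative noise is the natural model for integrated peak volumes.
* **Traces:** two Lorentzians of equal width (0.03 ppm) separated by 10
  linewidths, amplitudes proportional to populations, 1% additive noise.
* **Couplings:** forward tangent law at ζ = 13.05 ms; the "absent" case
  emits a cross peak below the detection threshold.
* **Melts:** forward α model with ΔH° = −200 kJ/mol, ΔS° = −0.6 kJ/(mol K)
  ($T_m$ = 333.3 K; typical small-hairpin values), sloped linear baselines,
  0.002 AU noise, five cycles, 283–383 K at 150 points — wide enough that
  both baseline windows are essentially transition-free.

What the generator does **not** emulate: correlated (ridge/phase) noise,
baseline distortions, peak overlap with third species, temperature-dependent
$R_1$, intermediate-exchange line broadening, or any tertiary-structure
contribution. Passing recovery tests therefore demonstrate correctness of
the estimators under the stated noise model, not robustness to every
artefact of real spectra.

## Problem sizes used in the checks

Recovery checks use 20 independent noise realizations per claim; the
oracle-equivalence property uses 1000 random parameter sets; Monte-Carlo
coverage uses 200 simulated experiments with 100 bootstrap refits each;
published-grade Monte-Carlo errors use 1000 runs. These sizes give binomial/
sampling error comfortably below the tolerances they are tested against
while keeping the whole suite quick on a laptop.

## Known limitations

* Two-site exchange only; no $n>2$ networks, CPMG/CEST, or cross-peak
  build-up fitting.
* The pucker model is the simplified two-state limit; a full pseudorotation
  (Karplus) analysis with multiple couplings is out of scope.
* Exactly two Lorentzians per trace; heavily merged peaks are flagged, not
  deconvolved further.
* Melting assumes a single monomolecular two-state transition; bimolecular
  models and multi-transition deconvolution are not provided.
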