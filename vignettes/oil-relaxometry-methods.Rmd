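---
title: "Methods: oil relaxometry and the chain-length calibration"
author: "relaxochain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oil relaxometry and the chain-length calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxochain)
```

## The physical picture

Proton relaxation in a neat oil is dominated by intramolecular dipole-dipole
coupling modulated by rotational tumbling. The Bloembergen-Purcell-Pound
(BPP) spectral-density model gives the two relaxation rates as functions of
the rotational correlation time $\tau_c$ and the Larmor frequency
$\omega_0 = 2\pi f$:

$$\frac{1}{T_1} = \frac{3}{10}\,C\left[\frac{\tau_c}{1+\omega_0^2\tau_c^2}
  + \frac{4\tau_c}{1+4\omega_0^2\tau_c^2}\right], \qquad
\frac{1}{T_2} = \frac{3}{20}\,C\left[3\tau_c
  + \frac{5\tau_c}{1+\omega_0^2\tau_c^2}
  + \frac{2\tau_c}{1+4\omega_0^2\tau_c^2}\right],$$

with $C = (\mu_0/4\pi)^2\gamma^4\hbar^2/l^6$ the dipolar coupling strength
for an inter-proton distance $l$. These are the canonical like-spin BPP
forms; they are the unique pair consistent with the qualitative behaviour
the model must reproduce — $T_1 = T_2$ in the fast-motion (extreme
narrowing) limit $\omega_0\tau_c \ll 1$, $T_2$ strictly decreasing in
$\tau_c$, and a unique $T_1$ minimum at $\omega_0\tau_c \approx 0.616$. The
prefactor cancels in the ratio $T_1/T_2$, which is therefore a universal,
monotone function of $\omega_0\tau_c$; `invert_tau_c_from_ratio()` inverts
it by bisection in $\log\tau_c$ (relative tolerance $10^{-10}$, default
bracket $[10^{-13}, 10^{-5}]$ s, which spans small molecules through
polymeric aggregates at a 23 MHz instrument).

Defaults: $f = 23$ MHz, $l = 1.79\,\mathrm{\AA}$ (a typical geminal
proton-proton distance), $\gamma = 2.675\times 10^8$ rad s$^{-1}$ T$^{-1}$.
No published value of $l$ exists for these mixtures, so the prefactor is
overridable; every ratio-based quantity is independent of it.

The fast-motion law $R_2 = c\,M_2\,\tau_c$ (second moment $M_2$, constant
$c = 10$ by convention) is exposed separately by `fast_motion_r2()` and only
for the regime $\omega_0\tau_c \ll 1$ where it holds. The printed constant
10 absorbs an unstated share of the dipolar prefactor, so it is kept
configurable rather than derived.

## Hydrodynamics

The link from bulk properties to $\tau_c$ is Stokes-Einstein-Debye:
$\tau_c = C_r\,\eta V / k_B T$, with the sphere volume $V = (4/3)\pi r^3$
and $C_r = 1$ by default, which makes `tau_c_sed()` exactly the inverse of
the Stokes-Einstein tumbling rate $1/\tau_c = 3k_BT/4\pi\eta r_g^3$ and
gives $\tau_c D_r = 1/6$ against the rotational diffusion coefficient
$D_r = k_BT/8\pi\eta R^3$. $C_r$ is an empirical shape/slip fitting
parameter in general. Viscosities cross the API in centipoise — the unit of
the bundled tables — and are converted to Pa s internally exactly once.

For unentangled chains the self-diffusion coefficient scales as
$M_w^{-\alpha}$ with $\alpha = 1$ below the entanglement coupling weight
$M_{wc}$; combining this with Stokes-Einstein-Debye makes $R_2/\eta$
proportional to $M_w$. No $M_{wc}$ is known for these oils, so the default
is effectively infinite and exceeding a user-supplied value warns rather
than fails. For chemically similar unbranched chains $M_w$ tracks the
carbon count, which motivates the calibration below; the hydrodynamic chain
fixes only proportionalities, so all absolute prediction lives in the
fitted coefficients.

## CPMG fitting

`fit_monoexponential()` estimates $T_2$ from an echo train two ways: an OLS
fit of $\log A$ on $t$, and (the default) Levenberg-Marquardt least squares
on the raw amplitudes warm-started from the log-linear estimate. The
log-linear stage drops echoes below three times a baseline-noise estimate
obtained from second differences of the train tail — the log transform
turns additive tail noise into gross outliers — while the nonlinear stage
uses every echo. Non-decaying input (fitted $T_2 \le 0$ or $> 10^6$ ms) is
an error, not a number. On noiseless data both methods agree to $10^{-8}$
relative; the fit is invariant to overall amplitude scaling.

$R_2$ is reported in s$^{-1}$ as $1000/T_2[\mathrm{ms}]$. The bundled
table's rate column is labelled ms$^{-1}$, but its values equal
$1000/T_2[\mathrm{ms}]$ row by row (e.g. 451 ms against 2.214), so the
header is treated as a unit typo and the rate is s$^{-1}$ throughout.

## The chain-length calibration

The central model is ordinary least squares of carbon chain length on the
viscosity-normalized rate over the 17 liquid reference oils:

$$\mathrm{CL} = a\,\frac{R_2}{\eta} + b.$$

`fit_calibration()` returns a classed model object with the usual verbs
(`print`, `summary`, `coef`, `predict`, `plot`, `residuals`, `simulate`).
Fitted on the bundled table it gives $a = +52.998$, $b = -1.5597$,
$R^2 = 0.95$. The published account of this regression prints $a$ with a
negative sign; the data trend (chain length rising with $R_2/\eta$ from
glycerol at 0.063 to the C24 soap at 0.499) and the refit both require the
positive sign, so the magnitude is kept and the sign treated as an erratum.
The predictor is $R_2/\eta$, not raw $R_2$: only the normalized rate
reproduces those coefficients.

Predictions report the real value, its nearest integer (ties away from
zero — a chain length is a carbon count), and an extrapolation flag when
the predictor leaves the training range. The calibration was established on
chain lengths 3-24; common vegetable-oil triglycerides are longer, so
extrapolation is the expected regime for them and the flag matters.
Solid-state records carry no meaningful bulk viscosity and are excluded
from fitting. `loo_cross_validate()` quantifies transferability by
leave-one-out refitting.

One bundled-table conflict is preserved as printed: the "Ketal glycerol"
row carries formula C7H12ClN3O2 and chain length 7 in the relaxation table
but C6H12O3 and chain length 6 in the preparation table; the relaxation
table is what the calibration was fitted to, so its row is used verbatim.

## T1-T2 correlation maps

`simulate_ir_cpmg()` generates inversion-recovery-CPMG data,
$\sum_j w_j(1 - 2e^{-\tau/T_{1j}})e^{-t/T_{2j}}$ plus Gaussian noise; the
inversion-recovery kernel is the conventional choice for this instrument
class and is the one assumed throughout. `invert_t1t2()` solves the
ill-posed 2-D inverse problem as Tikhonov-regularized nonnegative least
squares on SVD-compressed kernels:
$\min_{F\ge 0}\|K_1FK_2^T - D\|_F^2 + \lambda\|F\|_F^2$. No published
description of the original maps' inversion exists, so this standard
formulation is a design choice of the package. The solver is accelerated
projected-gradient (FISTA) with the exact Lipschitz step and adaptive
restart: any momentum step that would raise the objective is rejected and
replaced by a plain gradient step, so the recorded objective decreases
monotonically — the property the tests assert. Non-convergence within the
iteration cap is an error carrying the residual, not a silent answer.

Numerical defaults: 64-point grids log-spaced over 0.1-10000 ms on both
axes (covering every tabulated oil), singular values truncated at $10^{-8}$
of the largest, $\lambda = 10^{-4}$ relative to the squared product of the
largest singular values (oil signals are high-SNR; heavier smoothing is
available per call), iteration cap 5000, relative objective tolerance
$10^{-10}$. An optional constraint restricts the solution to the physical
half-plane $T_1 \ge T_2$; it is off by default because it pulls components
lying within a couple of grid cells of the diagonal onto it, while the
unconstrained solve already places peak maxima on the physical side.

Peaks are 8-neighbourhood local maxima above 5% of the map maximum; mass is
apportioned by nearest-peak assignment in log-log coordinates, which is
well defined for the well-separated components the method can resolve at
all. Classification follows the qualitative reading of oil maps: $T_2$
under 10 ms means a high-viscosity/saturated species; $T_1/T_2$ above 2
means anomalously slow rotation (aggregates, resins) — the source material
says only "longer than", and 2 is the configurable default that separates
its classes; anything else is free fluid. The gel diagnostic flags
rigid-network formation when the dominant peak's $T_2$ moves by less than
10% while $T_1$ grows by more than 50%, the signature of a sparse network
immobilizing a small mass fraction while the bulk keeps rotating.

## What the synthetic generator does and does not emulate

`make_cpmg()` emulates the bench acquisition: 23 MHz, TE 0.3 ms, 1000
echoes, 16 scans, TR 10 s, mono-exponential truth, additive Gaussian noise
with default $\sigma = 0.5\%$ of $M_0$ (a 16-scan neat-oil acquisition is
high-SNR; the true per-sample noise level is unreported, so this is a
stated convention). Per-oil truth is mono-exponential because that is how
the reference rates were obtained; multi-component truth is available only
through explicit component lists. $T_1$ values, absent from the reference
table, default to $T_1 = T_2$ as appropriate for free fluids in extreme
narrowing, and are overridable.

`make_oil_panel()` builds one train per liquid reference oil. Its
ground-truth $T_2$ defaults to $1000/R_2$ from the table's rate column
rather than the printed $T_2$ column: the $T_2$ column is rounded to 2-3
significant figures while the rate column retains the precision of the
original fits, and only the rate-derived truth closes the
generate-fit-normalize-calibrate round trip onto the published regression
(the rounded-$T_2$ panel refits with a slope of 53.45 rather than 52.998
— pure rounding artefact). `t2_source = "t2"` selects the printed column
when the rounded values are wanted, and `make_cpmg(oil = ...)` uses the
printed column since that is the table value a user will recognise.

The generator does not emulate instrument artefacts — B1 inhomogeneity,
stimulated echoes, baseline drift, temperature drift — or translational
diffusion and intermolecular relaxation pathways. Passing tests therefore
demonstrate correctness of the estimators and the pipeline under the
stated noise model, not robustness to hardware imperfections.

## Problem sizes in the test suite

The suite favours parameterized property checks at modest sizes: inversion
tests run on a 300-echo, 1-ms-TE CPMG window (extending coverage to 300 ms
at a fraction of the cost of the full acquisition) with the default 64x64
grid; Monte-Carlo estimator checks use 30-200 replicates of the full
1000-echo train. These sizes give stable statistics for every asserted
tolerance.

## Known limitations

- Absolute BPP predictions depend on $l$ (through $C$) and on $C_r$; only
  ratio- and calibration-based quantities are parameter-free.
- The calibration transfers only within chemically similar, unbranched,
  free-fluid oils; solids and gels violate its assumptions (the gel
  diagnostic exists precisely because viscosity cannot be read off
  relaxation once a network forms).
- The map inversion resolves components separated by roughly a factor of a
  few in both dimensions; nearby components merge, and mass apportionment
  between merged peaks is undefined.
- Viscosity is an input (20 C values in the bundled tables), not something
  the package models; temperature dependence is out of scope.
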