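---
title: "Diffusion model comparison: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion model comparison: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mmtid)
```

This vignette documents the models, the numerical machinery and the design
choices behind `mmtid`, in the spirit of a methods section: what is computed,
under which assumptions, and where the genuinely open choices were made.

## The two models

Multi-diffusion-time PGSE data probe whether water displacement is bounded.
In cellular tissue, water restricted inside cells explores less space as the
diffusion time grows, so the apparent diffusivity *falls* with the gradient
separation Δ. In necrotic or fluid-filled regions diffusion is effectively
free over the probed scales and the signal depends on the b-value alone.

**Microstructural model (MM).** Four parameters: sphere (cell) radius `R`
(0.1–25 µm), intracellular diffusivity `Di`, extracellular diffusivity `De`
(each 0.1–3 µm²/ms) and intracellular signal fraction `fi` (0.01–1):

$$S(b, \Delta) = f_i\,A_{\mathrm{sphere}}(R, D_i; G, \delta, \Delta)
  + (1 - f_i)\,e^{-b D_e}.$$

`fi` is a *signal* fraction at a fixed TE: the two protocols each hold TE
constant, so compartmental T2 weighting is absorbed into `fi` and not
modelled. The extracellular compartment is a pure monoexponential in b with a
free `De` — the "hindered" compartment carries no explicit tortuosity model or
time dependence, which is essential for the comparison logic below: all time
dependence in MM comes from restriction.

**Time-independent diffusion (TID).** One parameter `D'` (0.1–3 µm²/ms),
$S = e^{-bD'}$ fitted jointly across both diffusion times. It is a good
description precisely where diffusion is time-independent.

**Conventional ADC.** On the separate single-diffusion-time acquisition the
signal is normalised to the b = 150 s/mm² measurement rather than b = 0,
suppressing the perfusion (pseudo-diffusion) contribution of capillary blood:
$S/S_{b150} = e^{-(b-150)\,\mathrm{ADC}}$.

## Sphere attenuation and the gradient waveform

The restricted compartment uses the Gaussian-phase-distribution series
(Murday–Cotts) with eigenvalue roots $\mu_m$ of $j_1'(x) = 0$
(2.08158, 5.94037, 9.20584, ...):

$$\ln A = -2\gamma^2 G^2 \sum_m
  \frac{R^2}{\mu_m^2(\mu_m^2 - 2)\lambda_m^2}
  \Big[2\big(\lambda_m\delta - 1 + e^{-\lambda_m\delta}\big)
  + 2e^{-\lambda_m\Delta} - e^{-\lambda_m(\Delta-\delta)}
  - e^{-\lambda_m(\Delta+\delta)}\Big],
  \qquad \lambda_m = \mu_m^2 D_i / R^2 .$$

The series is truncated at 30 roots with an early exit once a term's relative
contribution drops below 1e-12; extending to 40 roots changes the attenuation
by less than 1e-8 on the protocol of interest.

The scanner plays *trapezoidal* gradient pulses. The quoted pulse duration
δ = 4.65 ms is the total trapezoid including both 0.245 ms ramps. Two
handlings are implemented:

- the default replaces each trapezoid by a rectangle of effective width
  δ<sub>eff</sub> = δ − ε, and uses the closed-form series above;
- `waveform = "trapezoid"` evaluates the GPD double time-integral of the true
  waveform numerically (piecewise-linear gradient on a 20 000-point grid with
  a recursive exponential accumulator).

At a 0.245 ms rise the two differ by about 1e-4 in attenuation, far below
fitting noise, so the fast closed form is used during fitting. b-values use
the same convention plus the standard trapezoid correction terms
$b = \gamma^2G^2[\delta_e^2(\Delta - \delta_e/3) + \epsilon^3/30 -
\delta_e\epsilon^2/6]$, with γ = 2.6752219×10⁸ rad s⁻¹ T⁻¹. This reproduces
the nominal 150/500/1000 s/mm² of the short-Δ protocol (computed 148.8, 499.2,
1000.2) and the long-Δ 2296/4592 to <0.5%; treating δ as the rectangular width
would overestimate all b by ~10%. One printed nominal value (689) is ~0.8% off
any convention we tried; the fitted models consistently consume the *computed*
b-values, so internal consistency is preserved regardless.

The GPD kernel is validated in the test suite against an independent
random-walk Monte-Carlo simulation in an impermeable sphere (specular
reflection, phase accumulated along the gradient axis), agreeing to well
within 2% attenuation across R ∈ {5, 10} µm × Di ∈ {0.5, 1, 2} µm²/ms.

## Voxel-wise fitting

Signals are normalised to the mean of the G = 0 measurements (TE is constant
within the protocol). Raw signals below `2 * s_noise` — where `s_noise` is the
mean signal in a background region, related to the Rician noise SD by
$\bar S_{bg} = \sigma\sqrt{\pi/2}$ — are discarded before fitting, and the
*same* retained set feeds both models so their AICc values are comparable.
The b = 0 points themselves are retained as residual points (they carry noise
after normalisation); dropping them would discard information about the
normalisation error and was not done.

Least squares uses a Nelder–Mead simplex on a logistic-transformed parameter
space, which enforces the box constraints smoothly (the same idea as the
bounded-simplex wrappers common in MATLAB pipelines). Tolerances are 1e-6 on
parameters and objective, at most 2000 evaluations per start. Each fit runs
from `n_starts` (default 100) start points drawn uniformly over the bounded
box. Start points come from a per-voxel stream seeded by (global seed, voxel
id, Di-block), with start *s* consuming a fixed slice of the stream: results
are bit-reproducible, independent of batch order and parallelisation, and the
best-of-starts objective is monotone in `n_starts` by construction.

Two strategies address the well-known instability of fitting `Di` from PGSE
data:

- **fit-Di**: all four MM parameters free;
- **discrete-Di**: `Di` fixed in turn to {0.5, 1.0, 1.5, 2.0, 2.5} µm²/ms,
  fitting (R, De, fi) each time; the sub-fit with the highest R² wins, ties
  going to the lower `Di`. R² is defined as 1 − RSS/TSS with TSS about the
  mean of the retained normalised signals.

Fits with any parameter within 1% of the constraints are flagged *extreme*.
"Within 1%" is interpreted as 1% of the parameter *range* (scale-free); an
alternative reading — 1% of the bound's value — is implemented via
`extreme_mode = "value"`. Extreme fits are excluded from parameter
distributions but still count in %MM, in that order. For an out-of-set true
`Di` the five sub-fits can be nearly degenerate (residuals within ~1% of each
other with quite different parameter sets); the lookup floor guarantees only
that estimated `Di` never falls below 0.5 µm²/ms.

## Model preference and %MM

$$\mathrm{AICc} = n\ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

with k = 4 (MM) and k = 1 (TID); the noise variance is not counted for either
model (adding it to both would shift only the small-sample term). MM is
preferred iff its AICc is strictly lower. Ties go to TID (parsimony). When
fewer than k + 2 points survive the noise floor the AICc is undefined; such
voxels default to TID rather than being dropped — with heavy signal loss the
simpler model is the only defensible description — and are flagged. Voxels
where nothing could be fitted are excluded from both numerator and denominator
of %MM. An exact-fit RSS of zero maps to an AICc of −∞, which resolves
correctly: a shared −∞ is a tie (TID).

The AICc penalty difference at the full n = 8 sets a detectability threshold:
MM wins only when its residual is at least $e^{(21.33-2.67)/8} \approx 10$
times smaller than TID's. This is the mechanism behind the method's
conservatism at realistic noise: weakly time-dependent MM voxels (low `Di`,
small mismatch) cannot clear the bar, so %MM is biased downward while TID
voxels are almost never misclassified.

## The synthetic-data generator and the validation studies

`generate_synthetic_tumor()` mixes MM and TID voxels in exact proportion to
the requested ground truth and adds Rician noise
($\sqrt{(S+n_1)^2+n_2^2}$, $n_i \sim N(0, 1/\mathrm{SNR})$) on signals
normalised to unit b = 0 expectation; SNR 54 matches the protocol's typical
b = 0 SNR. The default study sizes mirror the full design (10 datasets × 200
voxels per ground truth; 1500 replicates per microstructure in the
fitting-accuracy study), while the tests and the acceptance script run
desk-scale versions (3 datasets, 50 replicates, 10 restarts) chosen to keep a
single-core run in the ten-minute range; the studies scale linearly.

The original in-vivo voxel-wise parameter distributions that such a study
would ideally resample are not available, so the default pools are
reconstructed from reported group-level summaries: MM voxels draw
R ~ N(10, 1²) µm, fi ~ N(0.41, 0.03²), De ~ N(0.6, 0.1²) µm²/ms (truncated to
the fit bounds) with `Di` uniform over the discrete lookup set; TID voxels
draw D′ uniform on 1.0–2.5 µm²/ms, the upper diffusivity range typical of
necrotic regions. All pools are caller-overridable. Two consequences of this
reconstruction, both visible in the acceptance run rather than asserted away:

- specificity is extremely high and the noiseless study reproduces the
  ground truth exactly at every level — both structural properties of the
  selection rule, insensitive to the pools;
- sensitivity (and with it the accuracy at high ground truths, and the CoV at
  low ground truths, whose denominator is the — underestimated — mean %MM)
  depends strongly on how much of the MM pool lies above the detectability
  threshold. With `Di` spread uniformly over 0.5–2.5 µm²/ms roughly half the
  MM voxels sit below it, which yields lower sensitivity than a pool
  concentrated at high `Di` would. These quantities should be read as
  properties of *these* pools, not of the method alone.

What the generator does **not** emulate: spatial correlation between voxels,
partial-volume mixtures within a voxel, compartmental T2/TE effects, scanner
drift, motion, or imaging-gradient cross terms. Passing validation here
demonstrates the statistical behaviour of the estimator under the stated
noise model, not robustness to those effects.

`run_fitting_simulation()` reruns the accuracy study on the 96-microstructure
grid (R ∈ {5, 10} µm × Di, De ∈ {0.2, 1.1, 2.0, 2.9} µm²/ms ×
fi ∈ {0.25, 0.5, 0.75}), reporting per-parameter median absolute percentage
errors and the accepted-fit (non-extreme) fraction per strategy — the basis
for preferring discrete-Di, which accepts more fits on average.

## Conventional ADC analysis

`threshold_sweep()` computes, per dataset, the percentage of voxels with
ADC strictly below each threshold on a 0.1–3 µm²/ms grid (step 0.01) and
correlates it with an external reference fraction such as histological
% necrosis; the threshold with the largest |ρ| is the cut-off (ties to the
lowest). The strict inequality matters at the bounds, where clipped fits
accumulate exactly on 0.1 and 3. Any such cut-off is cohort- and
protocol-specific: diffusion times change ADC, so cut-offs do not transfer
across studies. Central-slice selection (for comparison with single-slice
histology) is the caller's responsibility via the ROI mask; the package does
not guess slice geometry.

## Degenerate inputs and edge rules

- A voxel whose b = 0 mean is non-positive, or with every signal below the
  noise floor, is unfittable.
- TID needs ≥2 retained points; MM needs ≥5 (free Di) or ≥4 (discrete).
- `s_noise = 0` disables the floor (noiseless synthetic data); a zero or
  empty background region is rejected with advice to pass sigma explicitly.
- ADC fitting requires the b ≈ 150 s/mm² reference itself to survive the
  floor.
- Protocols must share δ and ε across measurements; b is always recomputed
  from the waveform, never trusted from a sidecar.

## Known limitations

- Sensitivity of the MM/TID comparison is bounded by the AICc penalty gap;
  at SNR ≈ 54 the estimated %MM saturates well below 100% however cellular
  the tissue. %MM is therefore a *conservative* necrosis-complement marker.
- `Di` is poorly identified from PGSE data at these diffusion times — the
  motivation for the discrete strategy — and out-of-set truths produce
  degenerate sub-fit ties.
- No Rician-likelihood fitting: least squares on magnitudes with a noise
  floor, as in the original pipeline.
- No permeability, non-spherical geometries, perfusion compartment, or
  spatial regularisation.
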