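# mmtid — voxel-wise diffusion model comparison for tumor sub-regions

`mmtid` implements a diffusion-MRI analysis that classifies tumor voxels by
which of two signal models better describes their multi-diffusion-time pulsed
gradient spin echo (PGSE) data:

- **MM**, a two-compartment *microstructural model*: water restricted inside
  impermeable spheres (cell radius *R*, intracellular diffusivity *D<sub>i</sub>*,
  signal fraction *f<sub>i</sub>*) plus hindered extracellular water with
  diffusivity *D<sub>e</sub>*,

  *S(b, Δ) = f<sub>i</sub> · A<sub>sphere</sub>(R, D<sub>i</sub>; G, δ, Δ) +
  (1 − f<sub>i</sub>) · e<sup>−b D<sub>e</sub></sup>*,

  where *A<sub>sphere</sub>* is the Gaussian-phase-distribution (Murday–Cotts)
  echo attenuation for diffusion in a sphere;
- **TID**, a *time-independent diffusion* model: a single monoexponential
  *S = e<sup>−b D′</sup>* fitted across **both** diffusion times, which is only
  adequate where diffusion does not depend on the diffusion time.

Each voxel is fitted with both models on the identical retained measurements
(signals below twice the background noise level are discarded), and the model
with the lower small-sample-corrected Akaike Information Criterion (AICc,
k = 4 for MM vs k = 1 for TID) is preferred. The fraction of fittable voxels
preferring MM — **%MM** — is a biomarker of the restricted-diffusion
(cellular, non-necrotic) tissue fraction: necrotic or fluid regions show fast,
time-independent diffusion and fall to TID.

The package is aimed at preclinical imaging scientists running
multi-diffusion-time PGSE tumor protocols. It provides:

- trapezoid-aware b-value computation and JSON protocol sidecars
  (`compute_b_value`, `pgse_protocol`, `two_dt_protocol`);
- NIfTI volume I/O, noise/SNR estimation from a background region
  (`read_dwi_volume`, `estimate_snr`);
- GPD signal kernels validated against a random-walk Monte-Carlo oracle
  (`mm_signal`, `tid_signal`, `restricted_sphere_attenuation`);
- bounded multi-start simplex fitting with two strategies for the poorly
  conditioned intracellular diffusivity: free (`fit_di`) or fixed to a lookup
  set 0.5–2.5 µm²/ms with the highest-R² sub-fit winning (`discrete_di`);
- AICc model preference, %MM, parameter/preference maps (`fit_dwi_volume`,
  `build_maps`, `percent_mm`);
- conventional ADC mapping normalised to b = 150 s/mm² and ADC-threshold
  sweeps against an external reference fraction (`fit_adc`, `threshold_sweep`);
- Rician-noise simulators and the two in-silico validation studies:
  fitting accuracy over a 96-microstructure grid and %MM
  bias/precision/confusion statistics (`run_fitting_simulation`,
  `run_percentmm_validation`).

## Worked example

```r
library(mmtid)

prot <- two_dt_protocol()
prot
#> PGSE protocol 'two diffusion time': 8 measurements, 2 diffusion time(s)
#>    G delta Delta  rise      b
#>    0  4.65  9.86 0.245    0.0
#>  113  4.65  9.86 0.245  148.8
#>  207  4.65  9.86 0.245  499.2
#>  293  4.65  9.86 0.245 1000.2
#>    0  4.65 40.00 0.245    0.0
#>  113  4.65 40.00 0.245  683.2
#>  207  4.65 40.00 0.245 2292.7
#>  293  4.65 40.00 0.245 4593.5

# a synthetic "tumor" of 40 voxels, half MM and half TID, noiseless
ds <- generate_synthetic_tumor(50, n_voxels = 40, snr = Inf, seed = 1)
res <- analyze_synthetic_tumor(ds, fit_config(n_starts = 5, seed = 1))
res$percent_mm
#> [1] 50
unlist(res$confusion[c("accuracy", "sensitivity", "specificity")])
#>    accuracy sensitivity specificity
#>           1           1           1
```

Without noise every voxel is classified as its generating model, so the
estimated %MM equals the 50% ground truth exactly. At a realistic SNR the
classification becomes conservative: TID voxels are almost never called MM
(high specificity), while genuinely restricted voxels with weak
time-dependence are absorbed by the simpler model, so %MM is a downward-biased
estimate of the restricted fraction — quantifying that bias is what
`run_percentmm_validation()` is for.

A command-line front end for file-based pipelines
(`fit`, `simulate`, `adc-sweep`, `fixtures`) is installed at
`system.file("cli", "mmtid.R", package = "mmtid")`.

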