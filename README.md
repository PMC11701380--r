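# syndrs — diffuse reflectance spectroscopy of synovial fluid

Septic arthritis is screened by aspirating synovial fluid and counting white
blood cells (WBC); counts above 50,000/µL call for immediate operative
treatment, but laboratory results take the better part of an hour. Diffuse
reflectance spectroscopy (DRS) can read the same fluid optically, without
opening the syringe: broadband light delivered through the syringe wall is
multiply scattered by cells and absorbed by hemoglobin, and the diffusely
reflected spectrum at a 2.25 mm source–detector separation over 475–655 nm
carries both signals.

`syndrs` is an R package for everyone who wants to exercise that measurement
quantitatively — instrument builders validating against microsphere
phantoms, and analysts studying what the spectral biomarkers can and cannot
distinguish in small clinical cohorts. It implements:

* **Mie optics & phantom design** — reduced scattering of polystyrene
  microsphere suspensions, `μs′ = N·(πd²/4)·Qsca·(1−g)`, and its exact
  inverse for phantom recipes (`reduced_scattering()`, `design_phantom()`);
* **hemoglobin absorption** — Beer–Lambert conversion
  `μa = ln(10)·ε(λ)·C/64500` over a bundled oxyhemoglobin extinction table
  (`hb_absorption()`);
* **a forward model** — steady-state diffusion dipole reflectance of a
  semi-infinite medium at the probe's source–detector separation, plus an
  instrument layer (lamp shape, gain, integration time, shot-like noise)
  producing raw counts (`diffuse_reflectance()`, `instrument_counts()`);
* **the calibration pipeline** — background subtraction, time
  normalisation, division by a reflectance standard of known reflectivity,
  and the two ratio biomarkers **R490/R600** (scattering shape) and
  **R580/R600** (hemoglobin band) (`compute_reflectance()`,
  `extract_biomarkers()`);
* **a synthetic cohort simulator** — latent WBC/RBC counts, traumatic-tap
  and saline-dilution confounders, infection labels, triplicate acquisitions
  (`cohort_config()`, `simulate_cohort()`, `cohort_biomarkers()`);
* **exact small-cohort statistics** — Mann–Whitney U by network enumeration
  with midranks, Spearman correlation by full or Monte-Carlo permutation
  (`rank_sum_test()`, `spearman_test()`, `analyze_cohort()`,
  `power_study()`).

## Worked example

```r
library(syndrs)

# 1. Phantom design: the canonical microsphere concentration
reduced_scattering(sphere_suspension(0.75, 25.73e8), 600)
#> [1] 2.10011                       # cm^-1 at 600 nm
design_phantom(4.45, 600, 0.75)     # density for the absorption-phantom level
#> [1] 5452428108                   # ~54.5e8 parts/mL

# 2. Forward model -> biomarkers for a scattering-only phantom
grid <- seq(475, 655, by = 2)
props <- optical_properties(grid,
  scattering_spectrum(sphere_suspension(0.75, 25.73e8), grid),
  rep(0.002, length(grid)))
extract_biomarkers(diffuse_reflectance(props), sample_id = "phantom-2.1")
#> Biomarkers (phantom-2.1): R490/R600 = 1.3887, R580/R600 = 1.0900 [ok]

# 3. A synthetic 5-vs-13 cohort through the full pipeline
cfg <- cohort_config(master_seed = 5)
bm  <- cohort_biomarkers(cfg)
analyze_cohort(bm, seed = 5)
#> Cohort analysis: 5 infected vs 13 noninfected
#>   r490_600: U = 2, p = 0.0009337, infected lower
#>   r580_600: U = 5, p = 0.004435, infected lower
#>   ...
```

The phantom biomarkers read the physics directly: R490/R600 > 1 because the
microspheres scatter more strongly at short wavelengths, and R580/R600 near
1 because a bloodless phantom has no hemoglobin dip. In the synthetic
cohort, both ratios separate infected from noninfected samples (exact
Mann–Whitney p < 0.01, infected lower), echoing the significance pattern a
pilot clinical cohort of this size can show. On a larger simulated cohort
(`scale_cohort(cfg, 200)`), R580/R600 correlates negatively with the
reported red-cell count (ρ ≈ −0.39, permutation p < 1e-4) — the
blood-contamination axis — while R490/R600 *falls* with the white-cell
count in this simulator because reflectance at 2.25 mm rolls over at high
scattering; the methods vignette discusses why that sign cannot match the
group separation simultaneously.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/syndrs.R run-all --seed 5 --out out/       # simulate -> calibrate -> analyze
Rscript inst/cli/syndrs.R mie --diameter 0.75 --density 25.73e8 --wavelengths 600
```

`run-all` writes the raw spectra (comment-prefixed CSV dialect,
`# key: value` metadata lines then `wavelength_nm,value` rows), `lab.csv`,
`manifest.csv`, `biomarkers.csv` and `report.json`; identical seed and
configuration reproduce every file byte for byte.

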