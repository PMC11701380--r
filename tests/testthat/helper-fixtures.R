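# shared fixtures: all built in code, no stored data

grid_2nm <- seq(475, 655, by = 2)

# optical properties of a polystyrene-bead phantom with optional hemoglobin
phantom_props <- function(density_per_ml, hb_mg_ml = 0, grid = grid_2nm,
                          baseline_mua = 0.002) {
  mus <- scattering_spectrum(sphere_suspension(0.75, density_per_ml), grid)
  mua <- baseline_mua + hb_absorption(hb_mg_ml, grid)$mu_a
  optical_properties(grid, mus, mua)
}

zero_noise <- function(offset = 0) noise_model(0, 0, offset)

flat_lamp <- function(l) rep(1, length(l))

# calibration set for one true reflectance spectrum under a given noise model
make_cal_set <- function(truth, noise = zero_noise(), seed = 1,
                         reflectivity = 0.8, t_sample = 150, t_std = 150,
                         gain = 200, n_rep = 3, lamp = lamp_spectrum) {
  shots <- lapply(seq_len(n_rep), function(r) {
    instrument_counts(truth, t_sample, gain, noise, seed = seed + r,
                      lamp = lamp)
  })
  std <- simulate_standard_shot(reflectivity, truth$wavelengths_nm, t_std,
                                gain, noise, seed = seed + 100, lamp = lamp)
  calibration_set(lapply(shots, `[[`, "sample"), shots[[1]]$background,
                  std$standard, std$background, reflectivity)
}

# default-parameter cohort configuration with zero instrument noise
quiet_config <- function(...) {
  cohort_config(..., acquisition = list(additive_sd = 0, shot_factor = 0))
}
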