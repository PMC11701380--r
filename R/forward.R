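#' Probe geometry
#'
#' Geometry of the fiber-optic probe: source-detector separation distance
#' (SDSD), refractive-index mismatch at the fluid boundary and the usable
#' wavelength window. The defaults mirror a probe with 2.25 mm SDSD reading
#' 475-655 nm; `n_relative = 1` treats the boundary as index matched, which is
#' appropriate when the syringe wall and fiber indices are close.
#'
#' @param sdsd_mm Source-detector separation in mm (> 0).
#' @param n_relative Refractive index of the medium relative to its
#'   surroundings (>= 1; 1 means matched boundary).
#' @param window_nm Length-2 wavelength window (low, high) in nm.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(sdsd_mm = 2.25, n_relative = 1.0,
                           window_nm = c(475, 655)) {
  stopifnot(is.numeric(sdsd_mm), length(sdsd_mm) == 1L, sdsd_mm > 0,
            is.numeric(n_relative), length(n_relative) == 1L, n_relative >= 1,
            length(window_nm) == 2L, window_nm[1] < window_nm[2])
  structure(list(sdsd_mm = sdsd_mm, n_relative = n_relative,
                 window_nm = as.numeric(window_nm)),
            class = "probe_geometry")
}

#' Optical properties on a shared wavelength grid
#'
#' @param wavelengths_nm Strictly increasing grid in nm.
#' @param mus_prime Reduced scattering coefficient spectrum, cm^-1 (>= 0).
#' @param mu_a Absorption coefficient spectrum, cm^-1 (>= 0).
#' @return An object of class `optical_properties`.
#' @export
optical_properties <- function(wavelengths_nm, mus_prime, mu_a) {
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    stop("`wavelengths_nm` must be strictly increasing")
  }
  n <- length(wavelengths_nm)
  if (length(mus_prime) != n || length(mu_a) != n) {
    stop("`mus_prime` and `mu_a` must share the wavelength grid")
  }
  if (any(!is.finite(mus_prime)) || any(mus_prime < 0) ||
      any(!is.finite(mu_a)) || any(mu_a < 0)) {
    stop("optical properties must be finite and >= 0")
  }
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 mus_prime = as.numeric(mus_prime),
                 mu_a = as.numeric(mu_a)),
            class = "optical_properties")
}

# internal reflection parameter A from the relative refractive index
# (Groenhuis empirical form; A = 1 for a matched boundary)
boundary_A <- function(n_relative) {
  if (abs(n_relative - 1) < 1e-12) return(1)
  rd <- -1.440 / n_relative^2 + 0.710 / n_relative + 0.668 + 0.0636 * n_relative
  (1 + rd) / (1 - rd)
}

# dipole (Farrell) steady-state reflectance of a semi-infinite medium at radial
# distance rho_cm; vectorised over mus/mua
dipole_reflectance <- function(mus, mua, rho_cm, n_relative = 1.0) {
  mut <- mua + mus
  z0 <- 1 / mut
  D <- 1 / (3 * mut)
  mueff <- sqrt(3 * mua * mut)
  zb <- 2 * boundary_A(n_relative) * D
  r1 <- sqrt(z0^2 + rho_cm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_cm^2)
  (1 / (4 * pi)) * (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
                    (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
}

#' Diffuse reflectance from optical properties
#'
#' Steady-state diffusion-approximation reflectance of a semi-infinite
#' homogeneous medium at radial distance SDSD from a pencil source, using the
#' dipole construction: an isotropic point source buried at one transport mean
#' free path `1/(mu_a + mu_s')` and its image mirrored across the extrapolated
#' boundary placed via the internal-reflection parameter derived from
#' `n_relative`. The absolute scale is arbitrary up to `system_constant`
#' (probe throughput, syringe wall, collection efficiency); all downstream
#' biomarkers are ratios and do not depend on it.
#'
#' The diffusion approximation degrades when scattering is weak
#' (`mu_s' < 1 cm^-1`) or absorption-dominated (`mu_s' < 2 mu_a`); such
#' wavelengths are still evaluated but trigger a warning.
#'
#' @param props An [optical_properties()] object whose grid covers the probe
#'   window.
#' @param geom A [probe_geometry()].
#' @param system_constant Positive multiplicative scale (default 1).
#' @param check_validity Set `FALSE` to suppress the diffusion-validity
#'   warning (used by bulk simulation loops that log it once).
#' @return A [drs_spectrum()] of dimensionless reflectance on the grid
#'   restricted to the probe window, with `meta$role = "model"`.
#' @export
diffuse_reflectance <- function(props, geom = probe_geometry(),
                                system_constant = 1, check_validity = TRUE) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "probe_geometry"),
            is.numeric(system_constant), system_constant > 0)
  keep <- props$wavelengths_nm >= geom$window_nm[1] &
          props$wavelengths_nm <= geom$window_nm[2]
  if (!any(keep)) stop("optical-property grid does not cover the probe window")
  lam <- props$wavelengths_nm[keep]
  mus <- props$mus_prime[keep]
  mua <- props$mu_a[keep]
  if (all(mus == 0)) {
    stop("mu_s' is zero everywhere: the diffusion model is undefined ",
         "for a non-scattering medium")
  }
  if (check_validity) {
    shaky <- mus < pmax(2 * mua, 1)
    if (any(shaky)) {
      warning(sprintf(paste0("diffusion validity is questionable at %d of %d ",
                             "wavelengths (mu_s' < max(2*mu_a, 1 cm^-1))"),
                      sum(shaky), length(mus)))
    }
  }
  R <- system_constant *
    dipole_reflectance(mus, mua, geom$sdsd_mm / 10, geom$n_relative)
  drs_spectrum(lam, R, meta = list(role = "model",
                                   sdsd_mm = geom$sdsd_mm,
                                   system_constant = system_constant))
}

#' Halogen-like lamp spectral shape
#'
#' Smooth broadband illumination shape used by the instrument simulator: a
#' Planck curve at 3200 K normalised to its maximum on the grid, which rises
#' toward long wavelengths over 475-655 nm like a halogen source. The exact
#' shape cancels in calibration; only smoothness matters.
#'
#' @param wavelengths_nm Wavelength grid in nm.
#' @return Relative spectral intensity in (0, 1].
#' @export
lamp_spectrum <- function(wavelengths_nm) {
  lam_m <- wavelengths_nm * 1e-9
  h <- 6.62607015e-34; c0 <- 299792458; kB <- 1.380649e-23
  B <- 1 / (lam_m^5 * (exp(h * c0 / (lam_m * kB * 3200)) - 1))
  B / max(B)
}

#' Instrument noise model
#'
#' Additive detector noise plus shot-like noise whose variance is proportional
#' to the signal: `sd(counts) = sqrt(additive_sd^2 + shot_factor * signal)`.
#'
#' @param additive_sd Standard deviation of signal-independent noise, counts.
#' @param shot_factor Variance per unit signal (counts); 0 disables shot noise.
#' @param background_offset Mean dark/ambient offset, counts.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 4, shot_factor = 1,
                        background_offset = 400) {
  stopifnot(additive_sd >= 0, shot_factor >= 0, background_offset >= 0)
  structure(list(additive_sd = additive_sd, shot_factor = shot_factor,
                 background_offset = background_offset),
            class = "noise_model")
}

# run code with a private, restorable RNG stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

add_noise <- function(signal, noise) {
  sd <- sqrt(noise$additive_sd^2 + noise$shot_factor * pmax(signal, 0))
  signal + stats::rnorm(length(signal), sd = sd)
}

#' Simulate raw sample and background shots
#'
#' Turns a true reflectance spectrum into simulated spectrometer counts:
#' `counts = gain * integration_time * lamp_shape * R + offset + noise`, plus a
#' matching background spectrum carrying offset and noise only. Deterministic
#' given `seed`.
#'
#' @param true_reflectance A [drs_spectrum()] of dimensionless reflectance.
#' @param integration_time_ms Integration time in ms (linear count scaling).
#' @param gain Detector gain scale (counts per ms per unit radiance).
#' @param noise A [noise_model()].
#' @param seed Integer seed making the draw reproducible.
#' @param meta Extra metadata fields copied onto both output spectra.
#' @param lamp Function of wavelength (nm) giving the relative lamp shape
#'   (default [lamp_spectrum()]; the shape cancels in calibration).
#' @return List with elements `sample` and `background`, both [drs_spectrum()]s
#'   whose meta records role, integration time and gain.
#' @export
instrument_counts <- function(true_reflectance, integration_time_ms = 150,
                              gain = 200, noise = noise_model(), seed = 1,
                              meta = list(), lamp = lamp_spectrum) {
  stopifnot(inherits(true_reflectance, "drs_spectrum"),
            inherits(noise, "noise_model"),
            integration_time_ms > 0, gain > 0, is.function(lamp))
  lam <- true_reflectance$wavelengths_nm
  signal <- gain * integration_time_ms * lamp(lam) *
    true_reflectance$values
  with_seed(seed, {
    sample_counts <- add_noise(signal, noise) + noise$background_offset
    bg_counts <- add_noise(rep(0, length(lam)), noise) +
      noise$background_offset
    list(
      sample = drs_spectrum(lam, sample_counts, c(list(
        role = "sample", integration_time_ms = integration_time_ms,
        gain = gain), meta)),
      background = drs_spectrum(lam, bg_counts, c(list(
        role = "background", integration_time_ms = integration_time_ms,
        gain = gain), meta))
    )
  })
}

#' Simulate a reflectance-standard shot
#'
#' Counts for a diffuse reflectance standard of known reflectivity (flat in
#' wavelength), acquired with the same lamp shape, gain and offsets as sample
#' shots: used by the calibration pipeline exactly like an 80 percent bench
#' standard or a 55 percent barium-sulfate in-syringe standard.
#'
#' @param reflectivity Standard reflectivity in (0, 1].
#' @inheritParams instrument_counts
#' @return List with `standard` and `background` [drs_spectrum()]s.
#' @export
simulate_standard_shot <- function(reflectivity = 0.8, wavelengths_nm,
                                   integration_time_ms = 150, gain = 200,
                                   noise = noise_model(), seed = 1,
                                   meta = list(), lamp = lamp_spectrum) {
  if (!is.numeric(reflectivity) || length(reflectivity) != 1L ||
      reflectivity <= 0 || reflectivity > 1) {
    stop("`reflectivity` must lie in (0, 1]")
  }
  flat <- drs_spectrum(wavelengths_nm, rep(reflectivity,
                                           length(wavelengths_nm)))
  out <- instrument_counts(flat, integration_time_ms, gain, noise, seed,
                           meta = c(list(standard_reflectivity = reflectivity),
                                    meta), lamp = lamp)
  out$sample$meta$role <- "standard"
  out$background$meta$role <- "standard_background"
  list(standard = out$sample, background = out$background)
}
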