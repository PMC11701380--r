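#' Mie efficiencies for a homogeneous sphere
#'
#' Computes the scattering efficiency, extinction efficiency and anisotropy
#' factor of a single homogeneous, non-absorbing sphere from the Lorenz-Mie
#' series. The series is evaluated with the standard Wiscombe truncation order
#' `ceiling(x + 4.05 * x^(1/3) + 2)`; the logarithmic derivative of the
#' internal field is obtained by downward recurrence, the Riccati-Bessel
#' functions by upward recurrence.
#'
#' @param x Size parameter, `pi * d * n_medium / lambda_vacuum` (dimensionless,
#'   `> 0`).
#' @param m Refractive index of the sphere relative to the surrounding medium
#'   (real, `>= 1`; this implementation targets non-absorbing particles such as
#'   polystyrene microspheres and cell-like scatterers in the visible window).
#' @return A list of class `mie_result` with elements `x`, `m`, `Qsca`, `Qext`
#'   and `g` (mean cosine of the scattering angle).
#' @examples
#' # Rayleigh limit: Qsca -> (8/3) x^4 |(m^2-1)/(m^2+2)|^2
#' mie_efficiencies(0.05, 1.2)$Qsca
#' @export
mie_efficiencies <- function(x, m) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("size parameter `x` must be a single finite number > 0")
  }
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1) {
    stop("relative refractive index `m` must be a single real number >= 1")
  }

  nstop <- ceiling(x + 4.05 * x^(1 / 3) + 2)
  nmx <- max(nstop, ceiling(m * x)) + 16L

  # logarithmic derivative D_n(mx), downward recurrence (real for real m)
  mx <- m * x
  D <- numeric(nmx + 1L)
  for (n in nmx:1L) {
    D[n] <- n / mx - 1 / (D[n + 1L] + n / mx)
  }

  a <- complex(nstop)
  b <- complex(nstop)
  psi_nm1 <- cos(x) # psi_{-1}
  psi_n <- sin(x)   # psi_0
  chi_nm1 <- -sin(x)
  chi_n <- cos(x)
  for (n in seq_len(nstop)) {
    psi <- (2 * n - 1) / x * psi_n - psi_nm1
    chi <- (2 * n - 1) / x * chi_n - chi_nm1
    zeta <- complex(real = psi, imaginary = -chi)
    zeta_prev <- complex(real = psi_n, imaginary = -chi_n)
    da <- D[n + 1L] / m + n / x
    db <- D[n + 1L] * m + n / x
    a[n] <- (da * psi - psi_n) / (da * zeta - zeta_prev)
    b[n] <- (db * psi - psi_n) / (db * zeta - zeta_prev)
    psi_nm1 <- psi_n; psi_n <- psi
    chi_nm1 <- chi_n; chi_n <- chi
  }

  n <- seq_len(nstop)
  mod2 <- Mod(a)^2 + Mod(b)^2
  qsca <- 2 / x^2 * sum((2 * n + 1) * mod2)
  qext <- 2 / x^2 * sum((2 * n + 1) * Re(a + b))
  if (!is.finite(qsca) || !is.finite(qext)) {
    stop("Mie series failed to converge numerically (x = ", x, ", m = ", m,
         "): non-finite partial sums")
  }
  # convergence diagnostic: the truncated tail must be negligible
  tail_term <- (2 * nstop + 1) * mod2[nstop]
  if (qsca > 0 && tail_term > 1e-8 * x^2 * qsca / 2) {
    stop("Mie series not converged at truncation order ", nstop,
         " (x = ", x, ", m = ", m, "); residual term ", signif(tail_term, 3))
  }

  nm <- n[-nstop]
  g_cross <- sum(nm * (nm + 2) / (nm + 1) *
                   Re(a[nm] * Conj(a[nm + 1L]) + b[nm] * Conj(b[nm + 1L])))
  g_self <- sum((2 * n + 1) / (n * (n + 1)) * Re(a * Conj(b)))
  g <- 4 / (x^2 * qsca) * (g_cross + g_self)

  structure(list(x = x, m = m, Qsca = qsca, Qext = qext, g = g),
            class = "mie_result")
}

#' @export
print.mie_result <- function(x, ...) {
  cat(sprintf("Mie result: x = %.5g, m = %.5g\n", x$x, x$m))
  cat(sprintf("  Qsca = %.6g  Qext = %.6g  g = %.6g\n", x$Qsca, x$Qext, x$g))
  invisible(x)
}

#' Refractive index of polystyrene
#'
#' Sellmeier dispersion for polystyrene (Sultanova et al. form), giving
#' n(600 nm) = 1.590. Used for the microsphere phantoms.
#'
#' @param wavelength_nm Vacuum wavelength(s) in nm.
#' @return Refractive index (same length as `wavelength_nm`).
#' @export
polystyrene_index <- function(wavelength_nm) {
  lam2 <- (wavelength_nm / 1000)^2
  sqrt(1 + 1.4435 * lam2 / (lam2 - 0.020216))
}

#' Refractive index of water
#'
#' Treated as constant (1.332) over the 475-655 nm window; the variation over
#' this range is below 0.3 percent and negligible against the phantom
#' tolerances.
#'
#' @param wavelength_nm Vacuum wavelength(s) in nm (accepted for interface
#'   symmetry with [polystyrene_index()]).
#' @return Refractive index (recycled to the length of `wavelength_nm`).
#' @export
water_index <- function(wavelength_nm) {
  rep_len(1.332, length(wavelength_nm))
}

#' Describe a suspension of identical spheres
#'
#' @param diameter_um Sphere diameter in micrometres (> 0).
#' @param number_density_per_ml Particles per mL (>= 0).
#' @param n_particle Particle refractive index: a single number or a function
#'   of vacuum wavelength in nm (default: polystyrene dispersion).
#' @param n_medium Medium refractive index: a single number or a function of
#'   vacuum wavelength in nm (default: water, 1.332).
#' @return An object of class `sphere_suspension`.
#' @examples
#' sphere_suspension(0.75, 25.73e8)
#' @export
sphere_suspension <- function(diameter_um, number_density_per_ml,
                              n_particle = polystyrene_index,
                              n_medium = water_index) {
  if (!is.numeric(diameter_um) || length(diameter_um) != 1L ||
      !is.finite(diameter_um) || diameter_um <= 0) {
    stop("`diameter_um` must be a single finite number > 0")
  }
  if (!is.numeric(number_density_per_ml) || length(number_density_per_ml) != 1L ||
      !is.finite(number_density_per_ml) || number_density_per_ml < 0) {
    stop("`number_density_per_ml` must be a single finite number >= 0")
  }
  np <- if (is.function(n_particle)) n_particle else function(l) rep_len(n_particle, length(l))
  nm <- if (is.function(n_medium)) n_medium else function(l) rep_len(n_medium, length(l))
  probe <- c(np(550), nm(550))
  if (any(!is.finite(probe)) || any(probe < 1)) {
    stop("refractive indices must be finite and >= 1")
  }
  structure(list(diameter_um = diameter_um,
                 number_density_per_ml = number_density_per_ml,
                 n_particle = np, n_medium = nm),
            class = "sphere_suspension")
}

#' @export
print.sphere_suspension <- function(x, ...) {
  cat(sprintf("Sphere suspension: d = %.4g um, %.4g parts/mL\n",
              x$diameter_um, x$number_density_per_ml))
  cat(sprintf("  n_particle(600) = %.4f, n_medium(600) = %.4f\n",
              x$n_particle(600), x$n_medium(600)))
  invisible(x)
}

# per-particle reduced scattering cross-section sigma_s' = (pi d^2/4) Qsca (1-g),
# in cm^2, vectorised over wavelength; memoised because phantom and cohort code
# re-evaluate the same particle on the same grid many times
.mie_cache <- new.env(parent = emptyenv())

transport_cross_section <- function(suspension, wavelength_nm) {
  key <- paste0(format(suspension$diameter_um, digits = 15), "|",
                paste(format(suspension$n_particle(c(475, 550, 655)), digits = 15),
                      collapse = ","), "|",
                paste(format(suspension$n_medium(c(475, 550, 655)), digits = 15),
                      collapse = ","), "|",
                paste(format(wavelength_nm, digits = 15), collapse = ","))
  hit <- .mie_cache[[key]]
  if (!is.null(hit)) return(hit)
  d_cm <- suspension$diameter_um * 1e-4
  n_med <- suspension$n_medium(wavelength_nm)
  n_par <- suspension$n_particle(wavelength_nm)
  sig <- vapply(seq_along(wavelength_nm), function(i) {
    x <- pi * suspension$diameter_um * n_med[i] / (wavelength_nm[i] / 1000)
    mr <- mie_efficiencies(x, n_par[i] / n_med[i])
    (pi * d_cm^2 / 4) * mr$Qsca * (1 - mr$g)
  }, numeric(1))
  .mie_cache[[key]] <- sig
  sig
}

check_volume_fraction <- function(suspension) {
  d_cm <- suspension$diameter_um * 1e-4
  vf <- suspension$number_density_per_ml * pi / 6 * d_cm^3
  if (vf > 0.02) {
    warning(sprintf(paste0("volume fraction %.3g exceeds 2%%: independent-",
                           "scattering assumption is questionable"), vf))
  }
  invisible(vf)
}

#' Reduced scattering coefficient of a sphere suspension
#'
#' Maps a suspension to its reduced scattering coefficient
#' `mu_s' = N * (pi d^2 / 4) * Qsca * (1 - g)` at the requested vacuum
#' wavelength(s), with the size parameter computed in the suspending medium.
#' Assumes independent scattering (warns above 2 percent volume fraction).
#'
#' @param suspension A [sphere_suspension()].
#' @param wavelength_nm Vacuum wavelength(s) in nm, within 200-2000 nm.
#' @return `mu_s'` in cm^-1, one value per wavelength.
#' @examples
#' # the 25.73e8 parts/mL polystyrene phantom: ~2.1 cm^-1 at 600 nm
#' reduced_scattering(sphere_suspension(0.75, 25.73e8), 600)
#' @export
reduced_scattering <- function(suspension, wavelength_nm) {
  stopifnot(inherits(suspension, "sphere_suspension"))
  if (!is.numeric(wavelength_nm) || any(!is.finite(wavelength_nm)) ||
      any(wavelength_nm < 200) || any(wavelength_nm > 2000)) {
    stop("wavelengths must be finite and inside the supported 200-2000 nm range")
  }
  check_volume_fraction(suspension)
  suspension$number_density_per_ml *
    transport_cross_section(suspension, wavelength_nm)
}

#' Reduced scattering spectrum over a wavelength grid
#'
#' Vectorised [reduced_scattering()] over a sorted grid.
#'
#' @inheritParams reduced_scattering
#' @param wavelengths_nm Ascending wavelength grid in nm.
#' @return `mu_s'(lambda)` in cm^-1.
#' @export
scattering_spectrum <- function(suspension, wavelengths_nm) {
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    stop("`wavelengths_nm` must be sorted strictly ascending")
  }
  reduced_scattering(suspension, wavelengths_nm)
}

#' Number density achieving a target reduced scattering coefficient
#'
#' Inverts [reduced_scattering()] for the phantom recipe: since `mu_s'` is
#' exactly linear in number density, the inverse is the target divided by the
#' per-particle transport cross-section at the design wavelength.
#'
#' @param target_mus_prime Target `mu_s'` in cm^-1 (>= 0).
#' @param wavelength_nm Design vacuum wavelength in nm.
#' @param diameter_um Sphere diameter in micrometres.
#' @param n_particle,n_medium As in [sphere_suspension()].
#' @return Number density in particles per mL.
#' @examples
#' design_phantom(2.1, 600, 0.75) # ~25.7e8 parts/mL
#' @export
design_phantom <- function(target_mus_prime, wavelength_nm, diameter_um,
                           n_particle = polystyrene_index,
                           n_medium = water_index) {
  if (!is.numeric(target_mus_prime) || length(target_mus_prime) != 1L ||
      !is.finite(target_mus_prime) || target_mus_prime < 0) {
    stop("`target_mus_prime` must be a single finite number >= 0")
  }
  unit <- sphere_suspension(diameter_um, 1, n_particle, n_medium)
  sigma <- transport_cross_section(unit, wavelength_nm)
  if (sigma <= 0) {
    stop("per-particle scattering cross-section is zero at ", wavelength_nm,
         " nm; cannot design a phantom at this wavelength")
  }
  target_mus_prime / sigma
}
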