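#' Bundle raw shots for calibration
#'
#' Collects the raw spectra needed to compute calibrated diffuse reflectance
#' for one sample: the (typically triplicate) sample shots, their background,
#' the reflectance-standard shot and its background, plus the standard's known
#' reflectivity. All spectra must share one wavelength grid.
#'
#' @param sample_shots List of one or more sample [drs_spectrum()]s.
#' @param sample_background Background [drs_spectrum()] for the sample shots.
#' @param standard_shot Standard [drs_spectrum()].
#' @param standard_background Background [drs_spectrum()] for the standard.
#' @param standard_reflectivity Known reflectivity of the standard, in (0, 1].
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(sample_shots, sample_background, standard_shot,
                            standard_background, standard_reflectivity = 0.8) {
  if (inherits(sample_shots, "drs_spectrum")) sample_shots <- list(sample_shots)
  stopifnot(is.list(sample_shots), length(sample_shots) >= 1L,
            all(vapply(sample_shots, inherits, logical(1), "drs_spectrum")),
            inherits(sample_background, "drs_spectrum"),
            inherits(standard_shot, "drs_spectrum"),
            inherits(standard_background, "drs_spectrum"))
  if (!is.numeric(standard_reflectivity) || standard_reflectivity <= 0 ||
      standard_reflectivity > 1) {
    stop("`standard_reflectivity` must lie in (0, 1]")
  }
  ref <- sample_shots[[1L]]
  others <- c(sample_shots[-1L], list(sample_background, standard_shot,
                                      standard_background))
  if (!all(vapply(others, same_grid, logical(1), a = ref))) {
    stop("all spectra in a calibration set must share one wavelength grid")
  }
  structure(list(sample_shots = sample_shots,
                 sample_background = sample_background,
                 standard_shot = standard_shot,
                 standard_background = standard_background,
                 standard_reflectivity = standard_reflectivity),
            class = "calibration_set")
}

#' Average replicate shots
#'
#' Pointwise arithmetic mean of replicate spectra; the per-wavelength
#' coefficient of variation across replicates is stored in the metadata for
#' quality control.
#'
#' @param shots Non-empty list of [drs_spectrum()]s on one grid.
#' @return A [drs_spectrum()] with `meta$n_replicates` and
#'   `meta$replicate_cv` (median CV across wavelengths).
#' @export
average_replicates <- function(shots) {
  if (inherits(shots, "drs_spectrum")) shots <- list(shots)
  if (!is.list(shots) || length(shots) == 0L) {
    stop("`shots` must be a non-empty list of spectra")
  }
  ref <- shots[[1L]]
  if (length(shots) > 1L &&
      !all(vapply(shots[-1L], same_grid, logical(1), a = ref))) {
    stop("replicate shots must share one wavelength grid")
  }
  vals <- do.call(cbind, lapply(shots, `[[`, "values"))
  mean_vals <- rowMeans(vals)
  cv <- if (ncol(vals) > 1L) {
    s <- apply(vals, 1L, stats::sd)
    stats::median(ifelse(mean_vals != 0, s / abs(mean_vals), 0))
  } else 0
  meta <- ref$meta
  meta$n_replicates <- length(shots)
  meta$replicate_cv <- cv
  drs_spectrum(ref$wavelengths_nm, mean_vals, meta)
}

integration_time_of <- function(spec) {
  t <- spec$meta$integration_time_ms
  if (is.null(t)) 1 else as.numeric(t)
}

#' Calibrated diffuse reflectance from raw shots
#'
#' Implements the standard-referenced calibration: background-subtract the
#' replicate-averaged sample counts and the standard counts, normalise each by
#' its integration time, divide, and scale by the standard's known
#' reflectivity:
#' `R = rho_std * [(mean(S) - B_s)/t_s] / [(Std - B_std)/t_std]`.
#' The result is restricted to the probe window. Wavelengths where the
#' background-subtracted standard signal is not positive are flagged invalid
#' (set to `NA`) rather than failing; downstream ratio extraction errors only
#' if an extraction wavelength is affected.
#'
#' @param cal A [calibration_set()].
#' @param window_nm Wavelength window retained in the output.
#' @return A [drs_spectrum()] of dimensionless reflectance with
#'   `meta$role = "reflectance"` and `meta$n_invalid` counting flagged pixels.
#' @export
compute_reflectance <- function(cal, window_nm = c(475, 655)) {
  stopifnot(inherits(cal, "calibration_set"))
  s_mean <- average_replicates(cal$sample_shots)
  t_s <- integration_time_of(s_mean)
  t_std <- integration_time_of(cal$standard_shot)
  num <- (s_mean$values - cal$sample_background$values) / t_s
  den <- (cal$standard_shot$values - cal$standard_background$values) / t_std
  invalid <- !(den > 0)
  R <- ifelse(invalid, NA_real_, cal$standard_reflectivity * num / den)
  keep <- s_mean$wavelengths_nm >= window_nm[1] &
          s_mean$wavelengths_nm <= window_nm[2]
  if (!any(keep)) stop("no wavelengths inside the requested window")
  meta <- s_mean$meta
  meta$role <- "reflectance"
  meta$standard_reflectivity <- cal$standard_reflectivity
  meta$n_invalid <- sum(invalid[keep])
  drs_spectrum(s_mean$wavelengths_nm[keep], R[keep], meta)
}

#' Reflectance ratio at two wavelengths
#'
#' Evaluates `R(numerator_nm) / R(denominator_nm)` with linear interpolation
#' onto the exact requested wavelengths, which makes the ratio independent of
#' the spectrometer pixel grid.
#'
#' @param reflectance A [drs_spectrum()] of calibrated reflectance.
#' @param numerator_nm,denominator_nm Wavelengths in nm, inside the grid.
#' @return The dimensionless ratio.
#' @export
ratio_at <- function(reflectance, numerator_nm, denominator_nm) {
  stopifnot(inherits(reflectance, "drs_spectrum"))
  lam <- reflectance$wavelengths_nm
  for (w in c(numerator_nm, denominator_nm)) {
    if (w < min(lam) || w > max(lam)) {
      stop("requested wavelength ", w, " nm lies outside the spectrum grid")
    }
    nbr <- c(max(which(lam <= w)), min(which(lam >= w)))
    if (any(is.na(reflectance$values[nbr]))) {
      stop("reflectance is flagged invalid at ", w,
           " nm; cannot evaluate the ratio")
    }
  }
  num <- stats::approx(lam, reflectance$values, xout = numerator_nm)$y
  den <- stats::approx(lam, reflectance$values, xout = denominator_nm)$y
  if (!is.finite(den) || den <= 0) {
    stop("reflectance at the denominator wavelength ", denominator_nm,
         " nm is not positive")
  }
  num / den
}

#' Extract the two ratio biomarkers
#'
#' Computes the pair of ratio biomarkers used for infection screening:
#' `R490/R600` (shape of the scattering curve) and `R580/R600` (hemoglobin
#' absorption band against the minimal-absorption normaliser). Samples whose
#' reflectance at 600 nm falls below `qc_floor` are labelled `"low_signal"`
#' (they are reported, never auto-excluded).
#'
#' @param reflectance A calibrated reflectance [drs_spectrum()].
#' @param sample_id Optional sample identifier copied into the result.
#' @param qc_floor Reflectance floor at 600 nm under which the sample is
#'   flagged low-signal.
#' @return An object of class `drs_biomarkers`: list with `sample_id`,
#'   `r490_600`, `r580_600`, `r600` and `qc_flag` (`"ok"` or `"low_signal"`).
#' @export
extract_biomarkers <- function(reflectance, sample_id = NULL,
                               qc_floor = 0.02) {
  r600 <- stats::approx(reflectance$wavelengths_nm, reflectance$values,
                        xout = 600)$y
  out <- list(
    sample_id = if (is.null(sample_id)) reflectance$meta$sample_id else sample_id,
    r490_600 = ratio_at(reflectance, 490, 600),
    r580_600 = ratio_at(reflectance, 580, 600),
    r600 = r600,
    qc_flag = if (is.finite(r600) && r600 < qc_floor) "low_signal" else "ok"
  )
  structure(out, class = "drs_biomarkers")
}

#' @export
print.drs_biomarkers <- function(x, ...) {
  cat(sprintf("Biomarkers%s: R490/R600 = %.4f, R580/R600 = %.4f [%s]\n",
              if (!is.null(x$sample_id)) paste0(" (", x$sample_id, ")") else "",
              x$r490_600, x$r580_600, x$qc_flag))
  invisible(x)
}
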