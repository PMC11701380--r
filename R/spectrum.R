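#' Construct a spectrum object
#'
#' The basic container of the package: a wavelength grid, one value per
#' wavelength (raw counts or dimensionless reflectance) and a free-form
#' metadata record (acquisition role, integration time, replicate index,
#' sample id, gain, ...).
#'
#' @param wavelengths_nm Strictly increasing wavelength grid in nm.
#' @param values Numeric vector, one finite value per wavelength (NA allowed
#'   only for pixels flagged invalid downstream).
#' @param meta Named list of metadata (e.g. `role`, `integration_time_ms`,
#'   `replicate`, `sample_id`, `gain`).
#' @return An object of class `drs_spectrum`.
#' @export
drs_spectrum <- function(wavelengths_nm, values, meta = list()) {
  if (!is.numeric(wavelengths_nm) || length(wavelengths_nm) < 2L ||
      any(!is.finite(wavelengths_nm)) ||
      is.unsorted(wavelengths_nm, strictly = TRUE)) {
    stop("`wavelengths_nm` must be a strictly increasing numeric grid")
  }
  if (!is.numeric(values) || length(values) != length(wavelengths_nm)) {
    stop("`values` must be numeric with one entry per wavelength")
  }
  if (any(is.infinite(values))) stop("`values` must not contain infinities")
  stopifnot(is.list(meta))
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm),
                 values = as.numeric(values), meta = meta),
            class = "drs_spectrum")
}

#' @export
print.drs_spectrum <- function(x, ...) {
  rng <- range(x$wavelengths_nm)
  cat(sprintf("DRS spectrum: %d points, %.4g-%.4g nm\n",
              length(x$wavelengths_nm), rng[1], rng[2]))
  if (!is.null(x$meta$role)) cat("  role:", x$meta$role, "\n")
  keep <- setdiff(names(x$meta), "role")
  if (length(keep)) {
    cat("  meta:", paste(keep, unlist(x$meta[keep]), sep = "=", collapse = ", "),
        "\n")
  }
  cat(sprintf("  values: [%.6g, %.6g]\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Write a spectrum to the package CSV dialect
#'
#' The on-disk format is a comment-prefixed CSV: any number of `# key: value`
#' metadata lines, then the header `wavelength_nm,value`, then the data rows at
#' full double precision, so `read_spectrum(write_spectrum(s))` is lossless.
#'
#' @param spectrum A [drs_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "drs_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(spectrum$meta)) {
    writeLines(sprintf("# %s: %s", key,
                       format(spectrum$meta[[key]], digits = 17)), con)
  }
  writeLines("wavelength_nm,value", con)
  writeLines(paste(sprintf("%.17g", spectrum$wavelengths_nm),
                   sprintf("%.17g", spectrum$values), sep = ","), con)
  invisible(path)
}

#' Read a spectrum from the package CSV dialect
#'
#' @param path Path to a file written by [write_spectrum()] (or hand-authored
#'   in the same dialect).
#' @return A [drs_spectrum()]; `# key: value` comment lines are restored into
#'   `meta` (values that parse as numbers become numeric).
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("spectrum file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("parse error in ", path, ": file is empty")
  is_comment <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!is_comment]
  body_line_no <- which(!is_comment)
  if (length(body) == 0L || body[1] != "wavelength_nm,value") {
    stop("parse error in ", path, ": missing `wavelength_nm,value` header")
  }
  rows <- body[-1]
  row_no <- body_line_no[-1]
  if (length(rows) == 0L) stop("parse error in ", path, ": no data rows")
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad_shape <- which(lengths(parts) != 2L)
  if (length(bad_shape)) {
    stop("parse error in ", path, " at line ", row_no[bad_shape[1]],
         ": expected two comma-separated fields")
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2L, byrow = TRUE)
  bad_num <- which(apply(!is.finite(mat), 1L, any))
  if (length(bad_num)) {
    stop("parse error in ", path, " at line ", row_no[bad_num[1]],
         ": non-numeric value")
  }
  if (is.unsorted(mat[, 1L], strictly = TRUE)) {
    stop("parse error in ", path, ": wavelengths are not strictly increasing")
  }
  drs_spectrum(mat[, 1L], mat[, 2L], meta)
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelengths_nm) == length(b$wavelengths_nm) &&
    all(abs(a$wavelengths_nm - b$wavelengths_nm) <= tol)
}
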