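#' Configuration of the synthetic cohort
#'
#' Builds the nested configuration driving the synthetic-cohort simulator.
#' Defaults emulate a pilot study of 5 infected and 13 noninfected joint-fluid
#' samples:
#'
#' * Cell counts are lognormal. The infected group's white-cell location
#'   (median 150,000/uL) sits above the 50,000/uL operative threshold, the
#'   noninfected location (median 6,000/uL) below it, with spreads wide enough
#'   that the groups overlap as clinical counts do.
#' * A configurable fraction of noninfected samples are compromised: bloody
#'   taps carrying a high red-cell count (median 30,000/uL, i.e. roughly
#'   0.9 mg/mL hemoglobin) and saline-diluted samples whose cellular content
#'   is scaled down by a uniform dilution fraction.
#' * Optics: each white cell scatters like an ensemble of polystyrene-bead
#'   equivalents (110 beads of 0.75 um per cell, anchored so a 50,000/uL
#'   sample maps to mu_s'(600) of about 4.45 cm^-1, the validated phantom
#'   range); red cells contribute hemoglobin absorption at 30 pg per cell
#'   (typical mean corpuscular hemoglobin); acellular fluid carries a small
#'   spectrally flat scattering and absorption baseline.
#'
#' Every stochastic step derives its stream from `master_seed`.
#'
#' @param n_infected,n_noninfected Group sizes (>= 0).
#' @param master_seed Integer master seed.
#' @param infected,noninfected,optics,acquisition Named lists overriding
#'   individual defaults (unknown names are rejected).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_infected = 5, n_noninfected = 13, master_seed = 1,
                          infected = list(), noninfected = list(),
                          optics = list(), acquisition = list()) {
  stopifnot(n_infected >= 0, n_noninfected >= 0,
            is.numeric(master_seed), length(master_seed) == 1L)
  def_inf <- list(wbc_meanlog = log(150e3), wbc_sdlog = 0.45,
                  rbc_meanlog = log(1500), rbc_sdlog = 0.8)
  def_non <- list(wbc_meanlog = log(6e3), wbc_sdlog = 1.1,
                  rbc_meanlog = log(2000), rbc_sdlog = 0.9,
                  prob_bloody = 0.25,
                  bloody_rbc_meanlog = log(30e3), bloody_rbc_sdlog = 0.6,
                  prob_diluted = 0.2, dilution_range = c(0.4, 0.85))
  def_opt <- list(beads_per_wbc = 110, bead_diameter_um = 0.75,
                  baseline_mus600 = 1.8, baseline_slope = 0,
                  baseline_mua = 0.01, mch_pg = 30)
  def_acq <- list(wavelengths_nm = seq(475, 655, by = 2),
                  integration_time_ms = 150, gain = 200,
                  standard_reflectivity = 0.8,
                  additive_sd = 4, shot_factor = 1, background_offset = 400,
                  n_replicates = 3, sdsd_mm = 2.25, n_relative = 1,
                  qc_floor = 0.02)
  merge_block <- function(defaults, overrides, block) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown configuration key(s) in `", block, "`: ",
           paste(bad, collapse = ", "))
    }
    utils::modifyList(defaults, overrides)
  }
  cfg <- list(n_infected = as.integer(n_infected),
              n_noninfected = as.integer(n_noninfected),
              master_seed = as.integer(master_seed),
              infected = merge_block(def_inf, infected, "infected"),
              noninfected = merge_block(def_non, noninfected, "noninfected"),
              optics = merge_block(def_opt, optics, "optics"),
              acquisition = merge_block(def_acq, acquisition, "acquisition"))
  spread <- c(cfg$infected$wbc_sdlog, cfg$infected$rbc_sdlog,
              cfg$noninfected$wbc_sdlog, cfg$noninfected$rbc_sdlog,
              cfg$noninfected$bloody_rbc_sdlog)
  if (any(spread <= 0)) stop("all lognormal spreads must be > 0")
  if (cfg$noninfected$prob_bloody < 0 || cfg$noninfected$prob_bloody > 1 ||
      cfg$noninfected$prob_diluted < 0 || cfg$noninfected$prob_diluted > 1) {
    stop("confounder probabilities must lie in [0, 1]")
  }
  structure(cfg, class = "cohort_config")
}

#' Scale a cohort configuration to a new total size
#'
#' Keeps the infected:noninfected proportion (rounding the infected count)
#' while changing the total number of samples; used for sign-recovery runs on
#' larger synthetic cohorts.
#'
#' @param config A [cohort_config()].
#' @param n_total New total cohort size.
#' @return The rescaled `cohort_config`.
#' @export
scale_cohort <- function(config, n_total) {
  stopifnot(inherits(config, "cohort_config"), n_total >= 0)
  frac <- if (config$n_infected + config$n_noninfected > 0) {
    config$n_infected / (config$n_infected + config$n_noninfected)
  } else 0
  config$n_infected <- as.integer(round(n_total * frac))
  config$n_noninfected <- as.integer(n_total - config$n_infected)
  config
}

#' Probability that a group's WBC count exceeds a threshold
#'
#' Closed-form tail probability of the configured lognormal white-cell
#' distribution; the empirical exceedance fraction of a large simulated cohort
#' converges to this value.
#'
#' @param config A [cohort_config()].
#' @param group `"infected"` or `"noninfected"`.
#' @param threshold_per_ul Threshold in cells/uL (default: the 50,000/uL
#'   operative threshold).
#' @return Probability in (0, 1). Note dilution is not applied (native counts).
#' @export
prob_wbc_above <- function(config, group = c("infected", "noninfected"),
                           threshold_per_ul = 50e3) {
  group <- match.arg(group)
  g <- config[[group]]
  stats::plnorm(threshold_per_ul, g$wbc_meanlog, g$wbc_sdlog,
                lower.tail = FALSE)
}

#' Draw the latent biology of a cohort
#'
#' Samples per-patient latent states: native white- and red-cell counts,
#' saline-dilution fraction and the infection label. Deterministic given the
#' configuration's master seed.
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `sample_states` with columns `sample_id`,
#'   `infected` (logical), `wbc_per_ul`, `rbc_per_ul` (native, pre-dilution
#'   counts) and `dilution` in `[0, 1]`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_inf <- config$n_infected
  n_non <- config$n_noninfected
  with_seed(config$master_seed, {
    inf <- config$infected
    non <- config$noninfected
    wbc_i <- stats::rlnorm(n_inf, inf$wbc_meanlog, inf$wbc_sdlog)
    rbc_i <- stats::rlnorm(n_inf, inf$rbc_meanlog, inf$rbc_sdlog)
    wbc_n <- stats::rlnorm(n_non, non$wbc_meanlog, non$wbc_sdlog)
    bloody <- stats::runif(n_non) < non$prob_bloody
    rbc_n <- ifelse(bloody,
                    stats::rlnorm(n_non, non$bloody_rbc_meanlog,
                                  non$bloody_rbc_sdlog),
                    stats::rlnorm(n_non, non$rbc_meanlog, non$rbc_sdlog))
    diluted <- stats::runif(n_non) < non$prob_diluted
    dil_n <- ifelse(diluted,
                    stats::runif(n_non, non$dilution_range[1],
                                 non$dilution_range[2]),
                    0)
    n <- n_inf + n_non
    out <- data.frame(
      sample_id = sprintf("S%03d", seq_len(max(n, 0))),
      infected = rep(c(TRUE, FALSE), c(n_inf, n_non)),
      wbc_per_ul = c(wbc_i, wbc_n),
      rbc_per_ul = c(rbc_i, rbc_n),
      dilution = c(rep(0, n_inf), dil_n),
      stringsAsFactors = FALSE
    )
    class(out) <- c("sample_states", "data.frame")
    out
  })
}

#' Map one latent sample state to optical properties
#'
#' The scattering side represents each white cell as `beads_per_wbc`
#' polystyrene-bead equivalents (Mie transport cross-section of the configured
#' bead diameter in water), plus a spectrally smooth acellular baseline
#' `baseline_mus600 * (lambda/600)^(-baseline_slope)`. The absorption side
#' converts the red-cell count to a hemoglobin mass concentration through the
#' mean corpuscular hemoglobin and applies oxyhemoglobin extinction, plus a
#' flat acellular baseline. Saline dilution scales both cellular contributions
#' by `1 - dilution`, driving the sample toward the acellular baseline.
#'
#' @param state One row of [sample_cohort()] output (or any list with
#'   `wbc_per_ul`, `rbc_per_ul`, `dilution`).
#' @param wavelengths_nm Wavelength grid in nm.
#' @param optics The `optics` block of a [cohort_config()] (defaults used if
#'   omitted).
#' @return An [optical_properties()] object.
#' @export
biology_to_optics <- function(state, wavelengths_nm,
                              optics = cohort_config()$optics) {
  f <- 1 - state$dilution
  stopifnot(f >= 0, f <= 1, state$wbc_per_ul >= 0, state$rbc_per_ul >= 0)
  beads <- sphere_suspension(optics$bead_diameter_um, 1)
  sigma <- transport_cross_section(beads, wavelengths_nm)
  bead_density <- optics$beads_per_wbc * state$wbc_per_ul * 1e3 * f
  mus <- bead_density * sigma +
    optics$baseline_mus600 * (wavelengths_nm / 600)^(-optics$baseline_slope)
  hb_mg_ml <- state$rbc_per_ul * 1e3 * f * optics$mch_pg * 1e-9
  mua <- optics$baseline_mua + hb_absorption(hb_mg_ml, wavelengths_nm)$mu_a
  optical_properties(wavelengths_nm, mus, mua)
}

# deterministic per-sample/replicate seed stream below 2^31
derive_seed <- function(master, index, rep = 0L) {
  as.integer((as.numeric(master) * 48271 + index * 1009 + rep * 101) %%
               2147483647)
}

simulate_one_sample <- function(state, index, config, geom, noise) {
  acq <- config$acquisition
  props <- biology_to_optics(state, acq$wavelengths_nm, config$optics)
  truth <- diffuse_reflectance(props, geom, check_validity = FALSE)
  shots <- vector("list", acq$n_replicates)
  bg <- NULL
  for (r in seq_len(acq$n_replicates)) {
    raw <- instrument_counts(
      truth, acq$integration_time_ms, acq$gain, noise,
      seed = derive_seed(config$master_seed, index, rep = r),
      meta = list(sample_id = state$sample_id, replicate = r))
    shots[[r]] <- raw$sample
    if (r == 1L) bg <- raw$background
  }
  list(truth = truth, shots = shots, background = bg)
}

#' Simulate biomarkers for a whole cohort (in memory)
#'
#' End-to-end fast path: draw the cohort, map each sample to optical
#' properties, evaluate the forward model, simulate triplicate instrument
#' shots plus backgrounds and a standard shot, run the calibration pipeline
#' and extract both ratio biomarkers. Equivalent to [simulate_cohort()]
#' followed by reading the files back, without touching the disk.
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per sample: `sample_id`, `infected`,
#'   `wbc_per_ul`, `rbc_per_ul` (laboratory-reported counts, i.e. native
#'   counts scaled by `1 - dilution`), `dilution`, `r490_600`, `r580_600`,
#'   `r600`, `qc_flag`.
#' @export
cohort_biomarkers <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  states <- sample_cohort(config)
  acq <- config$acquisition
  geom <- probe_geometry(acq$sdsd_mm, acq$n_relative,
                         range(acq$wavelengths_nm))
  noise <- noise_model(acq$additive_sd, acq$shot_factor,
                       acq$background_offset)
  std <- simulate_standard_shot(acq$standard_reflectivity,
                                acq$wavelengths_nm,
                                acq$integration_time_ms, acq$gain, noise,
                                seed = derive_seed(config$master_seed, 0L))
  out <- states
  out$wbc_per_ul <- states$wbc_per_ul * (1 - states$dilution)
  out$rbc_per_ul <- states$rbc_per_ul * (1 - states$dilution)
  out$r490_600 <- NA_real_
  out$r580_600 <- NA_real_
  out$r600 <- NA_real_
  out$qc_flag <- NA_character_
  for (i in seq_len(nrow(states))) {
    sim <- simulate_one_sample(states[i, ], i, config, geom, noise)
    cal <- calibration_set(sim$shots, sim$background, std$standard,
                           std$background, acq$standard_reflectivity)
    refl <- compute_reflectance(cal, geom$window_nm)
    bm <- extract_biomarkers(refl, sample_id = states$sample_id[i],
                             qc_floor = acq$qc_floor)
    out$r490_600[i] <- bm$r490_600
    out$r580_600[i] <- bm$r580_600
    out$r600[i] <- bm$r600
    out$qc_flag[i] <- bm$qc_flag
  }
  out
}

#' Simulate a cohort and write the raw-data layout to disk
#'
#' Writes, under `out_dir`: one spectrum file per sample shot
#' (`<id>_rep<k>.csv`), one background per sample (`<id>_background.csv`), a
#' standard shot and its background, a laboratory table `lab.csv`
#' (`sample_id,infected,wbc_per_ul,rbc_per_ul,dilution`, counts as the lab
#' would report them, i.e. after dilution) and a `manifest.csv`
#' (`file,role,integration_time_ms,replicate,sample_id`) consumable by
#' [calibrate_manifest()].
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `lab` (the lab table), `manifest` (the
#'   manifest data frame) and `dir`.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  states <- sample_cohort(config)
  acq <- config$acquisition
  geom <- probe_geometry(acq$sdsd_mm, acq$n_relative,
                         range(acq$wavelengths_nm))
  noise <- noise_model(acq$additive_sd, acq$shot_factor,
                       acq$background_offset)
  std <- simulate_standard_shot(acq$standard_reflectivity,
                                acq$wavelengths_nm,
                                acq$integration_time_ms, acq$gain, noise,
                                seed = derive_seed(config$master_seed, 0L))
  manifest <- NULL
  emit <- function(spec, file, role, replicate, sample_id) {
    path <- file.path(out_dir, file)
    write_spectrum(spec, path)
    manifest <<- rbind(manifest, data.frame(
      file = file, role = role,
      integration_time_ms = integration_time_of(spec),
      replicate = replicate, sample_id = sample_id,
      stringsAsFactors = FALSE))
  }
  emit(std$standard, "standard.csv", "standard", NA, "")
  emit(std$background, "standard_background.csv", "standard_background",
       NA, "")
  for (i in seq_len(nrow(states))) {
    sid <- states$sample_id[i]
    sim <- simulate_one_sample(states[i, ], i, config, geom, noise)
    for (r in seq_along(sim$shots)) {
      emit(sim$shots[[r]], sprintf("%s_rep%d.csv", sid, r), "sample", r, sid)
    }
    emit(sim$background, sprintf("%s_background.csv", sid), "background",
         NA, sid)
  }
  lab <- data.frame(
    sample_id = states$sample_id,
    infected = states$infected,
    wbc_per_ul = states$wbc_per_ul * (1 - states$dilution),
    rbc_per_ul = states$rbc_per_ul * (1 - states$dilution),
    dilution = states$dilution,
    stringsAsFactors = FALSE)
  utils::write.csv(lab, file.path(out_dir, "lab.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(lab = lab, manifest = manifest, dir = out_dir))
}

#' Calibrate a directory of raw shots via its manifest
#'
#' Reads a `manifest.csv` as written by [simulate_cohort()] (or hand-built in
#' the same schema), groups shots by sample, runs the calibration pipeline and
#' extracts both ratio biomarkers per sample.
#'
#' @param manifest_path Path to the manifest CSV; spectrum paths are resolved
#'   relative to its directory.
#' @param standard_reflectivity Reflectivity of the standard referenced by the
#'   manifest.
#' @param qc_floor Low-signal threshold passed to [extract_biomarkers()].
#' @return Data frame `sample_id, r490_600, r580_600, r600, qc_flag`.
#' @export
calibrate_manifest <- function(manifest_path, standard_reflectivity = 0.8,
                               qc_floor = 0.02) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  root <- dirname(manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "role", "sample_id")
  if (!all(need %in% names(man))) {
    stop("manifest must have at least columns: ",
         paste(need, collapse = ", "))
  }
  load_one <- function(role) {
    rows <- man[man$role == role, , drop = FALSE]
    if (nrow(rows) != 1L) {
      stop("manifest must reference exactly one `", role, "` spectrum")
    }
    read_spectrum(file.path(root, rows$file))
  }
  std <- load_one("standard")
  std_bg <- load_one("standard_background")
  ids <- unique(man$sample_id[man$role == "sample"])
  res <- lapply(ids, function(sid) {
    shots <- lapply(man$file[man$role == "sample" & man$sample_id == sid],
                    function(f) read_spectrum(file.path(root, f)))
    bg_file <- man$file[man$role == "background" & man$sample_id == sid]
    if (length(bg_file) != 1L) {
      stop("sample ", sid, " must have exactly one background spectrum")
    }
    bg <- read_spectrum(file.path(root, bg_file))
    cal <- calibration_set(shots, bg, std, std_bg, standard_reflectivity)
    bm <- extract_biomarkers(compute_reflectance(cal), sample_id = sid,
                             qc_floor = qc_floor)
    data.frame(sample_id = sid, r490_600 = bm$r490_600,
               r580_600 = bm$r580_600, r600 = bm$r600, qc_flag = bm$qc_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
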