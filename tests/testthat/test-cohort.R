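test_that("cohort draws are deterministic and respect group sizes", {
  cfg <- cohort_config(master_seed = 9)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a, b)
  expect_identical(nrow(a), 18L)
  expect_identical(sum(a$infected), 5L)
  expect_true(all(a$wbc_per_ul >= 0 & a$rbc_per_ul >= 0))
  expect_true(all(a$dilution >= 0 & a$dilution <= 1))
  expect_true(all(a$dilution[a$infected] == 0))
  empty <- sample_cohort(cohort_config(0, 0))
  expect_identical(nrow(empty), 0L)
})

test_that("group WBC locations straddle the operative threshold", {
  cfg <- cohort_config()
  expect_gt(exp(cfg$infected$wbc_meanlog), 50e3)
  expect_lt(exp(cfg$noninfected$wbc_meanlog), 50e3)
  # empirical exceedance fraction matches the closed-form tail probability
  big <- sample_cohort(cohort_config(n_infected = 10000, n_noninfected = 0,
                                     master_seed = 4))
  p <- prob_wbc_above(cfg, "infected")
  frac <- mean(big$wbc_per_ul > 50e3)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("biology maps to optics as an independent hand-chained computation", {
  grid <- c(490, 600)
  state <- list(wbc_per_ul = 50e3, rbc_per_ul = 20e3, dilution = 0.25)
  opt <- cohort_config()$optics
  props <- biology_to_optics(state, grid, opt)
  # manual composition: Mie per bead, bead ensemble, Hb via MCH
  manual_mus <- vapply(grid, function(l) {
    x <- pi * opt$bead_diameter_um * water_index(l) / (l / 1000)
    mr <- mie_efficiencies(x, polystyrene_index(l) / water_index(l))
    sigma <- pi * (opt$bead_diameter_um * 1e-4)^2 / 4 * mr$Qsca * (1 - mr$g)
    opt$beads_per_wbc * 50e3 * 1e3 * 0.75 * sigma + opt$baseline_mus600
  }, numeric(1))
  expect_equal(props$mus_prime, manual_mus, tolerance = 1e-12)
  hb <- 20e3 * 1e3 * 0.75 * opt$mch_pg * 1e-9
  manual_mua <- opt$baseline_mua + hb_absorption(hb, grid)$mu_a
  expect_equal(props$mu_a, manual_mua, tolerance = 1e-12)
})

test_that("red-cell count drives absorption linearly; empty biology is dark", {
  grid <- seq(475, 655, by = 10)
  opt <- cohort_config()$optics
  s1 <- list(wbc_per_ul = 0, rbc_per_ul = 10e3, dilution = 0)
  s2 <- list(wbc_per_ul = 0, rbc_per_ul = 20e3, dilution = 0)
  a1 <- biology_to_optics(s1, grid, opt)$mu_a - opt$baseline_mua
  a2 <- biology_to_optics(s2, grid, opt)$mu_a - opt$baseline_mua
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
  opt0 <- opt
  opt0$baseline_mus600 <- 0
  opt0$baseline_mua <- 0
  z <- biology_to_optics(list(wbc_per_ul = 0, rbc_per_ul = 0, dilution = 0),
                         grid, opt0)
  expect_identical(z$mus_prime, rep(0, length(grid)))
  expect_identical(z$mu_a, rep(0, length(grid)))
})

test_that("dilution drives both coefficients monotonically toward baseline", {
  grid <- seq(475, 655, by = 10)
  opt <- cohort_config()$optics
  dils <- seq(0, 1, by = 0.2)
  mus600 <- vapply(dils, function(d) {
    biology_to_optics(list(wbc_per_ul = 80e3, rbc_per_ul = 50e3, dilution = d),
                      c(599, 600, 601), opt)$mus_prime[2]
  }, numeric(1))
  mua580 <- vapply(dils, function(d) {
    biology_to_optics(list(wbc_per_ul = 80e3, rbc_per_ul = 50e3, dilution = d),
                      c(579, 580, 581), opt)$mu_a[2]
  }, numeric(1))
  expect_true(all(diff(mus600) < 0))
  expect_true(all(diff(mua580) < 0))
  expect_equal(mus600[length(dils)], opt$baseline_mus600, tolerance = 1e-12)
  expect_equal(mua580[length(dils)], opt$baseline_mua, tolerance = 1e-12)
})

test_that("noiseless single-sample pipeline equals the analytic biomarkers", {
  cfg <- quiet_config(n_infected = 1, n_noninfected = 0, master_seed = 3)
  bm <- cohort_biomarkers(cfg)
  state <- sample_cohort(cfg)[1, ]
  props <- biology_to_optics(state, cfg$acquisition$wavelengths_nm,
                             cfg$optics)
  truth <- diffuse_reflectance(props, check_validity = FALSE)
  direct <- extract_biomarkers(truth)
  expect_equal(bm$r490_600, direct$r490_600, tolerance = 1e-9)
  expect_equal(bm$r580_600, direct$r580_600, tolerance = 1e-9)
})

test_that("simulated cohorts land on disk with the documented layout", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(master_seed = 21)
  res <- simulate_cohort(cfg, dir)
  expect_identical(nrow(res$lab), 18L)
  expect_identical(sum(res$manifest$role == "sample"), 54L)
  expect_identical(sum(res$manifest$role == "background"), 18L)
  expect_identical(sum(res$manifest$role == "standard"), 1L)
  expect_true(file.exists(file.path(dir, "lab.csv")))
  expect_true(all(file.exists(file.path(dir, res$manifest$file))))
  # lab counts are post-dilution (never above native)
  states <- sample_cohort(cfg)
  expect_true(all(res$lab$wbc_per_ul <= states$wbc_per_ul + 1e-9))
})

test_that("calibrating the written files reproduces the in-memory pipeline", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_infected = 2, n_noninfected = 3, master_seed = 8)
  simulate_cohort(cfg, dir)
  from_disk <- calibrate_manifest(file.path(dir, "manifest.csv"))
  in_memory <- cohort_biomarkers(cfg)
  expect_equal(from_disk$r490_600,
               in_memory$r490_600[match(from_disk$sample_id,
                                        in_memory$sample_id)],
               tolerance = 1e-12)
  expect_equal(from_disk$r580_600,
               in_memory$r580_600[match(from_disk$sample_id,
                                        in_memory$sample_id)],
               tolerance = 1e-12)
})

test_that("configuration validation names unknown keys and bad values", {
  expect_error(cohort_config(optics = list(bead_size = 1)), "bead_size")
  expect_error(cohort_config(infected = list(wbc_sdlog = -1)), "spread")
  expect_error(cohort_config(noninfected = list(prob_bloody = 2)),
               "probabilit")
  cfg <- cohort_config(optics = list(beads_per_wbc = 80))
  expect_identical(cfg$optics$beads_per_wbc, 80)
  expect_identical(cfg$optics$bead_diameter_um, 0.75) # untouched default
  scaled <- scale_cohort(cohort_config(), 200)
  expect_identical(scaled$n_infected + scaled$n_noninfected, 200L)
  expect_identical(scaled$n_infected, 56L)
})

test_that("run configuration files are schema-checked", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cohort:", "  n_infected: 3", "  noninfected:",
               "    prob_bloody: 0.5", "analysis:", "  holm: true"), p)
  cfg <- read_run_config(p)
  expect_identical(cfg$cohort$n_infected, 3L)
  expect_identical(cfg$cohort$noninfected$prob_bloody, 0.5)
  expect_true(cfg$analysis$holm)
  writeLines(c("cohort:", "  n_samples: 3"), p)
  expect_error(read_run_config(p), "n_samples")
  writeLines("unknown_block: 1", p)
  expect_error(read_run_config(p), "unknown_block")
  expect_error(read_run_config(file.path(tempdir(), "missing.yaml")),
               "not found")
})
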