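test_that("worked rank-sum examples match hand enumeration", {
  t1 <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(t1$p.value, 1 / 3)
  expect_identical(t1$statistic, 0)
  # completely separated 5 vs 13: only the two extreme assignments
  t2 <- rank_sum_test(1:5, 6:18)
  expect_identical(t2$statistic, 0)
  expect_equal(t2$p.value, 2 / choose(18, 5))
  expect_identical(t2$direction, -1)
  t3 <- rank_sum_test(14:18, 1:13)
  expect_identical(t3$statistic, 65)
  expect_equal(t3$p.value, 2 / choose(18, 5))
  # identical groups: maximal p, no direction
  t4 <- rank_sum_test(rep(2, 4), rep(2, 6))
  expect_equal(t4$p.value, 1)
  expect_identical(t4$direction, 0)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("exact rank-sum p equals brute-force enumeration for n <= 10", {
  withr::with_seed(17, {
    for (rep in 1:30) {
      n1 <- sample(1:5, 1)
      n2 <- sample(1:(10 - n1), 1)
      # draws from a small integer support force plenty of ties
      x <- sample(1:4, n1, replace = TRUE)
      y <- sample(1:4, n2, replace = TRUE)
      expect_equal(rank_sum_test(x, y)$p.value, enumerate_mw_p(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact rank-sum agrees with wilcox.test when there are no ties", {
  withr::with_seed(23, {
    for (rep in 1:15) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- stats::rnorm(n1); y <- stats::rnorm(n2)
      ours <- rank_sum_test(x, y)
      ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
      expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
      expect_equal(ours$statistic, unname(ref$statistic))
    }
  })
})

test_that("large-sample rank-sum falls back to a tie-corrected normal", {
  withr::with_seed(3, {
    x <- stats::rnorm(20, 1)
    y <- stats::rnorm(20)
    ours <- rank_sum_test(x, y)
    expect_false(ours$exact)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  })
})

test_that("Spearman rho hits the monotone extremes and rejects degenerates", {
  x <- c(3, 8, 1, 9, 4)
  expect_equal(spearman_test(x, exp(x))$statistic, 1)
  expect_equal(spearman_test(x, -x)$statistic, -1)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 1:2), ">= 3")
})

test_that("rho is invariant under strictly monotone transforms", {
  withr::with_seed(5, {
    x <- stats::rnorm(8)
    y <- stats::rnorm(8)
    base <- spearman_test(x, y)
    warped <- spearman_test(exp(x), atan(y))
    expect_identical(base$statistic, warped$statistic)
    expect_identical(base$p.value, warped$p.value)
  })
})

test_that("exact Spearman p equals brute-force enumeration", {
  withr::with_seed(29, {
    for (n in c(4, 5, 6)) {
      for (rep in 1:4) {
        x <- sample(1:3, n, replace = TRUE) + stats::runif(n, 0, 0.1)
        y <- stats::rnorm(n)
        expect_equal(spearman_test(x, y)$p.value, enumerate_spearman_p(x, y),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("Monte-Carlo Spearman p is seeded, stable and near the t-approximation", {
  withr::with_seed(31, {
    x <- stats::rnorm(30)
    y <- x + stats::rnorm(30, sd = 2)
    a <- spearman_test(x, y, mc_draws = 2e4, seed = 7)
    b <- spearman_test(x, y, mc_draws = 2e4, seed = 7)
    c <- spearman_test(x, y, mc_draws = 2e4, seed = 8)
    expect_identical(a$p.value, b$p.value)
    expect_false(a$exact)
    expect_lt(abs(a$p.value - a$p_asymptotic), 0.02)
    expect_false(identical(a$p.value, c$p.value))
  })
})

test_that("null p-values are uniform for both tests", {
  # empirical CDF of the p-value must hug the diagonal (KS distance <= 0.05);
  # the Spearman check exercises the Monte-Carlo permutation path, whose
  # p-values are nearly continuous (the exact path is discrete by nature and
  # is pinned against enumeration elsewhere)
  ks <- function(p) {
    p <- sort(p)
    n <- length(p)
    max(abs(p - seq_len(n) / n), abs(p - (seq_len(n) - 1) / n))
  }
  withr::with_seed(41, {
    p_mw <- replicate(2000, {
      rank_sum_test(stats::rnorm(12), stats::rnorm(12))$p.value
    })
    expect_lt(ks(p_mw), 0.05)
    p_sp <- vapply(1:2000, function(i) {
      spearman_test(stats::rnorm(12), stats::rnorm(12), mc_draws = 999,
                    seed = i)$p.value
    }, numeric(1))
    expect_lt(ks(p_sp), 0.05)
  })
})

test_that("cohort analysis assembles tests, summaries and safeguards", {
  cfg <- cohort_config(master_seed = 13)
  bm <- cohort_biomarkers(cfg)
  rep <- analyze_cohort(bm, mc_draws = 5000)
  expect_s3_class(rep, "drs_stat_report")
  expect_named(rep$correlations,
               c("r490_600_vs_wbc", "r490_600_vs_rbc",
                 "r580_600_vs_wbc", "r580_600_vs_rbc"))
  expect_match(rep$group_comparisons$r490_600$method, "Mann-Whitney")
  expect_true(all(vapply(rep$correlations, function(s) {
    is.na(s$statistic) || (s$statistic >= -1 && s$statistic <= 1)
  }, logical(1))))
  expect_identical(rep$n_infected, 5L)
  s <- rep$summaries$r490_600$infected
  expect_true(s$iqr[1] <= s$median && s$median <= s$iqr[2])
  # degenerate cohort: identical biomarkers
  degen <- bm
  degen$r490_600 <- 1
  degen$r580_600 <- 1
  rep2 <- analyze_cohort(degen, mc_draws = 1000)
  expect_equal(rep2$group_comparisons$r490_600$p.value, 1)
  expect_true(is.na(rep2$correlations$r490_600_vs_wbc$statistic))
  expect_match(rep2$correlations$r490_600_vs_wbc$method, "undefined")
  # duplicate ids break the one-to-one join
  dup <- rbind(bm, bm[1, ])
  expect_error(analyze_cohort(dup), "unique")
  expect_error(analyze_cohort(bm[bm$infected, ]), "both infected")
  # Holm flag reports adjusted p-values alongside
  rep3 <- analyze_cohort(bm, mc_draws = 1000, holm = TRUE)
  expect_true(all(unlist(rep3$p_holm) >=
                    c(rep3$group_comparisons$r490_600$p.value)))
})

test_that("reports serialise to JSON with bare numbers", {
  cfg <- cohort_config(master_seed = 2)
  rep <- analyze_cohort(cohort_biomarkers(cfg), mc_draws = 1000)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_true(is.numeric(parsed$group_comparisons$r490_600$p.value))
  expect_identical(parsed$n_infected, 5L)
})
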