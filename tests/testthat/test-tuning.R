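# Gaussian/line fits, axis comparison, distance and size effects.

test_that("noiseless Gaussian curves are recovered exactly", {
  x <- 0:6
  y <- 0.1 + 0.9 * exp(-(x - 2)^2 / (2 * 1^2))
  ft <- fit_gaussian(y, x, axis = "linear")
  expect_true(ft$converged)
  expect_equal(ft$center, 2, tolerance = 1e-6)
  expect_equal(ft$width_sd, 1, tolerance = 1e-6)
  expect_equal(ft$r_squared, 1, tolerance = 1e-9)
})

test_that("goodness of fit is invariant to positive rescaling of the curve", {
  set.seed(51)
  y <- exp(-((0:4) - 1.5)^2 / 3) + rnorm(5, 0, 0.05)
  f1 <- fit_gaussian(y, 0:4)
  f2 <- fit_gaussian(7.3 * y, 0:4)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-6)
})

test_that("a monotone-decreasing zero curve fits with center at or below zero", {
  y <- c(1, 0.55, 0.3, 0.17, 0.1)
  ft <- fit_gaussian(y, 0:4, axis = "linear")
  expect_true(ft$converged)
  expect_lte(ft$center, 0 + 1e-6)
})

test_that("fit quality degrades monotonically with noise on average", {
  set.seed(52)
  x <- 0:4
  base <- exp(-(x - 2)^2 / 2)
  mean_r2 <- vapply(c(0.02, 0.1, 0.3), function(s) {
    r2 <- replicate(40, fit_gaussian(base + rnorm(5, 0, s), x)$r_squared)
    mean(r2[is.finite(r2)])
  }, 0)
  expect_true(all(diff(mean_r2) < 0))
})

test_that("line fits: collinear r2 = 1, flat slope 0, log axis wins for exponential decay", {
  lf <- fit_line(c(1, 3, 5, 7, 9), 0:4)
  expect_equal(lf$r_squared, 1, tolerance = 1e-12)
  expect_equal(lf$slope, 2, tolerance = 1e-12)
  expect_equal(fit_line(rep(2, 5), 0:4)$slope, 0, tolerance = 1e-12)
  # y = 2^(-log2(x+1)) is exactly linear on the log axis
  y <- 2^(-log_axis(0:4))
  expect_gt(fit_line(y, 0:4, axis = "log")$r_squared,
            fit_line(y, 0:4, axis = "linear")$r_squared)
})

test_that("the paired Wilcoxon helper treats identical samples as no effect", {
  w <- nzero:::wilcoxon_paired(1:10, 1:10)
  expect_equal(w$p.value, 1)
  w2 <- nzero:::wilcoxon_paired(1:10 + 0.5, 1:10)
  expect_lt(w2$p.value, 0.01)
})

test_that("population curves average normalized tuning within preference groups", {
  tab <- fake_manifest(per_cell = 2)
  curve <- exp(-((0:4) - 2)^2 / 2)
  unit <- matrix(rep(curve[tab$numerosity + 1], each = 2), 2, byrow = FALSE)
  prof <- tuning_profiles(unit, tab)
  pop <- suppressWarnings(population_curves(prof))  # only one group present
  expect_equal(unname(pop$curves[1, ]),
               unname((curve - min(curve)) / (max(curve) - min(curve))))
  expect_true(all(pop$se == 0))
  # planted groups peak at their own preferred numerosity
  set.seed(53)
  pref <- rep(0:4, each = 30)
  acts <- synth_tuned_acts(fake_manifest(per_cell = 8), pref, width = 0.8,
                           noise_sd = 0.02)
  prof2 <- tuning_profiles(acts, fake_manifest(per_cell = 8))
  pop2 <- population_curves(prof2)
  peaks <- pop2$numerosities[apply(pop2$curves, 1, which.max)]
  expect_equal(as.numeric(peaks), as.numeric(pop2$preferred))
})

test_that("distance and size effects are detected in planted populations", {
  set.seed(54)
  tab <- fake_manifest(per_cell = 8)
  # zero-tuned units with monotone decay plus mid-range units of growing width
  pref <- c(rep(0, 100), rep(1:4, each = 25))
  width <- ifelse(pref == 0, 0.8, 0.4 + 0.35 * pref)  # width grows with preference
  acts <- do.call(rbind, lapply(seq_along(pref), function(i)
    synth_tuned_acts(tab, pref[i], width = width[i], noise_sd = 0.03,
                     axis = "log")))
  prof <- tuning_profiles(acts, tab)
  eff <- distance_size_effects(prof, axis = "log")
  expect_lt(eff$distance$p.value[eff$distance$comparison == "1_vs_2"], 0.01)
  expect_lt(eff$distance$p.value[eff$distance$comparison == "2_vs_3"], 0.01)
  expect_gt(eff$size_r, 0.5)
  expect_lt(eff$size_p, 1e-4)
})

test_that("distance tests are skipped with a warning when the zero group is tiny", {
  set.seed(55)
  tab <- fake_manifest(per_cell = 8)
  acts <- synth_tuned_acts(tab, rep(2:4, each = 10), noise_sd = 0.02)
  expect_warning(eff <- distance_size_effects(tuning_profiles(acts, tab)),
                 "skipped")
  expect_null(eff$distance)
})

test_that("the axis comparison discriminates log-Gaussian from linear-Gaussian tuning", {
  set.seed(56)
  tab <- fake_manifest(per_cell = 8)
  pref <- rep(0:4, each = 20)
  log_pop <- synth_tuned_acts(tab, pref, width = 0.7, noise_sd = 0.02,
                              axis = "log")
  lin_pop <- synth_tuned_acts(tab, pref, width = 1.2, noise_sd = 0.02,
                              axis = "linear")
  sc_log <- scale_comparison(tuning_profiles(log_pop, tab))
  sc_lin <- scale_comparison(tuning_profiles(lin_pop, tab))
  expect_gt(sc_log$mean_r2_log, sc_log$mean_r2_linear)
  expect_lt(sc_log$p.value, 0.01)
  expect_gt(sc_lin$mean_r2_linear, sc_lin$mean_r2_log)
  # identical fits on both axes => no effect
  same <- nzero:::wilcoxon_paired(rep(0.9, 10), rep(0.9, 10))
  expect_equal(same$p.value, 1)
  # too few pairs are refused
  one <- matrix(exp(-((0:4) - 2)^2), 1)
  expect_error(scale_comparison(one, 0:4), "at least 5")
})
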