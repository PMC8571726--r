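# Two-way ANOVA screen, tuning profiles and the repetition study.

test_that("the vectorized two-way ANOVA matches stats::aov on random balanced designs", {
  set.seed(31)
  tab <- fake_manifest(per_cell = 6)
  for (rep in 1:8) {
    y <- rnorm(nrow(tab)) +
      sample(c(0, 0.5), 1) * tab$numerosity +
      sample(c(0, 0.4), 1) * as.integer(factor(tab$set))
    res <- nzero:::anova_two_way_matrix(matrix(y, 1), tab$numerosity, tab$set)
    ref <- summary(aov(y ~ factor(numerosity) * factor(set), data = tab))[[1]]
    expect_equal(res$p_a, ref[["Pr(>F)"]][1], tolerance = 1e-8)
    expect_equal(res$p_b, ref[["Pr(>F)"]][2], tolerance = 1e-8)
    expect_equal(res$p_ab, ref[["Pr(>F)"]][3], tolerance = 1e-8)
  }
})

test_that("the screen labels planted numerosity-tuned units and excludes constants", {
  set.seed(32)
  tab <- fake_manifest(per_cell = 40)
  tuned <- matrix(tab$numerosity + rnorm(nrow(tab), 0, 0.3), 1)
  const <- matrix(1, 1, nrow(tab))
  noise <- synth_noise_acts(tab, 1)
  scr <- screen_selectivity(rbind(tuned, const, noise), tab)
  expect_true(scr$anova$selective[1])
  expect_lt(scr$anova$p_numerosity[1], 0.01)
  expect_true(scr$anova$excluded_constant[2])
  expect_false(scr$anova$selective[2])
  expect_identical(scr$n_units_total, 3L)
})

test_that("a set-driven unit is not numerosity-selective", {
  set.seed(33)
  tab <- fake_manifest(per_cell = 40)
  unit <- matrix(2 * as.integer(factor(tab$set)) + rnorm(nrow(tab), 0, 0.3), 1)
  scr <- screen_selectivity(unit, tab)
  expect_false(scr$anova$selective[1])
})

test_that("under pure noise the compound criterion fires well below 10%", {
  set.seed(34)
  tab <- fake_manifest(per_cell = 40)
  scr <- screen_selectivity(synth_noise_acts(tab, 3000), tab)
  expect_lt(scr$fraction_selective, 0.05)
  expect_gt(scr$n_selective, 0)  # but it is not degenerate either
})

test_that("screen results are invariant to unit and stimulus reordering", {
  set.seed(35)
  tab <- fake_manifest(per_cell = 10)
  acts <- rbind(synth_tuned_acts(tab, preferred = c(0, 2, 4), noise_sd = 0.05),
                synth_noise_acts(tab, 5))
  scr <- screen_selectivity(acts, tab)
  perm_u <- sample(nrow(acts))
  scr_u <- screen_selectivity(acts[perm_u, ], tab)
  expect_identical(scr$fraction_selective, scr_u$fraction_selective)
  expect_identical(sort(perm_u[scr_u$selective_units]), scr$selective_units)
  perm_s <- sample(ncol(acts))
  scr_s <- screen_selectivity(acts[, perm_s], tab[perm_s, ])
  expect_equal(scr$anova$p_numerosity, scr_s$anova$p_numerosity, tolerance = 1e-12)
})

test_that("unbalanced or under-replicated designs are refused", {
  tab <- fake_manifest(per_cell = 2)
  acts <- synth_noise_acts(tab, 2)
  expect_error(screen_selectivity(acts[, -1, drop = FALSE], tab[-1, ]),
               "unbalanced")
  tab1 <- fake_manifest(per_cell = 1)
  expect_error(screen_selectivity(synth_noise_acts(tab1, 2), tab1),
               "at least 2")
})

test_that("tuning profiles compute means, argmax preference and min-max normalization", {
  tab <- fake_manifest(per_cell = 2)
  # deterministic unit: responds 5,4,3,2,1 to numerosities 0-4
  unit <- matrix((5:1)[tab$numerosity + 1], 1)
  prof <- tuning_profiles(unit, tab)
  expect_identical(prof$preferred, 0)
  expect_equal(unname(prof$normalized[1, ]), c(1, 0.75, 0.5, 0.25, 0))
  # tie at the maximum resolves to the smaller numerosity
  tied <- matrix(c(3, 3, 1, 1, 1)[tab$numerosity + 1], 1)
  ptie <- tuning_profiles(tied, tab)
  expect_identical(ptie$preferred, 0)
  expect_identical(ptie$n_ties, 1L)
  # flat units are dropped with a warning
  expect_warning(
    expect_error(tuning_profiles(matrix(1, 1, nrow(tab)), tab), "non-flat"),
    "flat")
})

test_that("planted tuned populations are recovered with correct preferences", {
  set.seed(36)
  tab <- fake_manifest(per_cell = 40)
  pref <- rep(0:4, each = 40)
  acts <- rbind(synth_tuned_acts(tab, pref, width = 1, noise_sd = 0.05),
                synth_noise_acts(tab, 200))
  scr <- screen_selectivity(acts, tab)
  planted <- seq_along(pref)
  hits <- intersect(scr$selective_units, planted)
  expect_gte(length(hits) / length(planted), 0.95)
  prof <- tuning_profiles(acts, tab, units = hits)
  expect_gte(mean(prof$preferred == pref[hits]), 0.95)
})

test_that("the repetition study is reproducible and summarizes correctly", {
  s1 <- untrained_repetition_study(tiny_architecture(), n_reps = 2,
                                   n_images = 60, seed = 42)
  s2 <- untrained_repetition_study(tiny_architecture(), n_reps = 2,
                                   n_images = 60, seed = 42)
  expect_identical(s1$per_rep, s2$per_rep)
  expect_identical(s1$preferred_histogram, s2$preferred_histogram)
  expect_identical(nrow(s1$per_rep), 2L)
  expect_equal(unname(s1$mean["fraction_selective"]),
               mean(s1$per_rep$fraction_selective))
  expect_true(all(rowSums(s1$preferred_histogram) ==
                  round(s1$per_rep$fraction_selective * 784)))
  expect_error(untrained_repetition_study(tiny_architecture(), n_reps = 0),
               "at least 1")
})
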