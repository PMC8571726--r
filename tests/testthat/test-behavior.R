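# Matching task, categorization and silencing, exercised on synthetic codes.

test_that("matching trials are balanced, seeded and respect set restrictions", {
  rec <- onehot_recorder()
  tr <- build_matching_trials(rec, n_trials = 200, seed = 3)
  expect_identical(sum(tr$trials$label == "same"), 100L)
  expect_identical(sum(tr$trials$label == "different"), 100L)
  expect_true(all((tr$trials$sample_num == tr$trials$test_num) ==
                  (tr$trials$label == "same")))
  tr2 <- build_matching_trials(rec, n_trials = 200, seed = 3)
  expect_identical(tr$trials, tr2$trials)
  expect_identical(tr$sample_acts, tr2$sample_acts)
  only1 <- build_matching_trials(rec, n_trials = 40, sets = "control1", seed = 4)
  expect_true(all(only1$images$set == "control1"))
  expect_error(build_matching_trials(rec, n_trials = 10, numerosities = integer(0)),
               "empty")
})

test_that("a perfect one-hot code supports near-perfect matching; shuffled labels give chance", {
  rec <- onehot_recorder()
  tr <- build_matching_trials(rec, n_trials = 300, seed = 5)
  te <- build_matching_trials(rec, n_trials = 300, seed = 6)
  m <- train_test_matching(tr, te)
  expect_gt(m$accuracy, 0.97)
  expect_gt(m$accuracy_zero, 0.97)
  # diagonal of the performance function is its row-wise maximum
  for (s in seq_len(nrow(m$performance)))
    expect_identical(unname(which.max(m$performance[s, ])), s)
  # label shuffling destroys the mapping; predictions are granular at the
  # level of the 25 numerosity patterns, so average a few shuffles
  set.seed(7)
  accs <- vapply(1:5, function(i) {
    tr_sh <- tr
    tr_sh$trials$label <- sample(tr_sh$trials$label)
    train_test_matching(tr_sh, te)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 2.5 * 0.1 / sqrt(5))
})

test_that("a graded code shows the numerical distance effect at zero", {
  rec <- graded_recorder(width = 1.0, noise_sd = 0.25)
  ms <- matching_study(rec, n_reps = 3, n_train = 300, n_test = 300, seed = 11)
  perf <- ms$performance_mean
  expect_gt(perf["0", "1"], perf["0", "2"])  # zero confused more with 1 than 2
  expect_gt(perf["0", "0"], perf["0", "1"])  # and matched correctly most often
})

test_that("performance fits detect planted size effects and log symmetry", {
  nums <- 0:4
  widths <- 0.5 + 0.3 * nums
  perf <- t(vapply(seq_along(nums), function(i)
    exp(-(nums - nums[i])^2 / (2 * widths[i]^2)), numeric(5)))
  dimnames(perf) <- list(sample = nums, test = nums)
  pf <- performance_fits(perf)
  expect_gt(pf$size_r, 0.9)
  # functions symmetric on the log axis fit better there
  logperf <- t(vapply(seq_along(nums), function(i)
    exp(-(log_axis(nums) - log_axis(nums[i]))^2 / (2 * 0.5^2)), numeric(5)))
  dimnames(logperf) <- dimnames(perf)
  pf_log <- performance_fits(logperf)
  expect_gt(pf_log$scale$mean_r2_log, pf_log$scale$mean_r2_linear)
  # a flat function is flagged and excluded
  flat <- perf; flat[2, ] <- 0.5
  pf_flat <- performance_fits(flat)
  expect_true(2 %in% pf_flat$excluded)
})

test_that("categorization is accurate on a clean code with row-consistent confusions", {
  set.seed(21)
  labels <- rep(0:4, each = 40)
  acts <- outer(0:4, labels, function(a, b) as.numeric(a == b)) +
          matrix(rnorm(5 * 200, 0, 0.02), 5)
  ct <- categorize_numerosity(acts, labels, seed = 2)
  expect_gt(ct$accuracy, 0.95)
  expect_equal(unname(rowSums(ct$confusion)),
               unname(as.numeric(table(labels[-ct$train_ix]))))
  expect_equal(ct$accuracy, sum(diag(ct$confusion)) / sum(ct$confusion))
  # silencing nothing is identical to the intact condition
  ct0 <- categorize_numerosity(acts, labels, silence = integer(0), seed = 2)
  expect_identical(ct$confusion, ct0$confusion)
  expect_error(categorize_numerosity(acts, labels, silence = 99L), "index")
  # shuffled labels: five balanced classes decode at ~20% chance
  set.seed(22)
  ct_sh <- categorize_numerosity(acts, sample(labels), seed = 2)
  expect_lt(abs(ct_sh$accuracy - 0.2), 0.12)
})

test_that("silencing designated zero units collapses zero recognition only", {
  set.seed(23)
  n_per <- 8
  owner <- rep(0:4, each = n_per)
  labels <- rep(0:4, each = 60)
  acts <- outer(owner, labels, function(o, b) as.numeric(o == b)) +
          matrix(rnorm(length(owner) * length(labels), 0, 0.05), length(owner))
  zero_units <- which(owner == 0)
  intact <- categorize_numerosity(acts, labels, seed = 4)
  sil <- categorize_numerosity(acts, labels, silence = zero_units, seed = 4)
  expect_gt(intact$tpr["0"], 0.9)
  expect_lt(sil$tpr["0"], 0.4)                      # toward 20% chance
  for (k in as.character(1:4))
    expect_gt(sil$tpr[k], intact$tpr[k] - 0.1)      # others unaffected
  # matched random silencing of nonzero-tuned units leaves zero intact
  set.seed(5)
  rnd <- sample(which(owner != 0), length(zero_units))
  sil_r <- categorize_numerosity(acts, labels, silence = rnd, seed = 4)
  expect_gt(sil_r$tpr["0"], 0.9)
  # silencing all units tuned to numerosity 2 impairs class 2 specifically
  sil2 <- categorize_numerosity(acts, labels, silence = which(owner == 2), seed = 4)
  expect_lt(sil2$tpr["2"], 0.4)
  expect_gt(sil2$tpr["0"], 0.9)
})

test_that("the silencing study detects the zero-unit contribution across repetitions", {
  rec <- zero_code_recorder(n_per_class = 6, noise_sd = 0.05)
  owner <- rep(0:4, each = 6)
  st <- silencing_study(rec, units = seq_along(owner), preferred = owner,
                        conditions = list(
                          silencing_condition("zero_tuned"),
                          silencing_condition("random_nonzero_matched"),
                          silencing_condition("all_tuned_to_k", k = 3)),
                        n_reps = 6, n_trials = 120, seed = 31)
  tests <- st$tests
  expect_lt(tests$p.value[tests$condition == "zero_tuned"], 0.05)
  expect_gt(tests$p.value[tests$condition == "random_nonzero_matched"], 0.05)
  expect_lt(tests$p.value[tests$condition == "all_tuned_to_3"], 0.05)
  expect_lt(mean(st$zero_tpr[, "zero_tuned"]), 0.4)
  expect_gt(mean(st$zero_tpr[, "random_nonzero_matched"]), 0.85)
  expect_lt(mean(st$tpr[, "3", "all_tuned_to_3"]), 0.4)
  expect_error(silencing_study(rec, seq_along(owner), owner, n_reps = 2),
               "at least 5")
})
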