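#' @name behavior
#' @title Behavioral readout: matching, categorization, silencing
#'
#' @description
#' The "behavioral output" of the network is probed by training support
#' vector machine classifiers on the activity of numerosity-selective units:
#' a same/different matching task (radial-basis kernel - the library default;
#' an equality judgment is not linearly separable - unit cost, features =
#' concatenated sample and test response vectors) and a multi-class
#' one-vs-one categorization of numerosity. Unit silencing (zeroing selected
#' units' activity at classifier test time only) probes the functional
#' contribution of zero-tuned units.
NULL

#' Recorder over a fitted network
#'
#' Wraps a network into the `record_fn(specs, seed)` interface used by the
#' trial builders: it presents each stimulus image and returns final-layer
#' unit responses (with multiplicative noise by default).
#'
#' @param net a `nzero_network`.
#' @param noise [noise_params()].
#' @param layer_index layer to record (default: final feature layer).
#' @return A function `(specs, seed) -> units x stimuli matrix`.
#' @export
network_recorder <- function(net, noise = noise_params(),
                             layer_index = final_feature_layer(net)) {
  force(net); force(noise); force(layer_index)
  function(specs, seed) {
    forward_record(net, lapply(specs, `[[`, "image"),
                   layer_index = layer_index, noise = noise, seed = seed)$values
  }
}

#' Build matching-task trials
#'
#' Generates freshly rendered image pairs for the same/different numerosity
#' matching task, balanced 50/50 between "same" and "different" trials, with
#' numerosities sampled uniformly and stimulus sets sampled uniformly from
#' `sets`, and records unit responses to every image.
#'
#' @param record_fn function `(specs, seed)` returning a units x stimuli
#'   response matrix; see [network_recorder()].
#' @param n_trials number of trials.
#' @param numerosities candidate numerosities.
#' @param sets stimulus sets to draw from (restrict to a single control set
#'   for the control evaluations).
#' @param image_size stimulus size in pixels.
#' @param seed integer seed (stimulus geometry, trial composition, noise).
#' @return A list of class `nzero_trials`: `trials` (data frame with
#'   `trial`, `sample_num`, `test_num`, `label`), `sample_acts`, `test_acts`
#'   (units x trials matrices), `images` (per-image metadata incl. numerosity)
#'   and `image_acts` (units x images, sample images then test images).
#' @export
build_matching_trials <- function(record_fn, n_trials = 600,
                                  numerosities = 0:4, sets = STIM_SETS,
                                  image_size = 224, seed = 1L) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (!length(numerosities)) stop("numerosity range is empty")
  if (length(numerosities) < 2) stop("need at least 2 numerosities for 'different' trials")
  set.seed(seed)
  n_same <- n_trials %/% 2
  sample_num <- sample(numerosities, n_trials, replace = TRUE)
  test_num <- sample_num
  diff_ix <- seq_len(n_trials) > n_same
  test_num[diff_ix] <- vapply(sample_num[diff_ix], function(q)
    sample(setdiff(numerosities, q), 1), numeric(1))
  ord <- sample.int(n_trials)
  sample_num <- sample_num[ord]; test_num <- test_num[ord]
  label <- ifelse(sample_num == test_num, "same", "different")

  pick_set <- function(n) sample(sets, n, replace = TRUE)
  img_tab <- data.frame(
    image_id = seq_len(2 * n_trials),
    trial = rep(seq_len(n_trials), 2),
    role = rep(c("sample", "test"), each = n_trials),
    numerosity = c(sample_num, test_num),
    set = c(pick_set(n_trials), pick_set(n_trials))
  )
  specs <- vector("list", nrow(img_tab))
  for (i in seq_len(nrow(img_tab)))
    specs[[i]] <- generate_stimulus(img_tab$numerosity[i], img_tab$set[i],
                                    image_size = image_size)
  acts <- record_fn(specs, sample.int(.Machine$integer.max, 1))
  structure(list(
    trials = data.frame(trial = seq_len(n_trials), sample_num = sample_num,
                        test_num = test_num, label = label),
    sample_acts = acts[, seq_len(n_trials), drop = FALSE],
    test_acts = acts[, n_trials + seq_len(n_trials), drop = FALSE],
    images = img_tab, image_acts = acts,
    numerosities = sort(unique(numerosities)), seed = seed
  ), class = "nzero_trials")
}

trial_features <- function(tr, units) {
  t(rbind(tr$sample_acts[units, , drop = FALSE],
          tr$test_acts[units, , drop = FALSE]))
}

# radial-kernel bandwidth following the variance-scaled convention
# gamma = 1 / (n_features * var(X)), which self-normalizes to the feature
# scale (pooled element variance)
gamma_scale <- function(X) {
  v <- stats::var(as.vector(X))
  1 / (ncol(X) * max(v, .Machine$double.eps))
}

#' Train and test the same/different matching classifier
#'
#' Trains an SVM (radial kernel, cost 1) on the concatenated selective-unit response
#' vectors of the sample and test image of each training trial, then
#' evaluates it on independent test trials: overall accuracy, accuracy on
#' trials involving numerosity 0, and the performance tuning functions
#' (probability of predicting "same" per sample/test numerosity pair).
#'
#' @param trials_train,trials_test `nzero_trials` objects.
#' @param units integer ids of units used as classifier input (the
#'   numerosity-selective set); default all units.
#' @return A list of class `nzero_matching`: `accuracy`, `accuracy_zero`,
#'   `performance` (sample x test matrix of P("same")), `predictions`,
#'   `trials` (test-trial table with predictions and correctness).
#' @export
train_test_matching <- function(trials_train, trials_test, units = NULL) {
  if (is.null(units)) units <- seq_len(nrow(trials_train$sample_acts))
  ytr <- factor(trials_train$trials$label, levels = c("different", "same"))
  if (nlevels(droplevels(ytr)) < 2)
    stop("training trials contain a single class; cannot fit the classifier")
  Xtr <- trial_features(trials_train, units)
  fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = 1,
                    gamma = gamma_scale(Xtr), scale = FALSE)
  pred <- stats::predict(fit, trial_features(trials_test, units))
  tt <- trials_test$trials
  tt$prediction <- as.character(pred)
  tt$correct <- tt$prediction == tt$label
  zero_ix <- tt$sample_num == 0 | tt$test_num == 0
  nums <- trials_test$numerosities
  perf <- matrix(NA_real_, length(nums), length(nums),
                 dimnames = list(sample = nums, test = nums))
  for (s in seq_along(nums)) for (u in seq_along(nums)) {
    ix <- tt$sample_num == nums[s] & tt$test_num == nums[u]
    if (any(ix)) perf[s, u] <- mean(tt$prediction[ix] == "same")
  }
  structure(list(accuracy = mean(tt$correct),
                 accuracy_zero = if (any(zero_ix)) mean(tt$correct[zero_ix]) else NA,
                 performance = perf, predictions = pred, trials = tt,
                 model = fit, units = units),
            class = "nzero_matching")
}

#' Repeat the matching study over fresh data generations
#'
#' Runs `build_matching_trials` + `train_test_matching` `n_reps` times with
#' derived seeds and aggregates accuracies and performance tuning functions
#' (mean and across-repetition standard error).
#'
#' @inheritParams build_matching_trials
#' @param units classifier input units.
#' @param n_reps number of data-generation repetitions (reference protocol:
#'   50).
#' @param n_train,n_test trials per repetition.
#' @param test_sets stimulus sets for the test trials (defaults to `sets`).
#' @return A list of class `nzero_matching_study` with per-rep accuracies,
#'   `performance_mean`, `performance_se`, and the final repetition's trials
#'   (for downstream categorization).
#' @export
matching_study <- function(record_fn, units = NULL, n_reps = 50,
                           n_train = 600, n_test = 600, numerosities = 0:4,
                           sets = STIM_SETS, test_sets = sets,
                           image_size = 224, seed = 1L) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 2 * n_reps), ncol = 2)
  acc <- acc0 <- numeric(n_reps)
  perf_list <- vector("list", n_reps)
  last <- NULL
  for (r in seq_len(n_reps)) {
    tr <- build_matching_trials(record_fn, n_train, numerosities, sets,
                                image_size, seed = seeds[r, 1])
    te <- build_matching_trials(record_fn, n_test, numerosities, test_sets,
                                image_size, seed = seeds[r, 2])
    m <- train_test_matching(tr, te, units)
    acc[r] <- m$accuracy; acc0[r] <- m$accuracy_zero
    perf_list[[r]] <- m$performance
    last <- list(train = tr, test = te, matching = m)
  }
  perf_arr <- simplify2array(perf_list)
  structure(list(
    n_reps = n_reps,
    accuracy = acc, accuracy_zero = acc0,
    mean_accuracy = mean(acc), mean_accuracy_zero = mean(acc0, na.rm = TRUE),
    performance_mean = apply(perf_arr, 1:2, mean, na.rm = TRUE),
    performance_se = apply(perf_arr, 1:2, function(z)
      stats::sd(z, na.rm = TRUE) / sqrt(sum(is.finite(z)))),
    numerosities = sort(unique(numerosities)), last = last, seed = seed
  ), class = "nzero_matching_study")
}

#' Gaussian characterization of performance tuning functions
#'
#' Fits a Gaussian to each sample numerosity's performance function, tests
#' the numerical size effect (Pearson correlation between fitted width and
#' sample numerosity) and compares linear- versus log-axis goodness of fit.
#'
#' @param performance sample x test matrix of P("same") (e.g.
#'   `performance_mean` of [matching_study()]).
#' @param numerosities numerosities indexing the matrix.
#' @return A list of class `nzero_performance_fits`: `fits` (per sample
#'   numerosity), `widths`, `size_r`, `size_p`, `scale` (linear-vs-log
#'   comparison or NULL when too few functions converge).
#' @export
performance_fits <- function(performance,
                             numerosities = as.numeric(rownames(performance))) {
  if (nrow(performance) < 3)
    stop("need performance functions for at least 3 sample numerosities")
  fits <- lapply(seq_len(nrow(performance)), function(i)
    fit_gaussian(performance[i, ], numerosities, axis = "linear"))
  widths <- vapply(fits, function(f)
    if (f$converged && is.finite(f$r_squared)) f$width_sd else NA_real_, 0)
  ok <- is.finite(widths)
  if (sum(ok) >= 3 && stats::sd(numerosities[ok]) > 0 && stats::sd(widths[ok]) > 0) {
    ct <- stats::cor.test(numerosities[ok], widths[ok])
    size_r <- unname(ct$estimate); size_p <- ct$p.value
  } else {
    size_r <- NA_real_; size_p <- NA_real_
  }
  scale <- tryCatch(
    scale_comparison(performance[ok, , drop = FALSE], numerosities,
                     min_pairs = min(5, sum(ok))),
    error = function(e) NULL)
  structure(list(fits = fits, widths = widths, size_r = size_r,
                 size_p = size_p, excluded = which(!ok), scale = scale),
            class = "nzero_performance_fits")
}

#' Define a unit-silencing condition
#'
#' @param mode one of `"none"`, `"zero_tuned"` (silence all zero-preferring
#'   units), `"random_nonzero_matched"` (a random set of non-zero-preferring
#'   units of equal size) or `"all_tuned_to_k"` (all units preferring
#'   numerosity `k`).
#' @param k target numerosity for `all_tuned_to_k`.
#' @return A list of class `nzero_silencing`.
#' @export
silencing_condition <- function(mode = c("none", "zero_tuned",
                                         "random_nonzero_matched",
                                         "all_tuned_to_k"), k = NULL) {
  mode <- match.arg(mode)
  if (mode == "all_tuned_to_k" && is.null(k))
    stop("all_tuned_to_k requires k")
  structure(list(mode = mode, k = k), class = "nzero_silencing")
}

# resolve a silencing condition to unit ids, given the preferred numerosity
# of every classifier-input unit (names = unit ids)
silenced_unit_ids <- function(condition, unit_ids, preferred) {
  stopifnot(length(unit_ids) == length(preferred))
  zero_ids <- unit_ids[preferred == 0]
  switch(condition$mode,
         none = integer(0),
         zero_tuned = zero_ids,
         random_nonzero_matched = {
           pool <- unit_ids[preferred != 0]
           if (length(pool) < length(zero_ids))
             stop("not enough nonzero-tuned units to match the zero-tuned count")
           sample(pool, length(zero_ids))
         },
         all_tuned_to_k = unit_ids[preferred == condition$k])
}

#' Multi-class numerosity categorization with optional silencing
#'
#' Trains a multi-class (one-vs-one) linear SVM to categorize images by
#' numerosity from selective-unit activity, using half of the correct-trial
#' images; tests on the held-out half and, when supplied, on error-trial
#' images. Silencing (zeroing the named units' activity) is applied at test
#' time only, never during training.
#'
#' @param acts units x images activation matrix (classifier-input units,
#'   e.g. the selective set).
#' @param labels numerosity of each image.
#' @param silence integer ids (row indices into `acts`) to zero at test time.
#' @param error_acts,error_labels optional error-trial images.
#' @param seed seed for the train/test split.
#' @return A list of class `nzero_categorization`: `confusion` (true x
#'   predicted counts), `rates` (row-normalized), `accuracy`, `tpr`
#'   (per-class true-positive rate), and the same for the error set
#'   (`confusion_error`, `accuracy_error`) when supplied.
#' @export
categorize_numerosity <- function(acts, labels, silence = integer(0),
                                  error_acts = NULL, error_labels = NULL,
                                  seed = 1L) {
  if (length(silence) && (any(silence < 1) || any(silence > nrow(acts))))
    stop("silenced unit ids must index rows of the activation matrix")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 numerosity classes")
  set.seed(seed)
  tr_ix <- sort(sample(seq_along(y), floor(length(y) / 2)))
  te_ix <- setdiff(seq_along(y), tr_ix)
  Xtr <- t(acts[, tr_ix, drop = FALSE])
  fit <- e1071::svm(Xtr, y[tr_ix], kernel = "radial", cost = 1,
                    gamma = gamma_scale(Xtr), scale = FALSE)
  apply_silence <- function(m) { m[silence, ] <- 0; m }
  evaluate <- function(m, yy) {
    pred <- stats::predict(fit, t(apply_silence(m)))
    cm <- table(true = factor(yy, levels = levels(y)),
                predicted = factor(pred, levels = levels(y)))
    rs <- rowSums(cm)
    list(confusion = cm,
         rates = sweep(cm, 1, pmax(rs, 1), "/"),
         accuracy = mean(as.character(pred) == as.character(yy)),
         tpr = ifelse(rs > 0, diag(cm) / rs, NA))
  }
  held <- evaluate(acts[, te_ix, drop = FALSE], y[te_ix])
  out <- list(confusion = held$confusion, rates = held$rates,
              accuracy = held$accuracy, tpr = held$tpr,
              silenced = silence, classes = as.numeric(levels(y)),
              train_ix = tr_ix)
  if (!is.null(error_acts) && length(error_labels)) {
    err <- evaluate(error_acts, error_labels)
    out$confusion_error <- err$confusion
    out$accuracy_error <- err$accuracy
    out$tpr_error <- err$tpr
  }
  structure(out, class = "nzero_categorization")
}

# deduplicated correct/error-trial image pools from a matching result
correct_trial_images <- function(trials, matching) {
  tt <- matching$trials
  pool <- function(ok) {
    tr_ids <- tt$trial[ok]
    ix <- trials$images$trial %in% tr_ids
    list(acts = trials$image_acts[, trials$images$image_id[ix], drop = FALSE],
         labels = trials$images$numerosity[ix])
  }
  list(correct = pool(tt$correct), error = pool(!tt$correct))
}

#' Silencing study across repetitions
#'
#' Repeats trial generation, matching, and categorization under a set of
#' silencing conditions, then compares per-condition zero true-positive
#' rates (and per-class rates for `all_tuned_to_k` conditions) against the
#' intact condition with paired Wilcoxon signed-rank tests across
#' repetitions.
#'
#' @param record_fn stimulus recorder; see [network_recorder()].
#' @param units classifier-input unit ids (the selective set).
#' @param preferred preferred numerosity of each unit in `units`.
#' @param conditions list of [silencing_condition()] objects; the intact
#'   (`"none"`) condition is always included first.
#' @param n_reps repetitions (>= 5 for the paired tests).
#' @param n_trials matching trials per repetition (train and test).
#' @param numerosities,sets,image_size stimulus plan.
#' @param seed master seed.
#' @return A list of class `nzero_silencing_study`: `zero_tpr` (rep x
#'   condition matrix), `tpr` (per condition: rep x class), `accuracy`,
#'   `tests` (paired Wilcoxon vs intact per condition).
#' @export
silencing_study <- function(record_fn, units, preferred,
                            conditions = list(
                              silencing_condition("zero_tuned"),
                              silencing_condition("random_nonzero_matched")),
                            n_reps = 10, n_trials = 600, numerosities = 0:4,
                            sets = STIM_SETS, image_size = 224, seed = 1L) {
  if (n_reps < 5) stop("silencing study needs at least 5 repetitions for the paired tests")
  conditions <- c(list(silencing_condition("none")), conditions)
  cond_names <- vapply(conditions, function(cn)
    if (cn$mode == "all_tuned_to_k") sprintf("all_tuned_to_%d", cn$k) else cn$mode,
    "")
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 4 * n_reps), ncol = 4)
  classes <- sort(unique(numerosities))
  zero_tpr <- matrix(NA_real_, n_reps, length(conditions),
                     dimnames = list(NULL, cond_names))
  acc <- zero_tpr
  tpr <- array(NA_real_, c(n_reps, length(classes), length(conditions)),
               dimnames = list(NULL, classes, cond_names))
  for (r in seq_len(n_reps)) {
    tr <- build_matching_trials(record_fn, n_trials, numerosities, sets,
                                image_size, seed = seeds[r, 1])
    te <- build_matching_trials(record_fn, n_trials, numerosities, sets,
                                image_size, seed = seeds[r, 2])
    m <- train_test_matching(tr, te, units)
    pools <- correct_trial_images(te, m)
    sub_acts <- pools$correct$acts[units, , drop = FALSE]
    set.seed(seeds[r, 3])
    for (ci in seq_along(conditions)) {
      sil <- silenced_unit_ids(conditions[[ci]], seq_along(units), preferred)
      ct <- categorize_numerosity(sub_acts, pools$correct$labels,
                                  silence = sil, seed = seeds[r, 4])
      zero_tpr[r, ci] <- ct$tpr[as.character(0)]
      acc[r, ci] <- ct$accuracy
      tpr[r, , ci] <- ct$tpr[as.character(classes)]
    }
  }
  tests <- lapply(seq_along(conditions)[-1], function(ci) {
    cn <- conditions[[ci]]
    if (cn$mode == "all_tuned_to_k") {
      w <- wilcoxon_paired(tpr[, as.character(cn$k), 1],
                           tpr[, as.character(cn$k), ci])
      data.frame(condition = cond_names[ci], class = cn$k,
                 statistic = w$statistic, p.value = w$p.value)
    } else {
      w <- wilcoxon_paired(zero_tpr[, 1], zero_tpr[, ci])
      data.frame(condition = cond_names[ci], class = 0,
                 statistic = w$statistic, p.value = w$p.value)
    }
  })
  structure(list(zero_tpr = zero_tpr, accuracy = acc, tpr = tpr,
                 tests = do.call(rbind, tests), conditions = cond_names,
                 n_reps = n_reps, seed = seed),
            class = "nzero_silencing_study")
}
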