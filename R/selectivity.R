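#' @name selectivity
#' @title Numerosity-selectivity screen
#'
#' @description
#' A unit is numerosity-selective when a two-way fixed-effects ANOVA with
#' factors numerosity (e.g. 5 levels, 0-4) and stimulus set (3 levels) shows
#' a significant main effect of numerosity (p below `alpha`, default 0.01)
#' but no significant effect of stimulus set and no significant interaction
#' (both p at or above `alpha`). The design is balanced by construction
#' (equal image counts per cell), so the classical sequential, marginal and
#' partial sums of squares coincide. Units with zero response variance
#' cannot be tested and are flagged `excluded_constant`; they count as
#' non-selective but remain in the denominator of selective fractions.
NULL

# Vectorized balanced two-way ANOVA over the rows of a units x stimuli
# matrix. Returns per-unit p-values for factor A (numerosity), factor B
# (set) and the interaction.
anova_two_way_matrix <- function(values, fa, fb) {
  fa <- as.factor(fa); fb <- as.factor(fb)
  n <- ncol(values)
  stopifnot(length(fa) == n, length(fb) == n)
  cell <- interaction(fa, fb, drop = FALSE)
  counts <- table(cell)
  if (length(unique(counts)) != 1)
    stop("unbalanced design: the screen requires equal counts per numerosity x set cell")
  m <- unname(counts[1])
  if (m < 2) stop("need at least 2 observations per cell")
  a <- nlevels(fa); b <- nlevels(fb)

  ind <- function(f) {
    M <- matrix(0, n, nlevels(f))
    M[cbind(seq_len(n), as.integer(f))] <- 1
    M
  }
  Sa <- values %*% ind(fa)          # units x a sums
  Sb <- values %*% ind(fb)
  Sab <- values %*% ind(cell)       # units x (a*b)
  G <- rowSums(values)
  tot <- rowSums(values^2) - G^2 / n

  ss_a <- rowSums(Sa^2) / (m * b) - G^2 / n
  ss_b <- rowSums(Sb^2) / (m * a) - G^2 / n
  ss_cells <- rowSums(Sab^2) / m - G^2 / n
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- tot - ss_cells
  # guard tiny negatives from cancellation
  ss_a <- pmax(ss_a, 0); ss_b <- pmax(ss_b, 0)
  ss_ab <- pmax(ss_ab, 0); ss_e <- pmax(ss_e, 0)

  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b; df_e <- n - a * b
  mse <- ss_e / df_e
  pf_safe <- function(ss, df) {
    f <- (ss / df) / mse
    p <- stats::pf(f, df, df_e, lower.tail = FALSE)
    p[mse == 0 & ss > 0] <- 0       # perfect cell structure, no residual
    p[mse == 0 & ss == 0] <- 1
    p
  }
  list(p_a = pf_safe(ss_a, df_a), p_b = pf_safe(ss_b, df_b),
       p_ab = pf_safe(ss_ab, df_ab), constant = tot <= 0)
}

#' Screen units for numerosity selectivity
#'
#' @param acts an `nzero_activations` object (or bare units x stimuli matrix).
#' @param manifest an `nzero_manifest` (or data frame with `numerosity` and
#'   `set` columns, one row per stimulus/column of `acts`).
#' @param alpha significance level for the compound criterion (default 0.01).
#' @return A list of class `nzero_screen`: `anova` (data frame with `unit_id`,
#'   `p_numerosity`, `p_set`, `p_interaction`, `excluded_constant`,
#'   `selective`), `selective_units` (integer ids), `n_units_total`,
#'   `n_selective`, `fraction_selective` and `alpha`.
#' @export
screen_selectivity <- function(acts, manifest, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  values <- if (inherits(acts, "nzero_activations")) acts$values else acts
  tab <- if (inherits(manifest, "nzero_manifest")) manifest$manifest else manifest
  if (ncol(values) != nrow(tab))
    stop("activation columns and manifest rows do not match")
  res <- anova_two_way_matrix(values, tab$numerosity, tab$set)
  p_a <- res$p_a; p_b <- res$p_b; p_ab <- res$p_ab
  p_a[res$constant] <- NA; p_b[res$constant] <- NA; p_ab[res$constant] <- NA
  selective <- !res$constant & p_a < alpha & p_b >= alpha & p_ab >= alpha
  selective[is.na(selective)] <- FALSE
  anova <- data.frame(unit_id = seq_len(nrow(values)),
                      p_numerosity = p_a, p_set = p_b, p_interaction = p_ab,
                      excluded_constant = res$constant,
                      selective = selective)
  structure(list(anova = anova,
                 selective_units = which(selective),
                 n_units_total = nrow(values),
                 n_selective = sum(selective),
                 fraction_selective = mean(selective),
                 alpha = alpha),
            class = "nzero_screen")
}

#' @export
print.nzero_screen <- function(x, ...) {
  cat(sprintf("<nzero_screen> %d/%d units numerosity-selective (%.2f%%) at alpha = %g\n",
              x$n_selective, x$n_units_total, 100 * x$fraction_selective,
              x$alpha))
  invisible(x)
}

#' Tuning profiles and preferred numerosities
#'
#' Computes, for each requested unit, the mean response to every numerosity
#' within each stimulus set and pooled over sets; assigns the preferred
#' numerosity as the pooled-curve argmax (ties broken toward the smaller
#' numerosity); and min-max normalizes the pooled curve to `[0, 1]`. Units
#' with a flat pooled curve are dropped with a warning.
#'
#' @param acts activations (`nzero_activations` or matrix).
#' @param manifest stimulus manifest.
#' @param units integer vector of unit ids (default: all units).
#' @return A list of class `nzero_profiles`: `numerosities`, `units`,
#'   `mean_by_set` (3-d array unit x numerosity x set), `pooled` (matrix
#'   unit x numerosity), `normalized` (same shape, each row in `[0, 1]`),
#'   `preferred` (integer vector) and `n_ties` (count of argmax ties).
#' @export
tuning_profiles <- function(acts, manifest, units = NULL) {
  values <- if (inherits(acts, "nzero_activations")) acts$values else acts
  tab <- if (inherits(manifest, "nzero_manifest")) manifest$manifest else manifest
  if (is.null(units)) units <- seq_len(nrow(values))
  if (!length(units)) stop("unit subset is empty")
  values <- values[units, , drop = FALSE]
  nums <- as.numeric(sort(unique(tab$numerosity)))
  sets <- sort(unique(tab$set))

  pooled <- vapply(nums, function(q)
    rowMeans(values[, tab$numerosity == q, drop = FALSE]), numeric(nrow(values)))
  pooled <- matrix(pooled, nrow = nrow(values),
                   dimnames = list(NULL, as.character(nums)))
  by_set <- array(NA_real_, c(nrow(values), length(nums), length(sets)),
                  dimnames = list(NULL, as.character(nums), sets))
  for (s in seq_along(sets)) for (q in seq_along(nums)) {
    sel <- tab$set == sets[s] & tab$numerosity == nums[q]
    by_set[, q, s] <- rowMeans(values[, sel, drop = FALSE])
  }

  rng <- apply(pooled, 1, function(z) max(z) - min(z))
  flat <- rng <= 0
  if (any(flat)) {
    warning(sprintf("dropping %d unit(s) with flat pooled tuning curves", sum(flat)))
    keep <- !flat
    units <- units[keep]; pooled <- pooled[keep, , drop = FALSE]
    by_set <- by_set[keep, , , drop = FALSE]; rng <- rng[keep]
  }
  if (!nrow(pooled)) stop("no units with non-flat tuning curves")
  pref_idx <- apply(pooled, 1, which.max)  # first maximum = smaller numerosity
  ties <- apply(pooled, 1, function(z) sum(z == max(z)) > 1)
  normalized <- (pooled - apply(pooled, 1, min)) / rng

  structure(list(numerosities = nums, units = units, mean_by_set = by_set,
                 pooled = pooled, normalized = normalized,
                 preferred = nums[pref_idx], n_ties = sum(ties)),
            class = "nzero_profiles")
}

#' Variability of normalized tuning responses
#'
#' The headline statistic, `response_se`, is the standard error of a unit's
#' normalized single-image responses within each numerosity-by-set cell
#' (the error bars of per-set tuning curves), averaged over cells and units:
#' each unit's responses are normalized with its pooled tuning curve's
#' min-max range, the standard error over the images of a cell is taken, and
#' all cell values are averaged. Strong response noise relative to a unit's
#' tuning range inflates it; sharply tuned units shrink it. Two across-unit
#' summaries are also returned: `dispersion` (sd of normalized curve values
#' across units within preferred-numerosity groups) and `group_sem` (the
#' corresponding standard error of the group mean).
#'
#' @param profiles an `nzero_profiles` object.
#' @param acts activations the profiles were computed from
#'   (`nzero_activations` or matrix over all units).
#' @param manifest the stimulus manifest.
#' @return Named numeric vector: `response_se`, `dispersion`, `group_sem`.
#' @export
tuning_variability <- function(profiles, acts = NULL, manifest = NULL) {
  out <- c(response_se = NA_real_, dispersion = NA_real_, group_sem = NA_real_)
  groups <- split(seq_along(profiles$preferred), profiles$preferred)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups)) {
    sds <- lapply(groups, function(ix)
      apply(profiles$normalized[ix, , drop = FALSE], 2, stats::sd))
    ses <- mapply(function(s, ix) s / sqrt(length(ix)), sds, groups,
                  SIMPLIFY = FALSE)
    out["dispersion"] <- mean(unlist(sds))
    out["group_sem"] <- mean(unlist(ses))
  }
  if (!is.null(acts)) {
    values <- if (inherits(acts, "nzero_activations")) acts$values else acts
    tab <- if (inherits(manifest, "nzero_manifest")) manifest$manifest else manifest
    v <- values[profiles$units, , drop = FALSE]
    rng <- apply(profiles$pooled, 1, function(z) max(z) - min(z))
    nimg <- sweep(sweep(v, 1, apply(profiles$pooled, 1, min), "-"), 1, rng, "/")
    cells <- interaction(tab$numerosity, tab$set)
    sem_cell <- vapply(levels(cells), function(cl) {
      cols <- cells == cl
      mean(apply(nimg[, cols, drop = FALSE], 1, stats::sd)) / sqrt(sum(cols))
    }, 0)
    out["response_se"] <- mean(sem_cell)
  }
  out
}

#' Selectivity in untrained networks across repetitions
#'
#' Repeats the whole untrained-network protocol: fresh Xavier-initialized
#' weights, freshly generated stimuli, presentation with multiplicative
#' response noise, the ANOVA selectivity screen and tuning profiles. Reports
#' across-repetition means and standard errors of the selective fraction, the
#' zero-preferring share among selective units, the preferred-numerosity
#' histogram and the across-unit variability of normalized tuning responses.
#'
#' @param arch layer table (default: the full architecture).
#' @param numerosities,sets,n_images stimulus plan per repetition.
#' @param n_reps number of repetitions (the reference protocol uses 100;
#'   a handful already gives stable estimates at desk scale).
#' @param seed master seed; per-repetition seeds are derived from it.
#' @param alpha significance level of the screen.
#' @param noise response-noise parameters.
#' @param progress print one line per repetition.
#' @return A list of class `nzero_screen_summary` with per-repetition values
#'   and across-repetition `mean` / `se` summaries.
#' @export
untrained_repetition_study <- function(arch = default_architecture(),
                                       numerosities = 0:4,
                                       sets = STIM_SETS,
                                       n_images = 600,
                                       n_reps = 3, seed = 1L, alpha = 0.01,
                                       noise = noise_params(),
                                       progress = FALSE) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max, 3 * n_reps), ncol = 3)
  frac_sel <- frac_zero <- disp <- se_resp <- gsem <- numeric(n_reps)
  hist_mat <- matrix(0, n_reps, length(numerosities),
                     dimnames = list(NULL, as.character(numerosities)))
  for (r in seq_len(n_reps)) {
    net <- build_network(arch, seed = rep_seeds[r, 1])
    mf <- generate_manifest(numerosities, sets, n_images,
                            seed = rep_seeds[r, 2],
                            image_size = arch$size[1])
    acts <- forward_record(net, mf$images, noise = noise,
                           seed = rep_seeds[r, 3])
    scr <- screen_selectivity(acts, mf, alpha = alpha)
    frac_sel[r] <- scr$fraction_selective
    if (scr$n_selective > 0) {
      prof <- tuning_profiles(acts, mf, units = scr$selective_units)
      frac_zero[r] <- mean(prof$preferred == 0)
      tv <- tuning_variability(prof, acts, mf)
      disp[r] <- tv["dispersion"]; se_resp[r] <- tv["response_se"]
      gsem[r] <- tv["group_sem"]
      h <- table(factor(prof$preferred, levels = numerosities))
      hist_mat[r, ] <- as.numeric(h)
    } else {
      frac_zero[r] <- NA; disp[r] <- NA; se_resp[r] <- NA; gsem[r] <- NA
    }
    if (progress)
      message(sprintf("repetition %d/%d: %.2f%% selective, %.1f%% zero-preferring",
                      r, n_reps, 100 * frac_sel[r], 100 * frac_zero[r]))
  }
  sem <- function(z) if (length(z) > 1) stats::sd(z) / sqrt(length(z)) else NA_real_
  structure(list(
    n_reps = n_reps, seed = seed, numerosities = numerosities,
    per_rep = data.frame(rep = seq_len(n_reps), fraction_selective = frac_sel,
                         fraction_zero_preferring = frac_zero,
                         response_se = se_resp, tuning_dispersion = disp,
                         group_sem = gsem),
    preferred_histogram = hist_mat,
    mean = c(fraction_selective = mean(frac_sel),
             fraction_zero_preferring = mean(frac_zero, na.rm = TRUE),
             response_se = mean(se_resp, na.rm = TRUE),
             tuning_dispersion = mean(disp, na.rm = TRUE),
             group_sem = mean(gsem, na.rm = TRUE)),
    se = c(fraction_selective = sem(frac_sel),
           fraction_zero_preferring = sem(frac_zero),
           response_se = sem(se_resp),
           tuning_dispersion = sem(disp),
           group_sem = sem(gsem))
  ), class = "nzero_screen_summary")
}

#' @export
print.nzero_screen_summary <- function(x, ...) {
  cat(sprintf("<nzero_screen_summary> %d repetition(s)\n", x$n_reps))
  cat(sprintf("  selective fraction:    %.2f%% +/- %.2f%%\n",
              100 * x$mean["fraction_selective"], 100 * x$se["fraction_selective"]))
  cat(sprintf("  zero-preferring share: %.1f%% +/- %.1f%%\n",
              100 * x$mean["fraction_zero_preferring"],
              100 * x$se["fraction_zero_preferring"]))
  cat(sprintf("  normalized-response standard error: %.3f\n",
              x$mean["response_se"]))
  cat("  mean preferred-numerosity histogram:\n")
  print(round(colMeans(x$preferred_histogram), 1))
  invisible(x)
}
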