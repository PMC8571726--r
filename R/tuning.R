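#' @name tuning
#' @title Population tuning characterization
#'
#' @description
#' Characterizes the tuning of numerosity-selective units at the population
#' level: average tuning curves per preferred numerosity, Gaussian fits on a
#' linear versus a logarithmic number axis (the Weber-Fechner signature),
#' straight-line fits for zero-preferring units, the numerical distance
#' effect (higher response to numerosity 1 than 2, and 2 than 3, among
#' zero-preferring units) and the numerical size effect (tuning width growing
#' with preferred numerosity).
#'
#' Because numerosity 0 must sit at a finite position on the logarithmic
#' axis, the log transform used throughout is `x' = log2(x + 1)`, which maps
#' 0 to 0 and compresses spacing as magnitude grows.
NULL

#' Logarithmic number axis
#'
#' @param x numerosities (>= 0).
#' @return `log2(x + 1)`.
#' @export
log_axis <- function(x) log2(x + 1)

# paired Wilcoxon signed-rank with the degenerate all-ties case defined as
# "no effect" (p = 1); exact distribution for n <= 25 pairs, normal
# approximation beyond
wilcoxon_paired <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[is.finite(d)]
  if (!length(d) || all(d == 0))
    return(list(statistic = NA_real_, p.value = 1, n = length(d)))
  n_eff <- sum(d != 0)
  wt <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = n_eff <= 25, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, n = n_eff)
}

#' Population tuning curves per preferred numerosity
#'
#' Averages the normalized tuning curves of units sharing a preferred
#' numerosity (normalize-then-average) and reports across-unit standard
#' errors. Groups without units are omitted with a warning.
#'
#' @param profiles an `nzero_profiles` object.
#' @param normalize_first if `FALSE`, raw pooled curves are averaged within
#'   each group and the group mean is min-max normalized afterwards
#'   (average-then-normalize).
#' @return A list of class `nzero_population_curves`: `numerosities`,
#'   `curves` (group x numerosity matrix of means), `se` (same shape),
#'   `n_units` per group.
#' @export
population_curves <- function(profiles, normalize_first = TRUE) {
  stopifnot(inherits(profiles, "nzero_profiles"))
  nums <- profiles$numerosities
  groups <- split(seq_along(profiles$preferred), profiles$preferred)
  missing <- setdiff(as.character(nums), names(groups))
  if (length(missing))
    warning("no units preferring numerosity ", paste(missing, collapse = ", "),
            "; group(s) omitted")
  curves <- t(vapply(groups, function(ix) {
    if (normalize_first) {
      colMeans(profiles$normalized[ix, , drop = FALSE])
    } else {
      m <- colMeans(profiles$pooled[ix, , drop = FALSE])
      (m - min(m)) / (max(m) - min(m))
    }
  }, numeric(length(nums))))
  se <- t(vapply(groups, function(ix) {
    src <- if (normalize_first) profiles$normalized else profiles$pooled
    apply(src[ix, , drop = FALSE], 2, stats::sd) / sqrt(length(ix))
  }, numeric(length(nums))))
  structure(list(numerosities = nums, curves = curves, se = se,
                 n_units = lengths(groups),
                 preferred = as.numeric(names(groups))),
            class = "nzero_population_curves")
}

# deterministic Gaussian least squares on a prepared axis (Levenberg-
# Marquardt with box constraints; the low-level driver is robust to exact
# zero-residual fits)
fit_gaussian_xy <- function(x, y) {
  if (length(x) < 4) stop("Gaussian fit needs at least 4 curve points")
  if (max(y) - min(y) < 1e-12)   # flat curve carries no tuning to fit
    return(list(center = NA_real_, width_sd = NA_real_, amplitude = NA_real_,
                baseline = NA_real_, r_squared = -Inf, converged = FALSE))
  rng <- max(x) - min(x)
  start <- c(amp = max(max(y) - min(y), 1e-6), ctr = x[which.max(y)],
             wid = rng / 2, base = min(y))
  model <- function(p) p["base"] + p["amp"] * exp(-(x - p["ctr"])^2 /
                                                  (2 * p["wid"]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = function(p) y - model(p),
      lower = c(amp = 0, ctr = min(x) - 2 * rng, wid = 0.05 * rng,
                base = -Inf),
      upper = c(amp = Inf, ctr = max(x) + 2 * rng, wid = 10 * rng, base = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 2000)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:5) || !all(is.finite(fit$par)) ||
      fit$par["wid"] <= 0)
    return(list(center = NA_real_, width_sd = NA_real_, amplitude = NA_real_,
                baseline = NA_real_, r_squared = -Inf, converged = FALSE))
  cf <- fit$par
  ss_res <- sum((y - model(cf))^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else ifelse(ss_res < 1e-12, 1, -Inf)
  list(center = unname(cf["ctr"]), width_sd = unname(cf["wid"]),
       amplitude = unname(cf["amp"]), baseline = unname(cf["base"]),
       r_squared = r2, converged = TRUE)
}

prep_axis <- function(numerosities, axis = c("linear", "log")) {
  axis <- match.arg(axis)
  if (axis == "log") log_axis(numerosities) else as.numeric(numerosities)
}

#' Gaussian fit to a tuning (or performance) curve
#'
#' Least-squares fit of `y = base + amp * exp(-(x - ctr)^2 / (2 * sd^2))` on
#' the chosen number axis, with deterministic initialization (amplitude =
#' curve range, center = argmax, width = half the axis range, baseline =
#' curve minimum) and width bounded away from zero. Non-convergence yields a
#' flagged fit with `r_squared = -Inf`.
#'
#' @param curve numeric response values, one per numerosity.
#' @param numerosities the numerosities the curve samples.
#' @param axis `"linear"` or `"log"` (the `log2(x + 1)` transform).
#' @return A list of class `nzero_gaussian_fit`: `center`, `width_sd`,
#'   `amplitude`, `baseline`, `r_squared`, `converged`, `axis`.
#' @export
fit_gaussian <- function(curve, numerosities = seq_along(curve) - 1,
                         axis = c("linear", "log")) {
  axis <- match.arg(axis)
  x <- prep_axis(numerosities, axis)
  out <- fit_gaussian_xy(x, curve)
  out$axis <- axis
  structure(out, class = "nzero_gaussian_fit")
}

#' Straight-line fit to a tuning curve
#'
#' Ordinary least squares of response against the chosen number axis; used
#' to test whether zero-preferring units decay linearly in log-numerosity.
#'
#' @inheritParams fit_gaussian
#' @return List with `slope`, `intercept`, `r_squared`, `axis`.
#' @export
fit_line <- function(curve, numerosities = seq_along(curve) - 1,
                     axis = c("linear", "log")) {
  axis <- match.arg(axis)
  x <- prep_axis(numerosities, axis)
  fit <- stats::lm(curve ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((curve - mean(curve))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
       axis = axis)
}

#' Numerical distance and size effects
#'
#' Distance effect: among zero-preferring units, paired Wilcoxon signed-rank
#' tests of the normalized response to numerosity 1 versus 2 and 2 versus 3.
#' Size effect: Pearson correlation between each unit's preferred numerosity
#' and the standard deviation of the Gaussian fit to its tuning curve.
#'
#' @param profiles an `nzero_profiles` object (typically selective units).
#' @param axis axis for the size-effect Gaussian fits.
#' @param min_group minimum zero-preferring group size for the distance tests.
#' @return A list of class `nzero_effect_stats`: `distance` (data frame with
#'   comparison, statistic, p.value, n), `size_r`, `size_p`, `n_units_fit`,
#'   `widths`, `preferred`.
#' @export
distance_size_effects <- function(profiles, axis = "linear", min_group = 5) {
  stopifnot(inherits(profiles, "nzero_profiles"))
  nums <- profiles$numerosities
  zero_ix <- which(profiles$preferred == 0)
  distance <- NULL
  if (length(zero_ix) >= min_group && all(1:3 %in% nums)) {
    nc <- profiles$normalized[zero_ix, , drop = FALSE]
    cmp <- function(q1, q2) {
      w <- wilcoxon_paired(nc[, as.character(q1)], nc[, as.character(q2)])
      data.frame(comparison = sprintf("%d_vs_%d", q1, q2),
                 statistic = w$statistic, p.value = w$p.value, n = w$n)
    }
    distance <- rbind(cmp(1, 2), cmp(2, 3))
  } else {
    warning("zero-preferring group too small; distance tests skipped")
  }
  widths <- rep(NA_real_, nrow(profiles$normalized))
  for (i in seq_along(widths)) {
    ft <- fit_gaussian(profiles$normalized[i, ], nums, axis = axis)
    if (ft$converged && is.finite(ft$r_squared)) widths[i] <- ft$width_sd
  }
  ok <- is.finite(widths)
  if (sum(ok) >= 3 && stats::sd(profiles$preferred[ok]) > 0 &&
      stats::sd(widths[ok]) > 0) {
    ct <- stats::cor.test(profiles$preferred[ok], widths[ok],
                          method = "pearson")
    size_r <- unname(ct$estimate); size_p <- ct$p.value
  } else {
    size_r <- NA_real_; size_p <- NA_real_
  }
  structure(list(distance = distance, size_r = size_r, size_p = size_p,
                 n_units_fit = sum(ok), widths = widths,
                 preferred = profiles$preferred),
            class = "nzero_effect_stats")
}

#' Linear versus logarithmic axis comparison of Gaussian fits
#'
#' Fits each unit's normalized tuning curve with a Gaussian on the linear and
#' on the logarithmic number axis and compares the paired goodness-of-fit
#' (r-squared) values with a Wilcoxon signed-rank test. Units whose fit fails
#' to converge on either axis are excluded from the pairing.
#'
#' @param profiles an `nzero_profiles` object, or a numeric matrix of curves
#'   (rows = units) with `numerosities` supplied.
#' @param numerosities numerosities sampled by the curves (when `profiles`
#'   is a bare matrix).
#' @param min_pairs minimum number of fit pairs required (default 5).
#' @return A list of class `nzero_scale_comparison`: `r2_linear`, `r2_log`
#'   (per-unit vectors), `mean_r2_linear`, `mean_r2_log`, `statistic`,
#'   `p.value`, `n`.
#' @export
scale_comparison <- function(profiles, numerosities = NULL, min_pairs = 5) {
  if (inherits(profiles, "nzero_profiles")) {
    curves <- profiles$normalized
    numerosities <- profiles$numerosities
  } else {
    curves <- as.matrix(profiles)
    if (is.null(numerosities)) numerosities <- seq_len(ncol(curves)) - 1
  }
  r2 <- function(ax) apply(curves, 1, function(y)
    fit_gaussian(y, numerosities, axis = ax)$r_squared)
  r2_lin <- r2("linear"); r2_log <- r2("log")
  ok <- is.finite(r2_lin) & is.finite(r2_log)
  if (sum(ok) < min_pairs)
    stop(sprintf("scale comparison needs at least %d fit pairs (got %d)",
                 min_pairs, sum(ok)))
  w <- wilcoxon_paired(r2_log[ok], r2_lin[ok])
  structure(list(r2_linear = r2_lin, r2_log = r2_log,
                 mean_r2_linear = mean(r2_lin[ok]),
                 mean_r2_log = mean(r2_log[ok]),
                 statistic = w$statistic, p.value = w$p.value, n = w$n),
            class = "nzero_scale_comparison")
}

#' @export
print.nzero_scale_comparison <- function(x, ...) {
  cat(sprintf("<nzero_scale_comparison> mean r2 linear = %.3f, log = %.3f (n = %d, p = %.3g)\n",
              x$mean_r2_linear, x$mean_r2_log, x$n, x$p.value))
  invisible(x)
}
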