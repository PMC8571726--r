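#' @name pipeline
#' @title End-to-end experiment orchestration
#'
#' @description
#' `run_experiment()` composes the modules — network construction, stimulus
#' generation, selectivity screening, tuning characterization and behavioral
#' decoding — from a single seeded configuration, writes per-stage outputs
#' (CSV tables, JSON summary) and returns a results bundle that is fully
#' regenerable from its embedded configuration and seeds. A thin command-line
#' wrapper is installed at `inst/cli/nzero.R`.
NULL

#' Experiment configuration
#'
#' Defaults follow the reference protocol: 600 stimulus images (numerosities
#' 0-4, three sets), selectivity threshold 0.01, 100 selectivity repetitions
#' and 50 behavior repetitions. Desk-scale runs should lower the repetition
#' counts (3-5 selectivity repetitions already give stable estimates) or use
#' the tiny architecture.
#'
#' @param arch `"full"`, `"tiny"`, or a layer data frame.
#' @param mode `"untrained"` or `"trained-checkpoint"`.
#' @param checkpoint path to a saved network (for `trained-checkpoint`).
#' @param numerosities,sets,n_images stimulus plan.
#' @param alpha ANOVA significance threshold.
#' @param selectivity_reps repetitions of the untrained screen.
#' @param behavior logical: run the behavioral stage.
#' @param behavior_reps matching-task data-generation repetitions.
#' @param silencing_reps repetitions for the silencing study.
#' @param n_trials matching trials per repetition (train and test each).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory (`NULL` = no files written).
#' @return A list of class `nzero_config`.
#' @export
experiment_config <- function(arch = "full", mode = "untrained",
                              checkpoint = NULL,
                              numerosities = 0:4, sets = STIM_SETS,
                              n_images = 600, alpha = 0.01,
                              selectivity_reps = 100, behavior = FALSE,
                              behavior_reps = 50, silencing_reps = 10,
                              n_trials = 600, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode, c("untrained", "trained-checkpoint"))
  if (mode == "trained-checkpoint" &&
      (is.null(checkpoint) || !file.exists(checkpoint)))
    stop("trained-checkpoint mode requires an existing checkpoint file")
  cfg <- list(arch = arch, mode = mode, checkpoint = checkpoint,
              numerosities = numerosities, sets = sets, n_images = n_images,
              alpha = alpha, selectivity_reps = selectivity_reps,
              behavior = behavior, behavior_reps = behavior_reps,
              silencing_reps = silencing_reps, n_trials = n_trials,
              seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "nzero_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose keys match [experiment_config()] arguments.
#' @return A `nzero_config`.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(experiment_config, vals)
}

resolve_arch <- function(arch) {
  if (is.data.frame(arch)) return(arch)
  switch(arch, full = default_architecture(), tiny = tiny_architecture(),
         stop("arch must be 'full', 'tiny' or a layer table"))
}

write_stage <- function(out_dir, name, writer) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writer(file.path(out_dir, name))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run a configured experiment end to end
#'
#' Executes the configured stages: (1) repeated untrained-network selectivity
#' screen; (2) detailed tuning analysis of a representative repetition
#' (population curves, distance/size effects, linear-vs-log comparison);
#' (3) optionally, behavioral decoding (matching study, performance fits,
#' categorization with silencing conditions). Per-stage outputs are written
#' to `out_dir` as they complete; a top-level JSON summary with a provenance
#' block (configuration, seeds, package version) is written last.
#'
#' @param config a [experiment_config()] (or path to a YAML file).
#' @return A results bundle (list of class `nzero_bundle`) with elements
#'   `config`, `seeds`, `selectivity`, `tuning`, optionally `behavior`, and
#'   `summary`.
#' @export
run_experiment <- function(config = experiment_config()) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "nzero_config"))
  arch <- resolve_arch(config$arch)
  set.seed(config$seed)
  seeds <- as.list(sample.int(.Machine$integer.max, 6))
  names(seeds) <- c("screen", "net", "stimuli", "noise", "behavior", "silencing")
  out_dir <- config$out_dir

  summary <- list()

  ## stage 1: repeated selectivity screen
  sel <- stage("selectivity", {
    if (config$mode == "untrained") {
      untrained_repetition_study(
        arch, config$numerosities, config$sets, config$n_images,
        n_reps = config$selectivity_reps, seed = seeds$screen,
        alpha = config$alpha)
    } else NULL
  })
  if (!is.null(sel)) {
    write_stage(out_dir, "selectivity_reps.csv", function(p)
      utils::write.csv(sel$per_rep, p, row.names = FALSE))
    summary$fraction_selective <- unname(sel$mean["fraction_selective"])
    summary$fraction_zero_preferring <- unname(sel$mean["fraction_zero_preferring"])
    summary$response_se <- unname(sel$mean["response_se"])
    summary$preferred_histogram <- unname(colMeans(sel$preferred_histogram))
  }

  ## stage 2: detailed analysis of one network instance
  det <- stage("tuning", {
    net <- if (config$mode == "trained-checkpoint") {
      readRDS(config$checkpoint)
    } else build_network(arch, seed = seeds$net)
    mf <- generate_manifest(config$numerosities, config$sets, config$n_images,
                            seed = seeds$stimuli, image_size = arch$size[1])
    acts <- forward_record(net, mf$images, noise = noise_params(),
                           seed = seeds$noise)
    scr <- screen_selectivity(acts, mf, alpha = config$alpha)
    if (scr$n_selective < 5) {
      list(net = net, screen = scr, empty = TRUE)
    } else {
      prof <- tuning_profiles(acts, mf, units = scr$selective_units)
      pop <- population_curves(prof)
      eff <- distance_size_effects(prof)
      sc <- tryCatch(scale_comparison(prof), error = function(e) NULL)
      list(net = net, manifest_seed = seeds$stimuli, screen = scr,
           profiles = prof, population = pop, effects = eff, scale = sc,
           empty = FALSE)
    }
  })
  if (!isTRUE(det$empty)) {
    write_stage(out_dir, "unit_results.csv", function(p) {
      tab <- det$screen$anova[det$screen$selective_units, ]
      tab$preferred <- det$profiles$preferred[match(tab$unit_id, det$profiles$units)]
      utils::write.csv(cbind(tab, det$profiles$pooled), p, row.names = FALSE)
    })
    summary$distance_effect_p <- det$effects$distance$p.value
    summary$size_effect_r <- det$effects$size_r
    if (!is.null(det$scale)) {
      summary$r2_linear <- det$scale$mean_r2_linear
      summary$r2_log <- det$scale$mean_r2_log
      summary$scale_p <- det$scale$p.value
    }
  } else {
    summary$note <- "no numerosity-tuned units found in the detailed analysis"
  }

  ## stage 3: behavior
  beh <- NULL
  if (config$behavior && !isTRUE(det$empty)) {
    beh <- stage("behavior", {
      rec <- network_recorder(det$net)
      units <- det$screen$selective_units
      ms <- matching_study(rec, units = units, n_reps = config$behavior_reps,
                           n_train = config$n_trials, n_test = config$n_trials,
                           numerosities = config$numerosities,
                           sets = config$sets, image_size = arch$size[1],
                           seed = seeds$behavior)
      pf <- tryCatch(performance_fits(ms$performance_mean),
                     error = function(e) NULL)
      sil <- silencing_study(rec, units,
                             det$profiles$preferred,
                             n_reps = config$silencing_reps,
                             n_trials = config$n_trials,
                             numerosities = config$numerosities,
                             sets = config$sets, image_size = arch$size[1],
                             seed = seeds$silencing)
      list(matching = ms, fits = pf, silencing = sil)
    })
    write_stage(out_dir, "matching_trials.csv", function(p)
      utils::write.csv(beh$matching$last$matching$trials, p, row.names = FALSE))
    summary$matching_accuracy <- beh$matching$mean_accuracy
    summary$matching_accuracy_zero <- beh$matching$mean_accuracy_zero
    if (!is.null(beh$fits)) summary$performance_size_r <- beh$fits$size_r
    summary$zero_tpr <- colMeans(beh$silencing$zero_tpr)
    summary$silencing_tests <- beh$silencing$tests
  }

  bundle <- structure(list(config = unclass(config), seeds = seeds,
                           selectivity = sel, tuning = det, behavior = beh,
                           summary = summary,
                           provenance = list(
                             package_version = as.character(utils::packageVersion("nzero")),
                             r_version = R.version.string,
                             timestamp = format(Sys.time(), tz = "UTC"))),
                      class = "nzero_bundle")
  write_stage(out_dir, "summary.json", function(p)
    jsonlite::write_json(c(summary, list(config = unclass(config)[
      setdiff(names(config), "out_dir")], seeds = seeds)),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE))
  bundle
}

#' Render a human-readable report from a results bundle
#'
#' Produces a Markdown report of the bundle's headline numbers: selective
#' fractions, preferred-numerosity histogram, tuning effects (distance, size,
#' linear-vs-log), and — when the behavior stage ran — matching accuracies,
#' performance-fit statistics and the silencing comparison. Sections whose
#' stage did not run are omitted.
#'
#' @param bundle a `nzero_bundle` from [run_experiment()].
#' @param path optional file to write the report to.
#' @return The report as a character vector of lines, invisibly if `path`
#'   is given.
#' @export
report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "nzero_bundle"))
  s <- bundle$summary
  fmt_pct <- function(x) sprintf("%.2f%%", 100 * x)
  lines <- c("# Numerosity-tuning experiment report", "")
  if (!is.null(bundle$selectivity)) {
    sel <- bundle$selectivity
    lines <- c(lines,
      "## Selectivity screen",
      sprintf("- repetitions: %d", sel$n_reps),
      sprintf("- numerosity-selective units: %s (s.e. %s)",
              fmt_pct(sel$mean["fraction_selective"]),
              fmt_pct(sel$se["fraction_selective"])),
      sprintf("- zero-preferring among selective: %s",
              fmt_pct(sel$mean["fraction_zero_preferring"])),
      sprintf("- normalized-response standard error: %.3f",
              sel$mean["response_se"]),
      "",
      "| preferred numerosity | mean unit count |",
      "|---|---|",
      sprintf("| %s | %.1f |", colnames(sel$preferred_histogram),
              colMeans(sel$preferred_histogram)),
      "")
  }
  if (!is.null(bundle$tuning) && !isTRUE(bundle$tuning$empty)) {
    det <- bundle$tuning
    lines <- c(lines, "## Tuning characterization")
    if (!is.null(det$effects$distance))
      lines <- c(lines, sprintf(
        "- distance effect (zero-preferring units), %s: p = %.3g",
        det$effects$distance$comparison, det$effects$distance$p.value))
    lines <- c(lines, sprintf("- size effect: Pearson r = %.2f (p = %.3g)",
                              det$effects$size_r, det$effects$size_p))
    if (!is.null(det$scale))
      lines <- c(lines, sprintf(
        "- Gaussian fits, linear vs log axis: mean r2 = %.3f vs %.3f (p = %.3g)",
        det$scale$mean_r2_linear, det$scale$mean_r2_log, det$scale$p.value))
    lines <- c(lines, "")
  } else if (isTRUE(bundle$tuning$empty)) {
    lines <- c(lines, "## Tuning characterization",
               "No numerosity-tuned units were found.", "")
  }
  if (!is.null(bundle$behavior)) {
    b <- bundle$behavior
    lines <- c(lines, "## Behavioral decoding",
      sprintf("- matching accuracy: %s (zero-involving trials: %s)",
              fmt_pct(b$matching$mean_accuracy),
              fmt_pct(b$matching$mean_accuracy_zero)))
    if (!is.null(b$fits))
      lines <- c(lines, sprintf(
        "- performance-function size effect: r = %.2f", b$fits$size_r))
    lines <- c(lines, "", "### Silencing (zero true-positive rate)",
      "| condition | mean zero TPR |", "|---|---|",
      sprintf("| %s | %.3f |", colnames(b$silencing$zero_tpr),
              colMeans(b$silencing$zero_tpr)), "",
      "| comparison vs intact | p |", "|---|---|",
      sprintf("| %s | %.3g |", b$silencing$tests$condition,
              b$silencing$tests$p.value), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
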