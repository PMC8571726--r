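# Shared fixtures: synthetic activation codes, fake manifests and small
# recorders used across the behavioral and selectivity tests. Everything is
# generated in code; no stored data.

# balanced stimulus table without images (for synthetic activation matrices)
fake_manifest <- function(numerosities = 0:4,
                          sets = c("standard", "control1", "control2"),
                          per_cell = 6) {
  expand.grid(numerosity = numerosities, set = sets,
              rep = seq_len(per_cell), stringsAsFactors = FALSE)[, 1:2]
}

# units x stimuli matrix with Gaussian numerosity tuning (no set effect)
# planted on the chosen axis, plus i.i.d. response noise
synth_tuned_acts <- function(tab, preferred, width = 1, noise_sd = 0.05,
                             axis = c("linear", "log"), baseline = 0.2) {
  axis <- match.arg(axis)
  x <- if (axis == "log") log_axis(tab$numerosity) else tab$numerosity
  ctr <- if (axis == "log") log_axis(preferred) else preferred
  resp <- t(vapply(ctr, function(c0)
    baseline + exp(-(x - c0)^2 / (2 * width^2)), numeric(nrow(tab))))
  resp + matrix(stats::rnorm(length(resp), 0, noise_sd), nrow(resp))
}

# pure-noise activation matrix (no structure at all)
synth_noise_acts <- function(tab, n_units, sd = 1)
  matrix(stats::rnorm(n_units * nrow(tab), 0, sd), n_units)

# recorder interfaces for the behavior module ------------------------------

# clean one-hot numerosity code (plus small noise to avoid degenerate SVMs)
onehot_recorder <- function(numerosities = 0:4, noise_sd = 0.01) {
  function(specs, seed) {
    set.seed(seed)
    q <- vapply(specs, `[[`, 0L, "numerosity")
    m <- outer(numerosities, q, function(a, b) as.numeric(a == b))
    m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
  }
}

# graded code: Gaussian-tuned population whose overlap decays with numerical
# distance, so near numerosities are genuinely confusable
graded_recorder <- function(numerosities = 0:4, width = 1.0, noise_sd = 0.25) {
  function(specs, seed) {
    set.seed(seed)
    q <- vapply(specs, `[[`, 0L, "numerosity")
    m <- outer(numerosities, q, function(c0, x) exp(-(x - c0)^2 / (2 * width^2)))
    m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
  }
}

# code in which numerosity 0 is carried ONLY by designated zero units
# (units 1..n_zero); countable numerosities are carried by disjoint groups
zero_code_recorder <- function(numerosities = 0:4, n_per_class = 8,
                               noise_sd = 0.05) {
  n_units <- n_per_class * length(numerosities)
  owner <- rep(numerosities, each = n_per_class)
  function(specs, seed) {
    set.seed(seed)
    q <- vapply(specs, `[[`, 0L, "numerosity")
    m <- outer(owner, q, function(o, b) as.numeric(o == b))
    m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
  }
}

# lightweight stimulus "specs" (numerosity only) so recorders need not render
fake_spec_generator <- function() {
  # build_matching_trials renders real stimuli; for speed the behavior tests
  # use a tiny image size so rendering stays trivial
  32L
}

# tiny network shared across model tests (built once per test file load)
tiny_net <- function(seed = 7, n_classes = 5)
  build_network(tiny_architecture(n_classes), seed = seed)

# small images for the tiny network
tiny_image <- function(value = 0, size = 56) matrix(value, size, size)
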