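---
title: "Emergent coding of numerosity zero in a hierarchical convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent coding of numerosity zero in a hierarchical convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Single neurons tuned to the number of items in a visual display ("number
neurons") exist in monkeys, crows and humans, and — remarkably — some of them
treat the *empty set* as the smallest numerical quantity: they fire maximally
when a display contains nothing and their activity falls off as countable
numerosity grows. `nzero` implements a computational account of how such
tuning, including tuning to zero, can arise from generic visual processing:
units of a hierarchical convolutional neural network (HCNN), even one with
completely random weights, develop numerosity-selective responses when probed
with controlled dot displays.

The package provides the full analysis chain: the network model, the
controlled stimulus generator, the unit-selectivity screen, tuning-curve
characterization, behavioral decoding with classifiers, and unit-silencing
ablations, together with an orchestration layer and a command-line wrapper
(`inst/cli/nzero.R`).

## The network model

The model is a 16-layer feedforward HCNN (`default_architecture()`): 8
convolutional layers interleaved with 5 non-overlapping 2x2 max-pooling
stages (spatial chain 224 -> 112 -> 56 -> 28 -> 14 -> 7), followed by global
average pooling and a 1000-way softmax classifier. Every convolutional stage
applies, in order,

1. convolution (stride 1, zero padding preserving spatial size),
2. batch normalization,
3. rectification `f(x) = max(x, 0)`,
4. lateral-inhibition normalization across feature maps
   (`local_response_normalize()`):
   `b_i = a_i / (k + alpha * sum_j max(0, a_j)^2)^beta`, with the sum over
   the `n = 15` neighboring maps at the same location and constants `k = 2`,
   `alpha = 1e-4`, `beta = 0.75`. The displayed formulation in the source
   material omits the exponent on the denominator; we apply `beta` per the
   original divisive-normalization definition from which the constants were
   taken, and we keep the rectifying clamp inside the sum even though
   post-rectification inputs are already non-negative.

The final feature-extraction layer (layer 13) holds 768 maps of 7 x 7 units
= 37,632 units; these are the units analyzed for numerosity tuning.

Weights are Xavier-uniform initialized from a seed; biases use the fan-in
uniform convention (the initialization scheme statement covers weights only).
Multiplicative Gaussian response noise (`noise_params()`, mean 1, s.d. 0.15,
drawn independently per unit and per presentation) is injected into the
output of every convolutional stage at presentation time; it is what gives
the deterministic network trial-to-trial variability, in particular for the
constant empty-set stimulus. Noise is never applied during training.

Three modeling choices were genuinely open and are fixed as follows:

* **Input standardization.** Stimuli pass through the same per-channel
  standardization used for natural-image classification
  (`imagenet_input_norm()`), so a dark background enters the network as a
  strongly negative value, not as zero. This is how images reach a
  classifier trained on natural images, and it matters empirically: with raw
  `[0, 1]` input the untrained network yields only about 6% selective units,
  with standardized input about 15% — the regime the reference results
  describe.
* **Batch normalization in untrained networks** runs in evaluation mode with
  initialization-state running statistics (mean 0, variance 1), i.e. it is
  effectively the identity at initialization. A batch-statistics-calibrated
  variant was evaluated and moved the selectivity numbers away from the
  reference values, so the simpler evaluation-mode reading is kept.
* **Placement of lateral inhibition.** The normalization is applied after
  rectification in every convolutional stage; the source material does not
  enumerate which layers carried it, and uniform placement is the simplest
  consistent reading.

The training pathway (`train_object_recognition()`: mini-batch SGD with
momentum on the softmax cross-entropy, batch-statistics batch norm, per-epoch
checkpoints) is implemented and tested on small fixtures, but object
recognition training at the reference scale (1.2M images, 10 epochs) is a
GPU-scale undertaking: every analysis this package runs at desk scale uses
untrained, randomly initialized networks, for which the reference results
provide quantitative targets.

## The stimulus generator

`generate_stimulus()` / `generate_manifest()` produce 224 x 224 grayscale
displays of 0-4 (or more) bright items on a dark background, balanced across
numerosity and three cue-control sets, and `audit_stimulus()` independently
verifies every geometric constraint (flood-fill component counting, area,
luminance, pairwise distances, convex hull of item centers):

* **standard** — discs of constant radius 18 px; total area and luminance
  grow with numerosity.
* **control 1** — total disc area fixed at 1200 px^2 (so area and total
  luminosity are *constant* across numerosities), mean pairwise center
  distance held in 90-100 px (constant average density). Because all sets
  share one foreground intensity, fixing total area is what fixes average
  luminosity; a literal reading of the "20%" luminance level as an image
  mean would require a bright gray background, which contradicts the
  empty-set displays being purely dark and injects a gross stimulus-set
  confound — the ANOVA screen then rejects nearly every candidate unit.
* **control 2** — item shapes drawn uniformly from circle, rectangle,
  ellipse and triangle (area-matched to the radius-18 disc), and for more
  than two items the convex hull of the item centers is a triangle of random
  location and orientation (three items sit at the vertices, any further
  items strictly inside).

Numerosity 0 is always a pure dark background. Items keep at least 2 px
between boundaries (so component counts are exact under 8-connectivity) and
stay fully inside the image; rasterization tests pixel centers with no
anti-aliasing. Placement is rejection-sampled with a 10,000-attempt budget;
control-1 radii are trimmed by bisection so the *rasterized* total area hits
its target within 2%. All geometric constants are specified at 224 px and
scale linearly with image size, so the reduced 56 px stimuli used with the
tiny test architecture keep the same relative geometry. For dense wide-range
displays (up to 30 items) item sizes shrink (packing-fraction cap; interior
scaling for the hull constraint) since radius-18 discs cannot be packed
without overlap at those counts.

What the generator deliberately does *not* emulate: natural-image clutter,
item occlusion, color, or temporal presentation. Conclusions from these
synthetic displays therefore speak to geometry-controlled numerosity coding,
not to numerosity perception in natural scenes.

## The selectivity screen

`screen_selectivity()` runs, per unit, a classical balanced two-way
fixed-effects ANOVA with factors numerosity (5 levels) and stimulus set (3
levels), 40 images per cell. A unit is **numerosity-selective** iff the
numerosity main effect has `p < 0.01` while the set main effect and the
interaction both have `p >= 0.01` — activity must carry number, not
appearance. Constant-response (dead) units cannot be tested; they are
flagged, counted as non-selective, and retained in the denominator (the
37,632 total). The implementation is a vectorized sums-of-squares
computation over the whole unit matrix; it is checked against `stats::aov`
to `1e-8` in the tests. "No significant effect" is read as `p >= 0.01`,
the same threshold as the main factor.

`tuning_profiles()` averages each unit's responses per numerosity (per set
and pooled), assigns the **preferred numerosity** as the pooled-curve argmax
(ties, rare with continuous responses, break deterministically toward the
smaller numerosity), and min-max normalizes each curve to `[0, 1]`.
`untrained_repetition_study()` repeats the whole protocol — fresh weights,
fresh stimuli, fresh noise — and averages across repetitions.

### The variability statistic

The untrained network's tuning is much noisier than a trained one's, and the
reference analysis quantifies this as an "average standard error in
normalized response" of about 0.35. The phrase is ambiguous; dimensional
analysis settles it. An across-unit standard error within
preferred-numerosity groups is impossible at that magnitude (with thousands
of units per group it is ~0.01). The only reading on the right scale is the
per-set tuning-curve error bar: for each unit, numerosity and stimulus set,
the standard error over that cell's ~40 images of the unit's normalized
single-image responses, averaged over cells and units
(`tuning_variability()`, field `response_se`). When response noise is large
relative to a unit's tuning range, single-image normalized responses scatter
far beyond `[0, 1]` and this statistic grows; sharply tuned (trained) units
drive it down. The across-unit dispersion and group-mean standard error are
also reported as secondary statistics.

## Tuning characterization

`population_curves()` averages normalized curves within preferred-numerosity
groups (normalize-then-average; the average-then-normalize order is
available via `normalize_first = FALSE`). `distance_size_effects()` tests
the **numerical distance effect** (zero-preferring units respond more to 1
than to 2, and more to 2 than to 3; paired Wilcoxon signed-rank) and the
**numerical size effect** (Pearson correlation between preferred numerosity
and fitted Gaussian width). `scale_comparison()` fits each tuning curve with
a Gaussian on a linear and on a logarithmic number axis and compares paired
r-squared values (Wilcoxon signed-rank) — the Weber-Fechner signature is a
better fit on the log axis.

Numerical choices: the log axis uses `x' = log2(x + 1)` so numerosity 0 maps
to a finite position (0) and spacing compresses with magnitude; Gaussian
fits use Levenberg-Marquardt least squares with deterministic initialization
(amplitude = curve range, center = argmax, width = half the axis range,
baseline = curve minimum), width bounded below at 5% of the axis range, and
`r^2 = 1 - SS_res / SS_tot`; flat curves and failed fits are flagged
non-convergent (`r^2 = -Inf`) and excluded from paired comparisons; Wilcoxon
tests are two-sided, exact for 25 or fewer non-tied pairs, and a fully tied
comparison is defined as "no effect" (p = 1).

## Behavioral decoding and silencing

`build_matching_trials()` composes same/different trials (balanced 50/50,
numerosities and stimulus sets sampled uniformly; fresh images per trial)
and records selective-unit responses. `train_test_matching()` trains a
support vector machine on the concatenated sample-and-test response vectors.
The kernel is the radial basis function with the variance-scaled bandwidth
convention and unit cost — a deliberate choice: judging *equality* of two
codes is an XOR-type relation that no linear classifier can represent (a
linear SVM fails even on a perfect one-hot numerosity code), while in high
dimensions the variance-scaled RBF behaves near-linearly. Performance
tuning functions — P("same") per sample/test numerosity pair — exhibit the
distance and size effects when the underlying code does, and
`performance_fits()` quantifies them with the same Gaussian machinery as the
unit analysis.

`categorize_numerosity()` trains a multi-class one-vs-one SVM on half the
images of the matching task's correct trials (deduplicated by image) and
tests on the held-out half and on error-trial images. `silencing_study()`
repeats the whole chain under silencing conditions — zeroing all zero-tuned
units, an equal number of randomly chosen nonzero-tuned units, or all units
tuned to a chosen numerosity — always at test time only, and compares
per-condition true-positive rates against the intact classifier with paired
Wilcoxon tests across repetitions. In a code where the empty set is carried
by designated units, silencing exactly those units collapses zero
recognition toward the 20% five-class chance level while other classes are
untouched; matched random silencing leaves zero recognition intact.

## Reproducibility and problem sizes

Every random stage is seeded, and one master seed expands deterministically
into per-stage seeds (weights, stimuli, noise, trials, classifier splits);
identical configurations reproduce results bit for bit on one platform. The
convolution engine runs in single precision (im2col + BLAS GEMM) with
persistent workspaces, which makes the full 37,632-unit protocol practical
on one CPU core (about 2.5-3 minutes per 600-image repetition).

Desk-scale defaults used by the tests and the acceptance script: the
untrained-network statistics are averaged over 3 repetitions in the test
suite and 5 in `scripts/acceptance.R` (the reference protocol uses 100), on
the full architecture with the full 600-image stimulus plan. Repetition-to-
repetition spread of the selective fraction is large (roughly 6-22% across
seeds), which is why the headline quantities are compared within sampling
tolerances rather than exactly. The behavioral and property-based analyses
run on synthetic codes or the `tiny_architecture()` variant (56 px input,
three pooling stages, 784 final units) — that variant exists purely to
exercise code paths quickly and carries no scientific claims.

## Known limitations

* The trained-network results (10.47% selective units, 80%/96.6% matching
  accuracy, 84.6% categorization accuracy, the r = 0.56 / r = 0.73 size
  effects) require object-recognition training on 1.2M natural images and
  are not reproducible at desk scale; the package retains the full protocol
  so they can be recomputed from a trained checkpoint
  (`experiment_config(mode = "trained-checkpoint")`).
* The untrained-network selective fraction is sensitive to the input
  standardization and to initialization statistics; the package fixes one
  defensible convention (documented above) rather than sweeping them.
* Comparisons with electrophysiology (monkey, crow) and behavior are outside
  the package's scope; it computes the network-side statistics only.
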