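# Stimulus generation and the audit oracle.

test_that("zero-numerosity stimuli are pure dark backgrounds in every set", {
  set.seed(1)
  for (s in c("standard", "control1", "control2")) {
    sp <- generate_stimulus(0, s)
    expect_length(sp$items, 0)
    expect_true(all(sp$image == sp$background_intensity))
    expect_identical(audit_stimulus(sp$image, sp)$n_components, 0L)
  }
})

test_that("component counts equal the requested numerosity across sets (0-8)", {
  set.seed(2)
  for (s in c("standard", "control1", "control2")) for (n in 0:8) {
    sp <- generate_stimulus(n, s)
    a <- audit_stimulus(sp$image, sp)
    expect_identical(a$n_components, as.integer(n),
                     label = sprintf("set %s, n %d", s, n))
  }
})

test_that("standard stimuli are radius-18 discs", {
  set.seed(3)
  sp <- generate_stimulus(3, "standard")
  expect_identical(length(sp$items), 3L)
  for (it in sp$items) {
    expect_identical(it$shape, "circle")
    expect_equal(it$r, 18)
  }
  a <- audit_stimulus(sp$image, sp)
  # each rasterized component is close to a radius-18 disc in area
  expect_equal(a$foreground_area / 3, pi * 18^2, tolerance = 0.02)
})

test_that("control set 1 equates area, density and luminosity", {
  set.seed(4)
  lums <- numeric(0)
  for (n in 1:4) {
    sp <- generate_stimulus(n, "control1")
    a <- audit_stimulus(sp$image, sp)
    expect_lt(abs(a$foreground_area - 1200), 0.02 * 1200)
    if (n >= 2) expect_true(a$mean_pairwise_distance >= 90 &&
                            a$mean_pairwise_distance <= 100)
    lums <- c(lums, a$mean_luminance)
  }
  expect_lt(max(lums) - min(lums), 0.02 * mean(lums))
})

test_that("control set 2 has a triangular center hull and mixed shapes", {
  set.seed(5)
  shapes <- character(0)
  for (n in 3:6) {
    sp <- generate_stimulus(n, "control2")
    a <- audit_stimulus(sp$image, sp)
    expect_identical(a$hull_vertices, 3L)
    shapes <- c(shapes, vapply(sp$items, `[[`, "", "shape"))
  }
  expect_gt(length(unique(shapes)), 1)
})

test_that("generated stimuli pass their own audit (random property sweep)", {
  set.seed(6)
  for (i in 1:60) {
    n <- sample(0:4, 1)
    s <- sample(c("standard", "control1", "control2"), 1)
    sp <- generate_stimulus(n, s)
    a <- audit_stimulus(sp$image, sp)
    expect_true(a$pass, label = sprintf("audit %s n=%d (iter %d): %s",
      s, n, i, paste(names(a$checks)[!a$checks], collapse = ",")))
  }
})

test_that("manifests are balanced, seeded and strict about divisibility", {
  mf <- generate_manifest(0:4, c("standard", "control1", "control2"),
                          n_total = 60, seed = 9)
  tab <- table(mf$manifest$set, mf$manifest$numerosity)
  expect_true(all(tab == 4))
  mf2 <- generate_manifest(0:4, c("standard", "control1", "control2"),
                           n_total = 60, seed = 9)
  expect_identical(mf$images, mf2$images)        # byte-identical stacks
  mf3 <- generate_manifest(0:4, c("standard", "control1", "control2"),
                           n_total = 60, seed = 10)
  expect_false(identical(mf$images, mf3$images))
  expect_error(generate_manifest(0:4, "standard", n_total = 7), "divisible")
})

test_that("wide-range manifests cover the configured numerosity list", {
  mf <- generate_manifest(seq(0, 30, by = 10), "standard", n_total = 8, seed = 2)
  expect_setequal(unique(mf$manifest$numerosity), c(0, 10, 20, 30))
  set.seed(11)
  sp <- generate_stimulus(30, "standard")
  expect_identical(audit_stimulus(sp$image, sp)$n_components, 30L)
})

test_that("within control 1 area is numerosity-independent; in the standard set it grows linearly", {
  set.seed(12)
  ns <- rep(1:4, each = 8)
  area1 <- vapply(ns, function(n) {
    sp <- generate_stimulus(n, "control1")
    audit_stimulus(sp$image, sp)$foreground_area
  }, 0)
  # regression slope of area on numerosity ~ 0 for the control set
  expect_lt(abs(coef(lm(area1 ~ ns))[2]), 8)
  areaS <- vapply(ns, function(n) {
    sp <- generate_stimulus(n, "standard")
    audit_stimulus(sp$image, sp)$foreground_area
  }, 0)
  expect_equal(unname(coef(lm(areaS ~ ns))[2]), pi * 18^2, tolerance = 0.02)
})

test_that("stimuli and manifest round-trip to disk as PNG + CSV", {
  dir <- tempfile("stim")
  mf <- generate_manifest(0:1, "standard", n_total = 4, seed = 1)
  write_stimuli(mf, dir)
  tab <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(tab), 4L)
  img <- png::readPNG(file.path(dir, tab$file[1]))
  expect_equal(dim(img), c(224, 224))
  unlink(dir, recursive = TRUE)
})
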