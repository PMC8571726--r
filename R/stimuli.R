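#' @name stimuli
#' @title Controlled dot-display stimulus generation
#'
#' @description
#' Numerosity stimuli are 224 x 224 grayscale images showing 0 or more bright
#' items on a dark background. Three stimulus sets control non-numerical cues:
#'
#' * `standard`: every item is a disc of radius 18 px, randomly scattered.
#' * `control1`: discs whose total area is fixed at 1200 px^2 and whose mean
#'   pairwise center distance lies in 90-100 px (average density); at the
#'   shared foreground intensity the fixed total area also holds total and
#'   average image luminosity constant across all countable numerosities.
#' * `control2`: item shapes drawn uniformly from circle, rectangle, ellipse
#'   and triangle (area-matched to the radius-18 disc), with the convex hull
#'   of the item centers fixed to a triangle of random location and
#'   orientation for numerosities above 2.
#'
#' Numerosity 0 is a pure dark-background image in every set. Rasterization
#' tests pixel centers exactly (no
#' anti-aliasing) so connected-component counts are well defined. Items keep
#' at least 2 px between boundaries and stay fully inside the image.
NULL

STIM_SETS <- c("standard", "control1", "control2")

# --- geometry -----------------------------------------------------------

# An item is a list(shape, cx, cy, angle, intensity, ...size parameters...).
# Shapes are area-parameterized; `aspect` controls elongation where relevant.
make_item <- function(shape, cx, cy, area, angle = 0, aspect = 1,
                      intensity = 1) {
  it <- list(shape = shape, cx = cx, cy = cy, angle = angle,
             intensity = intensity, area = area)
  if (shape == "circle") {
    it$r <- sqrt(area / pi)
  } else if (shape == "rectangle") {
    it$w <- sqrt(area * aspect); it$h <- sqrt(area / aspect)
  } else if (shape == "ellipse") {
    it$a <- sqrt(area * aspect / pi); it$b <- sqrt(area / (aspect * pi))
  } else if (shape == "triangle") {
    # equilateral triangle with circumradius R: area = (3*sqrt(3)/4) R^2
    it$R <- sqrt(4 * area / (3 * sqrt(3)))
  } else stop("unknown shape: ", shape)
  it
}

# radius of the smallest disc containing the item, for overlap/border checks
bounding_radius <- function(it) {
  switch(it$shape,
         circle = it$r,
         rectangle = 0.5 * sqrt(it$w^2 + it$h^2),
         ellipse = max(it$a, it$b),
         triangle = it$R)
}

# pixel indices (row, col) covered by an item; pixel (r, c) has center (c, r)
item_pixels <- function(it, size) {
  br <- ceiling(bounding_radius(it)) + 1
  cs <- max(1, floor(it$cx - br)):min(size, ceiling(it$cx + br))
  rs <- max(1, floor(it$cy - br)):min(size, ceiling(it$cy + br))
  x <- rep(cs, each = length(rs)) - it$cx
  y <- rep(rs, times = length(cs)) - it$cy
  th <- it$angle * pi / 180
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  inside <- switch(it$shape,
    circle = x^2 + y^2 <= it$r^2,
    rectangle = abs(u) <= it$w / 2 & abs(v) <= it$h / 2,
    ellipse = (u / it$a)^2 + (v / it$b)^2 <= 1,
    triangle = {
      ang <- th + c(0, 2, 4) * pi / 3
      vx <- it$R * cos(ang); vy <- it$R * sin(ang)
      ok <- rep(TRUE, length(x))
      for (e in 1:3) {
        f <- e %% 3 + 1
        ok <- ok & ((vx[f] - vx[e]) * (y - vy[e]) -
                    (vy[f] - vy[e]) * (x - vx[e])) >= 0
      }
      ok
    })
  cbind(row = rep(rs, times = length(cs))[inside],
        col = rep(cs, each = length(rs))[inside])
}

rasterized_area <- function(it, size) nrow(item_pixels(it, size))

# scale an item's linear dimensions by s (area by s^2)
scale_item <- function(it, s) {
  make_item(it$shape, it$cx, it$cy, it$area * s^2, it$angle,
            aspect = switch(it$shape, rectangle = (it$w / it$h),
                            ellipse = (it$a / it$b), 1),
            intensity = it$intensity)
}

#' Rasterize a stimulus specification
#'
#' @param spec a `nzero_stimulus` specification.
#' @return A `size` x `size` numeric matrix with values in `[0, 1]`.
#' @export
render_stimulus <- function(spec) {
  img <- matrix(spec$background_intensity, spec$image_size, spec$image_size)
  for (it in spec$items) {
    px <- item_pixels(it, spec$image_size)
    img[px] <- it$intensity
  }
  img
}

# --- placement helpers --------------------------------------------------

ok_inside <- function(cx, cy, br, size, margin = 1) {
  cx - br >= margin + 1 && cx + br <= size - margin &&
  cy - br >= margin + 1 && cy + br <= size - margin
}

no_overlap <- function(items, it, gap = 2) {
  if (!length(items)) return(TRUE)
  br <- bounding_radius(it)
  for (o in items) {
    d <- sqrt((o$cx - it$cx)^2 + (o$cy - it$cy)^2)
    if (d < bounding_radius(o) + br + gap) return(FALSE)
  }
  TRUE
}

mean_pairwise_dist <- function(cx, cy) {
  if (length(cx) < 2) return(NA_real_)
  mean(stats::dist(cbind(cx, cy)))
}

gen_error <- function(constraint, numerosity, set_id) {
  stop(sprintf(paste0("stimulus generation failed for numerosity %d, set '%s': ",
                      "constraint '%s' unsatisfied within the attempt budget"),
               numerosity, set_id, constraint), call. = FALSE)
}

# scatter n items of the given areas/shapes uniformly, rejecting overlaps
scatter_items <- function(n, size, area_fn, shape_fn, max_attempts) {
  items <- list()
  attempts <- 0
  while (length(items) < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts) return(NULL)
    area <- area_fn(length(items) + 1)
    it <- shape_fn(area)
    br <- bounding_radius(it)
    it$cx <- stats::runif(1, br + 2, size - br - 1)
    it$cy <- stats::runif(1, br + 2, size - br - 1)
    if (no_overlap(items, it)) items <- c(items, list(it))
    else if (attempts %% 500 == 0) items <- list()  # restart if wedged
  }
  items
}

# --- per-set generators -------------------------------------------------

# All geometric constants are specified at the reference 224 px resolution
# and scale linearly with image size so reduced-resolution stimuli (used with
# the tiny test network) keep the same relative geometry.
stim_scale <- function(size) size / 224

gen_standard <- function(n, size, max_attempts) {
  # radius 18 for the core range; shrink for dense wide-range displays so
  # that random non-overlapping placement stays feasible
  r <- min(18 * stim_scale(size), sqrt(0.35 * size^2 / (max(n, 1) * pi)))
  items <- scatter_items(n, size, function(i) pi * r^2,
                         function(a) make_item("circle", 0, 0, a),
                         max_attempts)
  if (is.null(items)) gen_error("non-overlapping placement", n, "standard")
  list(items = items, background = 0)
}

gen_control1 <- function(n, size, max_attempts,
                         total_area = 1200 * stim_scale(size)^2,
                         dist_range = c(90, 100) * stim_scale(size),
                         dot_intensity = 1.0) {
  if (n == 0) return(list(items = list(), background = 0))
  min_area <- pi * max(1.5, 3 * stim_scale(size))^2
  # split the fixed total area across dots with mild size variation
  for (attempt in seq_len(max_attempts)) {
    w <- stats::runif(n, 0.8, 1.2)
    areas <- total_area * w / sum(w)
    if (any(areas < min_area)) next
    items <- lapply(areas, function(a) make_item("circle", 0, 0, a))
    brs <- vapply(items, bounding_radius, 0)
    # place centers, then rescale about the centroid to hit the target mean
    # pairwise distance (the mean scales linearly with the configuration)
    cx <- stats::runif(n, max(brs) + 2, size - max(brs) - 1)
    cy <- stats::runif(n, max(brs) + 2, size - max(brs) - 1)
    if (n >= 2) {
      target <- stats::runif(1, dist_range[1] + 1, dist_range[2] - 1)
      s <- target / mean_pairwise_dist(cx, cy)
      cx <- mean(cx) + (cx - mean(cx)) * s
      cy <- mean(cy) + (cy - mean(cy)) * s
    }
    for (i in seq_len(n)) { items[[i]]$cx <- cx[i]; items[[i]]$cy <- cy[i] }
    ok <- all(vapply(seq_len(n), function(i)
      ok_inside(cx[i], cy[i], brs[i], size), TRUE))
    if (ok) for (i in seq_len(n))
      if (!no_overlap(items[seq_len(i - 1)], items[[i]])) { ok <- FALSE; break }
    if (!ok) next
    # trim radii so the *rasterized* foreground area matches the target
    count_total <- function(s) sum(vapply(items, function(it)
      rasterized_area(scale_item(it, s), size), 0))
    lo <- 0.9; hi <- 1.1
    for (k in 1:14) {
      mid <- (lo + hi) / 2
      if (count_total(mid) > total_area) hi <- mid else lo <- mid
    }
    s_best <- (lo + hi) / 2
    items <- lapply(items, scale_item, s = s_best)
    fg <- sum(vapply(items, rasterized_area, 0, size = size))
    if (abs(fg - total_area) > max(0.015 * total_area, 3)) next
    items <- lapply(items, function(it) { it$intensity <- dot_intensity; it })
    return(list(items = items, background = 0))
  }
  gen_error("area/density/luminance placement", n, "control1")
}

gen_control2 <- function(n, size, max_attempts,
                         base_area = pi * (18 * stim_scale(size))^2) {
  shapes <- c("circle", "rectangle", "ellipse", "triangle")
  rand_shape <- function(a) make_item(sample(shapes, 1), 0, 0, a,
                                      angle = stats::runif(1, 0, 360),
                                      aspect = stats::runif(1, 0.6, 1.6))
  if (n <= 2) {
    area <- min(base_area, 0.3 * size^2 / max(n, 1))
    items <- scatter_items(n, size, function(i) area, rand_shape, max_attempts)
    if (is.null(items)) gen_error("non-overlapping placement", n, "control2")
    return(list(items = items, background = 0))
  }
  # item area shrinks for crowded displays so interior placement is feasible
  area <- if (n <= 4) base_area else min(base_area, base_area * (4.5 / n)^2)
  for (attempt in seq_len(max_attempts)) {
    br <- bounding_radius(make_item("triangle", 0, 0, area))  # generous bound
    m <- br + 3
    # vertices drawn in polar sectors around a jittered center: large
    # triangles of random orientation whose interior can host the rest
    c0 <- size / 2 + stats::runif(2, -15, 15)
    phi <- stats::runif(1, 0, 2 * pi) + 2 * pi * (0:2) / 3 +
           stats::runif(3, -0.5, 0.5)
    rmax <- pmin(
      ifelse(cos(phi) > 0, (size - m - c0[1]) / cos(phi), (m + 1 - c0[1]) / cos(phi)),
      ifelse(sin(phi) > 0, (size - m - c0[2]) / sin(phi), (m + 1 - c0[2]) / sin(phi)))
    if (any(rmax < 0.25 * size)) next
    rad <- stats::runif(3, 0.25 * size, rmax)
    vx <- c0[1] + rad * cos(phi); vy <- c0[2] + rad * sin(phi)
    sides <- c(sqrt((vx[1]-vx[2])^2+(vy[1]-vy[2])^2),
               sqrt((vx[2]-vx[3])^2+(vy[2]-vy[3])^2),
               sqrt((vx[3]-vx[1])^2+(vy[3]-vy[1])^2))
    if (min(sides) < 4 * br + 8 * stim_scale(size)) next
    items <- list()
    ok <- TRUE
    for (i in 1:3) {
      it <- rand_shape(area); it$cx <- vx[i]; it$cy <- vy[i]
      if (!ok_inside(it$cx, it$cy, bounding_radius(it), size) ||
          !no_overlap(items, it)) { ok <- FALSE; break }
      items <- c(items, list(it))
    }
    if (!ok) next
    # remaining items go strictly inside the hull, clear of its edges
    inner_tries <- 0
    while (ok && length(items) < n) {
      inner_tries <- inner_tries + 1
      if (inner_tries > 400) { ok <- FALSE; break }
      b <- stats::rexp(3); b <- b / sum(b)
      it <- rand_shape(area)
      it$cx <- sum(b * vx); it$cy <- sum(b * vy)
      # distance from each triangle edge, to keep the center well interior
      edge_d <- vapply(1:3, function(e) {
        f <- e %% 3 + 1
        abs((vx[f]-vx[e])*(it$cy-vy[e]) - (vy[f]-vy[e])*(it$cx-vx[e])) / sides[e]
      }, 0)
      if (min(edge_d) < max(3, 8 * stim_scale(size))) next
      if (ok_inside(it$cx, it$cy, bounding_radius(it), size) &&
          no_overlap(items, it)) items <- c(items, list(it))
    }
    if (ok) return(list(items = items, background = 0))
  }
  gen_error("triangular convex hull placement", n, "control2")
}

# --- public API ---------------------------------------------------------

#' Generate one numerosity stimulus
#'
#' Draws a stimulus specification satisfying all geometric constraints of the
#' requested set (rejection-sampled, bounded attempts) and rasterizes it.
#' Randomness comes from the current R RNG stream; seed externally for
#' reproducibility.
#'
#' @param numerosity integer >= 0; number of items.
#' @param set_id one of `"standard"`, `"control1"`, `"control2"`.
#' @param image_size image side in pixels.
#' @param max_attempts rejection-sampling budget before erroring.
#' @return A list of class `nzero_stimulus`: `numerosity`, `set_id`, `items`,
#'   `background_intensity`, `image_size`, and the rasterized `image`.
#' @export
generate_stimulus <- function(numerosity, set_id = "standard",
                              image_size = 224, max_attempts = 10000) {
  stopifnot(length(numerosity) == 1, numerosity >= 0,
            numerosity == round(numerosity))
  set_id <- match.arg(set_id, STIM_SETS)
  gen <- switch(set_id,
                standard = gen_standard(numerosity, image_size, max_attempts),
                control1 = gen_control1(numerosity, image_size, max_attempts),
                control2 = gen_control2(numerosity, image_size, max_attempts))
  spec <- structure(list(numerosity = as.integer(numerosity), set_id = set_id,
                         items = gen$items,
                         background_intensity = gen$background,
                         image_size = as.integer(image_size)),
                    class = "nzero_stimulus")
  spec$image <- render_stimulus(spec)
  spec
}

#' Generate a balanced stimulus manifest
#'
#' Produces `n_total` stimuli with equal counts in every numerosity-by-set
#' cell, fully reproducible from `seed`.
#'
#' @param numerosities integer vector of numerosities (default 0:4).
#' @param sets character vector of stimulus sets.
#' @param n_total total number of images; must be divisible by
#'   `length(numerosities) * length(sets)`.
#' @param seed integer RNG seed.
#' @param image_size image side in pixels.
#' @return A list of class `nzero_manifest` with `manifest` (data frame:
#'   `id`, `set`, `numerosity`), `specs` (list of `nzero_stimulus`), `images`
#'   (list of matrices), `numerosities`, `sets` and `seed`.
#' @export
generate_manifest <- function(numerosities = 0:4,
                              sets = STIM_SETS,
                              n_total = 600, seed = 1L, image_size = 224) {
  n_cells <- length(numerosities) * length(sets)
  if (n_total %% n_cells != 0)
    stop(sprintf("n_total = %d is not divisible by the %d numerosity x set cells",
                 n_total, n_cells))
  per_cell <- n_total %/% n_cells
  set.seed(seed)
  grid <- expand.grid(numerosity = numerosities, set = sets,
                      rep = seq_len(per_cell), stringsAsFactors = FALSE)
  specs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid)))
    specs[[i]] <- generate_stimulus(grid$numerosity[i], grid$set[i],
                                    image_size = image_size)
  structure(list(
    manifest = data.frame(id = seq_len(nrow(grid)), set = grid$set,
                          numerosity = grid$numerosity),
    specs = specs,
    images = lapply(specs, `[[`, "image"),
    numerosities = numerosities, sets = sets, seed = seed
  ), class = "nzero_manifest")
}

#' @export
print.nzero_manifest <- function(x, ...) {
  cat(sprintf("<nzero_manifest> %d stimuli, numerosities {%s}, sets {%s}, seed %d\n",
              nrow(x$manifest), paste(x$numerosities, collapse = ","),
              paste(x$sets, collapse = ","), x$seed))
  invisible(x)
}

#' Audit a rendered stimulus against its specification
#'
#' Independent verification of the generator: counts connected bright
#' components (8-connectivity flood fill), measures foreground area and mean
#' luminance, mean pairwise distance between component centroids, and the
#' number of convex-hull vertices of the item centers; reports pass/fail per
#' constraint of the stimulus set.
#'
#' @param image rasterized image matrix.
#' @param spec the claimed `nzero_stimulus` specification.
#' @return A list with measured quantities, per-constraint `checks`
#'   (named logical vector) and overall `pass`.
#' @export
audit_stimulus <- function(image, spec) {
  bg <- spec$background_intensity
  mask <- image > bg + 0.1
  lab <- cpp_label_components(mask)
  n_comp <- attr(lab, "n")
  fg_area <- sum(mask)
  lum <- mean(image)
  cent <- if (n_comp > 0) {
    t(vapply(seq_len(n_comp), function(k) {
      px <- which(lab == k, arr.ind = TRUE)
      c(cx = mean(px[, 2]), cy = mean(px[, 1]))
    }, c(cx = 0, cy = 0)))
  } else matrix(numeric(0), 0, 2)
  mpd <- if (n_comp >= 2) mean(stats::dist(cent)) else NA_real_
  centers <- vapply(spec$items, function(it) c(it$cx, it$cy), c(0, 0))
  hull_v <- if (spec$numerosity > 2)
    length(grDevices::chull(centers[1, ], centers[2, ])) else NA_integer_

  checks <- c(component_count = n_comp == spec$numerosity)
  if (spec$set_id == "standard" && spec$numerosity > 0) {
    radii <- vapply(spec$items, function(it) it$r, 0)
    checks["constant_radius"] <- all(abs(radii - radii[1]) < 1e-9)
  }
  if (spec$set_id == "control1") {
    sc <- stim_scale(spec$image_size)
    target <- 1200 * sc^2
    # fixed total area at fixed intensity => constant luminosity for n >= 1
    if (spec$numerosity >= 1)
      checks["constant_luminosity"] <-
        abs(lum - target / spec$image_size^2) <
          max(0.02 * target, 4) / spec$image_size^2
    if (spec$numerosity >= 1)
      checks["total_area_1200"] <-
        abs(fg_area - target) <= max(0.02 * target, 4)
    if (spec$numerosity >= 2)
      checks["pairwise_distance_90_100"] <- mpd >= 90 * sc && mpd <= 100 * sc
  }
  if (spec$set_id == "control2" && spec$numerosity > 2)
    checks["triangular_hull"] <- hull_v == 3
  list(n_components = n_comp, foreground_area = fg_area,
       mean_luminance = lum, mean_pairwise_distance = mpd,
       hull_vertices = hull_v, component_centroids = cent,
       checks = checks, pass = all(checks))
}

#' Write a manifest's images and table to disk
#'
#' Images go to 8-bit grayscale PNG files named
#' `{set}_{numerosity}_{index}.png`; the manifest table to a CSV.
#'
#' @param mf a `nzero_manifest`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest CSV path.
#' @export
write_stimuli <- function(mf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- mf$manifest
  tab$file <- sprintf("%s_%d_%04d.png", tab$set, tab$numerosity, tab$id)
  for (i in seq_len(nrow(tab)))
    png::writePNG(mf$images[[i]], file.path(dir, tab$file[i]))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
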