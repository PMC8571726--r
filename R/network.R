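#' Lateral-inhibition (local response normalization) parameters
#'
#' Divisive normalization across adjacent feature maps at the same spatial
#' location, mimicking lateral inhibition between units sharing a receptive
#' field:
#'   `b[x,y,i] = a[x,y,i] / (k + alpha * sum_j max(0, a[x,y,j])^2)^beta`
#' with `j` running over `max(0, i - n/2) ... min(N - 1, i + n/2)`.
#'
#' @param k offset constant (> 0).
#' @param alpha scale constant.
#' @param beta denominator exponent (>= 0).
#' @param n neighborhood size in feature maps.
#' @return A list of class `nzero_lrn_params`.
#' @export
lrn_params <- function(k = 2, alpha = 1e-4, beta = 0.75, n = 15) {
  if (!is.finite(k) || k <= 0) stop("LRN offset k must be a positive finite number")
  if (!is.finite(beta) || beta < 0) stop("LRN exponent beta must be >= 0")
  if (!is.finite(alpha)) stop("LRN scale alpha must be finite")
  structure(list(k = k, alpha = alpha, beta = beta, n = as.integer(n)),
            class = "nzero_lrn_params")
}

#' Multiplicative response-noise parameters
#'
#' Gaussian multiplicative noise injected into the outputs of all
#' convolutional units, independently per unit and per presentation. It
#' introduces response variation even for the constant empty-set stimulus.
#'
#' @param mu noise mean (1 leaves responses unbiased).
#' @param sigma noise standard deviation.
#' @param enabled logical switch.
#' @return A list of class `nzero_noise_params`.
#' @export
noise_params <- function(mu = 1.0, sigma = 0.15, enabled = TRUE) {
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  structure(list(mu = mu, sigma = sigma, enabled = isTRUE(enabled)),
            class = "nzero_noise_params")
}

#' Local response normalization of a feature-map stack
#'
#' @param a numeric array of shape (height, width, maps); a matrix is
#'   treated as a single map.
#' @param params an [lrn_params()] object.
#' @return Array of the same shape with normalized responses.
#' @export
local_response_normalize <- function(a, params = lrn_params()) {
  if (!inherits(params, "nzero_lrn_params")) params <- do.call(lrn_params, params)
  if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3) stop("input must be a (height, width, maps) array")
  if (!all(is.finite(a))) stop("non-finite values in LRN input")
  cpp_lrn(a, params$k, params$alpha, params$beta, params$n)
}

# Xavier (Glorot) uniform draw for a kernel of shape (kh, kw, cin, cout);
# biases use the fan-in uniform convention.
xavier_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  fan_out <- kh * kw * cout
  a <- sqrt(6 / (fan_in + fan_out))
  w <- array(stats::runif(kh * kw * cin * cout, -a, a), dim = c(kh, kw, cin, cout))
  b <- stats::runif(cout, -1 / sqrt(fan_in), 1 / sqrt(fan_in))
  list(w = w, b = b)
}

#' Build and initialize the network
#'
#' Constructs the hierarchical convolutional network from a layer table and
#' initializes convolution kernels with the Xavier uniform scheme, biases
#' with the fan-in uniform convention, and batch-normalization parameters at
#' their standard starting point (scale 1, shift 0, running mean 0, running
#' variance 1). Every convolutional stage applies, in order, convolution,
#' batch normalization, rectification `f(x) = max(x, 0)` and
#' lateral-inhibition normalization; pooling stages take maxima over
#' non-overlapping 2x2 patches.
#'
#' @param arch a layer table; see [default_architecture()].
#' @param seed integer seed for the weight draw.
#' @param lrn an [lrn_params()] object.
#' @param input_norm per-channel input standardization applied to every
#'   image before the first layer, `list(mean =, sd =)` with one value per
#'   channel; defaults to [imagenet_input_norm()], the preprocessing used
#'   for natural-image classification. `NULL` disables it.
#' @return An object of class `nzero_network`.
#' @export
build_network <- function(arch = default_architecture(), seed = 1L,
                          lrn = lrn_params(),
                          input_norm = imagenet_input_norm()) {
  validate_architecture(arch)
  set.seed(seed)
  layers <- vector("list", nrow(arch))
  cur_maps <- arch$maps[1]
  for (r in seq_len(nrow(arch))[-1]) {
    role <- arch$role[r]
    if (role == "conv") {
      k <- arch$kernel[r]
      out <- arch$maps[r]
      init <- xavier_conv(k, k, cur_maps, out)
      layers[[r]] <- list(
        w = init$w, b = init$b,
        bn = list(gamma = rep(1, out), beta = rep(0, out),
                  mean = rep(0, out), var = rep(1, out))
      )
      cur_maps <- out
    } else if (role == "softmax") {
      n_in <- cur_maps
      n_out <- arch$maps[r]
      a <- sqrt(6 / (n_in + n_out))
      layers[[r]] <- list(
        w = matrix(stats::runif(n_out * n_in, -a, a), n_out, n_in),
        b = stats::runif(n_out, -1 / sqrt(n_in), 1 / sqrt(n_in))
      )
    }
  }
  structure(list(arch = arch, layers = layers, lrn = lrn, seed = seed,
                 input_norm = input_norm, bn_eps = 1e-5, trained = FALSE,
                 engine_cache = new.env(parent = emptyenv())),
            class = "nzero_network")
}

#' @export
print.nzero_network <- function(x, ...) {
  ff <- final_feature_layer(x)
  arch <- x$arch
  fr <- arch[arch$index == ff, ]
  out_size <- fr$size  # conv preserves size
  cat(sprintf("<nzero_network> %d layers, %s, seed %d\n", nrow(arch),
              if (isTRUE(attr(arch, "tiny"))) "tiny variant" else "full architecture",
              x$seed))
  cat(sprintf("  final feature layer %d: %d maps x %d x %d = %d units\n",
              ff, fr$maps, out_size, out_size, fr$maps * out_size^2))
  invisible(x)
}

#' Standard natural-image input normalization
#'
#' Per-channel standardization constants conventionally used for networks
#' trained on large natural-image collections; stimuli are passed through the
#' same preprocessing as the training images, so a dark background maps to a
#' strongly negative input value rather than zero.
#'
#' @return `list(mean, sd)` with three per-channel values each.
#' @export
imagenet_input_norm <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

# apply per-channel standardization to an (H, W, 3) array
normalize_input <- function(x, input_norm) {
  if (is.null(input_norm)) return(x)
  npix <- prod(dim(x)[1:2])
  x <- (x - rep(input_norm$mean, each = npix)) / rep(input_norm$sd, each = npix)
  x
}

# Coerce an input image to an (H, W, 3) array; grayscale matrices are
# replicated across the three input channels.
as_input_array <- function(img, size) {
  if (is.matrix(img)) {
    if (nrow(img) != size || ncol(img) != size)
      stop(sprintf("image must be %d x %d for this network", size, size))
    array(img, dim = c(size, size, 3))
  } else if (is.array(img) && length(dim(img)) == 3) {
    if (dim(img)[1] != size || dim(img)[2] != size || dim(img)[3] != 3)
      stop(sprintf("image array must be %d x %d x 3", size, size))
    img
  } else stop("image must be a matrix or (H, W, 3) array")
}

# Evaluation-mode batch normalization using running statistics.
bn_eval <- function(x, bn, eps) {
  npix <- prod(dim(x)[1:2])
  s <- bn$gamma / sqrt(bn$var + eps)
  o <- bn$beta - bn$mean * s
  if (all(s == s[1]) && all(o == o[1])) {
    x * s[1] + o[1]
  } else {
    x * rep(s, each = npix) + rep(o, each = npix)
  }
}

# Compile the network into the single-precision inference engine (weights
# converted once, batch normalization folded into a per-map scale/offset).
# The handle is cached in an environment attached to the network object.
net_engine <- function(net) {
  cache <- net$engine_cache
  if (!is.null(cache$ptr) && cpp_xptr_valid(cache$ptr)) return(cache$ptr)
  arch <- net$arch
  role_code <- c(input = 0L, conv = 1L, maxpool = 2L, avgpool = 3L,
                 softmax = 4L)[arch$role]
  convs <- list()
  for (r in which(arch$role == "conv")) {
    ly <- net$layers[[r]]
    s <- ly$bn$gamma / sqrt(ly$bn$var + net$bn_eps)
    convs[[length(convs) + 1]] <- list(
      w = ly$w, b = ly$b, bn_scale = s, bn_off = ly$bn$beta - ly$bn$mean * s,
      pad = (arch$kernel[r] - 1L) %/% 2L
    )
  }
  fc_row <- which(arch$role == "softmax")
  spec <- list(role = unname(role_code), index = arch$index,
               in_size = arch$size[1],
               lrn = with(net$lrn, c(k, alpha, beta, n)),
               convs = convs,
               fcW = if (length(fc_row)) net$layers[[fc_row]]$w,
               fcb = if (length(fc_row)) net$layers[[fc_row]]$b)
  ptr <- cpp_net_create(spec)
  if (!is.null(cache)) cache$ptr <- ptr
  ptr
}

# Single-image forward pass (evaluation mode). Returns the activation of
# `record` (a layer index) or, if record is NULL, the softmax probabilities.
# Noise seeds are drawn from the current R RNG stream, one per presentation.
forward_eval <- function(net, img, record = NULL,
                         noise = noise_params(enabled = FALSE),
                         engine = net_engine(net)) {
  x <- normalize_input(as_input_array(img, net$arch$size[1]), net$input_norm)
  noise_seed <- if (noise$enabled) sample.int(.Machine$integer.max, 1L) else 0L
  cpp_net_forward(engine, x, if (is.null(record)) -1L else as.integer(record),
                  noise$enabled, noise$mu, noise$sigma, noise_seed)
}

#' Present stimuli and record unit activations
#'
#' Runs a batch of images through the feature-extraction network and records
#' the responses of every unit in the named layer. When noise is enabled,
#' every convolutional unit's output is multiplied by an independent Gaussian
#' draw (mean `mu`, s.d. `sigma`), re-drawn at each presentation, so even the
#' constant empty-set stimulus evokes variable responses.
#'
#' @param net a `nzero_network`.
#' @param images list of images (matrices or (H, W, 3) arrays).
#' @param layer_index index of a feature-extraction layer to record
#'   (default: the final one).
#' @param noise a [noise_params()] object.
#' @param seed integer seed for the noise draws.
#' @param stimulus_ids optional identifiers for the columns.
#' @return An object of class `nzero_activations`: list with `values`
#'   (units x stimuli matrix), `unit_coords` (data frame with `map`, `row`,
#'   `col` per unit), `stimulus_ids`, `layer_index`, `noise` and `seed`.
#' @export
forward_record <- function(net, images, layer_index = final_feature_layer(net),
                           noise = noise_params(), seed = 1L,
                           stimulus_ids = NULL) {
  stopifnot(inherits(net, "nzero_network"))
  if (is.array(images) && length(dim(images)) == 3 && dim(images)[3] != 3)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  if (!is.list(images)) images <- list(images)
  arch <- net$arch
  row <- which(arch$index == layer_index)
  if (!length(row) || arch$role[row] != "conv")
    stop("layer_index must name a convolutional (feature-extraction) layer")
  out_size <- arch$size[row]
  n_maps <- arch$maps[row]
  n_units <- n_maps * out_size^2
  set.seed(seed)
  engine <- net_engine(net)
  values <- matrix(NA_real_, n_units, length(images))
  for (i in seq_along(images))
    values[, i] <- as.vector(forward_eval(net, images[[i]], record = layer_index,
                                          noise = noise, engine = engine))
  if (is.null(stimulus_ids)) stimulus_ids <- seq_along(images)
  unit_coords <- data.frame(
    row = rep_len(seq_len(out_size), n_units),
    col = rep(rep(seq_len(out_size), each = out_size), n_maps),
    map = rep(seq_len(n_maps), each = out_size^2)
  )
  structure(list(values = values, unit_coords = unit_coords,
                 stimulus_ids = stimulus_ids, layer_index = layer_index,
                 noise = noise, seed = seed),
            class = "nzero_activations")
}

#' Top-k category predictions for an image
#'
#' @param net a `nzero_network`.
#' @param image input image.
#' @param k number of categories to return (1 to the number of classes).
#' @param noise optional [noise_params()]; disabled by default.
#' @return Data frame with `class` (integer category index) and `confidence`
#'   (softmax probability), sorted by descending confidence.
#' @export
top_k_predictions <- function(net, image, k = 5,
                              noise = noise_params(enabled = FALSE)) {
  n_classes <- net$arch$maps[nrow(net$arch)]
  if (k < 1) stop("k must be at least 1")
  if (k > n_classes) stop("k cannot exceed the number of categories")
  p <- forward_eval(net, image, noise = noise)
  ord <- order(p, decreasing = TRUE)[seq_len(k)]
  data.frame(class = ord, confidence = p[ord])
}
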