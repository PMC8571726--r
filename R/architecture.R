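#' Layer table of the full hierarchical convolutional network
#'
#' Returns the declarative description of the 16-layer network (input,
#' 8 convolutional layers, 5 max-pooling layers, a global average-pooling
#' layer and a 1000-way softmax classifier). The spatial size of each row is
#' the size of the layer's *input*; convolutions preserve spatial size
#' (stride 1, zero padding), pooling halves it, so the chain telescopes
#' 224 -> 112 -> 56 -> 28 -> 14 -> 7. The final feature-extraction layer
#' (layer 13) holds 768 maps of 7 x 7 units = 37,632 units.
#'
#' @return A data frame with columns `index`, `role`, `maps`, `size`
#'   (input spatial size in pixels) and `kernel` (kernel size in pixels),
#'   one row per layer. Carries the attribute `tiny = FALSE`.
#' @export
default_architecture <- function() {
  arch <- data.frame(
    index  = 0:15,
    role   = c("input", "conv", "maxpool", "conv", "maxpool", "conv",
               "maxpool", "conv", "maxpool", "conv", "maxpool", "conv",
               "conv", "conv", "avgpool", "softmax"),
    maps   = c(3, 32, 32, 48, 48, 96, 96, 192, 192, 384, 384, 768, 768, 768,
               768, 1000),
    size   = c(224, 224, 224, 112, 112, 56, 56, 28, 28, 14, 14, 7, 7, 7, 7, 1),
    kernel = c(NA, 9, 2, 9, 2, 7, 2, 5, 2, 5, 2, 5, 5, 5, 7, 1),
    stringsAsFactors = FALSE
  )
  attr(arch, "tiny") <- FALSE
  arch
}

#' Reduced architecture for fast tests
#'
#' A small network with the same stage structure (convolution, batch
#' normalization, rectification, lateral-inhibition normalization, 2x2
#' max pooling, global average pooling, softmax) but fewer feature maps,
#' a 56 x 56 input and three pooling stages. Used only to exercise code
#' paths quickly; all scientific numbers come from the full architecture.
#'
#' @param n_classes number of softmax output categories.
#' @return A layer data frame as in [default_architecture()], with
#'   attribute `tiny = TRUE`.
#' @export
tiny_architecture <- function(n_classes = 10) {
  arch <- data.frame(
    index  = 0:10,
    role   = c("input", "conv", "maxpool", "conv", "maxpool", "conv",
               "maxpool", "conv", "conv", "avgpool", "softmax"),
    maps   = c(3, 8, 8, 12, 12, 16, 16, 16, 16, 16, n_classes),
    size   = c(56, 56, 56, 28, 28, 14, 14, 7, 7, 7, 1),
    kernel = c(NA, 5, 2, 3, 2, 3, 2, 3, 3, 7, 1),
    stringsAsFactors = FALSE
  )
  attr(arch, "tiny") <- TRUE
  arch
}

#' Validate a layer table
#'
#' Checks that the layer chain telescopes (convolutions preserve spatial
#' size, pooling halves it, global average pooling collapses to 1 x 1) and,
#' for the full architecture, that it matches the canonical 16-layer table.
#'
#' @param arch a layer data frame.
#' @return `arch`, invisibly, if valid; otherwise an error naming the
#'   offending layer.
#' @export
validate_architecture <- function(arch) {
  stopifnot(is.data.frame(arch),
            all(c("index", "role", "maps", "size", "kernel") %in% names(arch)))
  if (arch$role[1] != "input")
    stop("layer 0 must be the input layer")
  cur_size <- arch$size[1]
  cur_maps <- arch$maps[1]
  for (r in seq_len(nrow(arch))[-1]) {
    role <- arch$role[r]
    if (arch$size[r] != cur_size)
      stop(sprintf("layer %d: listed spatial size %d does not match incoming size %d",
                   arch$index[r], arch$size[r], cur_size))
    if (role == "conv") {
      if (arch$kernel[r] %% 2 != 1)
        stop(sprintf("layer %d: convolution kernels must be odd for same-size padding",
                     arch$index[r]))
      cur_maps <- arch$maps[r]
    } else if (role == "maxpool") {
      if (cur_size %% 2 != 0)
        stop(sprintf("layer %d: cannot 2x2-pool an odd spatial size %d",
                     arch$index[r], cur_size))
      if (arch$maps[r] != cur_maps)
        stop(sprintf("layer %d: pooling cannot change the map count", arch$index[r]))
      cur_size <- cur_size / 2
    } else if (role == "avgpool") {
      if (arch$kernel[r] != cur_size)
        stop(sprintf("layer %d: global average pooling kernel must equal the spatial size",
                     arch$index[r]))
      cur_size <- 1
    } else if (role == "softmax") {
      if (cur_size != 1)
        stop(sprintf("layer %d: softmax classifier expects 1x1 input", arch$index[r]))
    } else {
      stop(sprintf("layer %d: unknown role '%s'", arch$index[r], role))
    }
  }
  if (!isTRUE(attr(arch, "tiny"))) {
    ref <- default_architecture()
    if (!identical(ref$role, arch$role) || !identical(ref$maps, arch$maps) ||
        !identical(ref$size, arch$size))
      stop("full architecture must match the canonical 16-layer table; ",
           "use a tiny = TRUE variant for reduced networks")
  }
  invisible(arch)
}

#' Index of the final feature-extraction layer
#'
#' The last convolutional layer before the classification stage; its
#' activations are the ones analyzed for numerosity tuning (layer 13 in the
#' full network, with 768 x 7 x 7 = 37,632 units).
#'
#' @param net a network from [build_network()].
#' @return Integer layer index.
#' @export
final_feature_layer <- function(net) {
  arch <- net$arch
  max(arch$index[arch$role == "conv"])
}

#' Read or write a layer table as YAML
#'
#' The YAML mirrors the layer table: one entry per layer with fields
#' `index`, `role`, `maps`, `size` and `kernel`, plus a top-level `tiny`
#' flag for reduced variants.
#'
#' @param path YAML file path.
#' @return For `read_architecture_yaml()`, a validated layer data frame.
#' @export
read_architecture_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  layers <- doc$layers
  arch <- data.frame(
    index  = vapply(layers, function(l) as.integer(l$index), 0L),
    role   = vapply(layers, function(l) as.character(l$role), ""),
    maps   = vapply(layers, function(l) as.integer(l$maps), 0L),
    size   = vapply(layers, function(l) as.integer(l$size), 0L),
    kernel = vapply(layers, function(l)
      if (is.null(l$kernel)) NA_integer_ else as.integer(l$kernel), 0L),
    stringsAsFactors = FALSE
  )
  attr(arch, "tiny") <- isTRUE(doc$tiny)
  validate_architecture(arch)
  arch
}

#' @rdname read_architecture_yaml
#' @param arch a layer data frame.
#' @export
write_architecture_yaml <- function(arch, path) {
  validate_architecture(arch)
  doc <- list(
    tiny = isTRUE(attr(arch, "tiny")),
    layers = lapply(seq_len(nrow(arch)), function(r) {
      l <- list(index = arch$index[r], role = arch$role[r],
                maps = arch$maps[r], size = arch$size[r])
      if (!is.na(arch$kernel[r])) l$kernel <- arch$kernel[r]
      l
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
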