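#' @name training
#' @title Object-recognition training pathway
#'
#' @description
#' The network can optionally be trained for object classification by
#' mini-batch gradient descent with momentum, minimizing the cross-entropy
#' between the softmax output and ground-truth labels. Batch normalization
#' uses batch statistics during training (updating running statistics used
#' at evaluation); response noise is never applied during training. Training
#' at the reference scale (1.2M natural images, 10 epochs) is a long-running
#' operation far beyond a desk machine; every numerosity analysis in this
#' package runs on untrained (randomly initialized) networks, and the
#' training pathway is exercised on small fixtures.
NULL

#' Training configuration
#'
#' @param epochs complete passes over the training data.
#' @param batch_size mini-batch size.
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum coefficient.
#' @param bn_momentum running-statistics update rate for batch normalization.
#' @param checkpoint_dir if non-NULL, a checkpoint is written per epoch.
#' @return A list of class `nzero_train_config`.
#' @export
train_config <- function(epochs = 10, batch_size = 256, learning_rate = 0.1,
                         momentum = 0.9, bn_momentum = 0.1,
                         checkpoint_dir = NULL) {
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, momentum = momentum,
                 bn_momentum = bn_momentum, checkpoint_dir = checkpoint_dir),
            class = "nzero_train_config")
}

# training-mode forward pass over a batch (list of input arrays); returns
# softmax probabilities and the caches needed for backpropagation
forward_train_batch <- function(net, batch) {
  arch <- net$arch
  B <- length(batch)
  xs <- lapply(batch, function(im)
    normalize_input(as_input_array(im, arch$size[1]), net$input_norm))
  caches <- vector("list", nrow(arch))
  for (r in seq_len(nrow(arch))[-1]) {
    role <- arch$role[r]
    if (role == "conv") {
      ly <- net$layers[[r]]
      pad <- (arch$kernel[r] - 1L) %/% 2L
      zero_b <- numeric(length(ly$b))  # bias added before BN via conv's own b
      zs <- lapply(xs, function(x) cpp_conv2d(x, ly$w, ly$b, pad))
      C <- dim(zs[[1]])[3]; npix <- prod(dim(zs[[1]])[1:2])
      m <- B * npix
      sums <- Reduce(`+`, lapply(zs, function(z) colSums(matrix(z, ncol = C))))
      mu <- sums / m
      sq <- Reduce(`+`, lapply(zs, function(z)
        colSums(matrix(z, ncol = C)^2)))
      v <- sq / m - mu^2          # biased batch variance
      inv_sd <- 1 / sqrt(v + net$bn_eps)
      xhats <- lapply(zs, function(z)
        (z - rep(mu, each = npix)) * rep(inv_sd, each = npix))
      ys <- lapply(xhats, function(xh) {
        y <- xh * rep(ly$bn$gamma, each = npix) + rep(ly$bn$beta, each = npix)
        y[y < 0] <- 0
        y
      })
      lrn <- net$lrn
      outs <- lapply(ys, function(y)
        cpp_lrn(y, lrn$k, lrn$alpha, lrn$beta, lrn$n))
      caches[[r]] <- list(x_in = xs, xhat = xhats, y_relu = ys,
                          inv_sd = inv_sd, mu = mu, var = v, m = m,
                          npix = npix, C = C, pad = pad)
      xs <- outs
    } else if (role == "maxpool") {
      pooled <- lapply(xs, cpp_maxpool2)
      caches[[r]] <- list(argmax = lapply(pooled, `[[`, "argmax"),
                          in_dim = dim(xs[[1]]))
      xs <- lapply(pooled, `[[`, "y")
    } else if (role == "avgpool") {
      caches[[r]] <- list(in_dim = dim(xs[[1]]))
      xs <- lapply(xs, function(x) colMeans(matrix(x, ncol = dim(x)[3])))
    } else if (role == "softmax") {
      ly <- net$layers[[r]]
      feats <- do.call(rbind, xs)                 # B x nfeat
      z <- feats %*% t(ly$w) + rep(ly$b, each = B)
      z <- z - apply(z, 1, max)
      p <- exp(z) / rowSums(exp(z))
      caches[[r]] <- list(feats = feats, probs = p)
    }
  }
  list(probs = caches[[nrow(arch)]]$probs, caches = caches)
}

# backpropagate the cross-entropy gradient and return per-layer gradients
backward_batch <- function(net, caches, labels) {
  arch <- net$arch
  B <- nrow(caches[[nrow(arch)]]$probs)
  grads <- vector("list", nrow(arch))
  r <- nrow(arch)
  p <- caches[[r]]$probs
  dz <- p
  dz[cbind(seq_len(B), labels)] <- dz[cbind(seq_len(B), labels)] - 1
  dz <- dz / B
  ly <- net$layers[[r]]
  grads[[r]] <- list(w = t(dz) %*% caches[[r]]$feats, b = colSums(dz))
  dfeat <- dz %*% ly$w                             # B x nfeat
  dxs <- NULL
  for (r in rev(seq_len(nrow(arch))[-1])) {
    role <- arch$role[r]
    if (role == "softmax") next
    if (role == "avgpool") {
      d <- caches[[r]]$in_dim
      npix <- prod(d[1:2])
      dxs <- lapply(seq_len(B), function(i)
        array(rep(dfeat[i, ], each = npix) / npix, dim = d))
    } else if (role == "maxpool") {
      cc <- caches[[r]]
      dxs <- lapply(seq_len(B), function(i)
        cpp_maxpool2_backward(dxs[[i]], cc$argmax[[i]], cc$in_dim))
    } else if (role == "conv") {
      cc <- caches[[r]]
      ly <- net$layers[[r]]
      lrn <- net$lrn
      npix <- cc$npix; C <- cc$C
      dw <- array(0, dim = dim(ly$w)); db <- numeric(length(ly$b))
      dgamma <- numeric(C); dbeta <- numeric(C)
      # pass 1: through LRN and ReLU; accumulate batch-norm sums
      dys <- vector("list", B)
      sum_dxhat <- numeric(C); sum_dxhat_xhat <- numeric(C)
      for (i in seq_len(B)) {
        dy <- cpp_lrn_backward(cc$y_relu[[i]], dxs[[i]],
                               lrn$k, lrn$alpha, lrn$beta, lrn$n)
        dy[cc$y_relu[[i]] <= 0] <- 0
        dym <- matrix(dy, ncol = C)
        xhm <- matrix(cc$xhat[[i]], ncol = C)
        dgamma <- dgamma + colSums(dym * xhm)
        dbeta <- dbeta + colSums(dym)
        dys[[i]] <- dy
      }
      dxhat_scale <- ly$bn$gamma
      sum_dxhat <- dbeta * dxhat_scale
      sum_dxhat_xhat <- dgamma * dxhat_scale
      m <- cc$m
      new_dxs <- vector("list", B)
      for (i in seq_len(B)) {
        dxhat <- dys[[i]] * rep(dxhat_scale, each = npix)
        xh <- cc$xhat[[i]]
        dzc <- (dxhat - rep(sum_dxhat / m, each = npix) -
                xh * rep(sum_dxhat_xhat / m, each = npix)) *
               rep(cc$inv_sd, each = npix)
        bk <- cpp_conv2d_backward(cc$x_in[[i]], ly$w, dzc, cc$pad)
        dw <- dw + bk$dw; db <- db + bk$db
        new_dxs[[i]] <- bk$dx
      }
      grads[[r]] <- list(w = dw, b = db, gamma = dgamma, beta = dbeta)
      dxs <- new_dxs
    }
  }
  grads
}

#' Train the network for object recognition
#'
#' Mini-batch SGD with momentum on the cross-entropy loss. The dataset is
#' either an in-memory list with elements `images` (list of input images)
#' and `labels` (integer class ids starting at 1, or a factor), or a path to
#' a directory of labeled images laid out one subdirectory per class
#' (PNG files). At the reference scale this is a long-running operation;
#' all desk-scale numerosity analyses in this package use untrained networks.
#'
#' @param net a `nzero_network` whose softmax width matches the class count.
#' @param dataset in-memory dataset or directory path (see Details).
#' @param cfg a [train_config()].
#' @param seed seed for batch shuffling.
#' @return The trained network, with a `training_log` attribute: data frame
#'   of per-epoch mean loss and accuracy.
#' @export
train_object_recognition <- function(net, dataset, cfg = train_config(),
                                     seed = 1L) {
  if (is.character(dataset)) {
    if (!dir.exists(dataset))
      stop("training dataset directory not found: ", dataset,
           ". Training requires a labeled natural-image collection; ",
           "all desk-scale numerosity analyses run with untrained networks ",
           "(build_network() without training).")
    classes <- sort(list.dirs(dataset, recursive = FALSE))
    if (!length(classes)) stop("no class subdirectories in ", dataset)
    files <- lapply(classes, list.files, pattern = "\\.png$", full.names = TRUE)
    labels <- rep(seq_along(classes), lengths(files))
    images <- lapply(unlist(files), function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3) im <- im[, , 1]
      im
    })
    dataset <- list(images = images, labels = labels)
  }
  images <- dataset$images
  labels <- as.integer(as.factor(dataset$labels))
  n_classes <- net$arch$maps[nrow(net$arch)]
  if (max(labels) > n_classes)
    stop("more classes in the dataset than softmax outputs")
  n <- length(images)
  set.seed(seed)
  vel <- lapply(net$layers, function(ly) {
    if (is.null(ly)) return(NULL)
    out <- list(w = ly$w * 0, b = ly$b * 0)
    if (!is.null(ly$bn))
      out <- c(out, list(gamma = ly$bn$gamma * 0, beta = ly$bn$beta * 0))
    out
  })
  log <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c(); hits <- c()
    for (start in seq(1, n, by = cfg$batch_size)) {
      ix <- ord[start:min(start + cfg$batch_size - 1, n)]
      if (length(ix) < 2) next   # batch statistics need >= 2 samples
      fw <- forward_train_batch(net, images[ix])
      p <- fw$probs
      losses <- c(losses, -mean(log(pmax(p[cbind(seq_along(ix), labels[ix])], 1e-12))))
      hits <- c(hits, mean(max.col(p) == labels[ix]))
      grads <- backward_batch(net, fw$caches, labels[ix])
      for (r in seq_along(net$layers)) {
        if (is.null(grads[[r]])) next
        for (nm in names(grads[[r]])) {
          g <- grads[[r]][[nm]]
          vel[[r]][[nm]] <- cfg$momentum * vel[[r]][[nm]] + g
          upd <- cfg$learning_rate * vel[[r]][[nm]]
          if (nm %in% c("w", "b")) {
            net$layers[[r]][[nm]] <- net$layers[[r]][[nm]] - upd
          } else {
            net$layers[[r]]$bn[[nm]] <- net$layers[[r]]$bn[[nm]] - upd
          }
        }
      }
      # update running statistics (evaluation-mode batch norm)
      for (r in seq_along(net$layers)) {
        cc <- fw$caches[[r]]
        if (!is.null(cc) && !is.null(cc$mu)) {
          bn <- net$layers[[r]]$bn
          bn$mean <- (1 - cfg$bn_momentum) * bn$mean + cfg$bn_momentum * cc$mu
          bn$var <- (1 - cfg$bn_momentum) * bn$var +
                    cfg$bn_momentum * cc$var * cc$m / (cc$m - 1)
          net$layers[[r]]$bn <- bn
        }
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = mean(losses),
                                 accuracy = mean(hits)))
    if (!is.null(cfg$checkpoint_dir)) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(net, file.path(cfg$checkpoint_dir, sprintf("epoch_%03d.rds", ep)))
    }
  }
  net$trained <- TRUE
  net$engine_cache <- new.env(parent = emptyenv())  # weights changed
  attr(net, "training_log") <- log
  net
}
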