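# Object-recognition training pathway, exercised on a reduced fixture:
# a 3-class synthetic shape-classification problem on the tiny architecture.

make_shape_dataset <- function(n_per_class = 16, size = 56, seed = 21) {
  set.seed(seed)
  images <- list(); labels <- integer(0)
  for (cls in 1:3) {
    for (i in seq_len(n_per_class)) {
      img <- matrix(0, size, size)
      cx <- sample(18:(size - 18), 1); cy <- sample(18:(size - 18), 1)
      if (cls == 1) {                       # disc
        for (r in 1:size) for (c in 1:size)
          if ((r - cy)^2 + (c - cx)^2 <= 100) img[r, c] <- 1
      } else if (cls == 2) {                # square
        img[(cy - 8):(cy + 8), (cx - 8):(cx + 8)] <- 1
      } else {                              # horizontal bar
        img[(cy - 3):(cy + 3), (cx - 14):(cx + 14)] <- 1
      }
      images <- c(images, list(img)); labels <- c(labels, cls)
    }
  }
  list(images = images, labels = labels)
}

test_that("training on a small fixture reduces the loss across epochs", {
  ds <- make_shape_dataset()
  net <- build_network(tiny_architecture(n_classes = 3), seed = 3)
  trained <- train_object_recognition(
    net, ds, train_config(epochs = 2, batch_size = 16, learning_rate = 0.05),
    seed = 5)
  log <- attr(trained, "training_log")
  expect_identical(nrow(log), 2L)
  expect_true(log$loss[2] < log$loss[1])
  expect_true(trained$trained)
})

test_that("a zero learning rate leaves the weights unchanged", {
  ds <- make_shape_dataset(n_per_class = 6)
  net <- build_network(tiny_architecture(n_classes = 3), seed = 3)
  frozen <- train_object_recognition(
    net, ds, train_config(epochs = 1, batch_size = 6, learning_rate = 0),
    seed = 5)
  for (r in seq_along(net$layers)) {
    if (is.null(net$layers[[r]])) next
    expect_equal(frozen$layers[[r]]$w, net$layers[[r]]$w)
    expect_equal(frozen$layers[[r]]$b, net$layers[[r]]$b)
  }
})

test_that("a missing dataset directory gives an instructive error", {
  net <- build_network(tiny_architecture(n_classes = 3), seed = 3)
  expect_error(train_object_recognition(net, "no/such/dir"),
               "untrained networks")
})

test_that("batch normalization standardizes each map over the batch before the affine stage", {
  net <- build_network(tiny_architecture(n_classes = 3), seed = 11)
  set.seed(2)
  batch <- replicate(8, matrix(runif(56 * 56), 56, 56), simplify = FALSE)
  fw <- nzero:::forward_train_batch(net, batch)
  conv_rows <- which(net$arch$role == "conv")
  cc <- fw$caches[[conv_rows[1]]]
  xh <- do.call(rbind, lapply(cc$xhat, function(z) matrix(z, ncol = cc$C)))
  expect_true(all(abs(colMeans(xh)) < 1e-6))
  expect_true(all(abs(apply(xh, 2, sd) - 1) < 1e-2))
})

test_that("conv backward matches numerical gradients on a small case", {
  set.seed(4)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3) * 0.1
  y <- nzero:::cpp_conv2d(x, w, b, 1L)
  dy <- array(rnorm(length(y)), dim = dim(y))
  bk <- nzero:::cpp_conv2d_backward(x, w, dy, 1L)
  loss <- function(xx, ww, bb) sum(nzero:::cpp_conv2d(xx, ww, bb, 1L) * dy)
  eps <- 1e-3
  for (ix in sample(length(x), 5)) {
    xp <- x; xp[ix] <- xp[ix] + eps
    xm <- x; xm[ix] <- xm[ix] - eps
    expect_equal(bk$dx[ix], (loss(xp, w, b) - loss(xm, w, b)) / (2 * eps),
                 tolerance = 1e-2)   # single-precision accumulation
  }
  for (ix in sample(length(w), 5)) {
    wp <- w; wp[ix] <- wp[ix] + eps
    wm <- w; wm[ix] <- wm[ix] - eps
    expect_equal(bk$dw[ix], (loss(x, wp, b) - loss(x, wm, b)) / (2 * eps),
                 tolerance = 1e-2)
  }
})

test_that("normalization backward matches numerical gradients", {
  set.seed(6)
  x <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  dy <- array(rnorm(length(x)), dim = dim(x))
  k <- 2; al <- 0.3; be <- 0.75; n <- 5   # larger alpha so the term matters
  dx <- nzero:::cpp_lrn_backward(x, dy, k, al, be, n)
  loss <- function(xx) sum(nzero:::cpp_lrn(xx, k, al, be, n) * dy)
  eps <- 1e-5
  for (ix in sample(length(x), 8)) {
    xp <- x; xp[ix] <- xp[ix] + eps
    xm <- x; xm[ix] <- xm[ix] - eps
    expect_equal(dx[ix], (loss(xp) - loss(xm)) / (2 * eps), tolerance = 1e-5)
  }
})
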