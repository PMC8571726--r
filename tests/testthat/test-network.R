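# Network construction, the forward pass and its component operations.

test_that("lateral-inhibition normalization matches the printed formula on a scalar", {
  # single map, single unit: b = a / (k + alpha * a^2)^beta
  a <- array(1, dim = c(1, 1, 1))
  b <- local_response_normalize(a, lrn_params(k = 2, alpha = 1e-4, beta = 0.75, n = 15))
  expect_equal(as.numeric(b), 1 / (2 + 1e-4)^0.75, tolerance = 1e-12)
  # zero input stays zero
  expect_equal(as.vector(local_response_normalize(array(0, c(3, 3, 4)))),
               rep(0, 36))
})

# naive triple-loop reference implementation of the normalization
lrn_oracle <- function(a, k = 2, alpha = 1e-4, beta = 0.75, n = 15) {
  d <- dim(a); N <- d[3]
  b <- array(NA_real_, d)
  half <- n %/% 2
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (i in seq_len(N)) {
    js <- max(1, i - half):min(N, i + half)
    s <- sum(pmax(0, a[x, y, js])^2)
    b[x, y, i] <- a[x, y, i] / (k + alpha * s)^beta
  }
  b
}

test_that("normalization agrees element-wise with a brute-force loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    d <- c(sample(2:8, 2, replace = TRUE), sample(1:8, 1))
    a <- array(rnorm(prod(d)), dim = d)
    prm <- lrn_params(k = runif(1, 0.5, 3), alpha = runif(1, 1e-4, 0.5),
                      beta = runif(1, 0.2, 1.5), n = sample(c(1, 3, 5, 15), 1))
    expect_equal(local_response_normalize(a, prm),
                 lrn_oracle(a, prm$k, prm$alpha, prm$beta, prm$n),
                 tolerance = 1e-10)
  }
})

test_that("normalization rejects invalid inputs and parameters", {
  a <- array(1, c(2, 2, 2))
  a_bad <- a; a_bad[1] <- NaN
  expect_error(local_response_normalize(a_bad), "non-finite")
  expect_error(lrn_params(k = 0), "k")
  expect_error(lrn_params(beta = -1), "beta")
})

test_that("architecture tables validate and telescope", {
  expect_silent(validate_architecture(default_architecture()))
  expect_silent(validate_architecture(tiny_architecture()))
  bad <- default_architecture()
  bad$size[4] <- 100                      # breaks the pooling chain
  expect_error(validate_architecture(bad), "layer 3")
  odd <- tiny_architecture()
  odd$size[odd$index >= 1] <- 57
  expect_error(validate_architecture(odd), "")
  # the full (non-tiny) table is pinned to the canonical 16-layer description
  shrunk <- default_architecture()
  shrunk$maps[12:14] <- 100
  expect_error(validate_architecture(shrunk), "canonical")
})

test_that("the full network exposes 37,632 final-layer units with a (768, 7, 7) layout", {
  net <- build_network(default_architecture(), seed = 1)
  img <- matrix(0, 224, 224); img[100:130, 100:130] <- 1
  acts <- forward_record(net, list(img), noise = noise_params(enabled = FALSE))
  expect_identical(nrow(acts$values), 37632L)
  expect_identical(max(acts$unit_coords$map), 768L)
  expect_identical(max(acts$unit_coords$row), 7L)
  expect_identical(max(acts$unit_coords$col), 7L)
  expect_true(all(is.finite(acts$values)))
  expect_true(all(acts$values >= 0))
  # classifier head: 1000 categories, softmax-normalized, sorted top-k
  pred <- top_k_predictions(net, img, k = 1000)
  expect_identical(nrow(pred), 1000L)
  expect_equal(sum(pred$confidence), 1, tolerance = 1e-5)
  expect_true(all(diff(pred$confidence) <= 0))
})

test_that("weight initialization is seed-deterministic", {
  a1 <- build_network(tiny_architecture(), seed = 5)
  a2 <- build_network(tiny_architecture(), seed = 5)
  b <- build_network(tiny_architecture(), seed = 6)
  expect_identical(a1$layers, a2$layers)
  expect_false(identical(a1$layers, b$layers))
})

test_that("noise injection creates per-presentation variation, disabled noise does not", {
  net <- tiny_net()
  dark <- tiny_image(0)
  quiet <- forward_record(net, list(dark, dark), noise = noise_params(enabled = FALSE))
  expect_identical(quiet$values[, 1], quiet$values[, 2])
  noisy <- forward_record(net, rep(list(dark), 10), noise = noise_params(), seed = 3)
  for (i in 2:10) expect_false(identical(noisy$values[, 1], noisy$values[, i]))
  # degenerate noise (sigma = 0, mu = 1) equals the noise-free pass
  degen <- forward_record(net, list(dark), noise = noise_params(sigma = 0), seed = 3)
  expect_equal(degen$values[, 1], quiet$values[, 1], tolerance = 1e-6)
  # fixed seed => bit-stable activations
  again <- forward_record(net, rep(list(dark), 10), noise = noise_params(), seed = 3)
  expect_identical(noisy$values, again$values)
})

test_that("max pooling matches a direct blockwise oracle", {
  set.seed(9)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  got <- nzero:::cpp_maxpool2(x)$y
  ref <- array(NA_real_, c(4, 4, 3))
  for (c in 1:3) for (i in 1:4) for (j in 1:4)
    ref[i, j, c] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  expect_equal(got, ref)
})

test_that("top-k guards its argument range", {
  net <- tiny_net(n_classes = 5)
  img <- tiny_image(0.5)
  expect_error(top_k_predictions(net, img, k = 0), "at least 1")
  expect_error(top_k_predictions(net, img, k = 6), "exceed")
  p5 <- top_k_predictions(net, img, k = 5)
  expect_identical(nrow(p5), 5L)
  expect_true(all(diff(p5$confidence) <= 0))
  # untrained network: tiny logits, near-uniform confidences
  expect_true(all(abs(p5$confidence - 0.2) < 0.1))
})

test_that("mismatched image sizes are rejected", {
  net <- tiny_net()
  expect_error(forward_record(net, list(matrix(0, 10, 10))), "56 x 56")
  expect_error(forward_record(build_network(tiny_architecture(), seed = 1),
                              list(tiny_image()), layer_index = 2),
               "convolutional")
})

test_that("layer tables round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_architecture_yaml(tiny_architecture(), path)
  back <- read_architecture_yaml(path)
  ref <- tiny_architecture()
  expect_equal(back$role, ref$role)
  expect_equal(back$maps, ref$maps)
  expect_equal(back$size, ref$size)
  expect_true(attr(back, "tiny"))
  unlink(path)
})
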