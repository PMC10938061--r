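test_that("forward pass dimensions follow the architecture", {
  nn <- tiny_nn()
  d <- tiny_data()
  ep <- matrix(rnorm(40 * 12), 40, 12)
  out <- nn_forward(nn, ep)
  expect_length(out, 4L)
  expect_error(nn_forward(nn, matrix(0, 5, 5)), "shape")
})

test_that("zero input with zero biases gives zero logits", {
  nn <- tiny_nn()
  nn0 <- nn
  nn0$b1[] <- 0; nn0$b2[] <- 0; nn0$b3[] <- 0
  out <- nn_forward(nn0, matrix(0, nn$n_times, nn$n_channels))
  expect_equal(out, rep(0, length(nn$classes)))
})

test_that("collapsed affine map reproduces eval-mode forward to 1e-5", {
  nn <- tiny_nn()
  col <- collapse_nn(nn)
  expect_equal(dim(col$weight),
               c(nn$n_times * nn$n_channels, length(nn$classes)))
  set.seed(31)
  worst <- 0
  for (i in 1:100) {
    ep <- matrix(rnorm(nn$n_times * nn$n_channels), nn$n_times)
    direct <- nn_forward(nn, ep)
    via <- drop(flatten_epoch(ep) %*% col$weight) + col$bias
    worst <- max(worst, max(abs(direct - via)) / max(1e-12, max(abs(direct))))
  }
  expect_lt(worst, 1e-5)
})

test_that("projection extraction is side-effect free and repeatable", {
  nn <- tiny_nn()
  p1 <- extract_projection(nn)
  expect_equal(dim(p1), c(nn$n_channels, nn$n_components))
  before <- nn_forward(nn, matrix(1, nn$n_times, nn$n_channels))
  p2 <- extract_projection(nn)
  after <- nn_forward(nn, matrix(1, nn$n_times, nn$n_channels))
  expect_identical(p1, p2)
  expect_identical(before, after)
})

test_that("a linearly separable toy problem is learned quickly", {
  # two constant spatial patterns, no noise
  n <- 20
  arr <- array(0, c(2 * n, 4, 10))
  for (i in 1:n) arr[i, , ] <- c(1, -1, 1, -1)
  for (i in (n + 1):(2 * n)) arr[i, , ] <- c(-1, 1, -1, 1)
  ep <- meg_epochs(arr, rep(0:1, each = n), 100)
  split <- list(train = seq_len(2 * n), validation = seq_len(2 * n))
  nn <- train_nn(ep, split,
                 nn_config(n_components = 2, h1 = 8, h2 = 4,
                           n_epochs = 200, dropout = 0.2, seed = 1))
  expect_equal(accuracy(nn, ep, split$train), 1.0)
})

test_that("training is deterministic under a fixed seed", {
  d <- tiny_data()
  split <- stratified_split(d$epochs$labels, 0.2, seed = 7)
  cfg <- nn_config(n_components = 4, h1 = 16, h2 = 8, n_epochs = 10,
                   seed = 3)
  a <- train_nn(d$epochs, split, cfg)
  b <- train_nn(d$epochs, split, cfg)
  expect_identical(a$W_dr, b$W_dr)
  expect_identical(a$W3, b$W3)
})

test_that("training validates its inputs", {
  d <- tiny_data()
  cfg <- nn_config(n_components = 4, h1 = 16, h2 = 8, n_epochs = 5,
                   seed = 3)
  # a class entirely missing from the training set is rejected up front
  bad <- list(train = which(d$epochs$labels != 0),
              validation = which(d$epochs$labels == 0))
  expect_error(train_nn(d$epochs, bad, cfg), "training trial")
  expect_error(nn_config(n_epochs = 0), "n_epochs")
  expect_error(nn_config(dropout = 1), "dropout")
})

test_that("decoder pipelines predict from raw epochs", {
  d <- tiny_data()
  split <- stratified_split(d$epochs$labels, 0.2, seed = 7)
  dec <- fit_decoder(d$epochs, split, method = "lda_pca", n_components = 6)
  pred <- predict(dec, d$epochs$data[split$validation, , , drop = FALSE])
  expect_length(pred, length(split$validation))
  expect_true(all(pred %in% 0:3))
  acc <- accuracy(dec, d$epochs, split$validation)
  expect_true(acc >= 0 && acc <= 1)
  expect_error(accuracy(dec, d$epochs, integer(0)), "non-empty")
})

test_that("label-shuffled training decodes at chance", {
  d <- tiny_data()
  ep <- d$epochs
  rng <- megdecode:::local_rng(99)
  ep_shuf <- meg_epochs(ep$data, rng$sample(ep$labels), ep$sfreq, ep$t0,
                        ep$layout)
  split <- stratified_split(ep_shuf$labels, 0.25, seed = 7)
  dec <- fit_decoder(ep_shuf, split, method = "lda_pca", n_components = 6)
  band <- chance_band(4, length(split$validation), level = 0.99)
  acc <- accuracy(dec, ep_shuf, split$validation)
  expect_gte(acc, band["lo"])
  expect_lte(acc, band["hi"])
})
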