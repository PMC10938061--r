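toy_setup <- function(n = 8, nch = 6, nt = 20, seed = 3) {
  set.seed(seed)
  lay <- make_sensor_layout(nch / 3, seed = 1)
  data <- array(rnorm(n * nch * nt), c(n, nch, nt))
  w <- array(rnorm(nch * nt), c(nch, nt))
  ep <- meg_epochs(data, rep(0:1, length.out = n), sfreq = 100,
                   layout = lay)
  list(ep = ep, model = toy_model(w))
}

test_that("channel permutation of channel-constant data is a no-op", {
  s <- toy_setup()
  ep <- s$ep
  # make every timepoint constant across channels
  for (i in seq_len(dim(ep$data)[1]))
    ep$data[i, , ] <- matrix(ep$data[i, 1, ], dim(ep$data)[2],
                             dim(ep$data)[3], byrow = TRUE)
  ep$labels <- predict(s$model, ep$data)  # baseline accuracy 1 by design
  map <- temporal_pfi(s$model, ep, seq_len(8), window = 5, step = 5,
                      plan = pfi_plan(3, seed = 1))
  expect_true(all(map$loss == 0))
})

test_that("time permutation of a constant channel contributes nothing", {
  s <- toy_setup()
  ep <- s$ep
  # site 1 (channels 1:3) constant in time
  for (i in seq_len(8)) for (c in 1:3) ep$data[i, c, ] <- ep$data[i, c, 1]
  ep$labels <- predict(s$model, ep$data)
  map <- spatial_pfi(s$model, ep, 1:8, plan = pfi_plan(3, seed = 1))
  expect_true(all(map$loss[map$site == 1] == 0))
  # site 2 is unconstrained: some permutation should change predictions
  expect_true(any(map$loss != 0))
})

test_that("constant spatiotemporal blocks give exactly zero loss", {
  s <- toy_setup()
  ep <- s$ep
  ep$data[] <- 1   # everything constant: all blocks permutation-invariant
  ep$labels <- predict(s$model, ep$data)
  map <- spatiotemporal_pfi(s$model, ep, 1:8, window = 5, step = 5,
                            plan = pfi_plan(2, seed = 1))
  expect_true(all(map$loss == 0))
})

test_that("PFI never mutates the evaluated data", {
  s <- toy_setup()
  ep <- s$ep
  ep$labels <- predict(s$model, ep$data)
  snapshot <- ep$data + 0
  invisible(temporal_pfi(s$model, ep, 1:8, window = 5, step = 2,
                         plan = pfi_plan(2, seed = 1)))
  invisible(spatial_pfi(s$model, ep, 1:8, plan = pfi_plan(2, seed = 1)))
  invisible(spectral_pfi(s$model, ep, 1:8, plan = pfi_plan(2, seed = 1)))
  invisible(temporospectral_pfi(s$model, ep, 1:8, stft_len = 5,
                                plan = pfi_plan(1, seed = 1)))
  expect_identical(ep$data, snapshot)
})

test_that("fixed plans give bit-identical maps; seeds change them", {
  s <- toy_setup()
  ep <- s$ep
  ep$labels <- predict(s$model, ep$data)
  a <- temporal_pfi(s$model, ep, 1:8, window = 5, plan = pfi_plan(3, 9))
  b <- temporal_pfi(s$model, ep, 1:8, window = 5, plan = pfi_plan(3, 9))
  cc <- temporal_pfi(s$model, ep, 1:8, window = 5, plan = pfi_plan(3, 10))
  expect_identical(a, b)
  expect_false(identical(a$loss, cc$loss))
})

test_that("DFT round trip: identity permutation reconstructs exactly", {
  s <- toy_setup()
  data <- s$ep$data
  fc <- megdecode:::trial_dfts(data)
  x2 <- megdecode:::spectral_permute(data, fc, bins = 0:10,
                                     ch_sel = 1:6, perm = 1:6)
  expect_lt(max(abs(x2 - data)), 1e-8)
  # a real permutation keeps the data real and changes it
  x3 <- megdecode:::spectral_permute(data, fc, bins = 3:4, ch_sel = 1:6,
                                     perm = c(2, 1, 4, 3, 6, 5))
  expect_true(is.numeric(x3))
  expect_gt(max(abs(x3 - data)), 1e-3)
})

test_that("spectral PFI of an out-of-band empty band is exactly zero", {
  # strictly band-limited data (no broadband burst, no white sensor
  # noise): nothing above 25 Hz, so permuting those bins is a no-op
  d <- generate_epochs(tiny_config(seed = 8, snr = 0,
                                   sensor_noise_sd = 0))
  ep <- d$epochs
  model <- toy_model(array(rnorm(prod(dim(ep$data)[2:3])),
                           dim(ep$data)[2:3]))
  ep$labels <- predict(model, ep$data)
  map <- spectral_pfi(model, ep, seq_len(dim(ep$data)[1]),
                      bands = list(c(30, 45)), plan = pfi_plan(3, 1))
  expect_true(all(abs(map$loss) < 1e-10))
})

test_that("STFT round trip is exact at hop 1", {
  set.seed(4)
  x <- rnorm(90)
  s <- stft(x, 10)
  expect_equal(dim(s), c(81L, 10L))
  xr <- istft(s)
  expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
  # odd window length too
  s2 <- stft(x, 7)
  expect_lt(max(abs(istft(s2) - x)), 1e-8)
})

test_that("temporo-spectral band centres follow the STFT resolution", {
  s <- toy_setup(nt = 30)
  ep <- s$ep
  ep$labels <- predict(s$model, ep$data)
  map <- temporospectral_pfi(s$model, ep, 1:8, stft_len = 10,
                             plan = pfi_plan(1, seed = 2))
  expect_equal(sort(unique(map$band_hz)), c(0, 10, 20, 30, 40, 50))
  # window centres: frames at every sample, centred start + L/2
  expect_equal(min(map$center_s), (0 + 5) / 100)
  expect_equal(max(map$center_s), (20 + 5) / 100)
})

test_that("summary aggregates repetitions with percentile intervals", {
  df <- data.frame(center_s = rep(c(0.1, 0.2), each = 4),
                   rep = rep(1:4, 2),
                   loss = c(1, 2, 3, 4, 5, 5, 5, 5))
  map <- megdecode:::new_pfi_map(df, "temporal", 0.9)
  s <- pfi_summary(map, level = 0.5)
  expect_equal(s$mean_loss, c(2.5, 5))
  expect_equal(s$lo[2], 5)
  expect_equal(s$hi[2], 5)
})

test_that("spatio-spectral PFI restricts disruption to a neighbourhood", {
  # strictly band-limited data: a band above the lowpass is empty, so
  # every neighbourhood yields exactly zero loss
  d <- generate_epochs(tiny_config(seed = 9, snr = 0, sensor_noise_sd = 0))
  ep <- d$epochs
  model <- toy_model(array(rnorm(prod(dim(ep$data)[2:3])),
                           dim(ep$data)[2:3]))
  ep$labels <- predict(model, ep$data)
  map <- spatiospectral_pfi(model, ep, seq_len(dim(ep$data)[1]),
                            bands = list(c(30, 45)), plan = pfi_plan(2, 1))
  expect_true(all(abs(map$loss) < 1e-10))
  expect_setequal(unique(map$site), 1:4)
  # an informative band produces site-resolved losses with repetitions
  map2 <- spatiospectral_pfi(model, ep, seq_len(dim(ep$data)[1]),
                             bands = list(c(5, 15)), plan = pfi_plan(2, 1))
  expect_equal(nrow(map2), 4 * 2)
  expect_true(any(map2$loss != 0))
})

test_that("per-timepoint temporal permutation is a distinct, valid mode", {
  s <- toy_setup()
  ep <- s$ep
  ep$labels <- predict(s$model, ep$data)
  joint <- temporal_pfi(s$model, ep, 1:8, window = 5, step = 5,
                        plan = pfi_plan(2, 4))
  per_t <- temporal_pfi(s$model, ep, 1:8, window = 5, step = 5,
                        plan = pfi_plan(2, 4), per_timepoint = TRUE)
  expect_equal(nrow(joint), nrow(per_t))
  expect_false(identical(joint$loss, per_t$loss))
})

test_that("PFI accepts the network model directly (model agnosticism)", {
  nn <- tiny_nn()
  d <- tiny_data()
  # the network was trained on whitened data, so evaluate it there too
  split <- stratified_split(d$epochs$labels, 0.2, seed = 7)
  w <- fit_whitener(d$epochs, split$train)
  ep <- apply_whitener(w, d$epochs)
  map <- temporal_pfi(nn, ep, split$validation, window = 10, step = 10,
                      plan = pfi_plan(2, 3))
  expect_s3_class(map, "meg_pfi")
  expect_true(all(is.finite(map$loss)))
})
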