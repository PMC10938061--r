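test_that("well-separated spherical classes are classified almost perfectly", {
  set.seed(10)
  n <- 200
  x <- rbind(matrix(rnorm(2 * n, 0), n, 2), matrix(rnorm(2 * n, 0), n, 2))
  x[1:n, 1] <- x[1:n, 1] + 5
  x[(n + 1):(2 * n), 1] <- x[(n + 1):(2 * n), 1] - 5
  y <- rep(0:1, each = n)
  m <- fit_lda(x, y, shrinkage = "auto")
  xv <- rbind(matrix(rnorm(2 * 100, 0), 100, 2) + cbind(rep(5, 100), 0),
              matrix(rnorm(2 * 100, 0), 100, 2) - cbind(rep(5, 100), 0))
  expect_gte(mean(predict(m, xv) == rep(0:1, each = 100)), 0.99)
})

test_that("full shrinkage reduces to a nearest-class-mean rule", {
  set.seed(2)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- rep(0:2, each = 20)
  m <- fit_lda(x, y, shrinkage = 1)
  xv <- matrix(rnorm(30 * 4), 30, 4)
  pred <- predict(m, xv)
  means <- m$means
  nearest <- apply(xv, 1, function(v)
    m$classes[which.min(colSums((t(means) - v)^2))])
  expect_equal(pred, nearest)
})

test_that("2-d discriminant matches the closed-form hand computation", {
  # 4 points per class at fixed coordinates
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
             c(3, 2), c(4, 2), c(3, 3), c(4, 3))
  y <- rep(0:1, each = 4)
  m <- fit_lda(x, y, shrinkage = 0)
  # oracle: pooled within-class covariance (biased, n denominator), its
  # inverse, and the two discriminant functions computed by hand
  mu0 <- colMeans(x[1:4, ]); mu1 <- colMeans(x[5:8, ])
  cen <- rbind(sweep(x[1:4, ], 2, mu0), sweep(x[5:8, ], 2, mu1))
  sig <- crossprod(cen) / 8
  si <- solve(sig)
  f <- function(v, mu) drop(v %*% si %*% mu - 0.5 * mu %*% si %*% mu +
                              log(0.5))
  for (v in list(c(0.5, 0.5), c(3, 3), c(2, 1.2))) {
    sc <- predict(m, matrix(v, 1), type = "scores")
    expect_equal(unname(drop(sc[, "0"])), f(v, mu0), tolerance = 1e-6)
    expect_equal(unname(drop(sc[, "1"])), f(v, mu1), tolerance = 1e-6)
  }
})

test_that("shrinkage-free fit agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  x <- matrix(rnorm(300 * 5), 300, 5)
  y <- rep(0:2, each = 100)
  x[y == 1, 1] <- x[y == 1, 1] + 2
  x[y == 2, 2] <- x[y == 2, 2] + 2
  m <- fit_lda(x, y, shrinkage = 0)
  ref <- MASS::lda(x, grouping = y)
  xv <- matrix(rnorm(100 * 5), 100, 5)
  expect_gte(mean(predict(m, xv) ==
                    as.integer(as.character(predict(ref, xv)$class))),
             0.99)
})

test_that("Ledoit-Wolf intensity is sensible at both extremes", {
  set.seed(8)
  # strongly anisotropic covariance at large n: shrinking toward a scaled
  # identity would distort it, so the intensity must be small
  x1 <- sweep(matrix(rnorm(5000 * 5), 5000, 5), 2, c(1, 2, 4, 8, 16), `*`)
  s1 <- ledoit_wolf_shrinkage(x1)
  expect_lt(s1, 0.05)
  # tiny n, large d: the sample covariance is hopeless, shrink hard
  x2 <- matrix(rnorm(10 * 200), 10, 200)
  s2 <- ledoit_wolf_shrinkage(x2)
  expect_gt(s2, 0.5)
  # isotropic truth: the target is exact, intensity should approach 1
  x3 <- matrix(rnorm(5000 * 5), 5000, 5)
  expect_gt(ledoit_wolf_shrinkage(x3), 0.8)
  expect_true(s1 >= 0 && s1 <= 1 && s2 >= 0 && s2 <= 1)
})

test_that("degenerate inputs are rejected and ties break low", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_lda(x, rep(0, 10)), "2 classes")
  # symmetric two-class toy: a point equidistant from both means with
  # equal priors scores identically; the lower class index wins
  xx <- rbind(c(-1, 0), c(-1, 0), c(1, 0), c(1, 0))
  m <- fit_lda(xx, c(0, 0, 1, 1), shrinkage = 1)
  expect_equal(predict(m, matrix(c(0, 0), 1)), 0L)
})

test_that("channel PCA is variance-ordered and complete at full rank", {
  d <- tiny_data()
  ep <- d$epochs
  nch <- dim(ep$data)[2]
  full <- fit_channel_pca(ep, seq_len(dim(ep$data)[1]), nch)
  expect_equal(attr(full, "explained_fraction"), 1, tolerance = 1e-8)
  ev <- attr(full, "explained_variance")
  expect_true(all(diff(ev) <= 1e-10))
  # rank-1 toy: first component captures essentially everything
  set.seed(3)
  base <- rnorm(50)
  arr <- array(0, c(5, 3, 50))
  for (i in 1:5) {
    a <- rnorm(1)
    for (c in 1:3) arr[i, c, ] <- c * base * a
  }
  ep1 <- meg_epochs(arr, rep(0L, 5), 100)
  p1 <- fit_channel_pca(ep1, 1:5, 1)
  expect_gt(attr(p1, "explained_fraction"), 0.99999)
  expect_error(fit_channel_pca(ep1, 1:5, 10), "components")
})
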