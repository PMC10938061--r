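#' Stratified train/validation split
#'
#' Splits trials class by class in a `(1 - ratio):ratio` proportion with
#' deterministic rounding: each class contributes
#' `max(1, floor(ratio * n_c))` validation trials, the rest train. The
#' assignment within a class is a seeded random draw, so the same
#' `labels`/`ratio`/`seed` always give the identical split.
#'
#' @param labels integer class labels, one per trial.
#' @param ratio validation fraction (default 0.2, i.e. a 4:1 split).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`
#'   (1-based, disjoint, covering all trials).
#' @examples
#' s <- stratified_split(rep(0:3, each = 30), ratio = 0.2, seed = 1)
#' table(rep(0:3, each = 30)[s$validation])  # 6 per class
#' @export
stratified_split <- function(labels, ratio = 0.2, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  labels <- as.integer(labels)
  counts <- table(labels)
  if (any(counts < 2))
    stop("every class needs at least 2 trials to split")
  rng <- local_rng(seed)
  val <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    n_val <- max(1L, floor(ratio * length(idx)))
    val <- c(val, sort(rng$sample(idx, n_val)))
  }
  val <- sort(val)
  list(train = setdiff(seq_along(labels), val), validation = val)
}

#' PCA whitening fitted on training trials
#'
#' Removes the per-channel mean and decorrelates channels so that the pooled
#' covariance over all training timepoints becomes the identity, retaining
#' all components. The transform is estimated from the training trials only
#' and then applied unchanged to any trials (in particular validation
#' trials, whose covariance is *not* guaranteed to be white).
#'
#' Rank-deficient covariance is regularised with a ridge of
#' `1e-12 * trace / n_channels` (with a warning) before inversion.
#'
#' @param epochs a [meg_epochs()] object.
#' @param train_idx trial indices to estimate from.
#' @return A `meg_whitener`: list with `mean` (per-channel) and `transform`
#'   (`channels x channels`, applied as `W %*% (x - mean)`).
#' @export
fit_whitener <- function(epochs, train_idx) {
  stopifnot(length(train_idx) >= 1)
  x <- epochs$data[train_idx, , , drop = FALSE]
  d <- dim(x)
  # pooled [n_obs x channels] over all training trials and timepoints
  m <- matrix(aperm(x, c(3L, 1L, 2L)), nrow = d[1L] * d[3L], ncol = d[2L])
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu)
  cov <- crossprod(m) / (nrow(m) - 1L)
  e <- eigen(cov, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol)) {
    warning("rank-deficient channel covariance; adding ridge")
    ridge <- 1e-12 * sum(diag(cov)) / ncol(cov)
    e$values <- e$values + max(ridge, tol)
  }
  transform <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  structure(list(mean = mu, transform = transform), class = "meg_whitener")
}

#' @rdname fit_whitener
#' @param w a fitted `meg_whitener`.
#' @return `apply_whitener()`: a `meg_epochs` object with transformed data.
#' @export
apply_whitener <- function(w, epochs) {
  d <- dim(epochs$data)
  out <- epochs$data
  for (tr in seq_len(d[1L])) {
    x <- matrix(out[tr, , ], nrow = d[2L])
    out[tr, , ] <- w$transform %*% (x - w$mean)
  }
  meg_epochs(out, epochs$labels, epochs$sfreq, epochs$t0, epochs$layout)
}

#' Sliding-window partition of an epoch
#'
#' Windows are half-open sample ranges `[start, start + length)` in 0-based
#' sample coordinates, advancing by `step`. The number of windows is
#' `floor((n_times - length) / step)`: the final placement flush with the
#' epoch end is deliberately dropped, so 100 samples partitioned into
#' 10-sample windows at step 1 give 90 windows (and an epoch exactly as long
#' as the window gives none -- use the full-epoch path there).
#'
#' @param n_times epoch length in samples.
#' @param length window length in samples (>= 1, <= `n_times`).
#' @param step hop between consecutive window starts, samples.
#' @return A `window_spec`: list with `starts` (0-based), `length`, `step`,
#'   `n_windows`, and `centers` (in samples: `start + length / 2`).
#' @examples
#' sliding_windows(100, 10, 1)$n_windows  # 90
#' @export
sliding_windows <- function(n_times, length, step = 1L) {
  stopifnot(length >= 1, step >= 1)
  if (length > n_times) stop("window longer than epoch")
  n_win <- floor((n_times - length) / step)
  starts <- if (n_win > 0) (seq_len(n_win) - 1L) * step else integer(0)
  structure(
    list(starts = as.integer(starts), length = as.integer(length),
         step = as.integer(step), n_windows = as.integer(n_win),
         centers = starts + length / 2),
    class = "window_spec"
  )
}

# 1-based sample indices of window i of a window_spec
window_samples <- function(spec, i) {
  spec$starts[i] + seq_len(spec$length)
}

# window centers in seconds for an epochs object
window_centers_s <- function(spec, epochs) {
  epochs$t0 + spec$centers / epochs$sfreq
}
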