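#' Epoched multichannel data container
#'
#' The universal input of the package: a 3-D array of epoched trials with
#' integer class labels, a sampling rate, the time of the first sample
#' relative to stimulus onset, and a sensor layout.
#'
#' @param data numeric array `[n_trials, n_channels, n_times]`, all finite.
#' @param labels integer class labels in `0 .. n_classes - 1`, one per trial.
#' @param sfreq sampling frequency in Hz.
#' @param t0 time of the first sample in seconds relative to stimulus onset.
#' @param layout a [make_sensor_layout()] layout whose channel count matches
#'   `dim(data)[2]`, or `NULL` for data without spatial structure.
#' @return An object of class `meg_epochs`.
#' @export
meg_epochs <- function(data, labels, sfreq, t0 = 0, layout = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array [trials, channels, times]")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1L])
    stop("one label per trial required")
  if (any(labels < 0L)) stop("labels must be non-negative integers")
  if (!is.null(layout) && layout$n_channels != dim(data)[2L])
    stop("layout channel count does not match data")
  if (sfreq <= 0) stop("`sfreq` must be positive")
  structure(
    list(data = data, labels = labels, sfreq = sfreq, t0 = t0,
         layout = layout),
    class = "meg_epochs"
  )
}

#' @export
print.meg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<meg_epochs> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$sfreq, " Hz, ", n_classes(x), " classes\n", sep = "")
  invisible(x)
}

#' @export
dim.meg_epochs <- function(x) dim(x$data)

#' Number of distinct classes in an epochs object
#' @param epochs a `meg_epochs` object.
#' @return integer count (labels are assumed to be `0 .. n_classes - 1`).
#' @export
n_classes <- function(epochs) length(unique(epochs$labels))

#' Sample times of an epochs object
#' @param epochs a `meg_epochs` object.
#' @return numeric vector of sample times in seconds relative to onset.
#' @export
epoch_times <- function(epochs) {
  epochs$t0 + (seq_len(dim(epochs$data)[3L]) - 1L) / epochs$sfreq
}

#' Subset trials of an epochs object
#' @param epochs a `meg_epochs` object.
#' @param idx trial indices (1-based).
#' @return a `meg_epochs` object containing the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  meg_epochs(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
             epochs$sfreq, epochs$t0, epochs$layout)
}

#' Flatten a reduced epoch matrix to a feature vector
#'
#' Row-major flattening of a `[n_times x n_components]` matrix: the features
#' of timepoint 1 come first, then timepoint 2, and so on. This is the
#' ordering used by every full-epoch and windowed classifier in the package.
#' [unflatten_epoch()] is its exact inverse.
#'
#' @param reduced numeric matrix `[n_times x n_components]`.
#' @return numeric vector of length `n_times * n_components`.
#' @examples
#' m <- matrix(1:6, nrow = 3)
#' identical(unflatten_epoch(flatten_epoch(m), 3, 2), m)
#' @export
flatten_epoch <- function(reduced) {
  if (!all(is.finite(reduced))) stop("non-finite values in input")
  as.vector(t(reduced))
}

#' @rdname flatten_epoch
#' @param v flattened vector.
#' @param n_times,n_components original matrix dimensions.
#' @export
unflatten_epoch <- function(v, n_times, n_components) {
  if (length(v) != n_times * n_components) stop("length mismatch")
  matrix(v, nrow = n_times, ncol = n_components, byrow = TRUE)
}

# Flatten many trials at once. x: [n_trials, n_channels, n_times] array,
# proj: [n_channels x k] projection or NULL. Returns [n_trials x (n_times*k)]
# with row-major (time-major) feature order per trial.
project_and_flatten <- function(x, proj = NULL, time_sel = NULL) {
  n <- dim(x)[1L]; nc <- dim(x)[2L]; nt <- dim(x)[3L]
  if (!is.null(time_sel)) {
    x <- x[, , time_sel, drop = FALSE]
    nt <- length(time_sel)
  }
  # reorganize to [(trial, time) x channels]
  m <- matrix(aperm(x, c(3L, 1L, 2L)), nrow = nt * n, ncol = nc)
  if (!is.null(proj)) m <- m %*% proj
  k <- ncol(m)
  # rows are ordered time-fastest within trial; per-trial row-major flatten
  # over [time x k] = concatenate time rows => feature index = (t-1)*k + j
  out <- matrix(0, nrow = n, ncol = nt * k)
  for (t in seq_len(nt)) {
    rows <- (seq_len(n) - 1L) * nt + t
    out[, (t - 1L) * k + seq_len(k)] <- m[rows, , drop = FALSE]
  }
  out
}
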