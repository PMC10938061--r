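#' Sliding-window decoding accuracy time course
#'
#' Trains an independent shrinkage LDA per time window on the flattened
#' `[window_length x n_components]` features of the projected data and
#' evaluates each on the validation trials. The channel projection (PCA or
#' network-derived) is fitted once on the full-epoch training data and
#' shared across windows; each window's classifier only ever sees its own
#' samples.
#'
#' @param epochs a [meg_epochs()] object (raw sensor space).
#' @param split a [stratified_split()] result.
#' @param spec a [sliding_windows()] window specification.
#' @param projection `channels x components` matrix ([fit_channel_pca()] or
#'   [extract_projection()]), or `NULL` to use all channels unprojected.
#' @param whitener optional [fit_whitener()] result applied before
#'   projecting (fit on training trials).
#' @param shrinkage LDA shrinkage.
#' @return An `accuracy_timecourse`: data.frame with `center_s` (window
#'   centre, seconds) and `accuracy`, with attributes `chance`
#'   (`1/n_classes`) and `spec`.
#' @export
train_windowed <- function(epochs, split, spec, projection = NULL,
                           whitener = NULL, shrinkage = "auto") {
  if (spec$n_windows < 1) stop("empty window specification")
  ep <- if (is.null(whitener)) epochs else apply_whitener(whitener, epochs)
  acc <- numeric(spec$n_windows)
  y_tr <- ep$labels[split$train]
  y_va <- ep$labels[split$validation]
  for (i in seq_len(spec$n_windows)) {
    sel <- window_samples(spec, i)
    f_tr <- project_and_flatten(ep$data[split$train, , , drop = FALSE],
                                projection, time_sel = sel)
    f_va <- project_and_flatten(ep$data[split$validation, , , drop = FALSE],
                                projection, time_sel = sel)
    m <- fit_lda(f_tr, y_tr, shrinkage)
    acc[i] <- mean(predict(m, f_va) == y_va)
  }
  structure(
    data.frame(center_s = window_centers_s(spec, epochs), accuracy = acc),
    chance = 1 / n_classes(epochs), spec = spec,
    class = c("accuracy_timecourse", "data.frame")
  )
}

#' Peak of an accuracy time course
#'
#' @param tc an `accuracy_timecourse` (or any data.frame with `center_s`
#'   and `accuracy`). Ties are broken toward the earliest window.
#' @return list with `center_s` and `accuracy` of the peak.
#' @export
peak_accuracy <- function(tc) {
  if (nrow(tc) < 1) stop("empty time course")
  i <- which.max(tc$accuracy)    # which.max returns the first maximum
  list(center_s = tc$center_s[i], accuracy = tc$accuracy[i])
}

#' Per-site full-epoch decoding map
#'
#' Trains one shrinkage LDA per sensor site on the flattened full-epoch
#' features of that site's three co-located channels (2 gradiometers + 1
#' magnetometer), a spatial "search-light" whose validation accuracy map is
#' the comparator for spatial permutation importance. Channels are used in
#' original sensor space (no whitening) so that each model sees only its
#' own site.
#'
#' @param epochs a [meg_epochs()] object with a layout.
#' @param split a [stratified_split()] result.
#' @param shrinkage LDA shrinkage.
#' @return A `sensor_accuracy_map`: data.frame with `site`, `x`, `y`,
#'   `accuracy`; attribute `chance`.
#' @export
per_sensor_lda <- function(epochs, split, shrinkage = "auto") {
  layout <- epochs$layout
  if (is.null(layout)) stop("epochs carry no sensor layout")
  if (any(lengths(layout$site_channels) != 3L))
    stop("each site must have exactly 3 channels")
  y_tr <- epochs$labels[split$train]
  y_va <- epochs$labels[split$validation]
  acc <- vapply(seq_len(layout$n_sites), function(s) {
    ch <- layout$site_channels[[s]]
    f_tr <- project_and_flatten(
      epochs$data[split$train, ch, , drop = FALSE], NULL)
    f_va <- project_and_flatten(
      epochs$data[split$validation, ch, , drop = FALSE], NULL)
    m <- fit_lda(f_tr, y_tr, shrinkage)
    mean(predict(m, f_va) == y_va)
  }, numeric(1))
  structure(
    data.frame(site = seq_len(layout$n_sites),
               x = layout$positions[, 1L], y = layout$positions[, 2L],
               accuracy = acc),
    chance = 1 / n_classes(epochs),
    class = c("sensor_accuracy_map", "data.frame")
  )
}

#' @export
plot.accuracy_timecourse <- function(x, ...) {
  graphics::plot(x$center_s * 1000, x$accuracy, type = "l",
                 xlab = "window centre (ms)", ylab = "validation accuracy",
                 ylim = c(0, max(x$accuracy) * 1.05), ...)
  graphics::abline(h = attr(x, "chance"), lty = 2)
  invisible(x)
}
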