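#' Fit a full-epoch decoder pipeline
#'
#' Bundles whitening, a channel projection and a classifier into one object
#' that predicts straight from raw epochs; this is the model handed to the
#' permutation-importance functions. Three methods are available:
#' \describe{
#'   \item{`"nn"`}{the linear network itself ([train_nn()]).}
#'   \item{`"lda_nn"`}{shrinkage LDA on features projected through the
#'     channel-reduction matrix learned by the network.}
#'   \item{`"lda_pca"`}{the same with an unsupervised, variance-ranked
#'     PCA projection ([fit_channel_pca()]).}
#' }
#'
#' @param epochs a [meg_epochs()] object (raw; whitening is handled here).
#' @param split a [stratified_split()] result.
#' @param method `"lda_nn"`, `"lda_pca"` or `"nn"`.
#' @param n_components projection width (ignored if `nn_model` given).
#' @param whiten fit a PCA whitener on the training trials and apply it
#'   inside the pipeline (default `TRUE`).
#' @param shrinkage LDA shrinkage, `"auto"` or a fraction.
#' @param nn a [nn_config()] used when the method needs a trained network.
#' @param nn_model optionally a pre-trained `meg_nn` (trained on the same
#'   whitened training data) to reuse instead of training afresh.
#' @param channels optional channel subset the decoder sees (e.g. one
#'   sensor site); applied after whitening, so normally used with
#'   `whiten = FALSE`.
#' @param verbose passed to [train_nn()].
#' @return A `meg_decoder` with a [predict()] method taking raw epochs (or
#'   a data array) and an [accuracy()] method.
#' @export
fit_decoder <- function(epochs, split,
                        method = c("lda_nn", "lda_pca", "nn"),
                        n_components = 80L, whiten = TRUE,
                        shrinkage = "auto", nn = nn_config(),
                        nn_model = NULL, channels = NULL,
                        verbose = FALSE) {
  method <- match.arg(method)
  whitener <- if (whiten) fit_whitener(epochs, split$train) else NULL
  ep_w <- if (whiten) apply_whitener(whitener, epochs) else epochs
  if (!is.null(channels))
    ep_w <- meg_epochs(ep_w$data[, channels, , drop = FALSE], ep_w$labels,
                       ep_w$sfreq, ep_w$t0, NULL)

  nnm <- nn_model
  if (method %in% c("nn", "lda_nn") && is.null(nnm))
    nnm <- train_nn(ep_w, split, nn, verbose = verbose)

  projection <- switch(method,
    nn = NULL,
    lda_nn = extract_projection(nnm),
    lda_pca = fit_channel_pca(ep_w, split$train, n_components))

  classifier <- if (method == "nn") {
    nnm
  } else {
    feats <- project_and_flatten(
      ep_w$data[split$train, , , drop = FALSE], projection)
    fit_lda(feats, ep_w$labels[split$train], shrinkage)
  }

  structure(
    list(method = method, whitener = whitener, channels = channels,
         projection = projection, classifier = classifier,
         nn_model = if (method == "lda_nn") nnm else
           if (method == "nn") classifier else NULL),
    class = "meg_decoder"
  )
}

# raw array [n, ch, t] -> whitened / channel-subset array
preprocess_array <- function(object, x) {
  if (!is.null(object$whitener)) {
    d <- dim(x)
    w <- object$whitener
    out <- x
    for (tr in seq_len(d[1L]))
      out[tr, , ] <- w$transform %*% (matrix(x[tr, , ], nrow = d[2L]) - w$mean)
    x <- out
  }
  if (!is.null(object$channels))
    x <- x[, object$channels, , drop = FALSE]
  x
}

#' @export
#' @rdname fit_decoder
#' @param object a fitted `meg_decoder`.
#' @param newdata a `meg_epochs` object or raw array
#'   `[n_trials x n_channels x n_times]` in original sensor space.
#' @param ... unused.
predict.meg_decoder <- function(object, newdata, ...) {
  if (inherits(newdata, "meg_epochs")) newdata <- newdata$data
  x <- preprocess_array(object, newdata)
  if (inherits(object$classifier, "meg_nn"))
    return(predict(object$classifier, x))
  feats <- project_and_flatten(x, object$projection)
  predict(object$classifier, feats)
}

#' @export
print.meg_decoder <- function(x, ...) {
  cat("<meg_decoder> method = ", x$method,
      if (!is.null(x$whitener)) ", whitened" else "", "\n", sep = "")
  invisible(x)
}

#' Top-1 classification accuracy of a decoder on selected trials
#'
#' @param model any object whose [predict()] method maps a
#'   `[n x channels x times]` array to labels (e.g. `meg_decoder`,
#'   `meg_nn`).
#' @param epochs a [meg_epochs()] object.
#' @param idx trial indices to evaluate (default: all).
#' @return fraction of correct top-1 predictions.
#' @export
accuracy <- function(model, epochs, idx = seq_len(dim(epochs$data)[1L])) {
  if (length(idx) < 1) stop("`idx` must be non-empty")
  pred <- predict(model, epochs$data[idx, , , drop = FALSE])
  mean(pred == epochs$labels[idx])
}
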