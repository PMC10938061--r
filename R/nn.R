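#' Training configuration for the linear network
#'
#' @param n_components width of the learnable channel projection.
#' @param h1,h2 hidden layer sizes. The defaults (1000, 300) suit inputs of
#'   a few thousand flattened features and ~100 classes; for smaller
#'   problems choose them roughly geometrically spaced between the flattened
#'   input size and the class count.
#' @param dropout dropout rate applied before each of the three affine
#'   layers during training (none on the channel-projection input).
#' @param n_epochs full passes over the training set (no early stopping).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size; the full batch is used when the
#'   training set is smaller.
#' @param seed integer seed for initialisation, dropout and batch order.
#' @param log_every record training loss/accuracy every this many epochs.
#' @return A `nn_config` list.
#' @export
nn_config <- function(n_components = 80L, h1 = 1000L, h2 = 300L,
                      dropout = 0.7, n_epochs = 2000L, lr = 1e-3,
                      batch_size = 64L, seed = 1L, log_every = 100L) {
  stopifnot(n_epochs >= 1, dropout >= 0, dropout < 1, lr > 0)
  structure(
    list(n_components = as.integer(n_components), h1 = as.integer(h1),
         h2 = as.integer(h2), dropout = dropout,
         n_epochs = as.integer(n_epochs), lr = lr,
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         log_every = as.integer(log_every)),
    class = "nn_config"
  )
}

init_linear <- function(fan_in, fan_out, rng) {
  b <- 1 / sqrt(fan_in)
  matrix(rng$runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

#' Train the linear network with supervised dimensionality reduction
#'
#' A four-layer fully connected *linear* network for full-epoch multiclass
#' decoding. The first layer multiplies each trial's
#' `[n_times x n_channels]` matrix by a learnable `[channels x components]`
#' weight matrix (a time-shared spatial projection, the supervised analogue
#' of channel PCA); the result is flattened and passed through three affine
#' layers, the last of width `n_classes`. The network is trained end to end
#' with softmax cross-entropy and Adam, with multiplicative (inverted)
#' dropout before each affine layer during training. There is no
#' nonlinearity, so the evaluation-mode network is a single affine map
#' (see [collapse_nn()]); depth and dropout still shape what the projection
#' learns because gradient-descent dynamics differ from the collapsed
#' parametrisation.
#'
#' Training runs for the configured number of epochs without early
#' stopping; the projection matrix is read off the finished model with
#' [extract_projection()]. Validation trials are used for reporting only.
#'
#' @param epochs a [meg_epochs()] object (typically whitened).
#' @param split a [stratified_split()] result.
#' @param cfg a [nn_config()].
#' @param verbose print the training trace.
#' @return A `meg_nn` model.
#' @export
train_nn <- function(epochs, split, cfg = nn_config(), verbose = FALSE) {
  d <- dim(epochs$data)
  n_ch <- d[2L]; nt <- d[3L]
  classes <- sort(unique(epochs$labels))
  k_cls <- length(classes)
  tr_idx <- split$train
  n_tr <- length(tr_idx)
  if (any(table(factor(epochs$labels[tr_idx], levels = classes)) < 1))
    stop("every class needs at least one training trial")
  rng <- local_rng(cfg$seed)
  k <- cfg$n_components

  W_dr <- init_linear(n_ch, k, rng)
  W1 <- init_linear(nt * k, cfg$h1, rng); b1 <- numeric(cfg$h1)
  W2 <- init_linear(cfg$h1, cfg$h2, rng); b2 <- numeric(cfg$h2)
  W3 <- init_linear(cfg$h2, k_cls, rng);  b3 <- numeric(k_cls)

  # raw per-timepoint design, rows ordered (trial-major, time-fastest)
  x_tr <- epochs$data[tr_idx, , , drop = FALSE]
  m_raw <- matrix(aperm(x_tr, c(3L, 1L, 2L)), nrow = n_tr * nt, ncol = n_ch)
  y <- match(epochs$labels[tr_idx], classes)
  y_onehot <- matrix(0, n_tr, k_cls)
  y_onehot[cbind(seq_len(n_tr), y)] <- 1

  params <- list(W_dr = W_dr, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 W3 = W3, b3 = b3)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  keep <- 1 - cfg$dropout
  bs <- min(cfg$batch_size, n_tr)
  trace <- list()

  for (ep in seq_len(cfg$n_epochs)) {
    ord <- rng$sample(n_tr)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n_tr, by = bs)) {
      batch <- ord[start:min(start + bs - 1L, n_tr)]
      nb <- length(batch)
      rows <- rep((batch - 1L) * nt, each = nt) + seq_len(nt)
      red <- m_raw[rows, , drop = FALSE] %*% params$W_dr   # [(nb*nt) x k]
      h0 <- batch_rows_to_features(red, nb, nt, k)          # [nb x nt*k]

      d0 <- matrix(rng$runif(nb * nt * k) < keep, nb) / keep
      h0d <- h0 * d0
      z1 <- h0d %*% params$W1
      z1 <- sweep(z1, 2L, params$b1, `+`)
      d1 <- matrix(rng$runif(nb * cfg$h1) < keep, nb) / keep
      z1d <- z1 * d1
      z2 <- z1d %*% params$W2
      z2 <- sweep(z2, 2L, params$b2, `+`)
      d2 <- matrix(rng$runif(nb * cfg$h2) < keep, nb) / keep
      z2d <- z2 * d2
      logits <- sweep(z2d %*% params$W3, 2L, params$b3, `+`)

      lg <- logits - apply(logits, 1L, max)
      p <- exp(lg); p <- p / rowSums(p)
      yb <- y_onehot[batch, , drop = FALSE]
      loss <- -mean(log(pmax(p[cbind(seq_len(nb), y[batch])], 1e-12)))
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + loss * nb
      ep_correct <- ep_correct +
        sum(max.col(logits, ties.method = "first") == y[batch])

      dlogits <- (p - yb) / nb
      g_W3 <- crossprod(z2d, dlogits); g_b3 <- colSums(dlogits)
      dz2 <- (dlogits %*% t(params$W3)) * d2
      g_W2 <- crossprod(z1d, dz2); g_b2 <- colSums(dz2)
      dz1 <- (dz2 %*% t(params$W2)) * d1
      g_W1 <- crossprod(h0d, dz1); g_b1 <- colSums(dz1)
      dh0 <- (dz1 %*% t(params$W1)) * d0
      dred <- features_to_batch_rows(dh0, nb, nt, k)
      g_Wdr <- crossprod(m_raw[rows, , drop = FALSE], dred)

      grads <- list(W_dr = g_Wdr, W1 = g_W1, b1 = g_b1, W2 = g_W2,
                    b2 = g_b2, W3 = g_W3, b3 = g_b3)
      step <- step + 1L
      for (nm in names(params)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    if (ep %% cfg$log_every == 0L || ep == cfg$n_epochs) {
      rec <- list(epoch = ep, loss = ep_loss / n_tr,
                  train_accuracy = ep_correct / n_tr)
      trace[[length(trace) + 1L]] <- rec
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  train acc %.3f",
                        ep, rec$loss, rec$train_accuracy))
    }
  }

  structure(
    list(W_dr = params$W_dr, W1 = params$W1, b1 = params$b1,
         W2 = params$W2, b2 = params$b2, W3 = params$W3, b3 = params$b3,
         n_channels = n_ch, n_times = nt, n_components = k,
         classes = classes, cfg = cfg,
         trace = do.call(rbind, lapply(trace, as.data.frame))),
    class = "meg_nn"
  )
}

# [(nb*nt) x k] per-timepoint rows -> [nb x nt*k] row-major trial features
batch_rows_to_features <- function(red, nb, nt, k) {
  out <- matrix(0, nb, nt * k)
  for (t in seq_len(nt))
    out[, (t - 1L) * k + seq_len(k)] <-
      red[(seq_len(nb) - 1L) * nt + t, , drop = FALSE]
  out
}

# inverse of batch_rows_to_features
features_to_batch_rows <- function(feat, nb, nt, k) {
  out <- matrix(0, nb * nt, k)
  for (t in seq_len(nt))
    out[(seq_len(nb) - 1L) * nt + t, ] <-
      feat[, (t - 1L) * k + seq_len(k), drop = FALSE]
  out
}

#' Forward pass of the linear network on one epoch
#'
#' @param model a trained `meg_nn`.
#' @param epoch numeric matrix `[n_times x n_channels]`.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout masks drawn
#'   from the session RNG).
#' @return numeric vector of unnormalised class logits.
#' @export
nn_forward <- function(model, epoch, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (!all(dim(epoch) == c(model$n_times, model$n_channels)))
    stop("epoch shape does not match model")
  h0 <- flatten_epoch(epoch %*% model$W_dr)
  keep <- 1 - model$cfg$dropout
  mask <- function(n) if (mode == "train")
    (stats::runif(n) < keep) / keep else rep(1, n)
  h0 <- h0 * mask(length(h0))
  z1 <- drop(h0 %*% model$W1) + model$b1
  z1 <- z1 * mask(length(z1))
  z2 <- drop(z1 %*% model$W2) + model$b2
  z2 <- z2 * mask(length(z2))
  drop(z2 %*% model$W3) + model$b3
}

#' @export
#' @rdname nn_forward
#' @param object a trained `meg_nn`.
#' @param newdata array `[n_trials x n_channels x n_times]` or a
#'   `meg_epochs` object.
#' @param type `"class"` or `"scores"`.
#' @param ... unused.
predict.meg_nn <- function(object, newdata, type = c("class", "scores"),
                           ...) {
  type <- match.arg(type)
  if (inherits(newdata, "meg_epochs")) newdata <- newdata$data
  feats <- project_and_flatten(newdata, object$W_dr)
  z <- sweep(feats %*% object$W1, 2L, object$b1, `+`)
  z <- sweep(z %*% object$W2, 2L, object$b2, `+`)
  scores <- sweep(z %*% object$W3, 2L, object$b3, `+`)
  if (type == "scores") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Collapse the evaluation-mode network to a single affine map
#'
#' Because every layer is affine, the eval-mode network equals one affine
#' transformation of the flattened raw epoch (row-major
#' `[n_times x n_channels]` order).
#'
#' @param model a trained `meg_nn`.
#' @return list with `weight` (`[n_times * n_channels x n_classes]`) and
#'   `bias` (`[n_classes]`).
#' @export
collapse_nn <- function(model) {
  k <- model$n_components; nt <- model$n_times; nc <- model$n_channels
  w123 <- model$W1 %*% (model$W2 %*% model$W3)       # [nt*k x K]
  weight <- matrix(0, nt * nc, ncol(w123))
  for (t in seq_len(nt))
    weight[(t - 1L) * nc + seq_len(nc), ] <-
      model$W_dr %*% w123[(t - 1L) * k + seq_len(k), , drop = FALSE]
  bias <- drop((drop(model$b1 %*% model$W2) + model$b2) %*% model$W3) +
    model$b3
  list(weight = weight, bias = bias)
}

#' Extract the learned channel-projection matrix
#'
#' The supervised dimensionality-reduction weights of a trained network,
#' used as the projection of the LDA-NN decoder.
#'
#' @param model a trained `meg_nn`.
#' @return numeric matrix `[n_channels x n_components]`.
#' @export
extract_projection <- function(model) {
  stopifnot(inherits(model, "meg_nn"))
  model$W_dr
}

#' @export
print.meg_nn <- function(x, ...) {
  cat("<meg_nn> ", x$n_channels, " channels -> ", x$n_components,
      " components; hidden ", x$cfg$h1, "/", x$cfg$h2, "; ",
      length(x$classes), " classes\n", sep = "")
  if (!is.null(x$trace) && nrow(x$trace))
    cat("  final train accuracy ",
        signif(utils::tail(x$trace$train_accuracy, 1), 3), "\n", sep = "")
  invisible(x)
}
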