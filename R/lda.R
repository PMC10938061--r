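#' Multiclass linear discriminant analysis with covariance shrinkage
#'
#' LDA with a shared class covariance shrunk toward a scaled identity,
#' `(1 - s) * S + s * (tr(S) / d) * I`. With `shrinkage = "auto"` the
#' intensity `s` is the Ledoit--Wolf analytic estimate computed from the
#' class-centred training data; any fixed fraction in `[0, 1]` is also
#' accepted. Shrinkage keeps the estimator well-posed when the feature
#' dimension exceeds the trial count, the usual regime for flattened
#' full-epoch features.
#'
#' @param x numeric feature matrix `[n_trials x d]`.
#' @param labels integer class labels (>= 2 distinct values).
#' @param shrinkage `"auto"` or a fraction in `[0, 1]`.
#' @return A `meg_lda` model: class means, priors, shrinkage intensity used,
#'   and the linear discriminant coefficients.
#' @examples
#' x <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' m <- fit_lda(x, rep(0:1, each = 20))
#' mean(predict(m, x) == rep(0:1, each = 20))
#' @export
fit_lda <- function(x, labels, shrinkage = "auto") {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("LDA needs at least 2 classes")
  if (nrow(x) != length(labels)) stop("one label per row required")
  d <- ncol(x)
  n <- nrow(x)

  means <- t(vapply(classes, function(cl)
    colMeans(x[labels == cl, , drop = FALSE]), numeric(d)))
  priors <- as.numeric(table(factor(labels, levels = classes))) / n

  centered <- x - means[match(labels, classes), , drop = FALSE]
  s_hat <- if (identical(shrinkage, "auto")) {
    ledoit_wolf_shrinkage(centered)
  } else {
    s <- as.numeric(shrinkage)
    if (is.na(s) || s < 0 || s > 1) stop("shrinkage must be 'auto' or in [0,1]")
    s
  }
  cov <- crossprod(centered) / n
  mu <- sum(diag(cov)) / d
  cov <- (1 - s_hat) * cov
  diag(cov) <- diag(cov) + s_hat * mu + max(mu, 1) * 1e-10  # numerical floor

  ch <- chol(cov)
  coef <- backsolve(ch, forwardsolve(t(ch), t(means)))   # Sigma^-1 M'
  intercept <- -0.5 * colSums(t(means) * coef) + log(priors)

  structure(
    list(means = means, priors = priors, classes = classes,
         shrinkage = s_hat, coef = coef, intercept = intercept, d = d),
    class = "meg_lda"
  )
}

# Ledoit-Wolf (2004) analytic shrinkage intensity toward (tr(S)/d) * I,
# computed from already-centred rows.
ledoit_wolf_shrinkage <- function(centered) {
  n <- nrow(centered); d <- ncol(centered)
  if (n < 2) return(1)
  s <- crossprod(centered) / n
  mu <- sum(diag(s)) / d
  s2 <- sum(s^2)
  delta2 <- (s2 - 2 * mu * sum(diag(s)) + d * mu^2) / d
  if (delta2 <= 0) return(0)
  beta2 <- (sum(rowSums(centered^2)^2) / n - s2) / (n * d)
  max(0, min(1, min(beta2, delta2) / delta2))
}

#' @export
#' @rdname fit_lda
#' @param object a fitted `meg_lda`.
#' @param newdata feature matrix `[n x d]`.
#' @param type `"class"` for labels (ties broken toward the lowest class
#'   index) or `"scores"` for the discriminant matrix.
#' @param ... unused.
predict.meg_lda <- function(object, newdata, type = c("class", "scores"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d) stop("feature dimension mismatch")
  scores <- newdata %*% object$coef
  scores <- sweep(scores, 2L, object$intercept, `+`)
  colnames(scores) <- object$classes
  if (type == "scores") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.meg_lda <- function(x, ...) {
  cat("<meg_lda> ", length(x$classes), " classes, d = ", x$d,
      ", shrinkage = ", signif(x$shrinkage, 3), "\n", sep = "")
  invisible(x)
}

#' Unsupervised channel-projection matrix from PCA
#'
#' Principal directions of the pooled `[timepoints x channels]` training
#' matrix (all timepoints of all training trials, channel means removed),
#' ordered by explained variance. Used as the unsupervised counterpart of
#' the network-learned projection.
#'
#' @param epochs a [meg_epochs()] object.
#' @param train_idx training trial indices.
#' @param n_components number of components (<= channels).
#' @return `channels x n_components` matrix with attributes
#'   `explained_variance` (per component) and `explained_fraction`
#'   (cumulative fraction retained).
#' @export
fit_channel_pca <- function(epochs, train_idx, n_components) {
  d <- dim(epochs$data)
  if (n_components > d[2L]) stop("more components than channels")
  x <- epochs$data[train_idx, , , drop = FALSE]
  m <- matrix(aperm(x, c(3L, 1L, 2L)), ncol = d[2L])
  m <- sweep(m, 2L, colMeans(m))
  cov <- crossprod(m) / (nrow(m) - 1L)
  e <- eigen(cov, symmetric = TRUE)
  proj <- e$vectors[, seq_len(n_components), drop = FALSE]
  attr(proj, "explained_variance") <- e$values[seq_len(n_components)]
  attr(proj, "explained_fraction") <-
    sum(e$values[seq_len(n_components)]) / sum(e$values)
  proj
}
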