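# Nearest-centroid classification in linear discriminant space.

#' Train a nearest-centroid LDA texture classifier
#'
#' Features are z-scored by training statistics, the pooled within-class
#' covariance is formed (with optional Ledoit-style shrinkage towards a
#' scaled identity), and its eigendecomposition provides a pseudo-inverse
#' whitening that tolerates singular covariances (feature dimension can
#' approach or exceed the sample count). Class means are then rotated onto at
#' most `nclass - 1` discriminant directions; classification assigns the
#' class whose centroid is nearest in Euclidean distance in that space.
#'
#' @param x numeric matrix, rows = training samples, columns = features.
#' @param grouping class labels (coerced to factor); every class needs at
#'   least two samples.
#' @param shrinkage mixing weight in `[0, 1]` towards
#'   `mean(diag(Sw)) * I`; `0` relies on the pseudo-inverse alone. The
#'   default 0.1 guards the whitening step against noise amplification when
#'   the feature dimension approaches the sample count (classification
#'   results are insensitive to values in roughly 0.05-0.5).
#' @param tol relative eigenvalue threshold for the pseudo-inverse.
#' @return Object of class `"texture_lda"`.
#' @seealso [predict.texture_lda()]
#' @export
texture_lda <- function(x, grouping, shrinkage = 0.1, tol = 1e-8) {
  x <- as.matrix(x)
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop("need at least two classes")
  nc <- table(grouping)
  if (any(nc < 2L))
    stop("every class needs at least two samples (",
         paste(names(nc)[nc < 2], collapse = ", "), " too small)")
  n <- nrow(x); p <- ncol(x); k <- nlevels(grouping)

  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sd, `/`)

  M <- matrix(0, k, p)                      # standardised class means
  Sw <- matrix(0, p, p)
  for (g in seq_len(k)) {
    xi <- xs[grouping == levels(grouping)[g], , drop = FALSE]
    M[g, ] <- colMeans(xi)
    Sw <- Sw + crossprod(sweep(xi, 2, M[g, ]))
  }
  Sw <- Sw / (n - k)
  if (shrinkage > 0)
    Sw <- (1 - shrinkage) * Sw + shrinkage * mean(diag(Sw)) * diag(p)

  ev <- eigen(Sw, symmetric = TRUE)
  if (max(ev$values, 0) <= 0)
    stop("within-class covariance is identically zero")
  # floor (rather than drop) near-null eigenvalues: directions with almost no
  # within-class spread are kept with a large finite weight, so between-class
  # separation living there is not discarded
  lam <- pmax(ev$values, tol * max(ev$values))
  Wh <- ev$vectors %*% diag(1 / sqrt(lam), p)    # whitener, p x p

  Mw <- M %*% Wh
  Bc <- sweep(Mw, 2, colMeans(Mw))
  sv <- svd(Bc)
  r <- min(k - 1L, sum(sv$d > tol * max(sv$d, 0)))
  if (r < 1L) r <- 1L
  scaling <- Wh %*% sv$v[, seq_len(r), drop = FALSE]  # p x r projection

  structure(list(levels = levels(grouping), center = mu, scale = sd,
                 scaling = scaling, centroids = M %*% scaling,
                 shrinkage = shrinkage, tol = tol, p = p),
            class = "texture_lda")
}

#' Classify feature vectors
#'
#' @param object a [texture_lda()] classifier.
#' @param newdata numeric matrix (or single feature vector) with the training
#'   feature length.
#' @param ... unused.
#' @return Factor of predicted class labels; ties in centroid distance go to
#'   the lowest class index.
#' @export
predict.texture_lda <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature length ", ncol(newdata), " does not match training length ",
         object$p)
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`) %*%
    object$scaling
  d2 <- outer(rowSums(z^2), rowSums(object$centroids^2), `+`) -
    2 * z %*% t(object$centroids)
  idx <- apply(d2, 1, function(row) which(row <= min(row) + 1e-12)[1])
  factor(object$levels[idx], levels = object$levels)
}

#' @export
print.texture_lda <- function(x, ...) {
  cat("Nearest-centroid LDA classifier:", length(x$levels), "classes,",
      x$p, "features,", ncol(x$scaling), "discriminant direction(s)\n")
  if (x$shrinkage > 0) cat("  covariance shrinkage:", x$shrinkage, "\n")
  invisible(x)
}
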