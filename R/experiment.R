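# Sub-image sampling classification experiment.

#' Colour-texture classification experiment
#'
#' Runs the fixed-split classification study on a set of source images, one
#' per texture class: `n_sub` square sub-images are sampled (uniformly over
#' valid top-left positions, with replacement) from the upper half of each
#' source as the training set and another `n_sub` from the lower half as the
#' test set. Each sub-image is summarised by its spectral/coherence feature
#' vector ([lws_features()]), a nearest-centroid LDA classifier is trained,
#' and the fraction of test sub-images assigned to their true class is
#' reported. Fully deterministic given `seed`.
#'
#' @param sources list of three-channel [ls2w_field()]s (or `R x S x 3`
#'   arrays) with identical dimensions, one per class.
#' @param n_sub sub-images per class per split.
#' @param size sub-image side length (dyadic).
#' @param seed integer seed for the position sampling.
#' @param J scales used for the features (default 4: on 64 x 64 sub-images
#'   the full depth would give more features than training samples).
#' @param filter,kernel,h estimator settings passed to [mvlws()].
#' @param abs_coherence use `|rho|` features (see [lws_features()]).
#' @param shrinkage LDA covariance shrinkage (see [texture_lda()]).
#' @param labels optional class labels (default `class1`, ... or source
#'   names).
#' @return Object of class `"texture_experiment"`: list with `rate` (fraction
#'   correct over all test sub-images), `confusion` (true class x assigned
#'   class counts), `per_class` rates, and the configuration.
#' @export
texture_experiment <- function(sources, n_sub = 50, size = 64, seed = NULL,
                               J = 4, filter = ls2w_filter("haar"),
                               kernel = "uniform", h = NULL,
                               abs_coherence = FALSE, shrinkage = 0.1,
                               labels = NULL) {
  stopifnot(is.list(sources), length(sources) >= 2)
  dims <- lapply(sources, function(s) dim(s)[1:2])
  if (length(unique(dims)) != 1L) stop("sources must share dimensions")
  R <- dims[[1]][1]; S <- dims[[1]][2]
  size <- as.integer(size)
  if (!.is_dyadic(size)) stop("sub-image side must be a power of two")
  if (size > R / 2) stop("sub-image side ", size,
                         " exceeds the half-height of the sources (", R / 2, ")")
  if (any(vapply(sources, function(s) dim(s)[3], 1L) != 3L))
    stop("sources must have three channels")
  if (is.null(labels))
    labels <- if (!is.null(names(sources))) names(sources) else
      paste0("class", seq_along(sources))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(h)) h <- sqrt(size)
  J <- as.integer(J)
  .check_field_dims(size, size, J)
  kernels <- .ndwt_kernels(size, size, J, filter)

  # top-left row ranges: training = upper half, test = lower half
  train_rows <- 1:(R / 2 - size + 1)
  test_rows <- (R / 2 + 1):(R - size + 1)
  cols <- 1:(S - size + 1)

  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  feats_of <- function(src, rows, n) {
    r0 <- resample(rows, n)
    c0 <- resample(cols, n)
    t(vapply(seq_len(n), function(i) {
      sub <- unclass(src)[r0[i]:(r0[i] + size - 1),
                          c0[i]:(c0[i] + size - 1), , drop = FALSE]
      lws_features(mvlws(sub, J = J, filter = filter, kernel = kernel, h = h,
                         kernels = kernels),
                   abs_coherence = abs_coherence)
    }, numeric(9L * 3L * J)))
  }

  train_x <- NULL; test_x <- NULL; train_y <- NULL; test_y <- NULL
  for (g in seq_along(sources)) {
    train_x <- rbind(train_x, feats_of(sources[[g]], train_rows, n_sub))
    test_x <- rbind(test_x, feats_of(sources[[g]], test_rows, n_sub))
    train_y <- c(train_y, rep(labels[g], n_sub))
    test_y <- c(test_y, rep(labels[g], n_sub))
  }
  clf <- texture_lda(train_x, train_y, shrinkage = shrinkage)
  pred <- predict(clf, test_x)
  truth <- factor(test_y, levels = labels)
  confusion <- table(truth = truth, assigned = pred)
  per_class <- diag(confusion) / n_sub
  structure(list(rate = mean(pred == truth), confusion = confusion,
                 per_class = per_class, classifier = clf,
                 config = list(n_sub = n_sub, size = size, seed = seed, J = J,
                               filter = filter$family, kernel = kernel, h = h,
                               abs_coherence = abs_coherence,
                               shrinkage = shrinkage, labels = labels)),
            class = "texture_experiment")
}

#' @export
print.texture_experiment <- function(x, ...) {
  cat("Colour-texture classification experiment\n")
  cfg <- x$config
  cat("  ", length(cfg$labels), " classes, ", cfg$n_sub, " + ", cfg$n_sub,
      " sub-images of ", cfg$size, " x ", cfg$size, " per class (J = ",
      cfg$J, ", ", cfg$filter, ", ", cfg$kernel, " h = ", format(cfg$h),
      ")\n", sep = "")
  cat(sprintf("  correct classification rate: %.2f%%\n", 100 * x$rate))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
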