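# Local wavelet spectral estimation: raw cross-periodograms, kernel
# smoothing, bias correction by the inverse inner-product matrix, coherence.

.pair_table <- function(m, diag = TRUE) {
  idx <- which(if (diag) upper.tri(diag(m), diag = TRUE) else
               upper.tri(diag(m)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

.pair_label <- function(pairs) paste0(pairs[, 1], ",", pairs[, 2])

#' Raw wavelet cross-periodogram
#'
#' The elementwise product `I[eta, u] = d_p[eta, u] * d_q[eta, u]` of the
#' non-decimated wavelet coefficients of two channels. With `p = q` this is
#' the (nonnegative) raw auto-periodogram. A biased, inconsistent estimator
#' of the local wavelet cross-spectrum; see [smooth_periodogram()] and
#' [correct_periodogram()] for the consistent version.
#'
#' @param dp,dq [ndwt2()] coefficient stacks from channels of the same field
#'   (identical dimensions and `J`).
#' @return Object of class `"ls2w_periodogram"`: a list of `3J` matrices with
#'   attributes `J`, `dim` and `stage = "raw"`.
#' @export
raw_periodogram <- function(dp, dq = dp) {
  stopifnot(inherits(dp, "ndwt2"), inherits(dq, "ndwt2"))
  if (!identical(attr(dp, "dims"), attr(dq, "dims")) ||
      !identical(attr(dp, "J"), attr(dq, "J")))
    stop("coefficient stacks have mismatched dimensions or J")
  out <- lapply(seq_along(dp), function(e) dp[[e]] * dq[[e]])
  structure(out, J = attr(dp, "J"), dims = attr(dp, "dims"), stage = "raw",
            class = "ls2w_periodogram")
}

#' @export
print.ls2w_periodogram <- function(x, ...) {
  cat("Wavelet periodogram (", attr(x, "stage"), "): ", length(x),
      " planes, ", paste(attr(x, "dims"), collapse = " x "), "\n", sep = "")
  invisible(x)
}

# normalised smoothing weights on the torus, as an FFT-ready kernel
.smoothing_kernel <- function(R, S, kernel, h) {
  dr <- pmin(0:(R - 1), R - (0:(R - 1)))
  dc <- pmin(0:(S - 1), S - (0:(S - 1)))
  D2 <- outer(dr^2, dc^2, `+`)
  K <- switch(kernel,
              uniform = (D2 <= h^2) * 1,
              gaussian = exp(-D2 / (2 * h^2)),
              epanechnikov = pmax(0, 1 - D2 / h^2))
  stats::fft(K / sum(K))
}

#' Kernel smoothing of a wavelet periodogram
#'
#' Nadaraya-Watson local averaging of each periodogram plane over locations:
#' `Ismooth[s] = sum_u w_u I[u]` with weights
#' `w_u = K_h(||s - u||) / sum_u K_h(||s - u||)`. Smoothing is what makes the
#' periodogram a consistent estimator (its variance vanishes as the bandwidth
#' and field grow together). Distances are Euclidean on the torus, so the
#' weights are the same at every location and the average is a circular
#' convolution.
#'
#' @param I an `"ls2w_periodogram"`.
#' @param kernel `"uniform"` (indicator of the Euclidean ball of radius `h`,
#'   the default), `"gaussian"` or `"epanechnikov"`.
#' @param h bandwidth in pixels, `> 0`. A uniform kernel with `h < 1` is the
#'   identity map.
#' @return The smoothed periodogram (`stage = "smoothed"`).
#' @export
smooth_periodogram <- function(I, kernel = c("uniform", "gaussian",
                                             "epanechnikov"), h) {
  stopifnot(inherits(I, "ls2w_periodogram"))
  kernel <- match.arg(kernel)
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("bandwidth h must be a positive number")
  d <- attr(I, "dims")
  fk <- .smoothing_kernel(d[1], d[2], kernel, h)
  out <- lapply(I, function(p)
    Re(stats::fft(stats::fft(p) * fk, inverse = TRUE)) / prod(d))
  structure(out, J = attr(I, "J"), dims = d, stage = "smoothed",
            kernel = kernel, h = h, class = "ls2w_periodogram")
}

#' Bias correction of a smoothed periodogram
#'
#' The expectation of the (smoothed) raw periodogram at `eta` mixes the true
#' spectrum across all scale-direction pairs through the inner-product matrix
#' `A`. Premultiplying the length-`3J` periodogram vector at each location by
#' `A^{-1}` removes this leakage, giving an asymptotically unbiased spectral
#' estimator.
#'
#' @param I an `"ls2w_periodogram"` with all `3J` planes present.
#' @param A an [ipm()] with matching `J`.
#' @return The corrected periodogram (`stage = "corrected"`).
#' @export
correct_periodogram <- function(I, A) {
  stopifnot(inherits(I, "ls2w_periodogram"), inherits(A, "ls2w_ipm"))
  if (attr(I, "J") != A$J)
    stop("periodogram J = ", attr(I, "J"), " does not match A_J with J = ", A$J)
  d <- attr(I, "dims")
  M <- do.call(rbind, lapply(I, as.vector))   # 3J x npix
  C <- A$Ainv %*% M
  out <- lapply(seq_len(nrow(C)), function(e) matrix(C[e, ], d[1], d[2]))
  structure(out, J = attr(I, "J"), dims = d, stage = "corrected",
            kernel = attr(I, "kernel"), h = attr(I, "h"),
            class = "ls2w_periodogram")
}

#' Fit the local wavelet spectral model to a multichannel field
#'
#' The estimation pipeline for an LS2Wmv field: channels are mean-centred,
#' transformed with the non-decimated 2D wavelet transform, raw
#' cross-periodograms are formed for every channel pair, smoothed by a
#' Nadaraya-Watson kernel average, bias-corrected by the inverse
#' autocorrelation-wavelet inner-product matrix, and converted to local
#' wavelet coherence
#' `rho[eta](z) = S^{p,q}[eta](z) / sqrt(S^{p,p}[eta](z) S^{q,q}[eta](z))`.
#' Coherence denominators are floored at `eps` and the ratio clipped to
#' `[-1, 1]`; the counts of floored and clipped points are retained.
#'
#' @param x an [ls2w_field()] or numeric `R x S x m` array (matrix for a
#'   single channel), dyadic dimensions.
#' @param J number of scales; default is the full dyadic depth
#'   `log2(min(R, S))`.
#' @param filter an [ls2w_filter()].
#' @param kernel,h smoothing kernel and bandwidth (see
#'   [smooth_periodogram()]); default bandwidth `sqrt(min(R, S))`.
#' @param eps floor applied to auto-spectra in coherence denominators.
#' @param kernels optional precomputed NDWT kernel FFTs (see [ndwt2()]).
#' @return Object of class `"mvlws"` with elements
#'   \describe{
#'     \item{`S`}{`R x S x 3J x m(m+1)/2` array of corrected auto-/cross-
#'       spectral estimates, pairs in row-major upper-triangle order.}
#'     \item{`rho`}{`R x S x 3J x m(m-1)/2` array of coherence estimates
#'       (`NULL` when `m = 1`).}
#'     \item{`pairs`, `cpairs`}{index tables mapping pair slots to `(p, q)`.}
#'     \item{`counts`}{floored/clipped point counts.}
#'   }
#'   plus the settings used.
#' @examples
#' x <- simulate(demo_process("P1"), seed = 1, dim = c(64, 64))
#' fit <- mvlws(x, J = 3)
#' fit
#' @export
mvlws <- function(x, J = NULL, filter = ls2w_filter("haar"),
                  kernel = c("uniform", "gaussian", "epanechnikov"), h = NULL,
                  eps = 1e-10, kernels = NULL) {
  kernel <- match.arg(kernel)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  R <- dim(x)[1]; S <- dim(x)[2]; m <- dim(x)[3]
  if (is.null(J)) J <- floor(log2(min(R, S)))
  J <- as.integer(J)
  .check_field_dims(R, S, J)
  if (is.null(h)) h <- sqrt(min(R, S))
  if (is.null(kernels)) kernels <- .ndwt_kernels(R, S, J, filter)
  A <- ipm(J, filter)
  fk <- .smoothing_kernel(R, S, kernel, h)
  npix <- R * S; nEta <- 3L * J

  # NDWT of each mean-centred channel
  d <- lapply(seq_len(m), function(i)
    ndwt2(x[, , i] - mean(x[, , i]), J, filter, kernels = kernels))

  pairs <- .pair_table(m, diag = TRUE)
  Sarr <- array(NA_real_, c(R, S, nEta, nrow(pairs)))
  for (k in seq_len(nrow(pairs))) {
    I <- raw_periodogram(d[[pairs[k, 1]]], d[[pairs[k, 2]]])
    Ism <- lapply(I, function(p)
      Re(stats::fft(stats::fft(p) * fk, inverse = TRUE)) / npix)
    M <- A$Ainv %*% do.call(rbind, lapply(Ism, as.vector))
    for (e in seq_len(nEta)) Sarr[, , e, k] <- M[e, ]
  }

  rho <- NULL; cpairs <- NULL
  floored <- 0L; clipped <- 0L
  if (m > 1) {
    slot <- function(p, q) which(pairs[, 1] == p & pairs[, 2] == q)
    cpairs <- .pair_table(m, diag = FALSE)
    rho <- array(NA_real_, c(R, S, nEta, nrow(cpairs)))
    for (k in seq_len(nrow(cpairs))) {
      p <- cpairs[k, 1]; q <- cpairs[k, 2]
      Spp <- Sarr[, , , slot(p, p), drop = FALSE]
      Sqq <- Sarr[, , , slot(q, q), drop = FALSE]
      floored <- floored + sum(Spp < eps) + sum(Sqq < eps)
      r <- Sarr[, , , slot(p, q), drop = FALSE] /
        sqrt(pmax(Spp, eps) * pmax(Sqq, eps))
      clipped <- clipped + sum(abs(r) > 1)
      rho[, , , k] <- pmin(1, pmax(-1, r))
    }
  }
  structure(list(S = Sarr, rho = rho, pairs = pairs, cpairs = cpairs,
                 m = m, J = J, dim = c(R, S), filter = filter,
                 kernel = kernel, h = h, eps = eps,
                 counts = c(floored = floored, clipped = clipped)),
            class = "mvlws")
}

#' Extract spectral or coherence planes from a fit
#'
#' @param fit an [mvlws()] fit.
#' @param p,q channel pair (`p = q` for an auto-spectrum; `p < q` for
#'   coherence).
#' @param eta scale-direction index, `1, ..., 3J`.
#' @return The requested `R x S` plane.
#' @export
lws_spectrum <- function(fit, p, q = p, eta) {
  stopifnot(inherits(fit, "mvlws"))
  pq <- sort(c(p, q))
  k <- which(fit$pairs[, 1] == pq[1] & fit$pairs[, 2] == pq[2])
  if (length(k) != 1L) stop("no such channel pair")
  fit$S[, , eta, k]
}

#' @rdname lws_spectrum
#' @export
lws_coherence <- function(fit, p, q, eta) {
  stopifnot(inherits(fit, "mvlws"))
  if (p == q) return(matrix(1, fit$dim[1], fit$dim[2]))
  pq <- sort(c(p, q))
  k <- which(fit$cpairs[, 1] == pq[1] & fit$cpairs[, 2] == pq[2])
  if (length(k) != 1L) stop("no such channel pair")
  fit$rho[, , eta, k]
}

#' @export
print.mvlws <- function(x, ...) {
  cat("Local wavelet spectral fit (LS2Wmv)\n")
  cat("  field: ", paste(x$dim, collapse = " x "), ", ", x$m,
      " channel(s), J = ", x$J, " (", 3 * x$J, " scale-direction pairs)\n",
      sep = "")
  cat("  filter:", x$filter$family,
      if (x$filter$family != "haar") paste0("(", x$filter$number, ")"),
      " smoothing:", x$kernel, "kernel, h =", format(x$h), "\n")
  cat("  coherence guard rails: ", x$counts["floored"], " floored, ",
      x$counts["clipped"], " clipped\n", sep = "")
  invisible(x)
}

#' @export
summary.mvlws <- function(object, ...) {
  lev <- eta_levels(object$J)
  auto <- which(object$pairs[, 1] == object$pairs[, 2])
  tab <- data.frame(lev,
                    vapply(auto, function(k)
                      apply(object$S[, , , k, drop = FALSE], 3, mean),
                      numeric(3 * object$J)))
  names(tab)[-(1:3)] <- paste0("S", object$pairs[auto, 1],
                               object$pairs[auto, 1])
  if (!is.null(object$rho)) {
    rtab <- vapply(seq_len(nrow(object$cpairs)), function(k)
      apply(object$rho[, , , k, drop = FALSE], 3, mean),
      numeric(3 * object$J))
    rtab <- matrix(rtab, nrow = 3 * object$J)
    colnames(rtab) <- paste0("rho", .pair_label(object$cpairs))
    tab <- cbind(tab, rtab)
  }
  structure(list(table = tab, fit = object), class = "summary.mvlws")
}

#' @export
print.summary.mvlws <- function(x, ...) {
  print(x$fit)
  cat("\nLocation-averaged spectra and coherence by scale-direction:\n")
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.mvlws <- function(x, p = 1, q = if (x$m > 1) 2 else 1, eta = 1,
                       what = c("coherence", "spectrum"), ...) {
  what <- match.arg(what)
  plane <- if (what == "coherence" && p != q) lws_coherence(x, p, q, eta)
           else lws_spectrum(x, p, q, eta)
  graphics::image(t(plane[rev(seq_len(nrow(plane))), ]),
                  col = grDevices::hcl.colors(64, "viridis"), axes = FALSE,
                  main = paste0(what, " (", p, ",", q, "), eta = ", eta), ...)
  invisible(x)
}
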