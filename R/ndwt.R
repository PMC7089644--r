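# Non-decimated 2D wavelet transform on the torus.

.is_dyadic <- function(n) {
  n <- as.integer(n)
  n >= 1L && bitwAnd(n, n - 1L) == 0L
}

# Wrap a small (or large) kernel into an R x S array anchored at the origin,
# folding values that extend beyond the lattice (periodic boundary).
.wrap_kernel <- function(values, R, S, row0 = 0L, col0 = 0L) {
  out <- matrix(0, R, S)
  nr <- nrow(values); nc <- ncol(values)
  ri <- ((row0 + seq_len(nr) - 1L) %% R) + 1L
  ci <- ((col0 + seq_len(nc) - 1L) %% S) + 1L
  for (b in seq_len(nc)) {
    col <- ci[b]
    for (a in seq_len(nr))
      out[ri[a], col] <- out[ri[a], col] + values[a, b]
  }
  out
}

# FFTs of the wrapped 2D wavelets for all eta = 1..3J; reusable across fields
# of the same dimensions (simulation, estimation, sub-image batches).
.ndwt_kernels <- function(R, S, J, filter) {
  lev <- eta_levels(J)
  lapply(seq_len(3L * J), function(e)
    stats::fft(.wrap_kernel(ndw_wavelet(lev$j[e], lev$direction[e], filter),
                            R, S)))
}

.check_field_dims <- function(R, S, J) {
  if (!.is_dyadic(R) || !.is_dyadic(S))
    stop("field dimensions must be powers of two (got ", R, " x ", S, ")")
  Jmax <- floor(log2(min(R, S)))
  if (J > Jmax)
    stop("J = ", J, " exceeds log2(min(R, S)) = ", Jmax)
  invisible(TRUE)
}

#' Non-decimated 2D wavelet transform
#'
#' Computes the empirical wavelet coefficients
#' `d[eta, u] = sum_r x[r] psi_eta(u - r)` for every scale-direction pair
#' `eta = 1, ..., 3J`: the periodic (torus) convolution of the channel with
#' each discrete 2D wavelet, evaluated by FFT. One coefficient plane per
#' `eta`, each the same size as the input.
#'
#' @param x numeric matrix with dyadic dimensions.
#' @param J number of scales; must satisfy `J <= log2(min(dim(x)))`.
#' @param filter an [ls2w_filter()].
#' @param kernels optional precomputed kernel FFTs from an earlier transform
#'   of a field with identical `dim`, `J` and `filter` (a performance hook for
#'   batch work; contents are not checked).
#' @return Object of class `"ndwt2"`: a list of `3J` coefficient matrices,
#'   with attributes `J`, `dim` and `filter`.
#' @export
ndwt2 <- function(x, J, filter = ls2w_filter("haar"), kernels = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  R <- nrow(x); S <- ncol(x); J <- as.integer(J)
  .check_field_dims(R, S, J)
  if (is.null(kernels)) kernels <- .ndwt_kernels(R, S, J, filter)
  fx <- stats::fft(x)
  d <- lapply(kernels, function(k)
    Re(stats::fft(fx * k, inverse = TRUE)) / (R * S))
  structure(d, J = J, dims = c(R, S), filter = filter, class = "ndwt2")
}

#' @export
print.ndwt2 <- function(x, ...) {
  cat("Non-decimated 2D wavelet coefficients:", length(x), "planes (J =",
      attr(x, "J"), "),", paste(attr(x, "dims"), collapse = " x "), "\n")
  invisible(x)
}
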