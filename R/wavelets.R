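# Discrete non-decimated wavelets, their autocorrelation functions and the
# inner-product matrix that links wavelet periodograms to local spectra.

#' Scale-direction index table
#'
#' The model indexes decomposition levels by a single integer
#' `eta = j + g(l)` combining scale `j` (1 = finest, ..., `J`) and direction
#' `l` in \{vertical, horizontal, diagonal\}, with `g = 0, J, 2J` respectively.
#'
#' @param J number of scales.
#' @return A data frame with columns `eta`, `j` and `direction` covering
#'   `eta = 1, ..., 3J`.
#' @export
eta_levels <- function(J) {
  J <- as.integer(J)
  stopifnot(J >= 1)
  data.frame(eta = seq_len(3L * J),
             j = rep(seq_len(J), 3L),
             direction = rep(c("v", "h", "d"), each = J),
             stringsAsFactors = FALSE)
}

#' @rdname eta_levels
#' @param j scale, 1 (finest) to `J`.
#' @param direction `"v"`, `"h"` or `"d"`.
#' @export
eta_index <- function(j, direction, J) {
  direction <- match.arg(direction, c("v", "h", "d"))
  j <- as.integer(j); J <- as.integer(J)
  stopifnot(j >= 1, j <= J)
  j + J * (match(direction, c("v", "h", "d")) - 1L)
}

# zero-insertion upsampling by `by`
.upsample <- function(x, by) {
  if (by == 1L) return(x)
  out <- numeric((length(x) - 1L) * by + 1L)
  out[seq(1L, length(out), by = by)] <- x
  out
}

# 1D discrete father/mother wavelet vectors at scale j, by the usual cascade:
#   phi_1 = lo, psi_1 = hi,
#   phi_j = phi_{j-1} * U^{j-1} lo,  psi_j = phi_{j-1} * U^{j-1} hi
# (U = dyadic zero insertion, * = convolution). Length (2^j - 1)(L - 1) + 1.
.discrete_1d <- function(j, filter) {
  phi <- 1
  for (i in seq_len(j - 1L))
    phi <- .conv_full(phi, .upsample(filter$lo, 2L^(i - 1L)))
  list(father = .conv_full(phi, .upsample(filter$lo, 2L^(j - 1L))),
       mother = .conv_full(phi, .upsample(filter$hi, 2L^(j - 1L))))
}

# full linear convolution (small vectors; FFT above a size cutoff)
.conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  if (n < 256L) {
    out <- numeric(n)
    for (i in seq_along(b))
      out[i:(i + length(a) - 1L)] <- out[i:(i + length(a) - 1L)] + b[i] * a
    return(out)
  }
  N <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(a, numeric(N - length(a)))) *
                stats::fft(c(b, numeric(N - length(b)))),
                inverse = TRUE))[seq_len(n)] / N
}

#' Two-dimensional discrete non-decimated wavelet
#'
#' The 2D discrete wavelets are tensor products of the 1D discrete mother and
#' father wavelets at scale `j`. The orientation convention is fixed package
#' wide: "vertical" places the mother (detail) filter on the first (row) axis,
#' so it responds to variation down the rows; "horizontal" is the transpose
#' arrangement; "diagonal" is mother x mother.
#'
#' @param j scale, 1 = finest.
#' @param direction `"v"`, `"h"` or `"d"`.
#' @param filter an [ls2w_filter()].
#' @return A numeric matrix (side length `(2^j - 1)(L - 1) + 1` for filter
#'   length `L`) with unit sum of squares; detail directions sum to zero.
#' @examples
#' ndw_wavelet(1, "d", ls2w_filter("haar"))  # entries +-1/2
#' @export
ndw_wavelet <- function(j, direction, filter) {
  direction <- match.arg(direction, c("v", "h", "d"))
  stopifnot(inherits(filter, "ls2w_filter"), j >= 1)
  w <- .discrete_1d(as.integer(j), filter)
  switch(direction,
         v = outer(w$mother, w$father),
         h = outer(w$father, w$mother),
         d = outer(w$mother, w$mother))
}

# lag autocorrelation of a vector: ac[t] = sum_v x[v] x[v+t], t = -(L-1)..(L-1)
.lag_autocorr <- function(x) .lag_crosscorr(x, x)

# ac[t] = sum_v x[v] y[v+t] over t = -(Lx-1)..(Ly-1); attr "zero" marks lag 0
.lag_crosscorr <- function(x, y) {
  structure(.conv_full(rev(x), y), zero = length(x))
}

# align two lag sequences on their zero positions and take the inner product
.lag_inner <- function(a, b) {
  za <- attr(a, "zero"); zb <- attr(b, "zero")
  lo <- max(1 - za, 1 - zb)
  hi <- min(length(a) - za, length(b) - zb)
  sum(a[(lo:hi) + za] * b[(lo:hi) + zb])
}

#' Two-dimensional autocorrelation wavelet
#'
#' `Psi_eta(tau) = sum_v psi_eta(v) psi_eta(v + tau)`, the lag autocorrelation
#' of the discrete wavelet. It factorises into 1D autocorrelations of the
#' mother/father components, satisfies `Psi_eta(0, 0) = 1` and is even in
#' `tau`. These kernels link the local wavelet spectra to the local
#' (cross-)covariance of the process.
#'
#' @inheritParams ndw_wavelet
#' @return A numeric matrix over lags `-(L_j - 1), ..., L_j - 1` in each
#'   coordinate, with attribute `"zero"` giving the index of lag 0.
#' @export
acw <- function(j, direction, filter) {
  direction <- match.arg(direction, c("v", "h", "d"))
  w <- .discrete_1d(as.integer(j), filter)
  am <- .lag_autocorr(w$mother)
  af <- .lag_autocorr(w$father)
  out <- switch(direction,
                v = outer(as.numeric(am), as.numeric(af)),
                h = outer(as.numeric(af), as.numeric(am)),
                d = outer(as.numeric(am), as.numeric(am)))
  structure(out, zero = attr(am, "zero"))
}

#' Autocorrelation-wavelet inner-product matrix
#'
#' The Gram matrix `A[eta, eta1] = sum_tau Psi_eta(tau) Psi_eta1(tau)` of the
#' 2D autocorrelation wavelets up to scale `J`, together with its inverse.
#' Pre-multiplying the vector of smoothed periodograms across `eta` by the
#' inverse removes the leakage between scale-direction pairs and yields an
#' asymptotically unbiased spectral estimator.
#'
#' Entries are computed through the tensor factorisation into 1D
#' autocorrelation lag sums (the 2D sum separates exactly).
#'
#' @param J number of scales.
#' @param filter an [ls2w_filter()].
#' @return An object of class `"ls2w_ipm"`: list with `J`, `A` (3J x 3J
#'   symmetric positive definite), `Ainv`, and the filter.
#' @examples
#' ip <- ipm(1, ls2w_filter("haar"))
#' ip$A[1, 1]  # 2.25
#' @export
ipm <- function(J, filter) {
  J <- as.integer(J)
  stopifnot(J >= 1, inherits(filter, "ls2w_filter"))
  am <- vector("list", J); af <- vector("list", J)
  for (j in seq_len(J)) {
    w <- .discrete_1d(j, filter)
    am[[j]] <- .lag_autocorr(w$mother)
    af[[j]] <- .lag_autocorr(w$father)
  }
  # 1D inner products between every (scale, type) pair; type m = mother, f = father
  Gmm <- matrix(0, J, J); Gff <- matrix(0, J, J); Gmf <- matrix(0, J, J)
  for (j1 in seq_len(J)) for (j2 in seq_len(J)) {
    Gmm[j1, j2] <- .lag_inner(am[[j1]], am[[j2]])
    Gff[j1, j2] <- .lag_inner(af[[j1]], af[[j2]])
    Gmf[j1, j2] <- .lag_inner(am[[j1]], af[[j2]])
  }
  lev <- eta_levels(J)
  # row/column factor type per direction: v = (m, f), h = (f, m), d = (m, m)
  rowt <- c(v = "m", h = "f", d = "m")[lev$direction]
  colt <- c(v = "f", h = "m", d = "m")[lev$direction]
  g1 <- function(t1, j1, t2, j2) {
    if (t1 == "m" && t2 == "m") Gmm[j1, j2]
    else if (t1 == "f" && t2 == "f") Gff[j1, j2]
    else if (t1 == "m") Gmf[j1, j2] else Gmf[j2, j1]
  }
  n <- 3L * J
  A <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in a:n) {
    A[a, b] <- g1(rowt[a], lev$j[a], rowt[b], lev$j[b]) *
               g1(colt[a], lev$j[a], colt[b], lev$j[b])
    A[b, a] <- A[a, b]
  }
  Ainv <- tryCatch(chol2inv(chol(A)),
                   error = function(e)
                     stop("inner-product matrix is numerically singular at J = ",
                          J, " (", conditionMessage(e), ")"))
  structure(list(J = J, A = A, Ainv = Ainv, filter = filter),
            class = "ls2w_ipm")
}

#' @export
print.ls2w_ipm <- function(x, ...) {
  cat("Autocorrelation-wavelet inner-product matrix, J =", x$J,
      "(", 3 * x$J, "x", 3 * x$J, "),", x$filter$family, "filter\n")
  cat("condition number:", format(kappa(x$A, exact = TRUE), digits = 4), "\n")
  invisible(x)
}
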