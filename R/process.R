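# LS2Wmv process specifications and simulation.

#' LS2Wmv process specification
#'
#' An m-variate 2D locally stationary wavelet process is built from
#' non-decimated wavelets modulated by transfer functions `W_eta^(i)(z)` on
#' the rescaled unit square, with cross-channel dependence injected through
#' per-(eta, location) coherence `rho_eta^(p,q)(z)` of the Gaussian
#' increments. Locations are 0-based, `z = (u1/R, u2/S)`.
#'
#' @param m number of channels.
#' @param transfer function `(i, eta, z1, z2)` returning the (nonnegative)
#'   transfer-function amplitude `W_eta^(i)` at rescaled locations; `z1`, `z2`
#'   arrive as equal-shaped arrays and the result must be a like-shaped array
#'   (scalars are recycled).
#' @param coherence function `(p, q, eta, z1, z2)` (`p < q`) returning the
#'   coherence in `[-1, 1]`, same shape rules as `transfer`.
#' @param J number of scales the process lives on, or `NA` to use the full
#'   dyadic depth of whatever lattice it is simulated on.
#' @param name optional label.
#' @return Object of class `"ls2w_process"`.
#' @seealso [demo_process()] for ready-made specifications,
#'   [simulate.ls2w_process()], [local_autocov()].
#' @export
ls2w_process <- function(m, transfer, coherence = NULL, J = NA, name = NULL) {
  stopifnot(m >= 1, is.function(transfer))
  if (m > 1 && is.null(coherence))
    coherence <- function(p, q, eta, z1, z2) 0
  structure(list(m = as.integer(m), transfer = transfer,
                 coherence = coherence, J = J, name = name),
            class = "ls2w_process")
}

#' @export
print.ls2w_process <- function(x, ...) {
  cat("LS2Wmv process specification",
      if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  channels:", x$m, " scales:",
      if (is.na(x$J)) "full dyadic depth" else x$J, "\n")
  invisible(x)
}

#' Built-in process specifications
#'
#' Trivariate processes with spectra and coherence surfaces used throughout
#' the package's simulation studies:
#' \describe{
#'   \item{`coherence_demo`}{auto-spectra constant at 2 for every
#'     scale-direction; `rho^{1,2} = 0.2` everywhere; `rho^{2,3}` a linear
#'     ramp from 0 to 0.8 along the horizontal axis.}
#'   \item{`P1`}{auto-spectra 2 everywhere; `rho^{1,2} = 0.2`,
#'     `rho^{2,3} = 0.4` everywhere.}
#'   \item{`P2`}{as `P1` but `rho^{2,3} = +0.4` on the left half of the image
#'     and `-0.4` on the right half.}
#'   \item{`P3`}{coherence as `P2`; auto-spectra ramp linearly from 0 to 0.8
#'     along the same axis at every scale-direction.}
#' }
#'
#' @param name one of `"coherence_demo"`, `"P1"`, `"P2"`, `"P3"`.
#' @param ramp_axis axis along which the nonstationary surfaces vary:
#'   `"horizontal"` (columns, the default) or `"vertical"` (rows).
#' @return An [ls2w_process()] specification.
#' @export
demo_process <- function(name = c("coherence_demo", "P1", "P2", "P3"),
                         ramp_axis = c("horizontal", "vertical")) {
  name <- match.arg(name)
  ramp_axis <- match.arg(ramp_axis)
  ax <- function(z1, z2) if (ramp_axis == "horizontal") z2 else z1
  W_const <- function(i, eta, z1, z2) sqrt(2) + 0 * z1
  rho23_split <- function(z1, z2) ifelse(ax(z1, z2) < 0.5, 0.4, -0.4)
  coh <- switch(name,
    coherence_demo = function(p, q, eta, z1, z2) {
      if (p == 1 && q == 2) 0.2 + 0 * z1
      else if (p == 2 && q == 3) 0.8 * ax(z1, z2)
      else 0 * z1
    },
    P1 = function(p, q, eta, z1, z2) {
      if (p == 1 && q == 2) 0.2 + 0 * z1
      else if (p == 2 && q == 3) 0.4 + 0 * z1
      else 0 * z1
    },
    function(p, q, eta, z1, z2) {   # P2, P3
      if (p == 1 && q == 2) 0.2 + 0 * z1
      else if (p == 2 && q == 3) rho23_split(z1, z2)
      else 0 * z1
    })
  trans <- if (name == "P3")
    function(i, eta, z1, z2) sqrt(0.8 * ax(z1, z2))
  else W_const
  ls2w_process(m = 3L, transfer = trans, coherence = coh, name = name)
}

# evaluate a surface function on the 0-based rescaled lattice
.lattice_z <- function(R, S) {
  list(z1 = matrix(rep((0:(R - 1)) / R, S), R, S),
       z2 = matrix(rep((0:(S - 1)) / S, each = R), R, S))
}

.eval_surface <- function(f, ..., z1, z2) {
  v <- f(..., z1 = z1, z2 = z2)
  if (length(v) == 1L) v <- matrix(v, nrow(z1), ncol(z1))
  stopifnot(all(is.finite(v)))
  matrix(v, nrow(z1), ncol(z1))
}

# Draw the m-channel increment arrays for one eta: i.i.d. over locations,
# standard Gaussian marginals, cross-channel correlation rho(z) at each
# location, applied through the symmetric square root of the coherence matrix.
.draw_increments <- function(spec, eta, z) {
  m <- spec$m
  npix <- length(z$z1)
  Z <- matrix(stats::rnorm(npix * m), npix, m)
  if (m == 1L) return(Z)
  pairs <- which(upper.tri(diag(m)), arr.ind = TRUE)
  C <- vapply(seq_len(nrow(pairs)), function(k)
    as.vector(.eval_surface(spec$coherence, pairs[k, 1], pairs[k, 2], eta,
                            z1 = z$z1, z2 = z$z2)),
    numeric(npix))
  C <- matrix(C, npix)
  key <- do.call(paste, c(lapply(seq_len(ncol(C)), function(k) C[, k]),
                          sep = ","))
  for (k in unique(key)) {
    idx <- which(key == k)
    Cm <- diag(m)
    Cm[upper.tri(Cm)] <- C[idx[1L], ]
    Cm[lower.tri(Cm)] <- t(Cm)[lower.tri(Cm)]
    ev <- eigen(Cm, symmetric = TRUE)
    if (min(ev$values) < -1e-10) {
      u <- arrayInd(idx[1L], dim(z$z1))
      stop("coherence matrix not positive semi-definite at eta = ", eta,
           ", location (", u[1] - 1L, ", ", u[2] - 1L, ")")
    }
    sq <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    Z[idx, ] <- Z[idx, , drop = FALSE] %*% sq
  }
  Z
}

#' Simulate an LS2Wmv process
#'
#' Generates realisations of the process on an `R x S` dyadic lattice: for
#' each scale-direction `eta`, a lattice of correlated Gaussian increments is
#' modulated by the transfer functions and circularly convolved with the
#' discrete 2D wavelet; channels are the sum over `eta`.
#'
#' @param object an [ls2w_process()].
#' @param nsim number of independent realisations.
#' @param seed optional integer seed (realisations are reproducible given the
#'   seed).
#' @param dim lattice dimensions `c(R, S)`, powers of two.
#' @param filter an [ls2w_filter()].
#' @param ... unused.
#' @return For `nsim = 1`, an `"ls2w_field"`: an `R x S x m` array. Otherwise
#'   a list of such fields.
#' @examples
#' x <- simulate(demo_process("P1"), seed = 1, dim = c(64, 64))
#' dim(x)
#' @export
simulate.ls2w_process <- function(object, nsim = 1, seed = NULL,
                                  dim = c(256, 256),
                                  filter = ls2w_filter("haar"), ...) {
  R <- as.integer(dim[1]); S <- as.integer(dim[2])
  J <- if (is.na(object$J)) floor(log2(min(R, S))) else as.integer(object$J)
  .check_field_dims(R, S, J)
  if (!is.null(seed)) set.seed(as.integer(seed))
  kernels <- .ndwt_kernels(R, S, J, filter)
  z <- .lattice_z(R, S)
  W <- lapply(seq_len(3L * J), function(eta)
    lapply(seq_len(object$m), function(i)
      .eval_surface(object$transfer, i, eta, z1 = z$z1, z2 = z$z2)))
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    X <- array(0, c(R, S, object$m))
    for (eta in seq_len(3L * J)) {
      Z <- .draw_increments(object, eta, z)
      for (i in seq_len(object$m)) {
        Y <- W[[eta]][[i]] * matrix(Z[, i], R, S)
        # X_r = sum_u Y_u psi_eta(u - r): cross-correlation with the kernel
        X[, , i] <- X[, , i] +
          Re(stats::fft(stats::fft(Y) * Conj(kernels[[eta]]),
                        inverse = TRUE)) / (R * S)
      }
    }
    out[[r]] <- ls2w_field(X, process = object$name, seed = seed)
  }
  if (nsim == 1L) out[[1L]] else out
}

#' Multichannel field container
#'
#' @param x numeric `R x S x m` array (or a matrix, treated as one channel).
#' @param process,seed optional provenance recorded as attributes.
#' @return Object of class `"ls2w_field"`.
#' @export
ls2w_field <- function(x, process = NULL, seed = NULL) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L, all(is.finite(x)))
  structure(x, process = process, seed = seed, class = "ls2w_field")
}

#' @export
print.ls2w_field <- function(x, ...) {
  d <- dim(x)
  cat("Multichannel field: ", d[3], " channel(s), ", d[1], " x ", d[2], sep = "")
  if (!is.null(attr(x, "process"))) cat(", process", attr(x, "process"))
  cat("\n")
  invisible(x)
}

#' @export
plot.ls2w_field <- function(x, channel = 1, ...) {
  graphics::image(t(x[rev(seq_len(nrow(x))), , channel]),
                  col = grDevices::gray.colors(128), axes = FALSE,
                  main = paste("channel", channel), ...)
  invisible(x)
}

#' Model local (cross-)covariance
#'
#' The local covariance between channels implied by a process specification,
#' `c^{(p,q)}(z, tau) = sum_eta S_eta^{p,q}(z) Psi_eta(tau)` with
#' `S_eta^{p,q}(z) = W_eta^{(p)}(z) W_eta^{(q)}(z) rho_eta^{p,q}(z)` (and
#' `rho^{p,p} = 1`). Serves as the analytic oracle for simulated fields.
#'
#' @param spec an [ls2w_process()].
#' @param z rescaled location, numeric length 2 in `(0, 1)^2`.
#' @param tau integer lag pair.
#' @param J scales to sum over (required if the spec leaves `J` open).
#' @param filter an [ls2w_filter()].
#' @return The `m x m` matrix of local cross-covariances at `(z, tau)`.
#' @export
local_autocov <- function(spec, z, tau, J = spec$J,
                          filter = ls2w_filter("haar")) {
  stopifnot(inherits(spec, "ls2w_process"), length(z) == 2, length(tau) == 2)
  if (is.na(J)) stop("spec has no fixed J; supply one")
  J <- as.integer(J)
  lev <- eta_levels(J)
  m <- spec$m
  z1 <- matrix(z[1]); z2 <- matrix(z[2])
  out <- matrix(0, m, m)
  for (e in seq_len(3L * J)) {
    P <- acw(lev$j[e], lev$direction[e], filter)
    zero <- attr(P, "zero")
    i1 <- zero + tau[1]; i2 <- zero + tau[2]
    Pt <- if (i1 >= 1 && i1 <= nrow(P) && i2 >= 1 && i2 <= ncol(P))
      P[i1, i2] else 0
    if (Pt == 0) next
    Wv <- vapply(seq_len(m), function(i)
      .eval_surface(spec$transfer, i, e, z1 = z1, z2 = z2)[1], numeric(1))
    for (p in seq_len(m)) for (q in p:m) {
      rho <- if (p == q) 1 else
        .eval_surface(spec$coherence, p, q, e, z1 = z1, z2 = z2)[1]
      out[p, q] <- out[p, q] + Wv[p] * Wv[q] * rho * Pt
      out[q, p] <- out[p, q]
    }
  }
  out
}
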