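# Texture feature vectors from spectral fits.

#' Colour-texture feature vector
#'
#' Summarises a trivariate spectral fit into the classification feature
#' vector: for each scale-direction pair `eta` the location averages of the
#' three auto-spectra, the three cross-spectra and the three coherences, in
#' the fixed order `S11, S22, S33, S12, S13, S23, rho12, rho13, rho23`.
#' Length `9 * 3J`.
#'
#' @param fit an [mvlws()] fit of a three-channel field.
#' @param abs_coherence average `|rho|` instead of signed coherence.
#' @return Named numeric vector of length `9 * 3J`.
#' @export
lws_features <- function(fit, abs_coherence = FALSE) {
  stopifnot(inherits(fit, "mvlws"))
  if (fit$m != 3L)
    stop("the feature vector is defined for three-channel fields (got m = ",
         fit$m, ")")
  nEta <- 3L * fit$J
  ord <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  out <- numeric(0)
  for (e in seq_len(nEta)) {
    s <- vapply(seq_len(nrow(ord)), function(k)
      mean(lws_spectrum(fit, ord[k, 1], ord[k, 2], e)), numeric(1))
    r <- vapply(seq_len(nrow(fit$cpairs)), function(k) {
      pl <- fit$rho[, , e, k]
      mean(if (abs_coherence) abs(pl) else pl)
    }, numeric(1))
    names(s) <- paste0("S", ord[, 1], ord[, 2], ".e", e)
    names(r) <- paste0("rho", fit$cpairs[, 1], fit$cpairs[, 2], ".e", e)
    out <- c(out, s, r)
  }
  out
}

#' @export
#' @rdname lws_features
#' @param object an `mvlws` fit.
#' @param ... passed to `lws_features`.
coef.mvlws <- function(object, ...) {
  if (object$m == 3L) lws_features(object, ...) else {
    auto <- which(object$pairs[, 1] == object$pairs[, 2])
    vapply(auto, function(k) mean(object$S[, , , k]), numeric(1))
  }
}
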