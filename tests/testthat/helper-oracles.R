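# Independent brute-force oracles, deliberately naive (double loops, direct
# lag sums) so they share no code path with the package internals.

# periodic convolution d[u] = sum_r x[r] psi(u - r), psi anchored at offset 0
direct_ndwt_plane <- function(x, psi) {
  R <- nrow(x); S <- ncol(x)
  d <- matrix(0, R, S)
  for (u1 in 0:(R - 1)) for (u2 in 0:(S - 1)) {
    acc <- 0
    for (t1 in 0:(nrow(psi) - 1)) for (t2 in 0:(ncol(psi) - 1)) {
      r1 <- (u1 - t1) %% R
      r2 <- (u2 - t2) %% S
      acc <- acc + x[r1 + 1, r2 + 1] * psi[t1 + 1, t2 + 1]
    }
    d[u1 + 1, u2 + 1] <- acc
  }
  d
}

# Psi(tau) = sum_v psi(v) psi(v + tau) by direct summation over a padded grid
brute_acw <- function(psi) {
  L1 <- nrow(psi); L2 <- ncol(psi)
  out <- matrix(0, 2 * L1 - 1, 2 * L2 - 1)
  for (t1 in -(L1 - 1):(L1 - 1)) for (t2 in -(L2 - 1):(L2 - 1)) {
    acc <- 0
    for (v1 in 1:L1) for (v2 in 1:L2) {
      w1 <- v1 + t1; w2 <- v2 + t2
      if (w1 >= 1 && w1 <= L1 && w2 >= 1 && w2 <= L2)
        acc <- acc + psi[v1, v2] * psi[w1, w2]
    }
    out[t1 + L1, t2 + L2] <- acc
  }
  structure(out, zero = c(L1, L2))
}

# A[eta, eta1] = sum_tau Psi_eta(tau) Psi_eta1(tau), aligning on lag 0
brute_ipm <- function(J, filter) {
  lev <- eta_levels(J)
  Psis <- lapply(seq_len(3 * J), function(e)
    brute_acw(ndw_wavelet(lev$j[e], lev$direction[e], filter)))
  A <- matrix(0, 3 * J, 3 * J)
  for (a in seq_len(3 * J)) for (b in seq_len(3 * J)) {
    Pa <- Psis[[a]]; Pb <- Psis[[b]]
    za <- attr(Pa, "zero"); zb <- attr(Pb, "zero")
    acc <- 0
    for (t1 in max(1 - za[1], 1 - zb[1]):min(nrow(Pa) - za[1], nrow(Pb) - zb[1]))
      for (t2 in max(1 - za[2], 1 - zb[2]):min(ncol(Pa) - za[2], ncol(Pb) - zb[2]))
        acc <- acc + Pa[t1 + za[1], t2 + za[2]] * Pb[t1 + zb[1], t2 + zb[2]]
    A[a, b] <- acc
  }
  A
}

# stationary trivariate spec with flat spectra 2 and fixed coherences
flat_trivariate <- function(J = NA, rho12 = 0.2, rho23 = 0.4) {
  ls2w_process(3,
    transfer = function(i, eta, z1, z2) sqrt(2) + 0 * z1,
    coherence = function(p, q, eta, z1, z2) {
      if (p == 1 && q == 2) rho12 + 0 * z1
      else if (p == 2 && q == 3) rho23 + 0 * z1
      else 0 * z1
    },
    J = J, name = "flat_trivariate")
}
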