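haar <- ls2w_filter("haar")
db2 <- ls2w_filter("daubechies", 2)

test_that("scale-direction indexing is a bijection", {
  lev <- eta_levels(3)
  expect_equal(lev$eta, 1:9)
  expect_equal(eta_index(2, "h", 3), 5)
  expect_equal(eta_index(1, "v", 3), 1)
  for (e in lev$eta)
    expect_equal(eta_index(lev$j[e], lev$direction[e], 3), e)
})

test_that("Haar 2D wavelets at the finest scale", {
  d1 <- ndw_wavelet(1, "d", haar)
  expect_equal(d1, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  v1 <- ndw_wavelet(1, "v", haar)
  expect_equal(sum(v1), 0)                 # detail direction sums to zero
  expect_equal(sum(v1^2), 1)
})

test_that("discrete wavelets have the expected support and unit energy", {
  for (f in list(haar, db2)) for (j in 1:4) for (dir in c("v", "h", "d")) {
    w <- ndw_wavelet(j, dir, f)
    L <- (2^j - 1) * (length(f$lo) - 1) + 1
    expect_equal(dim(w), c(L, L))
    expect_equal(sum(w^2), 1, tolerance = 1e-12)
    if (dir != "d") expect_equal(sum(w), 0, tolerance = 1e-10)
  }
})

test_that("autocorrelation wavelets are unit at lag zero, even, and match brute force", {
  for (f in list(haar, db2)) for (j in 1:2) for (dir in c("v", "h", "d")) {
    P <- acw(j, dir, f)
    z <- attr(P, "zero")
    expect_equal(P[z, z], 1, tolerance = 1e-12)
    expect_equal(unclass(P), P[rev(seq_len(nrow(P))), rev(seq_len(ncol(P)))],
                 ignore_attr = TRUE, tolerance = 1e-12)
    B <- brute_acw(ndw_wavelet(j, dir, f))
    expect_equal(unclass(P), unclass(B), ignore_attr = TRUE,
                 tolerance = 1e-10)
  }
})

test_that("the 1D Haar autocorrelation factor takes value -1/2 at lag 1", {
  P <- acw(1, "v", haar)    # rows = mother factor, cols = father factor
  z <- attr(P, "zero")
  expect_equal(P[z + 1, z], -0.5)   # mother lag 1 x father lag 0
  expect_equal(P[z - 1, z], -0.5)
})

test_that("inner-product matrix reproduces brute-force Haar values at J = 1", {
  ip <- ipm(1, haar)
  expect_equal(ip$A[1, 1], 2.25)    # vertical-vertical: 1.5 * 1.5
  expect_equal(ip$A[1, 2], 0.25)    # vertical-horizontal: 0.5^2
  expect_equal(ip$A, t(ip$A))
})

test_that("factorised inner products equal 2D brute force for Haar and Daubechies-2", {
  for (f in list(haar, db2)) for (J in 1:3)
    expect_equal(ipm(J, f)$A, brute_ipm(J, f), tolerance = 1e-10)
})

test_that("diagonal of A equals the energy of the autocorrelation wavelet", {
  J <- 3
  ip <- ipm(J, db2)
  lev <- eta_levels(J)
  for (e in lev$eta) {
    P <- acw(lev$j[e], lev$direction[e], db2)
    expect_equal(sum(P^2), ip$A[e, e], tolerance = 1e-10)
  }
})

test_that("A_J is invertible up to J = 7", {
  for (J in c(4, 7)) {
    ip <- ipm(J, haar)
    expect_lt(max(abs(ip$A %*% ip$Ainv - diag(3 * J))), 1e-8)
  }
})
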