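haar <- ls2w_filter("haar")

test_that("built-in process specifications take the documented values", {
  z1 <- matrix(0.3); zl <- matrix(0.2); zr <- matrix(199 / 256)
  p1 <- demo_process("P1")
  expect_equal(p1$coherence(2, 3, 1, z1, z1)[1], 0.4)
  expect_equal(p1$coherence(1, 2, 5, z1, z1)[1], 0.2)
  p2 <- demo_process("P2")
  expect_equal(p2$coherence(2, 3, 1, z1, zl)[1], 0.4)
  expect_equal(p2$coherence(2, 3, 1, z1, zr)[1], -0.4)  # column 200 of 256
  cd <- demo_process("coherence_demo")
  expect_equal(cd$coherence(2, 3, 1, z1, matrix(255 / 256))[1], 0.8,
               tolerance = 0.01)
  expect_equal(cd$coherence(1, 3, 1, z1, z1)[1], 0)
  p3 <- demo_process("P3")
  expect_equal(p3$transfer(1, 1, z1, matrix(0.5))[1]^2, 0.4)  # spectrum ramp
  expect_error(demo_process("P9"))
})

test_that("zero transfer functions give a zero field", {
  sp <- ls2w_process(2, transfer = function(i, eta, z1, z2) 0 * z1, J = 2)
  x <- simulate(sp, seed = 1, dim = c(32, 32))
  expect_true(all(x == 0))
})

test_that("simulation is deterministic given the seed", {
  sp <- flat_trivariate(J = 3)
  a <- simulate(sp, seed = 7, dim = c(32, 32))
  b <- simulate(sp, seed = 7, dim = c(32, 32))
  cc <- simulate(sp, seed = 8, dim = c(32, 32))
  expect_identical(unclass(a), unclass(b))
  expect_gt(max(abs(a - cc)), 0)
})

test_that("field variance matches the flat-spectrum model value", {
  sp <- ls2w_process(1, transfer = function(i, eta, z1, z2) sqrt(2) + 0 * z1,
                     J = 2)
  v <- mean(vapply(1:8, function(k)
    stats::var(as.vector(simulate(sp, seed = 40 + k, dim = c(64, 64)))),
    numeric(1)))
  expect_equal(v, 2 * 3 * 2, tolerance = 0.1)   # sum_eta S_eta Psi_eta(0)
})

test_that("channel means are near zero", {
  x <- simulate(flat_trivariate(J = 3), seed = 2, dim = c(64, 64))
  sdev <- sd(as.vector(x))
  for (i in 1:3) expect_lt(abs(mean(x[, , i])), sdev)
})

test_that("cross-channel correlation at a fixed pixel matches the coherence", {
  sp <- flat_trivariate(J = 2, rho12 = 0.2, rho23 = 0.4)
  reps <- vapply(1:200, function(k) {
    x <- simulate(sp, seed = 1000 + k, dim = c(16, 16))
    x[5, 5, ]
  }, numeric(3))
  # flat spectra: corr(X^(p), X^(q)) = rho^{p,q} exactly
  expect_equal(cor(reps[1, ], reps[2, ]), 0.2, tolerance = 3 / sqrt(200))
  expect_equal(cor(reps[2, ], reps[3, ]), 0.4, tolerance = 3 / sqrt(200))
  expect_equal(cor(reps[1, ], reps[3, ]), 0.0, tolerance = 3 / sqrt(200))
})

test_that("non-positive-semidefinite coherence is rejected with location info", {
  sp <- ls2w_process(3, transfer = function(i, eta, z1, z2) 1 + 0 * z1,
                     coherence = function(p, q, eta, z1, z2)
                       if (q - p == 1) 0.9 + 0 * z1 else 0 * z1,
                     J = 1)
  expect_error(simulate(sp, seed = 1, dim = c(16, 16)),
               "positive semi-definite at eta = 1")
})

test_that("model cross-covariance follows the spectral representation", {
  sp <- flat_trivariate(J = 2)
  z <- c(0.5, 0.5)
  C0 <- local_autocov(sp, z, c(0, 0))
  expect_equal(C0[1, 1], 2 * 3 * 2)            # sum_eta S_eta, Psi_eta(0) = 1
  expect_equal(C0[1, 2], 0.2 * 2 * 3 * 2)
  expect_equal(C0[1, 3], 0)                    # rho13 = 0 at all lags
  far <- local_autocov(sp, z, c(50, 0))
  expect_equal(far, matrix(0, 3, 3))           # beyond every wavelet support
})

test_that("uncorrelated channels have zero model cross-covariance at all lags", {
  sp <- flat_trivariate(J = 2, rho12 = 0, rho23 = 0)
  for (tau in list(c(0, 0), c(1, 2), c(-3, 1)))
    expect_equal(local_autocov(sp, c(0.25, 0.75), tau)[1, 2], 0)
})
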