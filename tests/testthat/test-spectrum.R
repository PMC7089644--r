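haar <- ls2w_filter("haar")

test_that("raw periodograms are symmetric products, nonnegative on the diagonal", {
  set.seed(3)
  x1 <- matrix(rnorm(256), 16, 16); x2 <- matrix(rnorm(256), 16, 16)
  d1 <- ndwt2(x1, 2, haar); d2 <- ndwt2(x2, 2, haar)
  I11 <- raw_periodogram(d1)
  expect_true(all(vapply(I11, function(p) all(p >= 0), TRUE)))
  I12 <- raw_periodogram(d1, d2); I21 <- raw_periodogram(d2, d1)
  expect_equal(unclass(I12), unclass(I21), ignore_attr = TRUE)
  d3 <- ndwt2(matrix(0, 32, 32), 2, haar)
  expect_error(raw_periodogram(d1, d3), "mismatched")
})

test_that("smoothing is an exact average: constants fixed, tiny uniform h is identity", {
  set.seed(4)
  x <- matrix(rnorm(256), 16, 16)
  I <- raw_periodogram(ndwt2(x, 2, haar))
  cst <- I; for (e in seq_along(cst)) cst[[e]] <- matrix(2.5, 16, 16)
  expect_equal(unclass(smooth_periodogram(cst, "uniform", 3)), unclass(cst),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(smooth_periodogram(I, "uniform", 0.5)), unclass(I),
               ignore_attr = TRUE, tolerance = 1e-12)
  # any kernel preserves the plane total (weights sum to one)
  for (k in c("uniform", "gaussian", "epanechnikov")) {
    sm <- smooth_periodogram(I, k, 2)
    expect_equal(sum(sm[[1]]), sum(I[[1]]), tolerance = 1e-10)
  }
  expect_error(smooth_periodogram(I, "uniform", -1), "positive")
})

test_that("correction inverts the inner-product mixing", {
  set.seed(5)
  x <- matrix(rnorm(1024), 32, 32)
  I <- smooth_periodogram(raw_periodogram(ndwt2(x, 2, haar)), "uniform", 2)
  ip <- ipm(2, haar)
  idmat <- ip; idmat$A <- diag(6); idmat$Ainv <- diag(6)
  expect_equal(unclass(correct_periodogram(I, idmat)), unclass(I),
               ignore_attr = TRUE)
  # A then A^{-1} round-trips
  mixed <- I
  M <- ip$A %*% do.call(rbind, lapply(I, as.vector))
  for (e in seq_along(mixed)) mixed[[e]] <- matrix(M[e, ], 32, 32)
  back <- correct_periodogram(mixed, ip)
  expect_equal(unclass(back), unclass(I), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_error(correct_periodogram(I, ipm(3, haar)), "does not match")
})

test_that("mean raw periodogram follows the A-mixed spectrum and correction unbiases it", {
  sp <- flat_trivariate(J = 2)
  J <- 2; K <- 30
  ip <- ipm(J, haar)
  expected_raw <- as.vector(ip$A %*% rep(2, 3 * J))
  raw_means <- matrix(0, K, 3 * J); cor_means <- matrix(0, K, 3 * J)
  for (k in 1:K) {
    x <- simulate(sp, seed = 600 + k, dim = c(64, 64))
    d <- ndwt2(x[, , 1] - mean(x[, , 1]), J, haar)
    I <- raw_periodogram(d)
    raw_means[k, ] <- vapply(I, mean, 1)
    fit <- mvlws(unclass(x), J = J)
    cor_means[k, ] <- vapply(seq_len(3 * J), function(e)
      mean(lws_spectrum(fit, 1, 1, e)), 1)
  }
  expect_equal(colMeans(raw_means), expected_raw, tolerance = 0.1)
  expect_equal(colMeans(cor_means), rep(2, 3 * J), tolerance = 0.1)
})

test_that("smoothing reduces periodogram variance monotonically in h", {
  sp <- flat_trivariate(J = 2)
  x <- simulate(sp, seed = 77, dim = c(64, 64))
  I <- raw_periodogram(ndwt2(x[, , 1], 2, haar))
  v <- vapply(c(1.5, 4, 8), function(h)
    stats::var(as.vector(smooth_periodogram(I, "uniform", h)[[1]])), 1)
  expect_lt(v[1], stats::var(as.vector(I[[1]])))
  expect_true(all(diff(v) < 0))
})

test_that("coherence of a fitted field is one on the diagonal and bounded", {
  x <- simulate(flat_trivariate(J = 3), seed = 9, dim = c(64, 64))
  fit <- mvlws(unclass(x), J = 3)
  expect_equal(lws_coherence(fit, 2, 2, 1), matrix(1, 64, 64))
  expect_true(all(abs(fit$rho) <= 1))
})

test_that("coherence of independent channels is centred on zero", {
  sp <- flat_trivariate(J = 2, rho12 = 0, rho23 = 0)
  K <- 15
  m12 <- vapply(1:15, function(k) {
    x <- simulate(sp, seed = 700 + k, dim = c(64, 64))
    mean(lws_coherence(mvlws(unclass(x), J = 2), 1, 2, 1))
  }, 1)
  expect_lt(abs(mean(m12)), 3 * stats::sd(m12) / sqrt(K))
})

test_that("the estimate is invariant to channel shifts and permutes with labels", {
  x <- unclass(simulate(flat_trivariate(J = 2), seed = 12, dim = c(32, 32)))
  fit <- mvlws(x, J = 2)
  shifted <- x; shifted[, , 2] <- shifted[, , 2] + 100
  expect_equal(mvlws(shifted, J = 2)$S, fit$S, tolerance = 1e-8)
  perm <- x[, , c(2, 1, 3)]
  pfit <- mvlws(perm, J = 2)
  expect_equal(lws_spectrum(pfit, 1, 1, 3), lws_spectrum(fit, 2, 2, 3))
  expect_equal(lws_coherence(pfit, 1, 3, 2), lws_coherence(fit, 2, 3, 2))
})

test_that("estimated coherence respects the sign split of process P2", {
  x <- simulate(demo_process("P2"), seed = 15, dim = c(128, 128))
  fit <- mvlws(unclass(x), J = 3)
  r <- lws_coherence(fit, 2, 3, 1)
  expect_gt(mean(r[, 1:56]), 0)      # interior of the +0.4 half
  expect_lt(mean(r[, 73:128]), 0)    # interior of the -0.4 half
})
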