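make_clouds <- function(n = 30, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = sep), n, 2))
  list(x = x, y = rep(c("a", "b"), each = n))
}

test_that("separable clouds are classified perfectly", {
  d <- make_clouds()
  clf <- texture_lda(d$x, d$y)
  expect_equal(as.character(predict(clf, d$x)), d$y)
})

test_that("the discriminant direction matches the closed-form Fisher solution", {
  set.seed(2)
  n <- 200
  Sig <- matrix(c(2, 0.6, 0.6, 1), 2)
  Ch <- chol(Sig)
  x <- rbind(matrix(rnorm(2 * n), n, 2) %*% Ch,
             sweep(matrix(rnorm(2 * n), n, 2) %*% Ch, 2, c(2, 1), `+`))
  y <- rep(c("a", "b"), each = n)
  clf <- texture_lda(x, y, shrinkage = 0)
  # closed form in the standardised coordinates the classifier works in
  sdv <- apply(x, 2, sd)
  xs <- sweep(sweep(x, 2, colMeans(x)), 2, sdv, `/`)
  mu <- rbind(colMeans(xs[y == "a", ]), colMeans(xs[y == "b", ]))
  Sw <- (cov(xs[y == "a", ]) * (n - 1) + cov(xs[y == "b", ]) * (n - 1)) /
    (2 * n - 2)
  fisher <- solve(Sw, mu[2, ] - mu[1, ])
  dir <- clf$scaling[, 1]
  cosine <- sum(fisher * dir) / sqrt(sum(fisher^2) * sum(dir^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-8)
})

test_that("predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  d <- make_clouds(n = 40, sep = 2.5, seed = 3)
  grid <- as.matrix(expand.grid(V1 = seq(-2, 5, length = 12),
                                V2 = seq(-2, 5, length = 12)))
  colnames(d$x) <- c("V1", "V2")
  ours <- predict(texture_lda(d$x, d$y, shrinkage = 0), grid)
  theirs <- predict(MASS::lda(d$x, grouping = d$y), grid)$class
  expect_gt(mean(as.character(ours) == as.character(theirs)), 0.98)
})

test_that("degenerate feature sets are handled", {
  d <- make_clouds()
  dup <- cbind(d$x, d$x[, 1])          # duplicated column: singular covariance
  clf <- texture_lda(dup, d$y)
  expect_equal(as.character(predict(clf, dup)), d$y)
  shr <- texture_lda(dup, d$y, shrinkage = 0.3)
  expect_equal(as.character(predict(shr, dup)), d$y)
})

test_that("ties go to the lowest class index and errors are informative", {
  x <- rbind(c(-1, 0), c(-1, 0.5), c(1, 0), c(1, 0.5))
  y <- c("a", "a", "b", "b")
  clf <- texture_lda(x, y)
  expect_equal(as.character(predict(clf, c(0, 0.25))), "a")  # equidistant
  expect_equal(as.character(predict(clf, x[3, ])), "b")      # on a centroid
  expect_error(predict(clf, c(1, 2, 3)), "does not match")
  expect_error(texture_lda(x, c("a", "a", "a", "a")), "two classes")
  expect_error(texture_lda(x, c("a", "a", "b", "c")), "at least two samples")
})
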