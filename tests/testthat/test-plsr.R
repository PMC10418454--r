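test_that("single-factor NIPALS fits a response carried by one direction", {
  set.seed(1)
  # in-sample orthogonal predictors: the first weight is then exactly
  # the informative column and one component reproduces y
  X <- qr.Q(qr(scale(matrix(rnorm(60), 20, 3), scale = FALSE)))
  y <- 2 * X[, 2] + 5
  m <- fitPLSR(X, y, 1)
  expect_equal(predict(m, X), y, tolerance = 1e-8)
})

test_that("NIPALS at full rank equals the least-squares solution", {
  set.seed(2)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  m <- fitPLSR(X, y, 10)
  ols <- qr.solve(cbind(1, X), y)
  expect_equal(coef(m), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(predict(m, X), unname(drop(cbind(1, X) %*% ols)),
    tolerance = 1e-6
  )
})

test_that("compiled NIPALS matches an independent R implementation", {
  set.seed(3)
  X <- matrix(rnorm(150), 30, 5)
  y <- X[, 1] - X[, 3] + rnorm(30, sd = 0.2)
  m <- fitPLSR(X, y, 4)
  o <- rNipals(X, y, 4)
  expect_equal(coef(m), o$beta, tolerance = 1e-10)
  expect_equal(m@intercept, o$intercept, tolerance = 1e-10)
})

test_that("NIPALS scores are orthogonal and reconstruction converges", {
  set.seed(4)
  X <- matrix(rnorm(120), 15, 8)
  y <- rnorm(15)
  m <- fitPLSR(X, y, 8)
  G <- crossprod(m@scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  # T P' reconstructs centered X as A -> rank
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(m@scores %*% t(m@xLoadings), Xc, tolerance = 1e-6)
  # factor-path prediction equals beta-path prediction
  tNew <- Xc %*% m@weights %*% solve(crossprod(m@xLoadings, m@weights))
  expect_equal(
    drop(tNew %*% m@yLoadings) + m@yMean, predict(m, X),
    tolerance = 1e-8
  )
})

test_that("fitting is invariant to sample permutation and y shifts", {
  set.seed(5)
  X <- matrix(rnorm(90), 18, 5)
  y <- rnorm(18)
  m <- fitPLSR(X, y, 3)
  p <- sample(18)
  m2 <- fitPLSR(X[p, ], y[p], 3)
  expect_equal(coef(m2), coef(m), tolerance = 1e-10)
  # adding a constant to y shifts predictions by that constant
  m3 <- fitPLSR(X, y + 11, 3)
  Xnew <- matrix(rnorm(25), 5, 5)
  expect_equal(predict(m3, Xnew), predict(m, Xnew) + 11, tolerance = 1e-8)
  # a sample equal to the training mean predicts the training y mean
  expect_equal(predict(m, rbind(colMeans(X))), mean(y), tolerance = 1e-10)
  expect_error(predict(m, matrix(0, 1, 4)), "columns")
})

test_that("one-component univariate PLSR equals simple linear regression", {
  set.seed(6)
  x <- rnorm(25)
  y <- 3 * x + rnorm(25)
  m <- fitPLSR(cbind(x), y, 1)
  lmfit <- lm(y ~ x)
  expect_equal(coef(m), unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(m@intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
})

test_that("training RMSEC is non-increasing in the component count", {
  set.seed(7)
  X <- matrix(rnorm(300), 30, 10)
  y <- rnorm(30)
  rmsec <- vapply(1:8, function(a) {
    sqrt(mean((predict(fitPLSR(X, y, a), X) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("LOOCV matches a brute-force refit oracle", {
  set.seed(8)
  n <- 22
  X <- matrix(rnorm(n * 12), n, 12)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.3)
  aMax <- 5
  cv <- loocvSelectLV(X, y, aMax)
  oracle <- matrix(NA_real_, n, aMax)
  for (i in seq_len(n)) {
    for (a in seq_len(aMax)) {
      m <- fitPLSR(X[-i, ], y[-i], a)
      oracle[i, a] <- predict(m, X[i, , drop = FALSE])
    }
  }
  rmsecvOracle <- sqrt(colMeans((oracle - y)^2))
  expect_equal(rmsecvCurve(cv), rmsecvOracle, tolerance = 1e-10)
  expect_equal(optimalLV(cv), which.min(rmsecvOracle))
})

test_that("LOOCV prefers one component for a noiseless linear response", {
  set.seed(9)
  X <- matrix(rnorm(80), 20, 4)
  y <- drop(X %*% c(1, 2, 0, 0))
  cv <- loocvSelectLV(X, y, 3)
  # parsimony tie-break: smallest LV count attaining the minimum
  expect_equal(rmsecvCurve(cv)[optimalLV(cv)], min(rmsecvCurve(cv)))
  expect_true(all(rmsecvCurve(cv)[seq_len(optimalLV(cv) - 1)] >
    min(rmsecvCurve(cv))))
})

test_that("LOOCV on pure noise shows no spurious predictivity", {
  set.seed(99)
  X <- matrix(rnorm(50 * 30), 50, 30)
  y <- rnorm(50)
  cv <- loocvSelectLV(X, y, 8)
  expect_lt(abs(cv@rCv), 0.4)
  # more components only overfit: curve roughly non-decreasing
  expect_gt(rmsecvCurve(cv)[8], rmsecvCurve(cv)[1] * 0.9)
})

test_that("rank deficiency truncates the curve with a warning", {
  # one informative direction only: component 2 has nothing left
  set.seed(10)
  x <- rnorm(12)
  X <- cbind(x, 2 * x)
  y <- 3 * x
  expect_warning(cv <- loocvSelectLV(X, y, 2), "truncated")
  expect_equal(length(rmsecvCurve(cv)), 1L)
  expect_error(fitPLSR(X, y, 2), "rank|component")
})
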