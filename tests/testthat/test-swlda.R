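test_that("OLS p-values agree with the normal-equations oracle and lm", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(30:80, 1); p <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * p), n))
    y <- rnorm(n) + X %*% runif(p + 1, -1, 1)
    a <- olsCoefPValues(X, y)
    b <- naiveOlsPValues(X, y)
    expect_equal(a$p, b$p, tolerance = 1e-10)
    expect_equal(a$coef, b$coef, tolerance = 1e-10)
  }
})

test_that("stepwise selection matches an independent stepwise oracle", {
  set.seed(202)
  for (i in 1:50) {
    n <- sample(40:120, 1); p <- sample(4:10, 1)
    y <- rep(c(TRUE, FALSE), length.out = n)
    X <- matrix(rnorm(n * p), n)
    # plant signal in a random subset of columns
    sig <- sample(p, sample(0:3, 1))
    for (j in sig) X[, j] <- X[, j] + ifelse(y, 1, -1) * runif(1, 0.2, 1)
    got <- suppressWarnings(swldaFit(X, y))
    want <- naiveStepwise(X, y)
    expect_equal(selectedFeatures(got), as.integer(want$selected))
    expect_equal(modelWeights(got), want$weights, tolerance = 1e-9)
    expect_equal(modelIntercept(got), want$intercept, tolerance = 1e-9)
  }
})

test_that("a perfect predictor is selected first", {
  set.seed(303)
  y <- rep(c(TRUE, FALSE), 30)
  X <- matrix(rnorm(60 * 8), 60)
  X[, 5] <- ifelse(y, 1, -1)      # exactly the coded label
  m <- swldaFit(X, y)
  expect_equal(selectedFeatures(m)[1], 5L)
})

test_that("under a pure-noise null few features survive", {
  set.seed(404)
  sizes <- integer(200)
  for (i in 1:200) {
    y <- rep(c(TRUE, FALSE), length.out = 500)
    X <- matrix(rnorm(500 * 16), 500)
    m <- suppressWarnings(swldaFit(X, y))
    sizes[i] <- length(selectedFeatures(m))
  }
  expect_lt(mean(sizes), 4)
})

test_that("retained features all satisfy the removal criterion on refit", {
  set.seed(505)
  for (i in 1:10) {
    n <- 200
    y <- rep(c(TRUE, FALSE), length.out = n)
    X <- matrix(rnorm(n * 16), n)
    X[, 1:3] <- X[, 1:3] + ifelse(y, 0.4, -0.4)
    m <- suppressWarnings(swldaFit(X, y))
    sel <- selectedFeatures(m)
    if (!length(sel)) next
    refit <- olsCoefPValues(cbind(1, X[, sel, drop = FALSE]),
                            ifelse(y, 1, -1))
    expect_true(all(refit$p[-1] <= 0.15))
  }
})

test_that("duplicated collinear features are skipped, not fatal", {
  set.seed(606)
  y <- rep(c(TRUE, FALSE), 50)
  X <- matrix(rnorm(100 * 6), 100)
  X[, 2] <- X[, 2] + ifelse(y, 1, -1)
  X <- cbind(X, X[, 2])            # exact duplicate of an informative column
  m <- swldaFit(X, y)
  expect_true(all(is.finite(modelWeights(m))))
  expect_lte(sum(selectedFeatures(m) %in% c(2L, 7L)), 1)
})

test_that("identical inputs give identical selections (determinism)", {
  set.seed(707)
  y <- rep(c(TRUE, FALSE), 100)
  X <- matrix(rnorm(200 * 16), 200)
  X[, 4] <- X[, 4] + ifelse(y, 0.5, -0.5)
  m1 <- swldaFit(X, y); m2 <- swldaFit(X, y)
  expect_identical(selectedFeatures(m1), selectedFeatures(m2))
  expect_identical(modelWeights(m1), modelWeights(m2))
})

test_that("separable two-cluster data is classified perfectly at resubstitution", {
  set.seed(808)
  y <- rep(c(TRUE, FALSE), each = 50)
  X <- matrix(rnorm(100 * 4, sd = 0.1), 100)
  X[y, 1] <- X[y, 1] + 5
  m <- swldaFit(X, y)
  sc <- swldaScore(m, X)
  expect_equal(sc > mean(sc), y)
})

test_that("scoring is affine and degenerate models score constant", {
  m <- new("SWLDAModel", selected = c(2L, 4L), weights = c(1.5, -0.5),
           intercept = 0.25, config = list(), trainingMeta = list())
  x <- c(1, 2, 3, 4)
  expect_equal(swldaScore(m, x), 0.25 + 2 * 1.5 - 4 * 0.5)
  a <- 3
  expect_equal(swldaScore(m, a * x) - 0.25, a * (swldaScore(m, x) - 0.25))
  m0 <- new("SWLDAModel", selected = integer(0), weights = numeric(0),
            intercept = 0.7, config = list(), trainingMeta = list())
  expect_equal(swldaScore(m0, matrix(rnorm(32), 2)), c(0.7, 0.7))
})

test_that("single-class input and bad thresholds are rejected", {
  X <- matrix(rnorm(200), 50)
  expect_error(swldaFit(X, rep(TRUE, 50)), "both classes")
  expect_error(swldaFit(X, rep(c(TRUE, FALSE), 25), pEnter = 0.2,
                        pRemove = 0.1))
})

test_that("target decision walks the score ranking through the candidate set", {
  sc <- c(`1` = 2.0, `2` = 3.0, `3` = 1.0, `4` = 0.5, `5` = 0.0)
  # bird (2) wins but is not a candidate -> duck (next rank)
  expect_equal(decideTarget(sc, c(1, 3, 5)), 1L)
  expect_equal(decideTarget(sc, 1:5), 2L)     # plain argmax
  sc2 <- c(`1` = 1, `2` = 5, `3` = 4.9, `4` = 4.8, `5` = 0)
  expect_equal(decideTarget(sc2, c(1, 3, 5)), 3L)
  # ties resolve to the lower label
  expect_equal(decideTarget(c(`1` = 1, `2` = 1, `3` = 0), 1:3), 1L)
  expect_error(decideTarget(sc[1:2], c(4, 5)), "candidate")
})

test_that("models survive a JSON round trip", {
  set.seed(909)
  y <- rep(c(TRUE, FALSE), 60)
  X <- matrix(rnorm(120 * 16), 120)
  X[, 3] <- X[, 3] + ifelse(y, 0.8, -0.8)
  m <- swldaFit(X, y)
  f <- tempfile(fileext = ".json")
  writeSwldaModel(m, f)
  m2 <- readSwldaModel(f)
  expect_identical(selectedFeatures(m2), selectedFeatures(m))
  expect_equal(modelWeights(m2), modelWeights(m))
  expect_equal(modelIntercept(m2), modelIntercept(m))
  expect_equal(swldaScore(m2, X), swldaScore(m, X))
})
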