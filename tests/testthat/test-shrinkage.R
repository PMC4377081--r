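test_that("sigmaSqR is RSS/(n - r) and scales quadratically", {
  D <- toyDesign(12, 6, seed = 71)
  E <- eigenDecompose(D)
  a <- pcrCoefficients(E, D@y)
  r <- 2L
  Zr <- E@Z[, 1:r, drop = FALSE]
  s2 <- sigmaSqR(D@y, Zr, a[1:r], D@n)
  ols <- lm.fit(Zr, D@y)                       # independent LS oracle
  expect_equal(s2, sum(ols$residuals^2) / (D@n - r), tolerance = 1e-10)
  expect_equal(sigmaSqR(3 * D@y, Zr, 3 * a[1:r], D@n), 9 * s2, tolerance = 1e-10)
  # response inside the span of the scores has zero residual variance
  expect_equal(sigmaSqR(drop(Zr %*% c(1, -2)), Zr, c(1, -2), D@n), 0)
  expect_error(sigmaSqR(D@y[1:2], Zr[1:2, ], a[1:r], 2L), "smaller than n")
})

test_that("k_r formulas obey their closed forms and homogeneity", {
  expect_equal(kRLinear(c(1, 1), sigma2 = 2, r = 2L), 2)
  expect_equal(kRLinear(c(2, 2), sigma2 = 2, r = 2L),
               kRLinear(c(1, 1), 2, 2L) / 4)
  expect_error(kRLinear(c(0, 0), 1, 2L), "zero")
  expect_equal(kRLogistic(2, r = 1L), 0.25)
  expect_equal(kRLogistic(c(3, 3, 3) * 2, 3L), kRLogistic(c(3, 3, 3), 3L) / 4)
  expect_error(kRLogistic(c(0, 0), 2L), "zero")
})

test_that("k_HKB matches independent OLS and the r = p identity", {
  D <- toyDesign(30, 5, seed = 81)
  k <- kHKB(D, D@y)
  ols <- lm.fit(D@X, D@y)
  s2 <- sum(ols$residuals^2) / (30 - 5)
  expect_equal(k, 5 * s2 / sum(ols$coefficients^2), tolerance = 1e-10)
  # algebraic identity: k_r at r = p equals k_HKB (rotation invariance)
  E <- eigenDecompose(D)
  a <- pcrCoefficients(E, D@y)
  s2p <- sigmaSqR(D@y, E@Z, a, D@n)
  expect_equal(kRLinear(a, s2p, E@t), k, tolerance = 1e-10)
  # not defined for p >= n
  Dwide <- toyDesign(5, 10, seed = 82)
  expect_error(kHKB(Dwide, Dwide@y), "not defined")
})

test_that("ridge degrees of freedom match explicit hat-matrix traces", {
  expect_equal(dfRidgeLinear(1, 1), list(model = 0.5, variance = 0.25))
  D <- toyDesign(8, 4, seed = 91)
  E <- eigenDecompose(D)
  expect_equal(unlist(dfRidgeLinear(E@lambdas, 0)), c(model = E@t, variance = E@t),
               tolerance = 1e-10)
  k <- 0.7
  H <- D@X %*% solve(crossprod(D@X) + k * diag(D@p)) %*% t(D@X)  # oracle
  df <- dfRidgeLinear(E@lambdas, k)
  expect_equal(df$model, sum(diag(H)), tolerance = 1e-8)
  expect_equal(df$variance, sum(diag(H %*% t(H))), tolerance = 1e-8)
})

test_that("df is strictly decreasing in k with variance below model df", {
  D <- toyDesign(10, 20, seed = 92)
  E <- eigenDecompose(D)
  ks <- c(0.01, 0.1, 1, 10, 100)
  dfm <- sapply(ks, function(k) dfRidgeLinear(E@lambdas, k)$model)
  dfv <- sapply(ks, function(k) dfRidgeLinear(E@lambdas, k)$variance)
  expect_true(all(diff(dfm) < 0) && all(diff(dfv) < 0))
  expect_true(all(dfv < dfm))
})

test_that("logistic df reduces to the closed form under constant weights", {
  D <- toyDesign(10, 4, seed = 93, family = "logistic")
  E <- eigenDecompose(D)
  k <- 0.8
  got <- dfRidgeLogistic(D, beta = numeric(4), intercept = 0, k = k)
  lamW <- E@lambdas / 4                       # W = I/4 at beta = 0
  expect_equal(got, sum((lamW / (lamW + 2 * k))^2), tolerance = 1e-10)
  expect_lt(dfRidgeLogistic(D, numeric(4), 0, 1e8), 1e-10)
})

test_that("logistic df matches the explicitly assembled hat matrix", {
  D <- toyDesign(10, 4, seed = 94, family = "logistic")
  k <- 0.5
  fit <- fitRidgeLogisticCLG(D, D@y, k, opts = clgControl(tol = 1e-10))
  beta <- fit@diagnostics$betaStd
  b0 <- fit@diagnostics$interceptStd
  got <- dfRidgeLogistic(D, beta, b0, k)
  phat <- plogis(b0 + drop(D@X %*% beta))
  W <- diag(phat * (1 - phat))
  H <- sqrt(W) %*% D@X %*%
    solve(crossprod(D@X, W %*% D@X) + 2 * k * diag(4)) %*%
    t(D@X) %*% sqrt(W)                        # oracle: explicit p x p route
  expect_equal(got, sum(diag(H %*% H)), tolerance = 1e-8)
})

test_that("findKForDf inverts the forward degrees-of-freedom map", {
  expect_equal(findKForDf(1, 0.25), 1, tolerance = 1e-6)
  set.seed(95)
  lam <- sort(rexp(12, 0.2), decreasing = TRUE)
  for (target in c(0.5, 2.5, 10)) {
    k <- findKForDf(lam, target)
    expect_lt(abs(dfRidgeLinear(lam, k)$variance - target), 1e-8)
  }
  # target close to t requires k close to 0
  expect_lt(findKForDf(lam, length(lam) - 1e-6), 1e-6)
  expect_error(findKForDf(lam, 12), "strictly between")
})

test_that("linear selection agrees with a brute-force scan", {
  D <- toyDesign(30, 10, seed = 101)
  E <- eigenDecompose(D)
  S <- selectRLinear(E, D@y)
  a <- pcrCoefficients(E, D@y)
  # independent re-derivation of the whole trace
  diffs <- rep(NA_real_, E@t)
  for (r in seq_len(E@t)) {
    Zr <- E@Z[, 1:r, drop = FALSE]
    rss <- sum(lm.fit(Zr, D@y)$residuals^2)
    if (rss <= 1e-8 * sum(D@y^2)) next
    k <- r * (rss / (30 - r)) / sum(a[1:r]^2)
    expect_equal(S@kR[r], k, tolerance = 1e-8)
    diffs[r] <- abs(sum((E@lambdas / (E@lambdas + k))^2) - r)
  }
  expect_equal(S@rHat, which.min(diffs))
  expect_equal(S@kHat, S@kR[S@rHat])
  expect_true(all(S@kR[!is.na(S@kR)] > 0))
  expect_true(all(S@dfR[!is.na(S@dfR)] > 0 & S@dfR[!is.na(S@dfR)] <= E@t))
})

test_that("selection with a single retained component picks r = 1", {
  v <- cbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 1L))
  G <- GenotypeMatrix(v)   # all columns proportional after centring: t = 1
  D <- standardizeGenotypes(G, c(0.3, 1.2, 2.1, 1.1))
  E <- eigenDecompose(D)
  expect_equal(E@t, 1L)
  S <- selectRLinear(E, D@y)
  expect_equal(S@rHat, 1L)
})

test_that("logistic selection matches an independent refit scan", {
  set.seed(111)
  sim <- simulateGwasStudy(p = 20, nTrain = 80, nTest = 20, nCausal = 5,
                           family = "logistic", seed = 112, mafFloor = 0.2, causalMafRange = c(0.2, 0.45),
                           nHap = 400, regionBp = 1e5)
  G <- sim$train$genotypes; y <- sim$train$phenotype
  D <- standardizeGenotypes(G, y, "logistic")
  E <- eigenDecompose(D)
  S <- suppressWarnings(selectRLogistic(E, D, y,
                                        fitOptions = clgControl(tol = 1e-7)))
  # brute-force: refit everything per candidate independently
  diffs <- ks <- rep(NA_real_, length(S@rGrid))
  for (i in seq_along(S@rGrid)) {
    r <- S@rGrid[i]
    p0 <- tryCatch(pclrCoefficients(E, y, r), error = function(e) NULL)
    if (is.null(p0)) next
    k <- r / sum(p0$alpha^2)
    fit <- fitRidgeLogisticCLG(D, y, k, opts = clgControl(tol = 1e-7))
    df <- dfRidgeLogistic(D, fit@diagnostics$betaStd,
                          fit@diagnostics$interceptStd, k)
    ks[i] <- k; diffs[i] <- abs(df - r)
  }
  expect_equal(S@kR, ks[!is.na(ks)], tolerance = 1e-6)
  expect_equal(S@rHat, S@rGrid[which.min(diffs)])
  # a one-point grid returns that point
  S1 <- selectRLogistic(E, D, y, rGrid = 3L)
  expect_equal(S1@rHat, 3L)
})

test_that("shrinkage trace serialises to a readable audit table", {
  D <- toyDesign(20, 6, seed = 121)
  E <- eigenDecompose(D)
  S <- selectRLinear(E, D@y)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeShrinkageTrace(S, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), length(S@rGrid))
  expect_equal(tab$r[tab$selected == 1], S@rHat)
})

test_that("ridge at kHat recovers coefficients better than OLS on orthonormal designs", {
  set.seed(451)
  n <- 40; p <- 8
  wins <- 0
  for (rep in 1:100) {
    Xo <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
    beta <- rnorm(p, sd = 0.7)
    y <- drop(Xo %*% beta) + rnorm(n)
    D <- new("StandardizedDesign", X = Xo, colMeans = numeric(p),
             colScales = rep(1, p), y = y - mean(y), yMean = mean(y),
             family = "linear", n = as.integer(n), p = as.integer(p),
             snpId = paste0("s", 1:p))
    E <- eigenDecompose(D)
    S <- selectRLinear(E, D@y)
    bOLS <- drop(crossprod(Xo, D@y))
    bR <- drop(E@Q %*% (drop(crossprod(E@Z, D@y)) / (E@lambdas + S@kHat)))
    if (sum((bR - beta)^2) < sum((bOLS - beta)^2)) wins <- wins + 1
  }
  expect_gte(wins, 80)
})
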