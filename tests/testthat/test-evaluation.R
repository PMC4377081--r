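test_that("prediction squared error follows its definition", {
  expect_equal(pse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pse(c(0, 0), c(1, 3)), 5)
  expect_error(pse(1:3, 1:2), "mismatch")
  # predicting pure noise by its mean sits at the unit noise floor
  set.seed(221)
  y <- rnorm(1e5)
  expect_lt(abs(pse(y, rep(0, 1e5)) - 1), 3 * sqrt(2 / 1e5))
})

test_that("classification error counts threshold mismatches with >= tie rule", {
  y <- c(0, 0, 1, 1, 1, 0)
  p <- c(0.1, 0.6, 0.8, 0.4, 0.5, 0.2)
  # by hand: calls are 0,1,1,0,1,0 -> mistakes at positions 2 and 4
  expect_equal(classificationError(y, p), 2 / 6)
  expect_equal(classificationError(y, p, tieCase = FALSE), 3 / 6)
  expect_equal(classificationError(y == 1, p), 2 / 6)
  yb <- rep(c(0, 1), 50)
  expect_equal(classificationError(yb, rep(0.5, 100)), 0.5)
  expect_equal(classificationError(y, p * 0 + y), 0)
  expect_error(classificationError(y, p + 1), "\\[0, 1\\]")
})

test_that("Brier score is the mean squared probability distance", {
  y <- c(1, 0, 1, 0)
  expect_equal(brierScore(y, y), 0)
  expect_equal(brierScore(y, rep(0.5, 4)), 0.25)
  expect_equal(brierScore(y, c(0.9, 0.2, 0.6, 0.1)),
               mean(c(0.01, 0.04, 0.16, 0.01)))
})

test_that("ROC curve is anchored, monotone, and symmetric under reversal", {
  set.seed(231)
  y <- rep(c(0, 1), each = 50)
  pPerfect <- y * 0.5 + 0.25
  rc <- rocCurve(y, pPerfect)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))   # passes through (0,1)
  expect_equal(range(rc$fpr), c(0, 1))
  expect_equal(range(rc$tpr), c(0, 1))
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  # random scores give area ~ 0.5
  y2 <- rbinom(1e4, 1, 0.5)
  s <- runif(1e4)
  expect_lt(abs(attr(rocCurve(y2, s), "auc") - 0.5), 0.02)
  # reversing scores reflects the area about 1/2
  a1 <- attr(rocCurve(y2, s), "auc")
  a2 <- attr(rocCurve(y2, 1 - s), "auc")
  expect_equal(a1 + a2, 1, tolerance = 1e-10)
  expect_error(rocCurve(rep(1, 5), runif(5)), "both classes")
})

test_that("bias-variance terms match explicit hat-matrix computation", {
  D <- toyDesign(12, 5, seed = 241)
  set.seed(242)
  betaTrue <- rnorm(5)
  s2 <- 1.3
  E <- eigenDecompose(D)
  XtX <- crossprod(D@X)
  for (spec in list(list(method = "ridge", k = 0.7),
                    list(method = "pcr", r = 3L))) {
    got <- do.call(biasVarianceDecompose,
                   c(list(D = D, betaTrue = betaTrue, sigma2 = s2, E = E), spec))
    H <- if (spec$method == "ridge") {
      D@X %*% solve(XtX + spec$k * diag(5)) %*% t(D@X)
    } else {
      Zr <- E@Z[, seq_len(spec$r), drop = FALSE]
      Zr %*% diag(1 / E@lambdas[seq_len(spec$r)], spec$r) %*% t(Zr)
    }
    b <- drop((H - diag(12)) %*% D@X %*% betaTrue)
    expect_equal(got$biasSq, sum(b^2), tolerance = 1e-8)
    expect_equal(got$variance, s2 * sum(diag(H %*% t(H))), tolerance = 1e-8)
    expect_equal(got$noise, 12 * s2)
  }
})

test_that("OLS is unbiased and PCR bias vanishes at full rank", {
  D <- toyDesign(15, 6, seed = 251)
  set.seed(252)
  betaTrue <- rnorm(6)
  E <- eigenDecompose(D)
  ols <- biasVarianceDecompose(D, betaTrue, 1, method = "ols", E = E)
  expect_equal(ols$biasSq, 0, tolerance = 1e-16)
  biases <- sapply(seq_len(E@t), function(r)
    biasVarianceDecompose(D, betaTrue, 1, method = "pcr", r = r, E = E)$biasSq)
  expect_true(all(diff(biases) <= 1e-10))   # bias shrinks as r grows
  expect_equal(biases[E@t], 0, tolerance = 1e-16)
  # ridge and PCR matched at equal df agree with the forward formulas
  kMatch <- findKForDf(E@lambdas, 3)
  rid <- biasVarianceDecompose(D, betaTrue, 1, method = "ridge", k = kMatch, E = E)
  expect_equal(rid$variance, 3, tolerance = 1e-6)
})

test_that("ridge PSE approaches its bias-variance prediction on average", {
  set.seed(261)
  G <- randomGenotypes(50, 20, seed = 262)
  D0 <- standardizeGenotypes(G, rnorm(50))
  betaStd <- rnorm(20, sd = 0.8)
  s2 <- 1
  E <- eigenDecompose(D0)
  k <- 2
  m <- drop(D0@X %*% betaStd)
  dec <- biasVarianceDecompose(D0, betaStd, s2, method = "ridge", k = k, E = E)
  # Monte-Carlo in-sample expected squared error of fitted values vs mean:
  # E||y* - H y||^2 = noise + variance + bias^2 over fresh noise draws
  reps <- 200
  tot <- 0
  shr <- E@lambdas / (E@lambdas + k)
  for (b in seq_len(reps)) {
    y <- m + rnorm(50, 0, sqrt(s2))
    yStar <- m + rnorm(50, 0, sqrt(s2))
    zc <- drop(crossprod(E@Z, y)) / E@lambdas
    fitted <- drop(E@Z %*% (shr * zc))
    tot <- tot + sum((yStar - fitted)^2)
  }
  mc <- tot / reps
  se <- dec$total * sqrt(6 / reps)  # generous Monte-Carlo band
  expect_lt(abs(mc - dec$total), se)
})

test_that("univariate baseline selects, deduplicates, and fits by rank", {
  sim <- simulateGwasStudy(p = 60, nTrain = 80, nTest = 40, nCausal = 5,
                           seed = 271, mafFloor = 0.2, causalMafRange = c(0.2, 0.45), nHap = 400,
                           regionBp = 1e6, effectRange = c(0.4, 0.8))
  G <- sim$train$genotypes; y <- sim$train$phenotype
  # top-1 equals simple regression on the best SNP
  ub1 <- univariateBaseline(G, y, sim$test$genotypes, proportion = 1 / 60)
  expect_length(ub1$snpId, 1L)
  best <- which.min(ub1$pValues)
  expect_equal(ub1$snpId, snpIds(G)[best])
  simple <- lm(y ~ g, data = data.frame(y = y, g = genotypes(G)[, best]))
  expect_equal(unname(coef(ub1$fit)), unname(coef(simple)), tolerance = 1e-10)
  # an exactly duplicated column keeps only the first by position
  v <- cbind(genotypes(G)[, 1:10], genotypes(G)[, 3])
  Gd <- GenotypeMatrix(v, posBp = c(positions(G)[1:10], positions(G)[10] + 50L))
  ubd <- univariateBaseline(Gd, y, proportion = 1)
  expect_false(paste0("snp", 11) %in% ubd$snpId)
  expect_true(snpIds(Gd)[3] %in% ubd$snpId)
  # too many survivors cannot be fitted
  Gw <- randomGenotypes(10, 30, seed = 272)
  set.seed(273)
  expect_error(univariateBaseline(Gw, rnorm(10), proportion = 1),
               "cannot be fitted")
})

test_that("cross-validated ridge is deterministic in its seed", {
  sim <- simulateGwasStudy(p = 40, nTrain = 60, nTest = 30, nCausal = 5,
                           seed = 281, mafFloor = 0.2, causalMafRange = c(0.2, 0.45), nHap = 400,
                           regionBp = 1e6)
  G <- sim$train$genotypes; y <- sim$train$phenotype
  grid <- c(0.5, 2, 8, 32)
  cv1 <- cvRidge(G, y, folds = 5, kGrid = grid, seed = 9)
  cv2 <- cvRidge(G, y, folds = 5, kGrid = grid, seed = 9)
  expect_identical(cv1$foldId, cv2$foldId)
  expect_identical(cv1$k, cv2$k)
  expect_identical(cv1$cvTable, cv2$cvTable)
  # a one-point grid returns that point
  cvOne <- cvRidge(G, y, folds = 5, kGrid = 3, seed = 9)
  expect_equal(cvOne$k, 3)
  expect_equal(cvOne$model@k, 3)
  expect_error(cvRidge(G, y, folds = 5, kGrid = c(-1, 2), seed = 1), "positive")
  expect_error(cvRidge(G, y, folds = 1, kGrid = grid), "at least 2")
})

test_that("cv loss agrees with glmnet's ridge path on shared folds", {
  skip_if_not_installed("glmnet")
  sim <- simulateGwasStudy(p = 30, nTrain = 90, nTest = 30, nCausal = 5,
                           seed = 291, mafFloor = 0.2, causalMafRange = c(0.2, 0.45), nHap = 400,
                           regionBp = 1e6, effectRange = c(0.3, 0.6))
  G <- sim$train$genotypes; y <- sim$train$phenotype
  D <- standardizeGenotypes(G, y)
  E <- eigenDecompose(D)
  k <- 4
  m <- fitRidgeLinear(D, E, k)
  # glmnet ridge with matching parameterisation: penalty k maps to
  # lambda = k/n * sd_n(y) because glmnet standardizes the gaussian
  # response internally with the 1/n standard deviation
  sy <- sd(D@y) * sqrt((D@n - 1) / D@n)
  gfit <- glmnet::glmnet(D@X, D@y, alpha = 0, lambda = k / D@n * sy,
                         standardize = FALSE, intercept = FALSE,
                         thresh = 1e-16, maxit = 1e6)
  expect_equal(m@diagnostics$betaStd, as.numeric(gfit$beta), tolerance = 1e-6)
})

test_that("p-value-threshold selection keeps exactly the passing SNPs", {
  sim <- simulateGwasStudy(p = 60, nTrain = 80, nTest = 40, nCausal = 5,
                           seed = 275, mafFloor = 0.2, causalMafRange = c(0.2, 0.45),
                           nHap = 400, regionBp = 1e6, effectRange = c(0.6, 1))
  G <- sim$train$genotypes; y <- sim$train$phenotype
  ub <- univariateBaseline(G, y, pThreshold = 1e-3)
  expect_setequal(ub$snpId, snpIds(G)[ub$pValues < 1e-3])
  expect_error(univariateBaseline(G, y), "exactly one")
  expect_error(univariateBaseline(G, y, proportion = 0.1, pThreshold = 0.1),
               "exactly one")
  expect_error(univariateBaseline(G, y, pThreshold = 1e-30), "no SNP passes")
})
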