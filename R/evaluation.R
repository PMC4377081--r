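#' Mean prediction squared error
#'
#' @param yTrue,yPred numeric vectors of equal length.
#' @return `mean((yTrue - yPred)^2)`.
#' @export
pse <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (!length(yTrue)) stop("empty input")
  mean((yTrue - yPred)^2)
}

#' Mean classification error
#'
#' Fraction of individuals whose thresholded predicted probability
#' disagrees with the observed class.  Predictions exactly at the
#' threshold are called cases (`>=` rule), configurable via `tieCase`.
#'
#' @param yTrue binary 0/1 vector.
#' @param pHat predicted probabilities in \[0, 1\].
#' @param threshold classification threshold (default 0.5).
#' @param tieCase call `pHat == threshold` a case (default `TRUE`).
#' @return scalar error rate.
#' @export
classificationError <- function(yTrue, pHat, threshold = 0.5, tieCase = TRUE) {
  if (length(yTrue) != length(pHat)) stop("length mismatch")
  if (any(pHat < 0 | pHat > 1)) stop("pHat must lie in [0, 1]")
  call <- if (tieCase) pHat >= threshold else pHat > threshold
  mean(call != (yTrue == 1))
}

#' Brier score
#'
#' Mean squared distance between predicted probability and binary
#' outcome; lies in \[0, 1\], smaller is better, and a constant
#' `pHat = 0.5` scores exactly 0.25.
#'
#' @inheritParams classificationError
#' @return scalar Brier score.
#' @export
brierScore <- function(yTrue, pHat) {
  if (length(yTrue) != length(pHat)) stop("length mismatch")
  if (any(pHat < 0 | pHat > 1)) stop("pHat must lie in [0, 1]")
  mean((pHat - yTrue)^2)
}

#' ROC curve of a probabilistic classifier
#'
#' True positive rate against false positive rate as the classification
#' threshold varies over all distinct predicted values, anchored at
#' (0,0) and (1,1).  Computed with \pkg{pROC}.
#'
#' @param yTrue binary 0/1 vector with both classes present.
#' @param pHat predicted probabilities or scores.
#' @return a `data.frame` with columns `fpr` and `tpr`, ordered along
#'   the curve, with the area under the curve in attribute `"auc"`.
#' @export
rocCurve <- function(yTrue, pHat) {
  if (length(unique(yTrue)) < 2L)
    stop("ROC requires both classes to be present")
  r <- pROC::roc(response = yTrue, predictor = pHat, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  out <- data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  attr(out, "auc") <- as.numeric(pROC::auc(r))
  out
}

#' Bias-variance decomposition of prediction squared error
#'
#' For a linear smoother with hat matrix `H` (ridge at `k`, principal
#' components regression with `r` components, or ordinary least
#' squares), the expected in-sample prediction squared error decomposes
#' into an irreducible noise term `n sigma2`, a variance term
#' `sigma2 tr(HH')`, and a squared bias `||b||^2` with
#' `b = (H - I) X betaTrue`.  OLS (full-rank design) is unbiased; the
#' PCR bias vanishes as `r` grows to the full rank `t`.
#'
#' All terms are computed through the eigensystem of the design, never
#' by forming `H` explicitly.
#'
#' @param D a [StandardizedDesign-class].
#' @param betaTrue true coefficients on the standardized scale
#'   (multiplying the columns of `D@X`).
#' @param sigma2 error variance.
#' @param method `"ridge"`, `"pcr"` or `"ols"`.
#' @param k ridge shrinkage parameter (method `"ridge"`).
#' @param r number of components (method `"pcr"`).
#' @param E optional precomputed [EigenSystem-class].
#' @return list with `biasSq`, `variance`, `noise`, and their `total`.
#' @export
biasVarianceDecompose <- function(D, betaTrue, sigma2,
                                  method = c("ridge", "pcr", "ols"),
                                  k = NULL, r = NULL, E = NULL) {
  method <- match.arg(method)
  if (is.null(E)) E <- eigenDecompose(D)
  lam <- E@lambdas; t <- E@t
  shrink <- switch(method,
    ridge = {
      if (is.null(k) || k < 0) stop("method 'ridge' needs k >= 0")
      lam / (lam + k)
    },
    pcr = {
      if (is.null(r) || r < 0 || r > t) stop("method 'pcr' needs r in 0..t")
      rep(c(1, 0), c(r, t - r))
    },
    ols = {
      if (t < D@p) stop("OLS requires a full-column-rank design")
      rep(1, t)
    })
  m <- drop(D@X %*% betaTrue)
  zm <- drop(crossprod(E@Z, m)) / lam       # PC coordinates of the mean
  b <- drop(E@Z %*% (shrink * zm)) - m      # (H - I) X betaTrue
  list(biasSq = sum(b^2),
       variance = sigma2 * sum(shrink^2),
       noise = length(m) * sigma2,
       total = length(m) * sigma2 + sigma2 * sum(shrink^2) + sum(b^2))
}

# vectorised univariate association p-values: t-test on the
# correlation (linear family) or score test (logistic family)
.univariatePvalues <- function(X, y, family) {
  n <- nrow(X)
  xc <- X - rep(colMeans(X), each = n)
  ss <- colSums(xc^2)
  if (family == "linear") {
    yc <- y - mean(y)
    r2 <- (drop(crossprod(xc, yc))^2) / (ss * sum(yc^2))
    r2 <- pmin(r2, 1 - 1e-15)
    tstat <- sqrt(r2 * (n - 2) / (1 - r2))
    2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  } else {
    ybar <- mean(y)
    u <- drop(crossprod(xc, y))
    v <- ybar * (1 - ybar) * ss
    z2 <- ifelse(v > 0, u^2 / v, 0)
    stats::pchisq(z2, df = 1, lower.tail = FALSE)
  }
}

#' Univariate-selection multiple-regression baseline
#'
#' Ranks SNPs by univariate association p-value, keeps the most
#' strongly associated subset (a fixed proportion, or all below a
#' p-value threshold), and fits an unpenalised multiple linear or
#' logistic regression on the survivors.  Among exactly collinear
#' selected SNPs only the first by position is kept, since both cannot
#' enter a multiple regression.  If the survivors are as numerous as
#' the observations the model cannot be fitted and an error is raised.
#'
#' @param GTrain,GTest training and test [GenotypeMatrix-class] panels.
#' @param y training phenotype.
#' @param proportion fraction of SNPs to keep (e.g. `0.001` for the top
#'   0.1%); mutually exclusive with `pThreshold`.
#' @param pThreshold keep SNPs with univariate p-value below this value.
#' @param family `"linear"` or `"logistic"`.
#' @return list with `snpId` (selected markers), `fit` (the `lm`/`glm`
#'   object), `predTest` (test-set predictions: response scale), and
#'   `pValues` (all univariate p-values).
#' @export
univariateBaseline <- function(GTrain, y, GTest = NULL, proportion = NULL,
                               pThreshold = NULL,
                               family = c("linear", "logistic")) {
  family <- match.arg(family)
  X <- GTrain@values
  n <- nrow(X); p <- ncol(X)
  pv <- .univariatePvalues(X, y, family)
  if (is.null(proportion) == is.null(pThreshold))
    stop("give exactly one of proportion or pThreshold")
  if (!is.null(proportion)) {
    m <- max(1L, round(proportion * p))
    sel <- order(pv)[seq_len(m)]     # stable: ties keep the first by position
  } else {
    sel <- which(pv < pThreshold)
  }
  if (!length(sel)) stop("no SNP passes the selection rule")
  sel <- sort(sel)                   # restore position order
  # among exactly collinear pairs keep the first by position
  if (length(sel) > 1L) {
    Xs <- scale(X[, sel, drop = FALSE])
    cc <- abs(crossprod(Xs) / (n - 1))
    drop <- rep(FALSE, length(sel))
    for (jj in seq_along(sel)[-1L]) {
      if (any(cc[seq_len(jj - 1L), jj] > 1 - 1e-12 & !drop[seq_len(jj - 1L)]))
        drop[jj] <- TRUE
    }
    sel <- sel[!drop]
  }
  if (length(sel) >= n)
    stop("selected predictors (", length(sel), ") must be fewer than ",
         "observations (", n, "): a multiple regression model cannot be fitted")
  dat <- data.frame(y = y, X[, sel, drop = FALSE], check.names = FALSE)
  fit <- if (family == "linear") stats::lm(y ~ ., data = dat)
         else stats::glm(y ~ ., data = dat, family = stats::binomial())
  predTest <- NULL
  if (!is.null(GTest)) {
    idx <- match(GTrain@snpId[sel], GTest@snpId)
    if (anyNA(idx)) stop("test panel is missing selected SNPs")
    nd <- as.data.frame(GTest@values[, idx, drop = FALSE])
    names(nd) <- GTrain@snpId[sel]
    predTest <- stats::predict(fit, newdata = nd, type = "response")
  }
  list(snpId = GTrain@snpId[sel], fit = fit, predTest = predTest, pValues = pv)
}

#' Ridge regression with the shrinkage parameter chosen by cross-validation
#'
#' K-fold cross-validation over a grid of shrinkage parameters.  Folds
#' come from a seeded permutation of the individuals; within each fold
#' the training-fold genotypes are re-standardized and the eigensystem
#' recomputed (and reused across the whole grid).  The held-out loss is
#' squared error for the linear family and deviance for the logistic
#' family; the `k` with the smallest mean held-out loss (ties toward
#' the larger `k`, i.e. more shrinkage) is refitted on all the data.
#'
#' @param G a [GenotypeMatrix-class].
#' @param y phenotype vector.
#' @param family `"linear"` or `"logistic"`.
#' @param folds number of folds (default 10).
#' @param kGrid candidate shrinkage values; by default 41 log-spaced
#'   points spanning `kHat/100` to `100 kHat` around the automatic
#'   estimate.
#' @param seed integer seed for the fold permutation.
#' @param fitOptions,penaltyFactor passed to the logistic solver.
#' @return list with `k` (chosen), `model` (the refitted
#'   [RidgeModel-class]), `cvTable` (mean held-out loss per `k`), and
#'   `foldId` (the fold assignment).
#' @export
cvRidge <- function(G, y, family = c("linear", "logistic"), folds = 10L,
                    kGrid = NULL, seed = 1L, fitOptions = clgControl(),
                    penaltyFactor = 2) {
  family <- match.arg(family)
  if (folds < 2L) stop("folds must be at least 2")
  n <- nrow(G@values)
  oldSeed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  foldId <- rep_len(seq_len(folds), n)[sample.int(n)]
  if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = .GlobalEnv)
  if (is.null(kGrid)) {
    anchor <- autoRidge(G, y, family, fitOptions = fitOptions,
                        penaltyFactor = penaltyFactor)
    kGrid <- exp(seq(log(anchor@k / 100), log(anchor@k * 100),
                     length.out = 41L))
  }
  kGrid <- sort(as.numeric(kGrid))
  if (any(!is.finite(kGrid) | kGrid <= 0)) stop("kGrid must be positive and finite")
  loss <- matrix(NA_real_, folds, length(kGrid))
  for (f in seq_len(folds)) {
    trIdx <- which(foldId != f); hoIdx <- which(foldId == f)
    Gtr <- G[trIdx, ]; Gho <- G[hoIdx, ]
    # columns constant within the training fold carry no information there
    mu <- colMeans(Gtr@values)
    ss <- colSums(Gtr@values^2) - nrow(Gtr@values) * mu^2
    keep <- which(ss > 1e-9)
    if (length(keep) < ncol(Gtr@values)) { Gtr <- Gtr[, keep]; Gho <- Gho[, keep] }
    D <- standardizeGenotypes(Gtr, y[trIdx], family)
    if (family == "linear") {
      # held-out predictions through the n x n eigensystem of the training
      # fold: beta = X'U (Lambda + k)^{-1} U'y, so eta_ho = M U (L+k)^{-1} U'y
      # with M = Xho_std Xtr_std'; the whole k grid reuses one decomposition
      e <- eigen(tcrossprod(D@X), symmetric = TRUE)
      keepE <- e$values > 1e-10 * max(e$values)
      lam <- e$values[keepE]
      U <- e$vectors[, keepE, drop = FALSE]
      uy <- drop(crossprod(U, D@y))
      Xho <- t((t(Gho@values) - D@colMeans) / D@colScales)
      MU <- tcrossprod(Xho, D@X) %*% U
      for (ik in seq_along(kGrid)) {
        eta <- D@yMean + drop(MU %*% (uy / (lam + kGrid[ik])))
        loss[f, ik] <- pse(y[hoIdx], eta)
      }
    } else {
      warm <- NULL
      for (ik in rev(seq_along(kGrid))) {   # strong penalty first: easy start
        m <- fitRidgeLogisticCLG(D, D@y, kGrid[ik], opts = fitOptions,
                                 penaltyFactor = penaltyFactor, init = warm)
        warm <- list(beta = m@diagnostics$betaStd,
                     intercept = m@diagnostics$interceptStd)
        ph <- predict(m, Gho)
        loss[f, ik] <- -2 * sum(y[hoIdx] * log(ph) + (1 - y[hoIdx]) * log1p(-ph))
      }
    }
  }
  meanLoss <- colMeans(loss)
  best <- max(which(meanLoss <= min(meanLoss) + 1e-12))
  kBest <- kGrid[best]
  model <- autoRidge(G, y, family, k = kBest, fitOptions = fitOptions,
                     penaltyFactor = penaltyFactor)
  list(k = kBest, model = model,
       cvTable = data.frame(k = kGrid, meanLoss = meanLoss),
       foldId = foldId)
}
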