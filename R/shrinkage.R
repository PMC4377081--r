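# numerically safe Bernoulli log-likelihood: sum over i of y*eta - log(1+e^eta)
.logLikBernoulli <- function(y, eta) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

#' Residual variance after regression on the first r components
#'
#' Residual sum of squares of the centred response on the first `r`
#' principal component scores, divided by `n - r`.  Because the scores
#' are orthogonal, the RSS is `y'y - sum(lambda_j * alpha_j^2)` over the
#' first `r` components.
#'
#' @param yCentred centred response (length n).
#' @param Zr n x r matrix of the first r principal component scores.
#' @param alphaR the first r PCR coefficients.
#' @param n number of observations.
#' @return the residual variance estimate (non-negative scalar).
#' @export
sigmaSqR <- function(yCentred, Zr, alphaR, n) {
  r <- ncol(Zr)
  if (r >= n) stop("r must be smaller than n")
  res <- yCentred - Zr %*% alphaR
  sum(res^2) / (n - r)
}

#' Shrinkage parameter from r principal components (linear family)
#'
#' `k_r = r * sigma2_r / sum(alpha_{1..r}^2)`, the
#' Hoerl-Kennard-Baldwin-style shrinkage parameter computed from the
#' first `r` principal components regression coefficients.  At
#' `r = p` (with `n > p`) this equals the classical `k_HKB`, since the
#' squared coefficient norm is invariant under the orthogonal rotation.
#'
#' @param alpha PCR coefficients (at least r of them).
#' @param sigma2 residual variance estimate on the first r components.
#' @param r number of components used.
#' @return positive scalar shrinkage parameter.
#' @seealso [kHKB()], [selectRLinear()]
#' @export
kRLinear <- function(alpha, sigma2, r) {
  aSq <- sum(alpha[seq_len(r)]^2)
  if (aSq == 0)
    stop("all PCR coefficients through component ", r,
         " are zero: shrinkage parameter is infinite")
  r * sigma2 / aSq
}

#' The Hoerl-Kennard-Baldwin ridge parameter
#'
#' `k_HKB = p * sigma2 / (betaOLS' betaOLS)` with `sigma2` the ordinary
#' least squares residual variance on `n - p` degrees of freedom.  Only
#' defined when there are more observations than predictors; for wider
#' problems use the principal-components generalisation in
#' [selectRLinear()].
#'
#' @param D a [StandardizedDesign-class] with `n > p`.
#' @param yCentred centred response.
#' @return positive scalar.
#' @export
kHKB <- function(D, yCentred) {
  n <- D@n; p <- D@p
  if (p >= n)
    stop("k_HKB is not defined when p >= n (OLS coefficients do not exist)")
  fit <- stats::lm.fit(D@X, yCentred)
  if (fit$rank < p) stop("k_HKB requires an invertible X'X (rank-deficient design)")
  beta <- fit$coefficients
  sigma2 <- sum(fit$residuals^2) / (n - p)
  p * sigma2 / sum(beta^2)
}

#' Shrinkage parameter from r components (logistic family)
#'
#' `k_r = r / sum(alpha_{1..r}^2)`, the ridge-type shrinkage parameter
#' of Schaefer's estimator computed from the first `r` principal
#' components logistic regression coefficients.  There is no residual
#' variance term in the logistic family.
#'
#' @param alpha PCLR coefficients (intercept excluded; at least r of them).
#' @param r number of components used.
#' @return positive scalar.
#' @export
kRLogistic <- function(alpha, r) {
  aSq <- sum(alpha[seq_len(r)]^2)
  if (aSq == 0)
    stop("all PCLR coefficients through component ", r,
         " are zero: shrinkage parameter is infinite")
  r / aSq
}

#' Effective degrees of freedom of linear ridge regression
#'
#' For the ridge hat matrix `H = X (X'X + kI)^{-1} X'` with eigenvalues
#' `lambda` of `X'X`:
#' `df_model = tr(H) = sum(lambda/(lambda+k))` and
#' `df_variance = tr(HH') = sum(lambda^2/(lambda+k)^2)`.
#' At `k = 0` both equal the rank `t`; both decrease strictly in `k` and
#' `df_variance <= df_model`.
#'
#' @param lambdas positive eigenvalues of `crossprod(X)`.
#' @param k non-negative shrinkage parameter.
#' @return list with elements `model` and `variance`.
#' @export
dfRidgeLinear <- function(lambdas, k) {
  if (k < 0) stop("k must be non-negative")
  s <- lambdas / (lambdas + k)
  list(model = sum(s), variance = sum(s^2))
}

#' Effective degrees of freedom for variance of logistic ridge
#'
#' `tr(H^2)` for the weighted hat matrix
#' `H = W^{1/2} X (X'WX + c k I)^{-1} X' W^{1/2}`, where
#' `W = diag(phat_i (1 - phat_i))` is built from the fitted
#' probabilities of a converged ridge-logistic model at `k`, and `c` is
#' the penalty curvature (2 under the default objective
#' `-logLik + k sum(beta^2)`).  Computed through the n x n matrix
#' `W^{1/2} X X' W^{1/2}`, whose eigenvalues `mu` give
#' `tr(H^2) = sum((mu/(mu + c k))^2)`; no p x p matrix is formed.
#'
#' @param D a [StandardizedDesign-class].
#' @param beta fitted coefficients on the standardized scale.
#' @param intercept fitted intercept.
#' @param k positive shrinkage parameter used in the fit.
#' @param penaltyFactor curvature of the penalty at the optimum
#'   (default 2, matching the `k * sum(beta^2)` objective; use 1 for the
#'   `k/2 * sum(beta^2)` convention).
#' @param XXt optional precomputed `tcrossprod(D@X)`, reused across
#'   candidate fits during selection.
#' @return scalar `tr(H^2)`.
#' @export
dfRidgeLogistic <- function(D, beta, intercept, k, penaltyFactor = 2,
                            XXt = NULL) {
  if (k <= 0) stop("k must be positive")
  eta <- drop(D@X %*% beta) + intercept
  phat <- stats::plogis(eta)
  if (any(phat < 1e-12 | phat > 1 - 1e-12))
    warning("fitted probabilities numerically at 0 or 1; weights floored")
  w <- pmax(phat * (1 - phat), 1e-10)
  sw <- sqrt(w)
  if (is.null(XXt)) XXt <- tcrossprod(D@X)
  K <- XXt * tcrossprod(sw)
  mu <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  mu <- pmax(mu, 0)
  sum((mu / (mu + penaltyFactor * k))^2)
}

#' Find the shrinkage parameter matching a target degrees of freedom
#'
#' Solves `sum(lambda^2/(lambda+k)^2) = targetDf` for `k`.  The left
#' side decreases strictly from `t` (at `k = 0`) to 0, so the root is
#' unique; it is bracketed and then polished by Newton steps until
#' `|df - targetDf| < 1e-8`.
#'
#' @param lambdas positive eigenvalues of `crossprod(X)`.
#' @param targetDf target degrees of freedom for variance, in `(0, t)`.
#' @return positive scalar `k`.
#' @export
findKForDf <- function(lambdas, targetDf) {
  t <- length(lambdas)
  if (targetDf <= 0 || targetDf >= t)
    stop("targetDf must lie strictly between 0 and t = ", t)
  f <- function(k) sum((lambdas / (lambdas + k))^2) - targetDf
  lo <- 0
  hi <- max(lambdas)
  while (f(hi) > 0) hi <- hi * 10
  k <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.5)$root
  for (i in 1:50) {
    val <- f(k)
    if (abs(val) < 1e-8) break
    grad <- -2 * sum(lambdas^2 / (lambdas + k)^3)
    k <- max(k - val / grad, k / 10)
  }
  k
}

#' Choose the number of components and shrinkage parameter (linear)
#'
#' For each candidate `r = 1..t`, computes the residual variance
#' `sigma2_r` of the PCR fit, the shrinkage parameter
#' `k_r = r sigma2_r / sum(alpha_{1..r}^2)`, and the effective degrees
#' of freedom for variance of ridge at `k_r`.  The selected `rHat`
#' minimises `|df(k_r) - r|` (ties toward the smaller `r`, i.e. more
#' shrinkage); `kHat = k_{rHat}`.  Candidates whose leading PCR
#' coefficients are all zero are skipped, not errors.
#'
#' The model degrees of freedom `tr(H)` are recorded alongside for
#' diagnostics, but selection always uses the variance definition
#' `tr(HH')`.
#'
#' @param E an [EigenSystem-class].
#' @param yCentred centred response.
#' @param alpha PCR coefficients; computed from `E` and `yCentred` when
#'   omitted.
#' @return a [ShrinkageResult-class].
#' @export
selectRLinear <- function(E, yCentred, alpha = NULL) {
  t <- E@t
  if (t < 1L) stop("eigensystem has no retained components")
  n <- length(yCentred)
  if (is.null(alpha)) alpha <- pcrCoefficients(E, yCentred)
  lam <- E@lambdas
  rGrid <- seq_len(t)
  aSqCum <- cumsum(alpha^2)
  yss <- sum(yCentred^2)
  rss <- pmax(yss - cumsum(lam * alpha^2), 0)
  sigma2 <- rss / (n - rGrid)
  kR <- ifelse(aSqCum > 0, rGrid * sigma2 / aSqCum, NA_real_)
  dfR <- vapply(kR, function(k)
    if (is.na(k)) NA_real_ else sum((lam / (lam + k))^2), numeric(1))
  dfM <- vapply(kR, function(k)
    if (is.na(k)) NA_real_ else sum(lam / (lam + k)), numeric(1))
  # candidates where the PCR fit is (numerically) perfect are degenerate:
  # k_r -> 0 there, and ridge at k = 0 does not exist when p > n.  When the
  # scores span the centred response (r = t = n - 1) this would otherwise
  # always "win" with |df - r| = 0.
  valid <- which(!is.na(kR) & rss > 1e-8 * yss)
  if (!length(valid)) stop("no valid candidate r: all PCR coefficients are zero")
  obj <- abs(dfR[valid] - rGrid[valid])
  rHat <- rGrid[valid][which.min(obj)]
  new("ShrinkageResult", family = "linear", rGrid = rGrid,
      alphaSqCum = aSqCum, sigma2R = sigma2, kR = kR, dfR = dfR,
      dfModelR = dfM, rHat = as.integer(rHat), kHat = kR[rHat])
}

# default logistic candidate grid: exhaustive for small t, otherwise
# log-spaced (the |df - r| profile is smooth in r)
.logisticRGrid <- function(t, size = 100L) {
  if (t <= 200L) return(seq_len(t))
  sort(unique(round(exp(seq(log(1), log(t), length.out = size)))))
}

#' Choose the number of components and shrinkage parameter (logistic)
#'
#' For each candidate `r`, fits an unpenalised principal components
#' logistic regression ([pclrCoefficients()]), computes
#' `k_r = r / sum(alpha_{1..r}^2)`, fits the full ridge-logistic model
#' at `k_r` ([fitRidgeLogisticCLG()]), and records the effective degrees
#' of freedom for variance `tr(H^2)` of that fit.  `rHat` minimises
#' `|df - r|`, ties toward the smaller `r`.  Candidates where the PCLR
#' separates are dropped from the grid with a warning.
#'
#' When the grid is coarse (large `t`), the scan is refined once with up
#' to 20 extra integer candidates between the neighbours of the running
#' minimiser.  Ridge fits are warm-started along the grid.
#'
#' @param E an [EigenSystem-class].
#' @param D the [StandardizedDesign-class] (logistic family).
#' @param y binary 0/1 response.
#' @param rGrid integer candidates; defaults to `1..t` for `t <= 200`,
#'   else ~100 log-spaced values with local refinement.
#' @param fitOptions a [clgControl()] list for the ridge-logistic fits.
#' @param penaltyFactor penalty curvature passed to [dfRidgeLogistic()].
#' @param refine add refinement candidates around the coarse minimiser
#'   (default `TRUE`; only relevant when the grid is coarse).
#' @return a [ShrinkageResult-class].
#' @export
selectRLogistic <- function(E, D, y, rGrid = NULL, fitOptions = clgControl(),
                            penaltyFactor = 2, refine = TRUE) {
  t <- E@t
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(rGrid)) rGrid <- .logisticRGrid(t)
  rGrid <- sort(unique(as.integer(rGrid)))
  if (any(rGrid < 1L | rGrid > t)) stop("rGrid must lie in 1..t")
  XXt <- tcrossprod(D@X)

  scanOne <- function(r, warmBeta) {
    pclr <- tryCatch(pclrCoefficients(E, y, r), error = function(e) e)
    if (inherits(pclr, "error")) {
      warning("candidate r = ", r, " dropped: ", conditionMessage(pclr))
      return(NULL)
    }
    aSq <- sum(pclr$alpha^2)
    if (aSq == 0) return(NULL)
    k <- r / aSq
    fit <- fitRidgeLogisticCLG(D, y, k, opts = fitOptions,
                               penaltyFactor = penaltyFactor,
                               init = warmBeta)
    betaStd <- fit@diagnostics$betaStd
    intStd <- fit@diagnostics$interceptStd
    df <- dfRidgeLogistic(D, betaStd, intStd, k,
                          penaltyFactor = penaltyFactor, XXt = XXt)
    list(r = r, aSq = aSq, k = k, df = df,
         warm = list(beta = betaStd, intercept = intStd))
  }

  scanGrid <- function(grid, warm) {
    out <- vector("list", length(grid))
    for (i in seq_along(grid)) {
      res <- scanOne(grid[i], warm)
      if (!is.null(res)) { warm <- res$warm; out[[i]] <- res }
    }
    out[!vapply(out, is.null, logical(1))]
  }

  hits <- scanGrid(rGrid, NULL)
  if (!length(hits)) stop("every candidate r failed (separation or zero coefficients)")
  getr <- function(h) vapply(h, `[[`, numeric(1), "r")
  best <- hits[[which.min(vapply(hits, function(h) abs(h$df - h$r), numeric(1)))]]
  if (refine && length(rGrid) < t) {
    rs <- getr(hits)
    i <- match(best$r, rs)
    loR <- if (i > 1L) rs[i - 1L] else max(1L, best$r - 1L)
    hiR <- if (i < length(rs)) rs[i + 1L] else min(t, best$r + 1L)
    cand <- setdiff(seq(loR, hiR), rs)
    if (length(cand) > 20L)
      cand <- unique(round(seq(loR, hiR, length.out = 22L)[-c(1L, 22L)]))
    if (length(cand))
      hits <- c(hits, scanGrid(sort(cand), best$warm))
  }
  ord <- order(getr(hits))
  hits <- hits[ord]
  rs <- getr(hits)
  ks <- vapply(hits, `[[`, numeric(1), "k")
  dfs <- vapply(hits, `[[`, numeric(1), "df")
  aSq <- vapply(hits, `[[`, numeric(1), "aSq")
  iHat <- which.min(abs(dfs - rs))
  new("ShrinkageResult", family = "logistic", rGrid = as.integer(rs),
      alphaSqCum = aSq, sigma2R = numeric(0), kR = ks, dfR = dfs,
      dfModelR = numeric(0), rHat = as.integer(rs[iHat]), kHat = ks[iHat])
}

#' @rdname ShrinkageResult-class
#' @export
setMethod("kHat", "ShrinkageResult", function(object) object@kHat)

#' @rdname ShrinkageResult-class
#' @export
setMethod("rHat", "ShrinkageResult", function(object) object@rHat)

setMethod("show", "ShrinkageResult", function(object) {
  cat(sprintf("ShrinkageResult (%s family)\n", object@family))
  cat(sprintf("  candidates scanned: %d\n", length(object@rGrid)))
  cat(sprintf("  selected rHat = %d, kHat = %.6g (df at kHat: %.3f)\n",
              object@rHat, object@kHat,
              object@dfR[match(object@rHat, object@rGrid)]))
  invisible(NULL)
})

#' Write / read a shrinkage selection trace
#'
#' Tab-delimited audit table with one row per candidate: `r`, `k_r`,
#' `df_r` and a flag marking the selected row.
#'
#' @param S a [ShrinkageResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeShrinkageTrace <- function(S, path) {
  tab <- data.frame(r = S@rGrid, k_r = S@kR, df_r = S@dfR,
                    selected = as.integer(S@rGrid == S@rHat))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
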