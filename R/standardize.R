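#' Standardize genotypes to correlation form
#'
#' Centres each genotype column and scales it to unit Euclidean norm, so
#' that the cross-product matrix of the resulting design is in
#' correlation form (`diag(crossprod(X)) = 1` exactly).  For the linear
#' family the phenotype is centred and its mean stored; for the logistic
#' family the 0/1 labels are kept as they are.  Constant genotype columns
#' carry no information and make the scale undefined, so they are
#' rejected with the offending SNP named.
#'
#' The stored means and scales allow any coefficient vector `b` fitted on
#' the standardized scale to be mapped back to the minor-allele-count
#' scale: `beta_j = b_j / colScales_j`, with intercept
#' `yMean - sum(beta * colMeans)` (linear) or
#' `b0 - sum(beta * colMeans)` (logistic).
#'
#' @param G a [GenotypeMatrix-class].
#' @param y numeric phenotype: continuous values (linear family) or 0/1
#'   labels (logistic family).
#' @param family `"linear"` or `"logistic"`.
#' @return a [StandardizedDesign-class].
#' @examples
#' G <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 3))
#' D <- standardizeGenotypes(G, y = c(1, 2, 3))
#' crossprod(D@X)  # unit diagonal
#' @export
standardizeGenotypes <- function(G, y, family = c("linear", "logistic")) {
  family <- match.arg(family)
  v <- G@values
  n <- nrow(v); p <- ncol(v)
  if (n < 2L) stop("at least 2 individuals are required")
  if (length(y) != n) stop("phenotype length must equal the number of individuals")
  X <- matrix(as.numeric(v), n, p)
  mu <- colMeans(X)
  X <- X - rep(mu, each = n)
  sc <- sqrt(colSums(X^2))
  if (any(sc == 0))
    stop("constant genotype column(s): ",
         paste(utils::head(G@snpId[sc == 0], 5L), collapse = ", "))
  X <- X / rep(sc, each = n)
  colnames(X) <- G@snpId
  if (family == "linear") {
    yMean <- mean(y)
    yOut <- y - yMean
  } else {
    if (!all(y %in% c(0, 1))) stop("logistic family requires 0/1 phenotypes")
    if (length(unique(y)) < 2L) stop("both classes must be present")
    yMean <- numeric(0)
    yOut <- as.numeric(y)
  }
  new("StandardizedDesign", X = X, colMeans = mu, colScales = sc,
      y = yOut, yMean = yMean, family = family,
      n = as.integer(n), p = as.integer(p), snpId = G@snpId)
}

#' Eigendecomposition of the standardized design
#'
#' Computes the eigenvectors `Q` and eigenvalues `lambda` of
#' `crossprod(X)` together with the principal component scores
#' `Z = X Q`, working through whichever Gram matrix of `X` is smaller:
#' the p x p cross-product when `p <= n`, otherwise the n x n
#' `tcrossprod(X)` (so no p x p matrix is ever formed in the wide-data
#' case).  Eigenvalues below `tol * max(lambda)` are treated as zero and
#' dropped; because the columns of `X` are centred, at most
#' `min(n - 1, p)` eigenvalues survive.
#'
#' @param D a [StandardizedDesign-class].
#' @param tol relative eigenvalue tolerance (default `1e-10`, the
#'   double-precision noise floor).
#' @return an [EigenSystem-class].
#' @export
eigenDecompose <- function(D, tol = 1e-10) {
  X <- D@X
  n <- D@n; p <- D@p
  if (p <= n) {
    e <- eigen(crossprod(X), symmetric = TRUE)
    lam <- e$values
    keep <- lam > tol * max(lam, 0)
    lam <- lam[keep]
    Q <- e$vectors[, keep, drop = FALSE]
    Z <- X %*% Q
  } else {
    e <- eigen(tcrossprod(X), symmetric = TRUE)
    lam <- e$values
    keep <- lam > tol * max(lam, 0)
    lam <- lam[keep]
    U <- e$vectors[, keep, drop = FALSE]
    # eigenvectors of X'X from those of XX': Q = X'U Lambda^{-1/2}
    Q <- crossprod(X, U) / rep(sqrt(lam), each = p)
    Z <- U * rep(sqrt(lam), each = n)
  }
  t <- as.integer(length(lam))
  if (t > min(n - 1L, p))  # numerical safeguard; centring bounds the rank
    t <- min(n - 1L, p)
  new("EigenSystem", Q = Q[, seq_len(t), drop = FALSE], lambdas = lam[seq_len(t)],
      Z = Z[, seq_len(t), drop = FALSE], t = t)
}

#' Principal components regression coefficients
#'
#' Least-squares coefficients of the centred response on the principal
#' component scores.  Because the scores are orthogonal with
#' `crossprod(Z) = diag(lambda)`, the solution is componentwise:
#' `alpha_j = z_j' y / lambda_j`.
#'
#' @param E an [EigenSystem-class].
#' @param yCentred centred numeric response of length n.
#' @return numeric vector `alpha` of length `E@t`.
#' @export
pcrCoefficients <- function(E, yCentred) {
  if (length(yCentred) != nrow(E@Z)) stop("response length must equal n")
  drop(crossprod(E@Z, yCentred)) / E@lambdas
}

#' Principal components logistic regression coefficients
#'
#' Unpenalised maximum-likelihood logistic regression of a binary
#' response on the first `r` principal component scores, fitted by
#' iteratively reweighted least squares with an (unpenalised) intercept.
#' The intercept is reported separately and is excluded from the
#' coefficient vector used downstream in the shrinkage-parameter
#' computation.
#'
#' @param E an [EigenSystem-class].
#' @param y binary 0/1 response of length n.
#' @param r number of leading components to use, `1 <= r <= E@t`.
#' @param maxIter IRLS iteration cap (default 100).
#' @param tol convergence threshold on the relative change in
#'   log-likelihood (default `1e-8`).
#' @return list with `alpha` (length r), `intercept`, `iterations`,
#'   `logLik`.
#' @export
pclrCoefficients <- function(E, y, r, maxIter = 100L, tol = 1e-8) {
  if (r < 1L || r > E@t) stop("r must be in 1..t")
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("y must be binary with both classes present")
  Z <- cbind(1, E@Z[, seq_len(r), drop = FALSE])
  n <- nrow(Z)
  beta <- numeric(r + 1L)
  ll <- -n * log(2)
  for (it in seq_len(maxIter)) {
    eta <- drop(Z %*% beta)
    phat <- stats::plogis(eta)
    if (all(abs(y - phat) < 1e-6))
      stop("separation detected in principal components logistic regression (r = ",
           r, "): fitted probabilities reached the data")
    w <- pmax(phat * (1 - phat), 1e-10)
    zwork <- eta + (y - phat) / w
    fit <- stats::lm.wfit(Z, zwork, w)
    beta <- fit$coefficients
    if (anyNA(beta) || !all(is.finite(beta)))
      stop("separation detected in principal components logistic regression (r = ",
           r, "): coefficients diverged")
    eta <- drop(Z %*% beta)
    llNew <- sum(y * eta - log1p(exp(eta)))
    if (abs(llNew - ll) < tol * (abs(ll) + tol)) {
      return(list(alpha = unname(beta[-1L]), intercept = unname(beta[1L]),
                  iterations = it, logLik = llNew))
    }
    ll <- llNew
  }
  stop("principal components logistic regression did not converge in ",
       maxIter, " iterations")
}
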