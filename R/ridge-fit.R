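#' Control options for the CLG ridge-logistic solver
#'
#' The CLG algorithm is a cyclic coordinate descent with per-coordinate
#' trust regions: each coefficient takes a Newton step computed with an
#' upper bound on the logistic curvature over the trust interval,
#' clipped to the region, and the region is then rescaled to
#' `max(2|step|, region/2)`.  The sweep converges when the total
#' absolute change of the linear predictors, relative to their total
#' magnitude, falls below `tol`.
#'
#' @param maxSweeps maximum number of full coordinate sweeps (default 200).
#' @param tol convergence threshold on
#'   `sum |delta eta| / (1 + sum |eta|)` per sweep (default `1e-4`).
#' @param trustDeltaInit initial trust-region half-width (default 1).
#' @param curvFloor lower floor on the per-coordinate curvature,
#'   guarding against degenerate steps (default `1e-10`).
#' @return a list of class `"clgControl"`.
#' @export
clgControl <- function(maxSweeps = 200L, tol = 1e-4, trustDeltaInit = 1,
                       curvFloor = 1e-10) {
  stopifnot(maxSweeps > 0, tol > 0, trustDeltaInit > 0, curvFloor > 0)
  structure(list(maxSweeps = as.integer(maxSweeps), tol = tol,
                 trustDeltaInit = trustDeltaInit, curvFloor = curvFloor),
            class = "clgControl")
}

# assemble a RidgeModel from standardized-scale coefficients
.backScale <- function(D, betaStd, interceptStd, family, k, rHat, diagnostics) {
  beta <- betaStd / D@colScales
  int0 <- if (family == "linear") D@yMean else interceptStd
  intercept <- int0 - sum(beta * D@colMeans)
  diagnostics$betaStd <- betaStd
  diagnostics$interceptStd <- interceptStd
  new("RidgeModel", family = family, snpId = D@snpId,
      beta = unname(beta), intercept = intercept, k = k,
      rHat = as.integer(rHat), diagnostics = diagnostics)
}

#' Fit linear ridge regression in closed form
#'
#' Ridge coefficients `(X'X + kI)^{-1} X'y` computed through the
#' eigendecomposition of the design:
#' `betaStd = Q (Lambda + kI)^{-1} Z' y`, so no p x p matrix is ever
#' inverted.  Coefficients are returned on the original
#' minor-allele-count scale with the intercept implied by the stored
#' standardization.
#'
#' `k = 0` (ordinary least squares) is permitted only when the design
#' has full column rank (`t = p <= n`).
#'
#' @param D a [StandardizedDesign-class] (linear family).
#' @param E the matching [EigenSystem-class].
#' @param k non-negative shrinkage parameter.
#' @param yCentred centred response; defaults to `D@y`.
#' @param rHat optional number of components behind an automatic `k`
#'   (recorded in the model).
#' @param trace optional [ShrinkageResult-class] stored in diagnostics.
#' @return a [RidgeModel-class].
#' @export
fitRidgeLinear <- function(D, E, k, yCentred = D@y, rHat = NA_integer_,
                           trace = NULL) {
  if (k < 0) stop("k must be non-negative")
  if (k == 0 && E@t < D@p)
    stop("k = 0 requires a full-column-rank design (t = p <= n); ",
         "got t = ", E@t, ", p = ", D@p)
  coefs <- drop(crossprod(E@Z, yCentred)) / (E@lambdas + k)
  betaStd <- drop(E@Q %*% coefs)
  diag <- list(converged = TRUE, iterations = 0L,
               fitted = drop(E@Z %*% coefs))
  if (!is.null(trace)) diag$trace <- trace
  .backScale(D, betaStd, 0, "linear", k, rHat, diag)
}

#' Fit ridge logistic regression by cyclic coordinate descent (CLG)
#'
#' Minimises `-logLik(beta) + k * sum(beta^2)` (intercept unpenalised)
#' by the CLG algorithm: cyclic coordinate-wise damped Newton steps with
#' per-coordinate trust regions, maintaining the vector of linear
#' predictors incrementally so each coordinate update costs O(n).  The
#' ridge penalty guarantees a finite optimum even for separable data.
#'
#' @param D a [StandardizedDesign-class] (logistic family).
#' @param y binary 0/1 response; defaults to `D@y`.
#' @param k positive shrinkage parameter.
#' @param opts a [clgControl()] list.
#' @param penaltyFactor curvature convention: 2 (default) for the
#'   `k * sum(beta^2)` objective, 1 for `k/2 * sum(beta^2)`.
#' @param init optional warm start, a list with `beta` (standardized
#'   scale) and `intercept`.
#' @return a [RidgeModel-class]; `diagnostics` holds the sweep count,
#'   per-sweep objective trace, convergence flag and the
#'   standardized-scale coefficients.
#' @export
fitRidgeLogisticCLG <- function(D, y = D@y, k, opts = clgControl(),
                                penaltyFactor = 2, init = NULL) {
  if (k <= 0) stop("k must be positive for the logistic family")
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L)
    stop("y must be binary with both classes present")
  beta0 <- if (is.null(init)) numeric(D@p) else init$beta
  int0 <- if (is.null(init)) 0 else init$intercept
  res <- .clgFit(D@X, as.numeric(y), k, opts$maxSweeps, opts$tol,
                 opts$trustDeltaInit, opts$curvFloor, penaltyFactor,
                 beta0, int0)
  if (!res$converged)
    warning("CLG did not converge in ", opts$maxSweeps, " sweeps")
  diag <- list(converged = res$converged, iterations = res$sweeps,
               objective = res$objective, fitted = stats::plogis(res$eta),
               penaltyFactor = penaltyFactor)
  .backScale(D, res$beta, res$intercept, "logistic", k, NA_integer_, diag)
}

#' Predictions from a fitted ridge model
#'
#' Columns of `newdata` are matched to the model's SNPs by identifier
#' (reordering is permitted; missing SNPs are an error).  The linear
#' family returns `intercept + G beta`; the logistic family returns
#' probabilities through the inverse logit.
#'
#' @param object a [RidgeModel-class].
#' @param newdata a [GenotypeMatrix-class].
#' @param type `"response"` (default: probabilities for the logistic
#'   family) or `"link"` (linear predictor).
#' @return numeric vector, one value per row of `newdata`.
#' @aliases predict,RidgeModel-method
#' @export
setMethod("predict", "RidgeModel", function(object, newdata,
                                            type = c("response", "link")) {
  type <- match.arg(type)
  idx <- match(object@snpId, newdata@snpId)
  if (anyNA(idx))
    stop("newdata is missing model SNPs: ",
         paste(utils::head(object@snpId[is.na(idx)], 5L), collapse = ", "))
  G <- newdata@values[, idx, drop = FALSE]
  eta <- object@intercept + unname(drop(G %*% object@beta))
  if (object@family == "logistic" && type == "response") {
    p <- stats::plogis(eta)
    eps <- .Machine$double.eps
    pmin(pmax(p, eps), 1 - eps)
  } else eta
})

#' Automatic ridge regression for genotype data
#'
#' End-to-end pipeline: standardize the genotypes to correlation form,
#' eigendecompose the design, compute PCR (linear) or PCLR (logistic)
#' coefficients, select the number of components and shrinkage
#' parameter by the degrees-of-freedom rule, and fit the ridge model at
#' the selected `kHat`.  The selection trace is kept in the model
#' diagnostics.
#'
#' @param G a [GenotypeMatrix-class] of training genotypes.
#' @param y phenotype vector (continuous, or 0/1 for logistic).
#' @param family `"linear"` or `"logistic"`.
#' @param k `"auto"` (default) for the degrees-of-freedom rule, or a
#'   positive number to skip selection and fit at that value.
#' @param rule `"df"` (default) selects `r` by the degrees-of-freedom
#'   match; `"max"` uses all components with non-zero eigenvalues
#'   (`r = t`), included as the reference rule it improves upon.
#' @param thinBp optional window (base pairs): the selection of `kHat`
#'   is carried out on a panel thinned with [thinByPosition()], and the
#'   final model is then fitted on the full panel at that `kHat`.
#' @param rGrid optional candidate grid for the logistic selection.
#' @param fitOptions [clgControl()] options for logistic fits.
#' @param penaltyFactor logistic penalty curvature convention (see
#'   [fitRidgeLogisticCLG()]).
#' @param verbose log the chosen `rHat`, `kHat` and degrees of freedom.
#' @return a [RidgeModel-class].
#' @examples
#' sim <- simulateGwasStudy(p = 300, nTrain = 120, nTest = 60,
#'                          nCausal = 10, seed = 7)
#' fit <- autoRidge(sim$train$genotypes, sim$train$phenotype, "linear")
#' pse(sim$test$phenotype, predict(fit, sim$test$genotypes))
#' @export
autoRidge <- function(G, y, family = c("linear", "logistic"), k = "auto",
                      rule = c("df", "max"), thinBp = NULL, rGrid = NULL,
                      fitOptions = clgControl(), penaltyFactor = 2,
                      verbose = FALSE) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  D <- standardizeGenotypes(G, y, family)
  E <- eigenDecompose(D)
  S <- NULL
  rSel <- NA_integer_
  if (identical(k, "auto")) {
    if (!is.null(thinBp)) {
      Gt <- thinByPosition(G, thinBp)
      Dt <- standardizeGenotypes(Gt, y, family)
      Et <- eigenDecompose(Dt)
    } else { Dt <- D; Et <- E }
    if (family == "linear") {
      S <- selectRLinear(Et, Dt@y)
    } else {
      S <- selectRLogistic(Et, Dt, Dt@y, rGrid = rGrid,
                           fitOptions = fitOptions,
                           penaltyFactor = penaltyFactor)
    }
    if (rule == "max") {
      rMax <- max(S@rGrid[!is.na(S@kR)])
      rSel <- rMax
      kUse <- S@kR[match(rMax, S@rGrid)]
      # with all components the PCR fit can be numerically perfect, driving
      # k to 0; floor it so the (near-interpolating) ridge fit exists
      kFloor <- 1e-12 * max(E@lambdas)
      if (!is.finite(kUse) || kUse < kFloor) kUse <- kFloor
    } else {
      rSel <- S@rHat
      kUse <- S@kHat
    }
    if (verbose)
      message(sprintf("autoRidge [%s, rule=%s]: rHat = %d, kHat = %.6g, df = %.3f",
                      family, rule, rSel, kUse,
                      S@dfR[match(rSel, S@rGrid)]))
  } else {
    kUse <- as.numeric(k)
    if (!is.finite(kUse) || kUse < 0) stop("k must be 'auto' or a non-negative number")
  }
  if (family == "linear") {
    fit <- fitRidgeLinear(D, E, kUse, rHat = rSel, trace = S)
  } else {
    fit <- fitRidgeLogisticCLG(D, D@y, kUse, opts = fitOptions,
                               penaltyFactor = penaltyFactor)
    fit@rHat <- as.integer(rSel)
    if (!is.null(S)) fit@diagnostics$trace <- S
  }
  fit
}

#' @rdname RidgeModel-class
#' @export
setMethod("coefOriginal", "RidgeModel",
          function(object) stats::setNames(object@beta, object@snpId))

#' @rdname RidgeModel-class
#' @export
setMethod("interceptOriginal", "RidgeModel", function(object) object@intercept)

#' @rdname RidgeModel-class
#' @export
setMethod("kHat", "RidgeModel", function(object) object@k)

#' @rdname RidgeModel-class
#' @export
setMethod("rHat", "RidgeModel", function(object) object@rHat)

setMethod("show", "RidgeModel", function(object) {
  cat(sprintf("RidgeModel (%s family): %d SNPs\n",
              object@family, length(object@beta)))
  cat(sprintf("  k = %.6g", object@k))
  if (!is.na(object@rHat)) cat(sprintf(" (automatic, rHat = %d)", object@rHat))
  cat("\n")
  cat(sprintf("  intercept = %.6g\n", object@intercept))
  if (!is.null(object@diagnostics$converged))
    cat(sprintf("  converged: %s\n", object@diagnostics$converged))
  invisible(NULL)
})

#' Write / read a fitted ridge model
#'
#' Tab-delimited serialisation: a header block (`family`, `k`, `rHat`,
#' `intercept`, as `#key<TAB>value` lines) followed by a two-column
#' table of `snp_id` and original-scale coefficient.  Values are written
#' at full precision so the round trip is exact.
#'
#' @param M a [RidgeModel-class].
#' @param path output file.
#' @return `writeRidgeModel` returns `path` invisibly; `readRidgeModel`
#'   returns the [RidgeModel-class].
#' @export
writeRidgeModel <- function(M, path) {
  hdr <- c(paste0("#family\t", M@family),
           paste0("#k\t", format(M@k, digits = 17)),
           paste0("#rHat\t", M@rHat),
           paste0("#intercept\t", format(M@intercept, digits = 17)),
           "snp_id\tbeta")
  body <- paste(M@snpId, format(M@beta, digits = 17, trim = TRUE), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname writeRidgeModel
#' @export
readRidgeModel <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  vals <- stats::setNames(kv[, 2L], kv[, 1L])
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  new("RidgeModel", family = vals[["family"]], snpId = as.character(tab$snp_id),
      beta = as.numeric(tab$beta), intercept = as.numeric(vals[["intercept"]]),
      k = as.numeric(vals[["k"]]),
      rHat = suppressWarnings(as.integer(vals[["rHat"]])),
      diagnostics = list())
}
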