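#' @import methods
NULL

#' GenotypeMatrix: SNP minor-allele counts with marker metadata
#'
#' Container for a genotype panel of `n` individuals typed at `p` SNPs.
#' Entries are minor-allele counts coded 0, 1, 2; missing values are never
#' stored (they must be resolved when the data are loaded, see
#' [readGenotypes()]).  SNPs carry an identifier, a chromosome label and a
#' base-pair position; within each chromosome SNPs are kept in
#' non-decreasing position order.
#'
#' @slot values integer matrix, individuals in rows, SNPs in columns,
#'   entries in \{0, 1, 2\}.
#' @slot snpId character vector of unique SNP identifiers (column names).
#' @slot chrom character vector of chromosome labels, one per SNP.
#' @slot posBp integer vector of base-pair positions, one per SNP.
#' @slot sampleId character vector of sample identifiers (row names).
#'
#' @seealso [GenotypeMatrix()], [readGenotypes()], [thinByPosition()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
         slots = c(values = "matrix",
                   snpId = "character",
                   chrom = "character",
                   posBp = "integer",
                   sampleId = "character"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (anyNA(v))
    msg <- c(msg, "genotype values contain NA; resolve missingness at load time")
  else if (!all(v == 0L | v == 1L | v == 2L))
    msg <- c(msg, "genotype values must be minor-allele counts in {0, 1, 2}")
  p <- ncol(v); n <- nrow(v)
  if (length(object@snpId) != p) msg <- c(msg, "snpId length must equal ncol(values)")
  if (length(object@chrom) != p) msg <- c(msg, "chrom length must equal ncol(values)")
  if (length(object@posBp) != p) msg <- c(msg, "posBp length must equal ncol(values)")
  if (length(object@sampleId) != n) msg <- c(msg, "sampleId length must equal nrow(values)")
  if (anyDuplicated(object@snpId)) msg <- c(msg, "snpId must be unique")
  if (length(object@posBp) && any(object@posBp < 0L)) msg <- c(msg, "posBp must be non-negative")
  if (p > 1L) {
    ord <- unlist(lapply(split(object@posBp, factor(object@chrom, unique(object@chrom))),
                         function(x) !is.unsorted(x)), use.names = FALSE)
    if (!all(ord)) msg <- c(msg, "posBp must be non-decreasing within each chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' StandardizedDesign: predictors in correlation form
#'
#' The design matrix `X` obtained by centring each genotype column and
#' scaling it to unit Euclidean norm, so that `crossprod(X)` is in
#' correlation form (unit diagonal).  The column means and scales are
#' retained so that coefficients fitted on the standardized scale can be
#' returned to the original minor-allele-count scale.  For a continuous
#' phenotype the response is stored centred with its mean in `yMean`; for
#' a binary phenotype the raw 0/1 labels are stored.
#'
#' @slot X numeric matrix, n x p, centred unit-norm columns.
#' @slot colMeans,colScales numeric, per-column centre and scale.
#' @slot y numeric response: centred values (linear) or 0/1 labels (logistic).
#' @slot yMean numeric(1) response mean (linear family), else numeric(0).
#' @slot family `"linear"` or `"logistic"`.
#' @slot n,p integer dimensions.
#' @slot snpId character SNP identifiers for the columns of `X`.
#'
#' @seealso [standardizeGenotypes()]
#' @exportClass StandardizedDesign
setClass("StandardizedDesign",
         slots = c(X = "matrix",
                   colMeans = "numeric",
                   colScales = "numeric",
                   y = "numeric",
                   yMean = "numeric",
                   family = "character",
                   n = "integer",
                   p = "integer",
                   snpId = "character"))

setValidity("StandardizedDesign", function(object) {
  msg <- character()
  if (!object@family %in% c("linear", "logistic"))
    msg <- c(msg, "family must be 'linear' or 'logistic'")
  if (nrow(object@X) != object@n || ncol(object@X) != object@p)
    msg <- c(msg, "dim(X) must equal (n, p)")
  if (length(object@colMeans) != object@p || length(object@colScales) != object@p)
    msg <- c(msg, "colMeans/colScales must have length p")
  if (any(object@colScales <= 0))
    msg <- c(msg, "colScales must be positive (constant columns are rejected)")
  if (length(object@y) != object@n)
    msg <- c(msg, "y must have length n")
  if (length(msg)) msg else TRUE
})

#' EigenSystem: eigendecomposition of the standardized design
#'
#' Eigenvectors `Q` and eigenvalues `lambdas` of `crossprod(X)` for a
#' [StandardizedDesign], together with the principal component scores
#' `Z = X Q`.  Only the `t` eigenvalues above a relative tolerance are
#' retained; `t <= min(n - 1, p)` because the columns of `X` are centred.
#' The decomposition is computed from the n x p matrix `X` itself (via the
#' n x n or p x p Gram matrix, whichever is smaller), so no p x p matrix is
#' formed when `p > n`.
#'
#' @slot Q numeric p x t matrix of orthonormal eigenvectors.
#' @slot lambdas numeric vector of t positive eigenvalues, descending.
#' @slot Z numeric n x t matrix of principal component scores, `Z = X Q`,
#'   satisfying `crossprod(Z) = diag(lambdas)`.
#' @slot t integer retained rank.
#'
#' @seealso [eigenDecompose()], [pcrCoefficients()]
#' @exportClass EigenSystem
setClass("EigenSystem",
         slots = c(Q = "matrix",
                   lambdas = "numeric",
                   Z = "matrix",
                   t = "integer"))

setValidity("EigenSystem", function(object) {
  msg <- character()
  t <- object@t
  if (length(object@lambdas) != t) msg <- c(msg, "lambdas must have length t")
  if (ncol(object@Q) != t || ncol(object@Z) != t) msg <- c(msg, "Q and Z must have t columns")
  if (t > 1L && is.unsorted(rev(object@lambdas))) msg <- c(msg, "lambdas must be descending")
  if (t > 0L && any(object@lambdas <= 0)) msg <- c(msg, "retained lambdas must be positive")
  if (length(msg)) msg else TRUE
})

#' ShrinkageResult: the degrees-of-freedom shrinkage selection trace
#'
#' Per-candidate trace of the semi-automatic shrinkage selection.  For
#' each candidate number of principal components `r`, the shrinkage
#' parameter `k_r` is computed from the first `r` principal-component
#' regression coefficients (with the residual variance estimate for the
#' linear family) and the effective degrees of freedom for variance of
#' the corresponding ridge fit, `df(k_r) = sum(lambda^2/(lambda+k_r)^2)`
#' (linear) or `tr(H^2)` of the weighted hat matrix (logistic), is
#' recorded.  The selected `rHat` minimises `|df(k_r) - r|`, ties broken
#' toward the smaller `r`; `kHat = k_{rHat}`.
#'
#' @slot family `"linear"` or `"logistic"`.
#' @slot rGrid integer candidates r (increasing).
#' @slot alphaSqCum cumulative sum of squared PCR/PCLR coefficients per r.
#' @slot sigma2R residual variance estimate per r (linear family; else empty).
#' @slot kR shrinkage parameter per r.
#' @slot dfR effective degrees of freedom for variance at `kR`, per r.
#' @slot dfModelR effective model degrees of freedom `tr(H)` at `kR`
#'   (linear family; recorded for diagnostics, not used for selection).
#' @slot rHat,kHat the selected number of components and shrinkage parameter.
#'
#' @seealso [selectRLinear()], [selectRLogistic()], [writeShrinkageTrace()]
#' @exportClass ShrinkageResult
setClass("ShrinkageResult",
         slots = c(family = "character",
                   rGrid = "integer",
                   alphaSqCum = "numeric",
                   sigma2R = "numeric",
                   kR = "numeric",
                   dfR = "numeric",
                   dfModelR = "numeric",
                   rHat = "integer",
                   kHat = "numeric"))

setValidity("ShrinkageResult", function(object) {
  msg <- character()
  m <- length(object@rGrid)
  if (length(object@kR) != m || length(object@dfR) != m)
    msg <- c(msg, "kR and dfR must align with rGrid")
  if (m > 0L && !(object@rHat %in% object@rGrid))
    msg <- c(msg, "rHat must be an element of rGrid")
  if (m > 0L && any(object@kR[is.finite(object@kR)] < 0))
    msg <- c(msg, "kR must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RidgeModel: a fitted ridge regression model on the genotype scale
#'
#' Coefficients of a linear or logistic ridge fit, returned to the
#' original minor-allele-count scale, with the intercept implied by the
#' standardization.  Predictions on new genotype data are obtained with
#' [predict()][predict,RidgeModel-method].
#'
#' @slot family `"linear"` or `"logistic"`.
#' @slot snpId character SNP identifiers, aligned with `beta`.
#' @slot beta numeric per-minor-allele-count effects (original scale).
#' @slot intercept numeric(1).
#' @slot k numeric(1) shrinkage parameter used in the fit.
#' @slot rHat integer(1) number of components behind the automatic choice
#'   of `k` (`NA` when `k` was supplied directly).
#' @slot diagnostics list: convergence information, the training linear
#'   predictors, and (for automatic fits) the [ShrinkageResult] trace.
#'
#' @seealso [autoRidge()], [fitRidgeLinear()], [fitRidgeLogisticCLG()]
#' @exportClass RidgeModel
setClass("RidgeModel",
         slots = c(family = "character",
                   snpId = "character",
                   beta = "numeric",
                   intercept = "numeric",
                   k = "numeric",
                   rHat = "integer",
                   diagnostics = "list"))

setValidity("RidgeModel", function(object) {
  msg <- character()
  if (!object@family %in% c("linear", "logistic"))
    msg <- c(msg, "family must be 'linear' or 'logistic'")
  if (length(object@beta) != length(object@snpId))
    msg <- c(msg, "beta and snpId must align")
  if (!all(is.finite(object@beta)))
    msg <- c(msg, "beta must be finite")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  if (length(msg)) msg else TRUE
})
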