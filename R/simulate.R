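# set the RNG seed for the duration of a call, restoring the caller's
# stream on exit; no-op when seed is NULL
.seedGuard <- function(seed) {
  if (is.null(seed)) return(function() NULL)
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  function() if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
}

#' Simulate a haplotype pool with MAF and LD structure
#'
#' Generates a panel of binary haplotypes emulating a panmictic
#' population sample over a contiguous genomic region: allele
#' frequencies follow a `1/f` site-frequency spectrum truncated below
#' at `mafFloor`, SNP positions are uniform over the region, and
#' linkage disequilibrium between nearby SNPs is induced by a
#' first-order latent Gaussian process whose autocorrelation is
#' `ldStrength * exp(-distance / ldDecayBp)`.  Each haplotype carries
#' allele 1 at SNP j when its latent value falls below the `f_j`
#' quantile, so marginal allele frequencies match the target spectrum
#' exactly in distribution.
#'
#' Defaults mirror a forward-in-time simulated panel of 21,000
#' haplotypes at 20,000 SNPs over ~7 Mb.
#'
#' @param p number of SNPs.
#' @param nHap number of haplotypes in the pool.
#' @param regionBp length of the simulated region in base pairs.
#' @param mafFloor lower bound of the allele-frequency spectrum.
#' @param ldStrength adjacent-SNP latent autocorrelation at zero
#'   distance, in `[0, 1)`.
#' @param ldDecayBp distance scale (bp) of LD decay.
#' @param seed optional integer seed (caller's RNG stream is restored).
#' @return a list of class `"haplotypePool"`: integer matrix
#'   `haplotypes` (`nHap` x `p`), `freq` (target allele frequencies),
#'   `posBp`, `snpId`, `chrom`, and the generating parameters.
#' @export
simulateHaplotypePool <- function(p = 20000L, nHap = 21000L, regionBp = 7e6,
                                  mafFloor = 0.01, ldStrength = 0.7,
                                  ldDecayBp = 10000, seed = NULL) {
  if (p < 1L || nHap < 2L || regionBp <= 0) stop("infeasible pool parameters")
  if (ldStrength < 0 || ldStrength >= 1) stop("ldStrength must lie in [0, 1)")
  if (mafFloor <= 0 || mafFloor >= 0.5) stop("mafFloor must lie in (0, 0.5)")
  restore <- .seedGuard(seed); on.exit(restore())
  posBp <- sort(as.integer(floor(stats::runif(p, 0, regionBp))))
  freq <- mafFloor * (0.5 / mafFloor)^stats::runif(p)   # truncated 1/f spectrum
  H <- matrix(0L, nHap, p)
  thr <- stats::qnorm(freq)
  g <- stats::rnorm(nHap)
  H[, 1L] <- as.integer(g < thr[1L])
  if (p > 1L) {
    a <- ldStrength * exp(-diff(posBp) / ldDecayBp)
    for (j in 2:p) {
      g <- a[j - 1L] * g + sqrt(1 - a[j - 1L]^2) * stats::rnorm(nHap)
      H[, j] <- as.integer(g < thr[j])
    }
  }
  structure(list(haplotypes = H, freq = freq, posBp = posBp,
                 snpId = paste0("snp", seq_len(p)),
                 chrom = rep("1", p), mafFloor = mafFloor,
                 ldStrength = ldStrength, ldDecayBp = ldDecayBp,
                 regionBp = regionBp),
            class = "haplotypePool")
}

#' Draw diploid genotypes from a haplotype pool
#'
#' Each individual's genotype is the sum of two haplotypes sampled
#' uniformly with replacement from the pool, giving minor-allele counts
#' in \{0, 1, 2\}.
#'
#' @param pool a pool from [simulateHaplotypePool()].
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return a [GenotypeMatrix-class].
#' @export
drawGenotypes <- function(pool, n, seed = NULL) {
  if (!inherits(pool, "haplotypePool")) stop("pool must be a haplotypePool")
  restore <- .seedGuard(seed); on.exit(restore())
  nHap <- nrow(pool$haplotypes)
  i1 <- sample.int(nHap, n, replace = TRUE)
  i2 <- sample.int(nHap, n, replace = TRUE)
  GenotypeMatrix(pool$haplotypes[i1, , drop = FALSE] +
                   pool$haplotypes[i2, , drop = FALSE],
                 snpId = pool$snpId, chrom = pool$chrom, posBp = pool$posBp)
}

# indices of SNPs whose MAF falls in the causal window
.eligibleCausal <- function(maf, range) {
  which(maf >= range[1L] & maf <= range[2L])
}

#' Simulate a continuous phenotype with sparse causal effects
#'
#' Samples `nCausal` causal SNPs uniformly among those whose minor
#' allele frequency lies in `causalMafRange` (the common-disease
#' common-variant window), assigns each a positive effect size drawn
#' from `U[effectRange]`, and generates
#' `Y = G beta + epsilon`, `epsilon ~ N(0, sigma^2)` on the raw
#' minor-allele-count scale.
#'
#' @param G a [GenotypeMatrix-class].
#' @param nCausal number of causal SNPs (default 200).
#' @param causalMafRange MAF window for causal SNPs (default 0.10-0.15).
#' @param effectRange uniform effect-size bounds (default 0.05-0.1).
#' @param sigma error standard deviation (default 1).
#' @param maf per-SNP minor allele frequencies used for eligibility;
#'   defaults to the empirical MAF of `G` (pass the pool frequencies
#'   when available).
#' @param seed optional integer seed.
#' @return list: `phenotype`, `betaTrue` (length p, `nCausal` non-zero
#'   entries), `causalIdx`.
#' @export
simulateContinuous <- function(G, nCausal = 200L,
                               causalMafRange = c(0.10, 0.15),
                               effectRange = c(0.05, 0.1), sigma = 1,
                               maf = NULL, seed = NULL) {
  restore <- .seedGuard(seed); on.exit(restore())
  if (is.null(maf)) maf <- mafGenotypes(G)
  elig <- .eligibleCausal(maf, causalMafRange)
  if (length(elig) < nCausal)
    stop("only ", length(elig), " SNPs fall in the causal MAF window; ",
         nCausal, " required")
  causalIdx <- sort(sample(elig, nCausal))
  betaTrue <- numeric(ncol(G@values))
  betaTrue[causalIdx] <- stats::runif(nCausal, effectRange[1L], effectRange[2L])
  y <- drop(G@values %*% betaTrue) + stats::rnorm(nrow(G@values), 0, sigma)
  list(phenotype = y, betaTrue = betaTrue, causalIdx = causalIdx)
}

#' Simulate a balanced case-control sample from a haplotype pool
#'
#' Individuals are generated one batch at a time as sums of two random
#' haplotypes; each individual's case probability is the inverse logit
#' of a centred additive predictor
#' `eta_i = sum_j beta_j (g_ij - 2 f_j)` (centring at twice the pool
#' allele frequencies keeps the prevalence near one half, so a balanced
#' sample is reachable), and case status is Bernoulli(`p_i`).  Sampling
#' repeats until exactly `n/2` cases and `n/2` controls are retained.
#'
#' @param pool a pool from [simulateHaplotypePool()].
#' @param n total sample size (even; `n/2` cases and `n/2` controls).
#' @param nCausal number of causal SNPs (default 200).
#' @param causalMafRange MAF window for causal SNPs (default 0.10-0.15).
#' @param logOrRange uniform log-odds-ratio bounds (default 0.1-0.5).
#' @param betaTrue optionally reuse a coefficient vector (e.g. to draw
#'   a test set under the training model).
#' @param seed optional integer seed.
#' @param maxFactor abort if more than `maxFactor * n` individuals must
#'   be generated (acceptance too low: re-centre the predictor).
#' @return list: `genotypes` ([GenotypeMatrix-class]), `phenotype`
#'   (0/1), `betaTrue`, `causalIdx`.
#' @export
simulateBinary <- function(pool, n, nCausal = 200L,
                           causalMafRange = c(0.10, 0.15),
                           logOrRange = c(0.1, 0.5), betaTrue = NULL,
                           seed = NULL, maxFactor = 50) {
  if (!inherits(pool, "haplotypePool")) stop("pool must be a haplotypePool")
  if (n %% 2L != 0L) stop("n must be even (equal cases and controls)")
  restore <- .seedGuard(seed); on.exit(restore())
  p <- length(pool$freq)
  hapMaf <- pmin(colMeans(pool$haplotypes), 1 - colMeans(pool$haplotypes))
  if (is.null(betaTrue)) {
    elig <- .eligibleCausal(hapMaf, causalMafRange)
    if (length(elig) < nCausal)
      stop("only ", length(elig), " SNPs fall in the causal MAF window")
    causalIdx <- sort(sample(elig, nCausal))
    betaTrue <- numeric(p)
    betaTrue[causalIdx] <- stats::runif(nCausal, logOrRange[1L], logOrRange[2L])
  } else causalIdx <- which(betaTrue != 0)
  centre <- 2 * colMeans(pool$haplotypes)
  offset <- sum(betaTrue * centre)
  need <- c(control = n / 2L, case = n / 2L)
  got <- c(control = 0L, case = 0L)
  rowsG <- vector("list", 0L)
  status <- integer(0)
  total <- 0L
  nHap <- nrow(pool$haplotypes)
  while (any(got < need)) {
    if (total > maxFactor * n)
      stop("case/control acceptance rate too low after ", total,
           " draws; re-centre the linear predictor")
    b <- as.integer(max(n, 2L * max(need - got)))
    Gb <- pool$haplotypes[sample.int(nHap, b, TRUE), , drop = FALSE] +
      pool$haplotypes[sample.int(nHap, b, TRUE), , drop = FALSE]
    eta <- drop(Gb %*% betaTrue) - offset
    isCase <- stats::rbinom(b, 1L, stats::plogis(eta))
    total <- total + b
    for (cls in 0:1) {
      nm <- if (cls == 0L) "control" else "case"
      idx <- which(isCase == cls)
      take <- utils::head(idx, need[nm] - got[nm])
      if (length(take)) {
        rowsG[[length(rowsG) + 1L]] <- Gb[take, , drop = FALSE]
        status <- c(status, rep(cls, length(take)))
        got[nm] <- got[nm] + length(take)
      }
    }
  }
  Gm <- do.call(rbind, rowsG)
  ord <- sample.int(nrow(Gm))    # shuffle cases and controls together
  G <- GenotypeMatrix(Gm[ord, , drop = FALSE], snpId = pool$snpId,
                      chrom = pool$chrom, posBp = pool$posBp)
  list(genotypes = G, phenotype = status[ord], betaTrue = betaTrue,
       causalIdx = causalIdx)
}

#' Simulate a complete training/test study from one haplotype pool
#'
#' Convenience wrapper reproducing the standard evaluation design:
#' one haplotype pool, training and test individuals drawn from it, a
#' single causal architecture shared by both sets (200 causal SNPs with
#' MAF 10-15% by default), and a continuous
#' (`Y = G beta + N(0, 1)`, effects `U[0.05, 0.1]`) or balanced
#' case-control (log-odds ratios `U[0.1, 0.5]`) phenotype.
#'
#' @param p number of SNPs (default 20000).
#' @param nTrain,nTest training and test sample sizes (default 1000/500).
#' @param nCausal number of causal SNPs (default 200).
#' @param family `"linear"` or `"logistic"`.
#' @param pool optionally reuse an existing haplotype pool.
#' @param seed integer seed controlling the whole replicate.
#' @param ... further arguments to [simulateHaplotypePool()],
#'   [simulateContinuous()] or [simulateBinary()].
#' @return list with `train` and `test` (each `genotypes` +
#'   `phenotype`), `betaTrue`, `causalIdx`.
#' @export
simulateGwasStudy <- function(p = 20000L, nTrain = 1000L, nTest = 500L,
                              nCausal = 200L,
                              family = c("linear", "logistic"),
                              pool = NULL, seed = NULL, ...) {
  family <- match.arg(family)
  restore <- .seedGuard(seed); on.exit(restore())
  dots <- list(...)
  if (is.null(pool)) {
    poolArgs <- dots[names(dots) %in% names(formals(simulateHaplotypePool))]
    pool <- do.call(simulateHaplotypePool, c(list(p = p), poolArgs))
  }
  if (family == "linear") {
    G <- drawGenotypes(pool, nTrain + nTest)
    phenoArgs <- dots[names(dots) %in% names(formals(simulateContinuous))]
    hapFreq <- colMeans(pool$haplotypes)
    sim <- do.call(simulateContinuous,
                   c(list(G = G, nCausal = nCausal,
                          maf = pmin(hapFreq, 1 - hapFreq)), phenoArgs))
    trIdx <- seq_len(nTrain)
    list(train = list(genotypes = G[trIdx, ],
                      phenotype = sim$phenotype[trIdx]),
         test = list(genotypes = G[-trIdx, ],
                     phenotype = sim$phenotype[-trIdx]),
         betaTrue = sim$betaTrue, causalIdx = sim$causalIdx)
  } else {
    binArgs <- dots[names(dots) %in% names(formals(simulateBinary))]
    tr <- do.call(simulateBinary, c(list(pool = pool, n = nTrain,
                                         nCausal = nCausal), binArgs))
    te <- do.call(simulateBinary, c(list(pool = pool, n = nTest,
                                         betaTrue = tr$betaTrue), binArgs))
    list(train = list(genotypes = tr$genotypes, phenotype = tr$phenotype),
         test = list(genotypes = te$genotypes, phenotype = te$phenotype),
         betaTrue = tr$betaTrue, causalIdx = tr$causalIdx)
  }
}

#' Benchmark regression scenarios with known truth
#'
#' The four classic benchmark designs of Zou and Hastie's elastic-net
#' study, used here to illustrate the bias-variance decomposition of
#' prediction error across correlation structures:
#' \describe{
#'   \item{1}{n = 20, p = 8, `beta = (3, 1.5, 0, 0, 2, 0, 0, 0)`,
#'     `sigma = 3`, `cor(x_i, x_j) = 0.5^|i-j|`.}
#'   \item{2}{as scenario 1 but all coefficients equal, `beta_j = 0.85`.}
#'   \item{3}{n = 100, p = 40, `beta` = blocks (0 x10, 2 x10, 0 x10,
#'     2 x10), `sigma = 15`, equicorrelation 0.5.}
#'   \item{4}{n = 50, p = 40, `beta` = (3 x15, 0 x25), `sigma = 15`;
#'     three groups of five predictors share a common latent factor
#'     (within-group correlation ~0.99), the rest are independent noise.}
#' }
#'
#' @param id scenario number, 1-4.
#' @param n optional sample-size override (defaults to the scenario's).
#' @param seed optional integer seed.
#' @return list: `X`, `y`, `betaTrue`, `sigma`, `Sigma` (implied
#'   predictor correlation matrix), `n`, `id`.
#' @export
zouHastieScenario <- function(id, n = NULL, seed = NULL) {
  if (!id %in% 1:4) stop("id must be 1, 2, 3 or 4")
  restore <- .seedGuard(seed); on.exit(restore())
  if (id %in% c(1L, 2L)) {
    p <- 8L; nDef <- 20L; sigma <- 3
    beta <- if (id == 1L) c(3, 1.5, 0, 0, 2, 0, 0, 0) else rep(0.85, 8)
    Sigma <- 0.5^abs(outer(1:p, 1:p, "-"))
  } else if (id == 3L) {
    p <- 40L; nDef <- 100L; sigma <- 15
    beta <- rep(c(0, 2, 0, 2), each = 10L)
    Sigma <- matrix(0.5, p, p); diag(Sigma) <- 1
  } else {
    p <- 40L; nDef <- 50L; sigma <- 15
    beta <- c(rep(3, 15), rep(0, 25))
  }
  if (is.null(n)) n <- nDef
  if (id == 4L) {
    grp <- rep(1:3, each = 5L)
    Zl <- matrix(stats::rnorm(n * 3L), n, 3L)
    X <- cbind(Zl[, grp] + stats::rnorm(n * 15L, sd = 0.1),
               matrix(stats::rnorm(n * 25L), n, 25L))
    v <- 1 + 0.01
    Sigma <- diag(p)
    for (g in 1:3) {
      ii <- which(grp == g)
      Sigma[ii, ii] <- 1 / v
      diag(Sigma)[ii] <- 1
    }
  } else {
    L <- chol(Sigma)
    X <- matrix(stats::rnorm(n * p), n, p) %*% L
  }
  y <- drop(X %*% beta) + stats::rnorm(n, 0, sigma)
  list(X = X, y = y, betaTrue = beta, sigma = sigma, Sigma = Sigma,
       n = n, id = id)
}
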