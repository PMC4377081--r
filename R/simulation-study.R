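#' Run the simulation study comparing shrinkage-selection rules
#'
#' Generates replicate training/test studies from one haplotype pool and
#' evaluates out-of-sample prediction for a panel of methods:
#' \describe{
#'   \item{`auto`}{ridge at the degrees-of-freedom-selected `kHat`.}
#'   \item{`max`}{ridge with `k` computed from all principal components
#'     with non-zero eigenvalues (the reference rule the selection
#'     improves upon; linear family only).}
#'   \item{`cv`}{ridge with `k` chosen by 10-fold cross-validation over
#'     a log-spaced grid anchored at the automatic estimate.}
#'   \item{`univariate`}{rank SNPs by univariate p-value, keep the top
#'     fraction, fit unpenalised multiple regression.}
#' }
#' The linear family reports test-set prediction squared error; the
#' logistic family reports classification error and Brier score.
#'
#' One pool is simulated per study (as with a fixed reference panel);
#' genotypes, causal SNPs and phenotypes are redrawn each replicate.
#' Per-replicate seeds are derived deterministically from `seed`.
#'
#' @param family `"linear"` or `"logistic"`.
#' @param replicates number of simulation replicates (default 10).
#' @param p number of SNPs (default 20000).
#' @param nTrain,nTest sample sizes (default 1000 / 500).
#' @param nCausal causal SNPs per replicate (default 200).
#' @param methods subset of `c("auto", "max", "cv", "univariate")`.
#' @param univariateProportion fraction kept by the univariate baseline
#'   (default 0.001, i.e. the top 0.1%).
#' @param cvFolds folds for the `cv` method (default 10).
#' @param rGrid candidate grid for the logistic selection; defaults to
#'   ~25 log-spaced values of r (a coarse scan; `|df - r|` is smooth).
#' @param seed integer seed for the whole study.
#' @param poolArgs list of overrides for [simulateHaplotypePool()].
#' @param verbose print one line per replicate.
#' @return list with `perReplicate` (long data.frame: replicate, method,
#'   metric, value) and `summary` (method, metric, mean, sd; sd over
#'   replicates with denominator replicates - 1).
#' @seealso [writeEvaluationReport()]
#' @export
simulationStudy <- function(family = c("linear", "logistic"),
                            replicates = 10L, p = 20000L, nTrain = 1000L,
                            nTest = 500L, nCausal = 200L,
                            methods = c("auto", "max", "cv", "univariate"),
                            univariateProportion = 0.001, cvFolds = 10L,
                            rGrid = NULL, seed = 1L, poolArgs = list(),
                            verbose = FALSE) {
  family <- match.arg(family)
  methods <- match.arg(methods, several.ok = TRUE)
  if (family == "logistic") methods <- setdiff(methods, "max")
  base <- (as.integer(seed) %% 1000000L) * 1000L
  pool <- do.call(simulateHaplotypePool,
                  c(list(p = p, seed = base + 1L), poolArgs))
  if (family == "logistic" && is.null(rGrid)) {
    tMax <- min(nTrain - 1L, p)
    rGrid <- sort(unique(round(exp(seq(log(1), log(tMax), length.out = 25L)))))
  }
  rows <- list()
  addRow <- function(rep, method, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(replicate = rep, method = method,
                                             metric = metric, value = value)
  for (r in seq_len(replicates)) {
    repSeed <- base + 10L * r
    sim <- simulateGwasStudy(p = p, nTrain = nTrain, nTest = nTest,
                             nCausal = nCausal, family = family,
                             pool = pool, seed = repSeed)
    Gtr <- sim$train$genotypes; yTr <- sim$train$phenotype
    Gte <- sim$test$genotypes; yTe <- sim$test$phenotype
    if (family == "linear") {
      D <- standardizeGenotypes(Gtr, yTr, "linear")
      E <- eigenDecompose(D)
      S <- selectRLinear(E, D@y)
      if ("auto" %in% methods) {
        m <- fitRidgeLinear(D, E, S@kHat, rHat = S@rHat)
        addRow(r, "auto", "pse", pse(yTe, predict(m, Gte)))
      }
      if ("max" %in% methods) {
        rMax <- max(S@rGrid[!is.na(S@kR)])
        kMax <- S@kR[rMax]
        kFloor <- 1e-12 * max(E@lambdas)
        if (!is.finite(kMax) || kMax < kFloor) kMax <- kFloor
        m <- fitRidgeLinear(D, E, kMax, rHat = rMax)
        addRow(r, "max", "pse", pse(yTe, predict(m, Gte)))
      }
      if ("cv" %in% methods) {
        grid <- exp(seq(log(S@kHat / 100), log(S@kHat * 100),
                        length.out = 41L))
        cv <- cvRidge(Gtr, yTr, "linear", folds = cvFolds, kGrid = grid,
                      seed = repSeed + 1L)
        addRow(r, "cv", "pse", pse(yTe, predict(cv$model, Gte)))
      }
      if ("univariate" %in% methods) {
        ub <- univariateBaseline(Gtr, yTr, Gte,
                                 proportion = univariateProportion)
        addRow(r, "univariate", "pse", pse(yTe, ub$predTest))
      }
    } else {
      m <- autoRidge(Gtr, yTr, "logistic", rGrid = rGrid)
      ph <- predict(m, Gte)
      addRow(r, "auto", "ce", classificationError(yTe, ph))
      addRow(r, "auto", "brier", brierScore(yTe, ph))
      if ("cv" %in% methods) {
        grid <- exp(seq(log(m@k / 100), log(m@k * 100), length.out = 41L))
        cv <- cvRidge(Gtr, yTr, "logistic", folds = cvFolds, kGrid = grid,
                      seed = repSeed + 1L)
        ph <- predict(cv$model, Gte)
        addRow(r, "cv", "ce", classificationError(yTe, ph))
        addRow(r, "cv", "brier", brierScore(yTe, ph))
      }
      if ("univariate" %in% methods) {
        ub <- univariateBaseline(Gtr, yTr, Gte,
                                 proportion = univariateProportion,
                                 family = "logistic")
        addRow(r, "univariate", "ce", classificationError(yTe, ub$predTest))
        addRow(r, "univariate", "brier", brierScore(yTe, ub$predTest))
      }
    }
    if (verbose) {
      last <- do.call(rbind, rows)
      last <- last[last$replicate == r, ]
      message(sprintf("replicate %d/%d: %s", r, replicates,
                      paste(sprintf("%s %s=%.3f", last$method, last$metric,
                                    last$value), collapse = ", ")))
    }
  }
  perReplicate <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ method + metric, perReplicate,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(method = agg$method, metric = agg$metric,
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  list(perReplicate = perReplicate, summary = summary,
       config = list(family = family, replicates = replicates, p = p,
                     nTrain = nTrain, nTest = nTest, nCausal = nCausal,
                     seed = seed))
}

#' Write a simulation-study report as a tab-delimited table
#'
#' One row per method, columns per metric holding `mean (sd)` strings,
#' mirroring the usual method-by-metric presentation of simulation
#' results.
#'
#' @param study result of [simulationStudy()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEvaluationReport <- function(study, path) {
  s <- study$summary
  methods <- unique(s$method)
  metrics <- unique(s$metric)
  out <- data.frame(method = methods)
  for (m in metrics) {
    idx <- match(methods, s$method[s$metric == m])
    sub <- s[s$metric == m, ]
    out[[m]] <- sprintf("%.3f (%.3f)", sub$mean[idx], sub$sd[idx])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
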