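# Small in-code fixtures shared across test files.

# random valid GenotypeMatrix with polymorphic columns
randomGenotypes <- function(n, p, seed = 1, maf = 0.3) {
  set.seed(seed)
  repeat {
    v <- matrix(rbinom(n * p, 2L, maf), n, p)
    if (all(apply(v, 2L, function(x) length(unique(x)) > 1L))) break
  }
  GenotypeMatrix(v, posBp = sort(sample.int(1e6, p)))
}

# small standardized design + response for algebra tests
toyDesign <- function(n = 8, p = 5, seed = 2, family = "linear") {
  G <- randomGenotypes(n, p, seed = seed)
  set.seed(seed + 100)
  y <- if (family == "linear") rnorm(n) else rbinom(n, 1L, 0.5)
  if (family == "logistic" && length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  standardizeGenotypes(G, y, family)
}

# negative penalised Bernoulli log-likelihood on the standardized scale,
# objective of the CLG solver: -logLik + (c/2) k sum(beta^2)
ridgeLogisticObjective <- function(par, X, y, k, penaltyFactor = 2) {
  eta <- par[1L] + drop(X %*% par[-1L])
  ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  -ll + 0.5 * penaltyFactor * k * sum(par[-1L]^2)
}
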