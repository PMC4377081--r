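#' Construct a GenotypeMatrix
#'
#' @param values integer matrix of minor-allele counts (0/1/2),
#'   individuals in rows, SNPs in columns.
#' @param snpId SNP identifiers; defaults to column names or `snp1..snpP`.
#' @param chrom chromosome labels per SNP; default `"1"`.
#' @param posBp base-pair positions per SNP; default `1..p` (distinct
#'   placeholder positions).
#' @param sampleId sample identifiers; defaults to row names or `ind1..indN`.
#' @return a validated [GenotypeMatrix-class] object.
#' @examples
#' G <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 1L, 0L, 2L), nrow = 3))
#' dim(G)
#' @export
GenotypeMatrix <- function(values, snpId = NULL, chrom = NULL,
                           posBp = NULL, sampleId = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  p <- ncol(values); n <- nrow(values)
  if (is.null(snpId)) snpId <- colnames(values)
  if (is.null(snpId)) snpId <- paste0("snp", seq_len(p))
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(posBp)) posBp <- seq_len(p)
  if (is.null(sampleId)) sampleId <- rownames(values)
  if (is.null(sampleId)) sampleId <- paste0("ind", seq_len(n))
  dimnames(values) <- list(sampleId, snpId)
  new("GenotypeMatrix", values = values, snpId = as.character(snpId),
      chrom = as.character(chrom), posBp = as.integer(posBp),
      sampleId = as.character(sampleId))
}

#' @rdname GenotypeMatrix-class
#' @aliases genotypes,GenotypeMatrix-method
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@values)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x) x@snpId)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("chromosomes", "GenotypeMatrix", function(x) x@chrom)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("positions", "GenotypeMatrix", function(x) x@posBp)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@sampleId)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@values))

#' @rdname GenotypeMatrix-class
#' @param i,j,drop sample (row) and SNP (column) indices; `drop` is ignored.
#' @param ... unused
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(j)) j <- match(j, x@snpId)
  GenotypeMatrix(x@values[i, j, drop = FALSE],
                 snpId = x@snpId[j], chrom = x@chrom[j],
                 posBp = x@posBp[j], sampleId = x@sampleId[i])
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs\n", d[1L], d[2L]))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(object@chrom), collapse = ", ")))
  if (d[2L] > 0L) {
    maf <- colMeans(object@values) / 2
    maf <- pmin(maf, 1 - maf)
    cat(sprintf("  MAF range: [%.3f, %.3f]\n", min(maf), max(maf)))
  }
  invisible(NULL)
})

#' Empirical minor allele frequencies
#'
#' Allele frequency of the counted allele per SNP, `colMeans(G)/2`,
#' folded to the minor side.
#'
#' @param G a [GenotypeMatrix-class]
#' @param fold fold frequencies above 0.5 to `1 - f` (default `TRUE`)
#' @return numeric vector of length `ncol(G)`
#' @export
mafGenotypes <- function(G, fold = TRUE) {
  f <- colMeans(G@values) / 2
  if (fold) f <- pmin(f, 1 - f)
  stats::setNames(f, G@snpId)
}
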