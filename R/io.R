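#' Read a genotype matrix from delimited text or PLINK .raw
#'
#' Two dialects are supported.  `"delimited"` is a tab-separated table
#' whose header row holds SNP identifiers (optionally preceded by an
#' `IID` column of sample identifiers); a sidecar map file
#' (`<path>.map`, tab-separated columns `snp_id`, `chrom`, `pos_bp`)
#' supplies marker coordinates when present.  `"plink_raw"` is the
#' PLINK `--recode A` layout: header `FID IID PAT MAT SEX PHENOTYPE`
#' followed by one column of minor-allele counts per SNP.
#'
#' Missing genotypes are a hard error by default: genotype QC and
#' imputation belong upstream.  With `impute = TRUE`, missing entries are
#' replaced by the column mean rounded to the nearest of 0, 1, 2.
#'
#' @param path file to read.
#' @param format `"delimited"` or `"plink_raw"`.
#' @param impute replace missing entries by the rounded column mean
#'   (default `FALSE`: missing values raise an error).
#' @param mapPath sidecar map file; defaults to `<path>.map` when that
#'   file exists.
#' @param phenotype for `"plink_raw"`, also return the PHENOTYPE column.
#' @return a [GenotypeMatrix-class]; if `phenotype = TRUE`, a list with
#'   elements `genotypes` and `phenotype`.
#' @seealso [writeGenotypes()]
#' @export
readGenotypes <- function(path, format = c("delimited", "plink_raw"),
                          impute = FALSE, mapPath = NULL, phenotype = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  naStrings <- if (format == "plink_raw") c("NA", "-9") else "NA"
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      na.strings = naStrings, colClasses = NA,
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  pheno <- NULL
  if (format == "plink_raw") {
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(tab) < 7L || !identical(names(tab)[1:6], lead))
      stop("malformed plink_raw file '", path,
           "': line 1 must start with 'FID IID PAT MAT SEX PHENOTYPE'")
    sampleId <- as.character(tab$IID)
    if (phenotype) pheno <- tab$PHENOTYPE
    tab <- tab[, -(1:6), drop = FALSE]
  } else {
    if (identical(names(tab)[1L], "IID")) {
      sampleId <- as.character(tab[[1L]])
      tab <- tab[, -1L, drop = FALSE]
    } else sampleId <- paste0("ind", seq_len(nrow(tab)))
  }
  vals <- as.matrix(tab)
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(vals), nrow(vals)))) &
                   !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
      stop("malformed file '", path, "': non-numeric genotype at line ",
           bad[1L, 1L] + 1L, ", SNP '", colnames(vals)[bad[1L, 2L]], "'")
    storage.mode(vals) <- "numeric"
  }
  if (anyNA(vals)) {
    if (!impute) {
      bad <- which(is.na(vals), arr.ind = TRUE)
      stop("missing genotype at line ", bad[1L, 1L] + 1L, ", SNP '",
           colnames(vals)[bad[1L, 2L]],
           "' (set impute = TRUE to mean-impute, rounded to {0,1,2})")
    }
    for (j in which(colSums(is.na(vals)) > 0L)) {
      m <- mean(vals[, j], na.rm = TRUE)
      if (is.nan(m)) stop("SNP '", colnames(vals)[j], "' is entirely missing")
      vals[is.na(vals[, j]), j] <- min(2, max(0, round(m)))
    }
  }
  if (!all(vals %in% c(0, 1, 2))) {
    bad <- which(matrix(!(vals %in% c(0, 1, 2)), nrow(vals)), arr.ind = TRUE)
    stop("genotype outside {0,1,2} at line ", bad[1L, 1L] + 1L, ", SNP '",
         colnames(vals)[bad[1L, 2L]], "'")
  }
  snpId <- colnames(tab)
  chrom <- rep("1", length(snpId)); posBp <- seq_along(snpId)
  if (is.null(mapPath)) {
    cand <- paste0(path, ".map")
    if (file.exists(cand)) mapPath <- cand
  }
  if (!is.null(mapPath)) {
    map <- utils::read.table(mapPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    idx <- match(snpId, map$snp_id)
    if (anyNA(idx))
      stop("map file '", mapPath, "' is missing SNPs: ",
           paste(utils::head(snpId[is.na(idx)], 5L), collapse = ", "))
    chrom <- as.character(map$chrom[idx])
    posBp <- as.integer(map$pos_bp[idx])
  }
  # order SNPs by position within chromosome (stable, so ties keep file order)
  ord <- order(match(chrom, unique(chrom)), posBp)
  G <- GenotypeMatrix(vals[, ord, drop = FALSE], snpId = snpId[ord],
                      chrom = chrom[ord], posBp = posBp[ord],
                      sampleId = sampleId)
  if (phenotype) list(genotypes = G, phenotype = pheno) else G
}

#' Write a genotype matrix to delimited text or PLINK .raw
#'
#' Writes the matrix in the requested dialect plus a sidecar map file
#' `<path>.map` carrying SNP coordinates, so that
#' `readGenotypes(writeGenotypes(...))` round-trips values and metadata
#' exactly.
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output file.
#' @param format `"delimited"` or `"plink_raw"`.
#' @param phenotype optional numeric vector written to the PHENOTYPE
#'   column of the plink_raw dialect (default `-9`, i.e. missing).
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(G, path, format = c("delimited", "plink_raw"),
                           phenotype = NULL) {
  format <- match.arg(format)
  vals <- G@values
  if (format == "plink_raw") {
    ph <- if (is.null(phenotype)) rep(-9, nrow(vals)) else phenotype
    out <- data.frame(FID = G@sampleId, IID = G@sampleId, PAT = 0L, MAT = 0L,
                      SEX = 0L, PHENOTYPE = ph, check.names = FALSE)
    out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  } else {
    out <- cbind(data.frame(IID = G@sampleId),
                 as.data.frame(vals, check.names = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(snp_id = G@snpId, chrom = G@chrom, pos_bp = G@posBp)
  utils::write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype vector
#'
#' One value per line, optional header `phenotype`.
#'
#' @param path file to read or write.
#' @return `readPhenotype` returns a numeric vector.
#' @export
readPhenotype <- function(path) {
  x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)[[1L]]
  if (identical(x[1L], "phenotype")) x <- x[-1L]
  as.numeric(x)
}

#' @rdname readPhenotype
#' @param y numeric phenotype vector to write.
#' @export
writePhenotype <- function(y, path) {
  writeLines(c("phenotype", format(y, digits = 17)), path)
  invisible(path)
}

#' Thin SNPs to one per base-pair window
#'
#' Within each chromosome, the genome is tiled into consecutive windows
#' of `windowBp` base pairs anchored at the first SNP's position, and the
#' first SNP by position in each non-empty window is retained (ties at
#' identical positions keep the first in file order).  Used to prevent
#' local regions of strong LD from dominating the leading principal
#' components before the shrinkage parameter is chosen; the default
#' window keeps roughly 1 SNP every 100 kb.
#'
#' Thinning is idempotent: applying the same window to an already
#' thinned panel returns it unchanged.
#'
#' @param G a [GenotypeMatrix-class].
#' @param windowBp window width in base pairs (default 100000).
#' @return the thinned [GenotypeMatrix-class].
#' @export
thinByPosition <- function(G, windowBp = 100000L) {
  if (ncol(G@values) == 0L) stop("cannot thin an empty GenotypeMatrix")
  if (windowBp <= 0) stop("windowBp must be positive")
  keep <- logical(length(G@posBp))
  for (ch in unique(G@chrom)) {
    idx <- which(G@chrom == ch)
    win <- (G@posBp[idx] - G@posBp[idx[1L]]) %/% as.integer(windowBp)
    keep[idx[!duplicated(win)]] <- TRUE
  }
  G[, which(keep)]
}
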