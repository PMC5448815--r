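#' Filter genotypes by minor allele frequency and LD pruning
#'
#' Removes monomorphic SNPs and SNPs with MAF strictly below \code{mafMin}
#' (a SNP sitting exactly at the threshold is retained), then greedily prunes
#' linkage disequilibrium left-to-right within each chromosome: walking SNPs
#' by ascending position, a SNP is dropped if any already-kept SNP within
#' \code{ldWindow} bp has squared Pearson correlation above \code{ldR2Max}.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param ldR2Max maximum tolerated pairwise r-squared within the window
#'   (default 0.99; pairs with r^2 strictly greater are pruned).
#' @param ldWindow window size in bp (default 10000).
#' @return The filtered \linkS4class{GenotypeMatrix} (possibly empty, with a
#'   warning).
#' @export
filterGenotypes <- function(G, mafMin = 0.05, ldR2Max = 0.99,
                            ldWindow = 10000L) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, ldWindow > 0)
  keep <- G@maf >= mafMin & G@maf > 0
  G2 <- subsetSnps(G, which(keep))
  if (ncol(G2@values) == 0L) {
    warning("no SNPs left after MAF filtering")
    return(G2)
  }
  ann <- G2@snpAnnotation
  vals <- G2@values
  keepIdx <- logical(ncol(vals))
  for (chr in unique(ann$chrom)) {
    onChr <- which(ann$chrom == chr)
    onChr <- onChr[order(ann$pos[onChr])]
    keptPos <- integer(0)   # indices (into vals) already kept on this chrom
    for (j in onChr) {
      near <- keptPos[abs(ann$pos[keptPos] - ann$pos[j]) <= ldWindow]
      prune <- FALSE
      if (length(near)) {
        r2 <- suppressWarnings(
          cor(vals[, j], vals[, near, drop = FALSE]))^2
        prune <- any(r2 > ldR2Max, na.rm = TRUE)
      }
      if (!prune) {
        keepIdx[j] <- TRUE
        keptPos <- c(keptPos, j)
      }
    }
  }
  out <- subsetSnps(G2, which(keepIdx))
  if (ncol(out@values) == 0L) warning("no SNPs left after LD pruning")
  out
}

#' Filter expression genes by zero-fraction and distribution skew
#'
#' Drops genes with a fraction of exact zeros strictly above
#' \code{zeroFracMax}, and genes whose values pile up in one tail: with the
#' default range interpretation a gene fails when more than \code{tailFrac}
#' of its values fall within the bottom band
#' \[min, min + tailQuantile * range\] or within the top band
#' \[max - tailQuantile * range, max\] of its own value range. The
#' \code{"quantile"} interpretation uses the empirical
#' \code{tailQuantile}/\code{1 - tailQuantile} quantiles as band edges
#' instead.
#'
#' @param E an \linkS4class{ExpressionMatrix}.
#' @param zeroFracMax maximum tolerated fraction of zero measurements
#'   (default 0.8).
#' @param tailFrac skew threshold (default 0.85).
#' @param tailQuantile tail width (default 0.2).
#' @param tailMode "range" (default) or "quantile".
#' @return Filtered \linkS4class{ExpressionMatrix}.
#' @export
filterExpression <- function(E, zeroFracMax = 0.8, tailFrac = 0.85,
                             tailQuantile = 0.2,
                             tailMode = c("range", "quantile")) {
  stopifnot(zeroFracMax > 0, zeroFracMax < 1, tailFrac > 0, tailFrac < 1,
            tailQuantile > 0, tailQuantile < 1)
  tailMode <- match.arg(tailMode)
  v <- E@values
  zeroFrac <- colMeans(v == 0)
  skewed <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    rng <- range(x)
    if (rng[1] == rng[2]) return(TRUE)  # constant gene: degenerate
    if (tailMode == "range") {
      lo <- rng[1] + tailQuantile * diff(rng)
      hi <- rng[2] - tailQuantile * diff(rng)
    } else {
      lo <- quantile(x, tailQuantile, names = FALSE)
      hi <- quantile(x, 1 - tailQuantile, names = FALSE)
    }
    mean(x <= lo) > tailFrac || mean(x >= hi) > tailFrac
  }, logical(1))
  keep <- zeroFrac <= zeroFracMax & !skewed
  if (!any(keep)) stop("all genes removed by expression filters")
  new("ExpressionMatrix", values = v[, keep, drop = FALSE],
      geneAnnotation = E@geneAnnotation[
        E@geneAnnotation$gene_id %in% colnames(v)[keep], , drop = FALSE],
      tag = E@tag)
}

#' Genotype principal components for population-structure covariates
#'
#' Columns of the returned matrix are the top left singular vectors of the
#' column-standardized genotype matrix: unit norm, mutually orthogonal, each
#' with its largest-magnitude entry made positive.
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param nPcs number of components (must be below the rank of the
#'   standardized matrix).
#' @return numeric matrix samples x nPcs with column names PC1..PCn.
#' @export
genotypePCs <- function(G, nPcs) {
  v <- G@values
  if (nPcs >= nrow(v)) stop("nPcs must be smaller than the sample count")
  sds <- apply(v, 2, sd)
  use <- sds > 0
  if (!any(use)) stop("no polymorphic SNPs available for PCs")
  z <- scale(v[, use, drop = FALSE])
  sv <- svd(z)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (nPcs > rank)
    stop(sprintf("nPcs = %d exceeds the rank (%d) of the genotype matrix",
                 nPcs, rank))
  pcs <- sv$u[, seq_len(nPcs), drop = FALSE]
  for (j in seq_len(nPcs)) {
    i <- which.max(abs(pcs[, j]))
    if (pcs[i, j] < 0) pcs[, j] <- -pcs[, j]
  }
  dimnames(pcs) <- list(rownames(v), paste0("PC", seq_len(nPcs)))
  pcs
}

#' Load a covariate table from TSV
#'
#' First column = sample id, remaining numeric columns = covariates. The
#' table must have full column rank together with an intercept.
#'
#' @param path TSV path.
#' @return numeric matrix samples x covariates.
#' @export
loadCovariates <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (qr(cbind(1, m))$rank < ncol(m) + 1L)
    stop("covariates are collinear with each other or the intercept")
  m
}
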