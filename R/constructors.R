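#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, samples x genes, with dimnames.
#' @param geneAnnotation optional data.frame (gene_id, chrom, start);
#'   genes without annotation are allowed but stay unlabeled in cis/trans
#'   classification.
#' @param tag provenance tag, one of "raw", "reconstructed-nongenetic",
#'   "simulated".
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
#' @examples
#' E <- ExpressionMatrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("g1", "g2", "g3"))))
ExpressionMatrix <- function(values, geneAnnotation = NULL, tag = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(geneAnnotation)) {
    geneAnnotation <- data.frame(gene_id = character(), chrom = character(),
                                 start = integer(),
                                 stringsAsFactors = FALSE)
  } else {
    geneAnnotation <- as.data.frame(geneAnnotation,
                                    stringsAsFactors = FALSE)
    geneAnnotation$gene_id <- as.character(geneAnnotation$gene_id)
    geneAnnotation$chrom <- as.character(geneAnnotation$chrom)
    missing <- setdiff(colnames(values), geneAnnotation$gene_id)
    if (length(missing))
      warning(sprintf(
        "%d gene(s) missing from annotation (e.g. %s); retained but excluded from cis/trans labeling",
        length(missing), missing[1]))
    geneAnnotation <-
      geneAnnotation[geneAnnotation$gene_id %in% colnames(values), ,
                     drop = FALSE]
    rownames(geneAnnotation) <- NULL
  }
  new("ExpressionMatrix", values = values,
      geneAnnotation = geneAnnotation, tag = tag)
}

#' Construct a GenotypeMatrix
#'
#' Computes per-SNP minor allele frequency from the counts; if an allele
#' coded as "minor" turns out to be the major one (frequency > 0.5) the
#' column is re-coded so stored values are always minor-allele counts.
#'
#' @param values numeric matrix samples x SNPs of allele counts with
#'   dimnames; may contain NA (resolved via \code{maxMissing}).
#' @param snpAnnotation data.frame (snp_id, chrom, pos) aligned to columns.
#' @param ploidy 1 (haploid, values 0/1) or 2 (diploid, values 0/1/2).
#' @param maxMissing maximum tolerated per-SNP missingness fraction; SNPs
#'   at or below it have missing entries imputed to the rounded SNP mean,
#'   above it the SNP is dropped with a warning. Default 0 (complete data
#'   only, missing SNPs dropped).
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(values, snpAnnotation, ploidy = 2L,
                           maxMissing = 0) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ploidy <- as.integer(ploidy)
  snpAnnotation <- as.data.frame(snpAnnotation, stringsAsFactors = FALSE)
  snpAnnotation$snp_id <- as.character(snpAnnotation$snp_id)
  snpAnnotation$chrom <- as.character(snpAnnotation$chrom)
  snpAnnotation$pos <- as.integer(snpAnnotation$pos)
  if (!identical(snpAnnotation$snp_id, colnames(values)))
    stop("snpAnnotation$snp_id must match genotype columns in order")

  missFrac <- colMeans(is.na(values))
  drop <- missFrac > maxMissing
  if (any(drop)) {
    warning(sprintf("dropping %d SNP(s) with missingness > %g (e.g. %s)",
                    sum(drop), maxMissing,
                    colnames(values)[which(drop)[1]]))
    values <- values[, !drop, drop = FALSE]
    snpAnnotation <- snpAnnotation[!drop, , drop = FALSE]
    missFrac <- missFrac[!drop]
  }
  if (ncol(values) == 0L) {
    colnames(values) <- character(0)
    return(new("GenotypeMatrix", values = values,
               snpAnnotation = snpAnnotation, maf = numeric(0),
               ploidy = ploidy))
  }
  # impute surviving missing entries to the rounded per-SNP mean count
  if (any(missFrac > 0)) {
    for (j in which(missFrac > 0)) {
      m <- round(mean(values[, j], na.rm = TRUE))
      values[is.na(values[, j]), j] <- m
    }
  }
  freq <- colMeans(values) / ploidy
  flip <- freq > 0.5
  if (any(flip)) {
    values[, flip] <- ploidy - values[, flip]
    freq[flip] <- 1 - freq[flip]
  }
  rownames(snpAnnotation) <- NULL
  new("GenotypeMatrix", values = values, snpAnnotation = snpAnnotation,
      maf = unname(freq), ploidy = ploidy)
}

#' Subset a GenotypeMatrix by SNP index or id, keeping annotation aligned
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param idx integer indices or character SNP ids.
#' @return The subset \linkS4class{GenotypeMatrix}.
#' @export
subsetSnps <- function(G, idx) {
  if (is.character(idx)) idx <- match(idx, colnames(G@values))
  new("GenotypeMatrix", values = G@values[, idx, drop = FALSE],
      snpAnnotation = G@snpAnnotation[idx, , drop = FALSE],
      maf = G@maf[idx], ploidy = G@ploidy)
}

#' Align expression, genotype and covariate samples
#'
#' Restricts all inputs to the intersection of their sample ids, preserving
#' the expression ordering.
#'
#' @param E an \linkS4class{ExpressionMatrix}.
#' @param G optional \linkS4class{GenotypeMatrix}.
#' @param C optional covariate matrix with sample rownames.
#' @return list with the aligned E (and G, C when given).
#' @export
alignSamples <- function(E, G = NULL, C = NULL) {
  ids <- rownames(E@values)
  if (!is.null(G)) ids <- ids[ids %in% rownames(G@values)]
  if (!is.null(C)) ids <- ids[ids %in% rownames(C)]
  if (length(ids) == 0L)
    stop("no overlapping samples between expression and genotype/covariates")
  out <- list(E = new("ExpressionMatrix",
                      values = E@values[ids, , drop = FALSE],
                      geneAnnotation = E@geneAnnotation, tag = E@tag))
  if (!is.null(G))
    out$G <- new("GenotypeMatrix",
                 values = G@values[ids, , drop = FALSE],
                 snpAnnotation = G@snpAnnotation, maf = G@maf,
                 ploidy = G@ploidy)
  if (!is.null(C)) out$C <- C[ids, , drop = FALSE]
  out
}
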