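#' @import methods
#' @importFrom stats cor cov var sd median pnorm pt qchisq p.adjust optimize
#'   rnorm rbinom runif prcomp quantile setNames complete.cases binom.test
#' @importFrom utils read.table write.table head
NULL

#' ExpressionMatrix: samples x genes expression values with gene annotation
#'
#' Container for a real-valued expression matrix (rows = samples, columns =
#' genes) together with per-gene genomic annotation (chromosome and 1-based
#' start position) used for cis/trans labeling. The \code{tag} slot records
#' provenance: \code{"raw"}, \code{"reconstructed-nongenetic"} (output of
#' \code{\link{reconstructNongenetic}}) or \code{"simulated"}.
#'
#' @slot values numeric matrix, samples x genes, finite, with unique dimnames.
#' @slot geneAnnotation data.frame with columns \code{gene_id},
#'   \code{chrom} (character) and \code{start} (1-based bp). Genes absent
#'   from the annotation stay in \code{values} but are excluded from
#'   cis/trans labeling.
#' @slot tag character(1) provenance tag.
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(values = "matrix", geneAnnotation = "data.frame",
                 tag = "character"),
  prototype(tag = "raw"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry sample and gene ids as dimnames")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicated sample id(s)")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicated gene id(s)")
  }
  if (is.numeric(v) && !all(is.finite(v)))
    msg <- c(msg, "all expression values must be finite")
  an <- object@geneAnnotation
  if (nrow(an) > 0) {
    need <- c("gene_id", "chrom", "start")
    if (!all(need %in% names(an)))
      msg <- c(msg, "geneAnnotation needs columns gene_id, chrom, start")
    else if (anyDuplicated(an$gene_id))
      msg <- c(msg, "duplicated gene_id in annotation")
  }
  if (length(object@tag) != 1L) msg <- c(msg, "tag must be length 1")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: samples x SNPs minor-allele counts with SNP positions
#'
#' Genotypes are coded as minor-allele counts: \{0,1,2\} for diploids or
#' \{0,1\} for haploid (yeast-like) data. Missing entries are resolved at
#' load time (mean imputation or SNP drop), so the stored matrix is complete.
#'
#' @slot values numeric matrix, samples x SNPs, entries in 0..2.
#' @slot snpAnnotation data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (1-based bp).
#' @slot maf numeric per-SNP minor allele frequency in [0, 0.5].
#' @slot ploidy integer(1), 1 or 2.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(values = "matrix", snpAnnotation = "data.frame",
                 maf = "numeric", ploidy = "integer"),
  prototype(ploidy = 2L))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || (ncol(v) > 0L && is.null(colnames(v))))
    msg <- c(msg, "values must carry sample and snp ids as dimnames")
  else if (anyDuplicated(colnames(v)))
    msg <- c(msg, "duplicated snp id(s)")
  if (anyNA(v)) msg <- c(msg, "missing genotypes must be resolved at load")
  if (is.numeric(v) && length(v) && (min(v) < 0 || max(v) > object@ploidy))
    msg <- c(msg, sprintf("genotype values must lie in 0..%d", object@ploidy))
  if (length(object@maf) != ncol(v))
    msg <- c(msg, "maf must have one entry per SNP")
  else if (length(object@maf) && (min(object@maf) < 0 ||
           max(object@maf) > 0.5 + 1e-12))
    msg <- c(msg, "maf must lie in [0, 0.5]")
  an <- object@snpAnnotation
  if (!all(c("snp_id", "chrom", "pos") %in% names(an)))
    msg <- c(msg, "snpAnnotation needs columns snp_id, chrom, pos")
  else if (!identical(as.character(an$snp_id),
                      if (is.null(colnames(v))) character(0)
                      else colnames(v)))
    msg <- c(msg, "snpAnnotation rows must match value columns in order")
  if (!(object@ploidy %in% c(1L, 2L)))
    msg <- c(msg, "ploidy must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' IcaDecomposition: Y = A S independent component decomposition
#'
#' Holds the mixing matrix \code{A} (n x k per-sample coefficients) and the
#' source matrix \code{S} (k x g per-gene weights) estimated by symmetric
#' FastICA from a per-gene mean-centered expression matrix, along with the
#' removed gene means and convergence provenance. Scale convention: each row
#' of S has unit sample variance and its largest-magnitude entry is positive;
#' A absorbs the complementary scale. Components are ordered by decreasing
#' variance of their A column.
#'
#' @slot A numeric matrix n x k.
#' @slot S numeric matrix k x g.
#' @slot k integer number of components.
#' @slot center numeric per-gene means removed before decomposition.
#' @slot seed integer seed that produced this decomposition.
#' @slot converged logical, did the fixed-point iteration reach tol.
#' @slot nIter integer iterations used in the final (accepted) run.
#' @exportClass IcaDecomposition
setClass("IcaDecomposition",
  representation(A = "matrix", S = "matrix", k = "integer",
                 center = "numeric", seed = "integer",
                 converged = "logical", nIter = "integer"))

setValidity("IcaDecomposition", function(object) {
  msg <- character()
  if (ncol(object@A) != object@k || nrow(object@S) != object@k)
    msg <- c(msg, "A columns and S rows must both equal k")
  if (ncol(object@A) && ncol(object@S) &&
      ncol(object@A) > min(nrow(object@A), ncol(object@S)))
    msg <- c(msg, "k must not exceed min(n, g)")
  if (length(object@center) != ncol(object@S))
    msg <- c(msg, "center must hold one mean per gene")
  if (length(msg)) msg else TRUE
})

#' SampleCovariance: n x n random-effect covariance matrix K
#'
#' Symmetric positive semi-definite sample covariance built either from the
#' reconstructed non-genetic expression (method \code{"confeti_i"}) or from
#' the full standardized expression matrix (method \code{"ice"}). The
#' eigendecomposition is cached for the mixed-model scan.
#'
#' @slot K numeric n x n symmetric matrix.
#' @slot method character(1): "confeti_i", "ice" or "external".
#' @slot eigenValues numeric eigenvalues (descending, clipped at 0).
#' @slot eigenVectors numeric n x n orthonormal eigenvector matrix.
#' @slot provenance list; for confeti_i holds k, r and the flagged set.
#' @exportClass SampleCovariance
setClass("SampleCovariance",
  representation(K = "matrix", method = "character",
                 eigenValues = "numeric", eigenVectors = "matrix",
                 provenance = "list"),
  prototype(provenance = list()))

setValidity("SampleCovariance", function(object) {
  K <- object@K
  msg <- character()
  if (nrow(K) != ncol(K)) msg <- c(msg, "K must be square")
  else if (max(abs(K - t(K))) > 1e-10)
    msg <- c(msg, "K must be symmetric to 1e-10")
  if (length(object@eigenValues) != nrow(K))
    msg <- c(msg, "eigendecomposition cache must match K")
  if (length(object@eigenValues) && min(object@eigenValues) < -1e-8)
    msg <- c(msg, "K must be PSD (eigenvalues >= -1e-8)")
  if (!object@method %in% c("confeti_i", "ice", "external"))
    msg <- c(msg, "method must be confeti_i, ice or external")
  if (length(msg)) msg else TRUE
})

#' ComponentFlagResult: genotype-screening result per independent component
#'
#' For each component the minimum regression p-value over all tested SNPs and
#' the SNP attaining it; \code{flagged} is the set of components whose
#' minimum p falls below the global Bonferroni threshold
#' \code{alpha / nTests} with \code{nTests = k * s_tested}.
#'
#' @slot minP numeric per-component minimum p-value.
#' @slot bestSnp character per-component SNP id attaining minP.
#' @slot flagged integer indices of candidate genetic components.
#' @slot alpha numeric family-wise level.
#' @slot nTests integer k times number of polymorphic SNPs tested.
#' @slot genotypeSubset character SNP ids tested (all SNPs if unrestricted).
#' @exportClass ComponentFlagResult
setClass("ComponentFlagResult",
  representation(minP = "numeric", bestSnp = "character",
                 flagged = "integer", alpha = "numeric",
                 nTests = "integer", genotypeSubset = "character"))

setValidity("ComponentFlagResult", function(object) {
  msg <- character()
  if (length(object@bestSnp) != length(object@minP))
    msg <- c(msg, "minP and bestSnp must align")
  thr <- object@alpha / object@nTests
  should <- which(object@minP < thr)
  if (!identical(sort(object@flagged), sort(should)))
    msg <- c(msg, "flagged must equal { j : minP_j < alpha / nTests }")
  if (length(msg)) msg else TRUE
})
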