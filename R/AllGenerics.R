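#' Accessors for confeti S4 containers
#'
#' Small accessor family: \code{exprValues}/\code{geneAnnotation} for
#' \linkS4class{ExpressionMatrix}; \code{genoValues}/\code{snpAnnotation}/
#' \code{snpMaf} for \linkS4class{GenotypeMatrix}; \code{mixingMatrix}/
#' \code{sourceMatrix} for \linkS4class{IcaDecomposition};
#' \code{covMatrix}/\code{covEigen}/\code{covMethod} for
#' \linkS4class{SampleCovariance}; \code{flaggedComponents} for
#' \linkS4class{ComponentFlagResult}.
#'
#' @param x an object of the matching class.
#' @return The underlying matrix, annotation data.frame or vector.
#' @name accessors
#' @examples
#' E <- ExpressionMatrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("g1", "g2", "g3"))))
#' dim(exprValues(E))
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))
#' @rdname accessors
#' @export
setGeneric("genoValues", function(x) standardGeneric("genoValues"))
#' @rdname accessors
#' @export
setGeneric("snpAnnotation", function(x) standardGeneric("snpAnnotation"))
#' @rdname accessors
#' @export
setGeneric("snpMaf", function(x) standardGeneric("snpMaf"))
#' @rdname accessors
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))
#' @rdname accessors
#' @export
setGeneric("sourceMatrix", function(x) standardGeneric("sourceMatrix"))
#' @rdname accessors
#' @export
setGeneric("covMatrix", function(x) standardGeneric("covMatrix"))
#' @rdname accessors
#' @export
setGeneric("covEigen", function(x) standardGeneric("covEigen"))
#' @rdname accessors
#' @export
setGeneric("covMethod", function(x) standardGeneric("covMethod"))
#' @rdname accessors
#' @export
setGeneric("flaggedComponents", function(x) standardGeneric("flaggedComponents"))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("geneAnnotation", "ExpressionMatrix", function(x) x@geneAnnotation)
#' @rdname accessors
setMethod("genoValues", "GenotypeMatrix", function(x) x@values)
#' @rdname accessors
setMethod("snpAnnotation", "GenotypeMatrix", function(x) x@snpAnnotation)
#' @rdname accessors
setMethod("snpMaf", "GenotypeMatrix", function(x) x@maf)
#' @rdname accessors
setMethod("mixingMatrix", "IcaDecomposition", function(x) x@A)
#' @rdname accessors
setMethod("sourceMatrix", "IcaDecomposition", function(x) x@S)
#' @rdname accessors
setMethod("covMatrix", "SampleCovariance", function(x) x@K)
#' @rdname accessors
setMethod("covEigen", "SampleCovariance",
  function(x) list(values = x@eigenValues, vectors = x@eigenVectors))
#' @rdname accessors
setMethod("covMethod", "SampleCovariance", function(x) x@method)
#' @rdname accessors
setMethod("flaggedComponents", "ComponentFlagResult", function(x) x@flagged)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [%s]: %d samples x %d genes (%d annotated)\n",
              object@tag, nrow(object@values), ncol(object@values),
              nrow(object@geneAnnotation)))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf(
    "GenotypeMatrix: %d samples x %d SNPs, ploidy %d, MAF range [%.3f, %.3f]\n",
    nrow(object@values), ncol(object@values), object@ploidy,
    if (length(object@maf)) min(object@maf) else NA_real_,
    if (length(object@maf)) max(object@maf) else NA_real_))
})

setMethod("show", "IcaDecomposition", function(object) {
  cat(sprintf(
    "IcaDecomposition: %d samples, %d genes, k = %d (seed %d, %s in %d iter)\n",
    nrow(object@A), ncol(object@S), object@k, object@seed,
    if (object@converged) "converged" else "NOT converged", object@nIter))
})

setMethod("show", "SampleCovariance", function(object) {
  cat(sprintf("SampleCovariance [%s]: %d x %d, top eigenvalue %.4g\n",
              object@method, nrow(object@K), ncol(object@K),
              if (length(object@eigenValues)) object@eigenValues[1] else NA))
  if (identical(object@method, "confeti_i") &&
      !is.null(object@provenance$r))
    cat(sprintf("  built from %d of %d components (%d flagged as genetic)\n",
                object@provenance$k - object@provenance$r,
                object@provenance$k, object@provenance$r))
})

setMethod("show", "ComponentFlagResult", function(object) {
  cat(sprintf(
    "ComponentFlagResult: %d components, %d flagged at alpha %.3g / %d tests\n",
    length(object@minP), length(object@flagged), object@alpha,
    object@nTests))
})
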