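#' Reconstruct the non-genetic expression signal
#'
#' Removes the flagged (candidate genetic) components from the decomposition
#' and rebuilds the expression matrix from the remaining k - r components:
#' Y* = A[, unflagged] \%*\% S[unflagged, ]. Sample and gene ids are
#' preserved; the result carries tag "reconstructed-nongenetic". If every
#' component is flagged an all-zero matrix is returned with a warning (the
#' downstream covariance then errors).
#'
#' @param D an \linkS4class{IcaDecomposition}.
#' @param flags a \linkS4class{ComponentFlagResult} for D (or an integer
#'   vector of component indices to drop).
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
reconstructNongenetic <- function(D, flags) {
  drop <- if (is(flags, "ComponentFlagResult")) flags@flagged
          else as.integer(flags)
  if (length(drop) && (min(drop) < 1 || max(drop) > D@k))
    stop("flagged component indices outside 1..k")
  keep <- setdiff(seq_len(D@k), drop)
  if (length(keep) == 0L) {
    warning("all components flagged as genetic: reconstruction is zero")
    ystar <- matrix(0, nrow(D@A), ncol(D@S),
                    dimnames = list(rownames(D@A), colnames(D@S)))
  } else {
    ystar <- D@A[, keep, drop = FALSE] %*% D@S[keep, , drop = FALSE]
  }
  new("ExpressionMatrix", values = ystar,
      geneAnnotation = data.frame(gene_id = character(),
                                  chrom = character(), start = integer(),
                                  stringsAsFactors = FALSE),
      tag = "reconstructed-nongenetic")
}

# standardize genes to mean 0 / unit variance, dropping zero-variance genes,
# then return the n x n sample covariance across genes (g - 1 denominator)
sampleCovFromStandardized <- function(v, method, provenance = list()) {
  mu <- colMeans(v)
  sds <- apply(v, 2, sd)
  usable <- sds > 0
  if (sum(usable) < 2L)
    stop("need at least 2 genes with nonzero variance to build K")
  if (!all(usable))
    warning(sprintf("dropping %d zero-variance gene(s) from K construction",
                    sum(!usable)))
  z <- sweep(sweep(v[, usable, drop = FALSE], 2, mu[usable]), 2,
             sds[usable], "/")
  gp <- ncol(z)
  K <- tcrossprod(z) / (gp - 1)
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("covariance matrix has eigenvalue below -1e-8: numerical failure")
  ev <- pmax(e$values, 0)
  new("SampleCovariance", K = K, method = method, eigenValues = ev,
      eigenVectors = e$vectors,
      provenance = c(provenance, list(nGenesUsed = gp)))
}

#' Build the CONFETI-I sample covariance matrix
#'
#' Location-scale normalizes each gene of the reconstructed non-genetic
#' expression Y* (Z*_ip = (Y*_ip - mu_p) / sigma_p, sample sd with g - 1
#' denominator; zero-variance genes dropped with a warning) and returns the
#' n x n sample covariance across genes, K = Z* Z*^T / (g' - 1), with its
#' eigendecomposition cached. The overall scale of K is immaterial
#' downstream: the mixed model's tau^2 absorbs it.
#'
#' @param Ystar an \linkS4class{ExpressionMatrix}, normally the output of
#'   \code{\link{reconstructNongenetic}}.
#' @param provenance optional list (k, r, flagged) recorded on the object.
#' @return A \linkS4class{SampleCovariance} with method "confeti_i".
#' @export
buildConfetiK <- function(Ystar, provenance = list()) {
  sampleCovFromStandardized(Ystar@values, "confeti_i", provenance)
}

#' Build the ICE baseline sample covariance matrix
#'
#' Same location-scale normalization and covariance as
#' \code{\link{buildConfetiK}} but applied to the full observed expression
#' matrix, without any component removal: the intersample-correlation
#' baseline that CONFETI-I reduces to when no component is flagged.
#'
#' @param E an \linkS4class{ExpressionMatrix} (raw expression).
#' @return A \linkS4class{SampleCovariance} with method "ice".
#' @export
buildIceK <- function(E) {
  sampleCovFromStandardized(E@values, "ice")
}

#' Wrap an externally computed covariance matrix
#'
#' Accepts an n x n symmetric PSD matrix estimated elsewhere (for example a
#' likelihood-optimized low-rank covariance) so it can be used as the
#' random effect in \code{\link{eqtlScan}}.
#'
#' @param K numeric symmetric matrix with sample ids as dimnames.
#' @return A \linkS4class{SampleCovariance} with method "external".
#' @export
externalK <- function(K) {
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("external covariance matrix is not PSD")
  new("SampleCovariance", K = K, method = "external",
      eigenValues = pmax(e$values, 0), eigenVectors = e$vectors)
}
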