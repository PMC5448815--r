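#' Run the full CONFETI-I analysis on one dataset
#'
#' Chains the framework end to end: component count selection at the
#' variance target, FastICA decomposition, genotype screening of the
#' component coefficients, reconstruction of the non-genetic expression,
#' CONFETI-I covariance construction, and the mixed-model genome-wide scan.
#' With \code{split = TRUE} the genotype-splitting strategy is used:
#' components are flagged against one random half of the SNPs while the
#' other half is scanned, roles are flipped, and the two scans are
#' concatenated so no genotype is both used for filtering and tested.
#'
#' @param E an \linkS4class{ExpressionMatrix}.
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param C optional covariate matrix.
#' @param varianceTarget PCA variance fraction fixing k (default 0.95).
#' @param alpha family-wise level of the component screen (default 0.05).
#' @param seed seed for the decomposition (and the split, if any).
#' @param split use the genotype-splitting strategy (default FALSE: the
#'   full dataset is used for both filtering and testing).
#' @param mode scan mode, "null_fixed" or "exact".
#' @param ... further arguments to \code{\link{icaDecompose}}.
#' @return list: scan table \code{table}, \code{decomposition},
#'   \code{flags} (or a list of two under splitting), \code{K}.
#' @export
confetiPipeline <- function(E, G, C = NULL, varianceTarget = 0.95,
                            alpha = 0.05, seed = 1L, split = FALSE,
                            mode = "null_fixed", ...) {
  al <- alignSamples(E, G, C)
  E <- al$E; G <- al$G; C <- al$C
  k <- selectComponentCount(E, varianceTarget)
  D <- icaDecompose(E, k = k, seed = seed, ...)
  if (!split) {
    flags <- flagGeneticComponents(D, G, alpha = alpha)
    K <- buildConfetiK(reconstructNongenetic(D, flags),
                       provenance = list(k = D@k,
                                         r = length(flags@flagged),
                                         flagged = flags@flagged))
    tab <- eqtlScan(E, G, K = K, C = C, method = "confeti_i", mode = mode)
    list(table = tab, decomposition = D, flags = flags, K = K)
  } else {
    plan <- makeSplitPlan(G, seed = seed)
    halves <- list(plan$subset1, plan$subset2)
    parts <- lapply(1:2, function(i) {
      filterSet <- halves[[i]]
      testSet <- halves[[3 - i]]
      flags <- flagGeneticComponents(D, G, alpha = alpha,
                                     genotypeSubset = filterSet)
      K <- buildConfetiK(reconstructNongenetic(D, flags),
                         provenance = list(k = D@k,
                                           r = length(flags@flagged),
                                           flagged = flags@flagged))
      tab <- eqtlScan(E, subsetSnps(G, testSet), K = K, C = C,
                      method = "confeti_i", mode = mode)
      list(tab = tab, flags = flags, K = K)
    })
    tab <- rbind(parts[[1]]$tab, parts[[2]]$tab)
    tab$p_adj <- bhAdjust(tab$p)   # re-adjust jointly over both halves
    list(table = tab, decomposition = D,
         flags = list(parts[[1]]$flags, parts[[2]]$flags),
         K = list(parts[[1]]$K, parts[[2]]$K), splitPlan = plan)
  }
}
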