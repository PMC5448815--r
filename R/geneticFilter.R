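#' Flag independent components carrying genotype (candidate genetic) signal
#'
#' For every component coefficient column of A and every polymorphic SNP,
#' fits an ordinary least squares regression of the coefficients on
#' intercept + genotype and records the two-sided p-value of the genotype
#' slope (t reference, n - 2 df). A component is flagged as a candidate
#' broad impact eQTL component when its minimum p over SNPs falls below the
#' global Bonferroni threshold \code{alpha / (k * s_tested)}. Monomorphic
#' SNPs are skipped and do not count toward \code{s_tested}.
#'
#' @param D an \linkS4class{IcaDecomposition} whose samples align with G.
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param alpha family-wise level (default 0.05).
#' @param genotypeSubset optional character vector of SNP ids to restrict
#'   testing to (the genotype-splitting strategy).
#' @return A \linkS4class{ComponentFlagResult}.
#' @export
flagGeneticComponents <- function(D, G, alpha = 0.05,
                                  genotypeSubset = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  A <- D@A
  gv <- G@values
  if (!is.null(rownames(A)) &&
      !identical(rownames(A), rownames(gv))) {
    if (!all(rownames(A) %in% rownames(gv)))
      stop("samples of the decomposition and genotypes do not align")
    gv <- gv[rownames(A), , drop = FALSE]
  }
  if (nrow(A) != nrow(gv))
    stop("samples of the decomposition and genotypes do not align")
  if (!is.null(genotypeSubset))
    gv <- gv[, colnames(gv) %in% genotypeSubset, drop = FALSE]
  sds <- apply(gv, 2, sd)
  poly <- sds > 0
  if (!any(poly)) stop("no polymorphic SNP to test against")
  gv <- gv[, poly, drop = FALSE]
  n <- nrow(A); k <- ncol(A); s <- ncol(gv)

  # slope p-value of lm(a ~ 1 + g) equals the correlation t-test, n - 2 df
  r <- cor(A, gv)                         # k x s
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)

  minIdx <- apply(p, 1, which.min)
  minP <- p[cbind(seq_len(k), minIdx)]
  nTests <- k * s
  flagged <- which(minP < alpha / nTests)
  new("ComponentFlagResult", minP = unname(minP),
      bestSnp = colnames(gv)[minIdx], flagged = as.integer(flagged),
      alpha = alpha, nTests = as.integer(nTests),
      genotypeSubset = colnames(gv))
}

#' Random disjoint split of the SNP set
#'
#' Produces two disjoint SNP subsets of (near-)equal size whose union is all
#' SNPs, reproducibly from a seed. Used by the genotype-splitting strategy:
#' components are flagged against one subset while the other is scanned, the
#' roles are flipped, and the two scans concatenated, so no genotype is both
#' used for filtering and tested.
#'
#' @param G a \linkS4class{GenotypeMatrix} with at least 2 SNPs.
#' @param seed integer seed.
#' @return list with character vectors \code{subset1}, \code{subset2} and
#'   the \code{seed}.
#' @export
makeSplitPlan <- function(G, seed = 1L) {
  ids <- colnames(G@values)
  if (length(ids) < 2L) stop("need at least 2 SNPs to split")
  set.seed(as.integer(seed))
  perm <- sample(ids)
  half <- ceiling(length(ids) / 2)
  list(subset1 = sort(perm[seq_len(half)]),
       subset2 = sort(perm[-seq_len(half)]),
       seed = as.integer(seed))
}
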