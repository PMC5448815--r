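#' Evaluate a scan against the planted ground truth
#'
#' Ranks all tested (gene, SNP) pairs by p-value and computes the ROC curve
#' and its AUC with positives = all planted pairs (broad impact loci count
#' one positive per affected gene), plus the per-category recovery rate at
#' each Benjamini-Hochberg FDR threshold: the fraction of planted pairs of
#' that category called significant. NA p-values (monomorphic SNPs) are
#' treated as p = 1.
#'
#' @param tab eQTL table covering all pairs of the simulation.
#' @param truth output of \code{\link{sampleArchitecture}}.
#' @param fdrGrid numeric vector of FDR thresholds
#'   (default c(0.01, 0.05, 0.1, 0.2)).
#' @return list: \code{auc}, \code{roc} (data.frame fpr/tpr), and
#'   \code{recovery} (data.frame category x fdr with the recovery rate).
#' @export
evaluateScan <- function(tab, truth, fdrGrid = c(0.01, 0.05, 0.1, 0.2)) {
  key <- paste(tab$snp, tab$gene, sep = "\r")
  trueKey <- paste(truth$pairs$snp_id, truth$pairs$gene_id, sep = "\r")
  if (!all(trueKey %in% key))
    stop("scan table does not cover all planted (snp, gene) pairs")
  isPos <- key %in% trueKey
  p <- ifelse(is.na(tab$p), 1, tab$p)

  # AUC as the rank-sum (Mann-Whitney) probability that a random positive
  # outranks a random negative, ties counted half
  r <- rank(p, ties.method = "average")
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  auc <- (sum(r[!isPos]) - nNeg * (nNeg + 1) / 2) / (nPos * nNeg)

  ord <- order(p)
  posOrd <- isPos[ord]
  tpr <- cumsum(posOrd) / nPos
  fpr <- cumsum(!posOrd) / nNeg
  step <- unique(round(seq(1, length(ord), length.out = 512)))
  roc <- data.frame(fpr = c(0, fpr[step]), tpr = c(0, tpr[step]))

  padj <- bhAdjust(p)
  cat2 <- truth$pairs$category[match(key, trueKey)]
  recovery <- do.call(rbind, lapply(fdrGrid, function(thr) {
    sig <- padj < thr
    do.call(rbind, lapply(unique(truth$pairs$category), function(cc) {
      inCat <- !is.na(cat2) & cat2 == cc
      data.frame(category = cc, fdr = thr,
                 recovery = sum(sig & inCat) / sum(inCat),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(auc = auc, roc = roc, recovery = recovery)
}

#' Recovery rate lookup helper
#'
#' @param metrics output of \code{\link{evaluateScan}}.
#' @param category "cis", "trans" or "broad".
#' @param fdr threshold present in the evaluated grid.
#' @return numeric recovery rate.
#' @export
recoveryAt <- function(metrics, category, fdr) {
  r <- metrics$recovery
  hit <- r$category == category & abs(r$fdr - fdr) < 1e-12
  if (!any(hit)) stop("no recovery entry for that category/fdr")
  r$recovery[hit]
}
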