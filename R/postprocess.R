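#' Label eQTL records as cis or trans
#'
#' A record is cis when the SNP and the gene lie on the same chromosome and
#' the distance between the SNP position and the annotated gene start is at
#' most \code{window} bp (boundary inclusive); otherwise trans. Genes
#' without annotation stay "unlabeled". The conventional window is 1 Mb for
#' real-data labeling; the simulation ground truth uses 100 kb.
#'
#' @param tab eQTL table from \code{\link{eqtlScan}}.
#' @param E \linkS4class{ExpressionMatrix} carrying gene annotation (or a
#'   data.frame gene_id/chrom/start).
#' @param G \linkS4class{GenotypeMatrix} carrying SNP positions.
#' @param window distance window in bp (default 1e6).
#' @return The table with the label column filled in.
#' @export
labelCisTrans <- function(tab, E, G, window = 1e6) {
  geneAnn <- if (is(E, "ExpressionMatrix")) E@geneAnnotation else E
  snpAnn <- snpAnnotation(G)
  gi <- match(tab$gene, geneAnn$gene_id)
  si <- match(tab$snp, snpAnn$snp_id)
  lab <- rep("unlabeled", nrow(tab))
  ok <- !is.na(gi) & !is.na(si)
  same <- ok & geneAnn$chrom[gi] == snpAnn$chrom[si]
  dist <- abs(as.numeric(snpAnn$pos[si]) -
              as.numeric(geneAnn$start[gi]))
  lab[ok] <- "trans"
  lab[same & dist <= window] <- "cis"
  tab$label <- lab
  tab
}

#' Read a UCSC-style cytoband table
#'
#' Five whitespace-separated columns: chrom, start, end, band, stain.
#' Coordinates are converted to 1-based inclusive on load.
#'
#' @param path file path (plain text, UCSC cytoBand layout, 0-based starts).
#' @return data.frame with chrom, start, end, band.
#' @export
loadCytobands <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "band",
                                  "stain")[1:5])
  data.frame(chrom = as.character(tab$chrom),
             start = as.integer(tab$start) + 1L,
             end = as.integer(tab$end), band = as.character(tab$band),
             stringsAsFactors = FALSE)
}

# map SNPs to cytoband labels; SNPs outside any band fall back to fixed
# 1-Mb bins (with a warning) so synthetic genomes stay runnable
assignCytoband <- function(chrom, pos, cytobands = NULL, binSize = 1e6) {
  out <- rep(NA_character_, length(pos))
  if (!is.null(cytobands)) {
    for (i in seq_along(pos)) {
      hit <- which(cytobands$chrom == chrom[i] &
                   cytobands$start <= pos[i] & cytobands$end >= pos[i])
      if (length(hit))
        out[i] <- paste0(chrom[i], ":", cytobands$band[hit[1]])
    }
    if (anyNA(out))
      warning(sprintf(
        "%d SNP(s) outside any cytoband: falling back to 1-Mb bins",
        sum(is.na(out))))
  }
  miss <- is.na(out)
  out[miss] <- paste0(chrom[miss], ":bin",
                      floor((pos[miss] - 1) / binSize))
  out
}

#' Collapse linked significant SNPs to one per cytoband per gene
#'
#' Among records significant at \code{fdrThreshold} (on p_adj), keeps for
#' each (gene, cytoband, label) group the record with the smallest raw p
#' (ties broken by smallest SNP position), so one gene contributes at most
#' one cis and one trans eQTL per chromosome band. Without a cytoband
#' table, SNPs are binned into fixed 1-Mb intervals with a warning.
#'
#' @param tab labeled eQTL table.
#' @param G \linkS4class{GenotypeMatrix} (for SNP positions).
#' @param cytobands optional data.frame from \code{\link{loadCytobands}}.
#' @param fdrThreshold significance threshold on p_adj (default 0.01).
#' @return Collapsed table with an added cytoband column.
#' @export
collapsePerCytoband <- function(tab, G, cytobands = NULL,
                                fdrThreshold = 0.01) {
  snpAnn <- snpAnnotation(G)
  sig <- tab[!is.na(tab$p_adj) & tab$p_adj < fdrThreshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    sig$cytoband <- character(0)
    return(sig)
  }
  si <- match(sig$snp, snpAnn$snp_id)
  sig$cytoband <- assignCytoband(snpAnn$chrom[si], snpAnn$pos[si],
                                 cytobands)
  sig$.pos <- snpAnn$pos[si]
  key <- paste(sig$gene, sig$cytoband, sig$label, sep = "\r")
  ord <- order(key, sig$p, sig$.pos)
  sig <- sig[ord, , drop = FALSE]
  sig <- sig[!duplicated(key[ord]), , drop = FALSE]
  sig$.pos <- NULL
  rownames(sig) <- NULL
  sig
}

#' Load a two-column gene-relation table
#'
#' Pairs of related genes (for example pseudogene and functional parent);
#' relations are symmetrized on load.
#'
#' @param path TSV with header and columns gene_id, related_gene_id (an
#'   optional third column names the relation type).
#' @return data.frame gene_id / related_gene_id, symmetric.
#' @export
loadGeneRelations <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  rel <- data.frame(gene_id = as.character(tab[[1]]),
                    related_gene_id = as.character(tab[[2]]),
                    stringsAsFactors = FALSE)
  sym <- rbind(rel, data.frame(gene_id = rel$related_gene_id,
                               related_gene_id = rel$gene_id,
                               stringsAsFactors = FALSE))
  unique(sym)
}

#' Load homology regions from BED
#'
#' BED intervals (0-based half-open on disk, converted to 1-based inclusive)
#' whose name column identifies the gene whose transcript matches the
#' region (at least half of the transcript aligning), used to screen
#' cross-mapping artifacts.
#'
#' @param path BED file path (chrom, start, end, gene_id).
#' @return data.frame gene_id / chrom / start / end.
#' @export
loadHomologyRegions <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = as.character(tab[[4]]),
             chrom = as.character(tab[[1]]),
             start = as.integer(tab[[2]]) + 1L,
             end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
}

#' Screen pseudo-trans artifacts
#'
#' Removes trans records whose SNP lies within \code{window} bp of (a) the
#' start of any gene related to the eQTL gene (pseudogene/parent pairs) or
#' (b) any genomic region homologous to the eQTL gene's transcript. Such
#' apparent trans associations typically arise from ambiguous read mapping
#' and are really cis effects on a sequence-similar locus. Cis records are
#' never touched. With no annotation the table passes through with a
#' warning.
#'
#' @param tab labeled eQTL table.
#' @param G \linkS4class{GenotypeMatrix} (SNP positions).
#' @param geneAnn gene annotation data.frame (gene_id, chrom, start) used
#'   to locate related genes.
#' @param relations data.frame from \code{\link{loadGeneRelations}}.
#' @param homology data.frame from \code{\link{loadHomologyRegions}}.
#' @param window distance window in bp (default 1e6).
#' @return list: \code{kept} (screened table) and \code{removed} (records
#'   dropped, with a reason column).
#' @export
pseudoTransScreen <- function(tab, G, geneAnn = NULL, relations = NULL,
                              homology = NULL, window = 1e6) {
  if (is(geneAnn, "ExpressionMatrix")) geneAnn <- geneAnn@geneAnnotation
  if ((is.null(relations) || nrow(relations) == 0L) &&
      (is.null(homology) || nrow(homology) == 0L)) {
    warning("no relation/homology annotation: pseudo-trans screen is a no-op")
    return(list(kept = tab, removed = tab[0, , drop = FALSE]))
  }
  snpAnn <- snpAnnotation(G)
  si <- match(tab$snp, snpAnn$snp_id)
  drop <- rep(FALSE, nrow(tab))
  reason <- rep(NA_character_, nrow(tab))
  isTrans <- tab$label == "trans"
  for (i in which(isTrans)) {
    sc <- snpAnn$chrom[si[i]]; sp <- snpAnn$pos[si[i]]
    if (is.na(sc)) next
    if (!is.null(relations) && nrow(relations)) {
      rel <- relations$related_gene_id[relations$gene_id == tab$gene[i]]
      if (length(rel) && !is.null(geneAnn)) {
        gi <- match(rel, geneAnn$gene_id)
        gi <- gi[!is.na(gi)]
        hit <- geneAnn$chrom[gi] == sc &
          abs(as.numeric(geneAnn$start[gi]) - sp) <= window
        if (any(hit)) {
          drop[i] <- TRUE
          reason[i] <- paste0("related-gene:", geneAnn$gene_id[gi][hit][1])
          next
        }
      }
    }
    if (!is.null(homology) && nrow(homology)) {
      hr <- homology[homology$gene_id == tab$gene[i] &
                     homology$chrom == sc, , drop = FALSE]
      if (nrow(hr)) {
        hit <- sp >= hr$start - window & sp <= hr$end + window
        if (any(hit)) {
          drop[i] <- TRUE
          reason[i] <- sprintf("homology-region:%s:%d-%d",
                               hr$chrom[which(hit)[1]],
                               hr$start[which(hit)[1]],
                               hr$end[which(hit)[1]])
        }
      }
    }
  }
  removed <- tab[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[drop]
  list(kept = tab[!drop, , drop = FALSE], removed = removed)
}

#' Count eQTL replication between two datasets
#'
#' Both tables must already be collapsed per cytoband
#' (\code{\link{collapsePerCytoband}}). Keys are (gene, cytoband, label);
#' the replication ratio per label is the number of keys significant in
#' both tables divided by the number significant in either.
#'
#' @param tab1,tab2 collapsed eQTL tables.
#' @return list with per-label data.frame \code{summary} (nOverlap, nUnion,
#'   replicationRatio) and the data.frame \code{replicating} of overlapping
#'   records (from tab1).
#' @export
countReplication <- function(tab1, tab2) {
  keyOf <- function(tt) paste(tt$gene, tt$cytoband, tt$label, sep = "\r")
  k1 <- keyOf(tab1); k2 <- keyOf(tab2)
  labels <- sort(unique(c(tab1$label, tab2$label)))
  summ <- do.call(rbind, lapply(labels, function(lb) {
    a <- unique(k1[tab1$label == lb]); b <- unique(k2[tab2$label == lb])
    ov <- length(intersect(a, b)); un <- length(union(a, b))
    data.frame(label = lb, nOverlap = ov, nUnion = un,
               replicationRatio = if (un > 0) ov / un else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(summary = summ,
       replicating = tab1[k1 %in% intersect(k1, k2), , drop = FALSE])
}

#' Detect broad impact eQTL among replicating trans associations
#'
#' A genotype locus (cytoband by default, SNP id optionally) is reported as
#' a broad impact eQTL candidate when its replicating trans associations
#' cover at least two genes whose chromosomes include at least two distinct
#' chromosomes different from the locus' own chromosome. Trans genes on the
#' locus' own chromosome (beyond the cis window) count toward the gene
#' number but not the chromosome diversity.
#'
#' @param replicating data.frame of replicating records (from
#'   \code{\link{countReplication}}).
#' @param G \linkS4class{GenotypeMatrix} (SNP chromosomes).
#' @param geneAnn gene annotation data.frame (gene chromosomes).
#' @param locus group by "cytoband" (default) or "snp".
#' @return data.frame: locus, chrom, nTransGenes, nTransChroms, genes
#'   (comma-separated) for each reported locus.
#' @export
detectBroadImpact <- function(replicating, G, geneAnn,
                              locus = c("cytoband", "snp")) {
  locus <- match.arg(locus)
  if (is(geneAnn, "ExpressionMatrix")) geneAnn <- geneAnn@geneAnnotation
  tr <- replicating[replicating$label == "trans", , drop = FALSE]
  if (nrow(tr) == 0L)
    return(data.frame(locus = character(), chrom = character(),
                      nTransGenes = integer(), nTransChroms = integer(),
                      genes = character(), stringsAsFactors = FALSE))
  snpAnn <- snpAnnotation(G)
  tr$snpChrom <- snpAnn$chrom[match(tr$snp, snpAnn$snp_id)]
  tr$geneChrom <- geneAnn$chrom[match(tr$gene, geneAnn$gene_id)]
  tr$.locus <- if (locus == "cytoband") tr$cytoband else tr$snp
  out <- lapply(split(tr, tr$.locus), function(grp) {
    genes <- unique(grp$gene)
    offChrom <- unique(grp$geneChrom[!is.na(grp$geneChrom) &
                                     grp$geneChrom != grp$snpChrom])
    if (length(genes) >= 2 && length(offChrom) >= 2)
      data.frame(locus = grp$.locus[1], chrom = grp$snpChrom[1],
                 nTransGenes = length(genes),
                 nTransChroms = length(offChrom),
                 genes = paste(sort(genes), collapse = ","),
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(locus = character(), chrom = character(),
                      nTransGenes = integer(), nTransChroms = integer(),
                      genes = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
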