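# small labeled table fixture shared across the postprocess checks
makeEqtlFixture <- function() {
  geneAnn <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr2", "chr1"),
    start = c(1400000L, 500000L, 5000000L), stringsAsFactors = FALSE)
  snpAnn <- data.frame(
    snp_id = c("m1", "m2", "m3", "m4"),
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    pos = c(500000L, 2400000L, 600000L, 5100000L),
    stringsAsFactors = FALSE)
  set.seed(1)
  v <- matrix(rbinom(6 * 4, 2, 0.4), 6, 4,
              dimnames = list(sampleIds(6), snpAnn$snp_id))
  v[, 1] <- c(0, 1, 2, 1, 0, 1)  # keep every SNP polymorphic
  G <- GenotypeMatrix(v, snpAnn)
  tab <- expand.grid(gene = geneAnn$gene_id, snp = snpAnn$snp_id,
                     stringsAsFactors = FALSE)
  tab$beta <- 0.1; tab$se <- 0.1
  tab$p <- c(1e-9, 1e-7, 1e-4, 0.2, 1e-8, 0.5,
             1e-6, 0.9, 1e-3, 0.7, 1e-5, 0.04)
  tab$p_adj <- bhAdjust(tab$p)
  tab$lambda_gene <- 1
  tab$label <- "unlabeled"
  tab$method <- "linear"
  list(tab = tab, G = G, geneAnn = geneAnn)
}

test_that("cis/trans labels follow the same-chromosome window rule", {
  fx <- makeEqtlFixture()
  lab <- labelCisTrans(fx$tab, fx$geneAnn, fx$G, window = 1e6)
  pick <- function(gene, snp) lab$label[lab$gene == gene & lab$snp == snp]
  expect_identical(pick("gA", "m1"), "cis")    # chr1, 900 kb apart
  expect_identical(pick("gA", "m2"), "cis")    # exactly 1 Mb: inclusive
  expect_identical(pick("gA", "m3"), "trans")  # different chromosome
  expect_identical(pick("gB", "m3"), "cis")    # chr2, 100 kb
  expect_identical(pick("gC", "m1"), "trans")  # chr1 but 4.5 Mb
  # gene without annotation stays unlabeled
  lab2 <- labelCisTrans(rbind(fx$tab,
    data.frame(gene = "gX", snp = "m1", beta = 0, se = 1, p = 0.5,
               p_adj = 1, lambda_gene = 1, label = "unlabeled",
               method = "linear")), fx$geneAnn, fx$G)
  expect_identical(lab2$label[lab2$gene == "gX"], "unlabeled")
})

test_that("cytoband collapsing keeps the best record per gene/band/label", {
  fx <- makeEqtlFixture()
  lab <- labelCisTrans(fx$tab, fx$geneAnn, fx$G, window = 1e6)
  cyto <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(1L, 3000001L, 1L),
                     end = c(3000000L, 8000000L, 8000000L),
                     band = c("p1", "q1", "p1"), stringsAsFactors = FALSE)
  col <- collapsePerCytoband(lab, fx$G, cytobands = cyto,
                             fdrThreshold = 0.01)
  # m1 and m2 share chr1:p1: for each gene/label only the smaller p stays
  key <- paste(col$gene, col$cytoband, col$label)
  expect_false(anyDuplicated(key) > 0)
  gAp1 <- col[col$gene == "gA" & col$cytoband == "chr1:p1", ]
  expect_identical(gAp1$snp, "m1")  # p 1e-9 beats m2's 1e-7
  # the same SNP may stay for two genes (collapse is per gene): m1 is the
  # band's best record for gA (cis) and for gC (trans)
  expect_setequal(col$gene[col$snp == "m1"], c("gA", "gC"))
  # brute-force group-by/min oracle over significant records
  sig <- lab[lab$p_adj < 0.01, ]
  si <- match(sig$snp, snpAnnotation(fx$G)$snp_id)
  band <- character(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    hit <- which(cyto$chrom == snpAnnotation(fx$G)$chrom[si[i]] &
                 cyto$start <= snpAnnotation(fx$G)$pos[si[i]] &
                 cyto$end >= snpAnnotation(fx$G)$pos[si[i]])
    band[i] <- paste0(cyto$chrom[hit], ":", cyto$band[hit])
  }
  oracle <- do.call(rbind, lapply(
    split(cbind(sig, band), paste(sig$gene, band, sig$label)),
    function(grp) grp[which.min(grp$p), c("gene", "snp", "label")]))
  got <- col[, c("gene", "snp", "label")]
  oracle <- oracle[order(oracle$gene, oracle$snp, oracle$label), ]
  got <- got[order(got$gene, got$snp, got$label), ]
  rownames(oracle) <- rownames(got) <- NULL
  expect_identical(got, oracle)
  # idempotence: collapsing the collapsed table changes nothing
  col2 <- collapsePerCytoband(col, fx$G, cytobands = cyto,
                              fdrThreshold = 0.01)
  expect_equal(col2[, names(col)], col, ignore_attr = TRUE)
  # without a cytoband table SNPs fall into 1-Mb bins
  expect_warning(colBins <- collapsePerCytoband(lab, fx$G,
    cytobands = cyto[cyto$chrom != "chr2", ], fdrThreshold = 0.01),
    "1-Mb bins")
  expect_true(any(grepl(":bin", colBins$cytoband)))
})

test_that("pseudo-trans screening removes artifact records only", {
  fx <- makeEqtlFixture()
  lab <- labelCisTrans(fx$tab, fx$geneAnn, fx$G, window = 1e6)
  # gB is related to gBpseudo sitting 200 kb from SNP m1 (chr1)
  geneAnn2 <- rbind(fx$geneAnn,
    data.frame(gene_id = "gBpseudo", chrom = "chr1", start = 700000L))
  relations <- data.frame(gene_id = "gB", related_gene_id = "gBpseudo",
                          stringsAsFactors = FALSE)
  # homology region of gC near SNP m3 on chr2
  homology <- data.frame(gene_id = "gC", chrom = "chr2",
                         start = 550000L, end = 580000L,
                         stringsAsFactors = FALSE)
  out <- pseudoTransScreen(lab, fx$G, geneAnn = geneAnn2,
                           relations = relations, homology = homology,
                           window = 1e6)
  rem <- out$removed
  expect_true(all(rem$label == "trans"))
  expect_true(any(rem$gene == "gB" & rem$snp == "m1"))
  expect_true(any(rem$gene == "gC" & rem$snp == "m3"))
  expect_true(any(grepl("related-gene:gBpseudo", rem$reason)))
  # trans records without nearby annotation pass through
  expect_true(any(out$kept$gene == "gA" & out$kept$snp == "m3"))
  # cis records are never touched and the table never grows
  expect_identical(nrow(out$kept) + nrow(rem), nrow(lab))
  expect_identical(sum(out$kept$label == "cis"),
                   sum(lab$label == "cis"))
  # brute-force interval-overlap oracle over the trans records
  snpAnn <- snpAnnotation(fx$G)
  oracle <- logical(nrow(lab))
  for (i in seq_len(nrow(lab))) {
    if (lab$label[i] != "trans") next
    sc <- snpAnn$chrom[match(lab$snp[i], snpAnn$snp_id)]
    sp <- snpAnn$pos[match(lab$snp[i], snpAnn$snp_id)]
    rel <- relations$related_gene_id[relations$gene_id == lab$gene[i]]
    for (rg in rel) {
      gi <- match(rg, geneAnn2$gene_id)
      if (geneAnn2$chrom[gi] == sc &&
          abs(geneAnn2$start[gi] - sp) <= 1e6) oracle[i] <- TRUE
    }
    hr <- homology[homology$gene_id == lab$gene[i], ]
    for (j in seq_len(nrow(hr)))
      if (hr$chrom[j] == sc && sp >= hr$start[j] - 1e6 &&
          sp <= hr$end[j] + 1e6) oracle[i] <- TRUE
  }
  expect_identical(paste(rem$gene, rem$snp),
                   paste(lab$gene[oracle], lab$snp[oracle]))
  expect_warning(pseudoTransScreen(lab, fx$G), "no-op")
})

test_that("replication counting is plain set arithmetic on keys", {
  mk <- function(genes, bands, labels) {
    data.frame(gene = genes, cytoband = bands, label = labels,
               snp = "mX", p = 1e-9, p_adj = 1e-9,
               stringsAsFactors = FALSE)
  }
  t1 <- mk(c("g1", "g2", "g3"), c("b1", "b1", "b2"),
           c("cis", "trans", "cis"))
  t2 <- mk(c("g1", "g2", "g4", "g5"), c("b1", "b1", "b3", "b4"),
           c("cis", "trans", "cis", "cis"))
  rep1 <- countReplication(t1, t2)
  cis <- rep1$summary[rep1$summary$label == "cis", ]
  expect_identical(cis$nOverlap, 1L)
  expect_identical(cis$nUnion, 4L)
  expect_equal(cis$replicationRatio, 0.25)
  trans <- rep1$summary[rep1$summary$label == "trans", ]
  expect_equal(trans$replicationRatio, 1.0)
  # identical tables replicate fully; disjoint tables not at all
  self <- countReplication(t1, t1)
  expect_true(all(self$summary$replicationRatio == 1))
  disj <- countReplication(t1, mk("g9", "b9", "cis"))
  expect_equal(disj$summary$replicationRatio[
    disj$summary$label == "cis"], 0)
})

test_that("broad impact calls demand two trans genes on two chromosomes", {
  geneAnn <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr20", "chr3", "chr3"),
    start = c(1e6, 2e6, 3e6, 4e6), stringsAsFactors = FALSE)
  snpAnn <- data.frame(snp_id = c("mQ", "mR", "mS"),
                       chrom = c("chr6", "chr2", "chr2"),
                       pos = c(1e6, 1e6, 2e6), stringsAsFactors = FALSE)
  set.seed(2)
  v <- matrix(rbinom(4 * 3, 2, 0.5), 4, 3,
              dimnames = list(sampleIds(4), snpAnn$snp_id))
  G <- GenotypeMatrix(v, snpAnn)
  mk <- function(snp, genes, band) {
    data.frame(gene = genes, snp = snp, cytoband = band, label = "trans",
               p = 1e-9, p_adj = 1e-9, stringsAsFactors = FALSE)
  }
  # mQ: trans genes on chr1 and chr20 (SNP on chr6) -> reported
  # mR: two trans genes both on chr3 -> not reported
  # mS: a single trans gene -> not reported
  repl <- rbind(mk("mQ", c("gA", "gB"), "chr6:b1"),
                mk("mR", c("gC", "gD"), "chr2:b1"),
                mk("mS", "gA", "chr2:b2"))
  out <- detectBroadImpact(repl, G, geneAnn)
  expect_identical(out$locus, "chr6:b1")
  expect_identical(out$nTransGenes, 2L)
  outSnp <- detectBroadImpact(repl, G, geneAnn, locus = "snp")
  expect_identical(outSnp$locus, "mQ")
  # trans genes on the SNP chromosome count for genes, not chromosomes
  repl2 <- mk("mR", c("gC", "gD"), "chr2:b1")
  repl2$gene <- c("gC", "gC2")
  geneAnn2 <- rbind(geneAnn, data.frame(gene_id = "gC2", chrom = "chr2",
                                        start = 9e6))
  expect_identical(nrow(detectBroadImpact(repl2, G, geneAnn2)), 0L)
})

test_that("annotation loaders convert coordinates and symmetrize", {
  cytoPath <- tempfile()
  writeLines(c("chr1\t0\t3000000\tp1\tgneg",
               "chr1\t3000000\t8000000\tq1\tgpos50"), cytoPath)
  cyto <- loadCytobands(cytoPath)
  expect_identical(cyto$start, c(1L, 3000001L))
  expect_identical(cyto$end, c(3000000L, 8000000L))
  relPath <- tempfile()
  writeLines(c("gene_id\trelated_gene_id", "gA\tgApseudo"), relPath)
  rel <- loadGeneRelations(relPath)
  expect_identical(nrow(rel), 2L)  # symmetric after loading
  expect_true(any(rel$gene_id == "gApseudo" & rel$related_gene_id == "gA"))
  bedPath <- tempfile()
  writeLines("chr2\t100\t500\tgB", bedPath)
  hom <- loadHomologyRegions(bedPath)
  expect_identical(hom$start, 101L)
  expect_identical(hom$end, 500L)
})
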