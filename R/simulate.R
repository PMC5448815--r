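#' Benchmark simulation configuration
#'
#' Bundles the parameters of the planted-eQTL benchmark: a yeast-like
#' synthetic genome (16 chromosomes) carrying SNPs and genes at uniform
#' random positions, a genetic architecture of single-gene cis and trans
#' eQTL plus broad impact loci each hitting a fixed fraction of all genes,
#' unit-variance Gaussian noise, and sparse and/or dense confounding
#' factors. Defaults are the benchmark's standard conditions: 2956
#' genotypes, 3000 genes, 2500 single pairs of which 80\% are cis (within
#' 100 kb on the same chromosome), 10 broad impact loci each affecting
#' 10\% of genes; cis effects ~ N(0.8, 1), trans and broad effects
#' ~ N(0.48, 1); sparse confounders touch 30\% of genes with weights
#' ~ N(1, 0.5), dense confounders touch all genes with weights ~ N(0, 1),
#' per-sample factor scores ~ N(0, 1). Scenario "sparse" uses 30 sparse
#' factors, "mixed" 15 sparse + 15 dense, "none" (the theoretical-maximum-
#' recovery reference) no confounders.
#'
#' @param nSamples samples (default 112).
#' @param nSnps SNPs (default 2956).
#' @param nGenes genes (default 3000).
#' @param nPairs single-gene eQTL pairs (default 2500).
#' @param cisFraction fraction of pairs that are cis (default 0.8).
#' @param nBroad broad impact loci (default 10).
#' @param broadGeneFraction genes per broad locus as a fraction of all
#'   genes (default 0.10).
#' @param cisWindowSim cis distance rule for the simulation, bp
#'   (default 1e5).
#' @param scenario "sparse", "mixed" or "none".
#' @param nSparse,nDense confounder counts; defaults follow the scenario
#'   (30/0 sparse, 15/15 mixed, 0/0 none).
#' @param cisEffect,transEffect mean/sd pairs of the effect-size normals.
#' @param sparseCoverage fraction of genes a sparse factor touches
#'   (default 0.3).
#' @param ploidy 1 (haploid, yeast-like default) or 2.
#' @param nChrom,chromLength synthetic genome shape (16 x 750 kb).
#' @param nDatasets replicate datasets per scenario (default 50).
#' @return list of class "SimulationConfig".
#' @export
simulationConfig <- function(nSamples = 112L, nSnps = 2956L,
                             nGenes = 3000L, nPairs = 2500L,
                             cisFraction = 0.8, nBroad = 10L,
                             broadGeneFraction = 0.10,
                             cisWindowSim = 1e5,
                             scenario = c("sparse", "mixed", "none"),
                             nSparse = NULL, nDense = NULL,
                             cisEffect = c(mean = 0.8, sd = 1),
                             transEffect = c(mean = 0.48, sd = 1),
                             sparseCoverage = 0.3, ploidy = 1L,
                             nChrom = 16L, chromLength = 750000L,
                             nDatasets = 50L) {
  scenario <- match.arg(scenario)
  if (is.null(nSparse))
    nSparse <- switch(scenario, sparse = 30L, mixed = 15L, none = 0L)
  if (is.null(nDense))
    nDense <- switch(scenario, sparse = 0L, mixed = 15L, none = 0L)
  stopifnot(cisFraction >= 0, cisFraction <= 1,
            broadGeneFraction >= 0, broadGeneFraction <= 1,
            sparseCoverage >= 0, sparseCoverage <= 1,
            nSamples >= 1, nSnps >= 1, nGenes >= 1)
  structure(list(nSamples = as.integer(nSamples),
                 nSnps = as.integer(nSnps), nGenes = as.integer(nGenes),
                 nPairs = as.integer(nPairs), cisFraction = cisFraction,
                 nBroad = as.integer(nBroad),
                 broadGeneFraction = broadGeneFraction,
                 cisWindowSim = cisWindowSim, scenario = scenario,
                 nSparse = as.integer(nSparse),
                 nDense = as.integer(nDense), cisEffect = cisEffect,
                 transEffect = transEffect,
                 sparseCoverage = sparseCoverage,
                 ploidy = as.integer(ploidy), nChrom = as.integer(nChrom),
                 chromLength = as.integer(chromLength),
                 nDatasets = as.integer(nDatasets)),
            class = "SimulationConfig")
}

#' Simulate a genotype matrix on the synthetic genome
#'
#' SNPs are placed uniformly on the configured chromosomes (positions
#' sorted within chromosome), per-SNP minor allele frequencies are drawn
#' Uniform(0.05, 0.5), and genotypes are binomial(ploidy, maf) per sample.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
simulateGenotypes <- function(config, seed = 1L) {
  set.seed(as.integer(seed))
  s <- config$nSnps; n <- config$nSamples
  chrom <- sort(sample.int(config$nChrom, s, replace = TRUE))
  pos <- integer(s)
  for (c0 in unique(chrom)) {
    idx <- which(chrom == c0)
    pos[idx] <- sort(sample.int(config$chromLength, length(idx)))
  }
  maf <- runif(s, 0.05, 0.5)
  vals <- matrix(rbinom(n * s, config$ploidy, rep(maf, each = n)), n, s)
  dimnames(vals) <- list(sprintf("sample%03d", seq_len(n)),
                         sprintf("snp%05d", seq_len(s)))
  ann <- data.frame(snp_id = colnames(vals),
                    chrom = paste0("chr", chrom), pos = pos,
                    stringsAsFactors = FALSE)
  GenotypeMatrix(vals, ann, ploidy = config$ploidy)
}

#' Simulate gene positions on the synthetic genome
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return data.frame gene_id / chrom / start.
#' @export
simulateGeneAnnotation <- function(config, seed = 1L) {
  set.seed(as.integer(seed) + 500000L)
  g <- config$nGenes
  chrom <- sort(sample.int(config$nChrom, g, replace = TRUE))
  start <- integer(g)
  for (c0 in unique(chrom)) {
    idx <- which(chrom == c0)
    start[idx] <- sort(sample.int(config$chromLength, length(idx)))
  }
  data.frame(gene_id = sprintf("gene%05d", seq_len(g)),
             chrom = paste0("chr", chrom), start = start,
             stringsAsFactors = FALSE)
}

#' Plant the genetic architecture
#'
#' Marks every (SNP, gene) pair cis-eligible when the SNP and the gene
#' start are within \code{cisWindowSim} bp on the same chromosome, samples
#' without replacement \code{round(cisFraction * nPairs)} cis pairs and the
#' remainder from trans-eligible pairs, then samples \code{nBroad} broad
#' impact SNPs (disjoint from the single-pair SNPs) each assigned a uniform
#' random gene set of size \code{round(broadGeneFraction * nGenes)}. Effect
#' sizes are independent draws per (SNP, gene) pair from the category's
#' normal distribution.
#'
#' @param G simulated \linkS4class{GenotypeMatrix}.
#' @param geneAnn gene annotation from \code{\link{simulateGeneAnnotation}}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return list of class "SimulationTruth": \code{pairs} data.frame
#'   (snp_id, gene_id, category, effect) and \code{config}.
#' @export
sampleArchitecture <- function(G, geneAnn, config, seed = 1L) {
  set.seed(as.integer(seed) + 1000000L)
  snpAnn <- snpAnnotation(G)
  s <- nrow(snpAnn); g <- nrow(geneAnn)
  nCis <- round(config$cisFraction * config$nPairs)
  nTrans <- config$nPairs - nCis

  # enumerate cis-eligible pairs chromosome by chromosome
  cisPairs <- vector("list", length(unique(snpAnn$chrom)))
  names(cisPairs) <- unique(snpAnn$chrom)
  for (chr in unique(snpAnn$chrom)) {
    siOn <- which(snpAnn$chrom == chr)
    giOn <- which(geneAnn$chrom == chr)
    if (!length(siOn) || !length(giOn)) next
    d <- abs(outer(snpAnn$pos[siOn], geneAnn$start[giOn], "-"))
    hit <- which(d <= config$cisWindowSim, arr.ind = TRUE)
    if (nrow(hit))
      cisPairs[[chr]] <- cbind(siOn[hit[, 1]], giOn[hit[, 2]])
  }
  cisAll <- do.call(rbind, cisPairs)
  if (is.null(cisAll)) cisAll <- matrix(integer(0), 0, 2)
  if (nrow(cisAll) < nCis)
    stop("not enough cis-eligible pairs; widen cisWindowSim or add SNPs")
  cisSel <- cisAll[sample.int(max(nrow(cisAll), 1), nCis), ,
                   drop = FALSE]

  # trans pairs: rejection-sample (SNP, gene) pairs violating the cis rule
  transSel <- matrix(integer(0), 0, 2)
  cisKey <- cisAll[, 1] + as.numeric(s) * cisAll[, 2]
  takenKey <- cisSel[, 1] + as.numeric(s) * cisSel[, 2]
  while (nrow(transSel) < nTrans) {
    m <- (nTrans - nrow(transSel)) * 2L + 10L
    cand <- cbind(sample.int(s, m, replace = TRUE),
                  sample.int(g, m, replace = TRUE))
    key <- cand[, 1] + as.numeric(s) * cand[, 2]
    ok <- !(key %in% cisKey) & !(key %in% takenKey) & !duplicated(key)
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand)) {
      take <- head(seq_len(nrow(cand)), nTrans - nrow(transSel))
      transSel <- rbind(transSel, cand[take, , drop = FALSE])
      takenKey <- c(takenKey, (cand[take, 1] +
                               as.numeric(s) * cand[take, 2]))
    }
  }

  singleSnps <- unique(c(cisSel[, 1], transSel[, 1]))
  pool <- setdiff(seq_len(s), singleSnps)
  if (length(pool) < config$nBroad)
    stop("not enough SNPs left for broad impact loci")
  broadSnps <- sample(pool, config$nBroad)
  nBroadGenes <- round(config$broadGeneFraction * g)
  broadList <- lapply(broadSnps, function(sn)
    cbind(sn, sample.int(g, nBroadGenes)))
  broadSel <- do.call(rbind, broadList)
  if (is.null(broadSel)) broadSel <- matrix(integer(0), 0, 2)

  mk <- function(sel, category, eff) {
    if (nrow(sel) == 0L)
      return(data.frame(snp_id = character(), gene_id = character(),
                        category = character(), effect = numeric(),
                        stringsAsFactors = FALSE))
    data.frame(snp_id = snpAnn$snp_id[sel[, 1]],
               gene_id = geneAnn$gene_id[sel[, 2]],
               category = category,
               effect = rnorm(nrow(sel), eff["mean"], eff["sd"]),
               stringsAsFactors = FALSE)
  }
  pairs <- rbind(mk(cisSel, "cis", config$cisEffect),
                 mk(transSel, "trans", config$transEffect),
                 mk(broadSel, "broad", config$transEffect))
  structure(list(pairs = pairs, geneAnn = geneAnn, config = config,
                 seed = as.integer(seed)),
            class = "SimulationTruth")
}

#' Simulate expression from the planted architecture
#'
#' Y[i, p] = sum over planted pairs (m, p) of beta_mp G[i, m]
#' + sum over confounders f of score_f[i] w_f[p] + noise, with noise
#' ~ N(0, 1). Sparse confounder weights are nonzero on a uniform random
#' \code{sparseCoverage} fraction of genes with values ~ N(1, 0.5); dense
#' weights cover all genes ~ N(0, 1); per-sample scores are ~ N(0, 1).
#'
#' @param G simulated \linkS4class{GenotypeMatrix}.
#' @param truth output of \code{\link{sampleArchitecture}}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return An \linkS4class{ExpressionMatrix} (tag "simulated") with a
#'   \code{confounders} attribute holding scores and weights.
#' @export
simulateExpression <- function(G, truth, config, seed = 1L) {
  set.seed(as.integer(seed) + 2000000L)
  gv <- G@values
  n <- nrow(gv); g <- config$nGenes
  geneIds <- truth$geneAnn$gene_id
  Y <- matrix(rnorm(n * g), n, g, dimnames = list(rownames(gv), geneIds))

  pr <- truth$pairs
  if (nrow(pr)) {
    si <- match(pr$snp_id, colnames(gv))
    gi <- match(pr$gene_id, geneIds)
    for (r in seq_len(nrow(pr)))
      Y[, gi[r]] <- Y[, gi[r]] + pr$effect[r] * gv[, si[r]]
  }

  nf <- config$nSparse + config$nDense
  confounders <- NULL
  if (nf > 0) {
    scores <- matrix(rnorm(n * nf), n, nf)
    weights <- matrix(0, nf, g)
    type <- c(rep("sparse", config$nSparse), rep("dense", config$nDense))
    for (f in seq_len(nf)) {
      if (type[f] == "sparse") {
        hit <- sample.int(g, round(config$sparseCoverage * g))
        weights[f, hit] <- rnorm(length(hit), 1, 0.5)
      } else {
        weights[f, ] <- rnorm(g)
      }
    }
    Y <- Y + scores %*% weights
    confounders <- list(scores = scores, weights = weights, type = type)
  }
  E <- ExpressionMatrix(Y, geneAnnotation = truth$geneAnn,
                        tag = "simulated")
  attr(E, "confounders") <- confounders
  E
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper chaining \code{\link{simulateGenotypes}},
#' \code{\link{simulateGeneAnnotation}}, \code{\link{sampleArchitecture}}
#' and \code{\link{simulateExpression}} off one seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return list with E (ExpressionMatrix), G (GenotypeMatrix), truth.
#' @export
simulateDataset <- function(config, seed = 1L) {
  G <- simulateGenotypes(config, seed)
  geneAnn <- simulateGeneAnnotation(config, seed)
  truth <- sampleArchitecture(G, geneAnn, config, seed)
  E <- simulateExpression(G, truth, config, seed)
  list(E = E, G = G, truth = truth)
}
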