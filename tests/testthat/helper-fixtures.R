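# shared fixtures and independent oracles, built in code at test time

sampleIds <- function(n) sprintf("s%03d", seq_len(n))
geneIds <- function(g) sprintf("g%03d", seq_len(g))
snpIds <- function(s) sprintf("m%03d", seq_len(s))

randomExpression <- function(n, g, seed = 1, annotate = TRUE) {
  set.seed(seed)
  v <- matrix(rnorm(n * g), n, g,
              dimnames = list(sampleIds(n), geneIds(g)))
  ann <- if (annotate)
    data.frame(gene_id = geneIds(g),
               chrom = paste0("chr", ((seq_len(g) - 1) %% 4) + 1),
               start = seq_len(g) * 50000L, stringsAsFactors = FALSE)
  else NULL
  ExpressionMatrix(v, geneAnnotation = ann)
}

randomGenotypes <- function(n, s, seed = 1, ploidy = 2L,
                            maf = NULL, chrom = NULL, pos = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(s, 0.1, 0.5)
  v <- matrix(rbinom(n * s, ploidy, rep(maf, each = n)), n, s,
              dimnames = list(sampleIds(n), snpIds(s)))
  if (is.null(chrom)) chrom <- paste0("chr", ((seq_len(s) - 1) %% 4) + 1)
  if (is.null(pos)) pos <- seq_len(s) * 10000L
  ann <- data.frame(snp_id = snpIds(s), chrom = chrom,
                    pos = as.integer(pos), stringsAsFactors = FALSE)
  GenotypeMatrix(v, ann, ploidy = ploidy)
}

identityK <- function(n) {
  m <- diag(n)
  dimnames(m) <- list(sampleIds(n), sampleIds(n))
  externalK(m)
}

# dense multivariate-normal likelihood oracle for the single-kinship LMM:
# profiled ML over a 1e4-point h2 grid with local grid refinement; direct
# solve/determinant linear algebra, no eigendecomposition
denseLmmOracle <- function(y, X, Km, nGrid = 10000L) {
  n <- length(y)
  evalAt <- function(h2) {
    V <- h2 * Km + (1 - h2) * diag(n)
    Vi <- solve(V)
    XtVi <- t(X) %*% Vi
    beta <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) +
                  as.numeric(determinant(V)$modulus) + n)
    se <- sqrt(diag(solve(XtVi %*% X)) * rss / (n - ncol(X)))
    list(ll = ll, h2 = h2, beta = drop(beta), se = se,
         p = 2 * pnorm(-abs(drop(beta)[1] / se[1])))
  }
  grid <- seq(0, 1 - 1e-6, length.out = nGrid)
  best <- list(ll = -Inf)
  for (h2 in grid) {
    f <- evalAt(h2)
    if (f$ll > best$ll) best <- f
  }
  width <- grid[2] - grid[1]
  fine <- seq(max(0, best$h2 - width), min(1 - 1e-6, best$h2 + width),
              length.out = 2001)
  for (h2 in fine) {
    f <- evalAt(h2)
    if (f$ll > best$ll) best <- f
  }
  best
}

# brute-force Benjamini-Hochberg step-up: p_(i) * m / i then cumulative
# minimum from the largest p downward, capped at 1
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# brute-force AUC: fraction of (positive, negative) pairs where the
# positive has the smaller p, ties counted half
aucOracle <- function(p, isPos) {
  pp <- p[isPos]; pn <- p[!isPos]
  tot <- 0
  for (a in pp) tot <- tot + sum(a < pn) + 0.5 * sum(a == pn)
  tot / (length(pp) * length(pn))
}

scaledBenchmarkConfig <- function(scenario = "sparse") {
  simulationConfig(nSamples = 150L, nSnps = 600L, nGenes = 600L,
                   nPairs = 400L, nBroad = 2L,
                   nSparse = if (scenario == "none") 0L else 10L,
                   nDense = 0L,
                   scenario = scenario, nDatasets = 10L)
}
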