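test_that("with K = I the mixed model collapses to the OLS Wald test", {
  set.seed(42)
  n <- 40
  y <- rnorm(n)
  gsnp <- rbinom(n, 2, 0.3)
  cv <- rnorm(n)
  f <- fitGeneLmm(y, cbind(gsnp, 1, cv), identityK(n))
  ols <- lm(y ~ gsnp + cv)
  seOls <- summary(ols)$coefficients["gsnp", "Std. Error"]
  pOls <- 2 * pnorm(-abs(coef(ols)[["gsnp"]] / seOls))
  expect_lt(abs(f$p - pOls), 1e-10)
  expect_lt(abs(f$beta[1] - coef(ols)[["gsnp"]]), 1e-10)
  expect_equal(f$wald, (f$beta[1] / f$seBeta[1])^2, tolerance = 1e-12)
})

test_that("exact fits match the dense likelihood-grid oracle", {
  set.seed(7)
  reps <- 12
  for (r in seq_len(reps)) {
    n <- sample(15:30, 1)
    Z <- matrix(rnorm(n * 6), n, 6)
    Km <- tcrossprod(Z) / 6
    Km <- Km / mean(diag(Km))
    dimnames(Km) <- list(sampleIds(n), sampleIds(n))
    gsnp <- rbinom(n, 2, 0.3)
    y <- 0.4 * gsnp + drop(chol(0.6 * Km + 0.4 * diag(n)) %*% rnorm(n))
    X <- cbind(gsnp, 1)
    f <- fitGeneLmm(y, X, externalK(Km))
    o <- denseLmmOracle(y, X, Km)
    expect_lt(abs(f$p - o$p), 1e-6)
    expect_lt(abs(f$loglik - o$ll) / abs(o$ll), 1e-6)
  }
})

test_that("noiseless signal is recovered with an underflowing p-value", {
  set.seed(9)
  n <- 30
  gsnp <- rbinom(n, 2, 0.4)
  cv <- rnorm(n)
  y <- 2 * gsnp + 0.5 * cv + 1
  Z <- matrix(rnorm(n * 5), n, 5)
  Km <- tcrossprod(Z) / 5
  dimnames(Km) <- list(sampleIds(n), sampleIds(n))
  f <- fitGeneLmm(y, cbind(gsnp, 1, cv), externalK(Km))
  expect_lt(abs(f$beta[1] - 2), 1e-8)
  expect_lt(f$p, 1e-100)
  # degenerate inputs
  expect_error(fitGeneLmm(rep(1, n), cbind(gsnp, 1), externalK(Km)),
               "zero-variance")
  fc <- fitGeneLmm(y, cbind(gsnp, 1, gsnp), externalK(Km))
  expect_true(is.na(fc$p))  # collinear design gives an NA record
})

test_that("variance components are nonnegative and h2 consistent", {
  set.seed(77)
  n <- 50
  Z <- matrix(rnorm(n * 8), n, 8)
  Km <- tcrossprod(Z) / 8
  dimnames(Km) <- list(sampleIds(n), sampleIds(n))
  K <- externalK(Km)
  for (r in 1:5) {
    y <- drop(chol(0.7 * Km / mean(diag(Km)) + 0.3 * diag(n)) %*% rnorm(n))
    gsnp <- rbinom(n, 2, 0.3)
    f <- fitGeneLmm(y, cbind(gsnp, 1), K)
    expect_gte(f$tau2, 0)
    expect_gte(f$sigma2, 0)
    expect_equal(f$h2, f$tau2 / (f$tau2 + f$sigma2), tolerance = 1e-9)
    expect_true(f$p >= 0 && f$p <= 1)
  }
})

test_that("the scan emits one record per (gene, SNP) pair", {
  E <- randomExpression(25, 2, seed = 51)
  G <- randomGenotypes(25, 3, seed = 52)
  tab <- eqtlScan(E, G, method = "linear")
  expect_identical(nrow(tab), 6L)
  expect_setequal(paste(tab$gene, tab$snp),
                  as.vector(outer(geneIds(2), snpIds(3), paste)))
  expect_true(all(tab$p_adj >= tab$p, na.rm = TRUE))
  expect_identical(unique(tab$method), "linear")
  # monomorphic SNP yields NA records but stays in the table
  v <- genoValues(G); v[, 2] <- 1
  Gm <- GenotypeMatrix(v, snpAnnotation(G))
  tabM <- eqtlScan(E, Gm, method = "linear")
  expect_identical(nrow(tabM), 6L)
  expect_true(all(is.na(tabM$p[tabM$snp == "m002"])))
})

test_that("linear-scan p-values are uniform under the null", {
  E <- randomExpression(100, 20, seed = 61)
  G <- randomGenotypes(100, 50, seed = 62)
  tab <- eqtlScan(E, G, method = "linear")
  ks <- suppressWarnings(ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixed-model scan matches per-pair exact fits in null_fixed mode", {
  set.seed(71)
  E <- randomExpression(30, 4, seed = 71)
  G <- randomGenotypes(30, 5, seed = 72)
  K <- buildIceK(E)
  tab <- eqtlScan(E, G, K = K, method = "ice", mode = "null_fixed")
  X0 <- matrix(1, 30, 1)
  for (gene in geneIds(4)) {
    y <- exprValues(E)[, gene]
    h2 <- nullModelH2(y, X0, K)
    for (snp in snpIds(5)) {
      f <- fitGeneLmm(y, cbind(genoValues(G)[, snp], 1), K, h2 = h2)
      row <- tab[tab$gene == gene & tab$snp == snp, ]
      expect_lt(abs(row$p - f$p), 1e-10)
      expect_lt(abs(row$beta - f$beta[1]), 1e-10)
    }
  }
  # exact mode agrees with fitGeneLmm's own optimum
  tabE <- eqtlScan(E, G, K = K, method = "ice", mode = "exact")
  y <- exprValues(E)[, "g002"]
  fE <- fitGeneLmm(y, cbind(genoValues(G)[, "m003"], 1), K)
  rowE <- tabE[tabE$gene == "g002" & tabE$snp == "m003", ]
  expect_equal(rowE$p, fE$p, tolerance = 1e-12)
})

test_that("scan results are invariant to permuting sample order", {
  E <- randomExpression(20, 3, seed = 81)
  G <- randomGenotypes(20, 4, seed = 82)
  K <- buildIceK(E)
  tab1 <- eqtlScan(E, G, K = K, method = "ice")
  set.seed(5)
  perm <- sample(20)
  Ep <- ExpressionMatrix(exprValues(E)[perm, ],
                         geneAnnotation = geneAnnotation(E))
  Gp <- GenotypeMatrix(genoValues(G)[perm, ], snpAnnotation(G))
  Kp <- buildIceK(Ep)
  tab2 <- eqtlScan(Ep, Gp, K = Kp, method = "ice")
  ord1 <- order(tab1$gene, tab1$snp); ord2 <- order(tab2$gene, tab2$snp)
  expect_equal(tab1$p[ord1], tab2$p[ord2], tolerance = 1e-9)
})

test_that("a planted cis effect wins its gene's row", {
  reps <- 15; wins <- 0
  for (r in seq_len(reps)) {
    set.seed(900 + r)
    n <- 100
    G <- randomGenotypes(n, 40, seed = 900 + r)
    Y <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(sampleIds(n), geneIds(5)))
    Y[, 2] <- Y[, 2] + 0.8 * genoValues(G)[, 17]
    tab <- eqtlScan(ExpressionMatrix(Y), G, method = "linear")
    row <- tab[tab$gene == "g002", ]
    if (row$snp[which.min(row$p)] == "m017") wins <- wins + 1
  }
  expect_gte(wins / reps, 0.95)
})

test_that("pca_fixed appends the rule-determined number of expression PCs", {
  E <- randomExpression(60, 50, seed = 91)
  G <- randomGenotypes(60, 5, seed = 92)
  tab <- eqtlScan(E, G, method = "pca_fixed", nFactorsSmall = 5L)
  expect_identical(nrow(tab), 250L)
  # removing expression PCs as fixed effects changes the p-values
  tabL <- eqtlScan(E, G, method = "linear")
  expect_gt(max(abs(tab$p - tabL$p), na.rm = TRUE), 1e-8)
  expect_error(eqtlScan(E, G, K = buildIceK(E), method = "linear"),
               "must not")
  expect_error(eqtlScan(E, G, method = "ice"), "needs a SampleCovariance")
})

test_that("genomic inflation follows the chi-square quantile identity", {
  expect_equal(genomicInflation(c(0.2, 0.5, 0.9))$lambda, 1,
               tolerance = 1e-12)
  expect_equal(genomicInflation(c(0.2, 0.5, 0.9))$lambdaDiff, 0,
               tolerance = 1e-12)
  gi <- genomicInflation(rep(0.25, 5))
  expect_equal(gi$lambda, qchisq(0.75, 1) / qchisq(0.5, 1),
               tolerance = 1e-12)
  expect_equal(genomicInflation(rep(1, 3))$lambda, 0, tolerance = 1e-12)
  expect_error(genomicInflation(c(0, 0.5)), "strictly positive")
  expect_error(genomicInflation(numeric(0)), "empty")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (r in 1:5) {
    p <- runif(sample(5:50, 1))^2
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("per-gene lambda is near 1 on null data scanned with its own K", {
  # K must be estimated from many more genes than samples, as in real
  # expression panels; with few genes the covariance memorizes each gene
  E <- randomExpression(200, 500, seed = 95)
  G <- randomGenotypes(200, 60, seed = 96)
  K <- buildIceK(E)
  tab <- eqtlScan(E, G, K = K, method = "ice")
  med <- median(tab$lambda_gene[!duplicated(tab$gene)])
  expect_gt(med, 0.9)
  expect_lt(med, 1.1)
})
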