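# Profiled log-likelihood machinery for the single-random-effect LMM
#   y = X beta + c + e,  c ~ N(0, tau2 K), e ~ N(0, sigma2 I).
# After rotating by the eigenvectors U of K (K = U D U'), the covariance is
# diagonal: s2tot * (h2 D + (1 - h2) I) with h2 = tau2 / (tau2 + sigma2).
# The total scale s2tot and beta are profiled out analytically; h2 is found
# by a bracketing grid plus bounded scalar refinement.

H2_MAX <- 1 - 1e-6

# profiled ML log-likelihood and GLS fit at a fixed h2 (rotated inputs)
profiledFit <- function(h2, yr, Xr, d) {
  n <- length(yr)
  w <- h2 * d + (1 - h2)
  sw <- sqrt(w)
  Xw <- Xr / sw
  yw <- yr / sw
  xtx <- crossprod(Xw)
  beta <- tryCatch(solve(xtx, crossprod(Xw, yw)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  s2ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2ml) + sum(log(w)) + n)
  list(beta = drop(beta), rss = rss, xtxInv = solve(xtx), ll = ll,
       s2ml = s2ml)
}

optimizeH2 <- function(yr, Xr, d, nGrid = 64L, tol = 1e-8) {
  # log-spaced bracketing grid over [0, H2_MAX]
  grid <- c(0, exp(seq(log(1e-6), log(H2_MAX), length.out = nGrid - 1L)))
  lls <- vapply(grid, function(h) {
    f <- profiledFit(h, yr, Xr, d)
    if (is.null(f)) -Inf else f$ll
  }, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (hi > lo) {
    opt <- optimize(function(h) profiledFit(h, yr, Xr, d)$ll,
                    interval = c(lo, hi), maximum = TRUE, tol = tol)
    if (opt$objective >= lls[i]) return(opt$maximum)
  }
  grid[i]
}

#' Fit the mixed model for one gene and one design
#'
#' Fits y = X beta + c + e with c ~ N(0, tau2 K) and e ~ N(0, sigma2 I) by
#' rotating y and X into the eigenbasis of K, profiling beta and the total
#' variance out of the Gaussian likelihood, and maximizing over the
#' heritability ratio h2 = tau2 / (tau2 + sigma2) on [0, 1 - 1e-6] with a
#' 64-point bracketing grid followed by bounded scalar refinement
#' (tolerance 1e-8). The genotype Wald statistic uses the generalized
#' least squares estimate at the optimum with residual scale estimated on
#' n - p degrees of freedom, referred to the standard normal (so with
#' K = I the p-value reduces exactly to the OLS normal-reference Wald p).
#'
#' @param y numeric response vector (one gene's expression).
#' @param X design matrix whose FIRST column is the genotype; an intercept
#'   column is appended automatically if absent.
#' @param K a \linkS4class{SampleCovariance} (eigendecomposition cached).
#' @param h2 optional fixed heritability ratio: supply the value estimated
#'   under the covariates-only null to get EMMAX-style per-SNP testing
#'   without re-optimizing (see \code{\link{nullModelH2}}).
#' @return list with elements beta, seBeta (genotype first), wald (squared
#'   z), p, tau2, sigma2, h2, loglik, converged.
#' @export
fitGeneLmm <- function(y, X, K, h2 = NULL) {
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1]))))
    X <- cbind(X, intercept = 1)
  n <- length(y)
  if (sd(y) == 0) stop("zero-variance expression vector")
  e <- covEigen(K)
  U <- e$vectors; d <- e$values
  d <- d / mean(d)   # normalize scale; absorbed by s2tot
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)
  if (qr(Xr)$rank < ncol(Xr)) {
    return(list(beta = NA_real_, seBeta = NA_real_, wald = NA_real_,
                p = NA_real_, tau2 = NA_real_, sigma2 = NA_real_,
                h2 = NA_real_, loglik = NA_real_, converged = FALSE))
  }
  if (is.null(h2)) h2 <- optimizeH2(yr, Xr, d)
  fit <- profiledFit(h2, yr, Xr, d)
  p <- ncol(X)
  s2df <- fit$rss / (n - p)
  se <- sqrt(diag(fit$xtxInv) * s2df)
  z <- fit$beta[1] / se[1]
  list(beta = fit$beta, seBeta = se, wald = z^2,
       p = 2 * pnorm(-abs(z)), tau2 = h2 * fit$s2ml,
       sigma2 = (1 - h2) * fit$s2ml, h2 = h2, loglik = fit$ll,
       converged = TRUE)
}

#' Heritability ratio under the covariates-only null model
#'
#' Estimates h2 = tau2 / (tau2 + sigma2) for one gene with the genotype
#' excluded from the design. Reusing this value for every SNP of the gene
#' (EMMAX-style) makes the genome-wide scan tractable.
#'
#' @param y numeric expression vector.
#' @param X0 covariate design including the intercept.
#' @param K a \linkS4class{SampleCovariance}.
#' @return numeric h2 in [0, 1).
#' @export
nullModelH2 <- function(y, X0, K) {
  e <- covEigen(K)
  d <- e$values / mean(e$values)
  yr <- drop(crossprod(e$vectors, y))
  Xr <- crossprod(e$vectors, as.matrix(X0))
  optimizeH2(yr, Xr, d)
}

#' Genome-wide eQTL scan
#'
#' Tests every (gene, SNP) pair with the selected analysis method and
#' returns one record per pair. Methods:
#' \describe{
#'   \item{confeti_i / ice / external}{linear mixed model with the supplied
#'     \linkS4class{SampleCovariance} as random effect. Mode
#'     \code{"null_fixed"} (default) estimates the variance-component ratio
#'     once per gene under the covariates-only null and reuses it for every
#'     SNP; mode \code{"exact"} re-optimizes per SNP.}
#'   \item{linear}{ordinary least squares with no confounder correction.}
#'   \item{pca_fixed}{OLS with expression principal components appended to
#'     the covariates; the component count follows the sample-size rule
#'     (n in (150, 250] uses 30, n > 250 uses 35, n <= 150 uses
#'     \code{nFactorsSmall}), capped at n - v - 3.}
#' }
#' Wald p-values use the standard normal reference; monomorphic SNPs give
#' NA records. Benjamini-Hochberg adjustment is applied globally across all
#' tested pairs, and the per-gene genomic inflation factor lambda is
#' attached to every record of a gene.
#'
#' @param E an \linkS4class{ExpressionMatrix}.
#' @param G a \linkS4class{GenotypeMatrix} (samples are aligned with E by
#'   id, preserving expression order).
#' @param K \linkS4class{SampleCovariance} for mixed-model methods; must be
#'   absent for linear / pca_fixed.
#' @param C optional numeric covariate matrix (samples x covariates).
#' @param method one of "confeti_i", "ice", "external", "linear",
#'   "pca_fixed".
#' @param mode "null_fixed" or "exact" (mixed-model methods only).
#' @param nFactorsSmall expression-PC count for n <= 150 (default 10).
#' @return data.frame (an eQTL table): gene, snp, beta, se, p, p_adj,
#'   lambda_gene, label ("unlabeled" until \code{\link{labelCisTrans}}),
#'   method.
#' @export
eqtlScan <- function(E, G, K = NULL, C = NULL,
                     method = c("confeti_i", "ice", "external", "linear",
                                "pca_fixed"),
                     mode = c("null_fixed", "exact"),
                     nFactorsSmall = 10L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  mixed <- method %in% c("confeti_i", "ice", "external")
  if (mixed && is.null(K))
    stop("method '", method, "' needs a SampleCovariance K")
  if (!mixed && !is.null(K))
    stop("method '", method, "' must not be given a K")
  if (mixed && !identical(covMethod(K), method) &&
      !(covMethod(K) == "external"))
    warning("K was built with method '", covMethod(K),
            "' but the scan is tagged '", method, "'")

  al <- alignSamples(E, G, C)
  Y <- al$E@values; gv <- al$G@values
  C <- if (is.null(C)) NULL else as.matrix(al$C)
  n <- nrow(Y); g <- ncol(Y); s <- ncol(gv)
  if (mixed && nrow(covMatrix(K)) != n)
    stop("K dimension does not match the aligned sample count")

  X0 <- cbind(intercept = rep(1, n), C)
  if (method == "pca_fixed") {
    v <- if (n <= 150) as.integer(nFactorsSmall)
         else if (n <= 250) 30L else 35L
    v <- min(v, n - ncol(X0) - 3L)
    yc <- sweep(Y, 2, colMeans(Y))
    sv <- svd(yc, nu = v, nv = 0)
    pcs <- sv$u[, seq_len(v), drop = FALSE]
    colnames(pcs) <- paste0("ExprPC", seq_len(v))
    X0 <- cbind(X0, pcs)
  }
  p0 <- ncol(X0)
  gSd <- apply(gv, 2, sd)
  poly <- gSd > 0

  beta <- se <- pval <- matrix(NA_real_, g, s)
  if (!mixed) {
    # OLS: residualize genotypes and responses on X0 once
    qrX <- qr(X0)
    Gr <- qr.resid(qrX, gv[, poly, drop = FALSE])
    gg <- colSums(Gr^2)
    Yr <- qr.resid(qrX, Y)
    yy <- colSums(Yr^2)
    gy <- crossprod(Yr, Gr)              # g x s_poly
    b <- sweep(gy, 2, gg, "/")
    rss <- pmax(yy - b * gy, 0)           # g x s_poly, yy recycled by column
    df <- n - p0 - 1L
    s2 <- rss / df
    seM <- sqrt(sweep(s2, 2, gg, "/"))
    zM <- b / seM
    pM <- 2 * pnorm(-abs(zM))
    beta[, poly] <- b; se[, poly] <- seM; pval[, poly] <- pM
  } else {
    e <- covEigen(K)
    U <- e$vectors
    d <- e$values / mean(e$values)
    Yr <- crossprod(U, Y)
    GrAll <- crossprod(U, gv[, poly, drop = FALSE])
    X0r <- crossprod(U, X0)
    df <- n - p0 - 1L
    for (pIdx in seq_len(g)) {
      yr <- Yr[, pIdx]
      if (mode == "exact") {
        for (jj in which(poly)) {
          f <- fitGeneLmm(Y[, pIdx], cbind(gv[, jj], X0), K)
          beta[pIdx, jj] <- f$beta[1]; se[pIdx, jj] <- f$seBeta[1]
          pval[pIdx, jj] <- f$p
        }
      } else {
        h2 <- optimizeH2(yr, X0r, d)
        w <- h2 * d + (1 - h2)
        sw <- sqrt(w)
        yw <- yr / sw
        Xw <- X0r / sw
        Gw <- GrAll / sw
        qrX <- qr(Xw)
        ywr <- qr.resid(qrX, yw)
        Gwr <- qr.resid(qrX, Gw)
        gg <- colSums(Gwr^2)
        gy <- drop(crossprod(Gwr, ywr))
        b <- gy / gg
        rss <- pmax(sum(ywr^2) - b * gy, 0)
        s2 <- rss / df
        sev <- sqrt(s2 / gg)
        z <- b / sev
        beta[pIdx, poly] <- b
        se[pIdx, poly] <- sev
        pval[pIdx, poly] <- 2 * pnorm(-abs(z))
      }
    }
  }

  lambda <- vapply(seq_len(g), function(pIdx) {
    pp <- pval[pIdx, ]
    pp <- pp[!is.na(pp)]
    if (!length(pp)) return(NA_real_)
    genomicInflation(pmax(pp, .Machine$double.xmin))$lambda
  }, numeric(1))

  tab <- data.frame(
    gene = rep(colnames(Y), times = s),
    snp = rep(colnames(gv), each = g),
    beta = as.vector(beta), se = as.vector(se), p = as.vector(pval),
    stringsAsFactors = FALSE)
  tab$p_adj <- bhAdjust(tab$p)
  tab$lambda_gene <- rep(lambda, times = s)
  tab$label <- "unlabeled"
  tab$method <- method
  tab
}

#' Per-gene genomic inflation factor
#'
#' lambda = qchisq(1 - median(p), 1) / qchisq(0.5, 1): the ratio of the
#' chi-square quantile at the observed median p-value to the null median of
#' the 1-df chi-square. lambda = 1 for a calibrated test, > 1 for inflation;
#' lambda_diff = 1 - lambda.
#'
#' @param p numeric vector of p-values in (0, 1]; p = 0 is an error
#'   (substitute the smallest representable positive value upstream).
#' @return list with medianP, lambda, lambdaDiff.
#' @export
genomicInflation <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p <= 0))
    stop("p-values must be strictly positive for the inflation factor")
  if (any(p > 1)) stop("p-values must be at most 1")
  m <- median(p)
  lambda <- qchisq(1 - m, df = 1) / qchisq(0.5, df = 1)
  list(medianP = m, lambda = lambda, lambdaDiff = 1 - lambda)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (monotone, capped at 1), order-preserving
#' with the input; NA entries stay NA and do not count toward the number of
#' tests.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  p.adjust(p, method = "BH")
}
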