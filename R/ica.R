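#' Choose the number of independent components from PCA variance
#'
#' Returns the smallest k such that the top-k principal components of the
#' per-gene mean-centered expression matrix explain at least
#' \code{varianceTarget} of the total variance. This keeps the retained ICA
#' subspace comparable across methods that fix their component count the
#' same way.
#'
#' @param E an \linkS4class{ExpressionMatrix}.
#' @param varianceTarget fraction of variance to capture, in (0, 1]
#'   (default 0.95).
#' @return integer k, between 1 and min(n, g) - 1 (or the full rank when
#'   \code{varianceTarget} is 1).
#' @export
selectComponentCount <- function(E, varianceTarget = 0.95) {
  stopifnot(varianceTarget > 0, varianceTarget <= 1)
  v <- E@values
  yc <- sweep(v, 2, colMeans(v))
  d2 <- svd(yc, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot <= 0) stop("expression matrix is constant: zero total variance")
  cum <- cumsum(d2) / tot
  k <- which(cum >= varianceTarget - 1e-12)[1]
  max(1L, as.integer(k))
}

# symmetric fixed-point FastICA, log-cosh contrast, on pre-whitened rows.
# Z: k x g whitened data (rows unit variance wrt 1/g); returns unmixing W.
fastIcaCore <- function(Z, tol, maxIter) {
  k <- nrow(Z); g <- ncol(Z)
  W <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  symDecorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), k) %*%
      t(e$vectors) %*% W
  }
  W <- symDecorrelate(W)
  it <- 0L; converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    WX <- W %*% Z
    gwx <- tanh(WX)
    W1 <- gwx %*% t(Z) / g - diag(rowMeans(1 - gwx^2), k) %*% W
    W1 <- symDecorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged, nIter = it)
}

#' FastICA decomposition of an expression matrix
#'
#' Centers each gene, whitens to the top-k principal subspace, and runs
#' symmetric (parallel) fixed-point FastICA with the log-cosh contrast to
#' estimate sources maximally non-Gaussian over genes. The decomposition
#' satisfies \code{A \%*\% S} = rank-k PCA truncation of the centered
#' matrix. Rows of S are scaled to unit sample variance with their
#' largest-magnitude entry positive; components are ordered by decreasing
#' variance of the corresponding column of A. On non-convergence the run is
#' restarted with incremented seeds up to \code{nRestarts} times before
#' returning with \code{converged = FALSE}.
#'
#' @param E an \linkS4class{ExpressionMatrix}; no gene may have zero
#'   variance (use \code{\link{filterExpression}} first).
#' @param k number of components (default from
#'   \code{\link{selectComponentCount}} at 95\% variance).
#' @param seed integer seed; identical inputs give bitwise-identical output.
#' @param tol fixed-point convergence tolerance (default 1e-4).
#' @param maxIter maximum fixed-point iterations per run (default 1000).
#' @param nRestarts restart attempts on non-convergence (default 3).
#' @param scaleGenes also divide each centered gene by its standard
#'   deviation before decomposition (default FALSE: centering only, so the
#'   reconstruction stays in the original units).
#' @return An \linkS4class{IcaDecomposition}.
#' @export
icaDecompose <- function(E, k = NULL, seed = 1L, tol = 1e-4,
                         maxIter = 1000L, nRestarts = 3L,
                         scaleGenes = FALSE) {
  v <- E@values
  n <- nrow(v); g <- ncol(v)
  center <- colMeans(v)
  yc <- sweep(v, 2, center)
  sds <- apply(v, 2, sd)
  if (any(sds == 0))
    stop("zero-variance gene present (e.g. ", colnames(v)[sds == 0][1],
         "); run filterExpression first")
  if (scaleGenes) yc <- sweep(yc, 2, sds, "/")
  if (is.null(k)) k <- selectComponentCount(E, 0.95)
  k <- as.integer(k)
  if (k > min(n, g)) stop("k must not exceed min(n, g)")

  # whiten: rows of Z = D^{-1/2} t(U) yc are uncorrelated, variance 1 (1/g)
  sv <- svd(yc, nu = k, nv = 0)
  if (sv$d[k] <= sv$d[1] * 1e-12)
    stop("centered expression matrix has rank below k")
  dk <- sv$d[seq_len(k)]
  Z <- t(sv$u) %*% yc * sqrt(g) / dk   # k x g

  attempt <- 0L; res <- NULL
  while (attempt <= nRestarts) {
    set.seed(as.integer(seed) + attempt)
    res <- fastIcaCore(Z, tol = tol, maxIter = maxIter)
    if (res$converged) break
    attempt <- attempt + 1L
  }
  S <- res$W %*% Z                       # k x g, rows ~ unit var (1/g)
  # A solves yc ~ A S in least squares; rows of S orthonormal wrt 1/g
  A <- yc %*% t(S) / g

  # scale convention: unit sample variance rows of S (g - 1 denominator)
  rowSd <- sqrt(rowSums(sweep(S, 1, rowMeans(S))^2) / (g - 1))
  S <- S / rowSd
  A <- A * rep(rowSd, each = n)
  # sign: largest |S| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(S[j, ]))
    if (S[j, i] < 0) { S[j, ] <- -S[j, ]; A[, j] <- -A[, j] }
  }
  # order by decreasing variance of A columns
  ord <- order(apply(A, 2, var), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  dimnames(A) <- list(rownames(v), paste0("IC", seq_len(k)))
  dimnames(S) <- list(paste0("IC", seq_len(k)), colnames(v))
  new("IcaDecomposition", A = A, S = S, k = k,
      center = unname(center), seed = as.integer(seed),
      converged = res$converged, nIter = res$nIter)
}

#' Component replication across independent ICA runs
#'
#' Runs \code{\link{icaDecompose}} with \code{nRuns} distinct seeds and
#' greedily matches components of every later run to the components of the
#' first run by maximal absolute Pearson correlation of their source (S)
#' rows. For each component of run 1 it reports the fraction of the other
#' runs containing a match with absolute correlation at or above
#' \code{matchThreshold}. A diagnostic for choosing an identifiable k:
#' strongly non-Gaussian sources replicate in every run, pure noise does
#' not.
#'
#' @param E an \linkS4class{ExpressionMatrix}.
#' @param k number of components.
#' @param nRuns number of runs (>= 2).
#' @param matchThreshold absolute-correlation threshold (default 0.9).
#' @param seed base seed; run r uses seed + (r - 1) * 1000.
#' @param ... further arguments passed to \code{\link{icaDecompose}}.
#' @return data.frame with columns component, replicationFraction,
#'   meanMatchCor.
#' @export
componentStability <- function(E, k, nRuns = 5L, matchThreshold = 0.9,
                               seed = 1L, ...) {
  stopifnot(nRuns >= 2)
  runs <- lapply(seq_len(nRuns), function(r)
    icaDecompose(E, k = k, seed = as.integer(seed + (r - 1) * 1000), ...))
  S1 <- runs[[1]]@S
  hits <- matrix(0, k, nRuns - 1L)
  cors <- matrix(NA_real_, k, nRuns - 1L)
  for (r in 2:nRuns) {
    cc <- abs(cor(t(S1), t(runs[[r]]@S)))   # k x k
    # greedy one-to-one matching by descending correlation
    for (m in seq_len(k)) {
      ij <- arrayInd(which.max(cc), dim(cc))
      i <- ij[1]; j <- ij[2]
      cors[i, r - 1L] <- cc[i, j]
      hits[i, r - 1L] <- as.numeric(cc[i, j] >= matchThreshold)
      cc[i, ] <- -1; cc[, j] <- -1
    }
  }
  data.frame(component = paste0("IC", seq_len(k)),
             replicationFraction = rowMeans(hits),
             meanMatchCor = rowMeans(cors))
}
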