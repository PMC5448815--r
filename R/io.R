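#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of gene ids and the first
#' column holding sample ids (samples x genes orientation). An optional
#' annotation table supplies per-gene chromosome and 1-based start position
#' for cis/trans labeling.
#'
#' @param path TSV file path.
#' @param annotationPath optional TSV with columns gene_id, chrom, start.
#' @param tag provenance tag stored on the object.
#' @return An \linkS4class{ExpressionMatrix}; rows/columns keep file order.
#' @export
loadExpression <- function(path, annotationPath = NULL, tag = "raw") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicated sample id in ", path, ": ",
         ids[duplicated(ids)][1])
  genes <- colnames(tab)[-1]
  if (anyDuplicated(genes))
    stop("duplicated gene id in ", path, ": ",
         genes[duplicated(genes)][1])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at sample '%s', gene '%s'",
                 ids[bad[1]], genes[bad[2]]))
  }
  dimnames(num) <- list(ids, genes)
  ann <- NULL
  if (!is.null(annotationPath)) {
    ann <- read.table(annotationPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    if (anyDuplicated(ann$gene_id))
      stop("duplicated gene_id in annotation: ",
           ann$gene_id[duplicated(ann$gene_id)][1])
  }
  ExpressionMatrix(num, geneAnnotation = ann, tag = tag)
}

#' Write an expression matrix to TSV
#'
#' Values are formatted with 17 significant digits so that a
#' \code{\link{loadExpression}} round-trip is bitwise exact.
#'
#' @param E an \linkS4class{ExpressionMatrix}.
#' @param path output TSV path.
#' @param annotationPath optional path for the gene annotation TSV.
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(E, path, annotationPath = NULL) {
  v <- E@values
  header <- paste(c("sample_id", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  if (!is.null(annotationPath) && nrow(E@geneAnnotation))
    write.table(E@geneAnnotation, annotationPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from TSV or a PLINK bed/bim/fam triplet
#'
#' TSV layout mirrors \code{\link{loadExpression}}: header = SNP ids, first
#' column = sample id, entries = allele counts (NA allowed, resolved per
#' \code{maxMissing}); an annotation TSV (snp_id, chrom, pos) supplies
#' positions. For PLINK, \code{path} is the prefix of a variant-major
#' \code{.bed} with its \code{.bim}/\code{.fam}; A1 allele counts are read
#' and re-coded to minor-allele counts.
#'
#' @param path TSV path, or PLINK prefix.
#' @param format "tsv" or "plink".
#' @param annotationPath SNP annotation TSV (tsv format only).
#' @param ploidy 1 or 2 (tsv format only; PLINK is diploid).
#' @param maxMissing per-SNP missingness tolerated before dropping; within
#'   tolerance missing entries are imputed to the rounded SNP mean count.
#' @return A \linkS4class{GenotypeMatrix}.
#' @export
loadGenotypes <- function(path, format = c("tsv", "plink"),
                          annotationPath = NULL, ploidy = 2L,
                          maxMissing = 0) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!file.exists(path)) stop("genotype file not found: ", path)
    tab <- read.table(path, header = TRUE, sep = "\t",
                      check.names = FALSE)
    ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
    if (is.null(annotationPath))
      stop("tsv genotypes need an annotation table (snp_id, chrom, pos)")
    ann <- read.table(annotationPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    ann <- ann[match(colnames(vals), ann$snp_id), , drop = FALSE]
    if (anyNA(ann$snp_id))
      stop("SNP(s) missing from annotation: ",
           colnames(vals)[which(is.na(ann$snp_id))[1]])
    GenotypeMatrix(vals, ann, ploidy = ploidy, maxMissing = maxMissing)
  } else {
    readPlink(path, maxMissing = maxMissing)
  }
}

#' Write genotypes (TSV plus annotation TSV)
#'
#' @param G a \linkS4class{GenotypeMatrix}.
#' @param path output TSV path for the count matrix.
#' @param annotationPath output TSV path for snp_id/chrom/pos.
#' @return Invisibly, \code{path}.
#' @export
writeGenotypes <- function(G, path, annotationPath) {
  v <- G@values
  header <- paste(c("sample_id", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], format(v[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  write.table(G@snpAnnotation, annotationPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# PLINK variant-major .bed reader. 2-bit codes per sample:
# 00 = 2 copies of A1, 10 = 1 copy, 11 = 0 copies, 01 = missing.
readPlink <- function(prefix, maxMissing = 0) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  famTab <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(famTab[[2]])
  bimTab <- tryCatch(
    read.table(bim, header = FALSE, stringsAsFactors = FALSE,
               col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2")),
    error = function(e) stop("malformed bim file ", bim, ": ",
                             conditionMessage(e)))
  if (any(is.na(bimTab$pos)))
    stop("malformed bim line ", which(is.na(bimTab$pos))[1], " in ", bim)
  n <- length(samples); s <- nrow(bimTab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only variant-major (SNP-major) bed files are supported")
  bytesPerSnp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytesPerSnp * s)
    stop("bed file size inconsistent with bim/fam dimensions")
  # decode all 2-bit pairs at once; sample 4(b-1)+p sits in bits 2(p-1)..2p-1
  # of byte b of each SNP's record
  m <- matrix(as.integer(body), nrow = bytesPerSnp, ncol = s)
  arr <- array(0L, c(4L, bytesPerSnp, s))
  arr[1, , ] <- m %% 4L
  arr[2, , ] <- (m %/% 4L) %% 4L
  arr[3, , ] <- (m %/% 16L) %% 4L
  arr[4, , ] <- m %/% 64L
  dim(arr) <- c(4L * bytesPerSnp, s)
  codes <- arr[seq_len(n), , drop = FALSE]
  counts <- matrix(NA_real_, n, s)
  counts[codes == 0L] <- 2   # hom A1
  counts[codes == 2L] <- 1   # het
  counts[codes == 3L] <- 0   # hom A2
  dimnames(counts) <- list(samples, bimTab$snp_id)
  ann <- data.frame(snp_id = bimTab$snp_id,
                    chrom = as.character(bimTab$chrom),
                    pos = as.integer(bimTab$pos),
                    stringsAsFactors = FALSE)
  GenotypeMatrix(counts, ann, ploidy = 2L, maxMissing = maxMissing)
}
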