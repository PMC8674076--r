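## Readers/writers for delimited expression matrices and the two
## preprocessing steps of the standard protocol: PCA reduction of the gene
## dimension and seeded K-means initialization of the indicators.

#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expects a rectangular table with a header row of sample identifiers and a
#' first column of gene identifiers. Non-numeric or missing cells are
#' rejected with the offending gene/sample named; duplicate sample
#' identifiers are an error.
#'
#' @param path File path.
#' @param sep Field delimiter (default tab; use "," for CSV).
#' @param transpose If TRUE the file stores samples in rows and is
#'   transposed after reading.
#' @return A numeric matrix with gene row names and sample column names.
#' @export
readExprMatrix <- function(path, sep = "\t", transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character", quote = "\"",
                      comment.char = ""),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 2L) stop("expected a gene-id column plus >= 1 sample ",
                           "column in ", path, call. = FALSE)
  geneIds <- tab[[1L]]
  sampleIds <- colnames(tab)[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  X <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(X) | !is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop(sprintf(
      "non-numeric value '%s' at gene '%s', sample '%s' in %s",
      vals[b[1L], b[2L]], geneIds[b[1L]], sampleIds[b[2L]], path),
      call. = FALSE)
  }
  dimnames(X) <- list(geneIds, sampleIds)
  if (transpose) X <- t(X)
  X
}

#' Write a genes-by-samples matrix as delimited text
#'
#' @param X Numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
writeExprMatrix <- function(X, path, sep = "\t") {
  X <- .validateExprMatrix(X)
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' PCA reduction of the gene dimension
#'
#' Expression matrices are high-dimensional with few samples, so the gene
#' dimension is reduced before clustering: genes are centered (row means
#' removed) and the samples are projected onto the top-d principal
#' directions.
#'
#' @param X Genes-by-samples numeric matrix.
#' @param d Number of components, 1 <= d <= min(m, n).
#' @return A d x n matrix with feature names PC1..PCd and the original
#'   sample names.
#' @export
pcaReduce <- function(X, d) {
  X <- .validateExprMatrix(X)
  d <- as.integer(d)
  if (d < 1L || d > min(dim(X)))
    stop("'d' must lie in 1..min(m, n)", call. = FALSE)
  pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  Y <- t(pc$x[, seq_len(d), drop = FALSE])
  dimnames(Y) <- list(paste0("PC", seq_len(d)), colnames(X))
  Y
}

#' Seeded K-means initialization of the cluster indicators
#'
#' Runs Lloyd's algorithm on the sample columns with k-means++ style center
#' seeding under a local random seed (the caller's RNG state is left
#' untouched). Deterministic given \code{seed}.
#'
#' @param X Genes-by-samples numeric matrix.
#' @param clusters Number of clusters, <= n.
#' @param seed Integer seed.
#' @return Integer labels in 1..clusters of length \code{ncol(X)}.
#' @export
kmeansInit <- function(X, clusters, seed = 1) {
  X <- as.matrix(X)
  n <- ncol(X)
  clusters <- as.integer(clusters)
  if (clusters < 1L || clusters > n)
    stop("'clusters' must lie in 1..n", call. = FALSE)
  if (clusters == 1L) return(rep(1L, n))
  pts <- t(X)
  .withSeed(seed, {
    chosen <- integer(clusters)
    chosen[1L] <- sample.int(n, 1L)
    d2 <- colSums((t(pts) - pts[chosen[1L], ])^2)
    for (i in 2L:clusters) {
      avail <- setdiff(seq_len(n), chosen[seq_len(i - 1L)])
      pick <- if (any(d2[avail] > 0))
        avail[sample.int(length(avail), 1L, prob = d2[avail])]
      else avail[sample.int(length(avail), 1L)]
      chosen[i] <- pick
      d2 <- pmin(d2, colSums((t(pts) - pts[pick, ])^2))
    }
    centers <- pts[chosen, , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(pts, centers = centers,
                                     iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) {
      # degenerate data (coincident centers): nearest-center assignment
      dd <- vapply(seq_len(clusters), function(i)
        colSums((t(pts) - centers[i, ])^2), numeric(n))
      max.col(-dd, ties.method = "first")
    } else as.integer(km$cluster)
  })
}
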