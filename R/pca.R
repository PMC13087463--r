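# Per-cluster principal-component phenotypes and the normalized
# shared-variance statistic.

#' Principal components of a gene cluster's expression
#'
#' PCA on per-gene standardized (zero-mean, unit-variance) residualized
#' expression, i.e. an eigendecomposition of the gene-gene correlation
#' matrix. On this scale the squared correlation-scale loading of PC1 on
#' gene i equals the fraction of that gene's variance explained by PC1,
#' which makes the 0%/100% endpoints of [normalized_shared_variance()]
#' exact. All n PCs are returned as phenotypes.
#'
#' PC signs are arbitrary; they are fixed so that the gene with the
#' largest absolute loading has a positive loading (QTL mapping is
#' sign-invariant but outputs must be reproducible).
#'
#' @param expr an [expression_matrix()] or a plain genes x samples
#'   matrix.
#' @param gene_ids genes of the cluster (default: all genes in `expr`).
#' @param cluster_id label, default `"cluster"`.
#' @return object of class `cluster_pcs`: `scores` (samples x n, named
#'   PC1..PCn), `loadings` (genes x n, correlation scale: eigenvector x
#'   sqrt(eigenvalue)), `eigvec`, `eigval`, `var_explained`,
#'   `shared_variance` (percent, PC1), `cluster_id`, `gene_ids`.
#' @export
cluster_pca <- function(expr, gene_ids = NULL, cluster_id = "cluster") {
  vals <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (!is.null(gene_ids)) vals <- vals[gene_ids, , drop = FALSE]
  n <- nrow(vals)
  if (n < 2) stop("a cluster needs >= 2 genes")
  if (ncol(vals) < n) stop("need at least as many samples as genes")
  sds <- apply(vals, 1, sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(vals)[sds == 0], collapse = ", "))
  E <- scale(t(vals))                    # samples x genes, unit variance
  C <- cor(t(vals))
  eig <- eigen(C, symmetric = TRUE)
  vec <- eig$vectors
  val <- pmax(eig$values, 0)
  # sign convention: largest-|loading| gene loads positively
  for (k in seq_len(n)) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  scores <- E %*% vec
  colnames(scores) <- paste0("PC", seq_len(n))
  rownames(scores) <- rownames(E)
  loadings <- vec * rep(sqrt(val), each = n)
  dimnames(loadings) <- list(rownames(vals), paste0("PC", seq_len(n)))
  pcs <- structure(list(cluster_id = cluster_id,
                        gene_ids = rownames(vals),
                        scores = scores, loadings = loadings,
                        eigvec = vec, eigval = val,
                        var_explained = val / sum(val),
                        shared_variance = NA_real_),
                   class = "cluster_pcs")
  pcs$shared_variance <- normalized_shared_variance(pcs)
  pcs
}

#' Normalized shared variance of PC1 (percent)
#'
#' The variance of gene i explained by PC1 is its squared
#' correlation-scale loading l_i^2; summing over the n genes, shared
#' variance is `(sum_i l_i^2 - 1) / (n - 1) * 100`. The statistic is 0
#' when all genes are mutually uncorrelated and 100 when they are
#' perfectly correlated, regardless of cluster size.
#'
#' @param pcs a [cluster_pca()] result.
#' @return scalar percent in `[0, 100]` (up to numerical tolerance).
#' @export
normalized_shared_variance <- function(pcs) {
  stopifnot(inherits(pcs, "cluster_pcs"))
  n <- length(pcs$gene_ids)
  if (n < 2) stop("normalized shared variance needs >= 2 genes")
  (sum(pcs$loadings[, 1]^2) - 1) / (n - 1) * 100
}

#' PC scores as phenotype BED rows
#'
#' Every PC becomes one phenotype with id `cluster_id:PCk`, anchored at
#' the cluster span (consistent with the +/-1 Mb cis-window definition).
#'
#' @param pcs a `cluster_pcs`.
#' @param chrom,span_start,span_end cluster anchor (1-based).
#' @return an [expression_matrix()] of PC phenotypes.
#' @export
pcs_as_phenotypes <- function(pcs, chrom, span_start, span_end) {
  vals <- t(pcs$scores)
  rownames(vals) <- paste0(pcs$cluster_id, ":", colnames(pcs$scores))
  expression_matrix(vals, chrom = rep(chrom, nrow(vals)),
                    start = rep(span_start, nrow(vals)),
                    end = rep(span_end, nrow(vals)))
}
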