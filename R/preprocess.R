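# Covariate residualization and the expression-level inclusion filter.

#' Residualize expression on covariates
#'
#' Per-gene ordinary least squares of expression on the covariate rows
#' plus an intercept (added internally); returns the residuals. This is
#' the standard pre-step before correlation and QTL scans: latent-factor
#' covariates (e.g. PEER) are consumed here as plain numeric rows.
#'
#' @param expr an [expression_matrix()].
#' @param cov numeric matrix covariates x samples; sample columns must
#'   match `expr` exactly (same ids, same order).
#' @return an [expression_matrix()] of residuals; each gene's residual
#'   vector is orthogonal to every covariate row and to the intercept.
#' @export
residualize <- function(expr, cov) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!identical(colnames(cov), expr$sample_ids))
    stop("covariate samples must match expression samples exactly ",
         "(same ids, same order); use intersect_samples() first")
  X <- cbind(intercept = 1, t(cov))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("covariates are rank deficient; collinear rows: ",
         paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qx, t(expr$values)))
  dimnames(res) <- dimnames(expr$values)
  expression_matrix(res, expr$anchors$chrom, expr$anchors$start,
                    expr$anchors$end)
}

#' Expression-level gene inclusion filter
#'
#' A gene is kept iff its TPM exceeds `tpm_floor` (strictly) in at least
#' `frac` of samples and its read count is at least `count_floor`
#' (inclusive) in at least `frac` of samples.
#'
#' @param tpm,counts numeric matrices genes x samples with identical
#'   dimnames.
#' @param tpm_floor default 0.1 (comparison is strict, `> 0.1`).
#' @param count_floor default 6 (comparison is inclusive, `>= 6`).
#' @param frac default 0.20; the sample-share comparison is `>=`.
#' @return named logical vector, `TRUE` for genes to keep.
#' @export
expression_filter <- function(tpm, counts, tpm_floor = 0.1,
                              count_floor = 6, frac = 0.20) {
  if (!identical(dimnames(tpm), dimnames(counts)))
    stop("tpm and counts must share gene and sample indices")
  rowMeans(tpm > tpm_floor) >= frac &
    rowMeans(counts >= count_floor) >= frac
}
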