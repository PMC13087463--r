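# Nominal association scans, permutation-based phenotype-level FDR, and
# allelic fold-change estimation.

#' Nominal cis scan: per-variant simple linear regression
#'
#' Regresses the phenotype on each variant's dosage separately and
#' reports slope, standard error, t statistic and two-sided p-value.
#'
#' @param y residualized phenotype (length n, n >= 3).
#' @param X dosage matrix n x p (windowed, MAF-filtered).
#' @return data.frame with `variant_id`, `slope`, `se`, `tstat`,
#'   `pval`. Zero-variance variants get slope 0 and p 1.
#' @export
nominal_scan <- function(y, X) {
  n <- length(y)
  if (n <= 2) stop("nominal_scan needs n > 2 samples")
  stopifnot(n == nrow(X))
  yc <- y - mean(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  d <- colSums(Xc^2)
  ok <- d > .Machine$double.eps
  xty <- drop(crossprod(Xc, yc))
  slope <- ifelse(ok, xty / d, 0)
  yty <- sum(yc^2)
  rss <- pmax(yty - slope^2 * d, 0)
  se <- ifelse(ok, sqrt(rss / (n - 2) / d), NA_real_)
  tstat <- ifelse(ok & se > 0, slope / se,
                  ifelse(ok & slope != 0, Inf, 0))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  data.frame(variant_id = colnames(X), slope = slope, se = se,
             tstat = tstat, pval = pval, stringsAsFactors = FALSE)
}

# min nominal p across variants for many permuted phenotypes at once;
# min p over variants == p of max |r| (monotone in |r| at fixed df)
perm_min_pvals <- function(Y, X) {
  n <- nrow(X)
  r <- suppressWarnings(cor(X, Y))
  r[is.na(r)] <- 0
  rmax <- apply(abs(r), 2, max)
  tt <- rmax * sqrt((n - 2) / pmax(1 - rmax^2, .Machine$double.eps))
  2 * pt(-tt, df = n - 2)
}

# Beta(a, b) maximum-likelihood fit (FastQTL-style approximation of the
# permutation min-p distribution)
fit_beta_mle <- function(p) {
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  m <- mean(p); v <- var(p)
  k0 <- max(m * (1 - m) / max(v, 1e-12) - 1, 0.1)
  init <- log(c(m * k0, (1 - m) * k0))
  nll <- function(ls) -sum(dbeta(p, exp(ls[1]), exp(ls[2]), log = TRUE))
  opt <- try(optim(init, nll, method = "Nelder-Mead"), silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$value)) return(NULL)
  list(shape1 = exp(opt$par[1]), shape2 = exp(opt$par[2]))
}

#' Permutation pass for one phenotype
#'
#' Permutes the phenotype across samples B times, records the minimum
#' nominal p-value per permutation, and reports (i) the direct
#' empirical p `(1 + #{perm min-p <= observed}) / (B + 1)` and (ii) the
#' tail probability of a Beta distribution fitted to the permutation
#' min-p values by maximum likelihood (the FastQTL/tensorQTL scheme,
#' which interpolates far tails beyond 1/B resolution).
#'
#' @param y phenotype (length n).
#' @param X dosage matrix n x p.
#' @param B number of permutations, default 1000 (a warning is issued
#'   below 100).
#' @param seed RNG seed.
#' @return list of class `permutation_result`: `p_nominal_best`,
#'   `best_variant`, `empirical_p_direct`, `beta_shape1`,
#'   `beta_shape2`, `empirical_p_beta`, `beta_ok` (FALSE means the Beta
#'   fit failed and the direct p was substituted).
#' @export
permutation_pass <- function(y, X, B = 1000, seed = 1) {
  if (B < 100) warning("B < 100 permutations gives a coarse empirical p")
  scan <- nominal_scan(y, X)
  obs <- min(scan$pval)
  best <- scan$variant_id[which.min(scan$pval)]
  set.seed(seed)
  n <- length(y)
  Y <- vapply(seq_len(B), function(b) y[sample.int(n)], numeric(n))
  pm <- perm_min_pvals(Y, X)
  direct <- (1 + sum(pm <= obs)) / (B + 1)
  fit <- fit_beta_mle(pm)
  if (is.null(fit)) {
    beta_p <- direct; ok <- FALSE
    s1 <- NA_real_; s2 <- NA_real_
  } else {
    s1 <- fit$shape1; s2 <- fit$shape2
    beta_p <- pbeta(obs, s1, s2)
    ok <- TRUE
  }
  structure(list(p_nominal_best = obs, best_variant = best,
                 empirical_p_direct = direct, beta_shape1 = s1,
                 beta_shape2 = s2, empirical_p_beta = beta_p,
                 beta_ok = ok, B = B),
            class = "permutation_result")
}

#' Storey q-values with smoother pi0 estimation
#'
#' Computes phenotype-level q-values from permutation empirical
#' p-values. pi0 is estimated by the smoother method (natural cubic
#' spline through `pi0(lambda)` evaluated at `lambda = 0.95`); with
#' fewer than 10 p-values pi0 is fixed at 1, which reduces to
#' Benjamini-Hochberg, and the result is flagged.
#'
#' @param p vector of empirical p-values (one per phenotype; pool all
#'   phenotypes of a condition).
#' @param pi0 optionally force pi0.
#' @return numeric vector of q-values with attributes `pi0` and
#'   `pi0_forced`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  forced <- FALSE
  if (is.null(pi0)) {
    if (m < 10) {
      pi0 <- 1
      forced <- TRUE
    } else {
      lambda <- seq(0.05, 0.95, 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- suppressWarnings(smooth.spline(lambda, pi0_l, df = 3))
      pi0 <- predict(fit, x = 0.95)$y
      pi0 <- min(max(pi0, 1 / m), 1)
    }
  }
  ord <- order(p)
  ranked <- pi0 * m * p[ord] / seq_len(m)
  q <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[ord] <- q
  attr(out, "pi0") <- pi0
  attr(out, "pi0_forced") <- forced
  out
}

#' Estimate the log2 allelic fold change of a variant on a gene
#'
#' Fits the allelic model `E[e | g] = c * (2 - g + g*k) / 2` (k the
#' fold change of the alt haplotype relative to ref) by least squares
#' on the log scale, i.e. minimizing
#' `sum (log e - log c - log(1 + g*(k-1)/2))^2` over (c, k). Expression
#' must be on a positive linear scale. The estimate is clipped to
#' `+/- log2(100)`, the conventional aFC cap.
#'
#' @param y_linear positive linear-scale expression (length n).
#' @param dosage alt-allele dosage in `[0, 2]`.
#' @param cap clip bound on |log2 aFC|, default `log2(100)`.
#' @return scalar log2 aFC.
#' @export
estimate_log2_afc <- function(y_linear, dosage, cap = log2(100)) {
  if (any(y_linear <= 0))
    stop("estimate_log2_afc requires positive linear-scale expression; ",
         "use the simulator's linear channel or back-transform upstream")
  stopifnot(length(y_linear) == length(dosage))
  ly <- log(y_linear)
  sse <- function(b) {
    k <- 2^b
    mu <- log1p(dosage * (k - 1) / 2)
    r <- ly - mu
    sum((r - mean(r))^2)          # log c profiled out
  }
  if (sd(dosage) == 0 || sd(ly) == 0 ||
      abs(cor(ly, dosage)) < 1e-12) return(0)
  opt <- optimize(sse, interval = c(-cap, cap))
  b <- opt$minimum
  # optimize() never returns the exact boundary; snap when pressed
  if (b > cap - 1e-4 && sse(cap) <= opt$objective) b <- cap
  if (b < -cap + 1e-4 && sse(-cap) <= opt$objective) b <- -cap
  b
}

#' Per-variant aFC scan for one gene
#'
#' @param y_linear positive linear-scale expression.
#' @param X dosage matrix n x p.
#' @param cap clip bound, default `log2(100)`.
#' @return named numeric vector of log2 aFC per variant.
#' @export
afc_scan <- function(y_linear, X, cap = log2(100)) {
  vapply(seq_len(ncol(X)),
         function(j) estimate_log2_afc(y_linear, X[, j], cap),
         0) |> setNames(colnames(X))
}
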