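# Sum-of-single-effects (SuSiE-style) fine-mapping on individual-level
# genotypes, with purity-filtered 95% credible sets and the
# genotype-shuffle calibration null.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bayesian single-effect regression
#'
#' For each variant j, the log Bayes factor of the single-effect model
#' (one causal variant with N(0, prior_var) effect) against the null:
#' `lbf_j = 0.5*log(s2_j/(s2_j+V)) + 0.5*z_j^2*V/(s2_j+V)` with `s2_j`
#' the OLS sampling variance of variant j's coefficient and
#' `z_j = bhat_j/s_j`. Posterior inclusion weights are
#' `alpha ~ exp(lbf)` under the uniform prior.
#'
#' @param y centered response (length n).
#' @param X column-centered dosage matrix (n x p).
#' @param prior_var prior effect variance V.
#' @param resid_var residual variance.
#' @return list: `lbf`, `alpha`, `mu` (posterior means given
#'   inclusion), `mu2` (posterior second moments), `lbf_model` (log BF
#'   of the whole single-effect model). Zero-variance columns get
#'   `lbf = 0` and minimal posterior weight.
#' @export
single_effect_bf <- function(y, X, prior_var, resid_var) {
  d <- colSums(X^2)
  ok <- d > .Machine$double.eps
  Xtr <- drop(crossprod(X, y))
  bhat <- ifelse(ok, Xtr / d, 0)
  s2 <- ifelse(ok, resid_var / d, Inf)
  z2 <- ifelse(ok, bhat^2 / s2, 0)
  lbf <- ifelse(ok & prior_var > 0,
                0.5 * log(s2 / (s2 + prior_var)) +
                  0.5 * z2 * prior_var / (s2 + prior_var),
                0)
  alpha <- exp(lbf - logsumexp(lbf))
  alpha <- alpha / sum(alpha)
  post_var <- ifelse(ok & prior_var > 0,
                     1 / (1 / prior_var + d / resid_var), 0)
  mu <- post_var * Xtr / resid_var
  mu2 <- post_var + mu^2
  list(lbf = lbf, alpha = alpha, mu = mu, mu2 = mu2,
       lbf_model = logsumexp(lbf) - log(length(lbf)))
}

# maximize the single-effect model log-likelihood over the prior
# variance (susieR's estimate_prior_variance="optim" analogue)
optimize_prior_variance <- function(y, X, resid_var, V_init) {
  neg_ll <- function(lV) {
    -single_effect_bf(y, X, exp(lV), resid_var)$lbf_model
  }
  opt <- optim(log(max(V_init, 1e-6)), neg_ll, method = "Brent",
               lower = -30, upper = 15)
  V <- exp(opt$par)
  # a point-null prior has lbf_model = 0; keep V only if it beats it
  if (-opt$value < 0) V <- 0
  V
}

#' Fit a sum-of-single-effects model by iterative Bayesian stepwise
#' selection (IBSS)
#'
#' Repeatedly fits each of L single effects to the residual of the
#' others until the evidence lower bound (ELBO) changes by less than
#' `tol`. The per-effect prior variance is estimated by maximizing its
#' single-effect likelihood; the residual variance is re-estimated every
#' iteration. The prior over variants is uniform.
#'
#' @param y phenotype vector (residualized expression or a cluster PC);
#'   centered internally.
#' @param X dosage matrix n x p for the cis window; column-centered
#'   internally.
#' @param L maximum number of effects, default 10.
#' @param tol ELBO convergence tolerance, default 1e-3.
#' @param max_iter maximum IBSS iterations, default 100.
#' @param estimate_prior_variance logical, default TRUE.
#' @param prior_var initial (or fixed) prior effect variance; default
#'   `0.2 * var(y)`.
#' @return object of class `susie_fit`: `alpha` (L x p, rows sum to 1),
#'   `mu`, `mu2`, `lbf_variable` (L x p), `V` (length L), `sigma2`,
#'   `pip` (`1 - prod_l(1 - alpha_lj)`), `elbo` trace, `niter`,
#'   `converged`, `variant_ids`.
#' @export
susie_fit <- function(y, X, L = 10, tol = 1e-3, max_iter = 100,
                      estimate_prior_variance = TRUE, prior_var = NULL) {
  stopifnot(length(y) == nrow(X))
  n <- length(y)
  p <- ncol(X)
  vids <- colnames(X)
  y <- y - mean(y)
  X <- scale(X, center = TRUE, scale = FALSE)
  d <- colSums(X^2)
  L <- min(L, p)
  vary <- var(y) * (n - 1) / n
  if (is.null(prior_var)) prior_var <- 0.2 * vary
  sigma2 <- vary
  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  mu2 <- matrix(0, L, p)
  lbf_var <- matrix(0, L, p)
  V <- rep(prior_var, L)
  b_bar <- alpha * mu
  Xb_all <- drop(X %*% colSums(b_bar))
  elbo <- -Inf
  elbo_trace <- numeric(0)
  converged <- FALSE
  niter <- 0
  for (it in seq_len(max_iter)) {
    niter <- it
    KL <- numeric(L)
    for (l in seq_len(L)) {
      Xb_l <- drop(X %*% b_bar[l, ])
      r_l <- y - Xb_all + Xb_l
      if (estimate_prior_variance)
        V[l] <- optimize_prior_variance(r_l, X, sigma2,
                                        if (V[l] > 0) V[l] else prior_var)
      ser <- single_effect_bf(r_l, X, V[l], sigma2)
      alpha[l, ] <- ser$alpha
      mu[l, ] <- ser$mu
      mu2[l, ] <- ser$mu2
      lbf_var[l, ] <- ser$lbf
      b_bar[l, ] <- ser$alpha * ser$mu
      Xb_l_new <- drop(X %*% b_bar[l, ])
      Xb_all <- Xb_all - Xb_l + Xb_l_new
      # KL(q_l || p_l) = -SER loglik + E_q[loglik], both against r_l
      Eb2 <- ser$alpha * ser$mu2
      post_e <- -0.5 / sigma2 *
        (-2 * sum(r_l * Xb_l_new) + sum(d * Eb2))
      KL[l] <- -ser$lbf_model + post_e
    }
    # expected residual sum of squares under the posterior
    XB_l2 <- vapply(seq_len(L),
                    function(l) sum(drop(X %*% b_bar[l, ])^2), 0)
    ERSS <- sum((y - Xb_all)^2) - sum(XB_l2) +
      sum(d * t(alpha * mu2))
    new_elbo <- -n / 2 * log(2 * pi * sigma2) - ERSS / (2 * sigma2) -
      sum(KL)
    elbo_trace <- c(elbo_trace, new_elbo)
    if (is.finite(elbo) && abs(new_elbo - elbo) < tol) {
      converged <- TRUE
      elbo <- new_elbo
      break
    }
    elbo <- new_elbo
    sigma2 <- max(ERSS / n, 1e-12)
  }
  pip <- 1 - apply(1 - alpha, 2, prod)
  structure(list(alpha = alpha, mu = mu, mu2 = mu2,
                 lbf_variable = lbf_var, V = V, sigma2 = sigma2,
                 pip = setNames(pip, vids), elbo = elbo_trace,
                 niter = niter, converged = converged,
                 variant_ids = vids, L = L, n = n),
            class = "susie_fit")
}

#' @export
print.susie_fit <- function(x, ...) {
  cat("susie_fit: L =", x$L, ", p =", length(x$pip), ", niter =",
      x$niter, if (x$converged) "(converged)" else "(NOT converged)",
      "\n")
  invisible(x)
}

#' Extract purity-filtered credible sets from a SuSiE fit
#'
#' For each effect with nonzero prior variance, the smallest variant
#' set (by descending posterior weight) with cumulative weight at least
#' `coverage`. A set is kept iff its purity - the minimum absolute
#' pairwise dosage correlation among members - is at least
#' `min_abs_corr` (single-variant sets have purity 1). Duplicate sets
#' across effects are collapsed, keeping the higher-purity instance.
#'
#' @param fit a [susie_fit()].
#' @param X the dosage matrix used in the fit (for purity).
#' @param coverage credible-set coverage, default 0.95.
#' @param min_abs_corr purity threshold, default 0.5.
#' @param phenotype_id label stored on each set.
#' @return list of `credible_set` objects: `cs_id`, `phenotype_id`,
#'   `variant_ids` (descending weight), `pips` (the effect's posterior
#'   weights for the members), `model_pip` (overall PIPs), `coverage`,
#'   `purity`, `lead_variant`, `effect`.
#' @export
extract_credible_sets <- function(fit, X, coverage = 0.95,
                                  min_abs_corr = 0.5,
                                  phenotype_id = "phenotype") {
  stopifnot(inherits(fit, "susie_fit"))
  sets <- list()
  for (l in seq_len(fit$L)) {
    if (fit$V[l] <= 0) next
    a <- fit$alpha[l, ]
    ord <- order(a, decreasing = TRUE)
    k <- which(cumsum(a[ord]) >= coverage)[1]
    if (is.na(k)) k <- length(a)
    members <- ord[seq_len(k)]
    purity <- if (length(members) == 1) 1 else {
      cc <- suppressWarnings(cor(X[, members, drop = FALSE]))
      cc[is.na(cc)] <- 0
      min(abs(cc[upper.tri(cc)]))
    }
    if (purity < min_abs_corr) next
    key <- paste(sort(members), collapse = ",")
    cs <- structure(list(
      cs_id = NA_character_, phenotype_id = phenotype_id,
      variant_ids = fit$variant_ids[members],
      pips = unname(a[members]),
      model_pip = unname(fit$pip[members]),
      coverage = coverage, purity = purity,
      lead_variant = fit$variant_ids[members[1]],
      effect = l, member_key = key), class = "credible_set")
    prev <- which(vapply(sets, `[[`, "", "member_key") == key)
    if (length(prev)) {
      if (purity > sets[[prev]]$purity) sets[[prev]] <- cs
    } else {
      sets[[length(sets) + 1]] <- cs
    }
  }
  for (i in seq_along(sets))
    sets[[i]]$cs_id <- sprintf("%s_L%d", phenotype_id, sets[[i]]$effect)
  sets
}

#' Credible sets as a data.frame
#' @param sets list of `credible_set`.
#' @return data.frame, one row per (set, variant).
#' @export
credible_sets_as_table <- function(sets) {
  if (!length(sets)) {
    return(data.frame(phenotype_id = character(0), cs_id = character(0),
                      variant_id = character(0), pip = numeric(0),
                      lead = logical(0), purity = numeric(0)))
  }
  do.call(rbind, lapply(sets, function(cs) {
    data.frame(phenotype_id = cs$phenotype_id, cs_id = cs$cs_id,
               variant_id = cs$variant_ids, pip = cs$pips,
               lead = cs$variant_ids == cs$lead_variant,
               purity = cs$purity, stringsAsFactors = FALSE)
  }))
}

#' Genotype-shuffle fine-mapping calibration
#'
#' For each phenotype, randomly permutes the individual-to-genotype
#' matching (phenotypes fixed), which removes genotype-phenotype
#' associations while preserving LD structure and phenotype
#' distributions, then runs the identical fine-mapping workflow and
#' counts purity-filtered credible sets.
#'
#' @param phenotypes samples x phenotypes matrix.
#' @param X dosage matrix n x p.
#' @param seed RNG seed (one permutation per phenotype, reproducible).
#' @param L,coverage,min_abs_corr passed to the fine-mapping workflow.
#' @return list: `n_cs` per phenotype, `rate` (credible sets per
#'   phenotype).
#' @export
shuffle_null_calibration <- function(phenotypes, X, seed = 1, L = 10,
                                     coverage = 0.95,
                                     min_abs_corr = 0.5) {
  phenotypes <- as.matrix(phenotypes)
  set.seed(seed)
  n <- nrow(X)
  n_cs <- vapply(seq_len(ncol(phenotypes)), function(j) {
    perm <- sample.int(n)
    fit <- susie_fit(phenotypes[, j], X[perm, , drop = FALSE], L = L)
    length(extract_credible_sets(fit, X[perm, , drop = FALSE],
                                 coverage = coverage,
                                 min_abs_corr = min_abs_corr))
  }, 1L)
  list(n_cs = n_cs, rate = mean(n_cs))
}
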