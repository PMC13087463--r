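# Independent oracles used across test files. These deliberately avoid
# the package's code paths: loops and direct formula evaluation only.

# exhaustive enumeration of the cluster scan: list every (start, size)
# window, order by size desc then start asc, greedily accept disjoint
# windows whose significant-pair count passes 0.7*C(n,2) <= m
oracle_call_clusters <- function(sig, max_size = 50) {
  N <- nrow(sig)
  wins <- list()
  for (n in 2:min(max_size, N)) {
    for (s in seq_len(N - n + 1)) {
      wins[[length(wins) + 1]] <- list(start = s, size = n)
    }
  }
  if (!length(wins)) return(list())
  sizes <- vapply(wins, `[[`, 1L, "size")
  starts <- vapply(wins, `[[`, 1L, "start")
  ord <- order(-sizes, starts)
  taken <- rep(FALSE, N)
  out <- list()
  for (i in ord) {
    idx <- starts[i]:(starts[i] + sizes[i] - 1)
    if (any(taken[idx])) next
    m <- 0
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a < b && isTRUE(sig[idx[a], idx[b]])) m <- m + 1
      }
    }
    if (0.7 * choose(length(idx), 2) <= m) {
      taken[idx] <- TRUE
      out[[length(out) + 1]] <- idx
    }
  }
  out[order(vapply(out, min, 1L))]
}

# brute-force coloc hypothesis sums by explicit configuration
# enumeration on small instances (no log-sum-exp)
oracle_coloc <- function(lbf_a, lbf_b, p1 = 1e-4, p2 = 1e-4,
                         p12 = 5e-6) {
  p <- length(lbf_a)
  bfa <- exp(lbf_a)
  bfb <- exp(lbf_b)
  s1 <- sum(bfa)
  s2 <- sum(bfb)
  s3 <- 0
  for (j in seq_len(p)) {
    for (k in seq_len(p)) {
      if (j != k) s3 <- s3 + bfa[j] * bfb[k]
    }
  }
  s4 <- sum(bfa * bfb)
  w <- c(1, p1 * s1, p2 * s2, p1 * p2 * s3, p12 * s4)
  w / sum(w)
}

# marginal likelihood of the single-effect model for one variant by
# 1-D quadrature over the effect size
oracle_single_variant_lbf <- function(y, x, prior_var, resid_var) {
  lik <- function(b) {
    vapply(b, function(bb) {
      exp(sum(dnorm(y, bb * x, sqrt(resid_var), log = TRUE)) -
            sum(dnorm(y, 0, sqrt(resid_var), log = TRUE))) *
        dnorm(bb, 0, sqrt(prior_var))
    }, 0)
  }
  bf <- integrate(lik, -20, 20, rel.tol = 1e-10)$value
  log(bf)
}

# tiny deterministic genotype fixture with block LD
fixture_genotypes <- function(n = 300, p = 60, seed = 11,
                              ld_decay = 0.6) {
  simulate_genotypes(n, p, maf_range = c(0.1, 0.5),
                     ld_decay = ld_decay, seed = seed)
}
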