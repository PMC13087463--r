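# Sliding-window detection of maximal runs of neighboring, co-expressed
# genes, plus matched null-cluster sampling.

#' Spearman correlation matrix for one chromosome
#'
#' Pairwise Spearman correlations between residualized expression
#' vectors of the genes on one chromosome, with two-sided p-values from
#' the t approximation and a Bonferroni significance matrix. The
#' Bonferroni divisor is C(N, 2) for the N genes on the chromosome.
#'
#' @param expr an [expression_matrix()] (residualized).
#' @param chrom chromosome to restrict to; `NULL` uses all genes in
#'   `expr` (which must then be a single chromosome).
#' @param alpha nominal significance level before correction, default
#'   0.05.
#' @return object of class `corr_matrix`: `gene_ids` (chromosome
#'   order), `rho`, `pval`, `sig` (logical), `alpha_bonf`, `n_samples`.
#'   Constant gene vectors yield undefined correlations, which are
#'   treated as non-significant (rho/pval `NA`).
#' @export
spearman_matrix <- function(expr, chrom = NULL, alpha = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"))
  keep <- if (is.null(chrom)) rep(TRUE, length(expr$gene_ids))
          else expr$anchors$chrom == chrom
  vals <- expr$values[keep, , drop = FALSE]
  N <- nrow(vals)
  n <- ncol(vals)
  if (N < 2) stop("need >= 2 genes on the chromosome")
  if (n < 3) stop("need >= 3 samples")
  constant <- apply(vals, 1, function(v) sd(v) == 0)
  if (any(constant))
    message("spearman_matrix: ", sum(constant),
            " constant gene vector(s); correlations set undefined")
  ranks <- t(apply(vals, 1, rank))       # average ranks on ties
  rho <- suppressWarnings(cor(t(ranks))) # rank-then-Pearson
  rho[constant, ] <- NA; rho[, constant] <- NA
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  diag(pval) <- NA
  n_pairs <- choose(N, 2)
  alpha_bonf <- alpha / n_pairs
  sig <- !is.na(pval) & pval < alpha_bonf
  diag(sig) <- FALSE
  structure(list(gene_ids = rownames(vals), rho = rho, pval = pval,
                 sig = sig, alpha_bonf = alpha_bonf, n_pairs = n_pairs,
                 n_samples = n),
            class = "corr_matrix")
}

#' Window acceptance rule
#'
#' A candidate window of n genes with m significant within-window pairs
#' is accepted iff `0.7 * C(n, 2) <= m` (at least 70% of pairs
#' significant).
#'
#' @param sig_sub logical significance submatrix for the candidate
#'   genes (NA treated as not significant).
#' @param accept_frac required fraction, default 0.7.
#' @return logical scalar.
#' @export
window_accept <- function(sig_sub, accept_frac = 0.7) {
  n <- nrow(sig_sub)
  m <- sum(sig_sub[upper.tri(sig_sub)], na.rm = TRUE)
  accept_frac * choose(n, 2) <= m
}

#' Call clusters of neighboring co-expressed genes
#'
#' Stepwise sliding-window scan: window sizes from `max_size` down to 2,
#' and within each size strictly left to right along the chromosome. A
#' window is recorded as a cluster iff it passes [window_accept()] and
#' none of its genes already belongs to a cluster, so every gene ends up
#' in the largest possible accepted window at its location and clusters
#' are disjoint.
#'
#' @param corr a [spearman_matrix()] result (genes in chromosome order).
#' @param anchors optional data.frame with `gene_id`, `chrom`, `start`,
#'   `end` used to fill cluster spans.
#' @param max_size maximum cluster size, default 50.
#' @param accept_frac fraction of significant pairs required, default
#'   0.7.
#' @param context label stored on each cluster (e.g. tissue), default
#'   `"ctx"`.
#' @param blacklist optional character vector of gene ids (e.g.
#'   cross-mappable genes); clusters containing any are flagged, not
#'   removed.
#' @return list of `gene_cluster` objects: `cluster_id`, `context`,
#'   `gene_ids` (contiguous, chromosome order), `n`, `m`, `chrom`,
#'   `span`, `sign_class`, `flagged`.
#' @export
call_clusters <- function(corr, anchors = NULL, max_size = 50,
                          accept_frac = 0.7, context = "ctx",
                          blacklist = character(0)) {
  stopifnot(inherits(corr, "corr_matrix"))
  N <- length(corr$gene_ids)
  clustered <- rep(FALSE, N)
  clusters <- list()
  for (n in seq(min(max_size, N), 2)) {
    if (n > N) next
    for (s in seq_len(N - n + 1)) {
      idx <- s:(s + n - 1)
      if (any(clustered[idx])) next
      sub <- corr$sig[idx, idx, drop = FALSE]
      if (window_accept(sub, accept_frac)) {
        clustered[idx] <- TRUE
        clusters[[length(clusters) + 1]] <- idx
      }
    }
  }
  clusters <- clusters[order(vapply(clusters, min, 1L))]
  lapply(seq_along(clusters), function(k) {
    idx <- clusters[[k]]
    gids <- corr$gene_ids[idx]
    m <- sum(corr$sig[idx, idx][upper.tri(diag(length(idx)))], na.rm = TRUE)
    span <- c(NA_integer_, NA_integer_); chrom <- NA_character_
    if (!is.null(anchors)) {
      a <- anchors[match(gids, anchors$gene_id), ]
      chrom <- a$chrom[1]
      span <- c(min(a$start), max(a$end))
    }
    cl <- structure(list(
      cluster_id = sprintf("%s_cluster_%d", context, k),
      context = context, gene_ids = gids, n = length(gids), m = m,
      chrom = chrom, span = span,
      sign_class = NA_character_,
      flagged = any(gids %in% blacklist),
      is_null = FALSE), class = "gene_cluster")
    cl$sign_class <- classify_sign(corr, cl)
    cl
  })
}

#' Classify the correlation sign structure of a cluster
#'
#' Based only on the significant within-cluster correlations.
#'
#' @param corr a `corr_matrix`.
#' @param cluster a `gene_cluster`.
#' @return `"all-positive"`, `"all-negative"`, or `"mixed"` (`NA` if no
#'   significant pair, which cannot happen for called clusters).
#' @export
classify_sign <- function(corr, cluster) {
  idx <- match(cluster$gene_ids, corr$gene_ids)
  sig <- corr$sig[idx, idx]
  rho <- corr$rho[idx, idx]
  ut <- upper.tri(sig)
  signs <- sign(rho[ut][sig[ut]])
  if (!length(signs)) return(NA_character_)
  if (all(signs > 0)) "all-positive"
  else if (all(signs < 0)) "all-negative"
  else "mixed"
}

#' Sample null clusters of neighboring, uncorrelated genes
#'
#' Null candidates are all windows of 2-5 contiguous genes (chromosome
#' order) none of which belongs to a called cluster. Candidates are
#' sampled so that the null size distribution matches the relative size
#' distribution of the called clusters (sizes clamped to the 2-5 range).
#'
#' @param corr a `corr_matrix` (defines the gene order).
#' @param clusters called clusters for the same context.
#' @param n_total number of nulls to draw; default equals the number of
#'   size-2-5 called clusters.
#' @param anchors optional anchor data.frame for spans.
#' @param seed RNG seed for reproducibility.
#' @param context label for the null clusters.
#' @return list of `gene_cluster` objects with `is_null = TRUE`. If a
#'   size stratum has fewer candidates than requested, all candidates
#'   are returned for it with a warning.
#' @export
sample_null_clusters <- function(corr, clusters, n_total = NULL,
                                 anchors = NULL, seed = 1,
                                 context = "ctx") {
  stopifnot(inherits(corr, "corr_matrix"))
  N <- length(corr$gene_ids)
  clustered <- corr$gene_ids %in% unlist(lapply(clusters, `[[`, "gene_ids"))
  sizes <- pmin(pmax(vapply(clusters, `[[`, 1L, "n"), 2L), 5L)
  sizes <- sizes[vapply(clusters, `[[`, 1L, "n") <= 5]
  if (!length(sizes)) sizes <- 2L
  probs <- tabulate(sizes, nbins = 5)[2:5]
  probs <- probs / sum(probs)
  if (is.null(n_total)) n_total <- length(sizes)
  candidates <- list()
  for (n in 2:5) {
    if (n > N) next
    for (s in seq_len(N - n + 1)) {
      idx <- s:(s + n - 1)
      if (!any(clustered[idx]))
        candidates[[length(candidates) + 1]] <- idx
    }
  }
  if (!length(candidates)) {
    warning("no null-cluster candidates available")
    return(list())
  }
  cand_sizes <- vapply(candidates, length, 1L)
  set.seed(seed)
  want <- as.vector(rmultinom(1, n_total, probs))  # sizes 2..5
  picked <- list()
  for (i in 1:4) {
    n <- i + 1L
    pool <- which(cand_sizes == n)
    if (want[i] > length(pool)) {
      warning("only ", length(pool), " null candidates of size ", n,
              " available (", want[i], " requested)")
      take <- pool
    } else {
      take <- sample(pool, want[i])
    }
    picked <- c(picked, candidates[take])
  }
  lapply(seq_along(picked), function(k) {
    idx <- picked[[k]]
    gids <- corr$gene_ids[idx]
    span <- c(NA_integer_, NA_integer_); chrom <- NA_character_
    if (!is.null(anchors)) {
      a <- anchors[match(gids, anchors$gene_id), ]
      chrom <- a$chrom[1]; span <- c(min(a$start), max(a$end))
    }
    structure(list(cluster_id = sprintf("%s_null_%d", context, k),
                   context = context, gene_ids = gids,
                   n = length(gids), m = NA_integer_, chrom = chrom,
                   span = span, sign_class = NA_character_,
                   flagged = FALSE, is_null = TRUE),
              class = "gene_cluster")
  })
}

#' Cluster list as a data.frame
#' @param clusters list of `gene_cluster`.
#' @return data.frame, one row per cluster.
#' @export
clusters_as_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, context = cl$context,
               chrom = cl$chrom, span_start = cl$span[1],
               span_end = cl$span[2], n = cl$n, m = cl$m,
               genes = paste(cl$gene_ids, collapse = ","),
               sign_class = cl$sign_class, flagged = cl$flagged,
               is_null = cl$is_null, stringsAsFactors = FALSE)
  }))
}
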