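# cluster_calling: correlations, window rule, sliding-window scan,
# null sampling, sign classes

expr_from_vals <- function(vals, chrom = "chr1") {
  expression_matrix(vals, rep(chrom, nrow(vals)),
                    seq_len(nrow(vals)) * 1e5,
                    seq_len(nrow(vals)) * 1e5 + 1e4)
}

# build an expr_matrix whose Bonferroni-significant pairs are exactly
# the edges of `blocks` (lists of gene index vectors sharing a factor)
block_expr <- function(N, blocks, n = 60, seed = 1, rho_noise = 0.02) {
  set.seed(seed)
  vals <- matrix(rnorm(N * n, 0, rho_noise), N, n)
  for (b in blocks) {
    f <- rnorm(n)
    for (g in b) vals[g, ] <- f + rnorm(n, 0, rho_noise)
  }
  rownames(vals) <- sprintf("g%02d", 1:N)
  colnames(vals) <- paste0("s", 1:n)
  expr_from_vals(vals)
}

test_that("spearman_matrix matches rank-then-Pearson with ties", {
  set.seed(31)
  vals <- matrix(sample(1:5, 6 * 30, replace = TRUE), 6, 30,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:30)))
  storage.mode(vals) <- "double"
  cm <- spearman_matrix(expr_from_vals(vals))
  oracle <- cor(apply(t(vals), 2, rank))
  expect_equal(unname(cm$rho), unname(oracle), tolerance = 1e-12)
  # monotone invariance and anti-correlation endpoints
  x <- rnorm(30)
  vals2 <- rbind(g1 = x, g2 = exp(x), g3 = -x)
  colnames(vals2) <- paste0("s", 1:30)
  cm2 <- spearman_matrix(expr_from_vals(vals2))
  expect_equal(cm2$rho["g1", "g2"], 1)
  expect_equal(cm2$rho["g1", "g3"], -1)
  # Bonferroni divisor is C(N,2)
  expect_equal(cm$alpha_bonf, 0.05 / choose(6, 2))
})

test_that("constant genes yield non-significant undefined correlations", {
  vals <- rbind(g1 = rep(1, 30), g2 = rnorm(30))
  colnames(vals) <- paste0("s", 1:30)
  expect_message(cm <- spearman_matrix(expr_from_vals(vals)), "constant")
  expect_true(is.na(cm$rho["g1", "g2"]))
  expect_false(any(cm$sig))
})

test_that("window_accept implements 0.7*C(n,2) <= m", {
  full3 <- matrix(TRUE, 3, 3)
  expect_true(window_accept(full3))                 # 0.7*3=2.1 <= 3
  s4 <- matrix(FALSE, 4, 4)
  s4[1, 2] <- s4[2, 1] <- s4[1, 3] <- s4[3, 1] <- TRUE
  s4[1, 4] <- s4[4, 1] <- s4[2, 3] <- s4[3, 2] <- TRUE
  expect_false(window_accept(s4))                   # 4 < 0.7*6=4.2
  s2 <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  expect_true(window_accept(s2))                    # 0.7 <= 1
})

test_that("call_clusters records maximal disjoint windows", {
  # exactly genes 1-3 pairwise correlated among 5
  em <- block_expr(5, list(1:3), seed = 55)
  corr <- spearman_matrix(em)
  cl <- call_clusters(corr, anchors = em$anchors)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$gene_ids, c("g01", "g02", "g03"))
  expect_identical(cl[[1]]$n, 3L)
  expect_identical(cl[[1]]$m, 3L)
  expect_identical(cl[[1]]$span,
                   c(em$anchors$start[1], em$anchors$end[3]))
  # all 4 correlated -> one 4-gene cluster, no sub-clusters
  em4 <- block_expr(4, list(1:4), seed = 33)
  cl4 <- call_clusters(spearman_matrix(em4), anchors = em4$anchors)
  expect_length(cl4, 1)
  expect_identical(cl4[[1]]$n, 4L)
  # no significant pairs -> empty
  em0 <- block_expr(5, list(), seed = 34)
  expect_length(call_clusters(spearman_matrix(em0)), 0)
})

test_that("scan equals exhaustive enumeration on <= 8-gene chromosomes", {
  set.seed(35)
  for (rep in 1:60) {
    N <- sample(2:8, 1)
    dens <- runif(1, 0.1, 0.9)
    sig <- matrix(FALSE, N, N)
    up <- which(upper.tri(sig))
    sig[up] <- runif(length(up)) < dens
    sig <- sig | t(sig)
    corr <- structure(list(gene_ids = sprintf("g%02d", 1:N),
                           rho = sig * 0.9, pval = NULL, sig = sig,
                           alpha_bonf = 1, n_pairs = choose(N, 2),
                           n_samples = 50), class = "corr_matrix")
    got <- lapply(call_clusters(corr), function(cl)
      match(cl$gene_ids, corr$gene_ids))
    want <- oracle_call_clusters(sig)
    expect_identical(got, want)
  }
})

test_that("cluster membership is unique and larger windows win", {
  em <- block_expr(8, list(1:4, 6:7), seed = 36)
  cl <- call_clusters(spearman_matrix(em), anchors = em$anchors)
  genes <- unlist(lapply(cl, `[[`, "gene_ids"))
  expect_identical(anyDuplicated(genes), 0L)
  sizes <- vapply(cl, `[[`, 1L, "n")
  expect_setequal(sizes, c(4L, 2L))
})

test_that("permuted samples destroy clusters (calibration)", {
  set.seed(37)
  em <- block_expr(8, list(1:4, 5:8), n = 80, seed = 37)
  # permute each gene's samples independently
  vals <- t(apply(em$values, 1, sample))
  colnames(vals) <- colnames(em$values)
  cl <- call_clusters(spearman_matrix(expr_from_vals(vals)))
  expect_length(cl, 0)
})

test_that("classify_sign uses significant pairs only", {
  em <- block_expr(3, list(1:3), seed = 38)
  corr <- spearman_matrix(em)
  cl <- call_clusters(corr)[[1]]
  expect_identical(classify_sign(corr, cl), "all-positive")
  # flip one gene -> its pairs turn negative -> mixed
  vals <- em$values
  vals["g03", ] <- -vals["g03", ]
  corr2 <- spearman_matrix(expr_from_vals(vals))
  cl2 <- call_clusters(corr2)[[1]]
  expect_identical(classify_sign(corr2, cl2), "mixed")
  # anti-correlated pair
  vals3 <- rbind(g1 = vals["g01", ],
                 g2 = -vals["g01", ] + rnorm(ncol(vals), 0, 0.05))
  colnames(vals3) <- colnames(vals)
  corr3 <- spearman_matrix(expr_from_vals(vals3))
  cl3 <- call_clusters(corr3)[[1]]
  expect_identical(classify_sign(corr3, cl3), "all-negative")
})

test_that("null clusters match size distribution and are reproducible", {
  em <- block_expr(40, list(3:4, 10:11, 20:22), n = 60, seed = 39)
  corr <- spearman_matrix(em)
  cl <- call_clusters(corr, anchors = em$anchors)
  expect_gte(length(cl), 2)
  nulls <- sample_null_clusters(corr, cl, n_total = 30, seed = 7)
  nulls2 <- sample_null_clusters(corr, cl, n_total = 30, seed = 7)
  expect_identical(clusters_as_table(nulls), clusters_as_table(nulls2))
  clustered <- unlist(lapply(cl, `[[`, "gene_ids"))
  expect_false(any(unlist(lapply(nulls, `[[`, "gene_ids")) %in% clustered))
  expect_true(all(vapply(nulls, `[[`, 1L, "n") %in% 2:5))
})

test_that("null size shares follow the real cluster distribution", {
  # real sizes at (90%, 7%, 3%) for 2/3/4 genes: multinomial check
  set.seed(40)
  fake_cluster <- function(id, genes) {
    structure(list(cluster_id = id, context = "ctx", gene_ids = genes,
                   n = length(genes), m = 1L, chrom = "chr1",
                   span = c(1L, 2L), sign_class = "all-positive",
                   flagged = FALSE, is_null = FALSE),
              class = "gene_cluster")
  }
  N <- 2500
  gene_ids <- sprintf("g%04d", 1:N)
  sizes <- c(rep(2, 90), rep(3, 7), rep(4, 3))
  clusters <- lapply(seq_along(sizes), function(i)
    fake_cluster(paste0("c", i), gene_ids[1:2]))  # membership proxy
  for (i in seq_along(sizes)) clusters[[i]]$n <- as.integer(sizes[i])
  corr <- structure(list(gene_ids = gene_ids,
                         rho = NULL, pval = NULL,
                         sig = matrix(FALSE, N, N), alpha_bonf = 1,
                         n_pairs = choose(N, 2), n_samples = 50),
                    class = "corr_matrix")
  nulls <- sample_null_clusters(corr, clusters, n_total = 500, seed = 8)
  shares <- tabulate(vapply(nulls, `[[`, 1L, "n"), 5)[2:4] / 500
  # ~3 binomial sd margins at n = 500
  expect_lt(abs(shares[1] - 0.90), 0.045)
  expect_lt(abs(shares[2] - 0.07), 0.04)
  expect_lt(abs(shares[3] - 0.03), 0.025)
})
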