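# enrichment: cluster annotation rules, logistic enrichment,
# PIP-weighted variant annotations

mk_cluster <- function(genes, id = "cl1", is_null = FALSE) {
  structure(list(cluster_id = id, context = "ctx", gene_ids = genes,
                 n = length(genes), m = 1L, chrom = "chr1",
                 span = c(NA, NA), sign_class = NA, flagged = FALSE,
                 is_null = is_null), class = "gene_cluster")
}

test_that("promoter and overlap labels follow the pairwise rules", {
  # opposite strands, 5' ends 500 bp apart -> bidirectional promoter
  gA <- gene_model("gA", "chr1", "+", cbind(10000, 20000)) # TSS 10000
  gB <- gene_model("gB", "chr1", "-", cbind(2000, 10500))  # TSS 10500
  ann <- annotate_cluster(mk_cluster(c("gA", "gB")),
                          list(gA = gA, gB = gB))
  expect_equal(ann$labels[["bidirectional_promoter"]], 1)
  expect_equal(ann$labels[["same_strand_promoter"]], 0)
  # overlapping but promoter-sharing pairs are excluded from overlap
  expect_equal(ann$labels[["overlap_opposite"]], 0)
  # same strand, close 5' ends
  gC <- gene_model("gC", "chr1", "+", cbind(10800, 30000))
  ann2 <- annotate_cluster(mk_cluster(c("gA", "gC")),
                           list(gA = gA, gC = gC))
  expect_equal(ann2$labels[["same_strand_promoter"]], 1)
  # overlap without promoter sharing, opposite strands
  gD <- gene_model("gD", "chr1", "-", cbind(12000, 18000)) # TSS 18000
  ann3 <- annotate_cluster(mk_cluster(c("gA", "gD")),
                           list(gA = gA, gD = gD))
  expect_equal(ann3$labels[["overlap_opposite"]], 1)
  expect_equal(ann3$labels[["bidirectional_promoter"]], 0)
  # distance > 1000 bp on the 5' ends is not a shared promoter
  gE <- gene_model("gE", "chr1", "-", cbind(2000, 11500))
  ann4 <- annotate_cluster(mk_cluster(c("gA", "gE")),
                           list(gA = gA, gE = gE))
  expect_equal(ann4$labels[["bidirectional_promoter"]], 0)
})

test_that("resource-backed labels: enhancer score, paralogs, GO, spans", {
  gA <- gene_model("gA", "chr1", "+", cbind(10000, 20000))
  gB <- gene_model("gB", "chr1", "+", cbind(40000, 60000))
  genes <- list(gA = gA, gB = gB)
  cl <- mk_cluster(c("gA", "gB"))
  # shared element below score threshold does not count
  enh_low <- data.frame(gene = c("gA", "gB"), element = "e1",
                        score = 0.05, class = "genic")
  expect_equal(annotate_cluster(cl, genes,
                                list(enhancers = enh_low))$labels[["shared_enhancer"]], 0)
  enh_hi <- data.frame(gene = c("gA", "gB"), element = "e1",
                       score = 0.2, class = "intergenic")
  expect_equal(annotate_cluster(cl, genes,
                                list(enhancers = enh_hi))$labels[["shared_enhancer"]], 1)
  # promoter-class elements are ignored even with high scores
  enh_prom <- data.frame(gene = c("gA", "gB"), element = "e1",
                         score = 0.9, class = "promoter")
  expect_equal(annotate_cluster(cl, genes,
                                list(enhancers = enh_prom))$labels[["shared_enhancer"]], 0)
  # paralogs in either order
  par <- data.frame(gene_a = "gB", gene_b = "gA")
  expect_equal(annotate_cluster(cl, genes,
                                list(paralogs = par))$labels[["paralogs"]], 1)
  # shared GO BP term
  go <- data.frame(gene = c("gA", "gB", "gB"),
                   term = c("GO:1", "GO:2", "GO:1"))
  expect_equal(annotate_cluster(cl, genes,
                                list(go = go))$labels[["shared_go_bp"]], 1)
  # CTCF peak at the span midpoint vs outside the span
  ctcf_in <- data.frame(chrom = "chr1", start = 34000, end = 34500)
  ctcf_out <- data.frame(chrom = "chr1", start = 90000, end = 90500)
  expect_equal(annotate_cluster(cl, genes,
                                list(ctcf = ctcf_in))$labels[["cross_ctcf"]], 1)
  expect_equal(annotate_cluster(cl, genes,
                                list(ctcf = ctcf_out))$labels[["cross_ctcf"]], 0)
  tad <- data.frame(chrom = "chr1", start = 30000, end = 30010)
  expect_equal(annotate_cluster(cl, genes,
                                list(tad = tad))$labels[["cross_tad"]], 1)
  # missing resources leave labels NA, not 0
  ann0 <- annotate_cluster(cl, genes)
  expect_true(is.na(ann0$labels[["shared_enhancer"]]))
  expect_true(is.na(ann0$labels[["cross_tad"]]))
  # symmetric in gene order
  ann_ab <- annotate_cluster(cl, genes, list(paralogs = par))
  cl_ba <- mk_cluster(c("gB", "gA"))
  ann_ba <- annotate_cluster(cl_ba, genes, list(paralogs = par))
  expect_identical(ann_ab$labels, ann_ba$labels)
})

fake_annotation <- function(label, is_null, n_genes = 2,
                            log_length = 10) {
  structure(list(cluster_id = "x", is_null = is_null,
                 labels = c(bidirectional_promoter = label,
                            same_strand_promoter = 0,
                            overlap_opposite = 0, overlap_same = 0,
                            shared_enhancer = 0, paralogs = 0,
                            shared_go_bp = 0, cross_ctcf = 0,
                            cross_tad = 0),
                 n_genes = n_genes, log_length = log_length),
            class = "cluster_annotation")
}

test_that("covariate-free enrichment equals the 2x2 odds ratio", {
  annos <- c(lapply(1:100, function(i) fake_annotation(i <= 30, FALSE)),
             lapply(1:100, function(i) fake_annotation(i <= 10, TRUE)))
  res <- logistic_enrichment(annos, "bidirectional_promoter")
  expect_false(res$skipped)
  expect_equal(res$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_true(res$ci95_low <= res$odds_ratio &&
                res$odds_ratio <= res$ci95_high)
})

test_that("balanced labels give OR ~ 1 and the skip rule fires", {
  set.seed(101)
  annos <- c(lapply(1:80, function(i)
    fake_annotation(runif(1) < 0.4, FALSE, n_genes = sample(2:4, 1),
                    log_length = rnorm(1, 10))),
    lapply(1:80, function(i)
      fake_annotation(runif(1) < 0.4, TRUE, n_genes = sample(2:4, 1),
                      log_length = rnorm(1, 10))))
  res <- logistic_enrichment(annos, "bidirectional_promoter")
  expect_true(res$ci95_low < 1 && 1 < res$ci95_high)
  # expected cell below 5 -> skipped (rare label)
  annos2 <- c(lapply(1:100, function(i) fake_annotation(i <= 4, FALSE)),
              lapply(1:100, function(i) fake_annotation(FALSE, TRUE)))
  res2 <- logistic_enrichment(annos2, "bidirectional_promoter")
  expect_true(res2$skipped)
  expect_match(res2$reason, "expected cell")
})

test_that("null-simulation CI coverage of OR = 1 is calibrated", {
  set.seed(102)
  cover <- vapply(1:150, function(i) {
    annos <- c(lapply(1:60, function(j) fake_annotation(runif(1) < 0.5,
                                                        FALSE)),
               lapply(1:60, function(j) fake_annotation(runif(1) < 0.5,
                                                        TRUE)))
    r <- logistic_enrichment(annos, "bidirectional_promoter")
    if (r$skipped) NA else (r$ci95_low <= 1 && 1 <= r$ci95_high)
  }, TRUE)
  expect_gt(mean(cover, na.rm = TRUE), 0.88)
})

test_that("pip_weighted_annotation computes normalized weighted shares", {
  cs <- structure(list(cs_id = "c", phenotype_id = "p",
                       variant_ids = paste0("v", 1:4),
                       pips = c(0.5, 0.25, 0.15, 0.05),
                       model_pip = c(0.5, 0.25, 0.15, 0.05),
                       coverage = 0.95, purity = 1,
                       lead_variant = "v1", effect = 1L,
                       member_key = ""), class = "credible_set")
  A <- cbind(promoter = c(1, 0, 1, 0), enhancer = c(1, 1, 1, 1))
  rownames(A) <- paste0("v", 1:4)
  got <- pip_weighted_annotation(cs, A)
  expect_equal(got[["promoter"]], (0.5 + 0.15) / 0.95, tolerance = 1e-12)
  expect_equal(got[["enhancer"]], 1, tolerance = 1e-12)
  raw <- pip_weighted_annotation(cs, A, normalize = FALSE)
  expect_equal(raw[["promoter"]], 0.65, tolerance = 1e-12)
  # single-variant set equals the indicator
  cs1 <- cs; cs1$variant_ids <- "v2"; cs1$pips <- 0.99
  expect_equal(pip_weighted_annotation(cs1, A)[["promoter"]], 0)
  expect_error(pip_weighted_annotation(cs, A[1:2, ]), "missing")
})
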