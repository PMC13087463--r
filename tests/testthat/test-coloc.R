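# coloc_grouping: Wakefield ABFs, pairwise colocalization, groups,
# novelty, GWAS linking

mk_sig <- function(id, source, lbf, ids = paste0("v", seq_along(lbf))) {
  signal_bf(id, source, ids, lbf)
}

test_that("wakefield_abf matches the formula and its endpoints", {
  gw <- gwas_stats("t", paste0("v", 1:30),
                   beta = rnorm(30, 0, 0.05),
                   se = runif(30, 0.01, 0.05))
  sig <- wakefield_abf(gw, prior_sd = 0.15)
  W <- 0.15^2
  oracle <- 0.5 * log(gw$se^2 / (gw$se^2 + W)) +
    0.5 * (gw$beta / gw$se)^2 * W / (gw$se^2 + W)
  expect_equal(sig$lbf, oracle, tolerance = 1e-12)
  # z = 0 everywhere: equal negative lbf
  gw0 <- gwas_stats("t0", paste0("v", 1:5), rep(0, 5), rep(0.02, 5))
  s0 <- wakefield_abf(gw0)
  expect_true(all(s0$lbf < 0))
  expect_equal(diff(range(s0$lbf)), 0)
  # W = 0: all lbf exactly 0
  expect_equal(wakefield_abf(gw, prior_sd = 0)$lbf, rep(0, 30))
})

test_that("coloc_pair matches brute-force configuration enumeration", {
  set.seed(91)
  for (rep in 1:20) {
    p <- sample(2:10, 1)
    la <- rnorm(p, 0, 4)
    lb <- rnorm(p, 0, 4)
    res <- coloc_pair(mk_sig("a", "eQTL", la), mk_sig("b", "pcQTL", lb))
    oracle <- oracle_coloc(la, lb)
    got <- c(res$pp_h0, res$pp_h1, res$pp_h2, res$pp_h3, res$pp_h4)
    expect_equal(log(got + 1e-300), log(oracle + 1e-300),
                 tolerance = 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-8)
  }
})

test_that("coloc_pair limiting cases behave as expected", {
  # all-zero lbf: posteriors proportional to priors, H0 dominates
  res <- coloc_pair(mk_sig("a", "eQTL", rep(0, 8)),
                    mk_sig("b", "pcQTL", rep(0, 8)))
  expect_gt(res$pp_h0, 0.99)
  # identical one-spike vectors: H4
  spike <- c(rep(0, 9), 30)
  res4 <- coloc_pair(mk_sig("a", "eQTL", spike),
                     mk_sig("b", "pcQTL", spike))
  expect_gt(res4$pp_h4, 0.99)
  # spikes on different variants: H3
  res3 <- coloc_pair(mk_sig("a", "eQTL", c(30, rep(0, 9))),
                     mk_sig("b", "pcQTL", spike))
  expect_gt(res3$pp_h3, 0.99)
  # non-overlapping variant sets warn and return pp_h4 = 0
  expect_warning(
    r0 <- coloc_pair(mk_sig("a", "eQTL", 1:3, ids = paste0("x", 1:3)),
                     mk_sig("b", "pcQTL", 1:3, ids = paste0("y", 1:3))),
    "overlap")
  expect_equal(r0$pp_h4, 0)
})

test_that("coloc_pair is symmetric", {
  set.seed(92)
  la <- rnorm(6, 0, 3); lb <- rnorm(6, 0, 3)
  ab <- coloc_pair(mk_sig("a", "eQTL", la), mk_sig("b", "pcQTL", lb))
  ba <- coloc_pair(mk_sig("b", "pcQTL", lb), mk_sig("a", "eQTL", la))
  expect_equal(ab$pp_h1, ba$pp_h2, tolerance = 1e-12)
  expect_equal(ab$pp_h2, ba$pp_h1, tolerance = 1e-12)
  expect_equal(ab$pp_h0, ba$pp_h0, tolerance = 1e-12)
  expect_equal(ab$pp_h3, ba$pp_h3, tolerance = 1e-12)
  expect_equal(ab$pp_h4, ba$pp_h4, tolerance = 1e-12)
})

sig_df <- function(ids, sources, genes = NA) {
  data.frame(signal_id = ids, source = sources, gene_id = genes,
             stringsAsFactors = FALSE)
}

coloc_df <- function(a, b, h4) {
  data.frame(signal_a = a, signal_b = b, pp_h4 = h4,
             stringsAsFactors = FALSE)
}

test_that("groups are connected components with correct typing", {
  sigs <- sig_df(c("A", "B", "C", "D"),
                 c("eQTL", "pcQTL", "eQTL", "pcQTL"),
                 c("g1", NA, "g2", NA))
  # edges A-B and B-C -> one group {A,B,C}; D isolated
  cl <- coloc_df(c("A", "B", "A"), c("B", "C", "D"),
                 c(0.9, 0.8, 0.2))
  gr <- build_groups(sigs, cl)
  expect_length(gr, 2)
  big <- gr[[which(vapply(gr, function(g) length(g$signal_ids), 1L) == 3)]]
  expect_setequal(big$signal_ids, c("A", "B", "C"))
  expect_identical(big$type, "both")
  expect_setequal(big$egene_ids, c("g1", "g2"))
  lone <- gr[[which(vapply(gr, function(g) length(g$signal_ids), 1L) == 1)]]
  expect_identical(lone$type, "pcQTL-only")
  # no edges: every signal its own group
  gr0 <- build_groups(sigs, coloc_df(character(0), character(0),
                                     numeric(0)))
  expect_length(gr0, 4)
  # order of coloc rows does not matter
  gr_rev <- build_groups(sigs, cl[c(3, 1, 2), ])
  ids <- function(g) sort(vapply(g, function(x)
    paste(x$signal_ids, collapse = ","), ""))
  expect_identical(ids(gr), ids(gr_rev))
})

test_that("novelty classification follows group type", {
  sigs <- sig_df(c("pc1", "pc2", "e1"), c("pcQTL", "pcQTL", "eQTL"),
                 c(NA, NA, "g1"))
  gr <- build_groups(sigs, coloc_df("pc1", "e1", 0.9))
  nov <- classify_novel_pcqtls(gr)
  expect_false(nov$novel[nov$signal_id == "pc1"])   # in a "both" group
  expect_true(nov$novel[nov$signal_id == "pc2"])    # pcQTL-only singleton
})

test_that("GWAS linking applies the threshold rule and collapses hits", {
  rows <- rbind(
    # hit1 in tissue T1: eQTL 0.8 and pcQTL 0.9 -> eQTL-linked
    data.frame(gwas_variant = "v1", trait = "height", tissue = "T1",
               qtl_source = c("eQTL", "pcQTL"), pp_h4 = c(0.8, 0.9)),
    # hit2: pcQTL 0.9, best eQTL 0.6 -> pcQTL-only
    data.frame(gwas_variant = "v2", trait = "height", tissue = "T1",
               qtl_source = c("eQTL", "pcQTL"), pp_h4 = c(0.6, 0.9)),
    # same (variant, trait) in three tissues counts once
    data.frame(gwas_variant = "v3", trait = "bmi",
               tissue = c("T1", "T2", "T3"),
               qtl_source = "eQTL", pp_h4 = 0.95),
    # same variant, second trait counts separately
    data.frame(gwas_variant = "v3", trait = "height", tissue = "T1",
               qtl_source = "eQTL", pp_h4 = 0.95))
  links <- link_gwas(rows)
  h <- links$hits
  expect_true(h$eqtl_linked[h$gwas_variant == "v1" & h$tissue == "T1"])
  expect_false(h$pcqtl_only_linked[h$gwas_variant == "v1"])
  expect_true(h$pcqtl_only_linked[h$gwas_variant == "v2"])
  expect_identical(links$n_unique_eqtl, 3L)   # v1, v3-bmi, v3-height
  expect_identical(links$n_unique_pcqtl_only, 1L)
})
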