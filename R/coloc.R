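# Pairwise colocalization of QTL and GWAS signals by Bayes-factor
# enumeration, credible-set group construction, novelty classification
# and GWAS linking.

#' Signal container for colocalization
#'
#' A fine-mapped signal reduced to per-variant log Bayes factors: the
#' SuSiE `lbf_variable` row of the signal's effect for QTLs, or
#' Wakefield ABFs for GWAS summary statistics.
#'
#' @param signal_id unique id.
#' @param source one of `"eQTL"`, `"pcQTL"`, `"GWAS"`.
#' @param variant_ids,lbf equal-length; lbf finite.
#' @param meta optional named list (e.g. `gene_id`, `trait_id`,
#'   `tissue`).
#' @return object of class `signal_bf`.
#' @export
signal_bf <- function(signal_id, source, variant_ids, lbf,
                      meta = list()) {
  stopifnot(length(variant_ids) == length(lbf), all(is.finite(lbf)),
            source %in% c("eQTL", "pcQTL", "GWAS"))
  structure(list(signal_id = signal_id, source = source,
                 variant_ids = as.character(variant_ids),
                 lbf = as.numeric(lbf), meta = meta),
            class = "signal_bf")
}

#' Wakefield approximate Bayes factors for GWAS summary statistics
#'
#' Per-variant log ABF of association against the null under a
#' `N(0, W)` effect prior:
#' `lbf_j = 0.5*log(se_j^2/(se_j^2+W)) + 0.5*z_j^2*W/(se_j^2+W)` with
#' `W = prior_sd^2`.
#'
#' @param gwas a [gwas_stats()].
#' @param prior_sd prior effect sd, default 0.15 (quantitative traits).
#' @return a [signal_bf()] with source `"GWAS"`.
#' @export
wakefield_abf <- function(gwas, prior_sd = 0.15) {
  stopifnot(inherits(gwas, "gwas_stats"))
  if (any(gwas$se == 0)) stop("se must be positive")
  W <- prior_sd^2
  v <- gwas$se^2
  z2 <- (gwas$beta / gwas$se)^2
  lbf <- 0.5 * log(v / (v + W)) + 0.5 * z2 * W / (v + W)
  signal_bf(paste0("GWAS_", gwas$trait_id), "GWAS", gwas$variant_ids,
            lbf, meta = list(trait_id = gwas$trait_id))
}

#' Colocalize two signals by Bayes-factor enumeration
#'
#' Enumerates causal-variant configurations over the common variant
#' index: H0 no signal, H1/H2 one signal only, H3 two distinct causal
#' variants, H4 one shared causal variant. Per-hypothesis sums are
#' `H1 ~ p1*sum_j exp(lbf_a_j)`, `H2 ~ p2*sum_j exp(lbf_b_j)`,
#' `H3 ~ p1*p2*sum_{j!=k} exp(lbf_a_j+lbf_b_k)`,
#' `H4 ~ p12*sum_j exp(lbf_a_j+lbf_b_j)`, normalized in log space
#' (log-sum-exp throughout).
#'
#' @param a,b [signal_bf()] objects.
#' @param p1,p2 prior probability a variant is causal for signal a (b)
#'   only; defaults 1e-4.
#' @param p12 prior probability a variant is causal for both; default
#'   5e-6.
#' @return object of class `coloc_result`: `signal_a`, `signal_b`,
#'   `pp_h0` .. `pp_h4` (sum to 1), `n_variants`, `colocalized`
#'   (`pp_h4 >= 0.75`). Non-overlapping variant sets yield `pp_h4 = 0`
#'   with a warning.
#' @export
coloc_pair <- function(a, b, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  stopifnot(inherits(a, "signal_bf"), inherits(b, "signal_bf"))
  common <- intersect(a$variant_ids, b$variant_ids)
  if (!length(common)) {
    warning("no overlapping variants between ", a$signal_id, " and ",
            b$signal_id)
    return(structure(list(signal_a = a$signal_id,
                          signal_b = b$signal_id,
                          pp_h0 = NA_real_, pp_h1 = NA_real_,
                          pp_h2 = NA_real_, pp_h3 = NA_real_,
                          pp_h4 = 0, n_variants = 0L,
                          colocalized = FALSE),
                     class = "coloc_result"))
  }
  la <- a$lbf[match(common, a$variant_ids)]
  lb <- b$lbf[match(common, b$variant_ids)]
  l1 <- logsumexp(la)
  l2 <- logsumexp(lb)
  l4 <- logsumexp(la + lb)
  # sum over j != k equals S1*S2 - S4; guard the single-variant /
  # rounding corner where the difference underflows
  delta <- l4 - (l1 + l2)
  l3 <- if (length(common) == 1 || delta >= 0) -Inf
        else l1 + l2 + log1p(-exp(delta))
  lpost <- c(h0 = 0,
             h1 = log(p1) + l1,
             h2 = log(p2) + l2,
             h3 = log(p1) + log(p2) + l3,
             h4 = log(p12) + l4)
  pp <- exp(lpost - logsumexp(lpost))
  pp <- pp / sum(pp)
  structure(list(signal_a = a$signal_id, signal_b = b$signal_id,
                 pp_h0 = unname(pp[1]), pp_h1 = unname(pp[2]),
                 pp_h2 = unname(pp[3]), pp_h3 = unname(pp[4]),
                 pp_h4 = unname(pp[5]), n_variants = length(common),
                 colocalized = unname(pp[5]) >= 0.75),
            class = "coloc_result")
}

#' Colocalization results as a data.frame
#' @param results list of `coloc_result`.
#' @return data.frame, one row per pair.
#' @export
coloc_as_table <- function(results) {
  if (!length(results)) {
    return(data.frame(signal_a = character(0), signal_b = character(0),
                      pp_h0 = numeric(0), pp_h1 = numeric(0),
                      pp_h2 = numeric(0), pp_h3 = numeric(0),
                      pp_h4 = numeric(0), colocalized = logical(0)))
  }
  do.call(rbind, lapply(results, function(r) {
    data.frame(signal_a = r$signal_a, signal_b = r$signal_b,
               pp_h0 = r$pp_h0, pp_h1 = r$pp_h1, pp_h2 = r$pp_h2,
               pp_h3 = r$pp_h3, pp_h4 = r$pp_h4,
               colocalized = r$colocalized, stringsAsFactors = FALSE)
  }))
}

#' Build credible-set groups from pairwise QTL colocalizations
#'
#' Undirected graph with one node per QTL credible set and an edge
#' wherever `pp_h4 >= edge_threshold`; groups are the connected
#' components. A group is `"pcQTL-only"` if it contains only pcQTL
#' credible sets, `"eQTL-only"` if only eQTL sets, otherwise `"both"`.
#' GWAS signals do not enter the graph; they are linked post hoc with
#' [link_gwas()].
#'
#' @param signals data.frame with `signal_id`, `source` (`eQTL` /
#'   `pcQTL`) and optionally `gene_id` (for eQTL signals).
#' @param coloc data.frame from [coloc_as_table()] restricted to
#'   QTL-QTL pairs.
#' @param edge_threshold default 0.75.
#' @return list of `credible_set_group`: `group_id`, `signal_ids`,
#'   `type`, `egene_ids`.
#' @export
build_groups <- function(signals, coloc, edge_threshold = 0.75) {
  stopifnot(all(signals$source %in% c("eQTL", "pcQTL")))
  g <- igraph::make_empty_graph(n = nrow(signals), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = signals$signal_id)
  if (nrow(coloc)) {
    edges <- coloc[!is.na(coloc$pp_h4) &
                     coloc$pp_h4 >= edge_threshold, , drop = FALSE]
    edges <- edges[edges$signal_a %in% signals$signal_id &
                     edges$signal_b %in% signals$signal_id, ,
                   drop = FALSE]
    if (nrow(edges))
      g <- igraph::add_edges(g, rbind(edges$signal_a, edges$signal_b))
  }
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(k) {
    ids <- names(comp$membership)[comp$membership == k]
    src <- signals$source[match(ids, signals$signal_id)]
    type <- if (all(src == "pcQTL")) "pcQTL-only"
            else if (all(src == "eQTL")) "eQTL-only"
            else "both"
    eg <- signals$gene_id[match(ids[src == "eQTL"], signals$signal_id)]
    structure(list(group_id = sprintf("group_%d", k),
                   signal_ids = sort(ids), type = type,
                   egene_ids = sort(unique(eg[!is.na(eg)]))),
              class = "credible_set_group")
  })
}

#' Flag novel pcQTL credible sets
#'
#' A pcQTL credible set is novel iff its group contains no eQTL
#' credible set for any gene of the cluster (group type pcQTL-only).
#'
#' @param groups list from [build_groups()].
#' @return data.frame: `signal_id`, `group_id`, `group_type`, `novel`.
#' @export
classify_novel_pcqtls <- function(groups) {
  do.call(rbind, lapply(groups, function(gr) {
    data.frame(signal_id = gr$signal_ids, group_id = gr$group_id,
               group_type = gr$type,
               novel = gr$type == "pcQTL-only",
               stringsAsFactors = FALSE)
  }))
}

#' Link GWAS hits to QTL signals and count unique hits
#'
#' Per (GWAS variant, trait, tissue, cluster): eQTL-linked if any eQTL
#' colocalization has `pp_h4 >= threshold`; pcQTL-only-linked if some
#' pcQTL reaches the threshold while every eQTL stays below it. Unique
#' hits collapse by (variant, trait) across tissues: the same pair in
#' several tissues counts once; the same variant with two traits counts
#' twice.
#'
#' @param gwas_coloc data.frame with columns `gwas_variant`, `trait`,
#'   `tissue`, `qtl_source` (`eQTL`/`pcQTL`), `pp_h4`.
#' @param edge_threshold default 0.75.
#' @return list: `hits` (per variant-trait-tissue linkage table),
#'   `n_unique_eqtl`, `n_unique_pcqtl_only`.
#' @export
link_gwas <- function(gwas_coloc, edge_threshold = 0.75) {
  need <- c("gwas_variant", "trait", "tissue", "qtl_source", "pp_h4")
  stopifnot(all(need %in% names(gwas_coloc)))
  key <- interaction(gwas_coloc$gwas_variant, gwas_coloc$trait,
                     gwas_coloc$tissue, drop = TRUE)
  hits <- do.call(rbind, lapply(split(gwas_coloc, key), function(d) {
    e <- d$pp_h4[d$qtl_source == "eQTL"]
    p <- d$pp_h4[d$qtl_source == "pcQTL"]
    eqtl_linked <- length(e) > 0 && any(e >= edge_threshold)
    pc_linked <- length(p) > 0 && any(p >= edge_threshold)
    data.frame(gwas_variant = d$gwas_variant[1], trait = d$trait[1],
               tissue = d$tissue[1], eqtl_linked = eqtl_linked,
               pcqtl_only_linked = pc_linked && !eqtl_linked,
               stringsAsFactors = FALSE)
  }))
  rownames(hits) <- NULL
  vt <- function(d) unique(paste(d$gwas_variant, d$trait, sep = "::"))
  list(hits = hits,
       n_unique_eqtl = length(vt(hits[hits$eqtl_linked, , drop = FALSE])),
       n_unique_pcqtl_only =
         length(vt(hits[hits$pcqtl_only_linked, , drop = FALSE])))
}
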