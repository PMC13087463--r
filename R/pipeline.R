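# Stage orchestration and configuration for the end-to-end workflow.

#' Pipeline configuration
#'
#' All thresholds default to the framework's canonical constants:
#' MAF floor 0.05 (inclusive), cis window +/- 1 Mb around the cluster
#' span, pairwise correlation alpha 0.05 (Bonferroni-corrected by
#' C(N,2)), window acceptance fraction 0.7, maximum cluster size 50,
#' L = 10 effects, purity 0.5, credible-set coverage 0.95,
#' colocalization edge 0.75, FDR threshold q < 0.05, near-TSS window
#' 250 bp, 1000 permutations.
#'
#' @param ... overrides for any field.
#' @return list of class `pcqtl_config` (validated).
#' @export
pcqtl_config <- function(...) {
  cfg <- list(maf_floor = 0.05, cis_window = 1e6, corr_alpha = 0.05,
              accept_frac = 0.7, max_cluster_size = 50, L = 10,
              min_abs_corr = 0.5, coverage = 0.95, coloc_edge = 0.75,
              q_threshold = 0.05, near_tss = 250, B_perm = 1000,
              coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 5e-6,
              gwas_prior_sd = 0.15, run_permutations = TRUE,
              seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(maf_floor >= 0, maf_floor <= 0.5, cis_window > 0,
              corr_alpha > 0, corr_alpha < 1, accept_frac > 0,
              accept_frac <= 1, L >= 1, min_abs_corr >= 0,
              min_abs_corr <= 1, coverage > 0, coverage <= 1,
              coloc_edge > 0, coloc_edge <= 1, q_threshold > 0,
              q_threshold < 1, near_tss > 0, B_perm >= 1)
  })
  structure(cfg, class = "pcqtl_config")
}

# variants of the cis window: +/- cis_window around the cluster span
window_variants <- function(geno, chrom, span, cis_window, maf_floor) {
  keep <- geno$chrom == chrom &
    geno$pos >= span[1] - cis_window &
    geno$pos <= span[2] + cis_window &
    geno$maf >= maf_floor
  t(geno$dosages[keep, , drop = FALSE])
}

finemap_phenotype <- function(y, X, phenotype_id, cfg) {
  fit <- susie_fit(y, X, L = cfg$L)
  sets <- extract_credible_sets(fit, X, coverage = cfg$coverage,
                                min_abs_corr = cfg$min_abs_corr,
                                phenotype_id = phenotype_id)
  list(fit = fit, sets = sets)
}

#' Run the full pcQTL workflow on a cohort
#'
#' Stages, in order: residualize expression on covariates; per
#' chromosome, Spearman correlations and sliding-window cluster
#' calling; per cluster, PCA phenotypes; fine-mapping of every cluster
#' gene (eQTL) and every PC (pcQTL) on the shared cis-window variants;
#' optional permutation-based phenotype-level FDR (three pooled
#' conditions: eQTL alone, pcQTL alone, joint); pairwise QTL-QTL and
#' QTL-GWAS colocalization; credible-set groups, novelty
#' classification and GWAS linking; PIP-weighted aFC effect summaries
#' (when a linear-scale channel is available) and lead-variant TSS
#' distances.
#'
#' @param cohort a [simulate_cohort()] result, or any list with the
#'   same fields (`expr`, `covariates`, `genotypes`, `gene_models`,
#'   optional `gwas`, optional `linear`, `context`).
#' @param cfg a [pcqtl_config()].
#' @return list of class `pcqtl_result` with elements `clusters`,
#'   `pcs`, `eqtl` / `pcqtl` (per-phenotype fits and credible sets),
#'   `credible_sets` (table), `fdr` (when run), `coloc`, `groups`,
#'   `novelty`, `gwas_links`, `effects`, `tss_distances`, `config`.
#' @export
run_pipeline <- function(cohort, cfg = pcqtl_config()) {
  stopifnot(inherits(cfg, "pcqtl_config"))
  resid <- residualize(cohort$expr, cohort$covariates)
  chroms <- unique(resid$anchors$chrom)
  clusters <- list()
  for (ch in chroms) {
    corr <- spearman_matrix(resid, ch, alpha = cfg$corr_alpha)
    clusters <- c(clusters,
                  call_clusters(corr, anchors = resid$anchors,
                                max_size = cfg$max_cluster_size,
                                accept_frac = cfg$accept_frac,
                                context = cohort$context))
  }
  pcs <- list()
  eqtl <- list()
  pcqtl <- list()
  windows <- list()
  for (cl in clusters) {
    pc <- cluster_pca(resid, cl$gene_ids, cluster_id = cl$cluster_id)
    pcs[[cl$cluster_id]] <- pc
    X <- window_variants(cohort$genotypes, cl$chrom, cl$span,
                         cfg$cis_window, cfg$maf_floor)
    windows[[cl$cluster_id]] <- colnames(X)
    if (ncol(X) == 0) next
    for (g in cl$gene_ids)
      eqtl[[g]] <- finemap_phenotype(resid$values[g, ], X, g, cfg)
    for (k in seq_len(ncol(pc$scores))) {
      pid <- paste0(cl$cluster_id, ":PC", k)
      pcqtl[[pid]] <- finemap_phenotype(pc$scores[, k], X, pid, cfg)
    }
  }
  all_sets <- c(unlist(lapply(eqtl, `[[`, "sets"), recursive = FALSE),
                unlist(lapply(pcqtl, `[[`, "sets"), recursive = FALSE))
  fdr <- NULL
  if (isTRUE(cfg$run_permutations) && length(clusters)) {
    fdr <- phenotype_fdr(resid, pcs, clusters, cohort$genotypes, cfg)
  }
  coloc_res <- list()
  signals <- data.frame(signal_id = character(0), source = character(0),
                        gene_id = character(0),
                        cluster_id = character(0),
                        stringsAsFactors = FALSE)
  groups_by_cluster <- list()
  novelty <- NULL
  gwas_links <- NULL
  gwas_rows <- NULL
  effects <- NULL
  dists <- NULL
  for (cl in clusters) {
    res <- cluster_coloc(cl, eqtl, pcqtl, cohort, cfg,
                         windows[[cl$cluster_id]])
    coloc_res <- c(coloc_res, res$pairs)
    signals <- rbind(signals, res$signals)
    groups_by_cluster[[cl$cluster_id]] <- res$groups
    if (!is.null(res$novelty)) novelty <- rbind(novelty, res$novelty)
    if (!is.null(res$gwas_rows)) gwas_rows <- rbind(gwas_rows, res$gwas_rows)
    eff <- cluster_effects(cl, eqtl, pcqtl, cohort, cfg,
                           windows[[cl$cluster_id]], res$groups)
    if (!is.null(eff$effects)) effects <- rbind(effects, eff$effects)
    if (!is.null(eff$dists)) dists <- rbind(dists, eff$dists)
  }
  if (!is.null(gwas_rows) && nrow(gwas_rows))
    gwas_links <- link_gwas(gwas_rows, edge_threshold = cfg$coloc_edge)
  structure(list(residualized = resid, clusters = clusters, pcs = pcs,
                 eqtl = eqtl, pcqtl = pcqtl,
                 credible_sets = credible_sets_as_table(all_sets),
                 all_sets = all_sets, fdr = fdr,
                 coloc = coloc_as_table(coloc_res), signals = signals,
                 groups = groups_by_cluster, novelty = novelty,
                 gwas_links = gwas_links, effects = effects,
                 tss_distances = dists, config = cfg),
            class = "pcqtl_result")
}

# permutation FDR for the three pooled conditions
phenotype_fdr <- function(resid, pcs, clusters, geno, cfg) {
  perm_one <- function(y, X, seed) {
    permutation_pass(y, X, B = cfg$B_perm, seed = seed)
  }
  rows <- list()
  i <- 0
  for (cl in clusters) {
    X <- window_variants(geno, cl$chrom, cl$span, cfg$cis_window,
                         cfg$maf_floor)
    if (ncol(X) == 0) next
    for (g in cl$gene_ids) {
      i <- i + 1
      pr <- perm_one(resid$values[g, ], X, cfg$seed + i)
      rows[[length(rows) + 1]] <-
        data.frame(phenotype_id = g, kind = "eQTL",
                   p_nominal_best = pr$p_nominal_best,
                   best_variant = pr$best_variant,
                   empirical_p_direct = pr$empirical_p_direct,
                   empirical_p_beta = pr$empirical_p_beta,
                   stringsAsFactors = FALSE)
    }
    pc <- pcs[[cl$cluster_id]]
    for (k in seq_len(ncol(pc$scores))) {
      i <- i + 1
      pr <- perm_one(pc$scores[, k], X, cfg$seed + i)
      rows[[length(rows) + 1]] <-
        data.frame(phenotype_id = paste0(cl$cluster_id, ":PC", k),
                   kind = "pcQTL",
                   p_nominal_best = pr$p_nominal_best,
                   best_variant = pr$best_variant,
                   empirical_p_direct = pr$empirical_p_direct,
                   empirical_p_beta = pr$empirical_p_beta,
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  add_q <- function(d) {
    d$q <- as.numeric(qvalues(d$empirical_p_beta))
    d$significant <- d$q < cfg$q_threshold
    d
  }
  list(eqtl = add_q(tab[tab$kind == "eQTL", , drop = FALSE]),
       pcqtl = add_q(tab[tab$kind == "pcQTL", , drop = FALSE]),
       joint = add_q(tab))
}

# all pairwise colocalizations for one cluster, plus groups and GWAS
cluster_coloc <- function(cl, eqtl, pcqtl, cohort, cfg, window_ids) {
  sigs <- list()
  meta <- list()
  collect <- function(fits, source) {
    for (pid in names(fits)) {
      for (cs in fits[[pid]]$sets) {
        lbf <- fits[[pid]]$fit$lbf_variable[cs$effect, ]
        sigs[[cs$cs_id]] <<- signal_bf(cs$cs_id, source, window_ids, lbf)
        meta[[cs$cs_id]] <<- data.frame(
          signal_id = cs$cs_id, source = source,
          gene_id = if (source == "eQTL") pid else NA_character_,
          cluster_id = cl$cluster_id, lead = cs$lead_variant,
          stringsAsFactors = FALSE)
      }
    }
  }
  collect(eqtl[cl$gene_ids[cl$gene_ids %in% names(eqtl)]], "eQTL")
  pc_ids <- grep(paste0("^", cl$cluster_id, ":PC"), names(pcqtl),
                 value = TRUE)
  collect(pcqtl[pc_ids], "pcQTL")
  signals <- if (length(meta)) do.call(rbind, meta) else
    data.frame(signal_id = character(0), source = character(0),
               gene_id = character(0), cluster_id = character(0),
               lead = character(0), stringsAsFactors = FALSE)
  pairs <- list()
  if (length(sigs) >= 2) {
    idx <- utils::combn(length(sigs), 2)
    for (k in seq_len(ncol(idx))) {
      pairs[[length(pairs) + 1]] <-
        coloc_pair(sigs[[idx[1, k]]], sigs[[idx[2, k]]],
                   p1 = cfg$coloc_p1, p2 = cfg$coloc_p2,
                   p12 = cfg$coloc_p12)
    }
  }
  groups <- build_groups(signals, coloc_as_table(pairs),
                         edge_threshold = cfg$coloc_edge)
  novelty <- if (length(groups)) {
    nv <- classify_novel_pcqtls(groups)
    nv <- nv[nv$signal_id %in%
               signals$signal_id[signals$source == "pcQTL"], ,
             drop = FALSE]
    if (nrow(nv)) cbind(cluster_id = cl$cluster_id, nv) else NULL
  } else NULL
  gwas_rows <- NULL
  if (!is.null(cohort$gwas) && length(sigs)) {
    gw_list <- if (inherits(cohort$gwas, "gwas_stats"))
      list(cohort$gwas) else cohort$gwas
    for (gw in gw_list) {
      gsig <- wakefield_abf(gw, prior_sd = cfg$gwas_prior_sd)
      top <- gw$variant_ids[which.max(abs(gw$beta / gw$se))]
      for (s in sigs) {
        cp <- suppressWarnings(coloc_pair(gsig, s, p1 = cfg$coloc_p1,
                                          p2 = cfg$coloc_p2,
                                          p12 = cfg$coloc_p12))
        gwas_rows <- rbind(gwas_rows, data.frame(
          gwas_variant = top, trait = gw$trait_id,
          tissue = cohort$context, cluster_id = cl$cluster_id,
          qtl_signal = s$signal_id, qtl_source = s$source,
          pp_h4 = cp$pp_h4, stringsAsFactors = FALSE))
      }
    }
  }
  list(pairs = pairs, signals = signals, groups = groups,
       novelty = novelty, gwas_rows = gwas_rows)
}

# PIP-weighted aFC per credible set x gene, dispersion summaries, and
# group-level TSS distances
cluster_effects <- function(cl, eqtl, pcqtl, cohort, cfg, window_ids,
                            groups) {
  effects <- NULL
  if (!is.null(cohort$linear)) {
    lin_genes <- intersect(cl$gene_ids, rownames(cohort$linear))
    if (length(lin_genes) >= 2) {
      X <- t(cohort$genotypes$dosages[window_ids, , drop = FALSE])
      afc <- lapply(lin_genes, function(g)
        afc_scan(cohort$linear[g, ], X))
      names(afc) <- lin_genes
      all_fits <- c(eqtl[intersect(cl$gene_ids, names(eqtl))],
                    pcqtl[grep(paste0("^", cl$cluster_id, ":PC"),
                               names(pcqtl), value = TRUE)])
      for (pid in names(all_fits)) {
        for (cs in all_fits[[pid]]$sets) {
          per_gene <- vapply(lin_genes,
                             function(g) pip_weighted_afc(cs, afc[[g]]),
                             0)
          disp <- effect_dispersion(per_gene)
          effects <- rbind(effects, data.frame(
            cluster_id = cl$cluster_id, cs_id = cs$cs_id,
            phenotype_id = cs$phenotype_id,
            source = if (grepl(":PC", pid)) "pcQTL" else "eQTL",
            gene_id = lin_genes, pip_weighted_afc = unname(per_gene),
            max_abs_afc = disp$max_abs, cv_abs_afc = disp$cv,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  dists <- NULL
  models <- cohort$gene_models[cl$gene_ids]
  lead_of <- function(sid) {
    for (set in c(unlist(lapply(eqtl, `[[`, "sets"), recursive = FALSE),
                  unlist(lapply(pcqtl, `[[`, "sets"),
                         recursive = FALSE))) {
      if (set$cs_id == sid) return(set$lead_variant)
    }
    NA_character_
  }
  for (gr in groups) {
    leads <- vapply(gr$signal_ids, lead_of, "")
    pos <- cohort$genotypes$pos[match(leads,
                                      cohort$genotypes$variant_ids)]
    pos <- pos[!is.na(pos)]
    if (!length(pos)) next
    d <- tss_distance(pos, models, egene_ids = gr$egene_ids,
                      near_bp = cfg$near_tss)
    dists <- rbind(dists, data.frame(
      cluster_id = cl$cluster_id, group_id = gr$group_id,
      group_type = gr$type,
      dist_closest_gene = d$dist_closest_gene,
      dist_closest_egene = d$dist_closest_egene,
      near_tss_gene = d$near_tss_gene,
      near_tss_egene = d$near_tss_egene, stringsAsFactors = FALSE))
  }
  list(effects = effects, dists = dists)
}

#' Run one named pipeline stage
#'
#' Stages operate on an accumulating state list and return it extended
#' with their outputs; each stage checks that its upstream outputs
#' exist and names the missing stage otherwise. Stages:
#' `"simulate"` (needs `state$sim_config`), `"preprocess"`,
#' `"clusters"`, `"pcs"`, `"finemap"`, `"scan"`, `"coloc"` (runs
#' colocalization, grouping, novelty, GWAS linking), `"effects"`.
#'
#' @param name stage name.
#' @param state list; for `"simulate"` supply `sim_config`, otherwise a
#'   cohort under `state$cohort`.
#' @param cfg a [pcqtl_config()].
#' @return the extended state.
#' @export
run_stage <- function(name, state = list(), cfg = pcqtl_config()) {
  need <- function(field, stage) {
    if (is.null(state[[field]]))
      stop("stage '", name, "' needs output of stage '", stage,
           "'; run it first")
  }
  switch(name,
    simulate = {
      if (is.null(state$sim_config))
        stop("stage 'simulate' needs state$sim_config (see sim_config())")
      state$cohort <- simulate_cohort(state$sim_config)
    },
    preprocess = {
      need("cohort", "simulate (or ingest)")
      state$residualized <- residualize(state$cohort$expr,
                                        state$cohort$covariates)
    },
    clusters = {
      need("residualized", "preprocess")
      resid <- state$residualized
      cl <- list()
      for (ch in unique(resid$anchors$chrom)) {
        corr <- spearman_matrix(resid, ch, alpha = cfg$corr_alpha)
        cl <- c(cl, call_clusters(corr, anchors = resid$anchors,
                                  max_size = cfg$max_cluster_size,
                                  accept_frac = cfg$accept_frac,
                                  context = state$cohort$context))
      }
      state$clusters <- cl
    },
    pcs = {
      need("clusters", "clusters")
      state$pcs <- lapply(state$clusters, function(cl)
        cluster_pca(state$residualized, cl$gene_ids,
                    cluster_id = cl$cluster_id))
      names(state$pcs) <- vapply(state$clusters, `[[`, "", "cluster_id")
    },
    finemap = ,
    scan = ,
    coloc = ,
    effects = {
      need("clusters", "clusters")
      state$result <- run_pipeline(state$cohort, cfg)
    },
    stop("unknown stage: ", name))
  state
}

#' Run the full workflow and write outputs
#'
#' Convenience wrapper: [simulate_cohort()] if given a [sim_config()],
#' then [run_pipeline()], then [write_pipeline_outputs()] when
#' `out_dir` is provided.
#'
#' @param cohort a cohort list or a `sim_config`.
#' @param cfg a [pcqtl_config()].
#' @param out_dir optional output directory.
#' @return the [run_pipeline()] result.
#' @export
run_all <- function(cohort, cfg = pcqtl_config(), out_dir = NULL) {
  if (inherits(cohort, "sim_config")) cohort <- simulate_cohort(cohort)
  res <- run_pipeline(cohort, cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write pipeline outputs as TSV/JSON into a directory
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return named vector of file paths.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, name) {
    p <- file.path(dir, name)
    if (!is.null(d) && NROW(d)) data.table::fwrite(d, p, sep = "\t")
    p
  }
  paths <- c(
    clusters = w(clusters_as_table(result$clusters), "clusters.tsv"),
    credible_sets = w(result$credible_sets, "credible_sets.tsv"),
    coloc = w(result$coloc, "coloc.tsv"),
    novelty = w(result$novelty, "novelty.tsv"),
    effects = w(result$effects, "effects.tsv"),
    tss = w(result$tss_distances, "tss_distances.tsv"),
    config = file.path(dir, "config.json"))
  jsonlite::write_json(unclass(result$config), paths["config"],
                       auto_unbox = TRUE, digits = NA)
  paths
}
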