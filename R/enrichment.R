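# Structural/functional cluster annotations, covariate-adjusted
# logistic-regression enrichments, and PIP-weighted variant annotations.

gene_span <- function(model) {
  c(min(model$transcripts[, "start"]), max(model$transcripts[, "end"]))
}

pair_shares_promoter <- function(a, b, window = 1000) {
  any(abs(outer(a$tss, b$tss, "-")) <= window)
}

pair_overlaps <- function(a, b) {
  sa <- gene_span(a); sb <- gene_span(b)
  sa[1] <= sb[2] && sb[1] <= sa[2]
}

#' Annotate a gene cluster with structural/functional labels
#'
#' Assigns the nine boolean labels used for cluster enrichment, each
#' defined over pairs of member genes (categories are not mutually
#' exclusive):
#' 1. `bidirectional_promoter` - some pair has 5' ends (any annotated
#'    transcript TSS) within 1,000 bp on opposite strands;
#' 2. `same_strand_promoter` - same proximity rule, same strand;
#' 3. `overlap_opposite` - some pair overlaps on opposite strands and
#'    does not share a promoter;
#' 4. `overlap_same` - overlapping, same strand, no shared promoter;
#' 5. `shared_enhancer` - some pair shares a genic/intergenic enhancer
#'    element with score > 0.1 (ABC-style links);
#' 6. `paralogs` - some pair is listed as paralogs;
#' 7. `shared_go_bp` - some pair shares a GO biological-process term;
#' 8. `cross_ctcf` - a CTCF peak lies within the cluster span (outer
#'    transcript edges);
#' 9. `cross_tad` - a TAD boundary lies within the cluster span.
#'
#' Missing resources leave the affected labels `NA` (missing), not 0.
#'
#' @param cluster a `gene_cluster`.
#' @param genes named list of [gene_model()] covering the cluster.
#' @param resources list with optional elements: `enhancers`
#'   (data.frame `gene`, `element`, `score`, `class`), `paralogs`
#'   (`gene_a`, `gene_b`), `go` (`gene`, `term`), `ctcf` (`chrom`,
#'   `start`, `end`), `tad` (`chrom`, `start`, `end`).
#' @param promoter_window bp window for shared promoters, default 1000.
#' @return object of class `cluster_annotation`: `cluster_id`,
#'   `is_null`, `labels` (named 0/1/NA), `n_genes`, `log_length`.
#' @export
annotate_cluster <- function(cluster, genes, resources = list(),
                             promoter_window = 1000) {
  models <- genes[cluster$gene_ids]
  if (any(vapply(models, is.null, TRUE)))
    stop("missing gene model(s) for cluster ", cluster$cluster_id)
  n <- length(models)
  pairs <- utils::combn(n, 2)
  lab <- c(bidirectional_promoter = 0, same_strand_promoter = 0,
           overlap_opposite = 0, overlap_same = 0,
           shared_enhancer = NA, paralogs = NA, shared_go_bp = NA,
           cross_ctcf = NA, cross_tad = NA)
  for (k in seq_len(ncol(pairs))) {
    a <- models[[pairs[1, k]]]; b <- models[[pairs[2, k]]]
    shares <- pair_shares_promoter(a, b, promoter_window)
    opp <- a$strand != b$strand
    if (shares && opp) lab["bidirectional_promoter"] <- 1
    if (shares && !opp) lab["same_strand_promoter"] <- 1
    if (!shares && pair_overlaps(a, b)) {
      if (opp) lab["overlap_opposite"] <- 1 else lab["overlap_same"] <- 1
    }
  }
  ids <- vapply(models, `[[`, "", "gene_id")
  if (!is.null(resources$enhancers)) {
    enh <- resources$enhancers
    enh <- enh[enh$class %in% c("genic", "intergenic") &
                 enh$score > 0.1, , drop = FALSE]
    lab["shared_enhancer"] <- 0
    for (k in seq_len(ncol(pairs))) {
      ea <- enh$element[enh$gene == ids[pairs[1, k]]]
      eb <- enh$element[enh$gene == ids[pairs[2, k]]]
      if (length(intersect(ea, eb))) {
        lab["shared_enhancer"] <- 1
        break
      }
    }
  }
  if (!is.null(resources$paralogs)) {
    pp <- resources$paralogs
    keys <- c(paste(pp$gene_a, pp$gene_b), paste(pp$gene_b, pp$gene_a))
    lab["paralogs"] <-
      as.numeric(any(paste(ids[pairs[1, ]], ids[pairs[2, ]]) %in% keys))
  }
  if (!is.null(resources$go)) {
    go <- resources$go
    lab["shared_go_bp"] <- 0
    for (k in seq_len(ncol(pairs))) {
      ta <- go$term[go$gene == ids[pairs[1, k]]]
      tb <- go$term[go$gene == ids[pairs[2, k]]]
      if (length(intersect(ta, tb))) {
        lab["shared_go_bp"] <- 1
        break
      }
    }
  }
  spans <- vapply(models, gene_span, c(0, 0))
  span <- c(min(spans[1, ]), max(spans[2, ]))
  chrom <- models[[1]]$chrom
  contains <- function(iv) {
    iv <- iv[iv$chrom == chrom, , drop = FALSE]
    as.numeric(any(iv$start >= span[1] & iv$end <= span[2]))
  }
  if (!is.null(resources$ctcf)) lab["cross_ctcf"] <- contains(resources$ctcf)
  if (!is.null(resources$tad)) lab["cross_tad"] <- contains(resources$tad)
  structure(list(cluster_id = cluster$cluster_id,
                 is_null = isTRUE(cluster$is_null), labels = lab,
                 n_genes = n,
                 log_length = log(span[2] - span[1] + 1)),
            class = "cluster_annotation")
}

#' Covariate-adjusted cluster enrichment for one annotation category
#'
#' Logistic regression of correlated-vs-null status on the annotation
#' label, adjusting for gene count and log cluster length:
#' `is_correlated ~ label + n_genes + log_length`. Reports the
#' label odds ratio with a Wald 95% CI. The computation is skipped when
#' any expected cell of the label x real/null 2x2 contingency table
#' (marginal-product expectation) is below 5. Constant covariates are
#' dropped, so a covariate-free instance reduces exactly to the 2x2
#' contingency odds ratio.
#'
#' @param annotations list of [annotate_cluster()] results for real and
#'   null clusters together.
#' @param category one of the nine label names.
#' @return object of class `enrichment_result`: `category`,
#'   `odds_ratio`, `ci95_low`, `ci95_high`, `p`, `skipped`, `reason`.
#'   Quasi-separation leaves the estimate flagged with an unbounded CI.
#' @export
logistic_enrichment <- function(annotations, category) {
  lab <- vapply(annotations, function(a) a$labels[[category]], 0)
  is_null <- vapply(annotations, `[[`, TRUE, "is_null")
  keep <- !is.na(lab)
  lab <- lab[keep]; is_null <- is_null[keep]
  y <- as.numeric(!is_null)
  if (length(unique(y)) < 2)
    stop("need both real and null clusters")
  out <- function(or = NA, lo = NA, hi = NA, p = NA, skipped = FALSE,
                  reason = NA_character_) {
    structure(list(category = category, odds_ratio = or,
                   ci95_low = lo, ci95_high = hi, p = p,
                   skipped = skipped, reason = reason),
              class = "enrichment_result")
  }
  tab <- table(factor(lab, levels = c(0, 1)),
               factor(y, levels = c(0, 1)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    return(out(skipped = TRUE,
               reason = sprintf("expected cell %.2f < 5", min(expected))))
  ng <- vapply(annotations, `[[`, 0, "n_genes")[keep]
  ll <- vapply(annotations, `[[`, 0, "log_length")[keep]
  df <- data.frame(y = y, label = lab, n_genes = ng, log_length = ll)
  covs <- c("n_genes", "log_length")
  covs <- covs[vapply(covs, function(v) sd(df[[v]]) > 0, TRUE)]
  form <- stats::reformulate(c("label", covs), response = "y")
  fit <- suppressWarnings(glm(form, data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  beta <- sm["label", "Estimate"]
  se <- sm["label", "Std. Error"]
  p <- sm["label", "Pr(>|z|)"]
  separated <- !fit$converged || se > 100
  out(or = exp(beta),
      lo = if (separated) 0 else exp(beta - 1.96 * se),
      hi = if (separated) Inf else exp(beta + 1.96 * se),
      p = p, skipped = FALSE,
      reason = if (separated) "separation: CI unbounded" else NA_character_)
}

#' PIP-weighted annotation probability of a credible set
#'
#' For each annotation, the PIP-weighted share of member variants
#' carrying it: `sum_i PIP_i * 1[variant i annotated]`, normalized by
#' `sum_i PIP_i` (default) so the result lies in `[0, 1]` even for 95%
#' sets; set `normalize = FALSE` for the raw weighted sum.
#'
#' @param cs a `credible_set`.
#' @param variant_annotations data.frame/matrix of 0/1 indicators with
#'   variant ids as rownames and one column per annotation.
#' @param normalize divide by the total PIP, default TRUE.
#' @return named numeric vector, one probability per annotation.
#' @export
pip_weighted_annotation <- function(cs, variant_annotations,
                                    normalize = TRUE) {
  stopifnot(inherits(cs, "credible_set"))
  miss <- setdiff(cs$variant_ids, rownames(variant_annotations))
  if (length(miss))
    stop("missing annotation row(s) for: ", paste(miss, collapse = ", "))
  A <- as.matrix(variant_annotations)[cs$variant_ids, , drop = FALSE]
  w <- cs$pips
  res <- drop(crossprod(A, w))
  if (normalize) res <- res / sum(w)
  res
}
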