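# Credible-set-level effect summaries and strand-aware QTL-to-TSS
# distances.

#' PIP-weighted log2 allelic fold change of a credible set on a gene
#'
#' `sum_i PIP_i * log2(aFC_iA) / sum_i PIP_i` over the credible set's
#' member variants, where aFC_iA is variant i's nominal aFC for gene A.
#' For a credible set mapped on a PC phenotype, the PIPs come from the
#' pcQTL fine-mapping and the aFCs from the nominal scans of the member
#' gene.
#'
#' @param cs a `credible_set`.
#' @param afc named numeric vector of per-variant log2 aFC for the gene
#'   (names are variant ids; must cover every member).
#' @return scalar PIP-weighted log2 aFC.
#' @export
pip_weighted_afc <- function(cs, afc) {
  stopifnot(inherits(cs, "credible_set"))
  if (!all(cs$variant_ids %in% names(afc)))
    stop("missing nominal aFC for credible-set variant(s): ",
         paste(setdiff(cs$variant_ids, names(afc)), collapse = ", "))
  w <- cs$pips
  if (sum(w) <= 0) stop("credible set has zero total PIP weight")
  sum(w * afc[cs$variant_ids]) / sum(w)
}

#' Dispersion of a credible set's per-gene effects
#'
#' Summarizes how concentrated or distributed a credible set's effects
#' are across its cluster: the maximum of |log2 aFC| over genes and the
#' coefficient of variation (sample sd / mean) of the absolute values.
#' A CV of 0 means perfectly equal effects; larger values mean the
#' effect is concentrated on fewer genes.
#'
#' @param afc_by_gene numeric vector of per-gene log2 aFC (length >= 2).
#' @return list: `max_abs`, `cv` (NA with a `cv_missing` flag when all
#'   effects are zero).
#' @export
effect_dispersion <- function(afc_by_gene) {
  if (length(afc_by_gene) < 2)
    stop("effect dispersion needs >= 2 genes")
  a <- abs(afc_by_gene)
  if (all(a == 0))
    return(list(max_abs = 0, cv = NA_real_, cv_missing = TRUE))
  list(max_abs = max(a), cv = sd(a) / mean(a), cv_missing = FALSE)
}

#' Strand-aware distance from group lead variants to gene TSSs
#'
#' For every (lead variant, transcript) pair the signed distance is
#' `variant - TSS` on the + strand and `TSS - variant` on the - strand
#' (so upstream variants are negative on either strand). The reported
#' distance is the signed value of the minimum-absolute pair, over all
#' cluster genes and, separately, over the group's eGenes.
#'
#' @param lead_pos integer vector of lead-variant positions (one per
#'   credible set in the group).
#' @param genes list of [gene_model()] for the cluster.
#' @param egene_ids gene ids with a significant eQTL credible set in
#'   the group (may be empty).
#' @param near_bp proximity threshold in bp, default 250.
#' @return list: `dist_closest_gene`, `dist_closest_egene` (NA when no
#'   eGenes), `near_tss_gene`, `near_tss_egene` (|distance| < near_bp).
#' @export
tss_distance <- function(lead_pos, genes, egene_ids = character(0),
                         near_bp = 250) {
  stopifnot(length(lead_pos) >= 1, length(genes) >= 1)
  signed_min <- function(models) {
    best <- NA_real_
    for (g in models) {
      s <- if (g$strand == "+") 1 else -1
      for (tss in g$tss) {
        d <- s * (lead_pos - tss)
        cand <- d[which.min(abs(d))]
        if (is.na(best) || abs(cand) < abs(best)) best <- cand
      }
    }
    best
  }
  d_gene <- signed_min(genes)
  ids <- vapply(genes, `[[`, "", "gene_id")
  eg <- genes[ids %in% egene_ids]
  d_egene <- if (length(eg)) signed_min(eg) else NA_real_
  list(dist_closest_gene = d_gene,
       dist_closest_egene = d_egene,
       near_tss_gene = is.finite(d_gene) && abs(d_gene) < near_bp,
       near_tss_egene = !is.na(d_egene) && abs(d_egene) < near_bp)
}
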