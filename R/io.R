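# Readers/writers for the standard formats the pipeline touches.
# Coordinate conventions: BED on disk is 0-based half-open; VCF positions
# are 1-based; every internal position in this package is 1-based.

#' Construct an expression matrix with genomic anchors
#'
#' Container for normalized (and optionally residualized) expression:
#' a genes x samples real matrix plus a per-gene genomic anchor. Genes
#' are stored sorted by (chrom, start); positions are 1-based.
#'
#' @param values numeric matrix, genes x samples, with rownames (gene
#'   ids) and colnames (sample ids).
#' @param chrom,start,end per-gene anchor vectors (start/end 1-based
#'   inclusive).
#' @return An object of class `expr_matrix` with elements `values`,
#'   `gene_ids`, `sample_ids`, `anchors` (data.frame).
#' @export
expression_matrix <- function(values, chrom, start, end) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (length(chrom) != nrow(values) || length(start) != nrow(values))
    stop("anchor length does not match gene count")
  ord <- order(chrom, start)
  values <- values[ord, , drop = FALSE]
  structure(list(
    values = values,
    gene_ids = rownames(values),
    sample_ids = colnames(values),
    anchors = data.frame(gene_id = rownames(values),
                         chrom = chrom[ord],
                         start = as.integer(start[ord]),
                         end = as.integer(end[ord]),
                         stringsAsFactors = FALSE)
  ), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples on", length(unique(x$anchors$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read a phenotype BED file (GTEx eQTL dialect)
#'
#' Tab-separated with a header; the first four columns are
#' chrom/start/end/phenotype_id and the remaining columns are samples.
#' On-disk starts are 0-based half-open and converted to 1-based.
#'
#' @param path file path (plain text or gzip).
#' @return An [expression_matrix()] sorted by (chrom, start).
#' @export
read_phenotype_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 5)
    stop("phenotype BED needs >= 5 columns (chrom/start/end/id + samples)")
  ids <- as.character(dt[[4]])
  if (anyDuplicated(ids))
    stop("duplicate phenotype_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sample_cols <- seq(5L, ncol(dt))
  for (j in sample_cols) {
    v <- dt[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric expression value at row ", bad[1],
             " (phenotype ", ids[bad[1]], "), column ", names(dt)[j])
      dt[[j]] <- num
    }
  }
  vals <- as.matrix(dt[, sample_cols, drop = FALSE])
  rownames(vals) <- ids
  expression_matrix(vals, chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]) + 1L,
                    end = as.integer(dt[[3]]))
}

#' Write a phenotype BED file
#'
#' Inverse of [read_phenotype_bed()]; internal 1-based starts are
#' written back as 0-based BED starts.
#'
#' @param x an `expr_matrix` (or `cluster_pcs` scores via
#'   [pcs_as_phenotypes()]).
#' @param path output path.
#' @export
write_phenotype_bed <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- data.frame(`#chr` = x$anchors$chrom,
                    start = x$anchors$start - 1L,
                    end = x$anchors$end,
                    phenotype_id = x$gene_ids,
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(x$values, check.names = FALSE))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Canonical variant id
#'
#' One builder used everywhere: `chrom_pos_ref_alt_build`.
#'
#' @param chrom,pos,ref,alt vectors describing biallelic SNVs.
#' @param build genome build tag, default `"b38"`.
#' @return character vector of ids.
#' @export
variant_id <- function(chrom, pos, ref, alt, build = "b38") {
  paste(chrom, as.integer(pos), ref, alt, build, sep = "_")
}

#' Construct a genotype dosage matrix
#'
#' @param dosages numeric matrix, variants x samples, values in `[0, 2]`
#'   (alt-allele dosage), rownames variant ids.
#' @param chrom,pos per-variant chromosome and 1-based position.
#' @param ref,alt alleles (optional, kept for writing).
#' @return object of class `genotype_matrix` with `dosages`, `chrom`,
#'   `pos`, `maf` (minor-allele frequency computed from dosages).
#' @export
genotype_matrix <- function(dosages, chrom, pos, ref = NULL, alt = NULL) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)))
  af <- rowMeans(dosages) / 2
  structure(list(
    dosages = dosages,
    variant_ids = rownames(dosages),
    chrom = chrom,
    pos = as.integer(pos),
    ref = ref,
    alt = alt,
    maf = pmin(af, 1 - af)
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "variants x",
      ncol(x$dosages), "samples\n")
  invisible(x)
}

#' Read biallelic SNP genotypes from a VCF as dosages
#'
#' Keeps biallelic SNVs only; dosage is the alt-allele count from the
#' GT field. Missing genotypes are mean-imputed per variant; variants
#' with more than `max_missing` missing calls, or with minor-allele
#' frequency below `maf_floor` (inclusive floor: MAF equal to the floor
#' is retained), are dropped.
#'
#' @param path VCF 4.x file.
#' @param region optional `list(chrom=, start=, end=)`, 1-based
#'   inclusive.
#' @param maf_floor minimum MAF, default 0.05.
#' @param max_missing maximum fraction of missing genotypes, default 0.1.
#' @return a [genotype_matrix()]; zero retained variants give an empty
#'   matrix, not an error.
#' @export
read_genotypes <- function(path, region = NULL, maf_floor = 0.05,
                           max_missing = 0.1) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  keep <- n_alt == 1 & nchar(ref) == 1 & nchar(alt) == 1 &
    alt %in% c("A", "C", "G", "T")
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  if (!is.null(region)) {
    keep <- keep & chrom == region$chrom & pos >= region$start &
      pos <= region$end
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("malformed VCF: no GT field in ", path)
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  ref <- ref[keep]; alt <- alt[keep]
  empty <- function() {
    m <- matrix(numeric(0), nrow = 0, ncol = ncol(gt),
                dimnames = list(character(0), colnames(gt)))
    structure(list(dosages = m, variant_ids = character(0),
                   chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   maf = numeric(0)), class = "genotype_matrix")
  }
  if (nrow(gt) == 0) return(empty())
  dos <- gt_to_dosage(gt)
  miss_frac <- rowMeans(is.na(dos))
  dos <- dos[miss_frac <= max_missing, , drop = FALSE]
  chrom <- chrom[miss_frac <= max_missing]
  pos <- pos[miss_frac <= max_missing]
  ref <- ref[miss_frac <= max_missing]; alt <- alt[miss_frac <= max_missing]
  if (nrow(dos) == 0) return(empty())
  for (i in which(rowSums(is.na(dos)) > 0)) {
    v <- dos[i, ]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    dos[i, ] <- v
  }
  af <- rowMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  pass <- maf >= maf_floor
  dos <- dos[pass, , drop = FALSE]
  if (nrow(dos) == 0) return(empty())
  chrom <- chrom[pass]; pos <- pos[pass]; ref <- ref[pass]; alt <- alt[pass]
  rownames(dos) <- variant_id(chrom, pos, ref, alt)
  genotype_matrix(dos, chrom, pos, ref, alt)
}

# GT strings ("0/1", "1|1", "./.") -> alt-allele dosage with NA for missing
gt_to_dosage <- function(gt) {
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
  dos <- matrix(lut[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  bad <- is.na(dos) & !(gt %in% c("./.", ".|.", "."))
  if (any(bad))
    stop("malformed VCF: unparseable GT value '", gt[bad][1], "'")
  dos
}

#' Write a genotype matrix as an uncompressed VCF
#'
#' Dosages are rendered as unphased GT calls (0/0, 0/1, 1/1); dosages
#' must be integral.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  ref <- if (is.null(g$ref)) rep("A", length(g$pos)) else g$ref
  alt <- if (is.null(g$alt)) rep("G", length(g$pos)) else g$alt
  samples <- colnames(g$dosages)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_along(g$pos), function(i) {
    d <- round(g$dosages[i, ])
    paste(c(g$chrom[i], g$pos[i], g$variant_ids[i], ref[i], alt[i], ".",
            "PASS", ".", "GT", gt_code[d + 1]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a transcript-level gene table into gene models
#'
#' One row per transcript: gene_id, chrom, strand, transcript_start,
#' transcript_end. The TSS of a transcript is its start on the + strand
#' and its end on the - strand.
#'
#' @param path TSV path.
#' @return named list of `gene_model` objects (fields `gene_id`,
#'   `chrom`, `strand`, `transcripts` 2-column matrix, `tss` vector).
#' @export
read_gene_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("gene_id", "chrom", "strand", "transcript_start",
            "transcript_end")
  if (!all(need %in% names(dt)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (!all(dt$strand %in% c("+", "-")))
    stop("strand must be '+' or '-', got: ",
         paste(unique(setdiff(dt$strand, c("+", "-"))), collapse = ", "))
  models <- lapply(split(dt, dt$gene_id), function(d) {
    gene_model(d$gene_id[1], d$chrom[1], d$strand[1],
               cbind(start = d$transcript_start, end = d$transcript_end))
  })
  models[unique(dt$gene_id)]
}

#' Construct a gene model
#'
#' @param gene_id,chrom,strand scalars; `strand` in `+`/`-`.
#' @param transcripts 2-column matrix of (start, end), 1-based.
#' @return object of class `gene_model`; `tss` is derived per transcript
#'   by the strand rule (start on +, end on -).
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), nrow(transcripts) >= 1)
  transcripts <- cbind(start = as.integer(transcripts[, 1]),
                       end = as.integer(transcripts[, 2]))
  tss <- if (strand == "+") transcripts[, "start"] else transcripts[, "end"]
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts, tss = as.integer(tss)),
            class = "gene_model")
}

#' Read GWAS summary statistics
#'
#' Accepts either `beta` and `se` columns or `z` and `n`. With only z
#' and n, effects are reconstructed on the standardized scale as
#' `se = 1/sqrt(n)`, `beta = z * se`; only z and n enter the Wakefield
#' approximate Bayes factors downstream, so the scaling is immaterial
#' for colocalization.
#'
#' @param path TSV with at least `variant_id` plus (`beta`, `se`) or
#'   (`z`, `n`).
#' @param cohort_variant_ids optional character vector; variants absent
#'   from it are dropped (count reported via `message()` and in the
#'   `n_dropped` attribute).
#' @param trait_id trait label, default taken from a `trait_id` column
#'   or the file name.
#' @return object of class `gwas_stats` with `trait_id`, `variant_ids`,
#'   `beta`, `se`, `n`.
#' @export
read_gwas_stats <- function(path, cohort_variant_ids = NULL,
                            trait_id = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (!"variant_id" %in% names(dt))
    stop("GWAS table needs a variant_id column")
  if (is.null(trait_id)) {
    trait_id <- if ("trait_id" %in% names(dt)) as.character(dt$trait_id[1])
                else sub("\\.[^.]*$", "", basename(path))
  }
  if (all(c("beta", "se") %in% names(dt))) {
    beta <- dt$beta; se <- dt$se
    n <- if ("n" %in% names(dt)) dt$n else rep(NA_real_, nrow(dt))
  } else if (all(c("z", "n") %in% names(dt))) {
    se <- 1 / sqrt(dt$n)
    beta <- dt$z * se
    n <- dt$n
  } else {
    stop("GWAS table needs (beta, se) or (z, n) columns")
  }
  if (any(se <= 0)) stop("GWAS se must be > 0")
  gw <- gwas_stats(trait_id, dt$variant_id, beta, se, n)
  n_dropped <- 0L
  if (!is.null(cohort_variant_ids)) {
    keep <- gw$variant_ids %in% cohort_variant_ids
    n_dropped <- sum(!keep)
    if (n_dropped > 0)
      message("read_gwas_stats: dropped ", n_dropped,
              " variants absent from the cohort")
    gw <- gwas_stats(trait_id, gw$variant_ids[keep], gw$beta[keep],
                     gw$se[keep], gw$n[keep])
  }
  attr(gw, "n_dropped") <- n_dropped
  gw
}

#' Construct GWAS summary statistics
#' @param trait_id trait label.
#' @param variant_ids,beta,se,n equal-length vectors; `se > 0`.
#' @return object of class `gwas_stats`.
#' @export
gwas_stats <- function(trait_id, variant_ids, beta, se,
                       n = rep(NA_real_, length(beta))) {
  stopifnot(length(beta) == length(variant_ids),
            length(se) == length(variant_ids))
  if (any(se <= 0)) stop("GWAS se must be > 0")
  structure(list(trait_id = trait_id,
                 variant_ids = as.character(variant_ids),
                 beta = as.numeric(beta), se = as.numeric(se),
                 n = as.numeric(n)),
            class = "gwas_stats")
}

#' Write GWAS summary statistics as TSV
#' @param gw a `gwas_stats` object.
#' @param path output path.
#' @export
write_gwas_stats <- function(gw, path) {
  data.table::fwrite(
    data.frame(variant_id = gw$variant_ids, beta = gw$beta, se = gw$se,
               n = gw$n, trait_id = gw$trait_id),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a covariate table (covariates x samples)
#'
#' GTEx covariate convention: first column is the covariate id, the
#' remaining columns are samples.
#'
#' @param path TSV path.
#' @return numeric matrix covariates x samples with dimnames.
#' @export
read_covariates <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a covariate table
#' @param cov numeric matrix covariates x samples.
#' @param path output path.
#' @export
write_covariates <- function(cov, path) {
  out <- data.frame(ID = rownames(cov), check.names = FALSE)
  out <- cbind(out, as.data.frame(cov, check.names = FALSE))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Deterministic, order-stable sample intersection
#'
#' Returns the samples present in every input set, in the order of the
#' first set.
#'
#' @param ... two or more character vectors of sample ids.
#' @return character vector.
#' @export
intersect_samples <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 2)
  keep <- sets[[1]]
  for (s in sets[-1]) keep <- keep[keep %in% s]
  keep
}
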