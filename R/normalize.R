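#' @noRd
counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
    return(counts)
  }
  if (!"gene_id" %in% names(counts)) {
    abort("Count tables need a `gene_id` column (or pass a named matrix).")
  }
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  as_tibble(m, rownames = "gene_id")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of the ratio of each sample's count to the gene's
#' geometric mean across samples. This is the standard library-size
#' normalization for NB-based RNA-seq testing.
#'
#' @param counts Wide count table (`gene_id` column plus one column per
#'   sample) or a numeric matrix with genes as rows.
#' @return A tibble with columns `sample` and `size_factor`.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 100), s2 = c(20, 200))
#' size_factors_median_ratios(counts)
#' @export
size_factors_median_ratios <- function(counts) {
  m <- counts_to_matrix(counts)
  if (any(m < 0)) abort("Counts must be nonnegative.")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste(
      "No gene has positive counts in every sample;",
      "relax filtering before computing size factors."
    ))
  }
  lg <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lg) # log geometric mean per gene
  sf <- apply(lg, 2, function(x) exp(median(x - ref)))
  tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Drop genes with low counts in every genotype
#'
#' A gene is excluded when its per-genotype median raw count falls below the
#' threshold in **all** genotypes (`drop_if = "all_below"`, the default,
#' which preserves genes silenced in a single parent). `drop_if =
#' "any_below"` switches to the strict rule that removes a gene as soon as
#' one genotype median is below the threshold.
#'
#' @param counts Wide count table (see [size_factors_median_ratios()]).
#' @param metadata Tibble with `sample` and `genotype` columns covering every
#'   count column.
#' @param threshold Minimum per-genotype median (default 5). The boundary is
#'   kept: a median exactly equal to the threshold is not "smaller than" it.
#' @param drop_if Exclusion rule, `"all_below"` or `"any_below"`.
#' @return The filtered count table (same columns, fewer rows).
#' @export
filter_low_expression <- function(counts, metadata, threshold = 5,
                                  drop_if = c("all_below", "any_below")) {
  drop_if <- match.arg(drop_if)
  m <- counts_to_matrix(counts)
  missing <- setdiff(colnames(m), metadata$sample)
  if (length(missing) > 0) {
    abort(paste0("Samples without metadata: ", paste(missing, collapse = ", ")))
  }
  geno <- metadata$genotype[match(colnames(m), metadata$sample)]
  med <- vapply(
    split(seq_len(ncol(m)), geno),
    function(j) apply(m[, j, drop = FALSE], 1, median),
    numeric(nrow(m))
  )
  below <- med < threshold
  keep <- if (drop_if == "all_below") rowSums(below) < ncol(below) else rowSums(below) == 0
  counts[keep, , drop = FALSE]
}

normalize_counts <- function(counts, size_factors) {
  m <- counts_to_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  if (anyNA(sf)) abort("Every sample needs a size factor.")
  matrix_to_counts(sweep(m, 2, sf, "/"))
}

#' Parental differential expression by NB GLM LRT
#'
#' Tests each gene for expression divergence between the wild (W) and
#' cultivated (C) parents: NB2 GLM with genotype as the tested factor,
#' median-of-ratios size factors as offsets, LRT of `~ genotype` against
#' `~ 1`, and BH adjustment across genes. The reported `log2fc` is wild over
#' cultivated, computed from size-factor-normalized means with a pseudocount.
#'
#' @param counts Wide count table containing the parental samples.
#' @param metadata Tibble with `sample` and `genotype` (values `W` and `C`;
#'   other genotypes are ignored).
#' @param alpha_fdr FDR threshold recorded with the result (default 0.05).
#' @param dispersion Optional fixed dispersion (estimated per gene if `NULL`).
#' @param pseudocount Added to normalized means before the log-ratio (0.5).
#' @return A tibble of class `de_results`: `gene_id`, `baseMean`, `log2fc`,
#'   `lrt_stat`, `df`, `pvalue`, `qvalue`.
#' @export
parental_de <- function(counts, metadata, alpha_fdr = 0.05,
                        dispersion = NULL, pseudocount = 0.5) {
  m <- counts_to_matrix(counts)
  meta <- metadata[match(colnames(m), metadata$sample), ]
  keep <- meta$genotype %in% c("W", "C")
  m <- m[, keep, drop = FALSE]
  meta <- meta[keep, ]
  if (sum(meta$genotype == "W") < 2 || sum(meta$genotype == "C") < 2) {
    abort("Need at least two replicates of each parent (W and C).")
  }
  sf_tbl <- size_factors_median_ratios(m)
  sf <- sf_tbl$size_factor
  X_full <- model.matrix(~genotype, data = transform(meta, genotype = factor(genotype, c("C", "W"))))
  X_red <- X_full[, 1, drop = FALSE]
  res <- nb_lrt_matrix(m, X_full, X_red, sf, dispersion = dispersion)
  norm <- sweep(m, 2, sf, "/")
  mean_w <- rowMeans(norm[, meta$genotype == "W", drop = FALSE])
  mean_c <- rowMeans(norm[, meta$genotype == "C", drop = FALSE])
  out <- tibble(
    gene_id = rownames(m),
    baseMean = rowMeans(norm),
    log2fc = log2((mean_w + pseudocount) / (mean_c + pseudocount)),
    lrt_stat = res$lrt_stat,
    df = res$df,
    pvalue = res$pvalue,
    qvalue = bh_adjust(res$pvalue)
  )
  class(out) <- c("de_results", class(out))
  attr(out, "alpha_fdr") <- alpha_fdr
  out
}

#' Per-genotype medians of normalized expression
#'
#' Collapses a normalized count table to one median value per gene and
#' genotype, the substrate for dominance-of-expression estimates.
#'
#' @inheritParams parental_de
#' @param size_factors Optional precomputed size factors (tibble with
#'   `sample`, `size_factor`); computed by median-of-ratios when `NULL`.
#' @return Tibble with `gene_id` and one column per genotype.
#' @export
genotype_medians <- function(counts, metadata, size_factors = NULL) {
  m <- counts_to_matrix(counts)
  size_factors <- size_factors %||% size_factors_median_ratios(m)
  norm <- counts_to_matrix(normalize_counts(m, size_factors))
  geno <- metadata$genotype[match(colnames(norm), metadata$sample)]
  med <- vapply(
    split(seq_len(ncol(norm)), geno),
    function(j) apply(norm[, j, drop = FALSE], 1, median),
    numeric(nrow(norm))
  )
  as_tibble(med, rownames = "gene_id")
}
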