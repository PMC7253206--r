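INHERITANCE_MODES <- c(
  "additive", "C-partially-recessive", "C-partially-dominant",
  "transgressive", "undefined"
)

#' Additive effect, dominance deviation and degree of dominance
#'
#' From per-genotype medians of a trait or of normalized expression:
#' additive effect `a = (W - C) / 2`, dominance deviation
#' `d = F1 - (W + C) / 2`, and degree of dominance `k = d / a`. `k` is
#' undefined (NA) when `|a|` is below `epsilon`. On this scale `k = 0` is
#' additivity, `k = 1` means the cultivated value is completely recessive
#' (hybrid at the wild value), `k = -1` completely dominant, and `|k| >
#' 1.25` transgressive.
#'
#' Vectorized; inputs are recycled to a common length.
#'
#' @param W,C,F1 Median values for the wild parent, cultivated parent and
#'   hybrid.
#' @param id Optional identifiers (gene or trait names).
#' @param epsilon Threshold below which `|a|` is treated as zero (1e-9).
#' @return Tibble of class `dominance_records`: `id`, `W`, `C`, `F1`, `a`,
#'   `d`, `k`, `mode`.
#' @examples
#' degree_of_dominance(W = 10, C = 6, F1 = 8) # additive midparent hybrid
#' @export
degree_of_dominance <- function(W, C, F1, id = NULL, epsilon = 1e-9) {
  n <- max(length(W), length(C), length(F1))
  W <- rep_len(W, n)
  C <- rep_len(C, n)
  F1 <- rep_len(F1, n)
  a <- (W - C) / 2
  d <- F1 - (W + C) / 2
  k <- if_else(abs(a) < epsilon, NA_real_, d / a)
  out <- tibble(
    id = id %||% paste0("item_", seq_len(n)),
    W = W, C = C, F1 = F1, a = a, d = d, k = k,
    mode = classify_inheritance(k)
  )
  class(out) <- c("dominance_records", class(out))
  out
}

#' Bin a degree of dominance into an inheritance mode
#'
#' Additive inside the open interval (-0.25, 0.25); cultivated-parent
#' partially recessive for k in \[0.25, 1.25\]; partially dominant for k in
#' \[-1.25, -0.25\]; transgressive strictly beyond |1.25|; undefined for
#' missing k. Boundaries at |k| = 0.25 and 1.25 belong to the
#' partial-dominance bins.
#'
#' @param k Numeric vector of dominance degrees (NA allowed).
#' @return Factor of inheritance modes.
#' @export
classify_inheritance <- function(k) {
  mode <- dplyr::case_when(
    is.na(k) ~ "undefined",
    abs(k) > 1.25 ~ "transgressive",
    k >= 0.25 ~ "C-partially-recessive",
    k <= -0.25 ~ "C-partially-dominant",
    TRUE ~ "additive"
  )
  factor(mode, levels = INHERITANCE_MODES)
}

#' Dominance of expression for differentially expressed genes
#'
#' Computes dominance records from per-genotype expression medians for the
#' genes called significant in the parental DE test only (mode of gene
#' action is interpretable only where the parents actually differ). Genes
#' with undefined `k` stay in the table (flagged `undefined`) but are
#' excluded from distribution summaries.
#'
#' @param de A `de_results` tibble from [parental_de()].
#' @param medians Tibble of per-genotype medians with columns `gene_id`,
#'   `W`, `C` and `F1` (or `CxW`), e.g. from [genotype_medians()].
#' @param alpha FDR threshold; defaults to the one recorded in `de`.
#' @return `dominance_records` tibble with `log2fc` and `qvalue` carried
#'   over from the DE results.
#' @export
dominance_for_degs <- function(de, medians, alpha = NULL) {
  alpha <- alpha %||% attr(de, "alpha_fdr") %||% 0.05
  if ("CxW" %in% names(medians) && !"F1" %in% names(medians)) {
    medians <- rename(medians, F1 = "CxW")
  }
  degs <- de %>% filter(.data$qvalue < alpha)
  joined <- degs %>% inner_join(medians, by = "gene_id")
  out <- degree_of_dominance(joined$W, joined$C, joined$F1, id = joined$gene_id)
  out$log2fc <- joined$log2fc
  out$qvalue <- joined$qvalue
  n_undef <- sum(is.na(out$k))
  if (n_undef > 0) {
    inform(sprintf("%d DEG(s) with undefined k (|a| ~ 0).", n_undef))
  }
  out
}

#' @rdname dominance_for_degs
#' @param x A `dominance_records` tibble.
#' @param ... Unused.
#' @details `glance()` summarises the k distribution over genes with
#'   defined k, including the Spearman correlation between `|k|` and the
#'   magnitude of differential expression (negative when near-additive genes
#'   show the larger parental differences).
#' @method glance dominance_records
#' @export
glance.dominance_records <- function(x, ...) {
  ok <- !is.na(x$k)
  rho <- if ("log2fc" %in% names(x) && sum(ok) > 2) {
    suppressWarnings(cor(abs(x$k[ok]), abs(x$log2fc[ok]), method = "spearman"))
  } else {
    NA_real_
  }
  tibble(
    n = nrow(x),
    n_defined = sum(ok),
    n_undefined = sum(!ok),
    median_k = median(x$k[ok]),
    prop_additive = mean(x$mode[ok] == "additive"),
    prop_transgressive = mean(x$mode[ok] == "transgressive"),
    spearman_absk_absfc = rho
  )
}

#' Histogram table of the k distribution
#'
#' @param x `dominance_records` tibble.
#' @param breaks Bin breaks over k (default steps of 0.25 across the
#'   nontransgressive range plus open tails).
#' @return Tibble `bin`, `n`.
#' @export
k_distribution <- function(x, breaks = c(-Inf, seq(-2, 2, by = 0.25), Inf)) {
  k <- x$k[!is.na(x$k)]
  b <- cut(k, breaks = breaks, include.lowest = TRUE)
  tibble(bin = levels(b), n = as.integer(table(b)))
}
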