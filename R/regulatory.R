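# Internal layout of an allele profile as a genes x observations matrix.
# Column blocks: F0 W reps | F0 C reps | F1 W reps | F1 C reps. The two F1
# allele columns of a replicate come from one sequencing library and share
# its size factor; each F0 column is its own parental library.
profile_matrices <- function(profile) {
  need <- c("gene_id", "replicate", "generation", "allele", "count")
  if (!all(need %in% names(profile))) {
    abort(paste0("Allele profile needs columns: ", paste(need, collapse = ", ")))
  }
  reps <- sort(unique(profile$replicate))
  nr <- length(reps)
  wide <- profile %>%
    mutate(obs = paste(.data$generation, .data$allele, .data$replicate, sep = ".")) %>%
    select("gene_id", "obs", "count") %>%
    tidyr::pivot_wider(names_from = "obs", values_from = "count")
  cols <- c(
    paste("F0", "W", reps, sep = "."), paste("F0", "C", reps, sep = "."),
    paste("F1", "W", reps, sep = "."), paste("F1", "C", reps, sep = ".")
  )
  if (!all(cols %in% names(wide))) {
    abort("Profile must contain both alleles for F0 and F1 in every replicate.")
  }
  m <- as.matrix(wide[cols])
  rownames(m) <- wide$gene_id
  if (anyNA(m)) abort("Allele profile has missing (gene, replicate, allele) cells.")
  obs <- tibble(
    generation = rep(c("F0", "F0", "F1", "F1"), each = nr),
    allele = rep(c("W", "C", "W", "C"), each = nr),
    replicate = rep(reps, 4),
    library = c(
      paste0("F0_W_", reps), paste0("F0_C_", reps),
      paste0("F1_", reps), paste0("F1_", reps)
    )
  )
  list(m = m, obs = obs, reps = reps)
}

#' Library size factors for an allele count profile
#'
#' Builds per-library totals (each parental replicate is one library; an F1
#' replicate's total is the sum of its two allele counts) and computes
#' median-of-ratios factors across libraries.
#'
#' @param profile Long allele profile tibble.
#' @return Tibble `library`, `size_factor`.
#' @export
ase_size_factors <- function(profile) {
  pm <- profile_matrices(profile)
  libs <- unique(pm$obs$library)
  totals <- matrix(0, nrow = nrow(pm$m), ncol = length(libs),
    dimnames = list(rownames(pm$m), libs)
  )
  for (l in libs) {
    totals[, l] <- rowSums(pm$m[, pm$obs$library == l, drop = FALSE])
  }
  sf <- size_factors_median_ratios(totals)
  tibble(library = sf$sample, size_factor = sf$size_factor)
}

regulatory_designs <- function(obs) {
  grp <- factor(
    paste(obs$generation, obs$allele, sep = "_"),
    levels = c("F0_W", "F0_C", "F1_W", "F1_C")
  )
  X_sat <- model.matrix(~ 0 + grp)
  colnames(X_sat) <- levels(grp)
  allele_w <- as.integer(obs$allele == "W")
  gen_f1 <- as.integer(obs$generation == "F1")
  list(
    # saturated group-mean design (equivalent to ~ allele * generation)
    X_sat = X_sat,
    # reduced designs for the three 1-df contrasts
    X_parental = cbind(F0 = X_sat[, 1] + X_sat[, 2], X_sat[, 3:4, drop = FALSE]),
    X_cis = cbind(X_sat[, 1:2, drop = FALSE], F1 = X_sat[, 3] + X_sat[, 4]),
    X_additive = cbind(`(Intercept)` = 1, alleleW = allele_w, genF1 = gen_f1)
  )
}

# Core per-gene engine for the three regulatory LRTs. The gene's NB2
# dispersion is estimated once, by Cox-Reid adjusted profile likelihood
# under the saturated four-group (generation x allele) model on all
# observations, and held fixed for every fit; the parental, cis and trans
# statistics are likelihood-ratio drops of one equality constraint each
# (F0 W = F0 C; F1 W = F1 C; no allele-by-generation interaction). Because
# the unconstrained groups cancel from the likelihood difference, the
# parental and cis statistics equal their single-generation versions with
# the same dispersion. P-values come from the chi-squared reference, the
# standard construction for GLM count LRTs with a gene-wise CR-estimated
# dispersion; with 8 residual degrees of freedom behind the dispersion this
# is adequately calibrated (unlike the 6-observation parental-only design,
# where parental_de() uses a quasi-likelihood F reference instead).
ase_lrt_engine <- function(m, obs, sf_obs, dispersion = NULL) {
  d <- regulatory_designs(obs)
  offset <- log(sf_obs)
  ngene <- nrow(m)
  out <- matrix(NA_real_, ngene, 7,
    dimnames = list(NULL, c(
      "p_parental", "p_cis", "p_trans",
      "stat_parental", "stat_cis", "stat_trans", "dispersion"
    ))
  )
  for (i in seq_len(ngene)) {
    y <- m[i, ]
    if (all(y == 0)) {
      out[i, ] <- c(1, 1, 1, 0, 0, 0, dispersion %||% 0)
      next
    }
    phi <- dispersion %||% estimate_dispersion(y, d$X_sat, offset)
    fit_sat <- nb_irls(y, d$X_sat, offset, phi)
    one_p <- function(X_red) {
      stat <- max(0, 2 * (fit_sat$ll - nb_irls(y, X_red, offset, phi)$ll))
      c(stat, max(pchisq(stat, df = 1, lower.tail = FALSE), 1e-300))
    }
    pp <- one_p(d$X_parental)
    pc <- one_p(d$X_cis)
    pt <- one_p(d$X_additive)
    out[i, ] <- c(pp[2], pc[2], pt[2], pp[1], pc[1], pt[1], phi)
  }
  as_tibble(out)
}

#' Run the parental, cis and trans LRTs and classify every gene
#'
#' For each gene in an allele-resolved count profile this fits NB2 GLMs and
#' runs three likelihood-ratio tests: parental divergence (allele effect
#' within the F0 libraries: full `~ allele` vs reduced `~ 1`), allelic
#' imbalance in the hybrid (the cis test, same contrast within F1, where the
#' two alleles share each replicate's library size factor), and the
#' allele-by-generation interaction (the trans test: full
#' `~ allele + generation + allele:generation` vs the additive reduced
#' model). P-values are BH-adjusted within each test family, effect
#' components are computed from normalized mean counts with a pseudocount,
#' and genes are sorted into the seven regulatory categories via
#' [classify_regulation()].
#'
#' @param profile Long allele profile tibble (`gene_id`, `replicate`,
#'   `generation`, `allele`, `count`).
#' @param alpha FDR threshold for category calls (default 0.05).
#' @param dispersion Optional fixed NB2 dispersion; estimated per gene and
#'   test by Cox-Reid adjusted profile likelihood when `NULL`.
#' @param pseudocount Added to each normalized mean before log-ratios (0.5).
#' @return Tibble of class `regulatory_calls` with per-gene p/q-values for
#'   the three tests, `parental_log2fc`, `hybrid_log2fc`, `cis_component`
#'   (= hybrid log2fc), `trans_component` (= parental - hybrid),
#'   `cis_percentage` and `category`.
#' @export
regulatory_divergence <- function(profile, alpha = 0.05, dispersion = NULL,
                                  pseudocount = 0.5) {
  pm <- profile_matrices(profile)
  sf_tbl <- ase_size_factors(profile)
  sf_obs <- sf_tbl$size_factor[match(pm$obs$library, sf_tbl$library)]
  tests <- ase_lrt_engine(pm$m, pm$obs, sf_obs, dispersion)

  norm <- sweep(pm$m, 2, sf_obs, "/")
  gmean <- function(gen, allele) {
    rowMeans(norm[, pm$obs$generation == gen & pm$obs$allele == allele, drop = FALSE])
  }
  parental_log2fc <- log2((gmean("F0", "W") + pseudocount) / (gmean("F0", "C") + pseudocount))
  hybrid_log2fc <- log2((gmean("F1", "W") + pseudocount) / (gmean("F1", "C") + pseudocount))

  calls <- tibble(
    gene_id = rownames(pm$m),
    p_parental = tests$p_parental,
    q_parental = bh_adjust(tests$p_parental),
    p_cis = tests$p_cis,
    q_cis = bh_adjust(tests$p_cis),
    p_trans = tests$p_trans,
    q_trans = bh_adjust(tests$p_trans),
    parental_log2fc = parental_log2fc,
    hybrid_log2fc = hybrid_log2fc,
    cis_component = hybrid_log2fc,
    trans_component = parental_log2fc - hybrid_log2fc
  )
  classify_regulation(calls, alpha = alpha)
}

#' Per-gene cis (allelic imbalance) test
#'
#' LRT for the allele effect among the F1 hybrid's allele-resolved counts
#' (full `~ allele`, reduced `~ 1`), with both alleles of a replicate
#' sharing that library's size factor. The fold change is the wild allele
#' over the cultivated allele.
#'
#' @inheritParams regulatory_divergence
#' @param gene Gene identifier present in the profile.
#' @return One-row tibble `gene_id`, `pvalue`, `log2fc`.
#' @export
cis_test <- function(profile, gene, dispersion = NULL, pseudocount = 0.5) {
  one_gene_test(profile, gene, "cis", dispersion, pseudocount)
}

#' Per-gene trans test (allele-by-generation interaction)
#'
#' LRT of `~ allele + generation + allele:generation` against
#' `~ allele + generation` over the F0 and F1 allele-resolved counts.
#' Significance means the parental allelic ratio differs from the hybrid
#' allelic ratio, i.e. trans-regulatory divergence.
#'
#' @inheritParams cis_test
#' @return One-row tibble `gene_id`, `pvalue`.
#' @export
trans_test <- function(profile, gene, dispersion = NULL) {
  one_gene_test(profile, gene, "trans", dispersion, 0.5)
}

one_gene_test <- function(profile, gene, which, dispersion, pseudocount) {
  if (!gene %in% profile$gene_id) abort(paste0("Gene not in profile: ", gene))
  if (!all(c("F0", "F1") %in% profile$generation)) {
    abort("Profile must contain both F0 and F1 generations.")
  }
  pm <- profile_matrices(profile)
  if (length(pm$reps) < 2) abort("Tests need at least 2 replicates.")
  # library factors need information across genes; a single-gene profile is
  # taken at face value (unit factors)
  sf_tbl <- if (nrow(pm$m) >= 2) {
    ase_size_factors(profile)
  } else {
    tibble(library = unique(pm$obs$library), size_factor = 1)
  }
  sf_obs <- sf_tbl$size_factor[match(pm$obs$library, sf_tbl$library)]
  res <- ase_lrt_engine(pm$m[gene, , drop = FALSE], pm$obs, sf_obs, dispersion)
  if (which == "cis") {
    f1 <- pm$obs$generation == "F1"
    norm <- pm$m[gene, ] / sf_obs
    w <- mean(norm[f1 & pm$obs$allele == "W"])
    cc <- mean(norm[f1 & pm$obs$allele == "C"])
    tibble(
      gene_id = gene, pvalue = res$p_cis,
      log2fc = log2((w + pseudocount) / (cc + pseudocount))
    )
  } else {
    tibble(gene_id = gene, pvalue = res$p_trans)
  }
}

#' Sort genes into the seven categories of regulatory divergence
#'
#' Given BH-adjusted significance of the parental test (P), the cis test (H)
#' and the trans test (T) at level `alpha`, genes are assigned:
#' `conserved` when nothing is significant; `cis_only` (P, H, not T);
#' `trans_only` (P, T, not H); `cis_plus_trans` (all three, cis and trans
#' components with the same sign); `cis_by_trans` (all three, opposing
#' signs); `compensatory` (H and T but not P — allelic imbalance and an
#' interaction that cancel in the parents); every remaining significance
#' pattern is `ambiguous`. A zero effect component when both H and T are
#' significant has no direction, so such genes fall to `ambiguous` (with a
#' message).
#'
#' @param calls Tibble with `q_parental`, `q_cis`, `q_trans`,
#'   `cis_component`, `trans_component`.
#' @param alpha FDR threshold (default 0.05).
#' @return `calls` with `category` and `cis_percentage`
#'   (100 |cis| / (|cis| + |trans|), `NA` when both components are 0) added,
#'   classed `regulatory_calls`.
#' @export
classify_regulation <- function(calls, alpha = 0.05) {
  P <- calls$q_parental < alpha
  H <- calls$q_cis < alpha
  T_ <- calls$q_trans < alpha
  s_cis <- sign(calls$cis_component)
  s_trans <- sign(calls$trans_component)
  same <- s_cis == s_trans & s_cis != 0
  opposite <- s_cis == -s_trans & s_cis != 0
  category <- dplyr::case_when(
    !P & !H & !T_ ~ "conserved",
    P & H & !T_ ~ "cis_only",
    P & !H & T_ ~ "trans_only",
    P & H & T_ & same ~ "cis_plus_trans",
    P & H & T_ & opposite ~ "cis_by_trans",
    !P & H & T_ ~ "compensatory",
    TRUE ~ "ambiguous"
  )
  n_tie <- sum(P & H & T_ & !same & !opposite)
  if (n_tie > 0) {
    inform(sprintf(
      "%d gene(s) with a zero effect component under joint cis/trans significance; classified ambiguous.",
      n_tie
    ))
  }
  denom <- abs(calls$cis_component) + abs(calls$trans_component)
  out <- calls %>%
    mutate(
      category = factor(category, levels = REGULATORY_CATEGORIES),
      cis_percentage = if_else(denom > 0, 100 * abs(.data$cis_component) / denom, NA_real_)
    )
  if (!inherits(out, "regulatory_calls")) {
    class(out) <- c("regulatory_calls", class(out))
  }
  attr(out, "alpha") <- alpha
  out
}

#' @rdname classify_regulation
#' @param x A `regulatory_calls` tibble.
#' @param ... Unused.
#' @method glance regulatory_calls
#' @export
glance.regulatory_calls <- function(x, ...) {
  counts <- table(x$category)
  divergent <- c("cis_only", "trans_only", "cis_plus_trans", "cis_by_trans", "compensatory")
  tibble(
    n_genes = nrow(x),
    n_divergent = sum(counts[divergent]),
    n_conserved = counts[["conserved"]],
    n_ambiguous = counts[["ambiguous"]],
    n_cis_only = counts[["cis_only"]],
    n_trans_only = counts[["trans_only"]],
    n_cis_plus_trans = counts[["cis_plus_trans"]],
    n_cis_by_trans = counts[["cis_by_trans"]],
    n_compensatory = counts[["compensatory"]],
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' Mean cis percentage within bins of parental effect size
#'
#' Bins genes by the absolute parental log2 fold change and averages the cis
#' percentage (100 |cis| / (|cis| + |trans|)) within each bin, over genes
#' with a defined denominator. Empty bins are reported with `NA`, not zero.
#'
#' @param calls `regulatory_calls` tibble.
#' @param bin_edges Increasing numeric bin edges over |parental log2fc|.
#' @return Tibble `bin`, `lower`, `upper`, `n`, `mean_cis_percentage`.
#' @export
cis_percentage_bins <- function(calls, bin_edges = c(0, 1, 2, 3, 4, Inf)) {
  if (nrow(calls) == 0) abort("`calls` is empty.")
  if (is.unsorted(bin_edges, strictly = TRUE)) abort("bin_edges must be strictly increasing.")
  eff <- abs(calls$parental_log2fc)
  bin <- cut(eff, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  ok <- !is.na(calls$cis_percentage)
  tibble(
    bin = levels(bin),
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1]
  ) %>%
    left_join(
      tibble(bin = as.character(bin[ok]), cis_percentage = calls$cis_percentage[ok]) %>%
        group_by(.data$bin) %>%
        summarise(n = n(), mean_cis_percentage = mean(.data$cis_percentage), .groups = "drop"),
      by = "bin"
    ) %>%
    mutate(n = if_else(is.na(.data$n), 0L, as.integer(.data$n)))
}

#' One-sample proportion z-test with continuity correction
#'
#' Two-sided z statistic for an observed proportion against `p0`:
#' `z = (|x - n p0| - 0.5) / sqrt(n p0 (1 - p0))`, signed by the direction
#' of the deviation.
#'
#' @param n_success,n_total Observed successes and trials.
#' @param p0 Null proportion in (0, 1) (default 0.5).
#' @return One-row tibble `z`, `p_value`.
#' @examples
#' proportion_test(960, 1062) # trans- vs cis-significant transcripts
#' @export
proportion_test <- function(n_success, n_total, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie strictly in (0, 1).")
  if (n_total <= 0 || n_success < 0 || n_success > n_total) {
    abort("Need 0 <= n_success <= n_total with n_total > 0.")
  }
  dev <- n_success - n_total * p0
  direction <- if (dev >= 0) 1 else -1
  z <- direction * (abs(dev) - 0.5) / sqrt(n_total * p0 * (1 - p0))
  tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Exact binomial test of up/down symmetry
#'
#' Two-sided exact binomial test of equal numbers of up- and downregulated
#' genes (null p = 0.5), summing tail probabilities no larger than the
#' observed outcome's probability.
#'
#' @param n_up,n_down Nonnegative counts.
#' @return One-row tibble `n_up`, `n_down`, `p_value`.
#' @examples
#' binomial_symmetry_test(4123, 4398)
#' @export
binomial_symmetry_test <- function(n_up, n_down) {
  if (n_up < 0 || n_down < 0) abort("Counts must be nonnegative.")
  p <- if (n_up + n_down == 0) 1 else binom.test(n_up, n_up + n_down, p = 0.5)$p.value
  tibble(n_up = n_up, n_down = n_down, p_value = p)
}

#' Compare absolute effect-size distributions (rank-sum test)
#'
#' Wilcoxon rank-sum comparison of absolute trans effects against absolute
#' cis (allelic-imbalance) effects: exact enumeration when both groups have
#' at most 10 observations and no ties, normal approximation with tie
#' correction otherwise.
#'
#' @param trans_effects,ase_effects Numeric vectors of absolute log2
#'   effects.
#' @return One-row tibble `median_trans`, `median_ase`, `p_value`, `method`.
#' @export
effect_size_comparison <- function(trans_effects, ase_effects) {
  if (length(trans_effects) == 0 || length(ase_effects) == 0) {
    abort("Both effect-size groups must be nonempty.")
  }
  exact <- length(trans_effects) <= 10 && length(ase_effects) <= 10 &&
    !any(duplicated(c(trans_effects, ase_effects)))
  wt <- suppressWarnings(
    wilcox.test(trans_effects, ase_effects, exact = exact, correct = !exact)
  )
  tibble(
    median_trans = median(trans_effects),
    median_ase = median(ase_effects),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal approximation"
  )
}
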