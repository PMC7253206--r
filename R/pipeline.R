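#' Configuration for an end-to-end pipeline run
#'
#' Gathers the thresholds the analysis uses (all overridable): FDR level
#' 0.05, low-expression threshold 5 (per-genotype median), SNP filters
#' QUAL > 30 and DP > 20, dominance bin edges 0.25 and 1.25, and the depth
#' reciprocity mode. Input is either a simulation request (`simulation`, a
#' [simulation_config()]) or real tables (`profile`, or SNP `records` plus
#' parental `counts`/`metadata`).
#'
#' @param simulation Optional [simulation_config()] to generate the input.
#' @param profile Optional allele profile tibble (alternative to
#'   `simulation`).
#' @param records,counts,metadata Optional SNP pair records plus total count
#'   table and sample metadata, for the extraction route.
#' @param profile_path Optional TSV path to read the profile from.
#' @param alpha_fdr,low_expression_threshold,qual_min,dp_min,k_bin_edges,
#'   depth_mode,depth_tol,pseudocount Analysis parameters.
#' @param out_json Optional path for the JSON report.
#' @param seed Integer seed recorded in the report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, profile = NULL,
                            records = NULL, counts = NULL, metadata = NULL,
                            profile_path = NULL,
                            alpha_fdr = 0.05, low_expression_threshold = 5,
                            qual_min = 30, dp_min = 20,
                            k_bin_edges = c(0.25, 1.25),
                            depth_mode = c("exact", "tolerance"), depth_tol = 0.1,
                            pseudocount = 0.5,
                            out_json = NULL, seed = 1) {
  depth_mode <- match.arg(depth_mode)
  if (alpha_fdr <= 0 || alpha_fdr >= 1) abort("alpha_fdr must lie in (0, 1).")
  if (low_expression_threshold < 0 || qual_min <= 0 || dp_min <= 0) {
    abort("Thresholds must be positive.")
  }
  if (is.unsorted(k_bin_edges, strictly = TRUE) || any(k_bin_edges <= 0)) {
    abort("k_bin_edges must be increasing positive values.")
  }
  structure(
    list(
      simulation = simulation, profile = profile, records = records,
      counts = counts, metadata = metadata, profile_path = profile_path,
      alpha_fdr = alpha_fdr,
      low_expression_threshold = low_expression_threshold,
      qual_min = qual_min, dp_min = dp_min, k_bin_edges = k_bin_edges,
      depth_mode = depth_mode, depth_tol = depth_tol,
      pseudocount = pseudocount, out_json = out_json, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full cis/trans divergence pipeline
#'
#' Executes extraction (when SNP records are supplied) or simulation, then
#' low-expression filtering, median-of-ratios normalization, parental DE,
#' the cis and trans LRTs, the seven-category classification, dominance of
#' expression for the DEGs, cis-percentage bins, and the three global
#' statistics (binomial up/down symmetry, the trans-vs-cis proportion
#' z-test, and the Wilcoxon comparison of absolute effect sizes). Every
#' filter's in/out counts are recorded in the report's `log`. The run is
#' deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @return A `cistrans_report` list; written as JSON when `out_json` is
#'   set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  truth <- NULL

  if (!is.null(config$profile_path)) {
    if (!file.exists(config$profile_path)) {
      abort(paste0("Input profile not found: ", config$profile_path))
    }
    profile <- read_allele_profile(config$profile_path)
  } else if (!is.null(config$records)) {
    if (is.null(config$counts) || is.null(config$metadata)) {
      abort("The extraction route needs `counts` and `metadata` alongside `records`.")
    }
    n0 <- nrow(config$records)
    filtered <- reciprocity_filter(config$records,
      qual_min = config$qual_min, dp_min = config$dp_min
    )
    log$reciprocity_filter <- c(records_in = n0, records_out = nrow(filtered))
    ok <- depth_reciprocity_check(filtered,
      mode = config$depth_mode, tol = config$depth_tol
    )
    log$depth_reciprocity <- c(records_in = nrow(filtered), records_out = sum(ok))
    f1 <- aggregate_to_genes(filtered[ok, , drop = FALSE])
    profile <- combine_ase_profile(f1, config$counts, config$metadata)
  } else if (!is.null(config$profile)) {
    profile <- config$profile
  } else if (!is.null(config$simulation)) {
    sim <- simulate_ase_counts(config$simulation)
    profile <- sim$profile
    truth <- sim$truth
  } else {
    abort("No input: supply `simulation`, `profile`, `profile_path`, or `records`.")
  }

  totals <- ase_totals(profile)
  n_before <- nrow(totals$counts)
  kept <- filter_low_expression(totals$counts, totals$metadata,
    threshold = config$low_expression_threshold
  )
  log$low_expression_filter <- c(genes_in = n_before, genes_out = nrow(kept))
  profile <- profile %>% filter(.data$gene_id %in% kept$gene_id)

  de <- parental_de(kept, totals$metadata, alpha_fdr = config$alpha_fdr,
    pseudocount = config$pseudocount
  )
  calls <- regulatory_divergence(profile,
    alpha = config$alpha_fdr, pseudocount = config$pseudocount
  )

  medians <- genotype_medians(kept, totals$metadata)
  dom <- dominance_for_degs(de, medians)
  dom_glance <- glance(dom)

  degs <- de %>% filter(.data$qvalue < config$alpha_fdr)
  symmetry <- binomial_symmetry_test(
    n_up = sum(degs$log2fc < 0), # upregulated in C = lower W/C fold change
    n_down = sum(degs$log2fc > 0)
  )
  divergent <- calls %>%
    filter(!.data$category %in% c("conserved", "ambiguous"))
  n_trans_sig <- sum(divergent$q_trans < config$alpha_fdr)
  n_cis_sig <- sum(divergent$q_cis < config$alpha_fdr)
  prop <- if (n_trans_sig + n_cis_sig > 0) {
    proportion_test(n_trans_sig, n_trans_sig + n_cis_sig)
  } else {
    tibble(z = NA_real_, p_value = NA_real_)
  }
  trans_eff <- abs(divergent$trans_component[divergent$q_trans < config$alpha_fdr])
  cis_eff <- abs(divergent$cis_component[divergent$q_cis < config$alpha_fdr])
  effects <- if (length(trans_eff) > 0 && length(cis_eff) > 0) {
    effect_size_comparison(trans_eff, cis_eff)
  } else {
    tibble(median_trans = NA_real_, median_ase = NA_real_, p_value = NA_real_, method = NA_character_)
  }

  report <- list(
    seed = config$seed,
    parameters = list(
      alpha_fdr = config$alpha_fdr,
      low_expression_threshold = config$low_expression_threshold,
      qual_min = config$qual_min, dp_min = config$dp_min,
      k_bin_edges = config$k_bin_edges, depth_mode = config$depth_mode
    ),
    log = log,
    n_genes_tested = nrow(calls),
    n_degs = nrow(degs),
    category_counts = as.list(table(calls$category)),
    k_summary = as.list(dom_glance),
    cis_percentage_bins = cis_percentage_bins(calls),
    statistics = list(
      binomial_symmetry = as.list(symmetry),
      proportion_z = as.list(prop),
      effect_sizes = as.list(effects)
    )
  )
  report$results <- list(calls = calls, de = de, dominance = dom, truth = truth)
  class(report) <- "cistrans_report"
  if (!is.null(config$out_json)) write_report(report, config$out_json)
  report
}

#' Write a pipeline report as JSON
#'
#' Serializes the scalar summaries of a report (not the per-gene tables) to
#' a JSON file; byte-identical across runs with the same seed.
#'
#' @param report A `cistrans_report`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- report[c(
    "seed", "parameters", "log", "n_genes_tested", "n_degs",
    "category_counts", "k_summary", "statistics"
  )]
  out$cis_percentage_bins <- report$cis_percentage_bins
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' @export
print.cistrans_report <- function(x, ...) {
  cat("cistrans pipeline report (seed", x$seed, ")\n")
  cat("Genes tested:", x$n_genes_tested, "| DEGs:", x$n_degs, "\n")
  cat("Categories:\n")
  print(unlist(x$category_counts))
  invisible(x)
}
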