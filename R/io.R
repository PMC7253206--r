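#' Write SNP pair records as minimal VCF 4.2 files
#'
#' One VCF per alignment view and replicate (files
#' `<prefix>_<view>view_<replicate>.vcf`), with QUAL, `DP` in INFO and a
#' single sample column carrying `GT:AD:DP`.
#'
#' @param records SNP pair tibble.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"snps"`).
#' @return Invisibly, a tibble of written paths with `view` and
#'   `replicate_id`.
#' @export
write_snp_vcfs <- function(records, dir, prefix = "snps") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  views <- c("C", "W")
  out <- list()
  for (v in views) {
    gt_col <- paste0("gt_", v, "view")
    for (r in unique(records$replicate_id)) {
      rec <- records[records$replicate_id == r, ]
      gt <- split_gt(rec[[gt_col]])
      ref <- rec[[paste0("ref_", v, "view")]]
      alt <- rec[[paste0("alt_", v, "view")]]
      gt_idx <- paste0(
        as.integer(gt[, 1] != ref), "/",
        as.integer(gt[, 2] != ref)
      )
      ad <- paste0(
        rec[[paste0("ad_ref_", v, "view")]], ",",
        rec[[paste0("ad_alt_", v, "view")]]
      )
      path <- file.path(dir, sprintf("%s_%sview_%s.vcf", prefix, v, r))
      header <- c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", r,
          sep = "\t"
        )
      )
      body <- paste(rec$chrom, rec$pos, ".", ref, alt,
        sprintf("%.2f", rec$qual), "PASS", paste0("DP=", rec$dp),
        "GT:AD:DP", paste0(gt_idx, ":", ad, ":", rec$dp),
        sep = "\t"
      )
      writeLines(c(header, body), path)
      out[[length(out) + 1]] <- tibble(view = v, replicate_id = r, path = path)
    }
  }
  invisible(bind_rows(out))
}

read_one_vcf <- function(path, view, replicate_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")[, 1]
  ad_raw <- vcfR::extract.gt(v, element = "AD")[, 1]
  ad <- stringr::str_split_fixed(ad_raw, stringr::fixed(","), 2)
  idx <- stringr::str_split_fixed(gt_raw, "[/|]", 2)
  pick <- function(i) ifelse(i == "0", fix$REF, fix$ALT)
  tb <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    replicate_id = replicate_id,
    qual = as.numeric(fix$QUAL),
    dp = as.integer(sub(".*DP=(\\d+).*", "\\1", fix$INFO))
  )
  tb[[paste0("ref_", view, "view")]] <- fix$REF
  tb[[paste0("alt_", view, "view")]] <- fix$ALT
  tb[[paste0("gt_", view, "view")]] <- paste0(pick(idx[, 1]), "/", pick(idx[, 2]))
  tb[[paste0("ad_ref_", view, "view")]] <- as.integer(ad[, 1])
  tb[[paste0("ad_alt_", view, "view")]] <- as.integer(ad[, 2])
  tb
}

#' Read paired pseudoreference VCFs into SNP pair records
#'
#' Reads per-replicate VCFs from the cultivated-parent and wild-parent
#' alignment views and joins them on chromosome, position and replicate.
#' Sites present in only one view get `NA` in the other view's columns (the
#' reciprocity filter excludes and reports them). If `intervals` is given,
#' gene assignment is applied via [assign_genes()].
#'
#' @param c_paths,w_paths Named character vectors of VCF paths (names =
#'   replicate ids) for the C view and W view.
#' @param intervals Optional gene interval tibble.
#' @return SNP pair tibble.
#' @export
read_snp_vcfs <- function(c_paths, w_paths, intervals = NULL) {
  stopifnot(length(c_paths) == length(w_paths))
  for (p in c(c_paths, w_paths)) {
    if (!file.exists(p)) abort(paste0("VCF not found: ", p))
  }
  reps <- names(c_paths) %||% paste0("rep", seq_along(c_paths))
  recs <- purrr::map2(seq_along(c_paths), reps, function(i, r) {
    cc <- read_one_vcf(c_paths[[i]], "C", r)
    ww <- read_one_vcf(w_paths[[i]], "W", r) %>% select(-"qual", -"dp")
    dplyr::full_join(cc, ww, by = c("chrom", "pos", "replicate_id"))
  }) %>% bind_rows()
  if (!is.null(intervals)) recs <- assign_genes(recs, intervals)
  recs
}

#' Read/write a long allele count profile as TSV
#'
#' @param profile Long allele profile tibble.
#' @param path TSV path.
#' @return `read_allele_profile()` returns the profile tibble;
#'   `write_allele_profile()` returns the path invisibly.
#' @export
write_allele_profile <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_allele_profile
#' @export
read_allele_profile <- function(path) {
  out <- readr::read_tsv(path, col_types = "cccci", progress = FALSE)
  class(out) <- c("allele_profile", class(out))
  out
}

#' Read a coexpression edge list and node annotations
#'
#' @param edges_path TSV with columns `node1`, `node2`, `mi`.
#' @param nodes_path Optional TSV with `node`, `is_tf` and optionally
#'   `log2fc`.
#' @return A coexpression network (see [coexpression_network()]).
#' @export
read_coexpression_network <- function(edges_path, nodes_path = NULL) {
  edges <- readr::read_tsv(edges_path, col_types = "ccd", progress = FALSE)
  nodes <- if (!is.null(nodes_path)) {
    readr::read_tsv(nodes_path, progress = FALSE, show_col_types = FALSE)
  }
  coexpression_network(edges, nodes)
}
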