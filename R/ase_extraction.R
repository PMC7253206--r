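split_gt <- function(gt) {
  stringr::str_split_fixed(gt, stringr::fixed("/"), 2)
}

#' Filter SNP pair records by quality, biallelism and genotype reciprocity
#'
#' Retains records that are (i) biallelic, (ii) heterozygous in both
#' pseudoreference views, (iii) reciprocal — the ordered genotype in the
#' wild-parent view is the reversal of the cultivated-parent view (e.g.
#' `A/G` vs `G/A`), (iv) strictly QUAL > `qual_min`, and (v) strictly
#' DP > `dp_min`. Records missing one alignment view are excluded with a
#' message, not an error. With `shared_positions_only`, only positions seen
#' in every replicate's record set are kept.
#'
#' The filter is idempotent: applying it to its own output changes nothing.
#'
#' @param records SNP pair tibble (see [simulate_snp_pairs()] for columns).
#' @param qual_min,dp_min Strict lower thresholds (defaults 30 and 20).
#' @param shared_positions_only Keep only positions present in all
#'   replicates (default FALSE).
#' @return The retained records.
#' @export
reciprocity_filter <- function(records, qual_min = 30, dp_min = 20,
                               shared_positions_only = FALSE) {
  gt_c <- split_gt(records$gt_Cview)
  gt_w <- split_gt(records$gt_Wview)
  missing_view <- is.na(records$gt_Cview) | is.na(records$gt_Wview) |
    gt_c[, 2] == "" | gt_w[, 2] == ""
  if (any(missing_view)) {
    inform(sprintf(
      "%d record(s) missing one alignment view; excluded.", sum(missing_view)
    ))
  }
  het_c <- gt_c[, 1] != gt_c[, 2]
  het_w <- gt_w[, 1] != gt_w[, 2]
  biallelic <- purrr::map2_lgl(
    paste(gt_c[, 1], gt_c[, 2]), paste(gt_w[, 1], gt_w[, 2]),
    function(a, b) {
      alleles <- unique(c(strsplit(a, " ")[[1]], strsplit(b, " ")[[1]]))
      length(setdiff(alleles, "")) == 2
    }
  )
  reciprocal <- gt_c[, 1] == gt_w[, 2] & gt_c[, 2] == gt_w[, 1]
  keep <- !missing_view & biallelic & het_c & het_w & reciprocal &
    records$qual > qual_min & records$dp > dp_min
  keep[is.na(keep)] <- FALSE
  out <- records[keep, , drop = FALSE]
  if (shared_positions_only) {
    n_rep <- length(unique(records$replicate_id))
    shared <- out %>%
      distinct(.data$chrom, .data$pos, .data$replicate_id) %>%
      dplyr::count(.data$chrom, .data$pos) %>%
      filter(.data$n == n_rep) %>%
      select("chrom", "pos")
    out <- out %>% dplyr::semi_join(shared, by = c("chrom", "pos"))
  }
  out
}

#' Check per-allele depth reciprocity between the two alignment views
#'
#' A record's depths are reciprocal when the (REF, ALT) depth pair in the
#' cultivated view equals the reversed pair in the wild view. `mode =
#' "exact"` requires equality; `mode = "tolerance"` accepts a maximum
#' relative deviation of `tol` on each mirrored pair (deviation measured
#' against the larger of the two depths), since alignments to two different
#' references rarely give identical depths.
#'
#' @param records SNP pair tibble.
#' @param mode `"exact"` (default) or `"tolerance"`.
#' @param tol Maximum relative deviation in tolerance mode (default 0.1).
#' @return Logical vector, one value per record.
#' @export
depth_reciprocity_check <- function(records, mode = c("exact", "tolerance"), tol = 0.1) {
  mode <- match.arg(mode)
  a1 <- records$ad_ref_Cview
  a2 <- records$ad_alt_Cview
  b1 <- records$ad_ref_Wview
  b2 <- records$ad_alt_Wview
  if (mode == "exact") {
    a1 == b2 & a2 == b1
  } else {
    rel <- function(x, y) {
      d <- abs(x - y) / pmax(x, y)
      d[x == 0 & y == 0] <- 0
      d
    }
    rel(a1, b2) <= tol & rel(a2, b1) <= tol
  }
}

#' Sum per-allele SNP depths into gene-level allele counts
#'
#' For each gene and replicate, the wild-allele count is the sum of the
#' wild-assigned depths over the gene's SNPs and likewise for the cultivated
#' allele. In the cultivated-parent pseudoreference view the reference
#' allele is the cultivated allele and the alternative allele is the wild
#' allele; depths are read from that view (identical to the wild view under
#' exact reciprocity). Genes with no retained SNPs are absent, not
#' zero-filled. Records without a gene assignment are dropped with a
#' message.
#'
#' @param records Filtered SNP pair tibble with a `gene_id` column.
#' @return Tibble `gene_id`, `replicate`, `allele` (`W`/`C`), `count` — the
#'   F1 half of an allele count profile.
#' @export
aggregate_to_genes <- function(records) {
  unmapped <- is.na(records$gene_id)
  if (any(unmapped)) {
    inform(sprintf("%d record(s) not mapped to a gene; dropped.", sum(unmapped)))
    records <- records[!unmapped, , drop = FALSE]
  }
  records %>%
    group_by(gene_id = .data$gene_id, replicate = .data$replicate_id) %>%
    summarise(
      W = sum(.data$ad_alt_Cview),
      C = sum(.data$ad_ref_Cview),
      .groups = "drop"
    ) %>%
    tidyr::pivot_longer(c("W", "C"), names_to = "allele", values_to = "count") %>%
    mutate(generation = "F1", count = as.integer(.data$count)) %>%
    select("gene_id", "replicate", "generation", "allele", "count") %>%
    arrange(.data$gene_id, .data$allele, .data$replicate)
}

#' Assign SNP records to gene models by genomic interval
#'
#' Positions are 1-based (VCF convention); intervals are 1-based inclusive
#' (`chrom`, `start`, `end`, `gene_id`), as produced by
#' [read_gene_intervals()]. A SNP covered by several overlapping gene models
#' is assigned to the widest covering interval, ties broken lexicographically
#' by `gene_id`.
#'
#' @param records SNP pair tibble (any `gene_id` column is replaced).
#' @param intervals Interval tibble.
#' @return `records` with `gene_id` filled (`NA` where no interval covers
#'   the position).
#' @export
assign_genes <- function(records, intervals) {
  hits <- records %>%
    mutate(.row = row_number()) %>%
    select(".row", "chrom", "pos") %>%
    inner_join(intervals,
      by = dplyr::join_by("chrom", "pos" >= "start", "pos" <= "end"),
      relationship = "many-to-many"
    ) %>%
    mutate(width = .data$end - .data$start + 1) %>%
    arrange(.data$.row, dplyr::desc(.data$width), .data$gene_id) %>%
    distinct(.data$.row, .keep_all = TRUE)
  records$gene_id <- hits$gene_id[match(seq_len(nrow(records)), hits$.row)]
  records
}

#' Read gene intervals from BED or GFF3
#'
#' BED input (0-based, half-open) is converted to 1-based inclusive
#' coordinates; the BED name column supplies `gene_id`. GFF3 is read via
#' rtracklayer and filtered to `type == "gene"` when present, using the
#' `ID`/`Name` attribute as `gene_id`.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"bed"` or `"gff3"`.
#' @return Tibble `chrom`, `start`, `end`, `gene_id` (1-based inclusive).
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    bed <- readr::read_tsv(path,
      col_names = c("chrom", "start", "end", "gene_id"),
      col_types = "ciic", comment = "#", progress = FALSE
    )
    bed %>% mutate(start = .data$start + 1L) # BED is 0-based half-open
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("Reading GFF3 requires the rtracklayer package.")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    md <- as.data.frame(gr)
    if ("type" %in% names(md) && any(md$type == "gene")) md <- md[md$type == "gene", ]
    ids <- md$ID %||% md$Name %||% paste0("gene_", seq_len(nrow(md)))
    tibble(
      chrom = as.character(md$seqnames),
      start = as.integer(md$start), end = as.integer(md$end),
      gene_id = as.character(ids)
    )
  }
}

#' Combine F1 allele counts with parental libraries into one profile
#'
#' Parental (F0) libraries are homozygous, so the W parent's replicates
#' provide the F0 wild-allele counts and the C parent's the cultivated-allele
#' counts; the F1 rows come from [aggregate_to_genes()]. Only genes present
#' in the F1 allele table are kept (genes without informative SNPs carry no
#' allele-specific signal).
#'
#' @param f1_allele_counts Output of [aggregate_to_genes()].
#' @param counts Wide total-count table including the parental samples.
#' @param metadata Sample metadata (`sample`, `genotype`, `replicate`).
#' @return Long `allele_profile` tibble.
#' @export
combine_ase_profile <- function(f1_allele_counts, counts, metadata) {
  m <- counts_to_matrix(counts)
  meta <- metadata %>% filter(.data$genotype %in% c("W", "C"), .data$sample %in% colnames(m))
  genes <- unique(f1_allele_counts$gene_id)
  f0 <- purrr::pmap(meta, function(sample, genotype, replicate, ...) {
    tibble(
      gene_id = genes,
      replicate = replicate,
      generation = "F0",
      allele = genotype,
      count = as.integer(m[match(genes, rownames(m)), sample])
    )
  }) %>% bind_rows()
  if (anyNA(f0$count)) abort("Some F1 genes are absent from the parental count table.")
  out <- bind_rows(f0, f1_allele_counts) %>%
    arrange(.data$gene_id, .data$generation, .data$allele, .data$replicate)
  class(out) <- c("allele_profile", class(out))
  out
}
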