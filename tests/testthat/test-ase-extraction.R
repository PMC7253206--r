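base_record <- function(...) {
  rec <- tibble::tibble(
    chrom = "chr01", pos = 1001L, gene_id = "g1", replicate_id = "rep1",
    ref_Cview = "A", alt_Cview = "G", gt_Cview = "A/G",
    ad_ref_Cview = 12L, ad_alt_Cview = 18L,
    ref_Wview = "G", alt_Wview = "A", gt_Wview = "G/A",
    ad_ref_Wview = 18L, ad_alt_Wview = 12L,
    qual = 50, dp = 30L, clean = TRUE
  )
  args <- list(...)
  for (nm in names(args)) rec[[nm]] <- args[[nm]]
  rec
}

test_that("reciprocity filter applies the printed rules strictly", {
  keep <- base_record() # A/G vs G/A, QUAL 50, DP 30
  not_recip <- base_record(gt_Wview = "A/G")
  qual_at_30 <- base_record(qual = 30) # strict: QUAL must exceed 30
  dp_at_20 <- base_record(dp = 20L)
  homozygous <- base_record(gt_Wview = "G/G")
  triallelic <- base_record(gt_Wview = "G/T", alt_Wview = "T")
  recs <- dplyr::bind_rows(keep, not_recip, qual_at_30, dp_at_20, homozygous, triallelic)
  out <- reciprocity_filter(recs)
  expect_equal(nrow(out), 1)
  expect_equal(out$qual, 50)
})

test_that("records missing one view are excluded with a message, not an error", {
  recs <- dplyr::bind_rows(base_record(), base_record(gt_Wview = NA_character_))
  expect_message(out <- reciprocity_filter(recs), "missing one alignment view")
  expect_equal(nrow(out), 1)
})

test_that("filter is idempotent and supports shared-positions mode", {
  recs <- simulate_snp_pairs(40, snps_per_gene = 2, seed = 4, contamination_rate = 0.3)
  once <- reciprocity_filter(recs)
  twice <- reciprocity_filter(once)
  expect_identical(once, twice)

  # a position absent from one replicate must vanish in shared mode
  drop_one <- recs[!(recs$replicate_id == "rep2" & recs$pos == recs$pos[1] &
    recs$chrom == recs$chrom[1]), ]
  shared <- reciprocity_filter(drop_one, shared_positions_only = TRUE)
  expect_false(any(shared$chrom == recs$chrom[1] & shared$pos == recs$pos[1]))
})

test_that("depth reciprocity distinguishes exact from tolerance mode", {
  exact_ok <- base_record(
    ad_ref_Cview = 12L, ad_alt_Cview = 7L,
    ad_ref_Wview = 7L, ad_alt_Wview = 12L
  )
  mirror_broken <- base_record(
    ad_ref_Cview = 12L, ad_alt_Cview = 7L,
    ad_ref_Wview = 12L, ad_alt_Wview = 7L
  )
  near <- base_record(
    ad_ref_Cview = 12L, ad_alt_Cview = 7L,
    ad_ref_Wview = 7L, ad_alt_Wview = 11L # 12 vs 11: rel dev 1/12 < 0.1
  )
  expect_true(depth_reciprocity_check(exact_ok))
  expect_false(depth_reciprocity_check(mirror_broken))
  expect_false(depth_reciprocity_check(near))
  expect_true(depth_reciprocity_check(near, mode = "tolerance", tol = 0.1))
})

test_that("gene aggregation sums per-allele depths and keeps absence semantics", {
  recs <- dplyr::bind_rows(
    base_record(pos = 1001L, ad_ref_Cview = 5L, ad_alt_Cview = 10L),
    base_record(pos = 1101L, ad_ref_Cview = 3L, ad_alt_Cview = 6L)
  )
  prof <- aggregate_to_genes(recs)
  expect_equal(prof$count[prof$allele == "W"], 16L) # alt in C view = wild allele
  expect_equal(prof$count[prof$allele == "C"], 8L)
  expect_false("g2" %in% prof$gene_id) # absent, not zero-filled

  # order invariance
  prof_rev <- aggregate_to_genes(recs[2:1, ])
  expect_equal(dplyr::arrange(prof, gene_id, allele), dplyr::arrange(prof_rev, gene_id, allele))

  expect_message(aggregate_to_genes(base_record(gene_id = NA_character_)), "not mapped")
})

test_that("clean simulator output survives the pipeline bit-exactly", {
  recs <- simulate_snp_pairs(25, snps_per_gene = 3, seed = 6, contamination_rate = 0)
  kept <- reciprocity_filter(recs)
  kept <- kept[depth_reciprocity_check(kept), ]
  prof <- aggregate_to_genes(kept)
  expect_equal(length(unique(prof$gene_id)), 25) # all genes recovered
  manual <- recs |>
    dplyr::group_by(gene_id, replicate_id) |>
    dplyr::summarise(W = sum(ad_alt_Cview), C = sum(ad_ref_Cview), .groups = "drop")
  got_w <- prof[prof$allele == "W", ]
  expect_equal(
    got_w$count[order(got_w$gene_id, got_w$replicate)],
    as.integer(manual$W[order(manual$gene_id, manual$replicate_id)])
  )
})

test_that("interval assignment picks widest covering gene, ties lexicographic", {
  ivs <- tibble::tibble(
    chrom = c("chr01", "chr01", "chr01"),
    start = c(900L, 950L, 950L),
    end = c(1100L, 1400L, 1400L),
    gene_id = c("short", "zlong", "along")
  )
  rec <- base_record(gene_id = NA_character_)
  out <- assign_genes(rec, ivs)
  expect_equal(out$gene_id, "along") # widest; lexicographic among equal widths
  miss <- assign_genes(base_record(pos = 99999L), ivs)
  expect_true(is.na(miss$gene_id))
})

test_that("VCF round trip preserves records", {
  dir <- withr::local_tempdir()
  recs <- simulate_snp_pairs(10, snps_per_gene = 2, seed = 3, n_replicates = 2)
  paths <- write_snp_vcfs(recs, dir)
  c_paths <- paths$path[paths$view == "C"]
  w_paths <- paths$path[paths$view == "W"]
  names(c_paths) <- paths$replicate_id[paths$view == "C"]
  names(w_paths) <- paths$replicate_id[paths$view == "W"]
  back <- read_snp_vcfs(c_paths, w_paths)
  key <- function(d) dplyr::arrange(d, chrom, pos, replicate_id)
  a <- key(recs)
  b <- key(back)
  expect_equal(nrow(b), nrow(a))
  for (col in c(
    "gt_Cview", "gt_Wview", "ad_ref_Cview", "ad_alt_Cview",
    "ad_ref_Wview", "ad_alt_Wview", "dp"
  )) {
    expect_equal(b[[col]], a[[col]], ignore_attr = TRUE)
  }
  expect_equal(b$qual, a$qual, tolerance = 0.01) # QUAL printed with 2 decimals
  expect_error(read_snp_vcfs("nope.vcf", w_paths[1]), "not found")
})

test_that("BED intervals convert to 1-based inclusive coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr01\t900\t1100\tgeneA", path)
  iv <- read_gene_intervals(path)
  expect_equal(iv$start, 901L)
  expect_equal(iv$end, 1100L)
  expect_equal(iv$gene_id, "geneA")
})
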