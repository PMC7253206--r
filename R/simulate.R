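#' Configuration for the allele-specific count simulator
#'
#' Bundles the generative parameters for [simulate_ase_counts()]. Counts are
#' NB2 distributed (variance = mu + phi * mu^2; `dispersion = 0` gives
#' Poisson counts). Genes are allocated to the six true regulatory classes
#' according to `category_mix`; each gene receives a signed cis effect `c`
#' and trans effect `t` (log2 units) from which allele means are derived:
#' the parental log2 fold change is `c + t` and the hybrid allelic log2
#' fold change is `c`.
#'
#' @param n_genes Number of genes to simulate.
#' @param baseline_log2_mean Log2 of the expected total count for an average
#'   gene (default 8, i.e. around 256 reads).
#' @param dispersion NB2 dispersion phi (>= 0; default 0.05, a typical
#'   biological-replicate value for bulk RNA-seq).
#' @param n_replicates Replicates per genotype (default 3, the usual layout for this design).
#' @param library_size_factors Optional positive per-library scale factors,
#'   ordered as W parent replicates, C parent replicates, F1 replicates
#'   (default all 1).
#' @param category_mix Named proportions over the six true categories
#'   `conserved`, `cis_only`, `trans_only`, `cis_plus_trans`,
#'   `cis_by_trans`, `compensatory`; must sum to 1.
#' @param cis_effect_log2,trans_effect_log2 Magnitudes (log2) of the cis and
#'   trans components for genes that carry them (default 2). Equal opposing
#'   magnitudes would cancel in the parents — which is the definition of
#'   `compensatory` — so `cis_by_trans` genes instead carry a half-magnitude
#'   cis component opposed by a full-magnitude trans component, mirroring
#'   the empirical asymmetry in interspecific ASE studies where trans
#'   effects are the larger ones.
#' @param trans_dominance Dominance of the hybrid trans environment in
#'   \[-1.25, 1.25\]; 0 (default) makes the hybrid trans milieu additive.
#' @param seed Integer master seed; per-gene substreams are derived from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 3000,
                              baseline_log2_mean = 8,
                              dispersion = 0.05,
                              n_replicates = 3,
                              library_size_factors = NULL,
                              category_mix = NULL,
                              cis_effect_log2 = 2,
                              trans_effect_log2 = 2,
                              trans_dominance = 0,
                              seed = 1) {
  category_mix <- category_mix %||%
    setNames(rep(1 / 6, 6), SIMULATED_CATEGORIES)
  if (is.null(names(category_mix)) ||
    !all(names(category_mix) %in% SIMULATED_CATEGORIES)) {
    abort(paste(
      "category_mix must be named with:",
      paste(SIMULATED_CATEGORIES, collapse = ", ")
    ))
  }
  if (abs(sum(category_mix) - 1) > 1e-9) {
    abort("category_mix must sum to 1 (within 1e-9).")
  }
  if (dispersion < 0) abort("dispersion must be nonnegative.")
  if (n_genes < 1 || n_replicates < 1) abort("n_genes and n_replicates must be positive.")
  if (abs(trans_dominance) > 1.25) abort("trans_dominance must lie in [-1.25, 1.25].")
  n_lib <- 3L * n_replicates
  library_size_factors <- library_size_factors %||% rep(1, n_lib)
  if (length(library_size_factors) != n_lib || any(library_size_factors <= 0)) {
    abort(sprintf("library_size_factors must be %d positive values.", n_lib))
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      baseline_log2_mean = baseline_log2_mean,
      dispersion = dispersion,
      n_replicates = as.integer(n_replicates),
      library_size_factors = library_size_factors,
      category_mix = category_mix[SIMULATED_CATEGORIES[SIMULATED_CATEGORIES %in% names(category_mix)]],
      cis_effect_log2 = cis_effect_log2,
      trans_effect_log2 = trans_effect_log2,
      trans_dominance = trans_dominance,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Largest-remainder allocation of n genes over the mix proportions.
allocate_categories <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

draw_counts <- function(mu, phi) {
  mu <- pmax(mu, 1e-8)
  if (phi < 1e-12) rpois(length(mu), mu) else rnbinom(length(mu), size = 1 / phi, mu = mu)
}

#' Simulate allele-specific counts with known regulatory ground truth
#'
#' Generates an allele-resolved count profile for two parents (F0) and their
#' F1 hybrid under the generative model in [simulation_config()]: with cis
#' effect `c` and trans effect `t`, the F0 wild and cultivated allele means
#' are `s * 2^(m0 + (c+t)/2)` and `s * 2^(m0 - (c+t)/2)`; the F1 allele
#' means are `s * 2^(m0 - 1 + c/2 + trans_dominance * t/4)` and
#' `s * 2^(m0 - 1 - c/2 + trans_dominance * t/4)` (each F1 allele carries
#' half the library). Counts are NB2 draws; the output is deterministic for
#' a fixed seed and invariant to gene order.
#'
#' @param config A [simulation_config()].
#' @return An `ase_simulation` list with `profile` (long tibble `gene_id`,
#'   `replicate`, `generation`, `allele`, `count`) and `truth` (tibble
#'   `gene_id`, `true_category`, `c`, `t`, `expected_parental_log2fc`,
#'   `expected_hybrid_allelic_log2fc`).
#' @examples
#' sim <- simulate_ase_counts(simulation_config(n_genes = 12, seed = 7))
#' head(sim$profile)
#' @export
simulate_ase_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  nr <- config$n_replicates
  m0 <- config$baseline_log2_mean
  phi <- config$dispersion
  td <- config$trans_dominance
  sf <- config$library_size_factors
  sf_w <- sf[seq_len(nr)]
  sf_c <- sf[nr + seq_len(nr)]
  sf_f1 <- sf[2 * nr + seq_len(nr)]

  cats <- allocate_categories(config$category_mix, n)
  gene_ids <- sprintf("gene_%05d", seq_len(n))
  reps <- paste0("rep", seq_len(nr))

  e_cis <- config$cis_effect_log2
  e_trans <- config$trans_effect_log2

  cvec <- numeric(n)
  tvec <- numeric(n)
  counts <- matrix(0L, nrow = n, ncol = 4 * nr) # F0W | F0C | F1W | F1C blocks
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    s <- if (runif(1) < 0.5) 1 else -1
    ct <- switch(cats[i],
      conserved = c(0, 0),
      cis_only = c(s * e_cis, 0),
      trans_only = c(0, s * e_trans),
      cis_plus_trans = c(s * e_cis, s * e_trans),
      cis_by_trans = c(s * e_cis / 2, -s * e_trans),
      compensatory = c(s * e_cis, -s * e_cis)
    )
    cc <- ct[1]
    tt <- ct[2]
    cvec[i] <- cc
    tvec[i] <- tt
    mu_f0w <- sf_w * 2^(m0 + (cc + tt) / 2)
    mu_f0c <- sf_c * 2^(m0 - (cc + tt) / 2)
    mu_f1w <- sf_f1 * 2^(m0 - 1 + cc / 2 + td * tt / 4)
    mu_f1c <- sf_f1 * 2^(m0 - 1 - cc / 2 + td * tt / 4)
    counts[i, ] <- c(
      draw_counts(mu_f0w, phi), draw_counts(mu_f0c, phi),
      draw_counts(mu_f1w, phi), draw_counts(mu_f1c, phi)
    )
  }

  block <- function(gen, allele) tibble(
    gene_id = rep(gene_ids, each = nr),
    replicate = rep(reps, times = n),
    generation = gen,
    allele = allele
  )
  profile <- bind_rows(
    block("F0", "W") %>% mutate(count = as.vector(t(counts[, seq_len(nr), drop = FALSE]))),
    block("F0", "C") %>% mutate(count = as.vector(t(counts[, nr + seq_len(nr), drop = FALSE]))),
    block("F1", "W") %>% mutate(count = as.vector(t(counts[, 2 * nr + seq_len(nr), drop = FALSE]))),
    block("F1", "C") %>% mutate(count = as.vector(t(counts[, 3 * nr + seq_len(nr), drop = FALSE])))
  ) %>%
    mutate(count = as.integer(.data$count)) %>%
    arrange(.data$gene_id, .data$generation, .data$allele, .data$replicate)
  class(profile) <- c("allele_profile", class(profile))

  truth <- tibble(
    gene_id = gene_ids,
    true_category = cats,
    c = cvec,
    t = tvec,
    expected_parental_log2fc = cvec + tvec,
    expected_hybrid_allelic_log2fc = cvec
  )
  structure(list(profile = profile, truth = truth, config = config),
    class = "ase_simulation"
  )
}

#' @export
print.ase_simulation <- function(x, ...) {
  cat(sprintf(
    "ASE simulation: %d genes x %d replicates (dispersion %.3g, seed %d)\n",
    x$config$n_genes, x$config$n_replicates, x$config$dispersion, x$config$seed
  ))
  print(table(x$truth$true_category))
  invisible(x)
}

#' Collapse an allele profile to total counts per library
#'
#' The W and C parent libraries contribute their single allele; each F1
#' library's total is the sum of its two allele counts. Returns the wide
#' count table and matching sample metadata used by the total-expression
#' analyses (filtering, parental DE, dominance).
#'
#' @param profile An allele-resolved long count tibble (see
#'   [simulate_ase_counts()]).
#' @return List with `counts` (wide tibble) and `metadata` (tibble with
#'   `sample`, `genotype`, `replicate`).
#' @export
ase_totals <- function(profile) {
  totals <- profile %>%
    mutate(
      genotype = if_else(.data$generation == "F0", .data$allele, "CxW"),
      sample = paste0(.data$genotype, "_", .data$replicate)
    ) %>%
    group_by(.data$gene_id, .data$sample, .data$genotype, .data$replicate) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  metadata <- totals %>%
    distinct(.data$sample, .data$genotype, .data$replicate) %>%
    arrange(.data$sample)
  counts <- totals %>%
    select("gene_id", "sample", "count") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "count", values_fill = 0L)
  list(counts = counts, metadata = metadata)
}

NUCS <- c("A", "C", "G", "T")

#' Simulate paired SNP records from two pseudoreference alignments
#'
#' Emits one record per SNP per F1 replicate as seen simultaneously in the
#' cultivated-parent view (reference allele = C) and the wild-parent view
#' (reference allele = W). Clean records are biallelic, heterozygous and
#' reciprocal (`A/G` vs `G/A`), pass QUAL > 30 and DP > 20, and have exactly
#' mirrored per-allele depths between the views. A `contamination_rate`
#' fraction of records violates one randomly chosen rule, to exercise the
#' filters.
#'
#' @param n_genes Genes to scatter SNPs over.
#' @param snps_per_gene SNPs per gene (default 3).
#' @param seed Integer seed.
#' @param contamination_rate Fraction in \[0, 1) of rule-violating records.
#' @param n_replicates F1 replicates (default 3).
#' @param mean_depth Mean total allele depth per SNP (default 40).
#' @return Tibble of SNP pair records: `chrom`, `pos`, `gene_id`,
#'   `replicate_id`, per-view REF/ALT and ordered genotypes, per-view allele
#'   depths (`ad_ref_*`, `ad_alt_*`), `qual`, `dp`, and `clean` (the
#'   generator's truth about whether the record should survive filtering).
#' @export
simulate_snp_pairs <- function(n_genes, snps_per_gene = 3, seed = 1,
                               contamination_rate = 0, n_replicates = 3,
                               mean_depth = 40) {
  if (contamination_rate < 0 || contamination_rate >= 1) {
    abort("contamination_rate must lie in [0, 1).")
  }
  if (n_genes < 1 || snps_per_gene < 1) abort("n_genes and snps_per_gene must be positive.")
  set.seed(substream_seed(seed, 0L))
  n_sites <- n_genes * snps_per_gene
  gene_ids <- rep(sprintf("gene_%05d", seq_len(n_genes)), each = snps_per_gene)
  chrom <- rep(sprintf("chr%02d", (seq_len(n_genes) - 1L) %% 12 + 1L), each = snps_per_gene)
  # 1-based positions, unique within chromosome: genes laid out on a 10 kb grid
  pos <- rep((seq_len(n_genes) - 1L) %/% 12 * 10000L, each = snps_per_gene) +
    1000L + (seq_len(n_sites) - 1L) %% snps_per_gene * 150L + 1L

  site_c <- sample(NUCS, n_sites, replace = TRUE)
  site_w <- vapply(site_c, function(a) sample(setdiff(NUCS, a), 1), character(1))

  recs <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(substream_seed(seed, r))
    d_c <- rpois(n_sites, mean_depth / 2) + 6L
    d_w <- rpois(n_sites, mean_depth / 2) + 6L
    qual <- 31 + stats::rexp(n_sites, rate = 1 / 40)
    clean <- runif(n_sites) >= contamination_rate
    gt_c <- paste0(site_c, "/", site_w) # C view: REF=C allele, ALT=W allele
    gt_w <- paste0(site_w, "/", site_c)
    ad_ref_c <- d_c
    ad_alt_c <- d_w
    ad_ref_w <- d_w
    ad_alt_w <- d_c
    bad <- which(!clean)
    if (length(bad) > 0) {
      mode <- sample(4, length(bad), replace = TRUE)
      i <- bad[mode == 1] # not reciprocal: same order in both views
      gt_w[i] <- gt_c[i]
      i <- bad[mode == 2] # homozygous in the W view
      gt_w[i] <- paste0(site_w[i], "/", site_w[i])
      i <- bad[mode == 3] # low mapping quality
      qual[i] <- runif(length(i), 5, 30)
      i <- bad[mode == 4] # depth reciprocity broken
      ad_ref_w[i] <- ad_ref_w[i] + pmax(2L, ceiling(0.5 * ad_ref_w[i]))
    }
    recs[[r]] <- tibble(
      chrom = chrom, pos = pos, gene_id = gene_ids,
      replicate_id = paste0("rep", r),
      ref_Cview = site_c, alt_Cview = site_w, gt_Cview = gt_c,
      ad_ref_Cview = as.integer(ad_ref_c), ad_alt_Cview = as.integer(ad_alt_c),
      ref_Wview = site_w, alt_Wview = site_c, gt_Wview = gt_w,
      ad_ref_Wview = as.integer(ad_ref_w), ad_alt_Wview = as.integer(ad_alt_w),
      qual = qual, dp = as.integer(d_c + d_w),
      clean = clean
    )
  }
  bind_rows(recs)
}

# Ellipse-derived default fruit dimensions (mm): a small round wild fruit and
# an elongated cultivated one. Perimeter by Ramanujan's approximation.
ellipse_traits <- function(major, minor) {
  a <- major / 2
  b <- minor / 2
  h <- ((a - b) / (a + b))^2
  c(
    area = pi * a * b,
    major_axis = major,
    minor_axis = minor,
    perimeter = pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  )
}

default_parent_means <- function() {
  list(W = ellipse_traits(9, 8), C = ellipse_traits(80, 15))
}

#' Simulate per-fruit morphometric measurements
#'
#' Draws fruit area, axis lengths and perimeter for the two parents and the
#' F1 hybrid. Hybrid trait means sit at midparent + k * a, where
#' a = (W - C)/2, so `trait_k = 0` is additive, `trait_k = 1` puts the
#' hybrid at the wild mean (cultivated phenotype fully recessive) and
#' `trait_k = -1` at the cultivated mean. Noise is lognormal with the given
#' coefficient of variation (mean-preserving).
#'
#' @param n_fruits_per_genotype Fruits per genotype.
#' @param parent_means Named list `W`, `C` of per-trait means (`area`,
#'   `major_axis`, `minor_axis`, `perimeter`); defaults emulate a small round
#'   wild chile and an elongated cultivated one.
#' @param trait_k Degree of dominance applied to every trait (default 1).
#' @param noise_cv Lognormal coefficient of variation (default 0.05).
#' @param seed Integer seed.
#' @return Tibble `fruit_id`, `genotype` (`W`, `C`, `CxW`), `area`,
#'   `major_axis`, `minor_axis`, `perimeter`.
#' @export
simulate_morphometrics <- function(n_fruits_per_genotype = 20,
                                   parent_means = NULL,
                                   trait_k = 1, noise_cv = 0.05, seed = 1) {
  parent_means <- parent_means %||% default_parent_means()
  traits <- c("area", "major_axis", "minor_axis", "perimeter")
  w <- parent_means$W[traits]
  c_ <- parent_means$C[traits]
  if (any(w <= 0) || any(c_ <= 0)) abort("Parent trait means must be positive.")
  a <- (w - c_) / 2
  hyb <- (w + c_) / 2 + trait_k * a
  if (any(hyb <= 0)) abort("Hybrid trait means are nonpositive under this trait_k.")
  means <- list(W = w, C = c_, CxW = hyb)
  set.seed(substream_seed(seed, 0L))
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- purrr::imap(means, function(mu, g) {
    vals <- vapply(mu, function(m) {
      if (noise_cv == 0) {
        rep(m, n_fruits_per_genotype)
      } else {
        stats::rlnorm(n_fruits_per_genotype, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
      }
    }, numeric(n_fruits_per_genotype))
    out <- as_tibble(vals)
    out$genotype <- g
    out
  })
  out <- bind_rows(rows) %>%
    mutate(
      fruit_id = sprintf("fruit_%03d", row_number()),
      # measurement convention: the major axis is the longer one
      major = pmax(.data$major_axis, .data$minor_axis),
      minor = pmin(.data$major_axis, .data$minor_axis),
      major_axis = .data$major, minor_axis = .data$minor
    ) %>%
    select("fruit_id", "genotype", "area", "major_axis", "minor_axis", "perimeter")
  out
}
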