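test_that("median-of-ratios size factors match hand computation and DESeq2", {
  counts <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    s1 = c(10, 100, 5, 40),
    s2 = c(20, 200, 10, 80) # exactly double: factors 1/sqrt(2), sqrt(2)
  )
  sf <- size_factors_median_ratios(counts)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)))

  set.seed(77)
  m <- matrix(rpois(300, 50) + 1, nrow = 50)
  colnames(m) <- paste0("s", 1:6)
  sf2 <- size_factors_median_ratios(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(sf2$size_factor, unname(ref), tolerance = 1e-10)

  same <- matrix(c(3, 7, 11), nrow = 3, ncol = 4)
  colnames(same) <- paste0("s", 1:4)
  expect_equal(size_factors_median_ratios(same)$size_factor, rep(1, 4))
  single <- matrix(c(3, 7), ncol = 1, dimnames = list(NULL, "s1"))
  expect_equal(size_factors_median_ratios(single)$size_factor, 1)
  zeros <- matrix(c(0, 1, 1, 0), 2, dimnames = list(NULL, c("a", "b")))
  expect_error(size_factors_median_ratios(zeros), "relax filtering")
})

test_that("low-expression filter follows the per-genotype median rule", {
  meta <- tibble::tibble(
    sample = c("W_1", "W_2", "W_3", "C_1", "C_2", "C_3", "F_1", "F_2", "F_3"),
    genotype = rep(c("W", "C", "CxW"), each = 3)
  )
  mk <- function(w, c, f) {
    tibble::tibble(
      gene_id = "g",
      W_1 = w, W_2 = w, W_3 = w, C_1 = c, C_2 = c, C_3 = c,
      F_1 = f, F_2 = f, F_3 = f
    )
  }
  low_all <- mk(4, 4, 4)
  silenced <- mk(0, 12, 6) # silenced in one parent: retained by default
  boundary <- mk(5, 5, 5) # 5 is not "smaller than five"
  counts <- dplyr::bind_rows(low_all, silenced, boundary)
  counts$gene_id <- c("low", "silenced", "boundary")
  kept <- filter_low_expression(counts, meta)
  expect_setequal(kept$gene_id, c("silenced", "boundary"))
  strict <- filter_low_expression(counts, meta, drop_if = "any_below")
  expect_equal(strict$gene_id, "boundary")
})

test_that("nb_loglik matches closed forms and is maximized at the mean", {
  expect_equal(nb_loglik(3, 3, 0), 3 * log(3) - 3 - log(6))
  expect_equal(nb_loglik(c(4, 6), c(4, 6), 0.1), sum(dnbinom(c(4, 6), size = 10, mu = c(4, 6), log = TRUE)))
  # appending a zero count with vanishing mean changes nothing
  base <- nb_loglik(c(5, 7), c(5, 7), 0.2)
  expect_equal(nb_loglik(c(5, 7, 0), c(5, 7, 1e-9), 0.2), base, tolerance = 1e-6)
  # score equation: likelihood over a common mu peaks at the sample mean
  y <- c(8, 12, 10, 14)
  mus <- seq(1, 30, by = 0.01)
  lls <- vapply(mus, function(m) nb_loglik(y, rep(m, 4), 0.1), numeric(1))
  expect_equal(mus[which.max(lls)], mean(y), tolerance = 0.02)
  expect_error(nb_loglik(3, 3, -1), "nonnegative")
})

test_that("BH step-up matches hand computation and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(99)
  p <- c(runif(40), NA, runif(9))
  got <- bh_adjust(p)
  expect_true(is.na(got[41]))
  expect_equal(got[-41], p.adjust(p[-41], "BH"))
  # order invariance
  o <- sample(length(p))
  expect_equal(bh_adjust(p[o]), got[o])
})

test_that("nb_glm_lrt behaves on null, signal and degenerate inputs", {
  x <- data.frame(group = factor(rep(c("A", "B"), each = 3)))
  null_fit <- nb_glm_lrt(rep(20L, 6), ~group, ~1, data = x, dispersion = 0.1)
  expect_lt(null_fit$lrt_stat, 1e-6)
  expect_gt(null_fit$pvalue, 0.99)

  strong <- nb_glm_lrt(c(100L, 110L, 90L, 10L, 9L, 11L), ~group, ~1, data = x, dispersion = 0.1)
  expect_lt(strong$pvalue, 1e-6)

  zero <- nb_glm_lrt(rep(0L, 6), ~group, ~1, data = x)
  expect_true(zero$degenerate)
  expect_equal(zero$pvalue, 1)

  expect_error(
    nb_glm_lrt(rep(5L, 6), ~1, ~group, data = x),
    "not nested"
  )
  td <- tidy(strong)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$pvalue, strong$pvalue)
})

test_that("LRT is invariant to size-factor rescaling and sample reordering", {
  x <- data.frame(group = factor(rep(c("A", "B"), each = 3)))
  y <- c(30L, 45L, 38L, 80L, 70L, 95L)
  f1 <- nb_glm_lrt(y, ~group, ~1, data = x, size_factors = rep(1, 6), dispersion = 0.05)
  # a common factor on every library is absorbed by the intercept
  f2 <- nb_glm_lrt(y, ~group, ~1, data = x, size_factors = rep(3, 6), dispersion = 0.05)
  expect_equal(f1$lrt_stat, f2$lrt_stat, tolerance = 1e-8)
  o <- c(4, 1, 6, 2, 3, 5)
  f3 <- nb_glm_lrt(y[o], ~group, ~1, data = data.frame(group = x$group[o]), dispersion = 0.05)
  expect_equal(f1$lrt_stat, f3$lrt_stat, tolerance = 1e-8)
  # normalized-mean fold changes are unchanged when counts and factors
  # double together (the counts themselves carry more information, so the
  # statistic legitimately grows; only the effect scale is invariant)
  norm_fc <- function(y, sf) {
    log2((mean(y[4:6] / sf[4:6]) + 0.5) / (mean(y[1:3] / sf[1:3]) + 0.5))
  }
  expect_equal(norm_fc(2L * y, rep(2, 6)), norm_fc(y, rep(1, 6)))
})

test_that("IRLS optimizer agrees with a dense-grid likelihood oracle", {
  set.seed(2024)
  phi <- 0.1
  xg <- rep(c(0, 1), each = 3)
  X <- cbind(1, xg)
  for (i in 1:8) {
    mu <- exp(runif(1, 2, 5) + xg * runif(1, -1.5, 1.5))
    y <- rnbinom(6, size = 1 / phi, mu = mu)
    if (all(y == 0)) next
    fit <- nb_glm_lrt(y, X, X[, 1, drop = FALSE], dispersion = phi)
    expect_lt(abs(fit$ll_full - grid_loglik_max(y, xg, phi)), 1e-3)
    expect_lt(abs(fit$ll_reduced - grid_loglik_max_1d(y, phi)), 1e-3)
  }
})

test_that("parental_de reports W-over-C fold changes with BH control", {
  cfg <- simulation_config(
    n_genes = 60, seed = 13, cis_effect_log2 = 1.5, trans_effect_log2 = 1.5,
    category_mix = stats::setNames(c(0.5, 0, 0, 0.5, 0, 0), cistrans:::SIMULATED_CATEGORIES)
  )
  sim <- simulate_ase_counts(cfg)
  tot <- ase_totals(sim$profile)
  de <- parental_de(tot$counts, tot$metadata)
  expect_s3_class(de, "de_results")
  expect_true(all(de$qvalue >= de$pvalue - 1e-12))
  joined <- dplyr::inner_join(de, sim$truth, by = "gene_id")
  up <- joined[joined$expected_parental_log2fc > 2, ]
  expect_true(all(up$log2fc > 0)) # c + t = 3: strong wild-ward fold change
  expect_gt(mean(up$qvalue < 0.05), 0.9)
  expect_error(
    parental_de(tot$counts, dplyr::filter(tot$metadata, genotype != "C")),
    "two replicates"
  )
})
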