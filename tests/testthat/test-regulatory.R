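test_that("cis test: symmetric F1 counts give no imbalance, labels flip signs", {
  prof <- make_profile(
    f0_w = c(200L, 210L, 190L), f0_c = c(60L, 55L, 65L),
    f1_w = c(50L, 55L, 45L), f1_c = c(50L, 45L, 55L)
  )
  res <- cis_test(prof, "g1", dispersion = 0.05)
  expect_gt(res$pvalue, 0.5)
  expect_lt(abs(res$log2fc), 0.2)

  # swapping allele labels flips the fold-change sign
  imb <- make_profile(
    f0_w = c(200L, 210L, 190L), f0_c = c(60L, 55L, 65L),
    f1_w = c(120L, 110L, 130L), f1_c = c(30L, 35L, 25L)
  )
  swapped <- imb
  swapped$allele <- ifelse(imb$allele == "W", "C", "W")
  a <- cis_test(imb, "g1", dispersion = 0.05)
  b <- cis_test(swapped, "g1", dispersion = 0.05)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-10)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-10)
})

test_that("trans test: equal allelic ratios across generations are null", {
  prof <- make_profile(
    f0_w = c(400L, 380L, 420L), f0_c = c(100L, 95L, 105L), # 4:1 in parents
    f1_w = c(200L, 190L, 210L), f1_c = c(50L, 48L, 52L) # 4:1 in hybrid
  )
  res <- trans_test(prof, "g1", dispersion = 0.01)
  expect_gt(res$pvalue, 0.5)
  bad <- prof[prof$generation == "F1", ]
  expect_error(trans_test(bad, "g1"), "F0 and F1")
})

test_that("classification follows the seven-category decision table", {
  grid <- tidyr::expand_grid(P = c(TRUE, FALSE), H = c(TRUE, FALSE), T = c(TRUE, FALSE))
  calls <- tibble::tibble(
    gene_id = paste0("g", seq_len(nrow(grid))),
    q_parental = ifelse(grid$P, 0.01, 0.5),
    q_cis = ifelse(grid$H, 0.01, 0.5),
    q_trans = ifelse(grid$T, 0.01, 0.5),
    cis_component = 1.0,
    trans_component = 0.5
  )
  out <- classify_regulation(calls)
  got <- setNames(as.character(out$category), paste(grid$P, grid$H, grid$T))
  expect_equal(got[["TRUE TRUE FALSE"]], "cis_only")
  expect_equal(got[["TRUE FALSE TRUE"]], "trans_only")
  expect_equal(got[["TRUE TRUE TRUE"]], "cis_plus_trans") # same-sign components
  expect_equal(got[["FALSE TRUE TRUE"]], "compensatory")
  expect_equal(got[["FALSE FALSE FALSE"]], "conserved")
  expect_equal(got[["TRUE FALSE FALSE"]], "ambiguous")
  expect_equal(got[["FALSE TRUE FALSE"]], "ambiguous")
  expect_equal(got[["FALSE FALSE TRUE"]], "ambiguous")

  # opposing components: cis x trans
  opp <- classify_regulation(dplyr::mutate(calls, trans_component = -0.4))
  expect_equal(as.character(opp$category[grid$P & grid$H & grid$T]), "cis_by_trans")
  # zero component with joint significance: ambiguous, with a message
  expect_message(
    tie <- classify_regulation(dplyr::mutate(calls, cis_component = 0)),
    "ambiguous"
  )
  expect_equal(as.character(tie$category[grid$P & grid$H & grid$T]), "ambiguous")
})

test_that("categories partition the gene set and components sum exactly", {
  sim <- simulate_ase_counts(simulation_config(n_genes = 120, seed = 21))
  calls <- regulatory_divergence(sim$profile)
  expect_equal(nrow(calls), 120)
  expect_false(anyNA(calls$category))
  expect_equal(sum(table(calls$category)), 120)
  expect_equal(
    calls$cis_component + calls$trans_component,
    calls$parental_log2fc
  )
  gl <- glance(calls)
  expect_equal(
    gl$n_divergent + gl$n_conserved + gl$n_ambiguous,
    gl$n_genes
  )
})

test_that("swapping W and C everywhere flips signs but keeps categories", {
  sim <- simulate_ase_counts(simulation_config(n_genes = 40, seed = 31))
  prof <- sim$profile
  swapped <- prof
  swapped$allele <- ifelse(prof$allele == "W", "C", "W")
  a <- regulatory_divergence(prof, dispersion = 0.05)
  b <- regulatory_divergence(swapped, dispersion = 0.05)
  expect_equal(a$parental_log2fc, -b$parental_log2fc, tolerance = 1e-8)
  expect_equal(a$hybrid_log2fc, -b$hybrid_log2fc, tolerance = 1e-8)
  expect_equal(as.character(a$category), as.character(b$category))
})

test_that("cis percentage arithmetic and binning", {
  calls <- tibble::tibble(
    gene_id = c("pure_cis", "pure_trans", "split"),
    q_parental = 0.01, q_cis = 0.01, q_trans = 0.01,
    parental_log2fc = c(2, 2, 2),
    hybrid_log2fc = c(2, 0, 1),
    cis_component = c(2, 0, 1),
    trans_component = c(0, 2, 1)
  )
  out <- classify_regulation(calls)
  expect_equal(out$cis_percentage, c(100, 0, 50))
  bins <- cis_percentage_bins(out, bin_edges = c(0, 1, 3, 5))
  expect_equal(bins$n, c(0L, 3L, 0L))
  expect_true(is.na(bins$mean_cis_percentage[1])) # empty bin: missing, not zero
  expect_equal(bins$mean_cis_percentage[2], 50)
  expect_error(cis_percentage_bins(out[0, ]), "empty")
})

test_that("proportion z-test reproduces hand-computed values", {
  expect_equal(proportion_test(960, 1062)$z, 26.29775, tolerance = 1e-5)
  expect_lt(abs(proportion_test(531, 1062)$z), 0.031) # exact null proportion
  expect_equal(proportion_test(9, 12)$z, (9 - 6 - 0.5) / sqrt(3), tolerance = 1e-12)
  expect_lt(proportion_test(960, 1062)$p_value, 0.001)
  expect_error(proportion_test(5, 10, p0 = 1), "strictly")
})

test_that("binomial symmetry test matches closed forms", {
  expect_equal(binomial_symmetry_test(10, 10)$p_value, 1)
  expect_equal(binomial_symmetry_test(0, 20)$p_value, 2 * 0.5^20)
  expect_equal(binomial_symmetry_test(0, 0)$p_value, 1)
  expect_equal(
    binomial_symmetry_test(4123, 4398)$p_value,
    binom.test(4123, 8521)$p.value
  )
})

test_that("effect-size comparison: exact enumeration and approximation", {
  same <- effect_size_comparison(c(1, 2, 3, 4), c(1, 2, 3, 4) + 1e-9)
  expect_gt(same$p_value, 0.6) # near-exchangeable groups
  sep <- effect_size_comparison(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$p_value, 0.1) # full enumeration of C(6,3) arrangements
  expect_equal(sep$method, "exact")
  set.seed(5)
  shifted <- effect_size_comparison(abs(rnorm(500)) + 0.5, abs(rnorm(500)))
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$method, "normal approximation")
  expect_error(effect_size_comparison(numeric(0), 1), "nonempty")
})
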