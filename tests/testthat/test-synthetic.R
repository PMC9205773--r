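test_that("identical seeds reproduce the cohort exactly, different seeds differ", {
  c1 <- generate_cohort(cohort_config(seed = 7, n_strains = 4, n_per_cell = 3,
                                      n_structures = 6,
                                      anxiety_groups = c(strain01 = "increased",
                                                         strain02 = "increased",
                                                         strain03 = "decreased",
                                                         strain04 = "decreased")))
  c2 <- generate_cohort(cohort_config(seed = 7, n_strains = 4, n_per_cell = 3,
                                      n_structures = 6,
                                      anxiety_groups = c(strain01 = "increased",
                                                         strain02 = "increased",
                                                         strain03 = "decreased",
                                                         strain04 = "decreased")))
  expect_identical(volume_matrix(c1$volumes), volume_matrix(c2$volumes))
  expect_identical(c1$truth, c2$truth)
  c3 <- small_cohort(seed = 8, n_structures = 6)
  expect_false(identical(volume_matrix(c1$volumes), volume_matrix(c3$volumes)))
})

test_that("per-cell counts match the configuration and volumes are positive", {
  coh <- small_cohort(n_per_cell = 5)
  tab <- table(coh$volumes$strain, coh$volumes$sex)
  expect_true(all(tab == 5))
  expect_equal(nrow(tab), 5)  # 4 mutants + WT
  expect_true(all(volume_matrix(coh$volumes) > 0))
  expect_identical(wildtype_strain(coh$volumes), "WT")
  expect_true(all(coh$truth$strain_effects["WT", ] == 0))
})

test_that("changing the cohort size does not perturb the true effects", {
  a <- generate_cohort(cohort_config(seed = 5, n_per_cell = 2))
  b <- generate_cohort(cohort_config(seed = 5, n_per_cell = 6))
  expect_identical(a$truth$strain_effects, b$truth$strain_effects)
  expect_identical(a$truth$sex_effects, b$truth$sex_effects)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_structures = 7), "n_structures")
  expect_error(cohort_config(base_volume_mm3 = c(-1, 2)), "positive")
  expect_error(cohort_config(anxiety_groups = c(strainXX = "increased")),
               "label every mutant strain")
  expect_error(cohort_config(anxiety_groups = stats::setNames(
    rep("wild", 6), sprintf("strain%02d", 1:6))), "increased/decreased")
  expect_error(cohort_config(within_group_corr = 1.2))
})

test_that("same-label strain effect vectors carry the configured correlation", {
  # Monte-Carlo check against the generating covariance over replicate seeds
  same_cors <- c(); diff_cors <- c()
  for (s in 1:40) {
    coh <- generate_cohort(cohort_config(seed = 1000 + s, n_structures = 60,
                                         n_per_cell = 2,
                                         within_group_corr = 0.9))
    eff <- coh$truth$strain_effects
    lab <- coh$config$anxiety_groups
    mut <- names(lab)
    for (i in seq_along(mut)[-1]) for (j in seq_len(i - 1)) {
      r <- stats::cor(eff[mut[i], ], eff[mut[j], ])
      if (lab[mut[i]] == lab[mut[j]]) same_cors <- c(same_cors, r)
      else diff_cors <- c(diff_cors, r)
    }
  }
  expect_equal(mean(same_cors), 0.9, tolerance = 0.05)
  expect_lt(abs(mean(diff_cors)), 0.06)
})

test_that("the latent predictor table inverts the volume transform exactly", {
  for (vm in c("multiplicative", "additive")) {
    coh <- small_cohort(seed = 3, volume_model = vm)
    eta <- volume_matrix(cohort_latent_table(coh))
    # WT females carry only intercept + noise: mean near 0 at this n
    wt <- eta[coh$volumes$strain == "WT", , drop = FALSE]
    expect_lt(abs(mean(wt)), 0.5)
    # reconstructing volumes from eta reproduces the table to rounding error
    base <- coh$config$base_volume_mm3
    rebuilt <- if (vm == "multiplicative")
      sweep(exp(coh$config$cv * eta), 2, base, "*")
    else sweep(1 + coh$config$cv * eta, 2, base, "*")
    expect_equal(unname(rebuilt), unname(volume_matrix(coh$volumes)),
                 tolerance = 1e-12)
  }
})

test_that("expression atlas plants enrichment, respects constraints, and round-trips GMT", {
  genes <- sprintf("gene%05d", 1:60)
  atlas <- generate_expression_atlas(
    300, structures = paste0("r", 1:10), roi_structures = paste0("r", 1:3),
    enriched_term_genes = list(planted = genes), boost = 4, seed = 2)
  expect_true(all(atlas$expression >= 0))
  expect_true(all(atlas$development >= 0))
  expect_equal(sort(unique(unname(atlas$archetype))),
               c("early_peak", "mid_peak", "rise_late", "rise_mid"))
  fc <- fold_change(atlas$expression, paste0("r", 1:3))
  planted_fc <- fc$fc[fc$gene %in% genes]
  expect_gt(median(planted_fc), median(fc$fc))
  gmt <- file.path(tempdir(), "sets.gmt")
  write_gmt(atlas$gene_sets, gmt)
  back <- read_gmt(gmt)
  expect_identical(lapply(back, as.character),
                   lapply(atlas$gene_sets, as.character))
  expect_error(generate_expression_atlas(10, "a", character(0)), "ROI")
  expect_error(generate_expression_atlas(
    10, "a", "a", enriched_term_genes = list(t = "nope")), "unknown gene")
  expect_error(generate_expression_atlas(10, "a", "a",
                                         timepoints = c("P4", "P14", "P28", "P56")),
               "embryonic")
})

test_that("without enrichment, planted genes look like background", {
  genes <- sprintf("gene%05d", 1:50)
  ps <- vapply(1:8, function(s) {
    atlas <- generate_expression_atlas(
      400, structures = paste0("r", 1:10), roi_structures = paste0("r", 1:3),
      enriched_term_genes = list(planted = genes), boost = 1, seed = 100 + s)
    fc <- fold_change(atlas$expression, paste0("r", 1:3))
    ks_compare(fc, genes, against = "complement")$p
  }, numeric(1))
  # null KS p-values should not pile up near zero
  expect_gt(mean(ps > 0.05), 0.7)
})
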