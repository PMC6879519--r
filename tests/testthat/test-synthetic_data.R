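test_that("default spike panels have the real panel sizes and are seed-stable", {
  p <- make_spike_panels(seed = 1)
  expect_identical(nrow(p$ercc), 92L)
  expect_identical(nrow(p$sequin), 78L)
  expect_identical(nrow(p$ercc) + nrow(p$sequin), 170L)
  expect_true(all(p$ercc$stock_concentration > 0))
  expect_identical(make_spike_panels(seed = 1), p)
  expect_false(identical(make_spike_panels(seed = 2), p))
  expect_identical(nrow(make_spike_panels(n_ercc = 1, seed = 1)$ercc), 1L)
})

test_that("titration truth records the designed fold changes", {
  sim <- make_titration(panels = make_spike_panels(seed = 2), noise = "none",
                        library_size = 5e5, seed = 2)
  d <- sim$truth$design
  expect_equal(expected_log2fc(d, "Sequin", "T1", "T5"), 2)
  expect_equal(expected_log2fc(d, "ERCC", "T1", "T5"), -2)
  # expected spike counts scale exactly with the relative dilution
  e <- sim$truth$expected_counts
  sq <- spike_ids(sim$counts, "sequin")
  expect_equal(e[sq, "T1"] / e[sq, "T5"], rep(4, length(sq)), ignore_attr = TRUE)
})

test_that("titration matrices are reproducible and respect the noise model", {
  a <- make_titration(panels = make_spike_panels(seed = 3), noise = "poisson",
                      library_size = 2e5, seed = 3)
  b <- make_titration(panels = make_spike_panels(seed = 3), noise = "poisson",
                      library_size = 2e5, seed = 3)
  expect_identical(a$counts$counts, b$counts$counts)
  none <- make_titration(panels = make_spike_panels(seed = 3), noise = "none",
                         library_size = 2e5, seed = 3)
  none99 <- make_titration(panels = make_spike_panels(seed = 3), noise = "none",
                           library_size = 2e5, seed = 99)
  spk <- spike_ids(none$counts)
  # spike counts under noise="none" are deterministic functions of the design
  expect_identical(none$counts$counts[spk, ], none99$counts$counts[spk, ])
  expect_error(make_titration(noise = "gamma"), "arg")
})

test_that("Poisson titration with high spike coverage keeps ~90% of deviations under 0.5", {
  # narrow stock range so every spike has expected counts >= 100
  sim <- make_titration(panels = make_spike_panels(dynamic_range_log2 = 2, seed = 4),
                        noise = "poisson", library_size = 1e6, seed = 4)
  expect_gte(min(sim$truth$expected_counts[spike_ids(sim$counts), ]), 100)
  tr <- trueness(sim$counts, sim$truth$design, pairs = "all")
  pooled <- tr$fraction_within
  expect_gte(pooled$fraction[pooled$threshold == 0.5], 0.90)
})

test_that("replicate matrices are seed-stable with planted single positives", {
  prof <- biofluid_profile("ePFP")
  a <- make_replicates(prof, library_size = 2e5, seed = 5)
  b <- make_replicates(prof, library_size = 2e5, seed = 5)
  expect_identical(a$counts$counts, b$counts$counts)
  noise <- a$truth$noise_gene_ids
  expect_length(noise, round(0.10 * prof$n_genes))
  nz <- a$counts$counts[noise, ]
  expect_true(all(rowSums(nz > 0) == 1))      # present in exactly one replicate
  expect_true(all(nz[nz > 0] %in% 1:3))
})

test_that("planted noise genes at counts <= 3 drive the chosen cutoff to 4", {
  sim <- make_replicates(biofluid_profile("ePFP"), library_size = 1e6, seed = 6)
  rep <- single_positive_analysis(sim$counts, "ePFP_rep1", "ePFP_rep2",
                                  cutoffs = 1:10, removal_target = 0.95)
  expect_identical(rep$chosen_cutoff, 4L)
  expect_gte(rep$per_cutoff$removed_single_positive_fraction[
    rep$per_cutoff$cutoff == 4], 0.95)
})

test_that("a zero single-positive rate yields a flagged filter report", {
  prof <- biofluid_profile("ePFP", n_genes = 500, single_positive_rate = 0,
                           abundance_sdlog = 0.3)
  sim <- make_replicates(prof, library_size = 1e6, seed = 7)
  rep <- single_positive_analysis(sim$counts, "ePFP_rep1", "ePFP_rep2")
  expect_true(rep$flag_no_single_positives)
  expect_identical(rep$chosen_cutoff, 1L)
})

test_that("library-prep replicates are more precise than RNA-isolation replicates", {
  prof <- biofluid_profile("ePFP")
  lp <- make_replicates(prof, library_size = 5e5, seed = 8,
                        replicate_level = "library_prep")
  ri <- make_replicates(prof, library_size = 5e5, seed = 8,
                        replicate_level = "rna_isolation")
  alc_lp <- replicate_ratios(lp$counts, "ePFP_rep1", "ePFP_rep2", 4)$alc
  alc_ri <- replicate_ratios(ri$counts, "ePFP_rep1", "ePFP_rep2", 4)$alc
  expect_lt(alc_lp, alc_ri)
})

test_that("Poisson-limit replicate ALC matches a Monte Carlo oracle", {
  prof <- biofluid_profile("ePFP", n_genes = 2000, single_positive_rate = 0)
  sim <- make_replicates(prof, library_size = 1e6, seed = 9, dispersion = 0)
  got <- replicate_ratios(sim$counts, "ePFP_rep1", "ePFP_rep2", 4)$alc

  # oracle: re-simulate Poisson replicate pairs from the planted expression
  mu <- sim$truth$expression_weights * sim$truth$endo_share * 1e6
  oracle <- withr::with_seed(1009, {
    mean(vapply(1:20, function(i) {
      ka <- rpois(length(mu), mu); kb <- rpois(length(mu), mu)
      keep <- ka >= 4 & kb >= 4
      mean(abs(log2(ka[keep] / kb[keep])))
    }, 0))
  })
  expect_equal(got, oracle, tolerance = 0.1)
})

test_that("combine_count_matrices unions features and rejects conflicts", {
  p <- make_spike_panels(seed = 10)
  a <- make_replicates(biofluid_profile("ePRP", n_genes = 300), seed = 10,
                       library_size = 1e4, panels = p)
  b <- make_replicates(biofluid_profile("urine", n_genes = 300), seed = 11,
                       library_size = 1e4, panels = p)
  cm <- combine_count_matrices(list(a$counts, b$counts))
  expect_setequal(sample_ids(cm), c(a$meta$sample_id, b$meta$sample_id))
  # urine genes are all zero in the ePRP columns
  ug <- setdiff(endogenous_ids(b$counts), endogenous_ids(a$counts))
  expect_true(all(cm$counts[ug, a$meta$sample_id] == 0))
  expect_error(combine_count_matrices(list(a$counts, a$counts)), "overlap")
})
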