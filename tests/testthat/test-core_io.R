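test_that("count matrix round-trips through TSV files", {
  mat <- matrix(c(0L, 5L, 12L, 3L, 0L, 7L), nrow = 3,
                dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  cm <- toy_counts(mat)
  cf <- withr::local_tempfile(fileext = ".tsv")
  af <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, cf, af)
  back <- read_count_matrix(cf, af)
  expect_identical(dim(back), c(3L, 2L))
  expect_identical(back$counts, cm$counts)
  expect_identical(back$annotation, cm$annotation)
})

test_that("validation rejects malformed count matrices", {
  bad_neg <- matrix(c(1, -1), nrow = 2,
                    dimnames = list(c("a", "b"), "s1"))
  expect_error(toy_counts(bad_neg), "negative count")
  bad_frac <- matrix(c(1, 2.5), nrow = 2,
                     dimnames = list(c("a", "b"), "s1"))
  expect_error(toy_counts(bad_frac), "non-integer count")

  mat <- matrix(1:2, nrow = 2, dimnames = list(c("a", "b"), "s1"))
  expect_error(count_matrix(mat, endo_annotation("a")), "absent from annotation.*b")
  expect_warning(count_matrix(mat, endo_annotation(c("a", "b", "ghost"))),
                 "ignored")
})

test_that("spike features must carry spike biotype and chrom class", {
  mat <- matrix(1:2, nrow = 2, dimnames = list(c("ERCC-1", "g1"), "s1"))
  ann <- data.frame(feature_id = c("ERCC-1", "g1"),
                    feature_class = c("spike_ercc", "endogenous"),
                    biotype = c("protein_coding", "protein_coding"),
                    chrom_class = c("spike", "nuclear"),
                    region_class = "not_applicable", stringsAsFactors = FALSE)
  expect_error(count_matrix(mat, ann), "spike features")
})

test_that("stage reports round-trip: integers exact, reals to 12 significant digits", {
  set.seed(42)
  res <- overlap(sprintf("g%d", 1:60), sprintf("g%d", 31:100))
  dir <- withr::local_tempdir()
  write_report(res, dir)
  back <- read_report(dir)
  expect_identical(back$summary$shared, 30L)
  expect_identical(back$summary$unique_a, 30L)
  expect_equal(back$summary$jaccard, res$jaccard, tolerance = 1e-12)

  mat <- matrix(rpois(40, 50) + 1, nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
  pr <- replicate_ratios(toy_counts(mat), "s1", "s2", cutoff = 1)
  dir2 <- withr::local_tempdir()
  write_report(pr, dir2)
  back2 <- read_report(dir2)
  expect_identical(as.integer(back2$tables$ratios$count_a), as.integer(pr$ratios$count_a))
  rel_err <- abs(back2$tables$ratios$abs_log2_ratio - pr$ratios$abs_log2_ratio) /
    pmax(abs(pr$ratios$abs_log2_ratio), 1e-300)
  expect_true(all(rel_err < 1e-12 | pr$ratios$abs_log2_ratio == 0))
  expect_equal(back2$summary$alc, pr$alc, tolerance = 1e-12)
})

test_that("trueness report summary carries slope, adjusted R2 and threshold fractions", {
  sim <- make_titration(panels = make_spike_panels(seed = 7), noise = "poisson",
                        library_size = 2e5, seed = 7)
  tr <- trueness(sim$counts, sim$truth$design, pairs = "reference")
  dir <- withr::local_tempdir()
  write_report(tr, dir)
  back <- read_report(dir)
  expect_true(all(c("slope", "adjusted_r2") %in% names(back$summary)))
  expect_true("fraction_within" %in% names(back$tables))
  expect_equal(back$summary$slope, tr$slope, tolerance = 1e-12)
})

test_that("an empty result table writes a header-only file without error", {
  res <- overlap(character(0), character(0),
                 counts = toy_counts(matrix(1:4, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))),
                 sample_a = "s1", sample_b = "s2")
  dir <- withr::local_tempdir()
  expect_no_error(write_report(res, dir))
  tab <- read.delim(file.path(dir, "unique_gene_abundance.tsv"))
  expect_identical(nrow(tab), 0L)
  expect_identical(names(tab), c("feature_id", "side", "count"))
})

test_that("sample metadata readers validate fields (YAML and TSV)", {
  meta <- data.frame(sample_id = c("s1", "s2"), fluid = "ePFP",
                     replicate_group = "d1", replicate_level = "rna_isolation",
                     input_volume = 200, ercc_dilution = 1 / 25000,
                     stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(meta, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_sample_meta(tf)
  expect_identical(got$sample_id, c("s1", "s2"))
  expect_true("sequin_dilution" %in% names(got))

  yf <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(seq_len(2), function(i) as.list(meta[i, ])), yf)
  got_y <- read_sample_meta(yf)
  expect_equal(got_y$ercc_dilution, meta$ercc_dilution)

  meta_bad <- meta; meta_bad$input_volume <- c(200, 0)
  write.table(meta_bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_meta(tf), "input_volume")
  meta_bad <- meta; meta_bad$ercc_dilution <- 2
  write.table(meta_bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sample_meta(tf), "dilution")
})

test_that("analysis config enforces its invariants", {
  cfg <- analysis_config()
  expect_identical(cfg$detection_cutoff, 4L)
  expect_identical(cfg$subsample_depth, 1e6)
  expect_identical(cfg$trueness_min_count, 10L)
  expect_error(analysis_config(removal_target = 1.2))
  expect_error(analysis_config(detection_cutoff = 0))
})
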