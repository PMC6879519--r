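test_that("composition fractions are computed per family and sum to one", {
  mat <- matrix(c(60, 30, 10), nrow = 3,
                dimnames = list(c("gN", "gM", "gR"), "s1"))
  ann <- data.frame(feature_id = c("gN", "gM", "gR"), feature_class = "endogenous",
                    biotype = c("protein_coding", "protein_coding", "miscRNA"),
                    chrom_class = c("nuclear", "mitochondrial", "rRNA"),
                    region_class = "exonic", stringsAsFactors = FALSE)
  res <- composition(count_matrix(mat, ann), "s1")
  expect_equal(res$chrom_class,
               list(nuclear = 0.6, mitochondrial = 0.3, rRNA = 0.1))
  expect_equal(sum(unlist(res$biotype)), 1)
  expect_equal(res$biotype$protein_coding, 0.9)

  # single biotype present -> fraction 1
  one <- composition(toy_counts(matrix(7, 1, dimnames = list("g1", "s1"))), "s1")
  expect_equal(one$biotype$protein_coding, 1)
})

test_that("all-zero families are reported absent, not 0/0", {
  mat <- matrix(c(10, 0), nrow = 2, dimnames = list(c("gI", "gE"), "s1"))
  ann <- endo_annotation(c("gI", "gE"), region_class = c("intronic", "exonic"))
  res <- composition(count_matrix(mat, ann), "s1")
  # no exonic reads -> no biotype family
  expect_true("biotype" %in% res$absent_families)
  expect_null(res$biotype)
  expect_equal(res$region_class$intronic, 1)
})

test_that("read-category fractions come from the pre-tagged tally table", {
  cm <- toy_counts(matrix(5, 1, dimnames = list("g1", "s1")))
  cats <- data.frame(sample_id = "s1",
                     category = c("unique", "multi", "too_short", "unmapped"),
                     reads = c(700, 100, 150, 50), stringsAsFactors = FALSE)
  res <- composition(cm, "s1", categories = cats)
  expect_equal(res$read_category$unique, 0.7)
  expect_equal(sum(unlist(res$read_category)), 1)
  expect_error(composition(cm, "s1", categories = within(cats, reads[1] <- -1)),
               "negative")
})

test_that("composition recovers planted chromosome and biotype weights", {
  prof <- biofluid_profile("ePRP")
  sim <- make_replicates(prof, library_size = 1e6, seed = 19)
  res <- composition(sim$counts, "ePRP_rep1")
  expect_equal(res$chrom_class$mitochondrial, 0.77, tolerance = 0.02 / 0.77)
  for (b in names(prof$biotype_weights)) {
    got <- res$biotype[[b]]
    expect_lt(abs(got - prof$biotype_weights[[b]]), 0.02)
  }
})

test_that("top-n consumption enumerates, saturates and is monotone", {
  mat <- matrix(c(50, 30, 10, 5, 5), nrow = 5, dimnames = list(NULL, "s1"))
  cm <- toy_counts(mat)
  expect_equal(top_n_consumption(cm, "s1", 2), 0.80)
  expect_equal(top_n_consumption(cm, "s1", 5), 1)
  expect_equal(top_n_consumption(cm, "s1", 50), 1)
  # uniform counts: top-1 share is 1/m
  unif <- toy_counts(matrix(rep(10, 4), nrow = 4, dimnames = list(NULL, "s1")))
  expect_equal(top_n_consumption(unif, "s1", 1), 1 / 4)
  fr <- vapply(1:5, function(n) top_n_consumption(cm, "s1", n), 0)
  expect_true(all(diff(fr) >= 0))
  empty <- toy_counts(matrix(0, 1, dimnames = list("g1", "s1")))
  expect_error(top_n_consumption(empty, "s1", 1), "no endogenous reads")
})

test_that("percentile coverage rescales to 100 mean-one bins", {
  expect_equal(percentile_coverage(rep(5, 1000)), rep(1, 100))
  ramp <- percentile_coverage(0:999)
  expect_length(ramp, 100)
  expect_true(all(diff(ramp) > 0))
  expect_equal(mean(ramp), 1)
  # length-100 input: bin identity after normalization
  v <- c(2, rep(1, 98), 4)
  expect_equal(percentile_coverage(v), v / mean(v))
  z <- percentile_coverage(rep(0, 50))
  expect_equal(z, rep(0, 100), ignore_attr = TRUE)
  expect_true(attr(z, "flag_all_zero"))
  short <- percentile_coverage(c(1, 2, 3))
  expect_length(short, 100)
  expect_equal(mean(short), 1)
})

test_that("overlap counts shared/unique genes and the Jaccard index", {
  a <- sprintf("g%d", 1:6)
  res <- overlap(a, sprintf("g%d", 4:9))
  expect_identical(res$shared, 3L)
  expect_identical(res$unique_a, 3L)
  expect_equal(res$jaccard, 3 / 9)
  expect_equal(overlap(a, a)$jaccard, 1)
  expect_equal(overlap(a, sprintf("x%d", 1:3))$jaccard, 0)
  empty <- overlap(character(0), character(0))
  expect_equal(empty$jaccard, 0)
  expect_true(empty$flag_both_empty)
})

test_that("overlap is symmetric up to side swap and tabulates unique-gene counts", {
  mat <- matrix(c(9, 0, 5, 2, 0, 6, 5, 30), nrow = 4,
                dimnames = list(sprintf("g%d", 1:4), c("s1", "s2")))
  cm <- toy_counts(mat)
  sa <- detected_genes(cm, "s1", 2); sb <- detected_genes(cm, "s2", 2)
  ab <- overlap(sa, sb, cm, "s1", "s2")
  ba <- overlap(sb, sa, cm, "s2", "s1")
  expect_equal(ab$jaccard, ba$jaccard)
  expect_identical(ab$unique_a, ba$unique_b)
  expect_identical(ab$unique_gene_abundance$count[ab$unique_gene_abundance$side == "a"],
                   9)
})

test_that("EV-unique genes planted as a low-abundance tail have lower median counts", {
  withr::with_seed(23, {
    shared_mu <- rlnorm(1500, 4, 1)
    fluid <- rpois(1500, shared_mu)
    ev <- rpois(1500, shared_mu)
    ev_unique <- rpois(300, 3) + 1   # low-abundance tail present only in EV
  })
  mat <- rbind(cbind(fluid, ev),
               cbind(rep(0, 300), ev_unique))
  rownames(mat) <- sprintf("g%04d", seq_len(nrow(mat)))
  colnames(mat) <- c("fluid", "ev")
  cm <- toy_counts(mat)
  res <- overlap(detected_genes(cm, "fluid", 4), detected_genes(cm, "ev", 4),
                 cm, "fluid", "ev")
  uniq_ev <- res$unique_gene_abundance$count[res$unique_gene_abundance$side == "b"]
  shared_ids <- intersect(detected_genes(cm, "fluid", 4), detected_genes(cm, "ev", 4))
  expect_lt(median(uniq_ev), median(cm$counts[shared_ids, "ev"]))
})
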