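# Small in-code fixtures shared across test files.

# Annotation for plain endogenous genes.
endo_annotation <- function(ids, biotype = "protein_coding",
                            chrom_class = "nuclear", region_class = "exonic") {
  data.frame(feature_id = ids, feature_class = "endogenous",
             biotype = rep_len(biotype, length(ids)),
             chrom_class = rep_len(chrom_class, length(ids)),
             region_class = rep_len(region_class, length(ids)),
             stringsAsFactors = FALSE)
}

# A count_matrix from a plain matrix of endogenous genes (annotation defaults
# can be overridden per column).
toy_counts <- function(mat, ...) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  count_matrix(mat, endo_annotation(rownames(mat), ...))
}

# A count_matrix holding one spike mix plus optional endogenous filler.
spike_toy_counts <- function(spike_mat, mix = "spike_ercc", endo_mat = NULL) {
  if (is.null(rownames(spike_mat)))
    rownames(spike_mat) <- sprintf("SPK-%02d", seq_len(nrow(spike_mat)))
  if (is.null(colnames(spike_mat)))
    colnames(spike_mat) <- sprintf("s%d", seq_len(ncol(spike_mat)))
  ann <- data.frame(feature_id = rownames(spike_mat), feature_class = mix,
                    biotype = "spike", chrom_class = "spike",
                    region_class = "not_applicable", stringsAsFactors = FALSE)
  mat <- spike_mat
  if (!is.null(endo_mat)) {
    rownames(endo_mat) <- sprintf("g%02d", seq_len(nrow(endo_mat)))
    colnames(endo_mat) <- colnames(spike_mat)
    ann <- rbind(ann, endo_annotation(rownames(endo_mat)))
    mat <- rbind(spike_mat, endo_mat)
  }
  count_matrix(mat, ann)
}

# Independent step-integration oracle for the area left of the empirical CDF:
# integrates x over probability as sum over the sorted sample of
# (distance between consecutive CDF breakpoints) * (mass above), i.e.
# integral of (1 - F(x)) dx from 0 to max(x). Deliberately different route
# from the mean used by alc().
alc_step_oracle <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  breaks <- c(0, xs)
  surv <- 1 - (0:n) / n          # P(X > breaks[i]) just right of each break
  sum(diff(breaks) * surv[seq_len(n)])
}
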