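# Replicate precision (ALC), count-cutoff determination, depth subsampling.

#' Subsample libraries to equal depth without replacement
#'
#' Draws exactly `depth` reads per sample from the observed reads, i.e. a
#' multivariate hypergeometric draw across features (implemented as
#' sequential conditional univariate hypergeometric draws). Column totals of
#' the result equal `depth` exactly, and the draw is deterministic for a
#' given seed. This mirrors read-level subsampling of sequencing libraries to
#' a common depth before comparison.
#'
#' @param counts A `count_matrix`.
#' @param depth Target reads per sample; must not exceed any column total.
#' @param seed Integer seed.
#' @return A `count_matrix` with every column summing to `depth`.
#' @export
subsample_counts <- function(counts, depth, seed) {
  stopifnot(depth > 0)
  k <- counts$counts
  tot <- colSums(k)
  short <- colnames(k)[tot < depth]
  if (length(short)) {
    stop("depth ", depth, " exceeds library total for sample(s): ",
         paste(short, collapse = ", "))
  }
  out <- k
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(k))) {
      out[, j] <- hypergeom_column(k[, j], depth)
    }
  })
  count_matrix(out, counts$annotation)
}

hypergeom_column <- function(k, depth) {
  res <- numeric(length(k))
  remaining_total <- sum(k)
  remaining_depth <- depth
  for (i in seq_along(k)) {
    if (remaining_depth == 0) break
    if (k[i] == 0) next
    if (remaining_total == k[i]) {  # everything left must be drawn from here
      res[i] <- remaining_depth
      break
    }
    d <- stats::rhyper(1L, m = k[i], n = remaining_total - k[i], k = remaining_depth)
    res[i] <- d
    remaining_depth <- remaining_depth - d
    remaining_total <- remaining_total - k[i]
  }
  res
}

#' Convert a log2 value to a linear fold change
#' @param x Log2 units (finite).
#' @return 2^x.
#' @export
log2_to_fold <- function(x) {
  if (any(!is.finite(x))) stop("log2_to_fold: non-finite input")
  2^x
}

#' Replicate precision: absolute log2 ratios and the ALC
#'
#' Restricts to endogenous genes detected (count >= `cutoff`) in BOTH
#' replicates, computes the absolute log2 ratio per gene, and summarises the
#' empirical cumulative distribution by the area left of the curve (ALC).
#' The ALC equals the arithmetic mean of the absolute log2 ratios; lower
#' values indicate better replication. The median absolute log2 ratio (the
#' value below which half of the genes fall) and the Pearson correlation of
#' log2 counts over retained genes are reported alongside.
#'
#' @param counts A `count_matrix`.
#' @param sample_a,sample_b Replicate sample ids.
#' @param cutoff Detection cutoff in counts (default 4), applied per sample.
#' @return `precision_result` with `ratios` table (feature_id, count_a,
#'   count_b, abs_log2_ratio), `alc`, `median_ratio`, `pearson_r`,
#'   `n_retained`.
#' @export
replicate_ratios <- function(counts, sample_a, sample_b, cutoff = 4) {
  ka <- get_sample_column(counts, sample_a)
  kb <- get_sample_column(counts, sample_b)
  endo <- endogenous_ids(counts)
  ka <- ka[endo]; kb <- kb[endo]
  keep <- ka >= cutoff & kb >= cutoff
  if (!any(keep)) stop("no retained genes at cutoff ", cutoff)
  r <- abs(log2(ka[keep] / kb[keep]))
  new_result(list(
    ratios = data.frame(feature_id = endo[keep], count_a = ka[keep],
                        count_b = kb[keep], abs_log2_ratio = r,
                        stringsAsFactors = FALSE, row.names = NULL),
    sample_a = sample_a, sample_b = sample_b, cutoff = cutoff,
    alc = alc(r),
    median_ratio = stats::median(r),
    pearson_r = if (stats::sd(ka[keep]) == 0 || stats::sd(kb[keep]) == 0) {
      if (all(ka[keep] == kb[keep])) 1 else NA_real_   # identical constants
    } else {
      stats::cor(log2(ka[keep]), log2(kb[keep]))
    },
    n_retained = sum(keep)
  ), "precision_result")
}

#' Area left of the cumulative curve of a non-negative sample
#'
#' Exact area between the empirical CDF of `x` and the vertical axis,
#' integrated over probability: sum of x_(i) * (1/n), i.e. the arithmetic
#' mean. Kept as a named function because it is the headline precision
#' statistic.
#'
#' @param x Non-negative finite values (absolute log2 ratios).
#' @return ALC in the units of `x`.
#' @export
alc <- function(x) {
  if (!length(x)) stop("alc: empty input")
  if (any(!is.finite(x)) || any(x < 0)) stop("alc: values must be finite and >= 0")
  mean(x)
}

#' Single-positive analysis to choose a count cutoff
#'
#' A single positive is a gene with a nonzero count in exactly one of two
#' technical replicates: noise by construction, since a truly present gene
#' should appear in both. For each candidate cutoff c, the removed fraction
#' is the share of single positives whose nonzero count is < c (they would be
#' filtered by requiring >= c). The chosen cutoff is the smallest c whose
#' removed fraction reaches `removal_target`. The fraction of double
#' positives that the same rule would discard (count < c in at least one
#' replicate) is reported as the cost side.
#'
#' @param counts A `count_matrix`.
#' @param sample_a,sample_b Replicate sample ids.
#' @param cutoffs Candidate integer cutoffs, default 1:10.
#' @param removal_target Required removed fraction of single positives,
#'   default 0.95.
#' @return `filter_report` with `per_cutoff` table, `chosen_cutoff`,
#'   `n_single_positive`, `n_double_positive`, `flag_no_single_positives`.
#' @export
single_positive_analysis <- function(counts, sample_a, sample_b,
                                     cutoffs = 1:10, removal_target = 0.95) {
  stopifnot(all(cutoffs > 0), removal_target > 0, removal_target < 1)
  cutoffs <- sort(unique(as.integer(cutoffs)))
  endo <- endogenous_ids(counts)
  ka <- get_sample_column(counts, sample_a)[endo]
  kb <- get_sample_column(counts, sample_b)[endo]
  single <- xor(ka > 0, kb > 0)
  double <- ka > 0 & kb > 0
  sp_val <- pmax(ka, kb)[single]          # the nonzero count of each single positive
  dp_min <- pmin(ka, kb)[double]

  per <- data.frame(
    cutoff = cutoffs,
    removed_single_positive_fraction = vapply(
      cutoffs, function(c) if (length(sp_val)) mean(sp_val < c) else NA_real_, 0),
    removed_double_positive_fraction = vapply(
      cutoffs, function(c) if (length(dp_min)) mean(dp_min < c) else NA_real_, 0))

  no_sp <- !length(sp_val)
  chosen <- if (no_sp) {
    min(cutoffs)
  } else {
    hit <- which(per$removed_single_positive_fraction >= removal_target)
    if (length(hit)) cutoffs[hit[1]] else NA_integer_
  }
  new_result(list(per_cutoff = per, chosen_cutoff = chosen,
                  sample_a = sample_a, sample_b = sample_b,
                  removal_target = removal_target,
                  n_single_positive = length(sp_val),
                  n_double_positive = length(dp_min),
                  flag_no_single_positives = no_sp),
             "filter_report")
}

#' Genes detected in a sample at a count cutoff
#' @param counts A `count_matrix`.
#' @param sample Sample id.
#' @param cutoff Minimum count for detection (default 4); spikes excluded.
#' @return Character vector of detected endogenous feature ids.
#' @export
detected_genes <- function(counts, sample, cutoff = 4) {
  k <- get_sample_column(counts, sample)
  endo <- endogenous_ids(counts)
  endo[k[endo] >= cutoff]
}
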