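# Composition summaries, top-N read consumption, gene-body coverage profile,
# and gene-detection overlap between samples.

frac_family <- function(values, labels) {
  s <- tapply(values, factor(labels, levels = unique(labels)), sum)
  s <- s[!is.na(s)]
  tot <- sum(s)
  if (tot == 0) return(NULL)
  as.list(s / tot)
}

#' Composition of a sample's reads
#'
#' Summarises, per sample, the fraction families used for sequencing QC:
#' read mapping category (unique / multi / too_short / unmapped — taken from a
#' pre-tagged tally table produced upstream of this package, never from
#' alignments), chromosome origin of endogenous reads (nuclear /
#' mitochondrial / rRNA), region class (exonic / intronic / intergenic), and
#' the biotype breakdown of exonic endogenous reads. Each family sums to 1;
#' families with a zero total are reported as absent rather than 0/0.
#'
#' @param counts A `count_matrix`.
#' @param sample Sample id.
#' @param categories Optional long data.frame (sample_id, category, reads)
#'   with upstream read-mapping tallies.
#' @return `composition_result` with named fraction lists `read_category`,
#'   `chrom_class`, `region_class`, `biotype`, plus `absent_families`.
#' @export
composition <- function(counts, sample, categories = NULL) {
  k <- get_sample_column(counts, sample)
  ann <- counts$annotation
  endo <- ann$feature_class == "endogenous"

  read_category <- NULL
  if (!is.null(categories)) {
    cc <- categories[categories$sample_id == sample, , drop = FALSE]
    if (any(cc$reads < 0)) stop("negative read-category tally")
    if (nrow(cc)) read_category <- frac_family(cc$reads, cc$category)
  }
  chrom_class <- frac_family(k[endo], ann$chrom_class[endo])
  region_class <- frac_family(k[endo], ann$region_class[endo])
  exonic <- endo & ann$region_class == "exonic"
  biotype <- frac_family(k[exonic], ann$biotype[exonic])

  fams <- list(read_category = read_category, chrom_class = chrom_class,
               region_class = region_class, biotype = biotype)
  absent <- names(fams)[vapply(fams, is.null, TRUE)]
  new_result(c(fams[!vapply(fams, is.null, TRUE)],
               list(sample = sample,
                    absent_families = if (length(absent)) absent else "none")),
             "composition_result")
}

#' Fraction of reads consumed by the n most abundant genes
#'
#' Spikes are excluded; ties in abundance are broken by feature id so the
#' result is deterministic.
#'
#' @param counts A `count_matrix`.
#' @param sample Sample id.
#' @param n Number of top genes (>= 1).
#' @return Fraction in (0, 1].
#' @export
top_n_consumption <- function(counts, sample, n) {
  stopifnot(n >= 1)
  endo <- endogenous_ids(counts)
  k <- get_sample_column(counts, sample)[endo]
  tot <- sum(k)
  if (tot == 0) stop("sample ", sample, " has no endogenous reads")
  ord <- order(-k, endo)
  sum(k[ord[seq_len(min(n, length(k)))]]) / tot
}

#' Gene-body coverage per percentile
#'
#' Rescales a per-base coverage vector onto 100 equal-width bins of the gene
#' body, averages coverage within each bin, and normalizes the profile to
#' mean 1 (so a perfectly uniform coverage maps to all ones). Vectors shorter
#' than 100 bases are linearly interpolated onto the percentile grid. An
#' all-zero input returns all zeros with attribute `flag_all_zero`.
#'
#' @param per_base_coverage Non-negative numeric vector, length >= 1.
#' @return Numeric vector of length 100 with mean 1 (or all zeros, flagged).
#' @export
percentile_coverage <- function(per_base_coverage) {
  v <- per_base_coverage
  if (!length(v)) stop("empty coverage vector")
  if (any(!is.finite(v)) || any(v < 0)) stop("coverage must be finite and >= 0")
  if (all(v == 0)) return(structure(rep(0, 100), flag_all_zero = TRUE))
  L <- length(v)
  if (L >= 100) {
    bin <- floor((seq_len(L) - 1) * 100 / L) + 1
    prof <- as.numeric(tapply(v, bin, mean))
  } else {
    prof <- stats::approx(x = (seq_len(L) - 0.5) / L, y = v,
                          xout = (seq_len(100) - 0.5) / 100, rule = 2)$y
  }
  prof / mean(prof)
}

#' Detected-gene overlap between two samples
#'
#' Counts shared and sample-unique detected genes and the Jaccard index
#' J = shared / (shared + unique_a + unique_b). When a `count_matrix` and the
#' two sample ids are supplied, the counts of the unique genes (in their own
#' sample) are tabulated, supporting the observation that genes unique to one
#' side are typically low-abundant.
#'
#' @param set_a,set_b Character vectors of detected feature ids (e.g. from
#'   [detected_genes()]).
#' @param counts Optional `count_matrix` for the abundance table.
#' @param sample_a,sample_b Sample ids matching `set_a`/`set_b` (required with
#'   `counts`).
#' @return `overlap_result` with `shared`, `unique_a`, `unique_b`, `jaccard`,
#'   `flag_both_empty` and (optionally) `unique_gene_abundance`.
#' @export
overlap <- function(set_a, set_b, counts = NULL, sample_a = NULL, sample_b = NULL) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  shared <- length(intersect(set_a, set_b))
  ua <- setdiff(set_a, set_b); ub <- setdiff(set_b, set_a)
  denom <- shared + length(ua) + length(ub)
  both_empty <- denom == 0
  j <- if (both_empty) 0 else shared / denom

  abun <- NULL
  if (!is.null(counts)) {
    if (is.null(sample_a) || is.null(sample_b))
      stop("sample_a and sample_b required with counts")
    abun <- rbind(
      data.frame(feature_id = ua, side = rep("a", length(ua)),
                 count = unname(get_sample_column(counts, sample_a)[ua]),
                 stringsAsFactors = FALSE),
      data.frame(feature_id = ub, side = rep("b", length(ub)),
                 count = unname(get_sample_column(counts, sample_b)[ub]),
                 stringsAsFactors = FALSE))
  }
  new_result(list(shared = shared, unique_a = length(ua), unique_b = length(ub),
                  jaccard = j, flag_both_empty = both_empty,
                  unique_gene_abundance = abun),
             "overlap_result")
}
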