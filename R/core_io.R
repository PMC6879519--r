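# Data model and file I/O shared by every analysis stage.

FEATURE_CLASSES <- c("endogenous", "spike_ercc", "spike_sequin")
BIOTYPES <- c("protein_coding", "lncRNA", "miscRNA", "pseudogene", "other", "spike")
CHROM_CLASSES <- c("nuclear", "mitochondrial", "rRNA", "spike")
REGION_CLASSES <- c("exonic", "intronic", "intergenic", "not_applicable")

#' Construct a validated count matrix
#'
#' Bundles a feature-by-sample table of non-negative integer counts with a
#' feature annotation table. The annotation assigns each feature a class
#' (endogenous gene or member of one of the two spike-in panels), a biotype,
#' a chromosome class (nuclear / mitochondrial / rRNA) and a region class
#' (exonic / intronic / intergenic). Every statistic in the package consumes
#' this container.
#'
#' @param counts Numeric matrix (or coercible) of non-negative integer counts,
#'   features in rows (rownames = feature ids), samples in columns.
#' @param annotation data.frame with columns `feature_id`, `feature_class`,
#'   `biotype`, `chrom_class` and optionally `region_class` (defaults to
#'   `"not_applicable"`). Must cover every feature in `counts`; extra rows are
#'   dropped with a warning.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `annotation` (data.frame aligned to the rows).
#' @export
count_matrix <- function(counts, annotation) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicated feature ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids in counts")
  if (!is.numeric(counts) || anyNA(counts)) stop("counts must be numeric and complete")
  if (any(counts < 0)) stop("negative count in matrix")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("non-integer count in matrix")
  storage.mode(counts) <- "double"  # doubles hold integer counts > .Machine$integer.max
  counts <- round(counts)

  need <- c("feature_id", "feature_class", "biotype", "chrom_class")
  if (!all(need %in% names(annotation))) {
    stop("annotation must contain columns: ", paste(need, collapse = ", "))
  }
  if (!"region_class" %in% names(annotation)) annotation$region_class <- "not_applicable"
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (anyDuplicated(annotation$feature_id)) stop("duplicated feature ids in annotation")

  missing <- setdiff(rownames(counts), annotation$feature_id)
  if (length(missing)) {
    stop("feature(s) in counts absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  extra <- setdiff(annotation$feature_id, rownames(counts))
  if (length(extra)) {
    warning(length(extra), " annotation row(s) without counts ignored")
  }
  annotation <- annotation[match(rownames(counts), annotation$feature_id), , drop = FALSE]
  rownames(annotation) <- NULL

  chk <- function(x, allowed, what) {
    bad <- setdiff(unique(x), allowed)
    if (length(bad)) stop("invalid ", what, ": ", paste(bad, collapse = ", "))
  }
  chk(annotation$feature_class, FEATURE_CLASSES, "feature_class")
  chk(annotation$biotype, BIOTYPES, "biotype")
  chk(annotation$chrom_class, CHROM_CLASSES, "chrom_class")
  chk(annotation$region_class, REGION_CLASSES, "region_class")

  is_spike <- annotation$feature_class %in% c("spike_ercc", "spike_sequin")
  if (any(is_spike & (annotation$biotype != "spike" | annotation$chrom_class != "spike"))) {
    stop("spike features must have biotype 'spike' and chrom_class 'spike'")
  }
  if (any(!is_spike & (annotation$biotype == "spike" | annotation$chrom_class == "spike"))) {
    stop("endogenous features may not carry the 'spike' biotype or chrom_class")
  }

  structure(list(counts = counts, annotation = annotation), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$annotation$feature_class)
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Sample and feature id accessors
#' @param x A `count_matrix`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname sample_ids
#' @export
feature_ids <- function(x) rownames(x$counts)

#' Feature ids of one class
#' @param x A `count_matrix`.
#' @param mix `"ercc"`, `"sequin"` or `"both"`.
#' @return Character vector of feature ids.
#' @export
spike_ids <- function(x, mix = c("both", "ercc", "sequin")) {
  mix <- match.arg(mix)
  cls <- switch(mix, both = c("spike_ercc", "spike_sequin"),
                ercc = "spike_ercc", sequin = "spike_sequin")
  feature_ids(x)[x$annotation$feature_class %in% cls]
}

#' @rdname spike_ids
#' @export
endogenous_ids <- function(x) {
  feature_ids(x)[x$annotation$feature_class == "endogenous"]
}

#' Subset a count matrix
#' @param x A `count_matrix`.
#' @param features,samples Character vectors of ids to keep (NULL keeps all).
#' @return A `count_matrix`.
#' @export
subset_counts <- function(x, features = NULL, samples = NULL) {
  if (is.null(features)) features <- feature_ids(x)
  if (is.null(samples)) samples <- sample_ids(x)
  bad <- setdiff(samples, sample_ids(x))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(features, feature_ids(x))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  count_matrix(x$counts[features, samples, drop = FALSE],
               x$annotation[x$annotation$feature_id %in% features, , drop = FALSE])
}

get_sample_column <- function(x, sample) {
  if (!sample %in% sample_ids(x)) stop("unknown sample: ", sample)
  stats::setNames(x$counts[, sample], rownames(x$counts))
}

#' Read a count matrix and its annotation sidecar
#'
#' Both files are tab-separated with a header row. The count file has feature
#' ids in the first column and one column per sample; the annotation file
#' carries the columns described in [count_matrix()].
#'
#' @param path Count table path.
#' @param annotation_path Feature annotation table path.
#' @return A validated `count_matrix`.
#' @export
read_count_matrix <- function(path, annotation_path) {
  for (p in c(path, annotation_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count table needs a feature id column plus >= 1 sample")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  annotation <- utils::read.delim(annotation_path, check.names = FALSE,
                                  stringsAsFactors = FALSE)
  count_matrix(counts, annotation)
}

#' Write a count matrix (and optionally its annotation) as TSV
#' @param x A `count_matrix`.
#' @param path Count table destination.
#' @param annotation_path Optional annotation destination.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, path, annotation_path = NULL) {
  tab <- data.frame(feature_id = feature_ids(x), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    utils::write.table(x$annotation, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}

#' Read sample metadata (TSV or YAML)
#'
#' Expected fields per sample: `sample_id`, `fluid`, `replicate_group`,
#' `replicate_level` (`rna_isolation` or `library_prep`), `input_volume`
#' (microlitres of original biofluid), `ercc_dilution` (dimensionless, in
#' (0, 1]) and optionally `sequin_dilution`.
#'
#' @param path `.tsv`, `.yaml` or `.yml` file.
#' @return data.frame, one row per sample.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    meta <- do.call(rbind, lapply(recs, function(r) {
      as.data.frame(r[lengths(r) == 1], stringsAsFactors = FALSE)
    }))
  } else {
    meta <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  validate_sample_meta(meta)
}

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "fluid", "replicate_group", "input_volume", "ercc_dilution")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!"replicate_level" %in% names(meta)) meta$replicate_level <- "library_prep"
  if (!"sequin_dilution" %in% names(meta)) meta$sequin_dilution <- NA_real_
  if (any(meta$input_volume <= 0)) stop("input_volume must be > 0")
  dil <- c(meta$ercc_dilution, meta$sequin_dilution[!is.na(meta$sequin_dilution)])
  if (any(dil <= 0 | dil > 1)) stop("dilution factors must lie in (0, 1]")
  bad <- setdiff(meta$replicate_level, c("rna_isolation", "library_prep"))
  if (length(bad)) stop("invalid replicate_level: ", paste(bad, collapse = ", "))
  meta
}

#' Read a spike panel table
#' @param path TSV with columns `spike_id`, `mix` (ERCC/Sequin) and
#'   `stock_concentration` (relative abundance units, > 0).
#' @return data.frame of class `spike_panel`.
#' @export
read_spike_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  spike_panel(tab$spike_id, tab$mix, tab$stock_concentration)
}

#' Construct a spike panel
#' @param spike_id Character ids, unique within a mix.
#' @param mix `"ERCC"` or `"Sequin"` (recycled).
#' @param stock_concentration Positive relative concentrations.
#' @return data.frame of class `spike_panel`.
#' @export
spike_panel <- function(spike_id, mix, stock_concentration) {
  tab <- data.frame(spike_id = as.character(spike_id),
                    mix = rep_len(mix, length(spike_id)),
                    stock_concentration = stock_concentration,
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(tab$mix), c("ERCC", "Sequin"))
  if (length(bad)) stop("invalid mix: ", paste(bad, collapse = ", "))
  if (any(tab$stock_concentration <= 0)) stop("stock_concentration must be > 0")
  for (m in unique(tab$mix)) {
    if (anyDuplicated(tab$spike_id[tab$mix == m])) stop("duplicated spike ids within mix ", m)
  }
  class(tab) <- c("spike_panel", "data.frame")
  tab
}

#' Analysis configuration
#'
#' Central defaults used across the pipeline: the detection cutoff (counts
#' needed to call a gene present), the depth libraries are subsampled to
#' before comparison, the minimum mean spike count for reliable fold-change
#' measurement, the log2 deviation threshold used in trueness summaries, the
#' removal target for the single-positive cutoff scan, and the random seed.
#'
#' @param detection_cutoff Integer, default 4 counts.
#' @param subsample_depth Integer reads per library, default 1e6; `NULL`
#'   disables subsampling.
#' @param trueness_min_count Integer, default 10 counts.
#' @param deviation_threshold Log2 units, default 0.5.
#' @param removal_target Fraction in (0,1), default 0.95.
#' @param random_seed Integer seed.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(detection_cutoff = 4L, subsample_depth = 1e6,
                            trueness_min_count = 10L, deviation_threshold = 0.5,
                            removal_target = 0.95, random_seed = 1L) {
  stopifnot(detection_cutoff > 0, trueness_min_count > 0, deviation_threshold > 0,
            removal_target > 0, removal_target < 1)
  if (!is.null(subsample_depth)) stopifnot(subsample_depth > 0)
  structure(list(detection_cutoff = as.integer(detection_cutoff),
                 subsample_depth = subsample_depth,
                 trueness_min_count = as.integer(trueness_min_count),
                 deviation_threshold = deviation_threshold,
                 removal_target = removal_target,
                 random_seed = as.integer(random_seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or TSV
#' @param path Config file; keys as in [analysis_config()].
#' @return `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    vals <- as.list(tab$value)
    names(vals) <- tab$key
    vals <- lapply(vals, function(v) if (grepl("^[0-9.eE+-]+$", v)) as.numeric(v) else v)
  }
  do.call(analysis_config, vals[intersect(names(vals), names(formals(analysis_config)))])
}

# ---- stage reports -------------------------------------------------------

new_result <- function(x, class) structure(x, class = c(class, "exrna_result"))

#' Write a stage result to disk
#'
#' Every data.frame element of the result becomes a TSV named after the
#' element; every scalar or short named vector goes into `summary.json`.
#' Integers round-trip exactly and reals to at least 12 significant digits,
#' so [read_report()] reproduces the values.
#'
#' @param result Any stage result (`trueness_result`, `precision_result`,
#'   `overlap_result`, `filter_report`, `composition_result`,
#'   `concentration_result`, ...).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) UseMethod("write_report")

#' @export
write_report.default <- function(result, dir) {
  stop("write_report: unsupported result of class ", paste(class(result), collapse = "/"))
}

#' @export
write_report.exrna_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  paths <- character(0)
  summ <- list(result_class = class(result)[1])
  for (nm in names(result)) {
    el <- result[[nm]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write_tsv_precise(el, p)
      paths <- c(paths, p)
    } else if (is.null(el)) {
      next
    } else if (is.atomic(el) || is.list(el)) {
      summ[[nm]] <- el
    }
  }
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, p))
}

write_tsv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- vapply(out[[j]], format_real, "")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

format_real <- function(v) {
  if (is.na(v)) return("NA")
  if (v == round(v) && abs(v) < 1e15) return(format(v, scientific = FALSE))
  format(v, digits = 15, scientific = TRUE)
}

#' Read back a stage report written by [write_report()]
#' @param dir Report directory.
#' @return List with `tables` (named list of data.frames) and `summary`.
#' @export
read_report <- function(dir) {
  if (!dir.exists(dir)) stop("no such report directory: ", dir)
  tsvs <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  tables <- lapply(tsvs, utils::read.delim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(tables) <- sub("\\.tsv$", "", basename(tsvs))
  sj <- file.path(dir, "summary.json")
  summary <- if (file.exists(sj)) jsonlite::read_json(sj, simplifyVector = TRUE) else list()
  list(tables = tables, summary = summary)
}
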