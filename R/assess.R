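# One-shot assessment pipeline: runs every applicable stage on a dataset and
# emits a combined, byte-reproducible report bundle.

fingerprint <- function(obj) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full performance assessment on one dataset
#'
#' Applies, in order: equal-depth subsampling (when configured), spike
#' titration trueness (needs a spike design and at least one spike panel in
#' the counts), relative concentration (needs sample metadata), replicate
#' precision and the single-positive cutoff scan (need a replicate-pair
#' table), per-sample composition, and detected-gene overlap per pair.
#' Stages whose required inputs are absent are skipped with a recorded
#' reason; stages that error are caught and recorded so the bundle is marked
#' partial. A contradictory configuration (subsampling depth larger than the
#' smallest library) fails before any stage runs. Reruns with the same
#' inputs, configuration and seed produce byte-identical output bundles.
#'
#' @param counts A `count_matrix`.
#' @param meta Optional sample metadata (see [read_sample_meta()]).
#' @param design Optional `spike_design`.
#' @param pairs Optional data.frame (sample_a, sample_b) of replicate pairs.
#' @param categories Optional read-category tally table for [composition()].
#' @param config [analysis_config()].
#' @param out_dir Optional directory; when given the bundle is written there.
#' @return `assess_bundle`: list with `stages`, `skipped`, `errors`,
#'   `manifest`.
#' @export
assess <- function(counts, meta = NULL, design = NULL, pairs = NULL,
                   categories = NULL, config = analysis_config(),
                   out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"), inherits(config, "analysis_config"))

  if (!is.null(config$subsample_depth)) {
    tot <- colSums(counts$counts)
    if (any(tot < config$subsample_depth)) {
      stop("contradictory config: subsample_depth ", config$subsample_depth,
           " exceeds smallest library (", min(tot), ", sample ",
           colnames(counts$counts)[which.min(tot)], ")")
    }
  }

  manifest <- list(
    tool = "exrnaperf", version = as.character(utils::packageVersion("exrnaperf")),
    seed = config$random_seed,
    config = unclass(config),
    inputs = list(counts = fingerprint(counts),
                  meta = if (is.null(meta)) NULL else fingerprint(meta),
                  design = if (is.null(design)) NULL else fingerprint(design),
                  pairs = if (is.null(pairs)) NULL else fingerprint(pairs)))

  work <- counts
  if (!is.null(config$subsample_depth)) {
    work <- subsample_counts(counts, config$subsample_depth, config$random_seed)
  }

  stages <- list(); skipped <- list(); errors <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      message("stage '", name, "' failed: ", conditionMessage(res))
    } else {
      stages[[name]] <<- res
    }
  }

  # trueness: per spike mix present in both counts and design
  if (is.null(design)) {
    skipped$trueness <- "no spike design provided"
  } else {
    present <- c(ERCC = length(spike_ids(work, "ercc")) > 0,
                 Sequin = length(spike_ids(work, "sequin")) > 0)
    mixes <- names(present)[present]
    if (!length(mixes)) {
      skipped$trueness <- "no spike features in counts"
    } else {
      if (!all(present)) {
        message("trueness: running ", paste(mixes, collapse = "+"),
                " only (other mix absent from counts)")
      }
      mix_arg <- if (length(mixes) == 2) "both" else mixes
      run_stage("trueness", trueness(
        work, design, mix = mix_arg, pairs = "reference", depth = NULL,
        seed = config$random_seed, min_count = config$trueness_min_count,
        thresholds = unique(c(config$deviation_threshold, 1))))
    }
  }

  if (is.null(meta)) {
    skipped$concentration <- "no sample metadata provided"
  } else {
    run_stage("concentration", concentration_profile(work, meta))
  }

  if (is.null(pairs) || !nrow(pairs)) {
    skipped$precision <- "no replicate pairs provided"
    skipped$filter_scan <- "no replicate pairs provided"
    skipped$overlap <- "no replicate pairs provided"
  } else {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$sample_a[i]; b <- pairs$sample_b[i]
      tag <- paste0(a, "_vs_", b)
      run_stage(paste0("precision.", tag),
                replicate_ratios(work, a, b, config$detection_cutoff))
      run_stage(paste0("filter_scan.", tag),
                single_positive_analysis(work, a, b, cutoffs = 1:10,
                                         removal_target = config$removal_target))
      run_stage(paste0("overlap.", tag), overlap(
        detected_genes(work, a, config$detection_cutoff),
        detected_genes(work, b, config$detection_cutoff),
        counts = work, sample_a = a, sample_b = b))
    }
  }

  for (s in sample_ids(work)) {
    run_stage(paste0("composition.", s), composition(work, s, categories))
  }

  bundle <- structure(list(stages = stages, skipped = skipped, errors = errors,
                           manifest = manifest),
                      class = "assess_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write an assessment bundle to disk
#'
#' One subdirectory per stage result (TSV tables + summary.json, via
#' [write_report()]) plus a combined `assess.json` holding the run manifest,
#' per-stage scalar summaries, skip reasons and errors. `partial` is true iff
#' any stage errored.
#'
#' @param bundle An `assess_bundle`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  for (nm in names(bundle$stages)) {
    res <- bundle$stages[[nm]]
    write_report(res, file.path(dir, gsub("[^A-Za-z0-9._-]", "_", nm)))
    summaries[[nm]] <- Filter(function(e) is.atomic(e) && length(e) == 1,
                              unclass(res))
  }
  combined <- list(manifest = bundle$manifest,
                   partial = length(bundle$errors) > 0,
                   errors = bundle$errors,
                   skipped = bundle$skipped,
                   stage_summaries = summaries)
  jsonlite::write_json(combined, file.path(dir, "assess.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.assess_bundle <- function(x, ...) {
  cat("assess_bundle:", length(x$stages), "stage result(s),",
      length(x$skipped), "skipped,", length(x$errors), "error(s)\n")
  if (length(x$errors)) {
    for (nm in names(x$errors)) cat("  ERROR", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}
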