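# Relative RNA concentration from the endogenous:spike read ratio.

#' Endogenous-to-spike read ratio of one sample
#'
#' The same amount of spike RNA added to every sample competes with the
#' endogenous RNA for reads, so the ratio of endogenous to spike reads is a
#' relative measure of RNA amount: a higher ratio means more endogenous RNA.
#'
#' @param counts A `count_matrix`.
#' @param sample Sample id.
#' @param mix Spike mix used as denominator; default `"ercc"` (the mix added
#'   to the isolation eluate), `"sequin"` or `"both"`.
#' @return R = sum(endogenous counts) / sum(spike counts). Zero endogenous
#'   reads give 0; zero spike reads are an error (failed spike recovery).
#' @export
endo_spike_ratio <- function(counts, sample, mix = "ercc") {
  k <- get_sample_column(counts, sample)
  spike_sum <- sum(k[spike_ids(counts, mix)])
  if (spike_sum == 0) stop("no spike reads in sample ", sample)
  sum(k[endogenous_ids(counts)]) / spike_sum
}

#' Relative RNA concentration per millilitre of biofluid
#'
#' Corrects the endogenous:spike ratio for the amount of spike RNA added
#' (represented by its dilution factor; the same stock is assumed across
#' compared samples) and for the original biofluid input volume:
#' rho = R * dilution / volume_ml, in arbitrary units per ml.
#'
#' @param ratio Endogenous:spike read ratio R.
#' @param input_volume Original biofluid volume in microlitres.
#' @param ercc_dilution Spike dilution factor in (0, 1].
#' @return rho, arbitrary units per ml.
#' @export
relative_concentration <- function(ratio, input_volume, ercc_dilution) {
  if (is.null(input_volume) || is.na(input_volume) || input_volume <= 0)
    stop("input_volume (microlitres) must be > 0")
  if (is.null(ercc_dilution) || is.na(ercc_dilution) || ercc_dilution <= 0)
    stop("ercc_dilution must be set and > 0")
  ratio * ercc_dilution / (input_volume / 1000)
}

#' Relative concentration profile across samples
#'
#' Applies [endo_spike_ratio()] and [relative_concentration()] to every sample
#' in the metadata table and scales to a reference sample (the reference gets
#' 1.0).
#'
#' @param counts A `count_matrix`.
#' @param meta Sample metadata (see [read_sample_meta()]); only its samples
#'   are profiled.
#' @param reference Sample id scaled to 1; default the first metadata row.
#' @param mix Spike mix, default `"ercc"`.
#' @return `concentration_result` with `per_sample` table (sample_id,
#'   endo_reads, spike_reads, ratio, ercc_dilution, input_volume,
#'   relative_concentration, scaled_to_reference) and `reference`.
#' @export
concentration_profile <- function(counts, meta, reference = NULL, mix = "ercc") {
  meta <- validate_sample_meta(meta)
  miss <- setdiff(meta$sample_id, sample_ids(counts))
  if (length(miss)) stop("metadata sample(s) missing from counts: ",
                         paste(miss, collapse = ", "))
  if (is.null(reference)) reference <- meta$sample_id[1]
  if (!reference %in% meta$sample_id) stop("reference sample not in metadata")

  endo <- endogenous_ids(counts); spk <- spike_ids(counts, mix)
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    s <- meta$sample_id[i]
    k <- get_sample_column(counts, s)
    er <- sum(k[endo]); sr <- sum(k[spk])
    R <- if (sr == 0) NA_real_ else er / sr
    rho <- if (is.na(R)) NA_real_ else
      relative_concentration(R, meta$input_volume[i], meta$ercc_dilution[i])
    data.frame(sample_id = s, endo_reads = er, spike_reads = sr, ratio = R,
               ercc_dilution = meta$ercc_dilution[i],
               input_volume = meta$input_volume[i],
               relative_concentration = rho, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (any(per$spike_reads == 0)) {
    stop("no spike reads in sample(s): ",
         paste(per$sample_id[per$spike_reads == 0], collapse = ", "))
  }
  rho_ref <- per$relative_concentration[per$sample_id == reference]
  per$scaled_to_reference <- per$relative_concentration / rho_ref
  new_result(list(per_sample = per, reference = reference, mix = mix),
             "concentration_result")
}

#' Fold difference in relative concentration between two samples
#' @param result A `concentration_result`.
#' @param sample_a,sample_b Sample ids in the result.
#' @return rho_a / rho_b.
#' @export
fold_difference <- function(result, sample_a, sample_b) {
  per <- result$per_sample
  get <- function(s) {
    i <- match(s, per$sample_id)
    if (is.na(i)) stop("sample not in concentration result: ", s)
    per$relative_concentration[i]
  }
  rb <- get(sample_b)
  if (rb == 0) stop("reference concentration is zero for sample ", sample_b)
  get(sample_a) / rb
}
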