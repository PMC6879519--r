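# Synthetic count-data generator: spike panels, opposing-dilution titration
# matrices, and replicate biofluid matrices with planted truth, so every
# analysis stage is testable without deposited sequencing data.

#' Biofluid expression profile presets
#'
#' Describes the generative model of one biofluid: number of expressed genes,
#' read-mass weights over biotypes, chromosome classes and region classes,
#' a log-normal gene-abundance shape, the rate at which low-count
#' single-positive noise genes are injected, and negative-binomial
#' overdispersion per replicate level (RNA-isolation replicates are more
#' dispersed than library-prep replicates). Presets: `"ePRP"` (mitochondria-
#' heavy platelet-rich plasma, mito weight 0.77), `"ePFP"` (platelet-free
#' plasma, mito weight 0.26) and `"urine"` (gene-rich, nuclear-dominated).
#'
#' @param name Preset name or a label for a custom profile.
#' @param n_genes,biotype_weights,chrom_weights,region_weights,abundance_meanlog,abundance_sdlog,single_positive_rate,dispersion
#'   Override any preset field; `dispersion` is a named list with elements
#'   `rna_isolation` and `library_prep` (>= 0, 0 = Poisson).
#' @return List of class `biofluid_profile`.
#' @export
biofluid_profile <- function(name, n_genes = NULL, biotype_weights = NULL,
                             chrom_weights = NULL, region_weights = NULL,
                             abundance_meanlog = NULL, abundance_sdlog = NULL,
                             single_positive_rate = NULL, dispersion = NULL) {
  presets <- list(
    ePRP = list(n_genes = 5000,
                chrom_weights = c(nuclear = 0.20, mitochondrial = 0.77, rRNA = 0.03),
                biotype_weights = c(protein_coding = 0.80, lncRNA = 0.08,
                                    miscRNA = 0.05, pseudogene = 0.04, other = 0.03)),
    ePFP = list(n_genes = 6000,
                chrom_weights = c(nuclear = 0.70, mitochondrial = 0.26, rRNA = 0.04),
                biotype_weights = c(protein_coding = 0.75, lncRNA = 0.10,
                                    miscRNA = 0.06, pseudogene = 0.05, other = 0.04)),
    urine = list(n_genes = 12000,
                 chrom_weights = c(nuclear = 0.90, mitochondrial = 0.05, rRNA = 0.05),
                 biotype_weights = c(protein_coding = 0.70, lncRNA = 0.12,
                                     miscRNA = 0.08, pseudogene = 0.06, other = 0.04)))
  base <- if (name %in% names(presets)) presets[[name]] else list(
    n_genes = 5000,
    chrom_weights = c(nuclear = 0.7, mitochondrial = 0.25, rRNA = 0.05),
    biotype_weights = c(protein_coding = 0.75, lncRNA = 0.10, miscRNA = 0.06,
                        pseudogene = 0.05, other = 0.04))
  p <- list(
    name = name,
    n_genes = if (is.null(n_genes)) base$n_genes else as.integer(n_genes),
    biotype_weights = if (is.null(biotype_weights)) base$biotype_weights else biotype_weights,
    chrom_weights = if (is.null(chrom_weights)) base$chrom_weights else chrom_weights,
    region_weights = if (is.null(region_weights))
      c(exonic = 0.85, intronic = 0.10, intergenic = 0.05) else region_weights,
    abundance_meanlog = if (is.null(abundance_meanlog)) 0 else abundance_meanlog,
    abundance_sdlog = if (is.null(abundance_sdlog)) 1.5 else abundance_sdlog,
    single_positive_rate = if (is.null(single_positive_rate)) 0.10 else single_positive_rate,
    dispersion = if (is.null(dispersion))
      list(rna_isolation = 0.08, library_prep = 0.02) else dispersion)
  for (w in c("biotype_weights", "chrom_weights", "region_weights")) {
    if (abs(sum(p[[w]]) - 1) > 1e-9) stop(w, " must sum to 1")
    if (any(p[[w]] < 0)) stop(w, " must be non-negative")
  }
  if (any(unlist(p$dispersion) < 0)) stop("dispersion must be >= 0")
  if (p$single_positive_rate < 0 || p$single_positive_rate >= 1)
    stop("single_positive_rate must be in [0, 1)")
  structure(p, class = "biofluid_profile")
}

#' Generate synthetic ERCC and Sequin spike panels
#'
#' Stock concentrations are log-spaced over `dynamic_range_log2` log2 units
#' and randomly assigned to member ids; panel sizes default to the real
#' panels (92 ERCC + 78 Sequin = 170 spike-in RNAs). Real concentration
#' sheets can be supplied instead via [read_spike_panel()].
#'
#' @param n_ercc,n_sequin Panel sizes (> 0).
#' @param dynamic_range_log2 Log2 span of stock concentrations, default 10.
#' @param seed Integer seed (controls the id assignment permutation).
#' @return List with `spike_panel` elements `ercc` and `sequin`.
#' @export
make_spike_panels <- function(n_ercc = 92L, n_sequin = 78L,
                              dynamic_range_log2 = 10, seed = 1L) {
  stopifnot(n_ercc > 0, n_sequin > 0, dynamic_range_log2 >= 0)
  mk <- function(n, mix, prefix) {
    conc <- if (n == 1) 2^(dynamic_range_log2 / 2) else
      2^seq(0, dynamic_range_log2, length.out = n)
    spike_panel(sprintf("%s-%03d", prefix, seq_len(n)), mix,
                conc[sample.int(length(conc))])
  }
  withr::with_seed(as.integer(seed), {
    list(ercc = mk(n_ercc, "ERCC", "ERCC"),
         sequin = mk(n_sequin, "Sequin", "SEQUIN"))
  })
}

spike_annotation <- function(ids, feature_class) {
  data.frame(feature_id = ids, feature_class = feature_class,
             biotype = "spike", chrom_class = "spike",
             region_class = "not_applicable", stringsAsFactors = FALSE)
}

round_half_even <- function(x) round(x)  # base R rounds half to even

#' Simulate an opposing-dilution spike titration experiment
#'
#' Expected spike counts are proportional to stock concentration times the
#' design dilution, scaled so that the two panels together consume about
#' `spike_share` of the library at the mid-range; the remainder of each
#' library is filled with log-normally abundant endogenous genes. With
#' `noise = "none"` per-spike base counts are anchored (rounded half-to-even)
#' at the most-dilute sample of each mix and multiplied by the relative
#' dilution, so sample pairs whose designed ratio is an integer (1:2:4 within
#' the default series) have exactly zero fold-change deviation; `"poisson"`
#' and `"nb"` draw counts from the stated law around the continuous
#' expectation.
#'
#' @param design A `spike_design` (default [default_titration_design()]).
#' @param panels Spike panels from [make_spike_panels()] or files.
#' @param library_size Expected reads per sample.
#' @param noise `"poisson"` (default), `"none"` or `"nb"`.
#' @param dispersion NB overdispersion (used for `noise = "nb"`).
#' @param spike_share Expected read fraction of both panels combined at the
#'   dilution mid-range, default 0.10.
#' @param n_endogenous Number of filler endogenous genes.
#' @param seed Integer seed.
#' @return List with `counts` (a `count_matrix`) and `truth` (expected count
#'   matrix, design, noise model, seed).
#' @export
make_titration <- function(design = default_titration_design(),
                           panels = make_spike_panels(),
                           library_size = 1e6,
                           noise = c("poisson", "none", "nb"),
                           dispersion = 0.05, spike_share = 0.10,
                           n_endogenous = 2000L, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(library_size > 0, spike_share > 0, spike_share < 1)
  samples <- design_samples(design)
  ns <- length(samples)

  expected <- NULL; ann <- NULL
  for (mix in c("ERCC", "Sequin")) {
    pan <- if (mix == "ERCC") panels$ercc else panels$sequin
    d <- vapply(samples, function(s) design_dilution(design, mix, s), 0)
    rel <- d / min(d)
    w <- pan$stock_concentration / sum(pan$stock_concentration)
    base <- w * (spike_share / 2) * library_size / mean(rel)
    if (noise == "none") base <- round_half_even(base)
    e <- outer(base, rel)                       # spikes x samples
    rownames(e) <- pan$spike_id
    expected <- rbind(expected, e)
    ann <- rbind(ann, spike_annotation(pan$spike_id, mix_feature_class(mix)))
  }

  withr::with_seed(as.integer(seed), {
    endo_ab <- stats::rlnorm(n_endogenous, 0, 1.5)
    endo_w <- endo_ab / sum(endo_ab)
    endo_e <- outer(endo_w, pmax(library_size - colSums(expected), 0))
    rownames(endo_e) <- sprintf("gene_%05d", seq_len(n_endogenous))
    expected <- rbind(expected, endo_e)
    colnames(expected) <- samples

    counts <- switch(noise,
      none = round_half_even(expected),
      poisson = matrix(stats::rpois(length(expected), expected),
                       nrow = nrow(expected), dimnames = dimnames(expected)),
      nb = {
        if (dispersion <= 0) {
          matrix(stats::rpois(length(expected), expected),
                 nrow = nrow(expected), dimnames = dimnames(expected))
        } else {
          matrix(stats::rnbinom(length(expected), mu = expected, size = 1 / dispersion),
                 nrow = nrow(expected), dimnames = dimnames(expected))
        }
      })
  })

  ann <- rbind(ann, data.frame(feature_id = rownames(endo_e),
                               feature_class = "endogenous",
                               biotype = "protein_coding", chrom_class = "nuclear",
                               region_class = "exonic", stringsAsFactors = FALSE))
  list(counts = count_matrix(counts, ann),
       truth = list(expected_counts = expected, design = design, noise = noise,
                    dispersion = dispersion, spike_share = spike_share,
                    seed = as.integer(seed)))
}

# Allocate n items over cells proportionally to weights; every cell with
# positive weight receives at least one item (largest-remainder method).
allocate_cells <- function(n, w) {
  pos <- w > 0
  k <- sum(pos)
  if (n < k) stop("too few genes to cover all weight cells")
  raw <- w[pos] * n
  base <- pmax(1L, floor(raw))
  while (sum(base) > n) {
    i <- which.max(base - raw)
    base[i] <- base[i] - 1L
  }
  rem <- raw - base
  while (sum(base) < n) {
    i <- which.max(rem)
    base[i] <- base[i] + 1L
    rem[i] <- -Inf
  }
  out <- integer(length(w)); out[pos] <- base
  out
}

#' Simulate replicate biofluid libraries with planted truth
#'
#' Draws a shared true expression vector (log-normal abundances rescaled so
#' the read mass of every biotype x chromosome-class x region-class cell
#' matches the profile's planted weights), then samples replicate counts from
#' a negative binomial with the profile's dispersion for the chosen replicate
#' level (0 = Poisson). Low-count single-positive noise genes (count drawn
#' uniformly from 1..3, present in exactly one replicate) are injected at the
#' profile's rate. Optionally, ERCC spikes are added so that the expected
#' endogenous:spike read ratio encodes a chosen true relative RNA
#' concentration.
#'
#' @param profile A [biofluid_profile()].
#' @param n_replicates >= 2.
#' @param library_size Expected reads per replicate.
#' @param seed Integer seed.
#' @param replicate_level `"library_prep"` or `"rna_isolation"` (selects the
#'   dispersion).
#' @param dispersion Optional override of the profile's dispersion.
#' @param panels Optional spike panels; when given, ERCC spikes are included.
#' @param true_concentration True relative RNA concentration (arbitrary
#'   units/ml) encoded in the endogenous:spike ratio. The default 0.01 with
#'   200 ul input and a 1/25000 dilution gives an endogenous:spike ratio of
#'   50, i.e. spikes consume about 2% of the library — the regime the
#'   titration design aims for (spike coverage inside the biofluid abundance
#'   range).
#' @param input_volume Biofluid input volume in microlitres (metadata).
#' @param ercc_dilution ERCC dilution factor (metadata and ratio scaling).
#' @param sample_prefix Prefix for sample ids, default the profile name.
#' @return List with `counts`, `meta` (data.frame, one row per replicate) and
#'   `truth` (planted weights, expression vector, noise-gene ids, seed).
#' @export
make_replicates <- function(profile, n_replicates = 2L, library_size = 1e6,
                            seed = 1L,
                            replicate_level = c("library_prep", "rna_isolation"),
                            dispersion = NULL, panels = NULL,
                            true_concentration = 0.01, input_volume = 200,
                            ercc_dilution = 1 / 25000,
                            sample_prefix = profile$name) {
  stopifnot(inherits(profile, "biofluid_profile"), n_replicates >= 2)
  replicate_level <- match.arg(replicate_level)
  disp <- if (is.null(dispersion)) profile$dispersion[[replicate_level]] else dispersion

  cells <- expand.grid(biotype = names(profile$biotype_weights),
                       chrom_class = names(profile$chrom_weights),
                       region_class = names(profile$region_weights),
                       stringsAsFactors = FALSE)
  cell_w <- profile$biotype_weights[cells$biotype] *
    profile$chrom_weights[cells$chrom_class] *
    profile$region_weights[cells$region_class]
  n_per_cell <- allocate_cells(profile$n_genes, cell_w)

  gene_ids <- sprintf("%s_g%05d", profile$name, seq_len(profile$n_genes))
  cell_of <- rep(seq_len(nrow(cells)), n_per_cell)
  samples <- sprintf("%s_rep%d", sample_prefix, seq_len(n_replicates))

  has_spikes <- !is.null(panels)
  if (has_spikes) {
    R_true <- true_concentration * (input_volume / 1000) / ercc_dilution
    endo_share <- R_true / (1 + R_true)
  } else {
    endo_share <- 1
  }

  withr::with_seed(as.integer(seed), {
    ab <- stats::rlnorm(profile$n_genes, profile$abundance_meanlog,
                        profile$abundance_sdlog)
    w <- numeric(profile$n_genes)
    for (c_i in which(n_per_cell > 0)) {
      idx <- cell_of == c_i
      w[idx] <- ab[idx] / sum(ab[idx]) * cell_w[c_i]
    }
    mu <- endo_share * library_size * w
    draw <- function(m) {
      if (disp > 0) stats::rnbinom(length(m), mu = m, size = 1 / disp)
      else stats::rpois(length(m), m)
    }
    counts <- vapply(seq_len(n_replicates), function(r) draw(mu),
                     numeric(profile$n_genes))
    rownames(counts) <- gene_ids
    colnames(counts) <- samples

    ann <- data.frame(feature_id = gene_ids, feature_class = "endogenous",
                      biotype = cells$biotype[cell_of],
                      chrom_class = cells$chrom_class[cell_of],
                      region_class = cells$region_class[cell_of],
                      stringsAsFactors = FALSE)

    n_noise <- round(profile$single_positive_rate * profile$n_genes)
    noise_ids <- character(0)
    if (n_noise > 0) {
      noise_ids <- sprintf("%s_noise%05d", profile$name, seq_len(n_noise))
      nz <- matrix(0, n_noise, n_replicates,
                   dimnames = list(noise_ids, samples))
      side <- sample(n_replicates, n_noise, replace = TRUE)
      nz[cbind(seq_len(n_noise), side)] <- sample(1:3, n_noise, replace = TRUE)
      counts <- rbind(counts, nz)
      ann <- rbind(ann, data.frame(feature_id = noise_ids,
                                   feature_class = "endogenous",
                                   biotype = "other", chrom_class = "nuclear",
                                   region_class = "exonic",
                                   stringsAsFactors = FALSE))
    }

    if (has_spikes) {
      pan <- panels$ercc
      sw <- pan$stock_concentration / sum(pan$stock_concentration)
      smu <- (1 - endo_share) * library_size * sw
      sc <- vapply(seq_len(n_replicates),
                   function(r) stats::rpois(length(smu), smu), numeric(length(smu)))
      rownames(sc) <- pan$spike_id
      colnames(sc) <- samples
      counts <- rbind(counts, sc)
      ann <- rbind(ann, spike_annotation(pan$spike_id, "spike_ercc"))
    }
  })

  meta <- data.frame(sample_id = samples, fluid = profile$name,
                     replicate_group = sample_prefix,
                     replicate_level = replicate_level,
                     input_volume = input_volume,
                     ercc_dilution = ercc_dilution,
                     sequin_dilution = NA_real_, stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, ann),
       meta = meta,
       truth = list(profile = profile, expression_weights = w,
                    cell_weights = cell_w, cells = cells,
                    noise_gene_ids = noise_ids,
                    true_concentration = true_concentration,
                    endo_share = endo_share, dispersion = disp,
                    seed = as.integer(seed)))
}

#' Merge count matrices over disjoint sample sets
#'
#' Features are unioned (missing combinations are zero); features shared
#' between inputs (e.g. spike panels) must carry identical annotation.
#'
#' @param matrices List of `count_matrix` objects with disjoint samples.
#' @return A `count_matrix`.
#' @export
combine_count_matrices <- function(matrices) {
  all_samples <- unlist(lapply(matrices, sample_ids))
  if (anyDuplicated(all_samples)) stop("sample ids overlap between matrices")
  ann <- unique(do.call(rbind, lapply(matrices, function(m) m$annotation)))
  if (anyDuplicated(ann$feature_id)) stop("conflicting annotation for shared features")
  big <- matrix(0, nrow(ann), length(all_samples),
                dimnames = list(ann$feature_id, all_samples))
  for (m in matrices) big[feature_ids(m), sample_ids(m)] <- m$counts
  count_matrix(big, ann)
}

#' Simulate a complete assessment dataset
#'
#' One 5-sample opposing-dilution titration (Poisson noise) plus replicate
#' pairs for three biofluid presets (ePRP, ePFP at a planted 17-fold lower
#' concentration, urine) with ERCC spikes, merged into one count matrix with
#' matching metadata, spike design and replicate-pair table — the standard
#' end-to-end input for [assess()].
#'
#' @param seed Integer seed.
#' @param library_size Expected reads per library.
#' @return List with `counts`, `meta`, `design`, `pairs` and `truth`.
#' @export
make_assessment_dataset <- function(seed = 1L, library_size = 3e5) {
  seed <- as.integer(seed)
  panels <- make_spike_panels(seed = seed)
  tit <- make_titration(panels = panels, library_size = library_size,
                        noise = "poisson", seed = seed)
  fluids <- list(
    make_replicates(biofluid_profile("ePRP"), library_size = library_size,
                    seed = seed + 1L, panels = panels,
                    true_concentration = 0.01),
    make_replicates(biofluid_profile("ePFP"), library_size = library_size,
                    seed = seed + 2L, panels = panels,
                    true_concentration = 0.01 / 17),
    make_replicates(biofluid_profile("urine"), library_size = library_size,
                    seed = seed + 3L, panels = panels,
                    true_concentration = 0.01))
  counts <- combine_count_matrices(c(list(tit$counts),
                                     lapply(fluids, `[[`, "counts")))
  meta <- do.call(rbind, lapply(fluids, `[[`, "meta"))
  pairs <- do.call(rbind, lapply(fluids, function(f) {
    data.frame(sample_a = f$meta$sample_id[1], sample_b = f$meta$sample_id[2],
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, meta = meta, design = tit$truth$design, pairs = pairs,
       truth = list(titration = tit$truth,
                    fluids = lapply(fluids, `[[`, "truth"), seed = seed))
}
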