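# End-to-end orchestration: configuration, validation, and the run_all
# pipeline (synthetic generation or file inputs -> caller reconciliation ->
# knockdown filtering -> motif model -> scanning/assignment -> mappability
# -> free motifs -> annotation -> chromatin landscape), with a structured
# run report and deterministic outputs.

#' Pipeline configuration
#'
#' All threshold defaults are the study constants consumed downstream:
#' bound-motif p 0.001, free-motif p 5e-6, 240-base filter window, 3-fold
#' criterion-2 depletion, 500-base promoters, 40-mer mappability in 400-base
#' windows, 100-base/step-50 composites, 400-base intensity windows, five
#' clusters, and a reference depletion of 10/7 (a reference locus retaining
#' under 70% of its signal after knockdown).
#'
#' @param ... overrides of any default field; unknown fields error.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # run mode and synthetic generation parameters
    synthetic = TRUE,
    out_dir = NULL,
    seed = 1,
    genome_length = 1e6,
    n_bound = 100, n_free = 150, n_decoy = 50,
    min_spacing = 2000,
    base_comp = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29),
    enrichment_fold = 40,
    kd_depletion = 40,
    background_rate = 0.02,
    fragment_shift = 75, fragment_sd = 25,
    gene_fraction = 0.6, mean_gene_length = 5000,
    factors = c("H3K4me3", "H3K9ac", "H4ac", "PolII", "H3K27me3"),
    assoc_prob_bound = c(0.7, 0.7, 0.7, 0.7, 0.1),
    assoc_prob_free = c(0.1, 0.1, 0.1, 0.1, 0.2),
    signal_fold = 4, noise_sd = 0.25,
    probe_spacing = 50, block_halfwidth = 300,
    # real-input paths (used when synthetic = FALSE)
    genome_fasta = NULL, genes_bed = NULL,
    tags_bed = NULL,     # named character vector: exp_hs, kd_hs, preimmune, ...
    tracks_bedgraph = NULL, tracks_regions = NULL,
    # analysis thresholds
    bound_p = 0.001,
    free_p = 5e-6,
    filter_window = 240,
    min_fold = 3,
    reference_depletion = 10 / 7,
    promoter_size = 500,
    mappability_k = 40,
    mappability_window = 400,
    composite_window = 100,
    composite_step = 50,
    composite_span = 2000,
    intensity_window = 400,
    clusters_k = 5,
    caller_fdr = 0.1,
    caller_window_region = 400,
    caller_window_point = 100,
    motif_flank = 60,
    search_halfwidth = 60)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return Character vector of violations (empty iff valid), each naming
#'   the offending field and rule.
#' @export
validate_config <- function(config) {
  v <- character(0)
  need_pos <- c("genome_length", "min_spacing", "filter_window", "min_fold",
                "promoter_size", "mappability_k", "mappability_window",
                "composite_window", "composite_step", "composite_span",
                "intensity_window", "clusters_k", "probe_spacing",
                "caller_window_region", "caller_window_point",
                "motif_flank", "search_halfwidth", "background_rate")
  for (f in need_pos) {
    if (!is.numeric(config[[f]]) || any(config[[f]] <= 0)) {
      v <- c(v, sprintf("%s: must be positive", f))
    }
  }
  for (f in c("bound_p", "free_p", "caller_fdr")) {
    p <- config[[f]]
    if (!is.numeric(p) || p <= 0 || p >= 1) {
      v <- c(v, sprintf("%s: must lie in (0, 1)", f))
    }
  }
  if (is.numeric(config$reference_depletion) &&
      config$reference_depletion < 1) {
    v <- c(v, "reference_depletion: must be >= 1")
  }
  if (is.numeric(config$kd_depletion) && config$kd_depletion < 1) {
    v <- c(v, "kd_depletion: must be >= 1")
  }
  if (is.numeric(config$composite_window) &&
      is.numeric(config$composite_step) &&
      config$composite_window < config$composite_step) {
    v <- c(v, "composite_window: must be >= composite_step")
  }
  if (any(config$assoc_prob_bound < 0 | config$assoc_prob_bound > 1) ||
      any(config$assoc_prob_free < 0 | config$assoc_prob_free > 1)) {
    v <- c(v, "assoc_prob: probabilities must lie in [0, 1]")
  }
  if (!config$synthetic) {
    for (f in c("genome_fasta", "genes_bed", "tags_bed")) {
      if (is.null(config[[f]])) {
        v <- c(v, sprintf("%s: required when synthetic = FALSE", f))
      }
    }
    if (!is.null(config$tags_bed) &&
        !all(c("exp_hs", "kd_hs", "preimmune") %in% names(config$tags_bed))) {
      v <- c(v, "tags_bed: needs named entries exp_hs, kd_hs, preimmune")
    }
  }
  v
}

#' Run the full knockdown-controlled ChIP-seq pipeline
#'
#' Stages, in order: simulate (or ingest) -> two-caller peak calling ->
#' reconciliation -> RNAi-sensitivity filtering -> motif-matrix discovery ->
#' genome scanning -> motif-to-peak assignment -> mappability -> free-motif
#' definition -> annotation -> chromatin-landscape profiling, association
#' and clustering.  With `out_dir` set, every stage output is written with a
#' provenance header; a rerun with the same config and seed is
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Object of class `run_report`: per-stage counts, key results, the
#'   config echo, and (for synthetic runs) the generation truth.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid config:\n", paste(" -", violations, collapse = "\n"))
  }
  seed <- config$seed
  truth <- NULL
  if (config$synthetic) {
    log_stage("stage simulate: generating genome, libraries and tracks")
    gen <- generate_genome(config$genome_length, config$n_bound,
                           config$n_free, config$n_decoy,
                           min_spacing = config$min_spacing,
                           base_comp = config$base_comp,
                           enrichment_fold = config$enrichment_fold,
                           gene_fraction = config$gene_fraction,
                           mean_gene_length = config$mean_gene_length,
                           seed = sub_seed(seed, 1))
    genome <- gen$genome
    truth <- gen$truth
    libs <- simulate_tag_libraries(truth,
                                   background_rate = config$background_rate,
                                   kd_depletion = config$kd_depletion,
                                   fragment_shift = config$fragment_shift,
                                   fragment_sd = config$fragment_sd,
                                   seed = sub_seed(seed, 2))
    sim <- simulate_chromatin_tracks(truth, factors = config$factors,
                                     assoc_prob_bound = config$assoc_prob_bound,
                                     assoc_prob_free = config$assoc_prob_free,
                                     signal_fold = config$signal_fold,
                                     noise_sd = config$noise_sd,
                                     probe_spacing = config$probe_spacing,
                                     block_halfwidth = config$block_halfwidth,
                                     seed = sub_seed(seed, 3))
    tracks <- sim$tracks
    truth <- sim$truth
    genes <- truth$gene_models
  } else {
    log_stage("stage ingest: reading inputs")
    genome <- Biostrings::readDNAStringSet(config$genome_fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    genes <- read_genes_bed(config$genes_bed)
    sizes <- genome_sizes(genome)
    libs <- lapply(stats::setNames(nm = names(config$tags_bed)), function(nm) {
      path <- config$tags_bed[[nm]]
      if (!file.exists(path)) {
        stop("stage ingest: tag library '", nm, "' not found at ", path)
      }
      read_tags_bed(path, chrom_sizes = sizes, library_id = nm)
    })
    tracks <- list()
    if (!is.null(config$tracks_bedgraph)) {
      tracks <- lapply(stats::setNames(nm = names(config$tracks_bedgraph)),
                       function(nm) {
        read_track_bedgraph(config$tracks_bedgraph[[nm]], factor = nm,
                            regions_path = config$tracks_regions[[nm]])
      })
    }
  }
  for (nm in c("exp_hs", "kd_hs", "preimmune")) {
    if (!nm %in% names(libs)) {
      stop("stage filter: required library '", nm, "' is missing")
    }
  }
  log_stage("stage call: two-caller peak calling")
  peaks_region <- call_windows_poisson(libs$exp_hs, libs$preimmune,
                                       window = config$caller_window_region,
                                       fdr_cutoff = config$caller_fdr,
                                       shift = config$fragment_shift,
                                       caller = "caller_A")
  peaks_point <- call_windows_poisson(libs$exp_hs, libs$preimmune,
                                      window = config$caller_window_point,
                                      fdr_cutoff = config$caller_fdr,
                                      shift = config$fragment_shift,
                                      caller = "caller_B")
  kd_peaks <- call_windows_poisson(libs$kd_hs, libs$preimmune,
                                   window = config$caller_window_point,
                                   fdr_cutoff = config$caller_fdr,
                                   shift = config$fragment_shift,
                                   caller = "caller_B")
  log_stage("stage reconcile: matching the two callers")
  candidates <- reconcile_callers(peaks_region, peaks_point)
  log_stage("stage filter: RNAi-sensitivity classification")
  classified <- classify_rnai_sensitivity(candidates, kd_peaks,
                                          libs$exp_hs, libs$kd_hs,
                                          reference_depletion =
                                            config$reference_depletion,
                                          window = config$filter_window,
                                          min_fold = config$min_fold)
  sensitive <- classified[grepl("^sensitive", classified$classification), ,
                          drop = FALSE]
  if (nrow(sensitive) == 0L) stop("stage filter: no RNAi-sensitive peak")
  log_stage("stage motif: seed-consensus matrix discovery")
  background <- genome_background(genome)
  mat <- discover_pswm(genome, sensitive, flank = config$motif_flank,
                       background = background)
  log_stage("stage scan: genome scanning")
  hits_bound_scan <- scan_genome(genome, mat, config$bound_p)
  hits_free_scan <- if (config$free_p < config$bound_p) {
    hits_bound_scan[hits_bound_scan$p_value <= config$free_p, , drop = FALSE]
  } else {
    scan_genome(genome, mat, config$free_p)
  }
  log_stage("stage assign: motif-to-peak assignment")
  sizes <- genome_sizes(genome)
  assign <- assign_peak_motifs(sensitive, hits_bound_scan,
                               p_threshold = config$bound_p,
                               search_halfwidth = config$search_halfwidth,
                               chrom_sizes = sizes,
                               seed = sub_seed(seed, 4))
  bound_idx <- assign$assignments$motif_index
  bound_motifs <- hits_bound_scan[bound_idx[!is.na(bound_idx)], , drop = FALSE]
  bound_motifs <- unique(bound_motifs)
  rownames(bound_motifs) <- NULL
  log_stage("stage mappability: exact k-mer uniqueness")
  mtrack <- kmer_uniqueness(genome, k = config$mappability_k)
  log_stage("stage free-motifs: factor-free motif definition")
  free_motifs <- find_free_motifs(hits_free_scan, mtrack, sensitive,
                                  bound_motifs = bound_motifs,
                                  p_threshold = config$free_p,
                                  mappability_window = config$mappability_window)
  log_stage("stage annotate: motif classification against gene models")
  comp_bound <- class_composition(bound_motifs, genes, config$promoter_size)
  comp_free <- if (nrow(free_motifs) > 0L) {
    class_composition(free_motifs, genes, config$promoter_size)
  } else NULL
  genome_comp <- genome_composition(genes, sum(sizes), config$promoter_size)
  log_stage("stage landscape: profiles, association, clustering")
  profiles <- list()
  associations <- NULL
  clusters <- NULL
  if (length(tracks) > 0L) {
    profiles <- lapply(tracks, function(tr) {
      list(bound = composite_profile(tr, bound_motifs,
                                     span = config$composite_span,
                                     window = config$composite_window,
                                     step = config$composite_step),
           free = composite_profile(tr, free_motifs,
                                    span = config$composite_span,
                                    window = config$composite_window,
                                    step = config$composite_step))
    })
    if (nrow(free_motifs) > 0L) {
      associations <- associate_tracks(tracks, bound_motifs, free_motifs)
    }
    all_motifs <- rbind(bound_motifs, free_motifs)
    if (nrow(all_motifs) >= config$clusters_k) {
      imat <- vapply(tracks, function(tr) {
        out <- numeric(nrow(all_motifs))
        for (chrom in unique(all_motifs$chrom)) {
          i <- all_motifs$chrom == chrom
          out[i] <- window_mean_intensity(tr, chrom, all_motifs$center[i],
                                          config$intensity_window)
        }
        out
      }, numeric(nrow(all_motifs)))
      clusters <- cluster_motifs(imat, k = config$clusters_k,
                                 seed = sub_seed(seed, 5))
      clusters$class <- rep(c("bound", "free"),
                            c(nrow(bound_motifs), nrow(free_motifs)))
    }
  }
  report <- structure(list(
    version = as.character(utils::packageVersion("kdchip")),
    seed = seed,
    config = unclass(config),
    counts = list(
      candidate_peaks = nrow(candidates),
      kd_peaks = nrow(kd_peaks),
      sensitive_criterion1 = sum(classified$classification ==
                                   "sensitive_criterion1"),
      sensitive_criterion2 = sum(classified$classification ==
                                   "sensitive_criterion2"),
      resistant = sum(classified$classification == "resistant"),
      sensitive = nrow(sensitive),
      motif_bearing_peaks = sum(!is.na(bound_idx)),
      motif_free_peaks = sum(is.na(bound_idx)),
      bound_motifs = nrow(bound_motifs),
      free_motifs = nrow(free_motifs)),
    pswm = mat,
    candidates = classified,
    sensitive = sensitive,
    assignments = assign$assignments,
    motif_distances = assign$distances,
    random_distances = assign$random_distances,
    bound_motifs = bound_motifs,
    free_motifs = free_motifs,
    composition_bound = comp_bound,
    composition_free = comp_free,
    genome_composition = genome_comp,
    profiles = profiles,
    associations = associations,
    clusters = clusters,
    truth = truth), class = "run_report")
  stopifnot(report$counts$sensitive + report$counts$resistant ==
              report$counts$candidate_peaks)
  if (!is.null(config$out_dir)) {
    write_run_outputs(report, libs, tracks, genome, genes, config)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("kdchip run report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
write_run_outputs <- function(report, libs, tracks, genome, genes, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  Biostrings::writeXStringSet(genome, p("genome.fa"), width = 70L)
  write_genes_bed12(genes, p("genes.bed"))
  for (nm in names(libs)) write_tags_bed(libs[[nm]], p(sprintf("tags_%s.bed", nm)))
  write_peaks_bed(report$candidates, p("peaks_classified.bed"))
  write_peaks_bed(report$sensitive, p("peaks_sensitive.bed"))
  write_pswm_meme(report$pswm, p("pswm.meme"))
  write_motifs_bed(report$bound_motifs, p("motifs_bound.bed"))
  write_motifs_bed(report$free_motifs, p("motifs_free.bed"))
  for (nm in names(tracks)) {
    write_track_bedgraph(tracks[[nm]], p(sprintf("track_%s.bedgraph", nm)),
                         regions_path = p(sprintf("regions_%s.bed", nm)))
  }
  if (!is.null(report$associations)) {
    write_tsv_headered(report$associations, p("associations.tsv"),
                       provenance_header("bound-vs-free Fisher association"))
  }
  if (length(report$profiles) > 0L) {
    prof_rows <- do.call(rbind, lapply(names(report$profiles), function(nm) {
      pr <- report$profiles[[nm]]
      do.call(rbind, lapply(c("bound", "free"), function(cls) {
        q <- pr[[cls]]
        data.frame(factor = nm, class = cls, offset = q$offsets,
                   mean_intensity = round(q$mean_intensity, 6),
                   se = round(q$se, 6), n_motifs = q$n_motifs)
      }))
    }))
    write_tsv_headered(prof_rows, p("composites.tsv"),
                       provenance_header("motif-centered composite profiles"))
  }
  if (!is.null(report$clusters)) {
    cl <- data.frame(motif = seq_along(report$clusters$cluster),
                     class = report$clusters$class,
                     cluster = report$clusters$cluster)
    write_tsv_headered(cl, p("clusters.tsv"),
                       provenance_header("k-means cluster assignments"))
  }
  json <- list(version = report$version, seed = report$seed,
               counts = report$counts,
               genome_composition = report$genome_composition)
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
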