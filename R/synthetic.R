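# Synthetic-data generator: genomes with planted HSE motifs of known class,
# tag libraries with knockdown-controlled peak enrichment, and probe-level
# chromatin tracks whose enrichment co-occurs with the bound motif class.
# Every generated feature is recorded in a SyntheticTruth object so each
# downstream stage can be tested against exact ground truth.

SYNTH_CHROM <- "chrS"

#' Generate a synthetic genome with planted HSE motifs
#'
#' Background bases are drawn i.i.d. from `base_comp`.  Motifs of three
#' classes are planted non-overlapping with at least `min_spacing` bases
#' between starts: `bound` motifs (each gets one true, knockdown-sensitive
#' peak centered on it), `free` motifs (no peak), and `decoy` direct-repeat
#' sites (AGAAN AGAAN AGAAN, the orientation the factor does not bind in
#' vivo) which carry the knockdown-*resistant* false-positive peaks.  Gene
#' models covering roughly `gene_fraction` of the genome are laid down for
#' the annotation stage.
#'
#' @param length genome length in bases.
#' @param n_bound,n_free,n_decoy motif counts per class.
#' @param motif_model `pswm` the bound/free instances are sampled from
#'   (default [hse_pswm()], the sharp inverted-repeat model).
#' @param min_spacing minimum distance between motif starts (default 2000).
#' @param base_comp background base composition (A, C, G, T); the default is
#'   AT-rich as in the fly genome.
#' @param enrichment_fold true-peak enrichment over background (default 40).
#' @param gene_fraction target fraction of the genome covered by gene
#'   bodies (default 0.6).
#' @param mean_gene_length mean simulated gene length (default 5000).
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return List with `genome` (a `DNAStringSet` holding chromosome `chrS`)
#'   and `truth` (class `synthetic_truth`): `genome_length`,
#'   `planted_motifs` (start, center, strand, class), `true_peaks` (center,
#'   enrichment_fold, kd_resistant), `gene_models`, `mark_states`, `seed`.
#' @export
generate_genome <- function(length, n_bound, n_free, n_decoy,
                            motif_model = hse_pswm(),
                            min_spacing = 2000,
                            base_comp = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29),
                            enrichment_fold = 40,
                            gene_fraction = 0.6,
                            mean_gene_length = 5000,
                            seed = 1) {
  length <- as.integer(length)
  n_tot <- n_bound + n_free + n_decoy
  w <- motif_model$width
  if (w > min_spacing) stop("motif width exceeds min_spacing")
  if (n_tot > 0 && length <= n_tot * min_spacing) {
    stop(sprintf(
      "infeasible packing: %d motifs at spacing %d do not fit in %d bases",
      n_tot, min_spacing, length))
  }
  with_seed(seed, {
    chars <- sample(DNA_BASES4, length, replace = TRUE, prob = base_comp)
    planted <- data.frame(start = integer(0), center = integer(0),
                          strand = character(0), class = character(0))
    if (n_tot > 0) {
      slack <- length - n_tot * min_spacing - w
      u <- sort(stats::runif(n_tot, 0, slack))
      starts <- as.integer(floor(u)) + (seq_len(n_tot) - 1L) * as.integer(min_spacing)
      classes <- sample(rep(c("bound", "free", "decoy"),
                            c(n_bound, n_free, n_decoy)))
      strands <- sample(c("+", "-"), n_tot, replace = TRUE)
      for (i in seq_len(n_tot)) {
        instance <- if (classes[i] == "decoy") {
          paste0("AGAA", sample(DNA_BASES4, 1), "AGAA",
                 sample(DNA_BASES4, 1), "AGAA", sample(DNA_BASES4, 1))
        } else {
          sample_pswm(motif_model)
        }
        if (strands[i] == "-") instance <- revcomp_chr(instance)
        chars[(starts[i] + 1L):(starts[i] + w)] <-
          strsplit(instance, "", fixed = TRUE)[[1]]
      }
      planted <- data.frame(start = starts,
                            center = starts + w %/% 2L,
                            strand = strands, class = classes)
    }
    genes <- simulate_gene_models(length, gene_fraction, mean_gene_length)
    is_peak <- planted$class %in% c("bound", "decoy")
    true_peaks <- data.frame(
      center = planted$center[is_peak],
      enrichment_fold = rep_len(enrichment_fold, sum(is_peak)),
      kd_resistant = planted$class[is_peak] == "decoy")
    truth <- structure(list(
      genome_length = length,
      chrom = SYNTH_CHROM,
      motif_width = w,
      planted_motifs = planted,
      true_peaks = true_peaks,
      gene_models = genes,
      mark_states = list(),
      seed = seed), class = "synthetic_truth")
    genome <- Biostrings::DNAStringSet(stats::setNames(
      paste0(chars, collapse = ""), SYNTH_CHROM))
    list(genome = genome, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic truth: %d bases, %d motifs (%d bound / %d free / %d decoy), %d peaks (%d kd-resistant), %d genes\n",
    x$genome_length, nrow(x$planted_motifs),
    sum(x$planted_motifs$class == "bound"),
    sum(x$planted_motifs$class == "free"),
    sum(x$planted_motifs$class == "decoy"),
    nrow(x$true_peaks), sum(x$true_peaks$kd_resistant),
    nrow(x$gene_models)))
  invisible(x)
}

# Alternating intergenic/gene segments targeting the requested coverage.
#' @keywords internal
#' @noRd
simulate_gene_models <- function(length, gene_fraction, mean_gene_length) {
  if (gene_fraction <= 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  mean_gap <- mean_gene_length * (1 - gene_fraction) / gene_fraction
  pos <- 0L
  start <- integer(0); end <- integer(0)
  while (pos < length) {
    gap <- as.integer(ceiling(stats::rexp(1, 1 / max(mean_gap, 1))))
    s <- pos + gap
    glen <- as.integer(ceiling(stats::rexp(1, 1 / mean_gene_length))) + 200L
    e <- min(s + glen, length)
    if (s >= length) break
    start <- c(start, s); end <- c(end, e)
    pos <- e
  }
  data.frame(chrom = SYNTH_CHROM, start = start, end = end,
             strand = sample(c("+", "-"), length(start), replace = TRUE))
}

#' Simulate the five knockdown-controlled tag libraries
#'
#' Libraries `exp_nhs`, `exp_hs`, `kd_nhs`, `kd_hs` and `preimmune` are
#' generated over the truth's genome.  Background tags are Poisson-uniform.
#' Peak tags are placed with strand-asymmetric displacement: plus-strand 5'
#' ends fall `~Normal(fragment_shift, fragment_sd)` bases left of the peak
#' center and minus-strand ends the mirror distance right, so downstream
#' tag-shifting is exercised.  True (non-resistant) peaks are enriched only
#' under heat shock, and their knockdown enrichment is
#' `1 + (fold - 1) / kd_depletion`; knockdown-resistant peaks keep full
#' enrichment in every antibody library under both conditions.  The
#' pre-immune library is background only.
#'
#' @param truth a `synthetic_truth` object.
#' @param background_rate background tag density (tags/base, default 0.02).
#' @param kd_depletion knockdown depletion factor (>= 1, default 40).
#' @param fragment_shift mean 5'-end displacement from the peak center
#'   (default 75).
#' @param fragment_sd displacement standard deviation (default 25).
#' @param library_sizes optional named vector of expected background tag
#'   counts per library, overriding `background_rate` per library.
#' @param signal_window effective width over which peak enrichment is
#'   expressed (default 240; expected extra tags per peak are
#'   `(fold - 1) * rate * signal_window`).
#' @param seed integer seed.
#' @return Named list of [tag_library()] objects.
#' @export
simulate_tag_libraries <- function(truth, background_rate = 0.02,
                                   kd_depletion = 40, fragment_shift = 75,
                                   fragment_sd = 25, library_sizes = NULL,
                                   signal_window = 240, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (kd_depletion < 1) stop("kd_depletion must be >= 1")
  if (any(truth$true_peaks$enrichment_fold < 1)) {
    stop("enrichment folds must be >= 1")
  }
  L <- truth$genome_length
  libs <- c("exp_nhs", "exp_hs", "kd_nhs", "kd_hs", "preimmune")
  peaks <- truth$true_peaks
  out <- list()
  for (li in seq_along(libs)) {
    lib <- libs[li]
    rate <- if (!is.null(library_sizes) && lib %in% names(library_sizes)) {
      library_sizes[[lib]] / L
    } else background_rate
    out[[lib]] <- with_seed(sub_seed(seed, li), {
      n_bg <- stats::rpois(1, rate * L)
      pos <- if (n_bg > 0) sample.int(L, n_bg, replace = TRUE) - 1L else integer(0)
      strand <- if (n_bg > 0) sample(c("+", "-"), n_bg, replace = TRUE) else character(0)
      if (nrow(peaks) > 0 && lib != "preimmune") {
        f <- peaks$enrichment_fold
        hs <- grepl("_hs$", lib)
        kd <- grepl("^kd_", lib)
        mult <- if (!hs) rep(1, nrow(peaks)) else if (kd) {
          1 + (f - 1) / kd_depletion
        } else f
        # antibody cross-reaction sites: full enrichment in every antibody
        # library under both conditions
        mult[peaks$kd_resistant] <- f[peaks$kd_resistant]
        extra <- stats::rpois(nrow(peaks), (mult - 1) * rate * signal_window)
        for (p in which(extra > 0)) {
          np <- extra[p]
          st <- sample(c("+", "-"), np, replace = TRUE)
          d <- round(stats::rnorm(np, fragment_shift, fragment_sd))
          ppos <- ifelse(st == "+", peaks$center[p] - d, peaks$center[p] + d)
          ppos <- pmin(pmax(ppos, 0L), L - 1L)
          pos <- c(pos, as.integer(ppos))
          strand <- c(strand, st)
        }
      }
      if (length(pos) == 0L) log_stage(sprintf("library %s is empty", lib))
      tag_library(lib,
                  data.frame(chrom = rep(SYNTH_CHROM, length(pos)),
                             pos = as.integer(pos), strand = strand),
                  chrom_sizes = stats::setNames(L, SYNTH_CHROM))
    })
  }
  out
}

#' Simulate probe-level chromatin tracks associated with the bound class
#'
#' Each factor gets a tiling-probe intensity track (baseline 1 plus Gaussian
#' noise) and a list of enriched regions.  Each bound-class motif is flagged
#' enriched with probability `assoc_prob_bound`, each free-class motif with
#' `assoc_prob_free` (decoys are never flagged: they are not HSE motifs);
#' flagged motifs receive a contiguous elevated block of half-width
#' `block_halfwidth` whose intensity is raised by `signal_fold - 1`.  The
#' truth's `mark_states` is updated with the flagged motif indices.
#'
#' @param truth a `synthetic_truth` object.
#' @param factors character vector of factor/mark names.
#' @param assoc_prob_bound,assoc_prob_free per-factor enrichment
#'   probabilities (scalars or vectors along `factors`).
#' @param signal_fold block intensity fold over baseline (default 4).
#' @param noise_sd probe noise standard deviation (default 0.25).
#' @param probe_spacing bases between probes (default 50).
#' @param block_halfwidth enriched-block half-width in bases (default 300).
#' @param seed integer seed.
#' @return List with `tracks` (named list of [chromatin_track()] objects)
#'   and `truth` (updated `mark_states`).
#' @export
simulate_chromatin_tracks <- function(truth, factors = c("H3K4me3", "H3K9ac",
                                                         "H4ac", "PolII"),
                                      assoc_prob_bound = 0.7,
                                      assoc_prob_free = 0.1,
                                      signal_fold = 4, noise_sd = 0.25,
                                      probe_spacing = 50,
                                      block_halfwidth = 300, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (probe_spacing < 1) stop("probe_spacing must be >= 1")
  apb <- rep_len(assoc_prob_bound, length(factors))
  apf <- rep_len(assoc_prob_free, length(factors))
  sf <- rep_len(signal_fold, length(factors))
  if (any(c(apb, apf) < 0 | c(apb, apf) > 1)) {
    stop("association probabilities must lie in [0, 1]")
  }
  L <- truth$genome_length
  motifs <- truth$planted_motifs
  probe_pos <- seq.int(0L, L - 1L, by = as.integer(probe_spacing))
  tracks <- list()
  for (fi in seq_along(factors)) {
    fac <- factors[fi]
    tracks[[fac]] <- with_seed(sub_seed(seed, 1000 + fi), {
      intensity <- 1 + stats::rnorm(length(probe_pos), 0, noise_sd)
      p_enr <- ifelse(motifs$class == "bound", apb[fi],
                      ifelse(motifs$class == "free", apf[fi], 0))
      flags <- stats::runif(nrow(motifs)) < p_enr
      regions <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0))
      if (any(flags)) {
        cs <- motifs$center[flags]
        rs <- pmax(cs - as.integer(block_halfwidth), 0L)
        re <- pmin(cs + as.integer(block_halfwidth), L)
        for (b in seq_along(cs)) {
          idx <- probe_pos >= rs[b] & probe_pos < re[b]
          intensity[idx] <- intensity[idx] + (sf[fi] - 1)
        }
        merged <- reduce0(rs, re)
        regions <- data.frame(chrom = SYNTH_CHROM, merged)
      }
      # the with_seed() argument is evaluated in this function's frame,
      # so this updates the local copy of truth
      truth$mark_states[[fac]] <- which(flags)
      chromatin_track(fac,
                      data.frame(chrom = SYNTH_CHROM, pos = probe_pos,
                                 intensity = intensity),
                      regions)
    })
  }
  list(tracks = tracks, truth = truth)
}
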