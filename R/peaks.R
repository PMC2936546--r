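# Peak calling plumbing, two-caller reconciliation, and RNAi-sensitivity
# classification.  The sliding-window Poisson caller is an internal
# substitute so synthetic runs need no external caller; production input is
# peak calls from MACS/SPP-style programs via read_peaks_bed().

#' Sliding-window Poisson peak caller (plumbing)
#'
#' Tags of both libraries are shifted `shift` bases in their strand
#' direction; counts in tiled windows are tested against the
#' background-scaled Poisson expectation (background window count floored at
#' its genome-wide mean, scaled by the ratio of library sizes), with
#' Benjamini-Hochberg control at `fdr_cutoff`.  Overlapping significant
#' windows are merged; the summit is the mean shifted-tag position within 30
#' bases of the maximum-count 10-base bin.
#'
#' @param lib experimental [tag_library()].
#' @param background control library (e.g. pre-immune); if empty, a uniform
#'   background is used (logged).
#' @param window window width in bases.
#' @param fdr_cutoff Benjamini-Hochberg threshold.
#' @param step window step (default `window / 2`).
#' @param shift strand shift applied before counting (default 75).
#' @param caller caller label recorded on the peaks.
#' @return Peak data frame: `chrom`, `start`, `end` (half-open boundary),
#'   `center` (summit), `caller`, `fdr`.
#' @export
call_windows_poisson <- function(lib, background, window = 100,
                                 fdr_cutoff = 0.05, step = window %/% 2,
                                 shift = 75, caller = "windows") {
  if (window <= 0) stop("window must be positive")
  sp_lib <- shifted_positions(lib, shift)
  sp_bg <- shifted_positions(background, shift)
  n_lib <- nrow(lib$tags)
  n_bg <- nrow(background$tags)
  uniform_bg <- n_bg == 0
  if (uniform_bg) log_stage("empty background library: uniform-background fallback")
  scale <- if (uniform_bg) NA_real_ else n_lib / n_bg
  win <- list()
  for (chrom in names(lib$chrom_sizes)) {
    L <- lib$chrom_sizes[[chrom]]
    if (L < window) next
    starts <- seq.int(0L, L - window, by = step)
    pos <- sp_lib[[chrom]]; if (is.null(pos)) pos <- numeric(0)
    cnt <- count_in_windows(pos, starts, starts + window)
    if (uniform_bg) {
      lambda <- rep(n_lib * window / sum(lib$chrom_sizes), length(starts))
    } else {
      bpos <- sp_bg[[chrom]]; if (is.null(bpos)) bpos <- numeric(0)
      bcnt <- count_in_windows(bpos, starts, starts + window)
      lambda <- scale * pmax(bcnt, mean(bcnt))
    }
    win[[chrom]] <- data.frame(chrom = chrom, start = starts,
                               count = cnt, lambda = lambda)
  }
  win <- do.call(rbind, win)
  peaks0 <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), center = integer(0),
                       caller = character(0), fdr = numeric(0))
  if (is.null(win) || nrow(win) == 0L) return(peaks0)
  pval <- stats::ppois(win$count - 1, win$lambda, lower.tail = FALSE)
  padj <- stats::p.adjust(pval, method = "BH")
  sig <- padj <= fdr_cutoff & win$count > 0
  if (!any(sig)) return(peaks0)
  out <- list()
  for (chrom in unique(win$chrom[sig])) {
    i <- sig & win$chrom == chrom
    merged <- reduce0(win$start[i], win$start[i] + window)
    fdrs <- vapply(seq_len(nrow(merged)), function(k) {
      inside <- i & win$start >= merged$start[k] & win$start < merged$end[k]
      min(padj[inside])
    }, numeric(1))
    pos <- sp_lib[[chrom]]
    summits <- vapply(seq_len(nrow(merged)), function(k) {
      refine_summit(pos, merged$start[k], merged$end[k])
    }, numeric(1))
    out[[chrom]] <- data.frame(chrom = chrom, start = merged$start,
                               end = merged$end,
                               center = as.integer(summits),
                               caller = caller, fdr = fdrs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Summit = mean shifted-tag position within +/-30 bases of the modal
# 10-base bin inside [start, end).
#' @keywords internal
#' @noRd
refine_summit <- function(pos, start, end) {
  inside <- pos[pos >= start & pos < end]
  if (length(inside) == 0L) return((start + end) %/% 2)
  bins <- floor(inside / 10) * 10
  tab <- table(bins)
  mode_bin <- as.numeric(names(tab)[which.max(tab)]) + 5
  near <- inside[abs(inside - mode_bin) <= 30]
  round(mean(near))
}

#' Reconcile peaks from a region caller and a point caller
#'
#' A point-caller peak and a region-caller peak are the same event when the
#' point center falls inside the region boundary; matched pairs merge into
#' one peak (center from the point caller, boundary from the region caller,
#' `caller = "both"`, FDR = the smaller of the two).  A center inside two
#' boundaries is assigned to the boundary whose own center is nearest
#' (logged).  Unmatched peaks from either caller are retained as candidates.
#'
#' @param peaks_region region-caller peaks (boundaries trusted).
#' @param peaks_point point-caller peaks (centers trusted).
#' @return Combined candidate peak data frame.
#' @export
reconcile_callers <- function(peaks_region, peaks_point) {
  nr <- nrow(peaks_region); np <- nrow(peaks_point)
  used_region <- rep(FALSE, nr)
  match_region <- rep(NA_integer_, np)
  for (i in seq_len(np)) {
    inside <- which(peaks_region$chrom == peaks_point$chrom[i] &
                    peaks_region$start <= peaks_point$center[i] &
                    peaks_point$center[i] < peaks_region$end[i])
    if (length(inside) == 0L) next
    if (length(inside) > 1L) {
      log_stage("point-caller center inside two region boundaries; nearest center chosen")
      inside <- inside[which.min(abs(peaks_region$center[inside] -
                                     peaks_point$center[i]))]
    }
    match_region[i] <- inside
    used_region[inside] <- TRUE
  }
  merged <- lapply(which(!is.na(match_region)), function(i) {
    r <- match_region[i]
    data.frame(chrom = peaks_point$chrom[i],
               start = peaks_region$start[r], end = peaks_region$end[r],
               center = peaks_point$center[i], caller = "both",
               fdr = min(peaks_point$fdr[i], peaks_region$fdr[r]))
  })
  only_region <- peaks_region[!used_region,
                              c("chrom", "start", "end", "center", "caller", "fdr")]
  only_point <- peaks_point[is.na(match_region),
                            c("chrom", "start", "end", "center", "caller", "fdr")]
  res <- rbind(do.call(rbind, merged), only_region, only_point)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), center = integer(0),
                      caller = character(0), fdr = numeric(0)))
  }
  res <- res[order(res$chrom, res$start, res$center), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify candidate peaks by RNAi sensitivity
#'
#' Depletion is the experimental-to-knockdown normalized window-count ratio
#' at the peak center (`window` bases, default 240); a pseudocount of one
#' normalized unit is added to both counts when the knockdown count is zero.
#' Criterion 1: the peak is also called in the knockdown data (boundary
#' overlap of at least one base) and its depletion exceeds
#' `reference_depletion` (the reference-locus anchor).  Criterion 2: the
#' peak is absent from the knockdown calls and depleted at least
#' `min_fold`-fold.  Everything else is knockdown-resistant.
#'
#' @param candidates candidate peak data frame (from [reconcile_callers()]).
#' @param kd_peaks peaks called in the knockdown library.
#' @param lib_exp,lib_kd experimental and knockdown [tag_library()] objects.
#' @param reference_depletion reference depletion ratio (>= 1); the default
#'   10/7 corresponds to a knockdown reference locus retaining less than 70%
#'   of its untreated signal.
#' @param window intensity window (default 240).
#' @param min_fold criterion-2 fold (default 3).
#' @return `candidates` with `intensity_exp`, `intensity_kd`, `depletion`
#'   and `classification` (`sensitive_criterion1`, `sensitive_criterion2`,
#'   `resistant`) columns appended.
#' @export
classify_rnai_sensitivity <- function(candidates, kd_peaks, lib_exp, lib_kd,
                                      reference_depletion = 10 / 7,
                                      window = 240, min_fold = 3) {
  if (reference_depletion < 1) stop("reference_depletion must be >= 1")
  if (window <= 0) stop("window must be positive")
  n <- nrow(candidates)
  ie <- ik <- numeric(n)
  for (chrom in unique(candidates$chrom)) {
    i <- candidates$chrom == chrom
    ie[i] <- window_count(lib_exp, chrom, candidates$center[i], window)
    ik[i] <- window_count(lib_kd, chrom, candidates$center[i], window)
  }
  zero_kd <- ik == 0
  if (any(zero_kd)) {
    log_stage(sprintf("%d peak(s) with zero knockdown window count: pseudocount applied",
                      sum(zero_kd)))
  }
  depletion <- ifelse(zero_kd, (ie + 1) / (ik + 1), ie / ik)
  in_kd <- rep(FALSE, n)
  for (chrom in unique(candidates$chrom)) {
    i <- candidates$chrom == chrom
    k <- kd_peaks$chrom == chrom
    in_kd[i] <- overlaps_any0(candidates$start[i], candidates$end[i],
                              kd_peaks$start[k], kd_peaks$end[k])
  }
  classification <- ifelse(in_kd & depletion > reference_depletion,
                           "sensitive_criterion1",
                    ifelse(!in_kd & depletion >= min_fold,
                           "sensitive_criterion2", "resistant"))
  out <- candidates
  out$intensity_exp <- ie
  out$intensity_kd <- ik
  out$depletion <- depletion
  out$called_in_kd <- in_kd
  out$classification <- classification
  out
}

#' Experimental/knockdown ratio distribution against a random-region null
#'
#' Per-region Ex/KD normalized window-count ratios are compared with the
#' same ratio at `n_random` random coordinates; the statistic returned is
#' the fraction of region ratios lying below the null's 95th percentile
#' (regions drawn from the null itself give ~0.95; strongly
#' knockdown-sensitive regions give values near 0).
#'
#' @param regions data frame with `chrom` and `center`.
#' @param lib_exp,lib_kd [tag_library()] objects.
#' @param window intensity window (default 240).
#' @param n_random number of random null coordinates (>= 100).
#' @param seed RNG seed for the null draw.
#' @return List: `ratios`, `random_ratios`, `null_quantile` (95th
#'   percentile), `fraction_below_upper_tail`.
#' @export
ex_kd_ratio_distribution <- function(regions, lib_exp, lib_kd, window = 240,
                                     n_random = 1000, seed = 1) {
  if (n_random < 100) stop("n_random must be >= 100")
  ratio_at <- function(chrom, center) {
    ie <- window_count(lib_exp, chrom, center, window)
    ik <- window_count(lib_kd, chrom, center, window)
    ifelse(ik == 0, (ie + 1) / (ik + 1), ie / ik)
  }
  ratios <- numeric(nrow(regions))
  for (chrom in unique(regions$chrom)) {
    i <- regions$chrom == chrom
    ratios[i] <- ratio_at(chrom, regions$center[i])
  }
  sizes <- lib_exp$chrom_sizes
  random_ratios <- with_seed(seed, {
    chrom <- sample(names(sizes), n_random, replace = TRUE,
                    prob = sizes / sum(sizes))
    half <- window %/% 2
    unlist(lapply(unique(chrom), function(ch) {
      nch <- sum(chrom == ch)
      centers <- floor(stats::runif(nch, half, sizes[[ch]] - half))
      ratio_at(ch, centers)
    }), use.names = FALSE)
  })
  q95 <- stats::quantile(random_ratios, 0.95, names = FALSE, type = 7)
  list(ratios = ratios, random_ratios = random_ratios,
       null_quantile = q95,
       fraction_below_upper_tail = mean(ratios < q95))
}
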