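# Chromatin-landscape profiling around motifs: composite profiles,
# enrichment membership, Fisher exact association of bound vs free motifs,
# k-means clustering of mark intensities, and intensity correlations.

#' Construct a chromatin track
#'
#' Probe-level intensities for one factor or histone modification, plus the
#' intervals called as regions of significant enrichment.
#'
#' @param factor factor/mark name.
#' @param probes data frame: `chrom`, `pos` (0-based), `intensity`.
#' @param enriched_regions data frame: `chrom`, `start`, `end` (half-open);
#'   overlapping intervals are merged.
#' @return Object of class `chromatin_track`.
#' @export
chromatin_track <- function(factor, probes, enriched_regions =
                              data.frame(chrom = character(0),
                                         start = integer(0),
                                         end = integer(0))) {
  stopifnot(all(c("chrom", "pos", "intensity") %in% names(probes)))
  probes <- probes[order(probes$chrom, probes$pos), , drop = FALSE]
  rownames(probes) <- NULL
  if (nrow(enriched_regions) > 0L) {
    parts <- lapply(split(enriched_regions, enriched_regions$chrom), function(d) {
      data.frame(chrom = d$chrom[1], reduce0(d$start, d$end))
    })
    enriched_regions <- do.call(rbind, parts)
    rownames(enriched_regions) <- NULL
  }
  structure(list(factor = factor, probes = probes,
                 enriched_regions = enriched_regions,
                 index = make_probe_index(probes)),
            class = "chromatin_track")
}

#' @keywords internal
#' @noRd
make_probe_index <- function(probes) {
  lapply(split(probes[c("pos", "intensity")], probes$chrom), function(d) {
    list(pos = d$pos, cum = c(0, cumsum(d$intensity)))
  })
}

#' @export
print.chromatin_track <- function(x, ...) {
  cat(sprintf("chromatin track '%s': %d probes, %d enriched region(s)\n",
              x$factor, nrow(x$probes), nrow(x$enriched_regions)))
  invisible(x)
}

#' Motif-centered composite profile of a chromatin track
#'
#' Mean probe intensity is computed per motif in `window`-base windows at
#' offsets `-span ... span` stepped by `step`, then averaged over motifs
#' with equal weight regardless of probe count.  Offsets are strand-flipped
#' so profiles are motif-oriented.  Motifs whose window holds no probe are
#' omitted from that offset's mean (count reported).
#'
#' @param track a [chromatin_track()].
#' @param motifs data frame with `chrom`, `center` and optionally `strand`.
#' @param span maximal offset in bases (default 2000).
#' @param window window width (default 100; must be >= `step`).
#' @param step offset step (default 50).
#' @return Object of class `composite_profile`: `factor`, `offsets`,
#'   `mean_intensity`, `se`, `n_motifs` (per offset), `window`, `step`.
#' @export
composite_profile <- function(track, motifs, span = 2000, window = 100,
                              step = 50) {
  stopifnot(inherits(track, "chromatin_track"))
  if (window < step) stop("window must be >= step")
  offsets <- seq.int(-span, span, by = step)
  strand <- if ("strand" %in% names(motifs)) motifs$strand else
    rep("+", nrow(motifs))
  flip <- ifelse(strand == "-", -1, 1)
  mean_intensity <- se <- numeric(length(offsets))
  n_motifs <- integer(length(offsets))
  per_motif <- matrix(NA_real_, nrow = nrow(motifs), ncol = length(offsets))
  for (chrom in unique(motifs$chrom)) {
    mi <- which(motifs$chrom == chrom)
    idx <- track$index[[chrom]]
    if (is.null(idx)) next
    for (oi in seq_along(offsets)) {
      ctr <- motifs$center[mi] + flip[mi] * offsets[oi]
      lo <- ctr - window %/% 2
      hi <- lo + window
      cnt <- count_in_windows(idx$pos, lo, hi)
      sums <- sum_in_windows(idx$pos, idx$cum, lo, hi)
      per_motif[mi[cnt > 0], oi] <- sums[cnt > 0] / cnt[cnt > 0]
    }
  }
  for (oi in seq_along(offsets)) {
    v <- per_motif[, oi]
    v <- v[!is.na(v)]
    n_motifs[oi] <- length(v)
    mean_intensity[oi] <- if (length(v)) mean(v) else NA_real_
    se[oi] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }
  structure(list(factor = track$factor, offsets = offsets,
                 mean_intensity = mean_intensity, se = se,
                 n_motifs = n_motifs, window = window, step = step),
            class = "composite_profile")
}

#' @export
print.composite_profile <- function(x, ...) {
  cat(sprintf("composite profile of '%s': %d offsets (%d-base windows, step %d)\n",
              x$factor, length(x$offsets), x$window, x$step))
  invisible(x)
}

#' Mean probe intensity in a window around a motif
#'
#' @param track a [chromatin_track()].
#' @param chrom chromosome name.
#' @param center window center(s), 0-based.
#' @param window window width (default 400).
#' @return Mean intensity per center; `NA` where the window holds no probe.
#' @export
window_mean_intensity <- function(track, chrom, center, window = 400) {
  stopifnot(inherits(track, "chromatin_track"))
  if (window <= 0) stop("window must be positive")
  idx <- track$index[[chrom]]
  if (is.null(idx)) return(rep(NA_real_, length(center)))
  lo <- center - window %/% 2
  hi <- lo + window
  cnt <- count_in_windows(idx$pos, lo, hi)
  sums <- sum_in_windows(idx$pos, idx$cum, lo, hi)
  ifelse(cnt > 0, sums / cnt, NA_real_)
}

#' Is each motif inside a region of significant enrichment?
#'
#' Membership is by motif center, half-open interval convention (a center
#' exactly at a region end is outside).
#'
#' @param motifs data frame with `chrom` and `center`.
#' @param regions enriched-region data frame (`chrom`, `start`, `end`) or a
#'   [chromatin_track()] (its `enriched_regions` are used).
#' @return Logical vector along `motifs`.
#' @export
enrichment_membership <- function(motifs, regions) {
  if (inherits(regions, "chromatin_track")) regions <- regions$enriched_regions
  out <- rep(FALSE, nrow(motifs))
  if (nrow(regions) == 0L) return(out)
  for (chrom in unique(motifs$chrom)) {
    i <- motifs$chrom == chrom
    k <- regions$chrom == chrom
    out[i] <- overlaps_any0(motifs$center[i], motifs$center[i] + 1L,
                            regions$start[k], regions$end[k])
  }
  out
}

# Exact two-sided Fisher p-value of a 2x2 table by hypergeometric tail-sum:
# the sum of all table probabilities not exceeding the observed one (with
# the customary 1e-7 relative tie tolerance).  One-sided alternatives are
# plain hypergeometric tails.  Vector-free, exact, cross-checked against
# stats::fisher.test in the test suite.
#' @keywords internal
#' @noRd
fisher_exact_p <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  obs <- dens[match(a, support)]
  switch(alternative,
         two.sided = sum(dens[dens <= obs * (1 + 1e-7)]),
         greater = sum(dens[support >= a]),
         less = sum(dens[support <= a]),
         stop("unknown alternative"))
}

#' Fisher exact association of bound vs free motifs with a mark
#'
#' Builds the 2x2 table (bound/free x enriched/unenriched) and computes the
#' exact Fisher p-value (two-sided by default) together with the sample
#' odds ratio (Haldane 0.5 correction when any cell is zero).
#'
#' @param bound_flags logical vector: enrichment membership of bound motifs.
#' @param free_flags logical vector: enrichment membership of free motifs.
#' @param factor optional factor name carried into the result.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return Object of class `association_result`: `factor`, `table` (2x2),
#'   `odds_ratio`, `p_value`.
#' @export
fisher_association <- function(bound_flags, free_flags, factor = NA_character_,
                               alternative = "two.sided") {
  if (length(bound_flags) == 0L || length(free_flags) == 0L) {
    stop("both motif classes must be non-empty")
  }
  a <- sum(bound_flags); b <- sum(!bound_flags)
  c <- sum(free_flags); d <- sum(!free_flags)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("bound", "free"),
                                c("enriched", "unenriched")))
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else (a * d) / (b * c)
  structure(list(factor = factor, table = tab, odds_ratio = or,
                 p_value = fisher_exact_p(a, b, c, d, alternative)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association '%s': OR = %.3g, p = %.3g\n",
              x$factor, x$odds_ratio, x$p_value))
  print(x$table)
  invisible(x)
}

#' Per-factor association table over a set of chromatin tracks
#'
#' Runs [fisher_association()] for every track and reports per-factor
#' counts, odds ratio, and p-value.  Per-factor p-values are reported
#' uncorrected (matching per-factor significance reporting); a
#' Benjamini-Hochberg column is emitted alongside for users.
#'
#' @param tracks named list of [chromatin_track()] objects.
#' @param bound_motifs,free_motifs motif data frames (`chrom`, `center`).
#' @param alternative passed to [fisher_association()].
#' @return Data frame: `factor`, `bound_enriched`, `bound_total`,
#'   `free_enriched`, `free_total`, `odds_ratio`, `p_value`, `p_bh`.
#' @export
associate_tracks <- function(tracks, bound_motifs, free_motifs,
                             alternative = "two.sided") {
  rows <- lapply(tracks, function(tr) {
    bf <- enrichment_membership(bound_motifs, tr)
    ff <- enrichment_membership(free_motifs, tr)
    assoc <- fisher_association(bf, ff, factor = tr$factor,
                                alternative = alternative)
    data.frame(factor = tr$factor,
               bound_enriched = sum(bf), bound_total = length(bf),
               free_enriched = sum(ff), free_total = length(ff),
               odds_ratio = assoc$odds_ratio, p_value = assoc$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' K-means clustering of motif x factor intensity matrices
#'
#' Columns (factors) are z-score standardized (switchable); missing window
#' intensities are imputed with the column mean before clustering.  The best
#' of `restarts` seeded initializations by within-cluster sum of squares is
#' returned; rows are canonically ordered internally so the result is
#' invariant to motif input order under a fixed seed.
#'
#' @param mat numeric matrix, motifs x factors (e.g. 400-base mean probe
#'   intensities).
#' @param k number of clusters (default 5).
#' @param restarts number of random initializations (default 10).
#' @param seed RNG seed.
#' @param standardize z-score columns before clustering (default TRUE).
#' @return List: `cluster` (assignment per input row), `centers` (on the
#'   clustering scale), `tot_withinss`, `imputed` (logical matrix of imputed
#'   cells).
#' @export
cluster_motifs <- function(mat, k = 5, restarts = 10, seed = 1,
                           standardize = TRUE) {
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("k must not exceed the number of motifs")
  imputed <- is.na(mat)
  if (any(imputed)) {
    for (j in seq_len(ncol(mat))) {
      mj <- mean(mat[, j], na.rm = TRUE)
      mat[is.na(mat[, j]), j] <- mj
    }
    log_stage(sprintf("cluster_motifs: %d missing cell(s) imputed with column means",
                      sum(imputed)))
  }
  x <- mat
  if (standardize) {
    x <- scale(mat)
    x[, attr(x, "scaled:scale") == 0 | is.na(attr(x, "scaled:scale"))] <- 0
  }
  ord <- do.call(order, c(as.data.frame(x), list(seq_len(nrow(x)))))
  fit <- with_seed(seed, {
    if (k == nrow(x)) {
      # degenerate: every motif its own cluster, objective 0
      list(cluster = seq_len(nrow(x)), centers = x[ord, , drop = FALSE],
           tot.withinss = 0)
    } else {
      stats::kmeans(x[ord, , drop = FALSE], centers = k, nstart = restarts,
                    iter.max = 100)
    }
  })
  cluster <- integer(nrow(x))
  cluster[ord] <- fit$cluster
  list(cluster = cluster, centers = fit$centers,
       tot_withinss = fit$tot.withinss, imputed = imputed)
}

#' Correlation of mark intensity with factor-binding intensity
#'
#' Pearson correlation (with two-sided p) between the 400-base mean probe
#' intensity and the 240-base normalized ChIP tag count at each motif;
#' intended for the motifs enriched for the mark in question.
#'
#' @param track a [chromatin_track()].
#' @param motifs data frame of motifs enriched for this mark (`chrom`,
#'   `center`; >= 3 rows).
#' @param hsf_lib ChIP [tag_library()] of the profiled factor.
#' @param hsf_window tag-count window (default 240).
#' @param intensity_window probe window (default 400).
#' @return List: `r`, `p_value`, `n`.
#' @export
intensity_binding_correlation <- function(track, motifs, hsf_lib,
                                          hsf_window = 240,
                                          intensity_window = 400) {
  if (nrow(motifs) < 3) stop("at least 3 enriched motifs are required")
  x <- y <- numeric(nrow(motifs))
  for (chrom in unique(motifs$chrom)) {
    i <- motifs$chrom == chrom
    x[i] <- window_mean_intensity(track, chrom, motifs$center[i],
                                  intensity_window)
    y[i] <- window_count(hsf_lib, chrom, motifs$center[i], hsf_window)
  }
  ok <- !is.na(x) & !is.na(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Binding intensity by motif p-value quartile
#'
#' Motifs are split into p-value quartiles; per-motif normalized tag counts
#' in the `window`-base window centered on the motif are reported per
#' quartile.  A window containing several motifs has its count divided by
#' the number of motifs in it.  If all p-values are equal the motifs form a
#' single group (reported as such).
#'
#' @param motifs data frame with `chrom`, `center`, `p_value` (>= 4 rows).
#' @param lib factor ChIP [tag_library()].
#' @param window tag-count window (default 240).
#' @return List: `groups` (named list of per-quartile count vectors),
#'   `table` (quartile, n, median, mean), `degenerate` (TRUE when p-values
#'   do not split).
#' @export
quartile_intensity <- function(motifs, lib, window = 240) {
  if (nrow(motifs) < 4) stop("at least 4 motifs are required")
  counts <- numeric(nrow(motifs))
  share <- numeric(nrow(motifs))
  for (chrom in unique(motifs$chrom)) {
    i <- which(motifs$chrom == chrom)
    counts[i] <- window_count(lib, chrom, motifs$center[i], window)
    ctr <- motifs$center[i]
    lo <- ctr - window %/% 2
    hi <- lo + window
    share[i] <- vapply(seq_along(i), function(j) {
      sum(ctr >= lo[j] & ctr < hi[j])
    }, numeric(1))
  }
  norm <- counts / share
  qs <- stats::quantile(motifs$p_value, c(0.25, 0.5, 0.75), type = 7)
  degenerate <- length(unique(qs)) < 3 || length(unique(motifs$p_value)) == 1
  if (degenerate && length(unique(motifs$p_value)) == 1) {
    groups <- list(all = norm)
  } else {
    grp <- cut(motifs$p_value,
               breaks = unique(c(-Inf, qs, Inf)),
               labels = FALSE)
    groups <- split(norm, paste0("Q", grp))
  }
  tab <- data.frame(quartile = names(groups),
                    n = vapply(groups, length, integer(1)),
                    median = vapply(groups, stats::median, numeric(1)),
                    mean = vapply(groups, mean, numeric(1)))
  rownames(tab) <- NULL
  list(groups = groups, table = tab,
       degenerate = length(groups) == 1)
}
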