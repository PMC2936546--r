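# Tag libraries: aligned 5'-end coordinates with strand, normalized window
# counts, shifted density tracks, and replicate correlation.

#' Construct a tag library
#'
#' A tag library is the unit of ChIP-seq signal: the 5'-end coordinate and
#' strand of every uniquely aligned sequence tag, plus the library total used
#' for per-10-million normalization.  The library total defaults to the
#' number of aligned tags (densities are computed from mapped tags).
#'
#' @param library_id character identifier.
#' @param tags data frame with columns `chrom`, `pos` (0-based 5'-end
#'   coordinate) and `strand` (`"+"`/`"-"`).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param library_total normalization denominator (default `nrow(tags)`).
#' @return Object of class `tag_library`.
#' @export
tag_library <- function(library_id, tags, chrom_sizes,
                        library_total = nrow(tags)) {
  stopifnot(is.data.frame(tags),
            all(c("chrom", "pos", "strand") %in% names(tags)))
  if (library_total < nrow(tags)) {
    stop("library_total must be at least the number of tags")
  }
  if (!all(tags$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(tags$chrom %in% names(chrom_sizes))) {
    stop("tag on a chromosome absent from chrom_sizes")
  }
  if (nrow(tags) > 0 &&
      any(tags$pos < 0 | tags$pos >= chrom_sizes[tags$chrom])) {
    stop("tag position outside its chromosome")
  }
  ord <- order(tags$chrom, tags$pos)
  tags <- tags[ord, , drop = FALSE]
  rownames(tags) <- NULL
  obj <- list(library_id = library_id, tags = tags,
              library_total = library_total,
              chrom_sizes = chrom_sizes,
              index = split(tags$pos, tags$chrom))
  class(obj) <- "tag_library"
  obj
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag library '%s': %d tags on %d chromosome(s), total %d\n",
              x$library_id, nrow(x$tags), length(x$chrom_sizes),
              x$library_total))
  invisible(x)
}

#' Normalized tag count in a window
#'
#' Number of tag 5' ends in the `width`-base window centered on `center`
#' (`[center - width/2, center + width/2)`, even widths placing the center
#' left of the middle pair), scaled to tags per 10 million library
#' sequences.  Vectorised over `center`.  Windows extending past a
#' chromosome edge are clipped (with a message).
#'
#' @param lib a [tag_library()].
#' @param chromosome chromosome name.
#' @param center window center(s), 0-based.
#' @param width window width in bases; the filtering window is 240, the
#'   replicate-correlation window 300, the qPCR-comparison window 320.
#' @return Normalized count(s).
#' @export
window_count <- function(lib, chromosome, center, width = 240) {
  stopifnot(inherits(lib, "tag_library"))
  if (width <= 0) stop("width must be positive")
  if (!chromosome %in% names(lib$chrom_sizes)) {
    stop("unknown chromosome: ", chromosome)
  }
  lo <- center - width %/% 2
  hi <- lo + width
  L <- lib$chrom_sizes[[chromosome]]
  if (any(lo < 0 | hi > L)) {
    log_stage("window_count: window clipped at chromosome edge")
    lo <- pmax(lo, 0)
    hi <- pmin(hi, L)
  }
  pos <- lib$index[[chromosome]]
  if (is.null(pos)) pos <- numeric(0)
  n <- count_in_windows(pos, lo, hi)
  if (lib$library_total == 0) return(rep(0, length(center)))
  n * 1e7 / lib$library_total
}

#' Shifted tag-density track
#'
#' Each tag 5' end is moved `shift` bases in its strand direction (plus
#' strand +shift, minus strand -shift), then binned; bin values are
#' normalized to shifted tags per `bin_width` bases per 10 million library
#' sequences.
#'
#' @param lib a [tag_library()].
#' @param shift shift in bases (>= 0).
#' @param bin_width bin width (default 10).
#' @return Object of class `density_track`: `bin_width`, `shift`, `values`
#'   (data frame `chrom`, `bin_start`, `value`).
#' @export
density_track <- function(lib, shift, bin_width = 10) {
  stopifnot(inherits(lib, "tag_library"))
  if (shift < 0) stop("shift must be >= 0")
  tags <- lib$tags
  spos <- tags$pos + ifelse(tags$strand == "+", shift, -shift)
  bins <- floor(spos / bin_width) * bin_width
  if (nrow(tags) == 0L) {
    values <- data.frame(chrom = character(0), bin_start = numeric(0),
                         value = numeric(0))
  } else {
    agg <- stats::aggregate(list(n = rep(1L, length(bins))),
                            by = list(chrom = tags$chrom, bin_start = bins),
                            FUN = sum)
    agg <- agg[order(agg$chrom, agg$bin_start), , drop = FALSE]
    rownames(agg) <- NULL
    values <- data.frame(chrom = agg$chrom, bin_start = agg$bin_start,
                         value = agg$n * 1e7 / lib$library_total)
  }
  structure(list(bin_width = bin_width, shift = shift, values = values,
                 library_id = lib$library_id,
                 library_total = lib$library_total),
            class = "density_track")
}

#' Replicate correlation over peak windows
#'
#' Per-peak densities are the window counts divided by the sum over all peak
#' windows (per library, so each library's densities sum to 1), correlated
#' by Pearson's r.
#'
#' @param peaks data frame with `chrom` and `center` columns (>= 3 rows).
#' @param libA,libB [tag_library()] objects.
#' @param width window width (default 300).
#' @return Pearson correlation coefficient.
#' @export
replicate_correlation <- function(peaks, libA, libB, width = 300) {
  if (nrow(peaks) < 3) stop("at least 3 peaks are required")
  ca <- cb <- numeric(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    i <- peaks$chrom == chrom
    ca[i] <- window_count(libA, chrom, peaks$center[i], width)
    cb[i] <- window_count(libB, chrom, peaks$center[i], width)
  }
  if (sum(ca) == 0 || sum(cb) == 0) {
    stop("all-zero library over the peak windows: correlation undefined")
  }
  stats::cor(ca / sum(ca), cb / sum(cb))
}

# Positions after strand-directed shifting, per chromosome, sorted.
#' @keywords internal
#' @noRd
shifted_positions <- function(lib, shift) {
  spos <- lib$tags$pos + ifelse(lib$tags$strand == "+", shift, -shift)
  lapply(split(spos, lib$tags$chrom), sort)
}
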