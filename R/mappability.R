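# k-mer mappability: exact uniqueness tracks (counting forward and
# reverse-complement occurrences jointly) and the definition of the
# factor-free motif set.

#' Exact k-mer uniqueness track
#'
#' A start position is unique iff its k-mer occurs exactly once in the
#' genome, counting forward and reverse-complement occurrences jointly (a
#' sequenced tag can originate from either strand).  A reverse-complement
#' palindromic k-mer therefore matches itself twice and is never unique.
#' k-mers containing N are marked non-unique.  Exact hash-based counting;
#' production genomes may substitute an external mappability track through
#' the same interface.
#'
#' @param genome genome object accepted by [scan_genome()].
#' @param k tag length in bases (default 40).
#' @return Object of class `mappability_track`: `k`, `chrom_sizes`, and
#'   `flags`, a per-chromosome logical vector over start positions
#'   `0 ... L - k`.
#' @export
kmer_uniqueness <- function(genome, k = 40) {
  g <- genome_as_character(genome)
  sizes <- vapply(g, nchar, integer(1))
  if (any(k > sizes)) stop("k exceeds a chromosome length")
  fwd <- lapply(g, function(s) {
    n <- nchar(s) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  })
  rc <- lapply(g, function(s) {
    r <- revcomp_chr(s)
    n <- nchar(r) - k + 1L
    substring(r, seq_len(n), seq_len(n) + k - 1L)
  })
  all_kmers <- c(unlist(fwd, use.names = FALSE), unlist(rc, use.names = FALSE))
  counts <- table(all_kmers)
  flags <- lapply(fwd, function(km) {
    ok <- as.vector(counts[km]) == 1L
    ok & !grepl("N", km, fixed = TRUE)
  })
  structure(list(k = k, chrom_sizes = sizes, flags = flags,
                 cache = new.env(parent = emptyenv())),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  total <- sum(vapply(x$flags, length, integer(1)))
  uniq <- sum(vapply(x$flags, sum, numeric(1)))
  cat(sprintf("mappability track (k = %d): %.1f%% of %d start positions unique\n",
              x$k, 100 * uniq / total, total))
  invisible(x)
}

#' Is the window around a motif fully mappable?
#'
#' TRUE iff every k-mer whose footprint lies fully inside the `window`-base
#' window centered on `motif_center` is unique.  Windows clipped at a
#' chromosome edge return FALSE (conservative, logged).  Vectorised over
#' `motif_center`.
#'
#' @param track a [kmer_uniqueness()] track.
#' @param chrom chromosome name.
#' @param motif_center window center(s), 0-based.
#' @param window window width (default 400; must be >= k).
#' @return Logical vector.
#' @export
window_fully_mappable <- function(track, chrom, motif_center, window = 400) {
  stopifnot(inherits(track, "mappability_track"))
  if (window < track$k) stop("window must be at least k")
  if (!chrom %in% names(track$flags)) stop("unknown chromosome: ", chrom)
  flags <- track$flags[[chrom]]
  cs_key <- paste0("cs_", chrom)
  cs <- track$cache[[cs_key]]
  if (is.null(cs)) {
    cs <- c(0, cumsum(flags))
    track$cache[[cs_key]] <- cs
  }
  L <- track$chrom_sizes[[chrom]]
  lo <- motif_center - window %/% 2          # first base of the window
  hi <- lo + window                          # one past the last base
  first <- lo                                # first k-mer start inside
  last <- hi - track$k                       # last k-mer start inside
  clipped <- lo < 0 | hi > L
  if (any(clipped)) log_stage("window_fully_mappable: window clipped at edge -> FALSE")
  n_start <- pmax(last - first + 1, 0)
  got <- numeric(length(motif_center))
  inb <- !clipped & n_start > 0
  if (any(inb)) {
    got[inb] <- cs[last[inb] + 2] - cs[first[inb] + 1]
  }
  !clipped & n_start > 0 & got == n_start
}

#' Define the factor-free motif set
#'
#' Free motifs are scan hits at or below `p_threshold` whose 400-base
#' flanking window is fully mappable and which neither overlap any
#' RNAi-sensitive peak boundary (by at least one base of motif footprint)
#' nor coincide with a bound motif assignment.  Bound and free sets are
#' disjoint by construction.
#'
#' @param hits motif hits from [scan_genome()] (scanned at or below
#'   `p_threshold`).
#' @param track a [kmer_uniqueness()] mappability track.
#' @param sensitive_peaks data frame of RNAi-sensitive peaks (boundaries
#'   `start`, `end`).
#' @param bound_motifs optional data frame of bound motif hits (their
#'   `chrom`/`start` rows are excluded).
#' @param p_threshold conservative motif conformity cutoff (default 5e-6).
#' @param mappability_window flanking window width (default 400).
#' @return Subset of `hits` forming the free class.
#' @export
find_free_motifs <- function(hits, track, sensitive_peaks,
                             bound_motifs = NULL, p_threshold = 5e-6,
                             mappability_window = 400) {
  if (nrow(hits) == 0L) return(hits)
  w <- nchar(hits$sequence[1])
  keep <- hits$p_value <= p_threshold
  for (chrom in unique(hits$chrom)) {
    i <- which(hits$chrom == chrom)
    keep[i] <- keep[i] & window_fully_mappable(track, chrom, hits$center[i],
                                               mappability_window)
    k <- sensitive_peaks$chrom == chrom
    if (any(k)) {
      ov <- overlaps_any0(hits$start[i], hits$start[i] + w,
                          sensitive_peaks$start[k], sensitive_peaks$end[k])
      keep[i] <- keep[i] & !ov
    }
  }
  if (!is.null(bound_motifs) && nrow(bound_motifs) > 0L) {
    keep <- keep & !(paste(hits$chrom, hits$start) %in%
                       paste(bound_motifs$chrom, bound_motifs$start))
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
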