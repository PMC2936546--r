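# Internal helpers shared across modules.
#
# Coordinate convention: all genomic coordinates in this package are 0-based,
# half-open [start, end), matching BED.  Conversion to the 1-based closed
# convention of IRanges happens only inside the helpers below.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators are pure
#' functions of (parameters, seed) without clobbering the session RNG.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stream sub-seed, kept below 2^31
#' @keywords internal
#' @noRd
sub_seed <- function(seed, stream) {
  (abs(as.double(seed)) + 104729 * as.double(stream)) %% 2147483587
}

# IRanges view of 0-based half-open intervals.
#' @keywords internal
#' @noRd
iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

#' Total number of bases covered by the union of 0-based half-open intervals
#' @keywords internal
#' @noRd
union_coverage0 <- function(start, end) {
  if (length(start) == 0L) return(0)
  sum(IRanges::width(IRanges::reduce(iranges0(start, end))))
}

#' For each query interval, does it overlap any subject interval (>= 1 base)?
#' Both sets 0-based half-open, on a single chromosome at a time.
#' @keywords internal
#' @noRd
overlaps_any0 <- function(qs, qe, ss, se) {
  if (length(qs) == 0L) return(logical(0))
  if (length(ss) == 0L) return(rep(FALSE, length(qs)))
  IRanges::overlapsAny(iranges0(qs, qe), iranges0(ss, se))
}

#' Merge 0-based half-open intervals into their union
#' @keywords internal
#' @noRd
reduce0 <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- IRanges::reduce(iranges0(start, end))
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

#' Counts of sorted integer positions falling in [lo, hi), vectorised over
#' windows.  `pos` must be sorted ascending.
#' @keywords internal
#' @noRd
count_in_windows <- function(pos, lo, hi) {
  findInterval(hi - 0.5, pos) - findInterval(lo - 0.5, pos)
}

#' As count_in_windows but returning sums of a companion value vector,
#' using a precomputed cumulative sum `cv = c(0, cumsum(values))`.
#' @keywords internal
#' @noRd
sum_in_windows <- function(pos, cv, lo, hi) {
  cv[findInterval(hi - 0.5, pos) + 1L] - cv[findInterval(lo - 0.5, pos) + 1L]
}

DNA_BASES4 <- c("A", "C", "G", "T")

#' Encode an ACGT string as integer codes (A=1, C=2, G=3, T=4, other=5)
#' @keywords internal
#' @noRd
encode_dna <- function(x) {
  raw <- utf8ToInt(toupper(x))
  code <- rep.int(5L, length(raw))
  code[raw == 65L] <- 1L  # A
  code[raw == 67L] <- 2L  # C
  code[raw == 71L] <- 3L  # G
  code[raw == 84L] <- 4L  # T
  code
}

#' Reverse complement of a character string (IUPAC bases other than ACGT
#' are mapped to N)
#' @keywords internal
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Coerce a genome to a named character vector of chromosome sequences
#' @keywords internal
#' @noRd
genome_as_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else if (methods::is(genome, "DNAString")) {
    out <- stats::setNames(as.character(genome), "chrS")
  } else if (is.character(genome)) {
    out <- genome
    if (is.null(names(out))) names(out) <- paste0("chr", seq_along(out))
  } else {
    stop("genome must be a DNAStringSet, DNAString or named character vector")
  }
  toupper(out)
}

#' @keywords internal
#' @noRd
genome_sizes <- function(genome) {
  g <- genome_as_character(genome)
  vapply(g, nchar, integer(1))
}

#' Stage-level log line
#' @keywords internal
#' @noRd
log_stage <- function(...) message("[kdchip] ", ...)
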