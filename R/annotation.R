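# Annotation of motifs against gene models: promoter / genic / intergenic
# classification and base-pair genome composition.

# TSS of a gene model under the 0-based half-open convention: start on the
# plus strand, end - 1 on the minus strand.
#' @keywords internal
#' @noRd
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Classify motifs against gene models
#'
#' A motif (positioned at its center) is `promoter` when it lies in the
#' 500-base window upstream of any TSS (strand-aware), `genic` when inside
#' any gene body, and `intergenic` when neither.  Promoter and genic may
#' both be true: a sequence can sit inside one gene and upstream of
#' another's TSS.  Promoter windows are not clipped by neighbouring gene
#' bodies.
#'
#' @param motifs data frame with `chrom` and `center` columns.
#' @param genes gene models: `chrom`, `start`, `end` (half-open), `strand`.
#' @param promoter_size upstream window in bases (default 500).
#' @return `motifs` with logical columns `promoter`, `genic`, `intergenic`
#'   appended.
#' @export
classify_motif <- function(motifs, genes, promoter_size = 500) {
  n <- nrow(motifs)
  promoter <- genic <- rep(FALSE, n)
  if (nrow(genes) > 0L) {
    prom <- promoter_windows(genes, promoter_size)
    for (chrom in unique(motifs$chrom)) {
      i <- motifs$chrom == chrom
      gk <- genes$chrom == chrom
      pk <- prom$chrom == chrom
      genic[i] <- overlaps_any0(motifs$center[i], motifs$center[i] + 1L,
                                genes$start[gk], genes$end[gk])
      promoter[i] <- overlaps_any0(motifs$center[i], motifs$center[i] + 1L,
                                   prom$start[pk], prom$end[pk])
    }
  }
  out <- motifs
  out$promoter <- promoter
  out$genic <- genic
  out$intergenic <- !promoter & !genic
  out
}

#' @keywords internal
#' @noRd
promoter_windows <- function(genes, promoter_size) {
  tss <- gene_tss(genes)
  start <- ifelse(genes$strand == "+", tss - promoter_size, tss + 1L)
  end <- start + promoter_size
  data.frame(chrom = genes$chrom,
             start = pmax(as.integer(start), 0L),
             end = as.integer(end))
}

#' Annotation-class composition of a motif set
#'
#' Per-class counts and fractions (fractions may sum to more than 1 because
#' promoter and genic membership overlap; the dual-membership count is
#' reported separately).
#'
#' @param motifs data frame with `chrom` and `center`.
#' @param genes gene models.
#' @param promoter_size upstream window (default 500).
#' @return Data frame with one row per class (`promoter`, `genic`,
#'   `intergenic`, `promoter_and_genic`): `count`, `fraction`.
#' @export
class_composition <- function(motifs, genes, promoter_size = 500) {
  if (nrow(motifs) == 0L) stop("at least one motif is required")
  cls <- classify_motif(motifs, genes, promoter_size)
  n <- nrow(cls)
  counts <- c(promoter = sum(cls$promoter),
              genic = sum(cls$genic),
              intergenic = sum(cls$intergenic),
              promoter_and_genic = sum(cls$promoter & cls$genic))
  data.frame(class = names(counts), count = as.integer(counts),
             fraction = as.numeric(counts) / n)
}

#' Genome-fraction composition of gene bodies and promoters
#'
#' Fraction of bases covered by the union of gene bodies, and by the union
#' of promoter windows (promoter bases inside gene bodies still count
#' toward the promoter fraction).
#'
#' @param genes gene models.
#' @param genome_length total genome length (scalar or named per-chromosome
#'   vector).
#' @param promoter_size upstream window (default 500).
#' @return List with `fraction_genic` and `fraction_promoter`.
#' @export
genome_composition <- function(genes, genome_length, promoter_size = 500) {
  total <- sum(genome_length)
  if (total <= 0) stop("genome_length must be positive")
  prom <- promoter_windows(genes, promoter_size)
  genic_bp <- 0
  prom_bp <- 0
  for (chrom in unique(genes$chrom)) {
    gk <- genes$chrom == chrom
    genic_bp <- genic_bp + union_coverage0(genes$start[gk], genes$end[gk])
    pk <- prom$chrom == chrom
    prom_bp <- prom_bp + union_coverage0(prom$start[pk], prom$end[pk])
  }
  list(fraction_genic = genic_bp / total,
       fraction_promoter = prom_bp / total)
}
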