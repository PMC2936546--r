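# Plain-text readers and writers for the pipeline's interchange formats.
# All coordinates written and read are 0-based half-open (BED convention).
# Tag BED files encode each tag as a 1-base interval at its 5' end: for a
# plus-strand tag start = 5' position, for a minus-strand tag end - 1 = 5'
# position, which coincide for 1-base intervals.  Output is deterministic:
# no timestamps, fixed column order.

#' @keywords internal
#' @noRd
provenance_header <- function(what, extra = NULL) {
  c(sprintf("# kdchip %s; %s",
            as.character(utils::packageVersion("kdchip")), what),
    if (!is.null(extra)) paste0("# ", extra))
}

#' @keywords internal
#' @noRd
write_tsv_headered <- function(df, path, header_lines) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write a tag library as 6-column BED
#'
#' @param lib a [tag_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tags_bed <- function(lib, path) {
  meta <- sprintf("library_id=%s; library_total=%d; chrom_sizes=%s",
                  lib$library_id, lib$library_total,
                  paste(sprintf("%s:%d", names(lib$chrom_sizes),
                                lib$chrom_sizes), collapse = ","))
  df <- data.frame(chrom = lib$tags$chrom, start = lib$tags$pos,
                   end = lib$tags$pos + 1L, name = lib$library_id,
                   score = 0L, strand = lib$tags$strand)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header("tag library BED6", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tag library from 6-column BED
#'
#' @param path BED file written by [write_tags_bed()] (or any BED6 of
#'   1-base 5'-end intervals with a `library_total`/`chrom_sizes` header).
#' @param chrom_sizes named vector of chromosome lengths; taken from the
#'   file header when absent.
#' @param library_id identifier; taken from the header or file name.
#' @return A [tag_library()].
#' @export
read_tags_bed <- function(path, chrom_sizes = NULL, library_id = NULL) {
  header <- grep("^#", readLines(path, n = 5L), value = TRUE)
  meta <- paste(header, collapse = " ")
  if (is.null(library_id)) {
    m <- regmatches(meta, regexpr("library_id=[^;]+", meta))
    library_id <- if (length(m)) sub("library_id=", "", m) else
      sub("\\.bed$", "", basename(path))
  }
  total <- NA_integer_
  m <- regmatches(meta, regexpr("library_total=[0-9]+", meta))
  if (length(m)) total <- as.integer(sub("library_total=", "", m))
  if (is.null(chrom_sizes)) {
    m <- regmatches(meta, regexpr("chrom_sizes=[^; ]+", meta))
    if (!length(m)) stop("chrom_sizes not given and absent from header")
    parts <- strsplit(sub("chrom_sizes=", "", m), ",")[[1]]
    kv <- strsplit(parts, ":")
    chrom_sizes <- stats::setNames(vapply(kv, function(x) as.integer(x[2]),
                                          integer(1)),
                                   vapply(kv, `[`, character(1), 1))
  }
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  tags <- data.frame(chrom = df$chrom, pos = df$start, strand = df$strand)
  if (is.na(total)) total <- nrow(tags)
  tag_library(library_id, tags, chrom_sizes, library_total = total)
}

#' Write peaks as BED6+ with classification columns
#'
#' Columns: chrom, start, end, name, -log10 FDR (capped at 1000), strand
#' ".", center, caller, classification, intensity_exp, intensity_kd.
#'
#' @param peaks peak data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  n <- nrow(peaks)
  get0c <- function(col, default) {
    if (col %in% names(peaks)) peaks[[col]] else rep(default, n)
  }
  df <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                   name = sprintf("peak_%d", seq_len(n)),
                   score = round(pmin(-log10(pmax(peaks$fdr, 1e-300)), 1000), 4),
                   strand = ".",
                   center = peaks$center,
                   caller = get0c("caller", "."),
                   classification = get0c("classification", "unclassified"),
                   intensity_exp = round(get0c("intensity_exp", NA_real_), 4),
                   intensity_kd = round(get0c("intensity_kd", NA_real_), 4))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header("peaks BED6+"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read peaks from BED6+ (external caller output)
#'
#' Accepts the format of [write_peaks_bed()]; files with only the first six
#' columns get `center = (start + end) / 2`.
#'
#' @param path BED file.
#' @param caller caller label to record when the file carries none.
#' @return Peak data frame.
#' @export
read_peaks_bed <- function(path, caller = "external") {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    center = if (ncol(df) >= 7) as.integer(df[[7]]) else
                      as.integer((df[[2]] + df[[3]]) %/% 2),
                    caller = if (ncol(df) >= 8) as.character(df[[8]]) else caller,
                    fdr = if (ncol(df) >= 5) 10^(-as.numeric(df[[5]])) else NA_real_)
  if (ncol(df) >= 9) out$classification <- as.character(df[[9]])
  out
}

#' Write motif hits as BED6+ (score = -log10 p, capped)
#'
#' @param hits motif hit data frame from [scan_genome()].
#' @param path output file.
#' @param extra optional extra columns (e.g. class flags) to append.
#' @return `path`, invisibly.
#' @export
write_motifs_bed <- function(hits, path, extra = NULL) {
  w <- if (nrow(hits)) nchar(hits$sequence[1]) else 0L
  df <- data.frame(chrom = hits$chrom, start = hits$start,
                   end = hits$start + w,
                   name = hits$sequence,
                   score = round(pmin(-log10(pmax(hits$p_value, 1e-300)), 1000), 4),
                   strand = hits$strand,
                   score_bits = round(hits$score, 4),
                   p_value = signif(hits$p_value, 6))
  if (!is.null(extra)) df <- cbind(df, extra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header("motif hits BED6+"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as BED12
#'
#' Single-block BED12 records (the pipeline does not model exon structure).
#'
#' @param genes gene model data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genes_bed12 <- function(genes, path) {
  n <- nrow(genes)
  df <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                   name = sprintf("gene_%d", seq_len(n)), score = 0L,
                   strand = genes$strand, thickStart = genes$start,
                   thickEnd = genes$end, itemRgb = "0,0,0", blockCount = 1L,
                   blockSizes = genes$end - genes$start,
                   blockStarts = 0L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header("gene models BED12"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED (6 or 12 columns)
#'
#' @param path BED file.
#' @return Gene model data frame (`chrom`, `start`, `end`, `strand`).
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("gene BED needs at least 6 columns (strand)")
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), strand = as.character(df[[6]]))
}

#' Write a chromatin track as bedGraph plus a BED of enriched regions
#'
#' Each probe is written as a `probe_span`-base bedGraph interval starting
#' at the probe position.
#'
#' @param track a [chromatin_track()].
#' @param path bedGraph output file.
#' @param regions_path optional BED output for the enriched regions.
#' @param probe_span interval width per probe (default 1).
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path, regions_path = NULL,
                                 probe_span = 1L) {
  df <- data.frame(chrom = track$probes$chrom, start = track$probes$pos,
                   end = track$probes$pos + probe_span,
                   value = round(track$probes$intensity, 6))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(sprintf("chromatin track '%s' bedGraph",
                                       track$factor)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(regions_path)) {
    rdf <- track$enriched_regions
    con2 <- file(regions_path, open = "wt")
    writeLines(provenance_header(sprintf("enriched regions of '%s'",
                                         track$factor)), con2)
    if (nrow(rdf) > 0L) {
      utils::write.table(rdf, con2, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    close(con2)
  }
  invisible(path)
}

#' Read a chromatin track from bedGraph (+ optional enriched-region BED)
#'
#' @param path bedGraph file (probe value at interval start).
#' @param factor factor name; default from the file name.
#' @param regions_path optional BED of enriched regions.
#' @return A [chromatin_track()].
#' @export
read_track_bedgraph <- function(path, factor = NULL, regions_path = NULL) {
  if (is.null(factor)) factor <- sub("\\.(bedgraph|bdg|wig)$", "",
                                     basename(path))
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE)
  probes <- data.frame(chrom = as.character(df[[1]]),
                       pos = as.integer(df[[2]]),
                       intensity = as.numeric(df[[4]]))
  regions <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0))
  if (!is.null(regions_path) && file.exists(regions_path)) {
    lines <- readLines(regions_path)
    if (any(!grepl("^#", lines) & nzchar(lines))) {
      rdf <- utils::read.table(regions_path, sep = "\t", comment.char = "#",
                               header = FALSE, stringsAsFactors = FALSE)
      regions <- data.frame(chrom = as.character(rdf[[1]]),
                            start = as.integer(rdf[[2]]),
                            end = as.integer(rdf[[3]]))
    }
  }
  chromatin_track(factor, probes, regions)
}

#' Serialize a PSWM in MEME minimal motif format
#'
#' @param pswm a [pswm()] object.
#' @param path output file.
#' @param name motif name (default "HSE").
#' @return `path`, invisibly.
#' @export
write_pswm_meme <- function(pswm, path, name = "HSE") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES4, pswm$background),
                     collapse = " "), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       pswm$width)), con)
  apply(pswm$probabilities, 2, function(p) {
    writeLines(paste(sprintf("%.6f", p), collapse = " "), con)
  })
  invisible(path)
}

#' Read a PSWM from MEME minimal motif format
#'
#' @param path MEME-format file (first motif is read).
#' @param pseudocount recorded pseudocount (default 0).
#' @return A [pswm()] object.
#' @export
read_pswm_meme <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, 8, by = 2)])
  }
  ml <- grep("^letter-probability matrix", lines)[1]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[ml]))
  rows <- lines[(ml + 1):(ml + w)]
  prob <- t(vapply(rows, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }, numeric(4)))
  dimnames(prob) <- NULL
  prob <- prob / rowSums(prob)               # guard rounding drift
  pswm(t(prob), background = bg, pseudocount = pseudocount)
}

#' Write the mappability track as a BED of non-unique intervals
#'
#' @param track a [kmer_uniqueness()] track.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mappability_bed <- function(track, path) {
  rows <- list()
  for (chrom in names(track$flags)) {
    f <- !track$flags[[chrom]]
    if (!any(f)) next
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                end = ends[keep])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(sprintf("non-unique %d-mer start intervals",
                                       track$k)), con)
  if (nrow(df) > 0L) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
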