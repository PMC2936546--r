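# Position-specific weight matrix (PSWM) model for the heat-shock element:
# construction from aligned occurrences, log-odds scoring, exact p-values by
# dynamic-programming convolution, genome scanning, and motif-to-peak
# assignment.

#' Construct a PSWM object
#'
#' Log-odds scores (bits) are quantised to the `score_granularity` lattice at
#' construction time, so that window scores and the exact score distribution
#' used for p-values live on one shared discrete score space.  At the default
#' granularity of 1e-3 bits the quantisation perturbs scores by at most
#' `width/2000` bits.
#'
#' @param probabilities 4 x width numeric matrix of per-position base
#'   probabilities, rows in A, C, G, T order; each column must sum to 1.
#' @param background length-4 base distribution of the background model
#'   (A, C, G, T), summing to 1.
#' @param pseudocount pseudocount mass recorded for provenance (the
#'   probabilities are taken as given).
#' @param score_granularity lattice step, in bits, for the discretised score
#'   space (default 1e-3).
#' @return An object of class `pswm` with elements `width`, `probabilities`,
#'   `background`, `pseudocount`, `logodds` (quantised bits) and
#'   `score_granularity`.
#' @export
pswm <- function(probabilities, background = rep(0.25, 4), pseudocount = 0,
                 score_granularity = 1e-3) {
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != 4L) stop("probabilities must have 4 rows (A, C, G, T)")
  if (any(probabilities < 0)) stop("probabilities must be non-negative")
  csum <- colSums(probabilities)
  if (any(abs(csum - 1) > 1e-9)) stop("each PSWM position must sum to 1")
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0)) {
    stop("background must be a positive length-4 distribution summing to 1")
  }
  rownames(probabilities) <- DNA_BASES4
  g <- score_granularity
  lo <- log2(probabilities / background)
  lo[probabilities == 0] <- -Inf
  loq <- round(lo / g) * g                  # -Inf preserved
  obj <- list(width = ncol(probabilities),
              probabilities = probabilities,
              background = background,
              pseudocount = pseudocount,
              score_granularity = g,
              logodds = loq,
              cache = new.env(parent = emptyenv()))
  class(obj) <- "pswm"
  obj
}

#' @export
print.pswm <- function(x, ...) {
  cat(sprintf("PSWM of width %d (granularity %g bits)\n", x$width,
              x$score_granularity))
  cat("consensus:", paste0(DNA_BASES4[apply(x$probabilities, 2, which.max)],
                           collapse = ""), "\n")
  invisible(x)
}

#' Build a PSWM from aligned motif occurrences
#'
#' Per-position probabilities are `(counts + pseudocount * background) /
#' (n + pseudocount)` where `n` counts the non-N bases at that position; N
#' bases contribute nothing.  Log-odds are `log2(probability / background)`.
#'
#' @param occurrences character vector of equal-length sequences over
#'   A/C/G/T/N.
#' @param background length-4 background base distribution (A, C, G, T).
#' @param pseudocount total pseudocount mass (default 0.25).
#' @param score_granularity passed to [pswm()].
#' @return A `pswm` object.
#' @export
build_pswm <- function(occurrences, background = rep(0.25, 4),
                       pseudocount = 0.25, score_granularity = 1e-3) {
  if (length(occurrences) == 0L) stop("at least one occurrence is required")
  occurrences <- toupper(occurrences)
  w <- unique(nchar(occurrences))
  if (length(w) != 1L) stop("all occurrences must have the same length")
  bad <- grepl("[^ACGTN]", occurrences)
  if (any(bad)) {
    stop("occurrence contains a symbol outside A/C/G/T/N: ",
         occurrences[which(bad)[1]])
  }
  chars <- matrix(unlist(strsplit(occurrences, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(occurrences), byrow = TRUE)
  counts <- vapply(seq_len(w), function(j) {
    tabulate(factor(chars[, j], levels = DNA_BASES4), nbins = 4L)
  }, numeric(4))
  counts <- matrix(counts, nrow = 4L)
  n_j <- colSums(counts)
  if (any(n_j + pseudocount == 0)) {
    stop("a position has no informative base and no pseudocount")
  }
  prob <- sweep(counts + pseudocount * background,
                2, n_j + pseudocount, "/")
  pswm(prob, background = background, pseudocount = pseudocount,
       score_granularity = score_granularity)
}

#' Score one window against a PSWM
#'
#' Sum of per-position log-odds (bits).  For the minus strand the window is
#' reverse-complemented before scoring.  Windows containing N (or any
#' non-ACGT symbol) score `-Inf` and can never become hits.
#'
#' @param pswm a [pswm()] object.
#' @param window character scalar, length equal to `pswm$width`.
#' @param strand `"+"` or `"-"`.
#' @return Score in bits (possibly `-Inf`).
#' @export
score_sequence <- function(pswm, window, strand = "+") {
  stopifnot(inherits(pswm, "pswm"))
  if (nchar(window) != pswm$width) {
    stop(sprintf("window length %d does not match PSWM width %d",
                 nchar(window), pswm$width))
  }
  if (strand == "-") window <- revcomp_chr(window)
  code <- encode_dna(window)
  if (any(code == 5L)) return(-Inf)
  sum(pswm$logodds[cbind(code, seq_len(pswm$width))])
}

# Exact distribution of the integer lattice score of a background-distributed
# window: dynamic-programming convolution of the per-position score
# distributions.  Cached on the pswm object.
#' @keywords internal
#' @noRd
pswm_score_distribution <- function(pswm) {
  cache <- pswm$cache
  if (!is.null(cache$dist)) return(cache$dist)
  g <- pswm$score_granularity
  E <- round(pswm$logodds / g)              # integer lattice, -Inf allowed
  bg <- pswm$background
  lo_j <- apply(E, 2, function(col) min(col[is.finite(col)]))
  hi_j <- apply(E, 2, function(col) max(col[is.finite(col)]))
  cur <- 1                                  # P(partial sum = cur_min + i - 1)
  cur_min <- 0
  for (j in seq_len(pswm$width)) {
    new_len <- length(cur) + (hi_j[j] - lo_j[j])
    new <- numeric(new_len)
    for (b in 1:4) {
      e <- E[b, j]
      if (!is.finite(e)) next               # mass falls to -Inf, dropped
      off <- e - lo_j[j]
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + bg[b] * cur
    }
    cur <- new
    cur_min <- cur_min + lo_j[j]
  }
  tail <- rev(cumsum(rev(cur)))             # tail[i] = P(score >= cur_min+i-1)
  dist <- list(min_total = cur_min,
               max_total = cur_min + length(cur) - 1L,
               tail = tail,
               finite_mass = sum(cur))
  cache$dist <- dist
  dist
}

#' Exact p-value of a PSWM score
#'
#' `P(score(random background window) >= score)`, computed exactly on the
#' PSWM's discrete score lattice by dynamic-programming convolution of the
#' per-position score distributions.  Vectorised over `score`.
#'
#' @param pswm a [pswm()] object.
#' @param score numeric vector of scores in bits (`-Inf`/`Inf` allowed).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
score_pvalue <- function(pswm, score) {
  stopifnot(inherits(pswm, "pswm"))
  d <- pswm_score_distribution(pswm)
  g <- pswm$score_granularity
  out <- numeric(length(score))
  neg <- is.infinite(score) & score < 0
  pos <- is.infinite(score) & score > 0
  fin <- is.finite(score)
  out[neg] <- 1
  out[pos] <- 0
  if (any(fin)) {
    t <- round(score[fin] / g)
    p <- numeric(sum(fin))
    below <- t <= d$min_total
    above <- t > d$max_total
    mid <- !below & !above
    # a finite query excludes -Inf outcomes, so the floor is the finite mass
    p[below] <- d$finite_mass
    p[above] <- 0
    p[mid] <- d$tail[t[mid] - d$min_total + 1]
    out[fin] <- p
  }
  out
}

# Lowest lattice score whose tail probability is <= p_threshold, or NULL if
# no achievable score qualifies.
#' @keywords internal
#' @noRd
pswm_score_threshold <- function(pswm, p_threshold) {
  d <- pswm_score_distribution(pswm)
  idx <- which(d$tail <= p_threshold)
  if (length(idx) == 0L) return(NULL)
  d$min_total + idx[1] - 1L
}

# Integer-lattice sliding scores of a coded sequence for an integer score
# matrix E5 (5 rows: A C G T other; column-major), -Inf poisoning non-ACGT.
#' @keywords internal
#' @noRd
sliding_scores <- function(code, E5, w) {
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) {
    s <- s + E5[(j - 1L) * 5L + code[j:(j + n - 1L)]]
  }
  s
}

#' Scan a genome for PSWM hits at a p-value threshold
#'
#' Every window on both strands whose exact p-value is at or below
#' `p_threshold` is reported.  Opposite-strand hits whose footprints overlap
#' by at least half the motif width are collapsed to the better-scoring
#' strand (ties: plus strand, then lower coordinate).
#'
#' @param genome `DNAStringSet`, `DNAString`, or named character vector of
#'   chromosome sequences.
#' @param pswm a [pswm()] object.
#' @param p_threshold hit threshold in (0, 1).
#' @param collapse_overlap minimum fractional footprint overlap for
#'   opposite-strand collapsing (default 0.5).
#' @return Data frame of motif hits: `chrom`, `start` (0-based), `strand`,
#'   `sequence` (motif-strand), `score` (bits), `p_value`, `center`.
#' @export
scan_genome <- function(genome, pswm, p_threshold, collapse_overlap = 0.5) {
  stopifnot(inherits(pswm, "pswm"))
  if (!(p_threshold > 0 && p_threshold < 1)) {
    stop("p_threshold must lie in (0, 1)")
  }
  g <- genome_as_character(genome)
  w <- pswm$width
  gr <- pswm$score_granularity
  t_star <- pswm_score_threshold(pswm, p_threshold)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), sequence = character(0),
                      score = numeric(0), p_value = numeric(0),
                      center = integer(0))
  if (is.null(t_star)) return(empty)
  E <- round(pswm$logodds / gr)
  E5 <- rbind(E, rep(-Inf, w))
  # minus-strand scores at the same start = scores of the reverse-complement
  # matrix on the forward sequence
  Erc <- E[4:1, w:1, drop = FALSE]
  E5rc <- rbind(Erc, rep(-Inf, w))
  out <- list()
  for (chrom in names(g)) {
    seqc <- g[[chrom]]
    if (nchar(seqc) < w) {
      log_stage(sprintf("scan_genome: %s shorter than motif width, skipped", chrom))
      next
    }
    code <- encode_dna(seqc)
    sp <- sliding_scores(code, E5, w)
    sm <- sliding_scores(code, E5rc, w)
    hit_p <- which(sp >= t_star)
    hit_m <- which(sm >= t_star)
    if (length(hit_p) + length(hit_m) == 0L) next
    df <- rbind(
      data.frame(start = hit_p - 1L, strand = rep("+", length(hit_p)),
                 int_score = sp[hit_p]),
      data.frame(start = hit_m - 1L, strand = rep("-", length(hit_m)),
                 int_score = sm[hit_m])
    )
    df <- df[order(df$start, df$strand), , drop = FALSE]
    df <- collapse_opposite_strand(df, w, collapse_overlap)
    seqs <- substring(seqc, df$start + 1L, df$start + w)
    minus <- df$strand == "-"
    if (any(minus)) {
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    }
    score <- df$int_score * gr
    out[[chrom]] <- data.frame(chrom = chrom, start = df$start,
                               strand = df$strand, sequence = seqs,
                               score = score,
                               p_value = score_pvalue(pswm, score),
                               center = df$start + w %/% 2L)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Collapse opposite-strand hits with footprint overlap >= frac * width,
# keeping the better score (tie: plus strand, then lower start).  `df` must
# be sorted by start.
#' @keywords internal
#' @noRd
collapse_opposite_strand <- function(df, w, frac) {
  n <- nrow(df)
  if (n < 2L) return(df)
  keep <- rep(TRUE, n)
  min_ov <- frac * w
  for (i in seq_len(n - 1L)) {
    if (!keep[i]) next
    j <- i + 1L
    while (j <= n && df$start[j] - df$start[i] < w) {
      if (keep[j] && df$strand[j] != df$strand[i]) {
        ov <- w - (df$start[j] - df$start[i])
        if (ov >= min_ov) {
          si <- df$int_score[i]; sj <- df$int_score[j]
          drop_j <- sj < si ||
            (sj == si && (df$strand[i] == "+" || df$start[i] < df$start[j]))
          if (drop_j) keep[j] <- FALSE else { keep[i] <- FALSE; break }
        }
      }
      j <- j + 1L
    }
  }
  df[keep, , drop = FALSE]
}

#' Assign the nearest qualifying motif to each peak
#'
#' Each peak receives the hit (p-value at or below `p_threshold`) whose
#' center is nearest the peak center; equidistant candidates are broken by
#' higher score, then lower coordinate.  Peaks with no qualifying hit within
#' `search_halfwidth` bases are flagged motif-free.  When `chrom_sizes` is
#' supplied a matched random-coordinate null distance distribution is drawn.
#'
#' @param peaks data frame with columns `chrom`, `center` (plus any others).
#' @param hits motif hit data frame as returned by [scan_genome()].
#' @param p_threshold motif p-value cutoff (default 0.001).
#' @param search_halfwidth maximum assignment distance in bases (default 60).
#' @param chrom_sizes optional named vector of chromosome lengths for the
#'   random-coordinate null.
#' @param n_random number of random coordinates (default `nrow(peaks)`).
#' @param seed RNG seed for the null draw.
#' @return List with `assignments` (one row per peak: `motif_index` into
#'   `hits` or NA, `distance` = peak center - motif center, `motif_free`),
#'   `distances` (assigned peaks only) and `random_distances` (or NULL).
#' @export
assign_peak_motifs <- function(peaks, hits, p_threshold = 0.001,
                               search_halfwidth = 60, chrom_sizes = NULL,
                               n_random = NULL, seed = NULL) {
  q_rows <- which(hits$p_value <= p_threshold)
  hits_q <- hits[q_rows, , drop = FALSE]
  n <- nrow(peaks)
  motif_index <- rep(NA_integer_, n)
  distance <- rep(NA_real_, n)
  nearest_distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- which(hits_q$chrom == peaks$chrom[i])
    if (length(cand) == 0L) next
    d <- peaks$center[i] - hits_q$center[cand]
    ord <- order(abs(d), -hits_q$score[cand], hits_q$start[cand])
    nearest_distance[i] <- d[ord[1]]
    if (abs(d[ord[1]]) <= search_halfwidth) {
      motif_index[i] <- q_rows[cand[ord[1]]]
      distance[i] <- d[ord[1]]
    }
  }
  random_distances <- NULL
  if (!is.null(chrom_sizes) && nrow(hits_q) > 0L) {
    if (is.null(n_random)) n_random <- n
    random_distances <- with_seed(seed, {
      chrom <- sample(names(chrom_sizes), n_random, replace = TRUE,
                      prob = chrom_sizes / sum(chrom_sizes))
      pos <- floor(stats::runif(n_random) * chrom_sizes[chrom])
      vapply(seq_len(n_random), function(i) {
        cand <- which(hits_q$chrom == chrom[i])
        if (length(cand) == 0L) return(NA_real_)
        d <- pos[i] - hits_q$center[cand]
        d[which.min(abs(d))]
      }, numeric(1))
    })
  }
  assignments <- data.frame(peak = seq_len(n), chrom = peaks$chrom,
                            peak_center = peaks$center,
                            motif_index = motif_index,
                            distance = distance,
                            nearest_distance = nearest_distance,
                            motif_free = is.na(motif_index))
  list(assignments = assignments,
       distances = distance[!is.na(distance)],
       random_distances = random_distances)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Degenerate inverted-repeat HSE seed matrix
#'
#' The seed used by the deterministic motif-discovery step: the 15-base
#' inverted tandem array of AGAAN-type units written as
#' `NTTCNNGAANNTTCN`, with `core_prob` on the consensus base at the nine
#' informative positions and background elsewhere.
#'
#' @param core_prob probability of the consensus base at informative
#'   positions (default 0.85).
#' @param background length-4 background distribution.
#' @return A `pswm` object of width 15.
#' @export
hse_seed_pswm <- function(core_prob = 0.85, background = rep(0.25, 4)) {
  consensus_pswm("NTTCNNGAANNTTCN", core_prob, background)
}

#' Sharp HSE generator matrix
#'
#' The planting model used by the synthetic-data generator: three
#' oppositely oriented AGAAN units, `NTTCT AGAAN NTTCT`, with twelve
#' informative positions at probability `core_prob` (default 1, i.e. the
#' core bases are deterministic) and background at the N positions.
#'
#' @param core_prob probability of the consensus base at informative
#'   positions.
#' @param background length-4 background distribution.
#' @return A `pswm` object of width 15.
#' @export
hse_pswm <- function(core_prob = 1, background = rep(0.25, 4)) {
  consensus_pswm("NTTCTAGAANNTTCT", core_prob, background)
}

#' Build a PSWM from a consensus string with N wildcards
#' @keywords internal
#' @noRd
consensus_pswm <- function(consensus, core_prob, background) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  prob <- matrix(0, nrow = 4, ncol = length(chars))
  for (j in seq_along(chars)) {
    if (chars[j] == "N") {
      prob[, j] <- background
    } else {
      prob[, j] <- (1 - core_prob) / 3
      prob[match(chars[j], DNA_BASES4), j] <- core_prob
    }
  }
  pswm(prob, background = background, pseudocount = 0)
}

#' Draw a motif instance from a PSWM
#' @param pswm a [pswm()] object.
#' @return Character scalar of length `pswm$width`.
#' @export
sample_pswm <- function(pswm) {
  paste0(vapply(seq_len(pswm$width), function(j) {
    sample(DNA_BASES4, 1L, prob = pswm$probabilities[, j])
  }, character(1)), collapse = "")
}

#' Deterministic seed-consensus motif discovery around peak centers
#'
#' In place of EM-based discovery, each peak's flanking window (the
#' `flank`-base region on either side of the center) is scanned with the
#' degenerate inverted-repeat seed; the best-scoring occurrence per peak is
#' collected and a matrix built from the collection.  One refinement
#' iteration rescans the windows with the built matrix and rebuilds.
#'
#' @param genome genome object accepted by [scan_genome()].
#' @param peaks data frame with `chrom` and `center` columns.
#' @param flank half-width of the search window around each center
#'   (default 60, the motif-discovery input window).
#' @param background background distribution; `NULL` estimates 0-order base
#'   frequencies from the genome.
#' @param pseudocount pseudocount for [build_pswm()].
#' @param iterations refinement iterations (default 1).
#' @param seed_matrix starting matrix (default [hse_seed_pswm()]).
#' @return A `pswm` object.
#' @export
discover_pswm <- function(genome, peaks, flank = 60, background = NULL,
                          pseudocount = 0.25, iterations = 1,
                          seed_matrix = NULL) {
  g <- genome_as_character(genome)
  if (is.null(background)) background <- genome_background(g)
  if (is.null(seed_matrix)) seed_matrix <- hse_seed_pswm(background = background)
  mat <- seed_matrix
  occ <- NULL
  for (it in seq_len(iterations + 1L)) {
    occ <- best_window_occurrences(g, peaks, mat, flank)
    if (length(occ) == 0L) stop("no motif occurrence found in any peak window")
    mat <- build_pswm(occ, background = background, pseudocount = pseudocount)
  }
  mat
}

#' 0-order background base frequencies of a genome
#' @param genome genome object accepted by [scan_genome()].
#' @return Length-4 frequency vector (A, C, G, T).
#' @export
genome_background <- function(genome) {
  g <- genome_as_character(genome)
  counts <- numeric(4)
  for (s in g) {
    code <- encode_dna(s)
    counts <- counts + tabulate(code[code <= 4L], nbins = 4L)
  }
  counts / sum(counts)
}

# Best-scoring motif-strand occurrence within +/- flank of each peak center.
#' @keywords internal
#' @noRd
best_window_occurrences <- function(g, peaks, mat, flank) {
  w <- mat$width
  gr <- mat$score_granularity
  E <- round(mat$logodds / gr)
  E5 <- rbind(E, rep(-Inf, w))
  E5rc <- rbind(E[4:1, w:1, drop = FALSE], rep(-Inf, w))
  occ <- character(0)
  for (i in seq_len(nrow(peaks))) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(g)) next
    L <- nchar(g[[chrom]])
    lo <- max(0L, as.integer(peaks$center[i]) - as.integer(flank) - w %/% 2L)
    hi <- min(L, as.integer(peaks$center[i]) + as.integer(flank) + w %/% 2L + 1L)
    if (hi - lo < w) next
    win <- substring(g[[chrom]], lo + 1L, hi)
    code <- encode_dna(win)
    sp <- sliding_scores(code, E5, w)
    sm <- sliding_scores(code, E5rc, w)
    best_p <- if (length(sp)) max(sp) else -Inf
    best_m <- if (length(sm)) max(sm) else -Inf
    if (!is.finite(best_p) && !is.finite(best_m)) next
    if (best_p >= best_m) {
      s <- which.max(sp)
      occ <- c(occ, substring(win, s, s + w - 1L))
    } else {
      s <- which.max(sm)
      occ <- c(occ, revcomp_chr(substring(win, s, s + w - 1L)))
    }
  }
  occ
}
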