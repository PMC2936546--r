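# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no stored data.

# A tag library with explicitly placed tags on one chromosome.
make_lib <- function(pos, strand = rep("+", length(pos)), total = NULL,
                     L = 10000L, id = "lib") {
  tags <- data.frame(chrom = rep("chrS", length(pos)),
                     pos = as.integer(pos), strand = strand)
  if (is.null(total)) total <- length(pos)
  tag_library(id, tags, chrom_sizes = c(chrS = as.integer(L)),
              library_total = total)
}

# A library whose 240-base window count at `center` is exactly `n` raw tags
# (placed uniformly inside the window), with `extra` tags far away.
make_window_lib <- function(center, n, extra = 0, L = 100000L,
                            total = 1e7, id = "lib") {
  pos <- integer(0)
  if (n > 0) pos <- center - 120L + round(seq(0, 239, length.out = n))
  if (extra > 0) pos <- c(pos, seq(L - 5000L, length.out = extra, by = 3L))
  make_lib(pos, total = total, L = L, id = id)
}

# A chromatin track from explicit probes on chrS.
make_track <- function(pos, intensity, regions = NULL, factor = "mark") {
  probes <- data.frame(chrom = rep("chrS", length(pos)),
                       pos = as.integer(pos), intensity = intensity)
  if (is.null(regions)) {
    regions <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
  }
  chromatin_track(factor, probes, regions)
}

# Random DNA string under a base composition.
random_genome <- function(L, seed, comp = rep(0.25, 4)) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = comp),
         collapse = "")
}

# Independent k-mer occurrence counter: sorted run-length route (counts
# forward plus reverse-complement occurrences jointly), used as the
# exhaustive comparer for the hash-based mappability implementation.
oracle_kmer_unique <- function(seqchr, k) {
  n <- nchar(seqchr) - k + 1L
  fwd <- substring(seqchr, seq_len(n), seq_len(n) + k - 1L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqchr)))
  rcs <- substring(rc, seq_len(n), seq_len(n) + k - 1L)
  srt <- sort(c(fwd, rcs), method = "radix")
  r <- rle(srt)
  once <- r$values[r$lengths == 1L]
  (fwd %in% once) & !grepl("N", fwd, fixed = TRUE)
}

# Independent two-sided Fisher p oracle by explicit choose() enumeration.
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  supp <- max(0, c1 - r2):min(r1, c1)
  mass <- choose(r1, supp) * choose(r2, c1 - supp) / choose(n, c1)
  obs <- mass[supp == a]
  sum(mass[mass <= obs * (1 + 1e-7)])
}

# Brute-force (all 4^W sequences) p-value oracle for a pswm, weighting each
# sequence by its background probability; returns a function of score.
oracle_enumeration <- function(ps) {
  W <- ps$width
  grid <- as.matrix(expand.grid(rep(list(1:4), W)))
  sc <- rowSums(matrix(ps$logodds[cbind(as.vector(grid),
                                        rep(seq_len(W), each = nrow(grid)))],
                       nrow(grid)))
  wt <- exp(rowSums(matrix(log(ps$background)[as.vector(grid)], nrow(grid))))
  list(scores = sc, weights = wt,
       pvalue = function(s) sum(wt[sc >= s - 1e-9]))
}
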