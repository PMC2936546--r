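# Motif model: matrix construction, scoring, exact p-values, scanning,
# and motif-to-peak assignment.

test_that("build_pswm recovers counts, pseudocount limits and errors", {
  # identical occurrences, no pseudocount: probability 1 at consensus
  m <- build_pswm(c("ACGT", "ACGT"), pseudocount = 0)
  expect_equal(unname(diag(m$probabilities[c(1, 2, 3, 4), ])), rep(1, 4))
  expect_equal(unname(m$logodds[1, 1]), log2(1 / 0.25))
  # one differing position -> 0.5/0.5
  m2 <- build_pswm(c("AA", "AC"), pseudocount = 0)
  expect_equal(unname(m2$probabilities[1:2, 2]), c(0.5, 0.5))
  # huge pseudocount -> background, log-odds -> 0
  m3 <- build_pswm(c("AA", "AA"), pseudocount = 1e9)
  expect_equal(max(abs(m3$logodds)), 0, tolerance = 1e-6)
  # N excluded from counts
  m4 <- build_pswm(c("AN", "AC"), pseudocount = 0)
  expect_equal(unname(m4$probabilities[2, 2]), 1)
  expect_error(build_pswm(character(0)), "at least one")
  expect_error(build_pswm(c("AX")), "AX")
  expect_error(build_pswm(c("AA", "AAA")), "same length")
})

test_that("score_sequence handles strands, uniform matrices and N masking", {
  u <- pswm(matrix(0.25, 4, 3))
  expect_equal(score_sequence(u, "ACG"), 0)
  aa <- build_pswm(c("AA", "AA"), pseudocount = 0)
  expect_equal(score_sequence(aa, "AA"), 4)           # 2 x log2(4)
  expect_equal(score_sequence(aa, "TT", strand = "-"), 4)
  expect_equal(score_sequence(aa, "AN"), -Inf)
  expect_error(score_sequence(aa, "AAA"), "width")
})

test_that("score_pvalue matches hand-enumerable cases and edge rules", {
  aa <- build_pswm(c("AA", "AA"), pseudocount = 0)
  expect_equal(score_pvalue(aa, 4), 1 / 16)           # all-16 dinucleotides
  expect_equal(score_pvalue(aa, -Inf), 1)
  expect_equal(score_pvalue(aa, Inf), 0)
  expect_equal(score_pvalue(aa, 4 + 1), 0)            # above max achievable
  # strictly positive matrix: minimum achievable score has p = 1
  m <- build_pswm(c("AC", "AG", "AT"), pseudocount = 1)
  d <- kdchip:::pswm_score_distribution(m)
  expect_equal(score_pvalue(m, d$min_total * m$score_granularity), 1)
})

test_that("score_pvalue agrees with full enumeration on random matrices", {
  set.seed(42)
  for (rep in 1:5) {
    W <- sample(2:7, 1)
    prob <- apply(matrix(stats::rgamma(4 * W, 1), 4), 2, function(x) x / sum(x))
    bg <- as.vector(stats::rgamma(4, 2)); bg <- bg / sum(bg)
    ps <- pswm(prob, background = bg)
    oracle <- oracle_enumeration(ps)
    us <- sort(unique(oracle$scores))
    probe <- us[seq(1, length(us), length.out = min(50, length(us)))]
    expect_equal(score_pvalue(ps, probe),
                 vapply(probe, oracle$pvalue, numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("p-value is non-increasing in score", {
  set.seed(7)
  prob <- apply(matrix(stats::rgamma(4 * 6, 1), 4), 2, function(x) x / sum(x))
  ps <- pswm(prob)
  grid <- seq(-25, 25, by = 0.01)
  expect_true(all(diff(score_pvalue(ps, grid)) <= 1e-15))
})

test_that("scan_genome recovers planted motifs and respects thresholds", {
  gen <- generate_genome(120000, n_bound = 25, n_free = 25, n_decoy = 10,
                         min_spacing = 1000, seed = 5)
  bg <- genome_background(gen$genome)
  hits <- scan_genome(gen$genome, hse_pswm(background = bg), 5e-6)
  planted <- gen$truth$planted_motifs
  hse <- planted[planted$class != "decoy", ]
  expect_gte(nrow(hits), nrow(hse))
  expect_true(all(hse$start %in% hits$start))
  m <- merge(hse, hits, by = "start")
  expect_true(all(m$strand.x == m$strand.y))
  # decoy direct repeats are never called
  expect_false(any(planted$start[planted$class == "decoy"] %in% hits$start))
  # tightening the threshold gives a nested hit set
  hits_tight <- scan_genome(gen$genome, hse_pswm(background = bg), 1e-7)
  expect_true(all(paste(hits_tight$start, hits_tight$strand) %in%
                    paste(hits$start, hits$strand)))
})

test_that("chance hit counts on random genomes match the binomial rate", {
  set.seed(19)
  prob <- apply(matrix(stats::rgamma(4 * 8, 1), 4), 2, function(x) x / sum(x))
  ps <- pswm(prob)
  L <- 60000L
  g <- c(chr1 = random_genome(L, seed = 77))
  hits <- scan_genome(g, ps, 1e-3)
  t_star <- kdchip:::pswm_score_threshold(ps, 1e-3)
  p_eff <- score_pvalue(ps, t_star * ps$score_granularity)
  expected <- 2 * (L - 8 + 1) * p_eff
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected) + 2)
})

test_that("hit set is invariant under reverse-complementing the genome", {
  set.seed(11)
  prob <- apply(matrix(stats::rgamma(4 * 6, 1), 4), 2, function(x) x / sum(x))
  ps <- pswm(prob)
  g <- random_genome(20000, seed = 13)
  hits_f <- scan_genome(c(chr1 = g), ps, 2e-3)
  grc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  hits_r <- scan_genome(c(chr1 = grc), ps, 2e-3)
  # map reverse-genome hits back to forward coordinates
  mapped_start <- sort(nchar(g) - 6 - hits_r$start)
  expect_equal(sort(hits_f$start), mapped_start)
  expect_equal(sort(hits_f$score), sort(hits_r$score))
})

test_that("genome scan and matrix build round-trip the generating model", {
  set.seed(23)
  gen_model <- hse_pswm(core_prob = 0.9)
  occ <- replicate(500, sample_pswm(gen_model))
  built <- build_pswm(occ, pseudocount = 0.25)
  tv <- 0.5 * colSums(abs(built$probabilities - gen_model$probabilities))
  expect_lt(max(tv), 0.05)
})

test_that("assign_peak_motifs picks the nearest qualifying hit", {
  hits <- data.frame(chrom = "chrS", start = c(93, 110, 290),
                     strand = "+", sequence = "NNNNNNNNNNNNNNN",
                     score = c(20, 15, 18), p_value = c(1e-8, 1e-6, 1e-7),
                     center = c(100, 117, 297))
  peaks <- data.frame(chrom = "chrS", center = c(100, 107, 600))
  res <- assign_peak_motifs(peaks, hits, p_threshold = 0.001,
                            search_halfwidth = 60)
  a <- res$assignments
  expect_equal(a$motif_index[1], 1L)         # exact center, distance 0
  expect_equal(a$distance[1], 0)
  expect_equal(a$motif_index[2], 1L)         # 7 beats 10
  expect_true(a$motif_free[3])               # nothing within 60
  # ties: equidistant hits resolved by higher score
  hits2 <- data.frame(chrom = "chrS", start = c(80, 100), strand = "+",
                      sequence = "NN", score = c(5, 9),
                      p_value = c(1e-4, 1e-4), center = c(90, 110))
  res2 <- assign_peak_motifs(data.frame(chrom = "chrS", center = 100), hits2)
  expect_equal(res2$assignments$motif_index, 2L)
})

test_that("seed-consensus discovery rebuilds a scanning-grade matrix", {
  gen <- generate_genome(150000, n_bound = 40, n_free = 0, n_decoy = 0,
                         min_spacing = 1500, seed = 31)
  peaks <- data.frame(chrom = "chrS",
                      center = gen$truth$planted_motifs$center)
  mat <- discover_pswm(gen$genome, peaks)
  expect_s3_class(mat, "pswm")
  hits <- scan_genome(gen$genome, mat, 0.001)
  # every planted site is hit (opposite-strand double matches may shift the
  # collapsed representative by a few bases)
  expect_true(all(vapply(gen$truth$planted_motifs$start, function(s)
    any(abs(hits$start - s) <= 7), TRUE)))
})
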