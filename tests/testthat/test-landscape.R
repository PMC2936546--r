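# Chromatin landscape: composite profiles, enrichment membership, Fisher
# association, clustering, and intensity relationships.

test_that("composite profiles reproduce hand-computable cases", {
  # constant track -> profile identically c at every offset
  tr <- make_track(seq(0, 9950, 50), rep(3.5, 200))
  motifs <- data.frame(chrom = "chrS", center = c(3000L, 6000L),
                       strand = c("+", "-"))
  prof <- composite_profile(tr, motifs, span = 1000)
  expect_true(all(prof$mean_intensity == 3.5))
  expect_equal(prof$offsets, seq(-1000, 1000, 50))
  # single motif, probes at -10/0/+10 with intensities 1/2/3
  tr2 <- make_track(c(990, 1000, 1010), c(1, 2, 3))
  m1 <- data.frame(chrom = "chrS", center = 1000L, strand = "+")
  p2 <- composite_profile(tr2, m1, span = 100)
  expect_equal(p2$mean_intensity[p2$offsets == 0], 2)
  # strand flipping mirrors the profile
  m1m <- data.frame(chrom = "chrS", center = 1000L, strand = "-")
  p2m <- composite_profile(tr2, m1m, span = 100)
  expect_equal(p2$mean_intensity[p2$offsets == 40],
               p2m$mean_intensity[p2m$offsets == -40])
  # probe-free windows are omitted and counted
  expect_true(any(p2$n_motifs == 0))
  expect_error(composite_profile(tr2, m1, window = 40, step = 50), ">= step")
})

test_that("planted block enrichment appears at the expected height", {
  gen <- generate_genome(3e5, 60, 60, 0, min_spacing = 1500, seed = 401)
  sim <- simulate_chromatin_tracks(gen$truth, factors = "mk",
                                   assoc_prob_bound = 1, assoc_prob_free = 0,
                                   signal_fold = 4, noise_sd = 0.2, seed = 5)
  pm <- gen$truth$planted_motifs
  bound <- data.frame(chrom = "chrS", center = pm$center[pm$class == "bound"],
                      strand = pm$strand[pm$class == "bound"])
  free <- data.frame(chrom = "chrS", center = pm$center[pm$class == "free"],
                     strand = pm$strand[pm$class == "free"])
  pb <- composite_profile(sim$tracks$mk, bound, span = 1000)
  pf <- composite_profile(sim$tracks$mk, free, span = 1000)
  # central enrichment ~ baseline + (fold - 1); flanks and free profile ~ 1
  expect_equal(pb$mean_intensity[pb$offsets == 0], 4, tolerance = 0.1)
  expect_equal(pf$mean_intensity[pf$offsets == 0], 1, tolerance = 0.1)
  expect_equal(pb$mean_intensity[abs(pb$offsets) == 1000], c(1, 1),
               tolerance = 0.1)
})

test_that("window_mean_intensity averages probes and propagates absence", {
  tr <- make_track(c(980, 1000, 1020), c(1, 2, 3))
  expect_equal(window_mean_intensity(tr, "chrS", 1000, 400), 2)
  expect_true(is.na(window_mean_intensity(tr, "chrS", 5000, 400)))
  trc <- make_track(seq(900, 1100, 20), rep(7, 11))
  expect_equal(window_mean_intensity(trc, "chrS", 1000, 400), 7)
})

test_that("enrichment membership uses half-open region intervals", {
  reg <- data.frame(chrom = "chrS", start = 100L, end = 200L)
  m <- data.frame(chrom = "chrS", center = c(100L, 150L, 200L, 50L))
  expect_equal(enrichment_membership(m, reg), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(enrichment_membership(m, reg[0, ]), rep(FALSE, 4))
})

test_that("fisher_association matches exact references and degenerate margins", {
  # 8/10 bound enriched vs 2/10 free: exact two-sided p
  a <- fisher_association(rep(c(TRUE, FALSE), c(8, 2)),
                          rep(c(TRUE, FALSE), c(2, 8)))
  expect_equal(a$p_value, 0.023014138, tolerance = 1e-7)
  expect_equal(a$odds_ratio, 16)
  # identical proportions -> p = 1
  expect_equal(fisher_association(rep(c(TRUE, FALSE), c(5, 5)),
                                  rep(c(TRUE, FALSE), c(5, 5)))$p_value, 1)
  # degenerate margin (nothing enriched) -> p = 1
  expect_equal(fisher_association(rep(FALSE, 10), rep(FALSE, 10))$p_value, 1)
  # Haldane-corrected odds ratio when a cell is zero
  z <- fisher_association(rep(TRUE, 4), rep(c(TRUE, FALSE), c(2, 2)))
  expect_equal(z$odds_ratio, (4.5 * 2.5) / (0.5 * 2.5))
  expect_error(fisher_association(logical(0), TRUE), "non-empty")
})

test_that("internal Fisher p agrees with stats::fisher.test across random tables", {
  set.seed(12)
  for (i in 1:60) {
    tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
    ours <- kdchip:::fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
    og <- kdchip:::fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                                  alternative = "greater")
    rg <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(og, rg, tolerance = 1e-12)
  }
})

test_that("associate_tracks reports per-factor tables with BH alongside", {
  gen <- generate_genome(2e5, 50, 50, 0, min_spacing = 900, seed = 421)
  sim <- simulate_chromatin_tracks(gen$truth, factors = c("a", "b"),
                                   assoc_prob_bound = c(0.9, 0.3),
                                   assoc_prob_free = c(0.1, 0.3), seed = 6)
  pm <- gen$truth$planted_motifs
  bound <- data.frame(chrom = "chrS", center = pm$center[pm$class == "bound"])
  free <- data.frame(chrom = "chrS", center = pm$center[pm$class == "free"])
  res <- associate_tracks(sim$tracks, bound, free)
  expect_equal(res$factor, c("a", "b"))
  expect_equal(res$bound_total, c(50, 50))
  expect_lt(res$p_value[1], 0.001)
  expect_true(all(res$p_bh >= res$p_value))
  expect_equal(res$bound_enriched[1], length(sim$truth$mark_states$a[
    sim$truth$mark_states$a %in% which(pm$class == "bound")]))
})

test_that("k-means clustering separates planted blobs and is order-invariant", {
  set.seed(91)
  blob <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 4),
                matrix(rnorm(40, 5, 0.3), ncol = 4))
  cl <- cluster_motifs(blob, k = 2, seed = 3)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_false(cl$cluster[1] == cl$cluster[20])
  # invariant to row order under a fixed seed
  perm <- sample(20)
  cl2 <- cluster_motifs(blob[perm, ], k = 2, seed = 3)
  expect_true(all((cl$cluster[perm] == cl$cluster[perm][1]) ==
                    (cl2$cluster == cl2$cluster[1])))
  # k = 1: centroid = column means (unstandardized space)
  c1 <- cluster_motifs(blob, k = 1, seed = 1, standardize = FALSE)
  expect_equal(as.numeric(c1$centers), colMeans(blob))
  # k = n: each motif its own cluster, zero objective
  cn <- cluster_motifs(blob, k = 20, seed = 1)
  expect_equal(cn$tot_withinss, 0)
  expect_equal(sort(unique(cn$cluster)), 1:20)
  expect_error(cluster_motifs(blob, k = 21), "exceed")
  # missing cells are imputed with column means, flagged
  blob_na <- blob; blob_na[3, 2] <- NA
  expect_message(cna <- cluster_motifs(blob_na, k = 2, seed = 3), "imputed")
  expect_true(cna$imputed[3, 2])
})

test_that("intensity-binding correlation hits its fixed points", {
  lib <- make_lib(rep(c(1000, 3000, 5000, 7000), c(10, 20, 30, 40)),
                  total = 1e7, L = 10000)
  motifs <- data.frame(chrom = "chrS", center = c(1000L, 3000L, 5000L, 7000L))
  counts <- window_count(lib, "chrS", motifs$center, 240)
  tr <- make_track(motifs$center, 2 * counts + 1)
  res <- intensity_binding_correlation(tr, motifs, lib)
  expect_equal(res$r, 1)
  tr2 <- make_track(motifs$center, -2 * counts + 100)
  expect_equal(intensity_binding_correlation(tr2, motifs, lib)$r, -1)
  trflat <- make_track(motifs$center, rep(5, 4))
  expect_error(intensity_binding_correlation(trflat, motifs, lib),
               "zero-variance")
  expect_error(intensity_binding_correlation(tr, motifs[1:2, ], lib),
               "at least 3")
})

test_that("quartile intensities split by p-value and share multi-motif windows", {
  lib <- make_lib(rep(seq(1000, 8000, 1000), each = 12), total = 1e7,
                  L = 10000)
  motifs <- data.frame(chrom = "chrS", center = seq(1000L, 8000L, 1000L),
                       p_value = c(1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4,
                                   1e-3, 1e-2))
  qi <- quartile_intensity(motifs, lib)
  expect_equal(length(qi$groups), 4)
  expect_equal(unname(vapply(qi$groups, length, 1L)), rep(2L, 4))
  expect_false(qi$degenerate)
  # all p equal -> a single reported group
  motifs_eq <- motifs; motifs_eq$p_value <- 1e-5
  qe <- quartile_intensity(motifs_eq, lib)
  expect_true(qe$degenerate)
  expect_length(qe$groups, 1)
  # two motifs in one window share its count
  m2 <- data.frame(chrom = "chrS", center = c(5000L, 5050L, 1000L, 8000L),
                   p_value = c(1e-8, 1e-6, 1e-4, 1e-2))
  lib2 <- make_lib(rep(c(5000, 5050, 1000, 8000), c(6, 6, 12, 12)),
                   total = 1e7, L = 10000)
  q2 <- quartile_intensity(m2, lib2)
  v <- unlist(q2$groups)
  expect_equal(sort(unique(v)), c(6, 12))
  expect_error(quartile_intensity(m2[1:3, ], lib2), "at least 4")
})
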