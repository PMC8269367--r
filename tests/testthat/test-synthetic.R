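test_that("make_genome gives the requested composition, reproducibly", {
  g1 <- make_genome(c(chr1 = 100000), gc_fraction = 0.4, seed = 7)
  g2 <- make_genome(c(chr1 = 100000), gc_fraction = 0.4, seed = 7)
  expect_identical(g1$seq, g2$seq)
  expect_equal(nchar(g1$seq[["chr1"]]), 100000)
  gc <- sum(strsplit(g1$seq[["chr1"]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.4), 0.01)

  expect_error(make_genome(c(chr1 = 0)), "1 kb")
  expect_error(make_genome(c(chr1 = 2000, chr1 = 3000)), "unique")
})

test_that("plant_motifs places recoverable motifs and records exact truth", {
  g <- make_genome(c(chr1 = 100000), gc_fraction = 0.45, seed = 3)
  pg <- plant_motifs(g, n_g4 = 10, n_im = 5, seed = 11)
  truth <- pg$truth
  expect_equal(sum(truth$motif_class == "G4"), 10)
  expect_equal(sum(truth$motif_class == "iM"), 5)
  expect_true(all(truth$start >= 0 & truth$end <= 100000))

  # scanner recovers every planted site at exact coordinates (>= n hits total)
  g4_hits <- scan_g4(genome_seq(pg$genome, "chr1"), chrom = "chr1")
  im_hits <- scan_imotif(genome_seq(pg$genome, "chr1"), chrom = "chr1")
  for (cls in c("G4", "iM")) {
    hits <- if (cls == "G4") g4_hits else im_hits
    tr <- truth[truth$motif_class == cls, ]
    found <- paste(hits$start, hits$end, hits$strand)
    expect_true(all(paste(tr$start, tr$end, tr$strand) %in% found),
                label = paste("planted", cls, "recall"))
  }
  expect_gte(nrow(g4_hits), 10)

  # identity case: nothing planted
  pg0 <- plant_motifs(g, n_g4 = 0, n_im = 0, seed = 1)
  expect_identical(pg0$genome$seq, g$seq)
  expect_equal(nrow(pg0$truth), 0)

  # pattern arithmetic: minimal motif spans 4*run + 3*loop
  g_small <- make_genome(c(chr1 = 5000), seed = 5)
  pg1 <- plant_motifs(g_small, n_g4 = 1, n_im = 0, run_len = 3,
                      loop_lens = 1, seed = 2)
  expect_equal(pg1$truth$end - pg1$truth$start, 15)

  expect_error(plant_motifs(g_small, n_g4 = 500, n_im = 0, seed = 1),
               "too small")
})

test_that("sample_intervals respects bounds, masks and determinism", {
  g <- small_genome(c(chrA = 1e6))
  x <- sample_intervals(g, 1000, c(100, 300), seed = 5)
  expect_equal(nrow(x), 1000)
  expect_true(all(x$start >= 0 & x$end <= 1e6))
  expect_true(all(diff(x$start) >= 0))          # sorted (single chromosome)
  expect_true(all(x$end - x$start >= 100 & x$end - x$start <= 300))
  expect_identical(x, sample_intervals(g, 1000, c(100, 300), seed = 5))

  mask <- tibble::tibble(chrom = "chrA", start = 200000, end = 210000)
  xm <- sample_intervals(g, 20, c(100, 300), seed = 2, mask = mask)
  expect_true(all(xm$start >= 200000 & xm$end <= 210000))

  expect_error(sample_intervals(g, 200, c(100, 300), seed = 2, mask = mask),
               "mask too small")

  xs <- sample_intervals(g, 300, c(100, 300), seed = 9,
                         allow_self_overlap = FALSE)
  expect_length(self_overlap_idx_test(xs), 0)
})

test_that("enriched sampling degenerates correctly and plants detectable enrichment", {
  g <- small_genome(c(chrA = 1e6))
  anchors <- tibble::tibble(chrom = "chrA", start = 500000, end = 500200)
  x1 <- sample_enriched_intervals(g, anchors, 1, n = 50, seed = 3)
  expect_equal(count_overlapping(x1, anchors), 50)

  expect_error(sample_enriched_intervals(g, anchors[0, ], 0.5, n = 10, seed = 1),
               "non-empty")

  # pi = 0 equals the plain sampler distributionally: same placement engine
  x0 <- sample_enriched_intervals(g, anchors, 0, n = 200, seed = 8)
  expect_true(all(x0$end <= 1e6) && nrow(x0) == 200)
})

test_that("simulate_methylation reproduces stratum means and noiseless values", {
  g <- small_genome(c(chrA = 5e4))
  strata <- list(
    list(intervals = tibble::tibble(chrom = "chrA", start = 10000, end = 20000),
         mean = 30)
  )
  tr0 <- simulate_methylation(g, strata, background_mean = 70, noise_sd = 0,
                              cpg_spacing = 100, seed = 1)
  inside <- tr0$pos >= 10000 & tr0$pos < 20000
  expect_true(all(tr0$percent[inside] == 30))
  expect_true(all(tr0$percent[!inside] == 70))

  # no strata: set-level median at background
  tr_bg <- simulate_methylation(g, list(), background_mean = 70, noise_sd = 3,
                                cpg_spacing = 100, seed = 2)
  expect_lt(abs(median(tr_bg$percent) - 70), 1)

  # innermost stratum wins under nesting
  strata2 <- c(strata, list(
    list(intervals = tibble::tibble(chrom = "chrA", start = 14000, end = 15000),
         mean = 5)
  ))
  tr2 <- simulate_methylation(g, strata2, noise_sd = 0, seed = 1)
  expect_true(all(tr2$percent[tr2$pos >= 14000 & tr2$pos < 15000] == 5))

  expect_error(simulate_methylation(g, list(list(
    intervals = tibble::tibble(chrom = "chrA", start = 0, end = 100),
    mean = 101))), "within")
})

test_that("simulate_mst_curve matches the titration design and the closed form", {
  cv <- simulate_mst_curve(kd = 100, protein_conc = 50, noise_sd = 0)
  expect_equal(nrow(cv), 16)
  expect_equal(max(cv$conc_nM), 20000)
  expect_equal(min(cv$conc_nM), 20000 / 2^15)   # ~0.61 nM
  expect_equal(cv$response,
               fraction_bound(cv$conc_nM, 50, 100))
  cv2 <- simulate_mst_curve(kd = 100, noise_sd = 0.05, seed = 4)
  expect_identical(cv2, simulate_mst_curve(kd = 100, noise_sd = 0.05, seed = 4))
})

test_that("simulate_cq_table inverts the ddCq formula exactly when noiseless", {
  t1 <- simulate_cq_table(c(s1 = 1), noise_sd = 0)
  expect_equal(summarize_occupancy(t1)$ddcq_mean, 1)
  t2 <- simulate_cq_table(c(s1 = 2), noise_sd = 0)
  expect_equal(summarize_occupancy(t2)$ddcq_mean, 2)
  expect_error(simulate_cq_table(c(s1 = -1)), "TRUE|positive")
})
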