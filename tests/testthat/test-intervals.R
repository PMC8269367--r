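test_that("BED round trip preserves canonical BED6 and catches malformed input", {
  g <- small_genome()
  set.seed(1)
  x <- random_intervals(g$sizes, 1000)
  x <- x[order(x$chrom, x$start, x$end), ]      # canonical sort incl. ties
  x$name <- paste0("iv_", seq_len(nrow(x)))
  x$score <- round(runif(nrow(x), 0, 100), 2)
  x$strand <- sample(c("+", "-"), nrow(x), replace = TRUE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path, genome = g)
  attr(y, "genome_sizes") <- NULL
  expect_equal(as.data.frame(y), as.data.frame(x))
  # file-level round trip
  path2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(y, path2)
  expect_identical(readLines(path), readLines(path2))

  p <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", p)
  b <- read_bed(p)
  expect_equal(as.data.frame(b), data.frame(chrom = "chr1", start = 10L, end = 20L))

  writeLines(c("track name=x", "# comment", "chr1\t20\t10"), p)
  expect_error(read_bed(p), "line 3")
  writeLines("chrZ\t10\t20", p)
  expect_error(read_bed(p, genome = g), "chrZ")
})

test_that("count_overlapping follows half-open arithmetic and the quadratic oracle", {
  A <- tibble::tibble(chrom = "c", start = 0L, end = 10L)
  B <- tibble::tibble(chrom = "c", start = 10L, end = 20L)
  expect_equal(count_overlapping(A, B), 0)          # abutment is not overlap
  expect_equal(count_overlapping(A, A), 1)

  g <- small_genome()
  set.seed(42)
  for (rep in 1:3) {
    A <- random_intervals(g$sizes, 500)
    B <- random_intervals(g$sizes, 500)
    expect_equal(count_overlapping(A, B), oracle_count_overlapping(A, B))
    expect_equal(count_overlapping(A, B, min_bp = 50),
                 oracle_count_overlapping(A, B, min_bp = 50))
  }
  # symmetric-identity property: A = B counts all
  expect_equal(count_overlapping(B, B), nrow(B))
})

test_that("classify_relative labels partition A and match the brute-force oracle", {
  B <- tibble::tibble(chrom = "c", start = c(1000L, 5000L), end = c(1200L, 5100L))
  A <- tibble::tibble(chrom = "c",
                      start = c(1150L, 1350L, 3000L, 790L),
                      end = c(1250L, 1450L, 3100L, 800L))
  lab <- classify_relative(A, B, flank_width = 200)$label
  # rows sorted by start: 790 (edge gap exactly 200 -> flank), 1150 (overlap,
  # precedence over flank), 1350 (150 bp from B1 -> flank), 3000 (free)
  expect_equal(as.character(lab), c("flank", "overlap", "flank", "free"))

  g <- small_genome()
  set.seed(11)
  A <- random_intervals(g$sizes, 400)
  B <- random_intervals(g$sizes, 150)
  got <- classify_relative(A, B, 200)
  expect_equal(as.character(got$label), oracle_classify(got, B, 200))
  expect_equal(sum(table(got$label)), nrow(A))      # exhaustive partition
})

test_that("coverage_fraction matches a per-base bitmask oracle; covered bp grows with flanks", {
  A <- tibble::tibble(chrom = "c", start = 100L, end = 200L)
  B <- tibble::tibble(chrom = "c", start = 0L, end = 500L)
  expect_equal(coverage_fraction(A, B), 1.0)
  expect_equal(coverage_fraction(B, A), 0.2)
  expect_equal(coverage_fraction(A, tibble::tibble(chrom = "c", start = 300L,
                                                   end = 400L)), 0.0)

  sizes <- c(chrA = 20000, chrB = 10000)
  set.seed(5)
  A <- random_intervals(sizes, 60, c(50, 300))
  B <- random_intervals(sizes, 40, c(50, 300))
  for (fl in c(0, 200)) {
    expect_equal(coverage_fraction(A, B, flank_width = fl, genome = sizes),
                 oracle_coverage_fraction(A, B, sizes, flank = fl))
  }
  # absolute covered bp is monotone in flank width (the fraction need not be)
  covered_bp <- vapply(c(0, 100, 200, 400), function(fl) {
    am <- quadcoloc:::merge_intervals0(pmax(0, A$start - fl), A$end + fl)
    den <- sum(am$end - am$start)
    coverage_fraction(A, B, fl, genome = sizes) * den
  }, numeric(1))
  expect_true(all(diff(covered_bp) >= -1e-9))
})

test_that("relative distances hit the defining identities and the oracle-free cases", {
  B <- tibble::tibble(chrom = "c", start = c(0L, 1000L, 3000L), end = c(100L, 1100L, 3100L))
  # A midpoint coincident with a B midpoint -> 0
  A0 <- tibble::tibble(chrom = "c", start = 1000L, end = 1100L)
  expect_equal(relative_distances(A0, B)$reldist, 0)
  # exactly halfway -> 0.5
  Ah <- tibble::tibble(chrom = "c", start = 525L, end = 575L)
  expect_equal(relative_distances(Ah, B)$reldist, 0.5)
  # outside the B midpoint range -> skipped
  Aout <- tibble::tibble(chrom = "c", start = 4000L, end = 4100L)
  expect_equal(nrow(relative_distances(Aout, B)), 0)
  # identical sets -> all zero
  expect_true(all(relative_distances(B, B)$reldist == 0))
})

test_that("profile_matrix shows a central peak for self-signal and zero for empty signal", {
  g <- small_genome(c(chrA = 1e5))
  anchors <- sample_intervals(g, 50, c(200, 200), seed = 3)
  p_self <- profile_matrix(anchors, anchors, half_window = 500, n_bins = 20,
                           genome = g)
  central <- p_self$mean_signal[p_self$bin %in% 10:11]
  expect_true(all(central == 1))
  expect_gt(mean(central), mean(p_self$mean_signal[c(1, 20)]))

  empty <- anchors[0, ]
  p_zero <- profile_matrix(anchors, empty, half_window = 500, n_bins = 20,
                           genome = g)
  expect_true(all(p_zero$mean_signal == 0))
})

test_that("venn_counts assigns each interval to exactly one pattern, per the membership oracle", {
  g <- small_genome()
  A <- tibble::tibble(chrom = "chrA", start = c(0L, 100L), end = c(50L, 150L))
  expect_equal(venn_counts(A, A, A)$count, c(0L, 0L, 0L, 2L))
  B <- tibble::tibble(chrom = "chrA", start = 1000L, end = 1100L)
  expect_equal(venn_counts(A, B)$count, c(2L, 0L))

  set.seed(21)
  A <- random_intervals(g$sizes, 300)
  B <- random_intervals(g$sizes, 200)
  C <- random_intervals(g$sizes, 100)
  vc <- venn_counts(A, B, C)
  inB <- vapply(seq_len(nrow(A)), function(i)
    oracle_count_overlapping(A[i, ], B) > 0, logical(1))
  inC <- vapply(seq_len(nrow(A)), function(i)
    oracle_count_overlapping(A[i, ], C) > 0, logical(1))
  expect_equal(vc$count,
               c(sum(!inB & !inC), sum(inB & !inC), sum(!inB & inC), sum(inB & inC)))
  expect_equal(sum(vc$count), nrow(A))
})

test_that("fast interval kernels agree with the GenomicRanges-backed operations", {
  sizes <- c(chrA = 3e4, chrB = 2e4)
  set.seed(33)
  A <- random_intervals(sizes, 200)
  B <- random_intervals(sizes, 150)
  a_by_chrom <- lapply(split(A, A$chrom), function(x) {
    c(quadcoloc:::merge_intervals0(x$start, x$end),
      list(raw_s = x$start, raw_e = x$end))
  })
  expect_equal(
    quadcoloc:::perm_statistic(a_by_chrom, B$chrom, B$start, B$end,
                               "count_overlapping"),
    count_overlapping(A, B)
  )
  expect_equal(
    quadcoloc:::perm_statistic(a_by_chrom, B$chrom, B$start, B$end,
                               "coverage_fraction"),
    coverage_fraction(A, B)
  )
})
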