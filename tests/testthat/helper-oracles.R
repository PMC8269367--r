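# Independent oracles used across the suite. These deliberately take naive
# code paths (regexes, nested loops, per-base bitmasks, factorial
# enumeration) distinct from the package implementation.

random_dna <- function(n, seed = NULL, gc = 0.45) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Regex brute-force scanner: enumerate maximal runs of `base`, then all
# windows of runs_required consecutive runs with in-bounds loops, score by
# the documented formula, and resolve overlaps with an independently coded
# greedy pass.
oracle_scan_strand <- function(seq, base, cfg, strand, motif_class) {
  m <- gregexpr(paste0(base, "{", cfg$min_run, ",}"), seq)[[1]]
  if (m[1] == -1) return(NULL)
  rs <- as.integer(m) - 1L                 # 0-based starts
  rl <- attr(m, "match.length")
  re <- rs + rl
  k <- cfg$runs_required
  out <- list()
  if (length(rs) >= k) {
    for (i in seq_len(length(rs) - k + 1)) {
      loops <- rs[(i + 1):(i + k - 1)] - re[i:(i + k - 2)]
      if (all(loops >= cfg$loop_min & loops <= cfg$loop_max)) {
        runs <- rl[i:(i + k - 1)]
        score <- cfg$alpha * sum(runs - cfg$min_run) -
          cfg$beta * sum(loops) + cfg$runs_required * cfg$min_run
        out[[length(out) + 1]] <- data.frame(
          start = rs[i], end = re[i + k - 1], strand = strand,
          motif_class = motif_class, score = score
        )
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

oracle_resolve <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(df)
  df <- df[order(-df$score, df$start, df$strand != "+"), ]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    same <- kept[kept$strand == df$strand[i], ]
    if (nrow(same) == 0 ||
        !any(df$start[i] < same$end & df$end[i] > same$start)) {
      kept <- rbind(kept, df[i, ])
    }
  }
  kept[order(kept$start, kept$end, kept$strand), ]
}

oracle_scan <- function(seq, cfg, motif_class = "G4") {
  plus_base <- if (motif_class == "G4") "G" else "C"
  minus_base <- if (motif_class == "G4") "C" else "G"
  df <- rbind(
    oracle_scan_strand(seq, plus_base, cfg, "+", motif_class),
    if (cfg$both_strands) oracle_scan_strand(seq, minus_base, cfg, "-", motif_class)
  )
  if (!is.null(cfg$score_threshold) && !is.null(df)) {
    df <- df[df$score >= cfg$score_threshold, ]
  }
  res <- oracle_resolve(df)
  if (is.null(res)) res <- data.frame(start = integer(), end = integer(),
                                      strand = character(), score = numeric())
  res
}

# Exact two-sided Fisher p by explicit enumeration of all feasible tables
# with the observed margins, using factorial probabilities.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  tab_p <- function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(ks, tab_p, numeric(1))
  p_obs <- tab_p(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Quadratic all-pairs overlap counting (half-open).
oracle_count_overlapping <- function(A, B, min_bp = 1) {
  cnt <- 0L
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (A$chrom[i] == B$chrom[j]) {
        shared <- min(A$end[i], B$end[j]) - max(A$start[i], B$start[j])
        if (shared >= min_bp) { cnt <- cnt + 1L; break }
      }
    }
  }
  cnt
}

# Per-base bitmask coverage fraction on a small genome.
oracle_coverage_fraction <- function(A, B, sizes, flank = 0) {
  num <- 0; den <- 0
  for (ch in names(sizes)) {
    a_mask <- logical(sizes[[ch]]); b_mask <- logical(sizes[[ch]])
    Ai <- A[A$chrom == ch, ]; Bi <- B[B$chrom == ch, ]
    for (i in seq_len(nrow(Ai))) {
      lo <- max(0, Ai$start[i] - flank); hi <- min(sizes[[ch]], Ai$end[i] + flank)
      if (hi > lo) a_mask[(lo + 1):hi] <- TRUE
    }
    for (i in seq_len(nrow(Bi))) {
      b_mask[(Bi$start[i] + 1):Bi$end[i]] <- TRUE
    }
    num <- num + sum(a_mask & b_mask); den <- den + sum(a_mask)
  }
  num / den
}

# Brute-force overlap/flank/free labels by pairwise distances.
oracle_classify <- function(A, B, flank) {
  vapply(seq_len(nrow(A)), function(i) {
    dmin <- Inf
    for (j in seq_len(nrow(B))) {
      if (A$chrom[i] != B$chrom[j]) next
      shared <- min(A$end[i], B$end[j]) - max(A$start[i], B$start[j])
      if (shared >= 1) return("overlap")
      dmin <- min(dmin, max(B$start[j] - A$end[i], A$start[i] - B$end[j]))
    }
    if (dmin <= flank) "flank" else "free"
  }, character(1))
}

small_genome <- function(sizes = c(chrA = 5e4, chrB = 3e4)) {
  structure(list(sizes = sizes, seq = NULL), class = "qc_genome")
}

random_intervals <- function(sizes, n, len_range = c(50, 400), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(names(sizes), n, replace = TRUE, prob = as.numeric(sizes))
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(sizes[[chrom[i]]] - len[i], 1) - 1L
  }, integer(1))
  tibble::tibble(chrom = chrom, start = start, end = start + len)[
    order(chrom, start), ]
}

random_table <- function(max_n = 200) {
  repeat {
    cells <- as.integer(rmultinom(1, sample(10:max_n, 1), prob = runif(4, 0.05, 1)))
    if (sum(cells) <= max_n) return(cells)
  }
}

# Independent self-overlap check: indices of intervals overlapping a
# same-chromosome predecessor after sorting.
self_overlap_idx_test <- function(x) {
  x <- x[order(x$chrom, x$start), ]
  bad <- integer(0)
  for (i in seq_len(nrow(x))[-1]) {
    if (x$chrom[i] == x$chrom[i - 1] && x$start[i] < max(x$end[seq_len(i - 1)][x$chrom[seq_len(i - 1)] == x$chrom[i]])) {
      bad <- c(bad, i)
    }
  }
  bad
}
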