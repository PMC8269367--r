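# Association statistics for interval colocalization: contingency
# construction, Pearson chi-squared, Fisher exact by hypergeometric
# summation, a genome-wide Fisher table construction, and Monte-Carlo
# permutation tests. These are authored here (not delegated) so that the
# exact conventions — uncorrected X², sample odds ratio ad/bc, Woolf CI,
# upper-tail empirical p = (r + 1) / (n + 1) — are explicit and testable.

#' Cross-tabulate two binary labellings into a 2x2 contingency table
#'
#' @param labels_1,labels_2 Logical vectors over the same item universe
#'   (e.g. per CpG island: harbors an in-cell G4 peak; overlaps a CTCF peak).
#' @return A `contingency_table`: list with cells `a` (both), `b` (1 only),
#'   `c` (2 only), `d` (neither) and `n`.
#' @export
build_table <- function(labels_1, labels_2) {
  stopifnot(length(labels_1) == length(labels_2))
  l1 <- as.logical(labels_1); l2 <- as.logical(labels_2)
  if (anyNA(l1) || anyNA(l2)) abort("labels must be binary without NA")
  ct <- contingency_table(sum(l1 & l2), sum(l1 & !l2), sum(!l1 & l2),
                          sum(!l1 & !l2))
  if (sum(c(ct$a, ct$b, ct$c, ct$d) > 0) <= 1L) {
    warn("degenerate contingency table: all items fall in a single cell")
  }
  ct
}

#' @param a,b,c,d Non-negative integer cell counts (rows: condition 1
#'   present/absent; columns: condition 2 present/absent).
#' @rdname build_table
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = sum(cells)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(cond1 = c("present", "absent"),
                              cond2 = c("present", "absent")))
  print(m)
  cat("N =", format(x$n, big.mark = ","), "\n")
  invisible(x)
}

as_contingency <- function(table) {
  if (inherits(table, "contingency_table")) return(table)
  if (is.matrix(table) && all(dim(table) == 2)) {
    return(contingency_table(table[1, 1], table[1, 2], table[2, 1], table[2, 2]))
  }
  if (is.numeric(table) && length(table) == 4) {
    return(contingency_table(table[1], table[2], table[3], table[4]))
  }
  abort("`table` must be a contingency_table, 2x2 matrix, or length-4 vector (a, b, c, d)")
}

odds_ratio_ci <- function(a, b, c, d) {
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)   # Woolf log-OR interval
  list(or = or, lo = exp(log(or) - 1.96 * se), hi = exp(log(or) + 1.96 * se),
       haldane = haldane)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected by default: `X2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' 1 degree of freedom. The Yates continuity correction is available but off,
#' matching how large-count genomic contingency statistics are conventionally
#' reported.
#'
#' @param table A `contingency_table`, 2x2 matrix, or `c(a, b, c, d)`.
#' @param continuity_correction Apply the Yates correction.
#' @return One-row tibble: `method`, `statistic`, `dof`, `p_value`, `n`,
#'   `odds_ratio`, `ci_lo`, `ci_hi`.
#' @examples
#' chi_square(c(4562, 1757, 6188, 15211))
#' @export
chi_square <- function(table, continuity_correction = FALSE) {
  t <- as_contingency(table)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d; n <- t$n
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("chi-squared undefined: zero margin")
  expected <- c((a + b) * (a + c), (a + b) * (b + d),
                (c + d) * (a + c), (c + d) * (b + d)) / n
  if (any(expected < 5)) {
    warn("expected cell count < 5; the asymptotic chi-squared approximation may be poor")
  }
  num <- abs(a * d - b * c)
  if (continuity_correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  orci <- odds_ratio_ci(a, b, c, d)
  tibble::tibble(
    method = if (continuity_correction) "chi2_yates" else "chi2",
    statistic = stat, dof = 1L,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    n = n, odds_ratio = orci$or, ci_lo = orci$lo, ci_hi = orci$hi
  )
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed margins,
#' the hypergeometric probabilities not exceeding that of the observed table
#' (with the customary `1 + 1e-7` relative tolerance). The reported odds
#' ratio is the sample odds ratio `ad / bc` (with the Haldane 0.5 correction
#' and a flag when a cell is zero), with a Woolf log-OR 95% interval — not
#' the conditional-MLE estimate.
#'
#' @inheritParams chi_square
#' @return One-row tibble as [chi_square()], plus `haldane` flag.
#' @export
fisher_exact <- function(table) {
  t <- as_contingency(table)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  r1 <- a + b; c1 <- a + c; n <- t$n
  k <- max(0, c1 - (c + d)):min(r1, c1)
  probs <- dhyper(k, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  orci <- odds_ratio_ci(a, b, c, d)
  tibble::tibble(
    method = "fisher", statistic = NA_real_, dof = NA_integer_,
    p_value = p, n = n, odds_ratio = orci$or,
    ci_lo = orci$lo, ci_hi = orci$hi, haldane = orci$haldane
  )
}

#' Genome-wide Fisher test for interval-set association
#'
#' Builds a 2x2 table from two interval sets in the bedtools-fisher style:
#' `n11` = overlapping pairs (the smaller of the two directional overlap
#' counts), `n12` / `n21` = intervals unique to each set, and `n22` = the
#' number of remaining placeable slots, estimated as
#' `genome_length / (mean_len(A) + mean_len(B))` minus the other cells.
#' The table construction is recorded in the result's `"construction"`
#' attribute so the statistic is interpretable.
#'
#' @param A,B Interval tibbles (merged internally).
#' @param genome Genome (sizes) the sets live on.
#' @return One-row tibble as [fisher_exact()], with attribute
#'   `"construction"`.
#' @export
genome_fisher <- function(A, B, genome) {
  sizes <- genome_sizes(genome)
  A <- validate_intervals(A, sizes, "A"); B <- validate_intervals(B, sizes, "B")
  if (nrow(A) == 0L || nrow(B) == 0L) abort("genome_fisher requires non-empty sets")
  Am <- granges_to_tbl(GenomicRanges::reduce(as_granges0(A)))
  Bm <- granges_to_tbl(GenomicRanges::reduce(as_granges0(B)))
  n11 <- min(count_overlapping(Am, Bm), count_overlapping(Bm, Am))
  n12 <- nrow(Am) - n11
  n21 <- nrow(Bm) - n11
  mean_len <- mean(Am$end - Am$start) + mean(Bm$end - Bm$start)
  slots <- sum(as.numeric(sizes)) / mean_len
  n22 <- max(0, round(slots) - n11 - n12 - n21)
  res <- fisher_exact(contingency_table(n11, n12, n21, n22))
  res$method <- "genome_fisher"
  attr(res, "construction") <- list(
    n11 = n11, n12 = n12, n21 = n21, n22 = n22,
    genome_bp = sum(as.numeric(sizes)), mean_len_sum = mean_len,
    note = "n22 = genome_length / (mean_len_A + mean_len_B) - other cells; Fisher on merged sets"
  )
  res
}

#' Monte-Carlo permutation test for interval colocalization
#'
#' The observed statistic (overlap count or bp coverage of `A` by `B`) is
#' compared with its null distribution obtained by randomizing `B`: per
#' chromosome, interval lengths and counts are preserved and starts are
#' redrawn uniformly — within the chromosome, or within the segments of an
#' open-chromatin `mask` when one is supplied (segments chosen
#' length-weighted among those large enough). The upper-tail empirical
#' p-value is `(r + 1) / (n_iter + 1)` where `r` counts null draws at or
#' above the observed value, so p can never fall below `1 / (n_iter + 1)`.
#'
#' @param A,B Interval tibbles on `genome`.
#' @param genome Genome (sizes).
#' @param n_iter Number of null draws (>= 19).
#' @param seed Integer seed; fixed seed gives a bit-identical result.
#' @param mask Optional interval tibble restricting randomized placements.
#' @param statistic `"count_overlapping"` (number of `A` intervals touching
#'   randomized `B`) or `"coverage_fraction"` (bp fraction of `A` covered).
#' @param alternative `"greater"` (enrichment, the default) or `"less"`.
#' @return A `qc_permtest` object: observed value, null draws, empirical p,
#'   and the run's parameters. `tidy()` gives a one-row summary.
#' @export
permutation_test <- function(A, B, genome, n_iter = 1000, seed = NULL,
                             mask = NULL,
                             statistic = c("count_overlapping", "coverage_fraction"),
                             alternative = c("greater", "less")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  sizes <- genome_sizes(genome)
  A <- validate_intervals(A, sizes, "A"); B <- validate_intervals(B, sizes, "B")
  if (n_iter < 19) abort("n_iter must be at least 19")
  if (!is.null(mask)) mask <- validate_intervals(mask, sizes, "mask")

  # A is fixed: pre-merge per chromosome once
  a_by_chrom <- lapply(split(A, A$chrom), function(x) {
    c(merge_intervals0(x$start, x$end), list(raw_s = x$start, raw_e = x$end))
  })
  observed <- perm_statistic(a_by_chrom, B$chrom, B$start, B$end, statistic)

  b_chrom <- B$chrom
  b_len <- B$end - B$start
  seg <- NULL
  if (!is.null(mask)) {
    seg <- mask |>
      dplyr::group_by(.data$chrom) |>
      dplyr::reframe(as.data.frame(merge_intervals0(.data$start, .data$end)))
    infeasible <- b_len > max(seg$end - seg$start)
    if (any(infeasible)) {
      abort("mask segment smaller than an interval to place and no feasible segment exists")
    }
  }
  null_draws <- numeric(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      if (is.null(seg)) {
        hi <- unname(sizes[b_chrom]) - b_len
        new_start <- floor(runif(length(b_len), 0, hi + 1))
        new_chrom <- b_chrom
      } else {
        seg_len <- seg$end - seg$start
        new_chrom <- character(length(b_len)); new_start <- numeric(length(b_len))
        for (i in seq_along(b_len)) {
          w <- pmax(0, seg_len - b_len[i] + 1)
          j <- sample.int(nrow(seg), 1, prob = w)
          new_chrom[i] <- seg$chrom[j]
          new_start[i] <- floor(runif(1, seg$start[j], seg$end[j] - b_len[i] + 1))
        }
      }
      null_draws[it] <- perm_statistic(a_by_chrom, new_chrom, new_start,
                                       new_start + b_len, statistic)
    }
  })
  r <- if (alternative == "greater") sum(null_draws >= observed)
       else sum(null_draws <= observed)
  structure(list(
    observed = observed, null = null_draws, n_iter = n_iter,
    empirical_p = (r + 1) / (n_iter + 1),
    null_mean = mean(null_draws), null_sd = sd(null_draws),
    null_quantiles = quantile(null_draws, c(0.025, 0.25, 0.5, 0.75, 0.975)),
    statistic = statistic, alternative = alternative, seed = seed,
    mask_name = if (is.null(mask)) NA_character_ else "mask"
  ), class = "qc_permtest")
}

# Statistic kernel shared by the observed value and every null draw.
perm_statistic <- function(a_by_chrom, b_chrom, b_start, b_end, statistic) {
  total <- 0; denom <- 0
  for (ch in names(a_by_chrom)) {
    a <- a_by_chrom[[ch]]
    ib <- which(b_chrom == ch)
    m <- merge_intervals0(b_start[ib], b_end[ib])
    if (statistic == "count_overlapping") {
      total <- total + sum(any_overlap0(a$raw_s, a$raw_e, m$start, m$end))
    } else {
      total <- total + sum(overlap_bp0(a$start, a$end, m$start, m$end))
      denom <- denom + sum(a$end - a$start)
    }
  }
  if (statistic == "coverage_fraction") total / denom else total
}

#' @export
print.qc_permtest <- function(x, ...) {
  cat("<permutation test>", x$statistic, "\n",
      "observed:", signif(x$observed, 5),
      " null mean:", signif(x$null_mean, 5),
      " (sd ", signif(x$null_sd, 4), ")\n",
      "empirical p (", x$alternative, "):", format(x$empirical_p), " [",
      x$n_iter, "draws ]\n")
  invisible(x)
}

#' @method tidy qc_permtest
#' @export
tidy.qc_permtest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, observed = x$observed, n_iter = x$n_iter,
    null_mean = x$null_mean, null_sd = x$null_sd,
    empirical_p = x$empirical_p, alternative = x$alternative
  )
}

#' Null-distribution box-plot style summary of a permutation test
#'
#' @param x A `qc_permtest`.
#' @param ... Unused.
#' @return One-row tibble with the null quantiles and the observed value.
#' @method glance qc_permtest
#' @export
glance.qc_permtest <- function(x, ...) {
  q <- x$null_quantiles
  tibble::tibble(observed = x$observed, null_q025 = q[[1]], null_q25 = q[[2]],
                 null_median = q[[3]], null_q75 = q[[4]], null_q975 = q[[5]],
                 empirical_p = x$empirical_p)
}

#' @rdname plot_quadcoloc
#' @method autoplot qc_permtest
#' @export
autoplot.qc_permtest <- function(object, ...) {
  ggplot2::ggplot(data.frame(null = object$null), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = paste("null", object$statistic), y = "draws",
      title = "Permutation null vs observed",
      subtitle = paste0("empirical p = ", format(object$empirical_p))
    ) +
    ggplot2::theme_minimal()
}
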