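# Interval-set operations: the manipulations a genomicist would do with
# bedtools, exposed as tidy verbs over interval tibbles (chrom / start / end,
# 0-based half-open). GenomicRanges supplies the overlap machinery.

#' Read / write BED interval files
#'
#' `read_bed()` accepts BED3-BED6; `track`, `browser` and `#` comment lines
#' are skipped. Coordinates are 0-based half-open, as in BED.
#'
#' @param path File path.
#' @param genome Optional genome; chromosome names and bounds are validated
#'   against it and its sizes travel with the result.
#' @return `read_bed()`: an interval tibble with any of `name`, `score`,
#'   `strand` present in the file; `write_bed()`: `path`, invisibly.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines[lineno], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("malformed BED line ", lineno[which(nf < 3)[1]],
                 ": fewer than 3 fields"))
  }
  ncol <- min(nf, 6L)
  get <- function(i) vapply(fields, function(f) f[i], character(1))
  out <- tibble::tibble(
    chrom = get(1),
    start = suppressWarnings(as.integer(get(2))),
    end = suppressWarnings(as.integer(get(3)))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    abort(paste0("malformed BED line ",
                 lineno[which(is.na(out$start) | is.na(out$end))[1]],
                 ": non-numeric coordinates"))
  }
  bad <- which(out$start >= out$end | out$start < 0)
  if (length(bad)) {
    abort(paste0("malformed BED line ", lineno[bad[1]],
                 ": requires 0 <= start < end"))
  }
  if (ncol >= 4) out$name <- get(4)
  if (ncol >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (ncol >= 6) out$strand <- get(6)
  out <- validate_intervals(out, genome, basename(path))
  if (!is.null(genome)) out <- set_genome_attr(out, genome)
  out
}

#' @param intervals Interval tibble; missing `name`/`score`/`strand` columns
#'   are filled with BED placeholders when higher columns are present.
#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  x <- tibble::as_tibble(intervals)
  cols <- list(x$chrom, x$start, x$end)
  has <- c(name = "name" %in% names(x), score = "score" %in% names(x),
           strand = "strand" %in% names(x))
  if (any(has)) cols <- c(cols, list(if (has["name"]) x$name else rep(".", nrow(x))))
  if (has["score"] || has["strand"]) {
    cols <- c(cols, list(if (has["score"]) x$score else rep(0, nrow(x))))
  }
  if (has["strand"]) cols <- c(cols, list(x$strand))
  readr::write_tsv(as.data.frame(setNames(cols, paste0("V", seq_along(cols)))),
                   path, col_names = FALSE)
  invisible(path)
}

#' Count query intervals overlapping a reference set
#'
#' @param A,B Interval tibbles on the same genome.
#' @param min_bp Minimum shared span (bp) for an overlap to count; half-open
#'   arithmetic, so abutting intervals share 0 bp. Strand-blind.
#' @return Integer: number of `A` intervals intersecting at least one `B`
#'   interval by `min_bp` or more.
#' @export
count_overlapping <- function(A, B, min_bp = 1) {
  A <- validate_intervals(A, arg = "A"); B <- validate_intervals(B, arg = "B")
  check_same_genome(A, B)
  if (nrow(A) == 0L || nrow(B) == 0L) return(0L)
  n <- GenomicRanges::countOverlaps(as_granges0(A), as_granges0(B),
                                    minoverlap = min_bp)
  sum(n > 0L)
}

#' Classify intervals as overlapping, flanking or free of a reference set
#'
#' Each `A` interval is labelled `overlap` if it shares >= 1 bp with some `B`
#' interval; otherwise `flank` if its edge-to-edge distance to the nearest
#' `B` interval is at most `flank_width` (default 200 bp, roughly one
#' nucleosome); otherwise `free`. Overlap takes precedence over flank.
#'
#' @inheritParams count_overlapping
#' @param flank_width Flank distance in bp.
#' @return `A` with an added `label` factor column
#'   (`overlap` / `flank` / `free`).
#' @export
classify_relative <- function(A, B, flank_width = 200) {
  A <- validate_intervals(A, arg = "A"); B <- validate_intervals(B, arg = "B")
  check_same_genome(A, B)
  label <- rep("free", nrow(A))
  if (nrow(A) && nrow(B)) {
    grA <- as_granges0(A); grB <- as_granges0(B)
    ov <- GenomicRanges::countOverlaps(grA, grB) > 0L
    d <- rep(Inf, nrow(A))
    nearest <- GenomicRanges::distanceToNearest(grA, grB)
    d[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance
    label[d <= flank_width] <- "flank"
    label[ov] <- "overlap"
  }
  A$label <- factor(label, levels = c("overlap", "flank", "free"))
  A
}

#' Summarize a classification into counts and percentages
#'
#' @param labels A factor/character vector of labels, or the output of
#'   [classify_relative()].
#' @return Tibble with `label`, `n`, `fraction` and `percent` (integer-rounded,
#'   the convention used when such fractions are reported).
#' @export
classification_summary <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- factor(labels, levels = union(c("overlap", "flank", "free"),
                                          unique(as.character(labels))))
  tab <- table(labels)
  tibble::tibble(
    label = names(tab),
    n = as.integer(tab),
    fraction = as.integer(tab) / sum(tab),
    percent = round(100 * as.integer(tab) / sum(tab))
  )
}

#' Base-pair coverage of one interval set by another
#'
#' Aggregate fraction of the (optionally flank-extended, then merged) `A`
#' footprint covered by merged `B` — the bedtools-style "coverage of
#' protein-bound sites with flanks". With `per_interval = TRUE` the mean of
#' per-interval covered fractions is returned instead, for the
#' per-interval-average reading of "average coverage".
#'
#' @inheritParams count_overlapping
#' @param flank_width Extension of each `A` interval on both sides, bp
#'   (clipped at chromosome bounds when the genome is known).
#' @param per_interval Average per extended interval instead of pooling bp.
#' @param genome Optional genome for clipping flanks.
#' @return A fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(A, B, flank_width = 0, per_interval = FALSE,
                              genome = NULL) {
  A <- validate_intervals(A, arg = "A"); B <- validate_intervals(B, arg = "B")
  check_same_genome(A, B)
  if (nrow(A) == 0L) return(NA_real_)
  sizes <- if (!is.null(genome)) genome_sizes(genome) else attr(A, "genome_sizes")
  A$start <- pmax(0L, A$start - as.integer(flank_width))
  A$end <- A$end + as.integer(flank_width)
  if (!is.null(sizes)) A$end <- pmin(A$end, unname(sizes[A$chrom]))
  per_chrom <- lapply(split(seq_len(nrow(A)), A$chrom), function(ia) {
    a <- merge_intervals0(A$start[ia], A$end[ia])
    bsub <- B[B$chrom == A$chrom[ia[1]], ]
    b <- merge_intervals0(bsub$start, bsub$end)
    if (per_interval) {
      cbind(overlap_bp0(A$start[ia], A$end[ia], b$start, b$end) /
              (A$end[ia] - A$start[ia]), 1)
    } else {
      cbind(sum(overlap_bp0(a$start, a$end, b$start, b$end)),
            sum(a$end - a$start))
    }
  })
  m <- do.call(rbind, per_chrom)
  if (per_interval) mean(m[, 1]) else sum(m[, 1]) / sum(m[, 2])
}

#' Relative-distance distribution between two interval sets
#'
#' The reldist statistic: for each `A` midpoint lying between two consecutive
#' `B` midpoints on the same chromosome, the distance to the nearer of the
#' two, scaled by the distance between them — a value in `[0, 0.5]` that is
#' uniform under spatial independence and piles up near 0 when the sets
#' colocalize. `A` midpoints outside the `B` midpoint range are skipped;
#' chromosomes with fewer than two distinct `B` midpoints are skipped.
#'
#' @inheritParams count_overlapping
#' @return Tibble with `chrom`, `midpoint` and `reldist` per scored `A`
#'   interval.
#' @export
relative_distances <- function(A, B) {
  A <- validate_intervals(A, arg = "A"); B <- validate_intervals(B, arg = "B")
  check_same_genome(A, B)
  out <- lapply(intersect(unique(A$chrom), unique(B$chrom)), function(ch) {
    am <- (A$start[A$chrom == ch] + A$end[A$chrom == ch]) / 2
    bm <- sort(unique((B$start[B$chrom == ch] + B$end[B$chrom == ch]) / 2))
    if (length(bm) < 2L) return(NULL)
    am <- am[am >= bm[1] & am <= bm[length(bm)]]
    if (!length(am)) return(NULL)
    j <- findInterval(am, bm)
    j[j == length(bm)] <- length(bm) - 1L   # midpoint coincident with last B
    d <- pmin(am - bm[j], bm[j + 1L] - am) / (bm[j + 1L] - bm[j])
    tibble::tibble(chrom = ch, midpoint = am, reldist = d)
  })
  dplyr::bind_rows(out)
}

#' Bin relative distances into a normalized histogram
#'
#' @param reldist Output of [relative_distances()] (or a numeric vector).
#' @param n_bins Number of equal-width bins on `[0, 0.5]`.
#' @return Tibble with `bin_mid` and `frequency` (sums to 1).
#' @export
reldist_histogram <- function(reldist, n_bins = 25) {
  v <- if (is.data.frame(reldist)) reldist$reldist else reldist
  breaks <- seq(0, 0.5, length.out = n_bins + 1)
  cnt <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
  tibble::tibble(bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 frequency = cnt / max(1L, length(v)))
}

#' Metaplot profile of signal intervals around anchor midpoints
#'
#' Windows of `2 * half_window` bp centered on anchor midpoints are divided
#' into `n_bins` equal bins; each bin's value is the fraction of windows with
#' at least one signal bp in that bin. Windows truncated by a chromosome edge
#' are dropped.
#'
#' @param anchors,signal Interval tibbles on the same genome.
#' @param half_window Half window width, bp.
#' @param n_bins Number of bins across the window.
#' @param genome Optional genome for edge handling (falls back to the sizes
#'   attached to `anchors`).
#' @return Tibble with `bin`, `offset_bp` (bin center relative to the anchor
#'   midpoint) and `mean_signal`.
#' @export
profile_matrix <- function(anchors, signal, half_window = 1000, n_bins = 40,
                           genome = NULL) {
  anchors <- validate_intervals(anchors, arg = "anchors")
  signal <- validate_intervals(signal, arg = "signal")
  check_same_genome(anchors, signal)
  sizes <- if (!is.null(genome)) genome_sizes(genome) else attr(anchors, "genome_sizes")
  mid <- floor((anchors$start + anchors$end) / 2)
  lo <- mid - half_window
  hi <- mid + half_window
  keep <- lo >= 0
  if (!is.null(sizes)) keep <- keep & hi <= unname(sizes[anchors$chrom])
  lo <- lo[keep]; chroms <- anchors$chrom[keep]
  if (!length(lo)) abort("no anchor window fits inside the genome")
  w <- 2 * half_window / n_bins
  edges <- (0:n_bins) * w
  hit_mat <- matrix(FALSE, length(lo), n_bins)
  for (ch in unique(chroms)) {
    ia <- which(chroms == ch)
    bsub <- signal[signal$chrom == ch, ]
    m <- merge_intervals0(bsub$start, bsub$end)
    for (b in seq_len(n_bins)) {
      qs <- lo[ia] + edges[b]
      qe <- lo[ia] + edges[b + 1]
      hit_mat[ia, b] <- any_overlap0(qs, qe, m$start, m$end)
    }
  }
  tibble::tibble(
    bin = seq_len(n_bins),
    offset_bp = (edges[-1] + edges[-(n_bins + 1)]) / 2 - half_window,
    mean_signal = colMeans(hit_mat)
  )
}

#' Venn-style overlap pattern counts
#'
#' Counts `A` intervals by their overlap pattern with `B` (and optionally
#' `C`). Note the reference-set asymmetry: patterns are assigned per `A`
#' interval, so counts are not symmetric in the arguments (recorded in the
#' `reference` attribute).
#'
#' @inheritParams count_overlapping
#' @param C Optional third interval set.
#' @return Tibble with `pattern` and `count`; attribute `reference = "A"`.
#' @export
venn_counts <- function(A, B, C = NULL) {
  A <- validate_intervals(A, arg = "A"); B <- validate_intervals(B, arg = "B")
  check_same_genome(A, B)
  grA <- as_granges0(A)
  inB <- GenomicRanges::countOverlaps(grA, as_granges0(B)) > 0L
  if (is.null(C)) {
    pat <- ifelse(inB, "A_and_B", "A_only")
    lev <- c("A_only", "A_and_B")
  } else {
    C <- validate_intervals(C, arg = "C")
    inC <- GenomicRanges::countOverlaps(grA, as_granges0(C)) > 0L
    pat <- dplyr::case_when(
      inB & inC ~ "A_and_B_and_C",
      inB ~ "A_and_B",
      inC ~ "A_and_C",
      TRUE ~ "A_only"
    )
    lev <- c("A_only", "A_and_B", "A_and_C", "A_and_B_and_C")
  }
  out <- tibble::tibble(pattern = lev,
                        count = as.integer(table(factor(pat, levels = lev))))
  attr(out, "reference") <- "A"
  out
}

#' Intersect two interval sets into fragments
#'
#' Merged-set intersection: the genomic fragments covered by both `A` and
#' `B`.
#'
#' @inheritParams count_overlapping
#' @return Interval tibble of intersection fragments.
#' @export
intersect_intervals <- function(A, B) {
  A <- validate_intervals(A, arg = "A"); B <- validate_intervals(B, arg = "B")
  check_same_genome(A, B)
  gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(as_granges0(A)),
    GenomicRanges::reduce(as_granges0(B))
  )
  out <- granges_to_tbl(gr)
  ga <- attr(A, "genome_sizes")
  if (!is.null(ga)) out <- set_genome_attr(out, ga)
  out
}
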