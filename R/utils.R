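# Internal helpers shared across modules.

# Deterministically derive a child seed from a master seed and a stage label,
# so every stochastic stage of a pipeline run has its own reproducible stream.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) + h * 7919) %% 2147483563 + 1)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- rlang::`%||%`

# Half-open [start, end) interval tibbles are the package currency; GRanges
# (1-based closed) only live inside functions that lean on GenomicRanges.
as_granges0 <- function(x, genome = NULL) {
  seqlengths <- NULL
  if (!is.null(genome)) seqlengths <- genome_sizes(genome)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    seqlengths = seqlengths
  )
}

granges_to_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Validate an interval tibble: required columns, half-open sanity, optional
# genome bounds. Returns the tibble sorted by (chrom, start, end).
validate_intervals <- function(x, genome = NULL, arg = "intervals") {
  if (!is.data.frame(x)) abort(paste0("`", arg, "` must be a data frame"))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("`", arg, "` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0L) return(x)
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    abort(paste0("`", arg, "`: invalid interval (need 0 <= start < end) at row ",
                 bad[1]))
  }
  if (!is.null(genome)) {
    sizes <- genome_sizes(genome)
    unknown <- setdiff(unique(x$chrom), names(sizes))
    if (length(unknown)) {
      abort(paste0("`", arg, "`: chromosome(s) not in genome: ",
                   paste(unknown, collapse = ", ")))
    }
    over <- which(x$end > unname(sizes[x$chrom]))
    if (length(over)) {
      abort(paste0("`", arg, "`: interval exceeds chromosome length at row ",
                   over[1]))
    }
  }
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

# Accepts a qc_genome, a named numeric vector, or a two-column data frame.
genome_sizes <- function(genome) {
  if (inherits(genome, "qc_genome")) return(genome$sizes)
  if (is.data.frame(genome)) {
    return(setNames(as.integer(genome[[2]]), as.character(genome[[1]])))
  }
  if (is.numeric(genome) && !is.null(names(genome))) {
    return(setNames(as.integer(genome), names(genome)))
  }
  abort("`genome` must be a qc_genome, a named vector of sizes, or a two-column data frame")
}

check_same_genome <- function(A, B) {
  ga <- attr(A, "genome_sizes")
  gb <- attr(B, "genome_sizes")
  if (!is.null(ga) && !is.null(gb) && !identical(ga[order(names(ga))], gb[order(names(gb))])) {
    abort("interval sets come from different genomes")
  }
  invisible(TRUE)
}

set_genome_attr <- function(x, genome) {
  attr(x, "genome_sizes") <- genome_sizes(genome)
  x
}

# --- fast sorted-interval kernels (used by the permutation engine; tested
# --- against the GenomicRanges-backed public operations) -------------------

# Merge possibly-overlapping half-open intervals given as equal-length start /
# end vectors (any order); returns list(start, end) sorted and disjoint.
merge_intervals0 <- function(start, end) {
  if (length(start) == 0L) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  cummax_e <- cummax(e)
  # a new block starts where this start exceeds the running max end so far
  new_block <- c(TRUE, s[-1] > cummax_e[-length(e)])
  grp <- cumsum(new_block)
  list(
    start = s[new_block],
    end = as.numeric(tapply(e, grp, max))
  )
}

# For query half-open intervals [qs, qe) and a merged (sorted, disjoint)
# reference, return logical: does each query overlap >= 1 reference bp?
any_overlap0 <- function(qs, qe, ms, me) {
  if (length(ms) == 0L || length(qs) == 0L) return(rep(FALSE, length(qs)))
  i <- findInterval(qe - 1L, ms)      # rightmost ref with start < qe
  hit <- i >= 1L
  hit[hit] <- me[i[hit]] > qs[hit]
  hit
}

# Total bp of the merged reference lying below position x (vectorized).
covered_below0 <- function(x, ms, me) {
  if (length(ms) == 0L) return(rep(0, length(x)))
  lens <- me - ms
  cum <- c(0, cumsum(lens))
  i <- findInterval(x, ms)
  out <- cum[i + 1L]
  inside <- i >= 1L & x < me[pmax(i, 1L)]
  out[inside] <- cum[i[inside]] + (x[inside] - ms[i[inside]])
  out
}

# Intersection bp between query intervals and the merged reference.
overlap_bp0 <- function(qs, qe, ms, me) {
  covered_below0(qe, ms, me) - covered_below0(qs, ms, me)
}
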