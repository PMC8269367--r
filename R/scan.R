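# Consensus-pattern G-quadruplex / i-motif scanner. The canonical pattern is
# four runs of >= 3 G (or C) separated by 1-7 nt loops; runs are maximal
# (contiguous G absorbed into one run) and overlapping candidates are
# resolved greedily by a run/loop stability heuristic.

#' Scanner configuration
#'
#' @param min_run Minimum run length (>= 2; consensus default 3).
#' @param loop_min,loop_max Allowed loop length bounds (default 1-7, the
#'   standard quadruplex-prediction convention).
#' @param runs_required Number of runs per motif (default 4).
#' @param both_strands Also report the complementary-strand pattern (C-runs
#'   for a G4 scan) as minus-strand hits.
#' @param score_threshold Optional minimum stability score; hits below it are
#'   dropped. A configurable proxy for stability filters used in the field.
#' @param alpha,beta Stability-score weights: `alpha` per run base beyond the
#'   minimum, `beta` penalty per loop base.
#' @return A `scan_config` list.
#' @export
scan_config <- function(min_run = 3, loop_min = 1, loop_max = 7,
                        runs_required = 4, both_strands = TRUE,
                        score_threshold = NULL, alpha = 1, beta = 0.5) {
  stopifnot(min_run >= 2, loop_min >= 1, loop_min <= loop_max,
            runs_required >= 2, alpha >= 0, beta >= 0)
  structure(list(min_run = as.integer(min_run), loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 runs_required = as.integer(runs_required),
                 both_strands = isTRUE(both_strands),
                 score_threshold = score_threshold, alpha = alpha, beta = beta),
            class = "scan_config")
}

#' Scan a sequence for G-quadruplex motifs
#'
#' Finds every maximal-extent arrangement of `runs_required` G-runs (each of
#' length >= `min_run`) separated by loops within the configured bounds, then
#' resolves overlapping candidates with [resolve_overlaps()]. With
#' `both_strands = TRUE`, C-run matches on the given strand (the footprint of
#' a minus-strand G4) are reported with strand `"-"`.
#'
#' @param sequence Character scalar over `{A, C, G, T, N}` (case-insensitive);
#'   `N` never matches a run.
#' @param config A [scan_config()].
#' @param chrom Chromosome name recorded in the output.
#' @return A tibble of hits: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `motif_class`, `run_count`, `run_lengths` and `loop_lengths`
#'   (list columns), `score`.
#' @examples
#' scan_g4("GGGAGGGAGGGAGGG")
#' @export
scan_g4 <- function(sequence, config = scan_config(), chrom = "seq1") {
  scan_quadruplex(sequence, config, chrom, motif_class = "G4")
}

#' Scan a sequence for i-motif candidates
#'
#' As [scan_g4()] with C-runs on the plus strand (and G-runs reported as
#' minus-strand i-motifs when `both_strands = TRUE`): the i-motif is the
#' C-rich structure on the strand complementary to a G4-prone sequence.
#'
#' @inheritParams scan_g4
#' @return A tibble of hits (see [scan_g4()]).
#' @examples
#' scan_imotif("CCCCTCCCCTCCCCTCCCC")
#' @export
scan_imotif <- function(sequence, config = scan_config(), chrom = "seq1") {
  scan_quadruplex(sequence, config, chrom, motif_class = "iM")
}

scan_quadruplex <- function(sequence, config, chrom, motif_class) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) return(empty_hits())
  if (grepl("[^ACGTN]", sequence)) {
    abort("sequence contains characters outside {A, C, G, T, N}")
  }
  plus_base <- if (motif_class == "G4") "G" else "C"
  minus_base <- if (motif_class == "G4") "C" else "G"
  hits <- candidate_hits(sequence, plus_base, config, chrom, motif_class, "+")
  if (config$both_strands) {
    hits <- dplyr::bind_rows(
      hits, candidate_hits(sequence, minus_base, config, chrom, motif_class, "-")
    )
  }
  if (nrow(hits) == 0L) return(empty_hits())
  hits$score <- score_motif(hits, alpha = config$alpha, beta = config$beta,
                            min_run = config$min_run,
                            runs_required = config$runs_required)
  if (!is.null(config$score_threshold)) {
    hits <- hits[hits$score >= config$score_threshold, ]
  }
  resolve_overlaps(hits)
}

empty_hits <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), motif_class = character(),
                 run_count = integer(), run_lengths = list(),
                 loop_lengths = list(), score = numeric())
}

# Enumerate all candidate windows of `runs_required` consecutive maximal runs
# of `base` with loops inside the configured bounds.
candidate_hits <- function(sequence, base, config, chrom, motif_class, strand) {
  r <- charToRaw(sequence) == charToRaw(base)
  runs <- rle(r)
  ends <- cumsum(runs$lengths)                 # 1-based inclusive ends
  starts0 <- ends - runs$lengths               # 0-based starts
  keep <- runs$values & runs$lengths >= config$min_run
  rs <- starts0[keep]                          # 0-based run starts
  re <- ends[keep]                             # 0-based half-open run ends
  k <- config$runs_required
  nruns <- length(rs)
  if (nruns < k) return(empty_hits())
  gaps <- rs[-1] - re[-nruns]                  # loop lengths between runs
  gap_ok <- gaps >= config$loop_min & gaps <= config$loop_max
  # window i spans runs i..i+k-1: valid iff all k-1 gaps are in bounds
  ok_run <- rle(c(gap_ok, FALSE))
  valid_i <- integer(0)
  pos <- 1L
  for (j in seq_along(ok_run$lengths)) {
    if (ok_run$values[j] && ok_run$lengths[j] >= k - 1L) {
      valid_i <- c(valid_i, pos:(pos + ok_run$lengths[j] - (k - 1L)))
    }
    pos <- pos + ok_run$lengths[j]
  }
  if (!length(valid_i)) return(empty_hits())
  tibble::tibble(
    chrom = chrom,
    start = as.integer(rs[valid_i]),
    end = as.integer(re[valid_i + k - 1L]),
    strand = strand,
    motif_class = motif_class,
    run_count = as.integer(k),
    run_lengths = lapply(valid_i, function(i) as.integer(re[i:(i + k - 1L)] - rs[i:(i + k - 1L)])),
    loop_lengths = lapply(valid_i, function(i) as.integer(gaps[i:(i + k - 2L)]))
  )
}

#' Stability score of motif hits
#'
#' A simple monotone heuristic: longer runs stabilize, longer loops
#' destabilize. `score = alpha * sum(run_lengths - min_run) -
#' beta * sum(loop_lengths) + runs_required * min_run`, so the minimal
#' consensus motif has a positive baseline score.
#'
#' @param hits A hit tibble (see [scan_g4()]).
#' @param alpha Reward per run base beyond `min_run`.
#' @param beta Penalty per loop base.
#' @param min_run,runs_required Pattern parameters the baseline is computed
#'   from.
#' @return Numeric score vector, one per hit.
#' @export
score_motif <- function(hits, alpha = 1, beta = 0.5, min_run = 3,
                        runs_required = 4) {
  extra <- vapply(hits$run_lengths, function(r) sum(r - min_run), numeric(1))
  loops <- vapply(hits$loop_lengths, sum, numeric(1))
  alpha * extra - beta * loops + runs_required * min_run
}

#' Resolve overlapping motif candidates
#'
#' Greedy selection by descending score; ties broken by leftmost start, then
#' plus strand first. Retained hits are mutually non-overlapping per strand
#' (plus- and minus-strand hits may still co-locate and are reported
#' separately).
#'
#' @param hits A hit tibble.
#' @return The retained hits, sorted by position.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  ord <- order(-hits$score, hits$start, hits$strand != "+")
  keep <- logical(nrow(hits))
  for (grp in split(ord, paste(hits$chrom[ord], hits$strand[ord]))) {
    taken_s <- numeric(0); taken_e <- numeric(0)
    for (i in grp) {
      if (!any(hits$start[i] < taken_e & hits$end[i] > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, hits$start[i])
        taken_e <- c(taken_e, hits$end[i])
      }
    }
  }
  out <- hits[keep, ]
  out[order(out$chrom, out$start, out$end, out$strand), ]
}

#' Convert motif hits to a BED-style interval tibble
#'
#' @param hits A hit tibble from [scan_g4()] / [scan_imotif()].
#' @param genome Optional genome whose sizes are attached for downstream
#'   checks.
#' @return Interval tibble with BED6 semantics: `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`.
#' @export
hits_to_intervals <- function(hits, genome = NULL) {
  out <- tibble::tibble(
    chrom = hits$chrom, start = hits$start, end = hits$end,
    name = paste0(tolower(hits$motif_class), "_", seq_len(nrow(hits))),
    score = hits$score, strand = hits$strand
  )
  if (!is.null(genome)) out <- set_genome_attr(out, genome)
  out
}

#' Scan a whole genome for quadruplex motifs
#'
#' Convenience wrapper running [scan_g4()] or [scan_imotif()] over every
#' chromosome of a genome.
#'
#' @param genome A `qc_genome` with sequence.
#' @param config A [scan_config()].
#' @param motif_class `"G4"` or `"iM"`.
#' @return A hit tibble across all chromosomes.
#' @export
scan_genome <- function(genome, config = scan_config(), motif_class = c("G4", "iM")) {
  motif_class <- match.arg(motif_class)
  if (is.null(genome$seq)) abort("genome carries no sequence")
  f <- if (motif_class == "G4") scan_g4 else scan_imotif
  dplyr::bind_rows(lapply(names(genome$seq), function(ch) {
    f(genome$seq[[ch]], config, chrom = ch)
  }))
}
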