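# Synthetic-data module: every input the pipeline consumes can be generated
# here with known ground truth, so the whole analysis runs offline.

#' Plant G-quadruplex and i-motif sequences into a genome
#'
#' Writes consensus quadruplex sequences (four G-runs separated by short
#' non-G loops; C-runs for i-motifs) at random non-overlapping positions.
#' Flanking sequence (one base more than the longest allowed loop, each side)
#' is rewritten to A/T so that no accidental G- or C-run abuts a planted site
#' and no candidate motif can cross a planted-site boundary: planted sites
#' are therefore recovered exactly by the scanner, by construction.
#'
#' @param genome A `qc_genome` with sequence.
#' @param n_g4,n_im Number of G4 and i-motif sites to plant.
#' @param run_len Length of each of the four runs (>= 3).
#' @param loop_lens Candidate loop lengths (subset of 1..7 by default).
#' @param seed Integer seed.
#' @return A list with `genome` (edited copy) and `truth`, a tibble of planted
#'   sites (`chrom`, `start`, `end`, `motif_class`, `strand`, `name`).
#' @examples
#' g <- make_genome(c(chr1 = 50000), seed = 1)
#' pg <- plant_motifs(g, n_g4 = 5, n_im = 2, seed = 2)
#' pg$truth
#' @export
plant_motifs <- function(genome, n_g4 = 50, n_im = 20, run_len = 3,
                         loop_lens = 1:7, seed = NULL) {
  if (is.null(genome$seq)) abort("genome carries no sequence")
  stopifnot(run_len >= 3, all(loop_lens >= 1), all(loop_lens <= 7))
  n_g4 <- as.integer(n_g4); n_im <- as.integer(n_im)
  if (n_g4 + n_im == 0L) {
    return(list(genome = genome, truth = empty_truth()))
  }
  buffer <- max(loop_lens) + 1L
  sizes <- genome$sizes
  raws <- lapply(genome$seq, charToRaw)

  with_seed(seed, {
    classes <- c(rep("G4", n_g4), rep("iM", n_im))
    strands <- sample(c("+", "-"), n_g4 + n_im, replace = TRUE)
    placed <- vector("list", n_g4 + n_im)
    occupied <- lapply(sizes, function(.) cbind(start = numeric(0), end = numeric(0)))
    max_len <- 4L * run_len + 3L * max(loop_lens)
    if (sum(pmax(0, sizes - 2 * buffer)) < (n_g4 + n_im) * (max_len + 2 * buffer)) {
      abort("genome too small for the requested number of planted motifs")
    }
    for (i in seq_len(n_g4 + n_im)) {
      motif <- build_motif_seq(classes[i], strands[i], run_len, loop_lens)
      len <- nchar(motif)
      ok <- FALSE
      for (try in 1:200) {
        chrom <- sample(names(sizes), 1, prob = as.numeric(sizes))
        hi <- sizes[[chrom]] - len - buffer
        if (hi <= buffer) next
        start <- floor(runif(1, buffer, hi + 1))
        occ <- occupied[[chrom]]
        # keep a full buffer between planted sites (expanded-interval check)
        if (nrow(occ) && any(occ[, 1] < start + len + buffer &
                             occ[, 2] > start - buffer)) next
        ok <- TRUE
        break
      }
      if (!ok) abort("could not place all motifs without overlap; genome too small")
      occupied[[chrom]] <- rbind(occupied[[chrom]], c(start, start + len))
      # A/T pad each side, then the motif itself
      pad_l <- sample(c("A", "T"), buffer, replace = TRUE)
      pad_r <- sample(c("A", "T"), buffer, replace = TRUE)
      piece <- charToRaw(paste0(paste(pad_l, collapse = ""), motif,
                                paste(pad_r, collapse = "")))
      raws[[chrom]][(start - buffer + 1):(start + len + buffer)] <- piece
      placed[[i]] <- tibble::tibble(
        chrom = chrom, start = start, end = start + len,
        motif_class = classes[i], strand = strands[i]
      )
    }
    truth <- dplyr::bind_rows(placed) |>
      dplyr::mutate(name = paste0("planted_", tolower(.data$motif_class), "_",
                                  dplyr::row_number())) |>
      dplyr::arrange(.data$chrom, .data$start)
    genome$seq <- setNames(vapply(raws, rawToChar, character(1)), names(raws))
    list(genome = genome, truth = set_genome_attr(truth, genome))
  })
}

empty_truth <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 motif_class = character(), strand = character(),
                 name = character())
}

# One consensus motif sequence. Plus-strand G4 = G-runs; minus-strand G4 is
# represented on the given strand by its reverse complement (C-runs); i-motif
# is the converse.
build_motif_seq <- function(motif_class, strand, run_len, loop_lens) {
  loops <- sample(loop_lens, 3, replace = TRUE)
  loop_alphabet <- c("A", "C", "T")      # no G: planted runs stay maximal
  run <- strrep("G", run_len)
  parts <- character(7)
  parts[c(1, 3, 5, 7)] <- run
  parts[c(2, 4, 6)] <- vapply(loops, function(l) {
    paste(sample(loop_alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
  s <- paste(parts, collapse = "")
  g_pattern <- (motif_class == "G4") == (strand == "+")
  if (g_pattern) s else revcomp(s)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Sample random intervals on a genome
#'
#' Uniform placement: chromosomes chosen proportionally to their length (or,
#' with a mask, mask segments chosen proportionally to the number of feasible
#' start positions), starts uniform, interval lengths uniform in
#' `length_range`. This same placement engine is the null sampler used by the
#' permutation test.
#'
#' @param genome A `qc_genome` or named size vector.
#' @param n Number of intervals.
#' @param length_range Two-element vector `(min, max)` bp; lengths drawn
#'   uniformly. Default 100-500 bp emulates ChIP-seq peak widths.
#' @param seed Integer seed.
#' @param mask Optional interval tibble; all placements fall inside it.
#' @param allow_self_overlap If `FALSE`, intervals of the returned set are
#'   mutually non-overlapping (bounded rejection sampling).
#' @param name Set name stored in the `name` column prefix.
#' @return Sorted interval tibble (`chrom`, `start`, `end`, `name`).
#' @export
sample_intervals <- function(genome, n, length_range = c(100, 500), seed = NULL,
                             mask = NULL, allow_self_overlap = TRUE,
                             name = "region") {
  sizes <- genome_sizes(genome)
  n <- as.integer(n)
  stopifnot(n >= 0, length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  if (!is.null(mask)) mask <- validate_intervals(mask, genome, "mask")
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    out <- place_intervals(sizes, lens, mask)
    if (!allow_self_overlap) {
      for (round in 1:100) {
        conflict <- self_overlap_idx(out)
        if (!length(conflict)) break
        repl <- place_intervals(sizes, out$len[conflict], mask)
        out[conflict, c("chrom", "start", "end")] <-
          repl[, c("chrom", "start", "end")]
        if (round == 100) abort("infeasible placement: could not avoid self-overlap after bounded retries")
      }
    }
    out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end) |>
      dplyr::mutate(name = paste0(name, "_", dplyr::row_number())) |>
      dplyr::select("chrom", "start", "end", "name")
    set_genome_attr(out, sizes)
  })
}

# Core placement: lengths fixed, positions uniform (optionally inside a mask).
place_intervals <- function(sizes, lens, mask = NULL) {
  n <- length(lens)
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), len = integer()))
  }
  if (is.null(mask)) {
    too_big <- lens > max(sizes)
    if (any(too_big)) abort("interval length exceeds every chromosome")
    chrom <- sample(names(sizes), n, replace = TRUE, prob = as.numeric(sizes))
    hi <- unname(sizes[chrom]) - lens
    # a chromosome drawn too small for this length: redraw among feasible ones
    bad <- which(hi < 0)
    while (length(bad)) {
      chrom[bad] <- sample(names(sizes), length(bad), replace = TRUE,
                           prob = as.numeric(sizes))
      hi <- unname(sizes[chrom]) - lens
      bad <- which(hi < 0)
    }
    start <- floor(runif(n, 0, hi + 1))
    return(tibble::tibble(chrom = chrom, start = as.integer(start),
                          end = as.integer(start + lens), len = as.integer(lens)))
  }
  # mask path: merged segments, chosen length-weighted among feasible ones
  segs <- mask |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(as.data.frame(merge_intervals0(.data$start, .data$end)))
  if (sum(segs$end - segs$start) < max(lens) * n) {
    abort("mask too small: must cover at least n * max(length) bp")
  }
  seg_len <- segs$end - segs$start
  chrom <- character(n); start <- integer(n)
  for (i in seq_len(n)) {
    w <- pmax(0, seg_len - lens[i] + 1)
    if (all(w == 0)) abort("infeasible placement: no mask segment can hold an interval of the requested length")
    j <- sample.int(nrow(segs), 1, prob = w)
    chrom[i] <- segs$chrom[j]
    start[i] <- floor(runif(1, segs$start[j], segs$end[j] - lens[i] + 1))
  }
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + lens), len = as.integer(lens))
}

self_overlap_idx <- function(x) {
  o <- order(x$chrom, x$start)
  xs <- x[o, ]
  clash <- logical(nrow(xs))
  prev_end <- -Inf; prev_chrom <- ""
  for (i in seq_len(nrow(xs))) {
    if (xs$chrom[i] == prev_chrom && xs$start[i] < prev_end) {
      clash[i] <- TRUE
    } else {
      prev_end <- xs$end[i]; prev_chrom <- xs$chrom[i]
    }
  }
  o[clash]
}

#' Sample intervals enriched around an anchor set
#'
#' Mixture placement: each interval overlaps a uniformly chosen anchor with
#' probability `mixture_weight`, and is placed uniformly otherwise. This
#' emulates the overlap enrichment observed between quadruplex maps and
#' protein-binding peak sets, with the mixture weight as the known truth.
#'
#' @inheritParams sample_intervals
#' @param anchors Interval tibble to enrich around (non-empty when
#'   `mixture_weight > 0`).
#' @param mixture_weight Probability in `[0, 1]` that an interval is anchored.
#' @return Sorted interval tibble; the realized `mixture_weight` is stored as
#'   an attribute `"mixture_weight"`.
#' @export
sample_enriched_intervals <- function(genome, anchors, mixture_weight, n,
                                      length_range = c(100, 500), seed = NULL,
                                      name = "peak") {
  sizes <- genome_sizes(genome)
  stopifnot(mixture_weight >= 0, mixture_weight <= 1)
  anchors <- validate_intervals(anchors, sizes, "anchors")
  if (mixture_weight > 0 && nrow(anchors) == 0L) {
    abort("anchors must be non-empty when mixture_weight > 0")
  }
  with_seed(seed, {
    n <- as.integer(n)
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    anchored <- runif(n) < mixture_weight
    out <- place_intervals(sizes, lens)
    if (any(anchored)) {
      idx <- which(anchored)
      a <- anchors[sample.int(nrow(anchors), length(idx), replace = TRUE), ]
      lo <- pmax(0, a$start - lens[idx] + 1)
      hi <- pmin(unname(sizes[a$chrom]) - lens[idx], a$end - 1)
      hi <- pmax(hi, lo)   # degenerate chromosome edges: clamp
      start <- floor(runif(length(idx), lo, hi + 1))
      out$chrom[idx] <- a$chrom
      out$start[idx] <- as.integer(start)
      out$end[idx] <- as.integer(start + lens[idx])
    }
    out <- dplyr::arrange(out, .data$chrom, .data$start, .data$end) |>
      dplyr::mutate(name = paste0(name, "_", dplyr::row_number())) |>
      dplyr::select("chrom", "start", "end", "name")
    out <- set_genome_attr(out, sizes)
    attr(out, "mixture_weight") <- mixture_weight
    out
  })
}

#' Simulate a per-CpG methylation track with region-dependent means
#'
#' CpG sites are laid out every `cpg_spacing` bp; each site's methylation
#' percentage is the mean of the innermost stratum containing it (background
#' otherwise) plus clipped Gaussian noise. Strata emulate the observed
#' ordering of methylation across region classes (protein-bound sites <
#' CpG islands < in-cell G4 sites).
#'
#' @param genome A `qc_genome` or named size vector.
#' @param strata List of strata, each `list(intervals = <tibble>, mean = <pct>)`;
#'   the innermost (smallest) containing interval wins where strata overlap.
#' @param background_mean Percentage used outside all strata.
#' @param noise_sd Gaussian noise SD on the percentage scale; values are
#'   clipped to `[0, 100]`.
#' @param cpg_spacing Distance between simulated CpG sites, bp.
#' @param seed Integer seed.
#' @return A methylation track tibble (`chrom`, `pos`, `percent`, `coverage`).
#' @export
simulate_methylation <- function(genome, strata = list(), background_mean = 70,
                                 noise_sd = 5, cpg_spacing = 100, seed = NULL) {
  sizes <- genome_sizes(genome)
  means <- vapply(strata, function(s) s$mean, numeric(1))
  if (length(means) && (any(means < 0) || any(means > 100))) {
    abort("stratum means must be within [0, 100]")
  }
  stopifnot(background_mean >= 0, background_mean <= 100, cpg_spacing >= 1)
  pos_list <- lapply(names(sizes), function(ch) {
    p <- seq.int(cpg_spacing, sizes[[ch]] - 2L, by = cpg_spacing)
    tibble::tibble(chrom = ch, pos = as.integer(p))
  })
  track <- dplyr::bind_rows(pos_list)
  site_mean <- rep(background_mean, nrow(track))
  site_width <- rep(Inf, nrow(track))
  pts <- GenomicRanges::GRanges(track$chrom,
                                IRanges::IRanges(track$pos + 1L, track$pos + 1L))
  for (s in strata) {
    iv <- validate_intervals(s$intervals, sizes, "stratum intervals")
    if (nrow(iv) == 0L) next
    gr <- as_granges0(iv)
    hits <- GenomicRanges::findOverlaps(pts, gr)
    if (!length(hits)) next
    w <- GenomicRanges::width(gr)[S4Vectors::subjectHits(hits)]
    q <- S4Vectors::queryHits(hits)
    # innermost containing interval of THIS stratum per site
    min_w <- tapply(w, q, min)
    sites <- as.integer(names(min_w))
    ambiguous <- min_w == site_width[sites]
    if (any(ambiguous)) {
      warn(paste0(sum(ambiguous), " CpG site(s) fall in equally sized ",
                  "intervals of different strata; first stratum kept"))
    }
    take <- min_w < site_width[sites]
    site_mean[sites[take]] <- s$mean
    site_width[sites[take]] <- min_w[take]
  }
  with_seed(seed, {
    pct <- site_mean + if (noise_sd > 0) rnorm(nrow(track), 0, noise_sd) else 0
    track$percent <- pmin(100, pmax(0, pct))
    track$coverage <- rpois(nrow(track), 30) + 1L
    track
  })
}

#' Simulate a microscale-thermophoresis (MST) dose-response curve
#'
#' A two-fold serial dilution of the unlabeled ligand (default 16 points from
#' 20 uM down to ~0.61 nM) titrated against a fixed labeled-protein
#' concentration (default 50 nM). The response is the 1:1
#' titrant-depletion isotherm between the free- and bound-state plateaus,
#' plus additive Gaussian noise.
#'
#' @param kd True dissociation constant, nM.
#' @param protein_conc Fixed labeled-protein concentration, nM.
#' @param f_free,f_bound Response plateaus (normalized fluorescence units).
#' @param n_points Number of dilution points.
#' @param top_conc Highest ligand concentration, nM.
#' @param dilution Serial dilution factor (> 1).
#' @param noise_sd Additive Gaussian noise SD, response units.
#' @param seed Integer seed.
#' @return A binding-curve tibble (`conc_nM`, `response`, `protein_nM`) with
#'   the generating parameters stored in attribute `"truth"`.
#' @examples
#' simulate_mst_curve(kd = 100, seed = 1)
#' @export
simulate_mst_curve <- function(kd = 100, protein_conc = 50, f_free = 0,
                               f_bound = 1, n_points = 16, top_conc = 20000,
                               dilution = 2, noise_sd = 0, seed = NULL) {
  stopifnot(kd > 0, protein_conc > 0, dilution > 1, n_points >= 2)
  conc <- top_conc / dilution^(0:(n_points - 1))
  fb <- fraction_bound(conc, protein_conc, kd)
  with_seed(seed, {
    resp <- f_free + (f_bound - f_free) * fb +
      if (noise_sd > 0) rnorm(n_points, 0, noise_sd) else 0
    out <- tibble::tibble(conc_nM = conc, response = resp,
                          protein_nM = protein_conc)
    attr(out, "truth") <- list(kd = kd, f_free = f_free, f_bound = f_bound)
    out
  })
}

#' Simulate a ChIP-qPCR Cq table with planted fold changes
#'
#' Builds quantification-cycle values whose delta-delta-Cq exactly recovers
#' the requested fold changes in the noiseless case: the immunoprecipitated
#' (IP) Cq at a site is shifted by `-log2(fold)` relative to the control
#' site, while input Cq values are flat. Gaussian cycle noise is added to
#' every well.
#'
#' @param true_fold_changes Named positive vector, fold change per site
#'   (relative to the control site, normalized to input).
#' @param base_cq Baseline quantification cycle.
#' @param replicates Biological replicates.
#' @param tech_reps Technical replicates per biological replicate.
#' @param noise_sd Per-well Gaussian noise, cycles.
#' @param seed Integer seed.
#' @param control_site Name of the quadruplex-free control site.
#' @param condition Condition label.
#' @return A Cq tibble (`sample`, `condition`, `site`, `bio_rep`, `tech_rep`,
#'   `cq`) with `control_site` and the truth stored as attributes.
#' @export
simulate_cq_table <- function(true_fold_changes, base_cq = 24, replicates = 2,
                              tech_reps = 2, noise_sd = 0, seed = NULL,
                              control_site = "control", condition = "treated") {
  stopifnot(all(true_fold_changes > 0), !is.null(names(true_fold_changes)))
  if (control_site %in% names(true_fold_changes)) {
    abort("control_site must not appear among true_fold_changes")
  }
  sites <- c(names(true_fold_changes), control_site)
  shift <- c(-log2(true_fold_changes), 0)
  grid <- tidyr::expand_grid(
    sample = c("IP", "input"), site = sites,
    bio_rep = seq_len(replicates), tech_rep = seq_len(tech_reps)
  )
  with_seed(seed, {
    mu <- base_cq + ifelse(grid$sample == "IP", shift[match(grid$site, sites)], 0)
    grid$cq <- mu + if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
    out <- grid |>
      dplyr::mutate(condition = condition, .after = "sample") |>
      tibble::as_tibble()
    attr(out, "control_site") <- control_site
    attr(out, "truth") <- true_fold_changes
    out
  })
}
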