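#' Build a random synthetic genome
#'
#' Generates a toy multi-chromosome genome with i.i.d. bases at a chosen G+C
#' fraction. This stands in for a real assembly at desk scale: every
#' downstream operation (scanning, interval statistics, methylation
#' aggregation) only needs chromosome names, lengths and, for scanning,
#' sequence.
#'
#' @param chrom_sizes Named numeric vector (or two-column data frame) of
#'   chromosome lengths in bp. Each chromosome must be at least 1 kb.
#' @param gc_fraction Target G+C fraction in `[0, 1]`; bases are drawn i.i.d.
#'   with `P(G) = P(C) = gc_fraction / 2`.
#' @param seed Integer seed; fixed seed gives a bit-identical genome.
#' @param sequence If `FALSE`, only names and lengths are stored (enough for
#'   interval statistics on large genomes).
#'
#' @return A `qc_genome`: a list with `sizes` (named integer vector) and
#'   `seq` (named character vector of sequences, or `NULL`).
#' @examples
#' g <- make_genome(c(chr1 = 10000, chr2 = 5000), gc_fraction = 0.4, seed = 1)
#' g
#' @export
make_genome <- function(chrom_sizes = default_chrom_sizes(), gc_fraction = 0.41,
                        seed = NULL, sequence = TRUE) {
  sizes <- genome_sizes(chrom_sizes)
  if (anyDuplicated(names(sizes))) abort("chromosome names must be unique")
  if (any(sizes < 1000)) {
    abort("chromosome sizes must be >= 1 kb (got one smaller; empty or tiny chromosomes are rejected)")
  }
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  seqs <- NULL
  if (sequence) {
    prob <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
              (1 - gc_fraction) / 2)
    seqs <- with_seed(seed, {
      vapply(sizes, function(n) {
        intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE, prob = prob)])
      }, character(1))
    })
  }
  structure(list(sizes = sizes, seq = seqs), class = "qc_genome")
}

#' Default synthetic genome scale: 5 chromosomes of 2 Mb
#' @return Named integer vector of chromosome sizes.
#' @export
default_chrom_sizes <- function() {
  setNames(rep(2e6L, 5), paste0("chr", 1:5))
}

#' @export
print.qc_genome <- function(x, ...) {
  cat("<qc_genome> ", length(x$sizes), " chromosome(s), ",
      format(sum(x$sizes), big.mark = ","), " bp total",
      if (is.null(x$seq)) " (sizes only)" else " (with sequence)", "\n", sep = "")
  invisible(x)
}

#' Chromosome sizes of a genome as a tibble
#' @param genome A `qc_genome`.
#' @return Tibble with `chrom` and `length` columns.
#' @export
chrom_sizes_tbl <- function(genome) {
  sizes <- genome_sizes(genome)
  tibble::tibble(chrom = names(sizes), length = unname(sizes))
}

#' Write a genome to FASTA / read a genome from FASTA
#'
#' @param genome A `qc_genome` carrying sequence.
#' @param path File path.
#' @return `read_genome_fasta()` returns a `qc_genome`; `write_genome_fasta()`
#'   returns `path` invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$seq)) abort("genome carries no sequence")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  structure(list(sizes = setNames(nchar(seqs), names(seqs)), seq = seqs),
            class = "qc_genome")
}

#' Genome sequence for one chromosome
#' @param genome A `qc_genome` with sequence.
#' @param chrom Chromosome name.
#' @return Character scalar.
#' @export
genome_seq <- function(genome, chrom) {
  if (is.null(genome$seq)) abort("genome carries no sequence")
  if (!chrom %in% names(genome$seq)) abort(paste0("unknown chromosome: ", chrom))
  unname(genome$seq[[chrom]])
}
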