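#' Define a genome as an ordered set of chromosomes
#'
#' A genome specification is the minimal coordinate system every stage of the
#' pipeline works against: an ordered set of uniquely named chromosomes with
#' their lengths in base pairs. Internally all coordinates are 1-based
#' inclusive (VCF-native); conversion to 0-based half-open happens only at BED
#' boundaries.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (all >= 1).
#' @return A `csmfr_genome` object: a data.frame with columns `chrom` and
#'   `length`.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_spec <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths)) {
    stop("`chroms` and `lengths` must have equal length")
  }
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths < 1)) {
    stop("chromosome lengths must be >= 1")
  }
  structure(
    data.frame(chrom = chroms, length = lengths, stringsAsFactors = FALSE),
    class = c("csmfr_genome", "data.frame")
  )
}

#' Default toy genome: three chromosomes of 10 Mb
#'
#' Small enough that brute-force oracles over all positions are feasible,
#' large enough that independently placed mutations are sparse at realistic
#' per-base densities.
#'
#' @return A `csmfr_genome`.
#' @export
default_genome <- function() {
  genome_spec(paste0("chr", 1:3), rep(1e7, 3))
}

genome_lengths <- function(genome) {
  stats::setNames(genome$length, genome$chrom)
}

#' @keywords internal
assert_genome <- function(genome) {
  if (!inherits(genome, "csmfr_genome")) {
    if (is.data.frame(genome) && all(c("chrom", "length") %in% names(genome))) {
      return(genome_spec(genome$chrom, genome$length))
    }
    stop("expected a genome built by genome_spec()")
  }
  genome
}

#' Convert a region table to GRanges
#'
#' Regions are stored as data.frames with 1-based inclusive `start`/`end`;
#' interval arithmetic is delegated to GenomicRanges.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `cls`.
#' @param genome Optional `csmfr_genome` used to set seqlengths.
#' @return A `GRanges`.
#' @export
regions_to_granges <- function(regions, genome = NULL) {
  if (nrow(regions) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = regions$chrom,
      ranges = IRanges::IRanges(start = regions$start, end = regions$end)
    )
    if (!is.null(regions$cls)) S4Vectors::mcols(gr)$cls <- regions$cls
  }
  if (!is.null(genome)) {
    genome <- assert_genome(genome)
    GenomeInfoDb::seqlevels(gr) <- genome$chrom
    GenomeInfoDb::seqlengths(gr) <- genome_lengths(genome)
  }
  gr
}

#' Convert GRanges back to the package's region table
#' @param gr A `GRanges`.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive) and any
#'   metadata columns.
#' @export
granges_to_regions <- function(gr) {
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) out <- cbind(out, mc)
  out
}

# overlap query tolerant of disjoint seqlevel sets (plain "no overlap")
overlaps_any <- function(query, subject) {
  suppressWarnings(IRanges::overlapsAny(query, subject))
}

mutations_to_granges <- function(mutations, genome = NULL) {
  regions_to_granges(
    data.frame(chrom = mutations$chrom, start = mutations$pos,
               end = mutations$pos, stringsAsFactors = FALSE),
    genome = genome
  )
}

#' Derive per-stage child seeds from one global seed
#'
#' One integer seed drives the whole pipeline. Stages draw their own seeds
#' from this deterministic stream so that any stage can be reproduced in
#' isolation: child i is the i-th draw of `sample.int(.Machine$integer.max - 1)`
#' under the parent seed.
#'
#' @param seed Integer parent seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each usable as a seed.
#' @export
child_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a toy reference sequence for a genome
#'
#' Uniform i.i.d. bases; used to exercise trinucleotide-spectrum extraction on
#' a reference whose context composition is exactly countable.
#'
#' @param genome A `csmfr_genome`.
#' @param seed Integer seed.
#' @return A `Biostrings::DNAStringSet` named by chromosome.
#' @export
simulate_genome_sequence <- function(genome, seed) {
  genome <- assert_genome(genome)
  withr::with_seed(as.integer(seed), {
    seqs <- vapply(genome$length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
  stats::setNames(Biostrings::DNAStringSet(seqs), genome$chrom)
}
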