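#' Read biallelic SNV calls from a single-sample VCF
#'
#' Parses a VCF 4.x file via vcfR, splits multi-allelic records into biallelic
#' candidates, discards non-SNV alleles, and extracts depth and alt-read
#' support from the sample's DP/AD fields (falling back to INFO/DP). Positions
#' stay 1-based.
#'
#' @param path Path to a VCF file with one sample column.
#' @param sample_id Sample identifier to attach; defaults to the VCF sample
#'   column name (or the file basename when the column is unnamed).
#' @return data.frame with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_reads`, `vaf`, `filter_flag`.
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_mutation_table(sample_id %||% basename(path)))
  }
  gt <- v@gt
  if (is.null(sample_id)) {
    sample_id <- if (ncol(gt) >= 2) colnames(gt)[2] else basename(path)
  }
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1]))
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ref <- fix$REF[i]
    if (nchar(ref) != 1) return(NULL)                # SNVs only
    counts <- suppressWarnings(as.numeric(ad_split[[i]]))
    keep <- which(nchar(alts) == 1 & alts != ref & alts %in% c("A", "C", "G", "T"))
    if (!length(keep)) return(NULL)
    depth_i <- dp[i]
    if (is.na(depth_i) && length(counts)) depth_i <- sum(counts, na.rm = TRUE)
    if (is.na(depth_i) || depth_i <= 0) {
      stop("VCF record without usable depth at ", fix$CHROM[i], ":", fix$POS[i],
           " (record ", i, ")")
    }
    data.frame(
      sample_id = sample_id,
      chrom = fix$CHROM[i],
      pos = as.numeric(fix$POS[i]),
      ref = ref,
      alt = alts[keep],
      depth = as.integer(depth_i),
      alt_reads = if (length(counts) > 1) as.integer(counts[keep + 1L])
                  else NA_integer_,
      filter_flag = fix$FILTER[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_mutation_table(sample_id))
  out$vaf <- compute_vaf(out$alt_reads, out$depth)
  rownames(out) <- NULL
  out[, c("sample_id", "chrom", "pos", "ref", "alt", "depth", "alt_reads",
          "vaf", "filter_flag")]
}

empty_mutation_table <- function(sample_id = character(0)) {
  data.frame(
    sample_id = character(0), chrom = character(0), pos = numeric(0),
    ref = character(0), alt = character(0), depth = numeric(0),
    alt_reads = numeric(0), vaf = numeric(0), filter_flag = character(0),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write one sample's mutations as a VCF 4.2 file
#'
#' Serializes calls with INFO/DP and FORMAT GT:DP:AD (AD = ref,alt with
#' ref reads = depth - alt reads), so that [read_vcf()] recovers position,
#' alleles, depth, alt count and FILTER exactly.
#'
#' @param mutations Mutation table rows for a single sample.
#' @param path Output path.
#' @param genome Optional genome for contig header lines.
#' @param sample_id Sample column name; defaults to the table's sample id.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(mutations, path, genome = NULL, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (nrow(mutations)) mutations$sample_id[1] else "SAMPLE"
  }
  if (nrow(mutations) && length(unique(mutations$sample_id)) > 1) {
    stop("write_sample_vcf() expects mutations from a single sample")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=csmfr",
    if (!is.null(genome)) {
      genome <- assert_genome(genome)
      sprintf("##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length))
    },
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  body <- character(0)
  if (nrow(mutations)) {
    m <- mutations[order(mutations$chrom, mutations$pos, mutations$alt), ]
    flt <- if (is.null(m$filter_flag)) rep("PASS", nrow(m)) else m$filter_flag
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d\tGT:DP:AD\t0/1:%d:%d,%d",
      m$chrom, as.integer(m$pos), m$ref, m$alt, flt,
      as.integer(m$depth), as.integer(m$depth),
      as.integer(m$depth - m$alt_reads), as.integer(m$alt_reads)
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED3+ file into a 1-based region table
#'
#' Import goes through rtracklayer, which performs the 0-based half-open to
#' 1-based inclusive conversion; `"chr1 99 200"` becomes the internal region
#' 100-200 (width 101). Overlapping intervals are preserved, never merged.
#'
#' @param path BED file path.
#' @return Region data.frame (`chrom`, `start`, `end`, plus `name`/`score`
#'   columns when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_regions(gr)
}

#' Write a region table as BED
#'
#' Inverse of [read_bed()]: 1-based inclusive regions are written 0-based
#' half-open, tab separated, in input order (no sorting, no merging). A `cls`
#' or `name` column becomes BED column 4.
#'
#' @param regions Region data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  if (nrow(regions) && any(regions$end < regions$start)) {
    stop("region with end < start")
  }
  name <- regions$name %||% regions$cls
  if (nrow(regions) == 0) {
    writeLines(character(0), path)
  } else if (is.null(name)) {
    writeLines(sprintf("%s\t%d\t%d", regions$chrom,
                       as.integer(regions$start - 1), as.integer(regions$end)),
               path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom,
                       as.integer(regions$start - 1), as.integer(regions$end),
                       name), path)
  }
  invisible(path)
}

#' Read a named set of BED tracks as GRanges
#' @param paths Named character vector of BED paths.
#' @param genome Optional genome for seqlengths.
#' @return Named list of `GRanges`.
#' @export
read_tracks <- function(paths, genome = NULL) {
  lapply(paths, function(p) regions_to_granges(read_bed(p), genome = genome))
}

#' Read / write the cohort metadata table
#'
#' Tab-separated with columns `sample_id`, `group` (CEN or YC) and `age`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "age")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  validate_groups(md$group)
  md
}

#' @rdname read_metadata
#' @param metadata Metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_groups <- function(groups) {
  bad <- setdiff(unique(groups), c("CEN", "YC"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  invisible(groups)
}

#' Write a mutation table as TSV
#' @param mutations Mutation data.frame.
#' @param path Output path.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutations
#' @export
read_mutations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
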