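# two-sided rank-sum p; fully tied data carry no evidence -> p = 1
wilcox_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1)
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

#' Per-sample mutation burden and group comparison
#'
#' Counts mutations per sample (zero-burden samples included via the
#' metadata), summarizes each group and compares the two burden distributions
#' with a two-sided Wilcoxon rank-sum test (exact for small untied samples,
#' tie-corrected normal approximation otherwise, as implemented by
#' [stats::wilcox.test()]).
#'
#' @param mutations Mutation table.
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @return list with `per_sample` (data.frame sample_id, group, burden),
#'   `group_means` (named numeric), `wilcoxon_p`.
#' @export
burden_summary <- function(mutations, metadata) {
  validate_groups(metadata$group)
  for (g in c("CEN", "YC")) {
    if (!any(metadata$group == g)) stop("group with 0 samples: ", g)
  }
  counts <- table(factor(mutations$sample_id, levels = metadata$sample_id))
  per_sample <- data.frame(
    sample_id = metadata$sample_id, group = metadata$group,
    burden = as.integer(counts), stringsAsFactors = FALSE
  )
  cen <- per_sample$burden[per_sample$group == "CEN"]
  yc <- per_sample$burden[per_sample$group == "YC"]
  p <- wilcox_p(cen, yc)
  list(
    per_sample = per_sample,
    group_means = c(CEN = mean(cen), YC = mean(yc)),
    wilcoxon_p = p
  )
}

#' Pearson correlation between mutation burden and age
#'
#' @param burdens Per-sample burden vector.
#' @param ages Matching ages (years), n >= 3.
#' @return list with `r`, `p` (t-distribution) and `n`.
#' @export
burden_age_correlation <- function(burdens, ages) {
  if (length(burdens) != length(ages)) stop("length mismatch")
  if (length(burdens) < 3) stop("need at least 3 samples")
  if (stats::sd(burdens) == 0 || stats::sd(ages) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(ages, burdens, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(burdens))
}

#' Per-sample deleterious-mutation ratio and group comparison
#'
#' Computes, per sample, the fraction of mutations predicted deleterious
#' (CADD PHRED > 15, FATHMM damaging, or either) and compares the two groups
#' with a Wilcoxon rank-sum test. Samples with zero mutations have no defined
#' ratio and are excluded with a warning.
#'
#' @param mutations Mutation table with annotations.
#' @param metadata Sample metadata.
#' @param predictor Passed to [is_deleterious()].
#' @return list with `per_sample` (sample_id, group, n, ratio),
#'   `group_ratios` (pooled fraction per group), `wilcoxon_p`.
#' @export
deleterious_ratio <- function(mutations, metadata, predictor = "any") {
  validate_groups(metadata$group)
  del <- is_deleterious(mutations, predictor = predictor)
  f <- factor(mutations$sample_id, levels = metadata$sample_id)
  n <- as.integer(table(f))
  ndel <- as.integer(tapply(as.integer(del), f, sum, default = 0L))
  per_sample <- data.frame(
    sample_id = metadata$sample_id, group = metadata$group,
    n = n, ratio = ifelse(n > 0, ndel / n, NA_real_),
    stringsAsFactors = FALSE
  )
  if (any(n == 0)) {
    warning(sum(n == 0), " sample(s) with zero mutations excluded from ratios")
  }
  ok <- per_sample$n > 0
  cen <- per_sample$ratio[ok & per_sample$group == "CEN"]
  yc <- per_sample$ratio[ok & per_sample$group == "YC"]
  pooled <- function(g) {
    i <- mutations$group == g
    if (!any(i)) NA_real_ else mean(del[i])
  }
  p <- if (length(cen) && length(yc)) wilcox_p(cen, yc) else NA_real_
  list(per_sample = per_sample,
       group_ratios = c(CEN = pooled("CEN"), YC = pooled("YC")),
       wilcoxon_p = p)
}

#' Fisher tests of mutation distribution across genomic partitions
#'
#' For each category of a genomic partition (compartments, ChromHMM-style
#' segments, active/inactive transcription, essential genes, regulatory
#' tracks, ...), builds the pooled per-group 2x2 table (mutations inside vs
#' outside the category, CEN vs YC) and applies a two-sided Fisher's exact
#' test. Counts are pooled across samples; a per-sample variant is available
#' via `per_sample = TRUE`, which instead compares per-sample in-category
#' proportions by Wilcoxon.
#'
#' @param mutations Mutation table with `group`.
#' @param partition Either a named list of tracks (`GRanges` or region tables;
#'   each category tested against its complement) or the name of a character
#'   column in `mutations` holding category labels.
#' @param per_sample Use the per-sample Wilcoxon variant instead of pooled
#'   Fisher tests.
#' @return data.frame with one row per category: counts in/out per group,
#'   `odds_ratio` (sample OR) and `p`.
#' @export
partition_fisher <- function(mutations, partition, per_sample = FALSE) {
  validate_groups(mutations$group)
  is_cen <- mutations$group == "CEN"
  membership <- partition_membership(mutations, partition)
  rows <- lapply(names(membership), function(cat) {
    inside <- membership[[cat]]
    if (!any(inside)) {
      warning("empty partition category skipped: ", cat)
      return(NULL)
    }
    if (per_sample) {
      sf <- factor(mutations$sample_id)
      prop <- tapply(inside, sf, mean)
      grp <- tapply(is_cen, sf, any)
      p <- suppressWarnings(stats::wilcox.test(prop[grp], prop[!grp])$p.value)
      or <- NA_real_
      a <- sum(inside & is_cen); b <- sum(!inside & is_cen)
      c2 <- sum(inside & !is_cen); d <- sum(!inside & !is_cen)
    } else {
      a <- sum(inside & is_cen); b <- sum(!inside & is_cen)
      c2 <- sum(inside & !is_cen); d <- sum(!inside & !is_cen)
      tab <- matrix(c(a, b, c2, d), nrow = 2, byrow = TRUE)
      p <- stats::fisher.test(tab)$p.value
      or <- (a * d) / (b * c2)
    }
    data.frame(category = cat, cen_in = a, cen_out = b, yc_in = c2,
               yc_out = d, odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(category = character(0), cen_in = integer(0),
                      cen_out = integer(0), yc_in = integer(0),
                      yc_out = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

partition_membership <- function(mutations, partition) {
  if (is.character(partition) && length(partition) == 1) {
    labels <- mutations[[partition]]
    if (is.null(labels)) stop("no column `", partition, "` in mutations")
    cats <- sort(unique(labels))
    stats::setNames(lapply(cats, function(x) labels == x), cats)
  } else if (is.list(partition)) {
    if (is.null(names(partition))) stop("partition tracks must be named")
    gr <- mutations_to_granges(mutations)
    lapply(partition, function(track) {
      tr <- if (inherits(track, "GRanges")) track else regions_to_granges(track)
      overlaps_any(gr, tr)
    })
  } else {
    stop("partition must be a named list of tracks or a label column name")
  }
}

canonical_96_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (up in bases) for (dn in bases) {
      out <- c(out, paste0(up, "[", s, "]", dn))
    }
  }
  out
}

#' Trinucleotide mutational spectrum (96 contexts)
#'
#' Maps each SSBS to one of the 96 pyrimidine-centric context classes
#' (C>A/C>G/C>T/T>A/T>C/T>G by 16 flanking-base combinations); mutations with
#' a purine reference are reverse-complemented first, collapsing strands.
#' The reference allele of every mutation is checked against the FASTA base.
#'
#' @param mutations Mutation table with `chrom`, `pos`, `ref`, `alt`.
#' @param reference A `Biostrings::DNAStringSet` named by chromosome, or the
#'   path to a FASTA file.
#' @return A `csmfr_spectrum` list: `counts` and `fractions` (named 96-vectors
#'   in canonical order; fractions sum to 1), `n` mutations counted.
#' @export
trinucleotide_spectrum <- function(mutations, reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  ctx_names <- canonical_96_contexts()
  counts <- stats::setNames(integer(96), ctx_names)
  if (nrow(mutations) == 0) {
    return(structure(list(counts = counts,
                          fractions = stats::setNames(rep(NA_real_, 96), ctx_names),
                          n = 0L), class = "csmfr_spectrum"))
  }
  missing_chrom <- setdiff(unique(mutations$chrom), names(reference))
  if (length(missing_chrom)) {
    stop("reference lacks chromosome(s): ", paste(missing_chrom, collapse = ", "))
  }
  lens <- stats::setNames(Biostrings::width(reference), names(reference))
  edge <- mutations$pos < 2 | mutations$pos > lens[mutations$chrom] - 1
  if (any(edge)) {
    warning(sum(edge), " mutation(s) at chromosome edges lack a trinucleotide",
            " context and were skipped")
    mutations <- mutations[!edge, , drop = FALSE]
  }
  ctx <- character(nrow(mutations))
  for (ch in unique(mutations$chrom)) {
    i <- which(mutations$chrom == ch)
    v <- Biostrings::extractAt(
      reference[[ch]],
      IRanges::IRanges(start = mutations$pos[i] - 1, width = 3))
    ctx[i] <- as.character(v)
  }
  center <- substr(ctx, 2, 2)
  bad <- center != mutations$ref
  if (any(bad)) {
    ex <- utils::head(paste0(mutations$chrom[bad], ":", mutations$pos[bad],
                             " ref=", mutations$ref[bad], " fasta=", center[bad]), 5)
    stop("reference allele mismatch with FASTA at ", sum(bad), " site(s): ",
         paste(ex, collapse = "; "))
  }
  # collapse purine-reference mutations onto the pyrimidine strand
  purine <- mutations$ref %in% c("A", "G")
  rc <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  }
  ctx[purine] <- rc(ctx[purine])
  ref <- mutations$ref
  alt <- mutations$alt
  ref[purine] <- rc(ref[purine])
  alt[purine] <- rc(alt[purine])
  cls <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  tab <- table(factor(cls, levels = ctx_names))
  counts <- stats::setNames(as.integer(tab), ctx_names)
  structure(list(counts = counts, fractions = counts / sum(counts),
                 n = sum(counts)), class = "csmfr_spectrum")
}

#' @export
print.csmfr_spectrum <- function(x, ...) {
  cat("96-context mutational spectrum over", x$n, "SSBS\n")
  top <- sort(x$fractions, decreasing = TRUE)[1:5]
  cat("top contexts:",
      paste(sprintf("%s %.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
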