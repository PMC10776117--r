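#' Variant allele frequency of a call
#'
#' Defined as the ratio of reads supporting the mutant allele to all mapped
#' reads at the site.
#'
#' @param alt_reads Reads supporting the alternative allele.
#' @param depth Total read depth (> 0).
#' @return `alt_reads / depth`, vectorized.
#' @examples
#' compute_vaf(5, 20) # 0.25
#' @export
compute_vaf <- function(alt_reads, depth) {
  if (any(depth == 0, na.rm = TRUE)) stop("depth must be > 0")
  if (any(alt_reads < 0 | alt_reads > depth, na.rm = TRUE)) {
    stop("alt_reads must lie in [0, depth]")
  }
  alt_reads / depth
}

#' Filter thresholds for the eight-criterion SSBS filter
#'
#' Defaults follow the blood-SSBS filtering scheme the pipeline implements:
#' PASS flag, autosomes + X, no segmental-duplication overlap, VAF below 0.5,
#' depth in \[20, 120\], at least 3 alt reads, population (gnomAD popmax)
#' allele frequency below 1%, and a site observed in at most one cohort
#' individual. Depth bounds are inclusive ("not less than / not more than");
#' VAF and population-frequency bounds are strict ("less than").
#'
#' @param min_depth,max_depth Inclusive depth bounds.
#' @param min_alt_reads Minimum alt-supporting reads (inclusive).
#' @param max_vaf Exclusive VAF upper bound.
#' @param max_popmax_af Exclusive population-AF upper bound.
#' @param max_cohort_occurrence Maximum number of cohort individuals carrying
#'   the site (1 = private mutations only).
#' @param allowed_chroms Chromosomes retained; default autosomes + X in both
#'   `chr`-prefixed and bare naming, plus the toy-genome chromosomes.
#' @param superdups Segmental-duplication track (`GRanges` or region
#'   data.frame), or `NULL` to skip criterion 3.
#' @return A `csmfr_filterconfig` list.
#' @export
filter_config <- function(min_depth = 20, max_depth = 120, min_alt_reads = 3,
                          max_vaf = 0.5, max_popmax_af = 0.01,
                          max_cohort_occurrence = 1,
                          allowed_chroms = NULL, superdups = NULL) {
  if (min_depth > max_depth) stop("min_depth must be <= max_depth")
  if (any(c(min_depth, min_alt_reads, max_vaf, max_popmax_af,
            max_cohort_occurrence) < 0)) {
    stop("thresholds must be nonnegative")
  }
  if (is.null(allowed_chroms)) {
    allowed_chroms <- c(paste0("chr", c(1:22, "X")), c(1:22, "X"))
  }
  if (!is.null(superdups) && !inherits(superdups, "GRanges")) {
    superdups <- regions_to_granges(superdups)
  }
  structure(
    list(min_depth = min_depth, max_depth = max_depth,
         min_alt_reads = min_alt_reads, max_vaf = max_vaf,
         max_popmax_af = max_popmax_af,
         max_cohort_occurrence = max_cohort_occurrence,
         allowed_chroms = allowed_chroms, superdups = superdups),
    class = "csmfr_filterconfig"
  )
}

#' Dual-caller consensus: keep calls confirmed by a second caller
#'
#' Calls are keyed by (sample, chrom, pos, ref, alt); a call from the primary
#' caller is retained iff the confirming caller reports the same key. Depth,
#' allele counts and all other fields come from the primary set.
#'
#' @param primary_calls,confirm_calls Mutation tables.
#' @return The subset of `primary_calls` present in both sets.
#' @export
intersect_callsets <- function(primary_calls, confirm_calls) {
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  out <- primary_calls[key(primary_calls) %in% key(confirm_calls), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count how many cohort individuals carry each site
#'
#' Sets `cohort_site_count` to the number of distinct individuals carrying the
#' identical (chrom, pos, ref, alt) site; recurrent sites are later removed by
#' filter criterion 8 ("observed less than twice in the cohort").
#'
#' @param mutations Full-cohort mutation table.
#' @return `mutations` with `cohort_site_count` filled in.
#' @export
count_cohort_occurrence <- function(mutations) {
  if (nrow(mutations) == 0) {
    mutations$cohort_site_count <- integer(0)
    return(mutations)
  }
  site <- paste(mutations$chrom, mutations$pos, mutations$ref, mutations$alt,
                sep = "\r")
  carriers <- tapply(mutations$sample_id, site,
                     function(s) length(unique(s)))
  mutations$cohort_site_count <- as.integer(carriers[site])
  mutations
}

filter_criteria_names <- c(
  "1_filter_flag", "2_chromosome", "3_superdups", "4_vaf",
  "5_depth", "6_alt_reads", "7_population_af", "8_cohort_recurrence"
)

#' Apply the eight-criterion somatic SSBS filter
#'
#' A mutation is retained iff all criteria hold, in this order: (1) FILTER is
#' PASS; (2) chromosome in the allowed set (autosomes + X); (3) position not
#' covered by the segmental-duplication track; (4) VAF < 0.5; (5) depth in
#' \[20, 120\]; (6) >= 3 alt-supporting reads; (7) population allele frequency
#' < 1% (missing annotation counts as absent, AF 0); (8) site carried by at
#' most one cohort individual. Each rejected mutation is attributed to the
#' first criterion it fails, so rejection counts are reproducible bookkeeping
#' while the retained set itself is order-independent. Filtering is
#' idempotent.
#'
#' @param mutations Mutation table; `cohort_site_count` is computed on the fly
#'   (via [count_cohort_occurrence()]) when absent.
#' @param config A `csmfr_filterconfig`.
#' @return A `csmfr_filter_result` list: `retained` (mutation table),
#'   `rejections` (named integer vector, one count per criterion), `n_input`.
#' @export
apply_filters <- function(mutations, config = filter_config()) {
  if (!inherits(config, "csmfr_filterconfig")) {
    stop("`config` must come from filter_config()")
  }
  if (is.null(mutations$cohort_site_count) ||
      anyNA(mutations$cohort_site_count)) {
    mutations <- count_cohort_occurrence(mutations)
  }
  n <- nrow(mutations)
  if (n == 0) {
    return(structure(list(
      retained = mutations,
      rejections = stats::setNames(integer(8), filter_criteria_names),
      n_input = 0L
    ), class = "csmfr_filter_result"))
  }

  unknown <- setdiff(
    unique(mutations$chrom),
    c(config$allowed_chroms, "chrY", "Y", "chrM", "MT", "M")
  )
  if (length(unknown)) {
    warning("unknown chromosome name(s) rejected under criterion 2: ",
            paste(unknown, collapse = ", "))
  }

  in_superdups <- if (is.null(config$superdups)) rep(FALSE, n) else
    overlaps_any(mutations_to_granges(mutations), config$superdups)
  popmax <- mutations$popmax_af %||% rep(0, n)
  popmax[is.na(popmax)] <- 0
  vaf <- mutations$vaf %||% compute_vaf(mutations$alt_reads, mutations$depth)

  fails <- cbind(
    mutations$filter_flag != "PASS",
    !(mutations$chrom %in% config$allowed_chroms),
    in_superdups,
    !(vaf < config$max_vaf),
    !(mutations$depth >= config$min_depth & mutations$depth <= config$max_depth),
    !(mutations$alt_reads >= config$min_alt_reads),
    !(popmax < config$max_popmax_af),
    !(mutations$cohort_site_count <= config$max_cohort_occurrence)
  )
  first_fail <- apply(fails, 1, function(f) if (any(f)) which(f)[1] else 0L)
  rejections <- stats::setNames(
    tabulate(first_fail[first_fail > 0], nbins = 8), filter_criteria_names)
  retained <- mutations[first_fail == 0L, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(retained = retained, rejections = rejections,
                 n_input = n), class = "csmfr_filter_result")
}

#' @export
print.csmfr_filter_result <- function(x, ...) {
  cat("SSBS filter:", x$n_input, "calls in,", nrow(x$retained), "retained\n")
  cat("rejections by first failed criterion:\n")
  print(x$rejections)
  invisible(x)
}
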