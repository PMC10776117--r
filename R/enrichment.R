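#' Sample width-matched random regions
#'
#' One random region per template: the width multiset of the templates is
#' preserved exactly, and each region is placed uniformly over all valid
#' start positions genome-wide (chromosome chosen proportional to its number
#' of valid starts, i.e. length - width + 1). Sampled regions may overlap one
#' another.
#'
#' @param genome A `csmfr_genome`.
#' @param template_regions Region table whose widths are matched.
#' @param seed Integer seed.
#' @param chrom_mode `"length"` (default): chromosome proportional to valid
#'   starts; `"template"`: keep each template's own chromosome.
#' @return Region data.frame with a `width` column.
#' @export
sample_random_regions <- function(genome, template_regions, seed,
                                  chrom_mode = c("length", "template")) {
  genome <- assert_genome(genome)
  chrom_mode <- match.arg(chrom_mode)
  widths <- template_regions$end - template_regions$start + 1
  if (length(widths) && max(widths) > max(genome$length)) {
    stop("template wider than every chromosome")
  }
  withr::with_seed(as.integer(seed), {
    out <- sample_regions_raw(genome, widths,
                              chrom = if (chrom_mode == "template")
                                template_regions$chrom else NULL)
  })
  out
}

# vectorized placement core, runs under the caller's RNG state
sample_regions_raw <- function(genome, widths, chrom = NULL) {
  n <- length(widths)
  if (n == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), width = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(chrom)) {
    ci <- integer(n)
    for (w in unique(widths)) {
      i <- widths == w
      ci[i] <- sample_chrom_idx(genome, sum(i), w)
    }
    chrom <- genome$chrom[ci]
  } else {
    ci <- match(chrom, genome$chrom)
    if (anyNA(ci)) stop("template chromosome not in genome")
    if (any(genome$length[ci] < widths)) {
      stop("template wider than its own chromosome")
    }
  }
  valid <- genome$length[ci] - widths + 1
  start <- floor(stats::runif(n) * valid) + 1
  data.frame(chrom = chrom, start = start, end = start + widths - 1,
             width = widths, stringsAsFactors = FALSE)
}

#' Number of regions overlapping an annotation track
#'
#' Counts regions with at least one base of overlap with at least one track
#' interval ("located in" the track).
#'
#' @param regions Region table or `GRanges`.
#' @param track `GRanges` (or region table) of track intervals.
#' @return Integer count.
#' @export
count_overlapping_regions <- function(regions, track) {
  gr <- if (inherits(regions, "GRanges")) regions else regions_to_granges(regions)
  tr <- if (inherits(track, "GRanges")) track else regions_to_granges(track)
  sum(overlaps_any(gr, tr))
}

#' Randomized-region permutation test
#'
#' Compares an observed region-level statistic against its distribution over
#' width- and count-matched random region sets. The default statistic is the
#' number of regions located in `track`; any function of a region table may be
#' supplied instead (e.g. DSMs covered, via [dsm_coverage()]). The empirical p
#' uses add-one smoothing: `(1 + #{null >= observed}) / (n_reps + 1)` for
#' `tail = "greater"` (mirrored for `"less"`), so p is never exactly zero.
#'
#' @param observed_regions Region table whose statistic is tested.
#' @param track Track (`GRanges`) for the default overlap-count statistic;
#'   ignored when `stat_fn` is given.
#' @param genome A `csmfr_genome` for null placement.
#' @param n_reps Number of random replicates (default 1000).
#' @param tail `"greater"` (enrichment) or `"less"` (depletion).
#' @param seed Integer seed.
#' @param stat_fn Optional function(region table) -> single number.
#' @return A `csmfr_perm` list: `observed`, `null_values`, `n_reps`,
#'   `empirical_p`, `tail`, `seed`.
#' @export
permutation_test <- function(observed_regions, track = NULL, genome,
                             n_reps = 1000, tail = c("greater", "less"),
                             seed = 1L, stat_fn = NULL) {
  tail <- match.arg(tail)
  genome <- assert_genome(genome)
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(stat_fn) && is.null(track)) {
    stop("either a track or a stat_fn is required")
  }
  widths <- observed_regions$end - observed_regions$start + 1
  if (length(widths) == 0) stop("observed region set is empty")
  if (max(widths) > max(genome$length)) {
    stop("template wider than every chromosome")
  }

  if (is.null(stat_fn)) {
    tr <- if (inherits(track, "GRanges")) track else regions_to_granges(track)
    observed <- count_overlapping_regions(observed_regions, tr)
    null_values <- withr::with_seed(as.integer(seed), {
      # batch all replicates into one overlap query
      all_regions <- sample_regions_raw(genome, rep(widths, n_reps))
      hit <- overlaps_any(regions_to_granges(all_regions), tr)
      as.integer(rowsum(as.integer(hit),
                        rep(seq_len(n_reps), each = length(widths))))
    })
  } else {
    observed <- stat_fn(observed_regions)
    null_values <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_reps), function(i) {
        stat_fn(sample_regions_raw(genome, widths))
      }, numeric(1))
    })
  }
  k <- if (tail == "greater") sum(null_values >= observed) else
    sum(null_values <= observed)
  structure(list(
    observed = observed, null_values = null_values, n_reps = n_reps,
    empirical_p = (1 + k) / (n_reps + 1), tail = tail, seed = as.integer(seed)
  ), class = "csmfr_perm")
}

#' @export
print.csmfr_perm <- function(x, ...) {
  cat(sprintf(
    "permutation test (%d reps, tail=%s): observed %.4g, null mean %.4g, p = %.4g\n",
    x$n_reps, x$tail, x$observed, mean(x$null_values), x$empirical_p))
  invisible(x)
}

#' Fisher's exact test comparing track overlap between region classes
#'
#' Tests whether CSM-FRs are located in a track preferentially compared to
#' CSM-CRs, via a two-sided exact test on the 2x2 table of in/out counts per
#' class. The reported odds ratio is the sample (cross-product) odds ratio.
#'
#' @param n_fr_in,n_fr_total CSM-FRs in the track / total.
#' @param n_cr_in,n_cr_total CSM-CRs in the track / total.
#' @return list with `odds_ratio`, `p`, and the underlying `table`.
#' @export
fisher_region_class_comparison <- function(n_fr_in, n_fr_total,
                                           n_cr_in, n_cr_total) {
  if (n_fr_total == 0 || n_cr_total == 0) stop("zero-total region class")
  if (n_fr_in > n_fr_total || n_cr_in > n_cr_total ||
      any(c(n_fr_in, n_cr_in) < 0)) {
    stop("counts must satisfy 0 <= in <= total")
  }
  tab <- matrix(c(n_fr_in, n_fr_total - n_fr_in,
                  n_cr_in, n_cr_total - n_cr_in),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("CSM_FR", "CSM_CR"), c("in", "out")))
  p <- stats::fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = p, table = tab)
}

#' Disease-susceptibility-mutation coverage of a region set
#'
#' @param regions Region table or `GRanges`.
#' @param dsm_positions data.frame with `chrom` and `pos` (1-based points).
#' @return list with `n_dsms_covered` (DSMs inside any region) and
#'   `n_regions_with_dsm` (regions containing at least one DSM).
#' @export
dsm_coverage <- function(regions, dsm_positions) {
  gr <- if (inherits(regions, "GRanges")) regions else regions_to_granges(regions)
  if (nrow(dsm_positions) == 0 || length(gr) == 0) {
    return(list(n_dsms_covered = 0L, n_regions_with_dsm = 0L))
  }
  pts <- regions_to_granges(data.frame(
    chrom = dsm_positions$chrom, start = dsm_positions$pos,
    end = dsm_positions$pos, stringsAsFactors = FALSE))
  list(
    n_dsms_covered = sum(overlaps_any(pts, gr)),
    n_regions_with_dsm = sum(overlaps_any(gr, pts))
  )
}

#' Flag deleterious mutations
#'
#' A mutation is deleterious when its CADD PHRED score exceeds 15 or its
#' FATHMM-MKL class is damaging; the two predictors are also available
#' separately.
#'
#' @param mutations Mutation table with `cadd_phred` and/or `fathmm_class`.
#' @param predictor `"any"` (default), `"cadd"` or `"fathmm"`.
#' @param cadd_cutoff PHRED cutoff (default 15, strict `>`).
#' @return Logical vector.
#' @export
is_deleterious <- function(mutations, predictor = c("any", "cadd", "fathmm"),
                           cadd_cutoff = 15) {
  predictor <- match.arg(predictor)
  cadd <- if (is.null(mutations$cadd_phred)) rep(NA_real_, nrow(mutations)) else
    mutations$cadd_phred
  fathmm <- if (is.null(mutations$fathmm_class))
    rep(NA_character_, nrow(mutations)) else mutations$fathmm_class
  by_cadd <- !is.na(cadd) & cadd > cadd_cutoff
  by_fathmm <- !is.na(fathmm) & fathmm == "damaging"
  switch(predictor, any = by_cadd | by_fathmm, cadd = by_cadd,
         fathmm = by_fathmm)
}

#' Are deleterious YC mutations over-represented inside CSM-FRs?
#'
#' The observed statistic is the number of deleterious YC mutations located in
#' CSM-FRs. Each null replicate counts the deleterious mutations among a
#' uniform random sample (without replacement) of all YC mutations, of size
#' equal to the number of YC mutations inside CSM-FRs; that count is exactly
#' hypergeometric, and replicates are drawn accordingly.
#'
#' @param yc_mutations YC mutation table with deleteriousness annotations.
#' @param csm_frs CSM-FR region table.
#' @param n_reps Replicates (default 1000).
#' @param seed Integer seed.
#' @param predictor Passed to [is_deleterious()].
#' @return A `csmfr_perm`.
#' @export
deleterious_mutation_enrichment <- function(yc_mutations, csm_frs,
                                            n_reps = 1000, seed = 1L,
                                            predictor = "any") {
  del <- is_deleterious(yc_mutations, predictor = predictor)
  in_fr <- if (nrow(csm_frs) == 0) rep(FALSE, nrow(yc_mutations)) else
    overlaps_any(mutations_to_granges(yc_mutations),
                         regions_to_granges(csm_frs))
  k <- sum(in_fr)
  if (k > nrow(yc_mutations)) stop("fewer YC mutations than sample size")
  observed <- sum(del & in_fr)
  null_values <- withr::with_seed(as.integer(seed), {
    stats::rhyper(n_reps, m = sum(del), n = sum(!del), k = k)
  })
  kk <- sum(null_values >= observed)
  structure(list(
    observed = observed, null_values = null_values, n_reps = n_reps,
    empirical_p = (1 + kk) / (n_reps + 1), tail = "greater",
    seed = as.integer(seed)
  ), class = "csmfr_perm")
}
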