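#' Recall of a reference region set in a re-detected set
#'
#' A reference region counts as recovered when a test region overlaps it by at
#' least one base (or, optionally, by at least `min_overlap_frac` of the
#' reference width). Recall is the recovered fraction.
#'
#' @param reference_regions Non-empty region table (1-based inclusive).
#' @param test_regions Region table to search (may be empty).
#' @param min_overlap_frac Minimum overlap as a fraction of reference width;
#'   default 0 means any >= 1 bp overlap.
#' @return A `csmfr_recall` list: `recall`, `hits` (logical per reference
#'   region), `n_reference`.
#' @export
region_recall <- function(reference_regions, test_regions,
                          min_overlap_frac = 0) {
  if (nrow(reference_regions) == 0) stop("reference region set is empty")
  ref <- regions_to_granges(reference_regions)
  if (nrow(test_regions) == 0) {
    hits <- rep(FALSE, length(ref))
  } else {
    test <- regions_to_granges(test_regions)
    if (min_overlap_frac <= 0) {
      hits <- overlaps_any(ref, test)
    } else {
      ov <- suppressWarnings(GenomicRanges::findOverlaps(ref, test))
      inter <- GenomicRanges::pintersect(ref[S4Vectors::queryHits(ov)],
                                         test[S4Vectors::subjectHits(ov)])
      frac <- GenomicRanges::width(inter) /
        GenomicRanges::width(ref[S4Vectors::queryHits(ov)])
      good <- unique(S4Vectors::queryHits(ov)[frac >= min_overlap_frac])
      hits <- seq_along(ref) %in% good
    }
  }
  structure(list(recall = mean(hits), hits = hits,
                 n_reference = length(ref)),
            class = "csmfr_recall")
}

#' Distance-threshold sensitivity of CSM-FR detection
#'
#' Re-runs region detection at alternative gap thresholds and reports, for
#' each, the recall of the CSM-FRs found at the reference threshold.
#'
#' @param mutations Filtered cohort mutation table with `group` labels.
#' @param thresholds Gap thresholds (bp) to test; default 3, 4, 6, 8 and
#'   10 kb.
#' @param reference_gap Reference threshold (default 5000).
#' @param min_size Minimum cluster size.
#' @return data.frame with `threshold`, `n_fr` (CSM-FRs found at that
#'   threshold) and `recall` of the reference CSM-FRs.
#' @export
threshold_sensitivity <- function(mutations,
                                  thresholds = c(3000, 4000, 6000, 8000, 10000),
                                  reference_gap = 5000, min_size = 3) {
  ref <- detect_regions(mutations, gap_bp = reference_gap, min_size = min_size)
  if (nrow(ref$fr_regions) == 0) {
    stop("no CSM-FRs at the reference threshold; recall undefined")
  }
  rows <- lapply(thresholds, function(g) {
    det <- detect_regions(mutations, gap_bp = g, min_size = min_size)
    data.frame(
      threshold = g, n_fr = nrow(det$fr_regions),
      recall = region_recall(ref$fr_regions, det$fr_regions)$recall
    )
  })
  do.call(rbind, rows)
}

#' Leave-one-out recall of CSM-FRs
#'
#' For every sample, its mutations are removed, CSM-FRs re-detected, and the
#' recall of the full-cohort CSM-FRs computed; the mean over samples measures
#' how much detection depends on any single individual.
#'
#' @param mutations Filtered cohort mutation table.
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @param gap_bp,min_size Clustering parameters.
#' @return list with `per_sample` (named recall vector) and `mean_recall`.
#' @export
leave_one_out_recall <- function(mutations, metadata, gap_bp = 5000,
                                 min_size = 3) {
  if (nrow(metadata) < 2) stop("leave-one-out needs at least 2 samples")
  ref <- detect_regions(mutations, gap_bp = gap_bp, min_size = min_size)
  if (nrow(ref$fr_regions) == 0) {
    stop("no CSM-FRs in the full cohort; recall undefined")
  }
  rec <- vapply(metadata$sample_id, function(sid) {
    det <- detect_regions(mutations[mutations$sample_id != sid, , drop = FALSE],
                          gap_bp = gap_bp, min_size = min_size)
    region_recall(ref$fr_regions, det$fr_regions)$recall
  }, numeric(1))
  list(per_sample = rec, mean_recall = mean(rec))
}

#' Persistence of CSM-FRs after excluding flagged samples
#'
#' Removes all mutations of the excluded samples (e.g. putative clonal
#' hematopoiesis carriers, identified upstream from a curated variant list),
#' re-detects CSM-FRs and reports the fraction of the original CSM-FRs that
#' persist.
#'
#' @param mutations Filtered cohort mutation table.
#' @param metadata Sample metadata.
#' @param excluded_sample_ids Sample ids to drop (must be a subset of the
#'   cohort; excluding an entire group is an error).
#' @param gap_bp,min_size Clustering parameters.
#' @return Persistence fraction in \[0, 1\].
#' @export
exclusion_persistence <- function(mutations, metadata, excluded_sample_ids,
                                  gap_bp = 5000, min_size = 3) {
  if (!all(excluded_sample_ids %in% metadata$sample_id)) {
    stop("excluded ids must be cohort sample ids")
  }
  for (g in unique(metadata$group)) {
    ids <- metadata$sample_id[metadata$group == g]
    if (length(ids) && all(ids %in% excluded_sample_ids)) {
      stop("cannot exclude every sample of group ", g)
    }
  }
  ref <- detect_regions(mutations, gap_bp = gap_bp, min_size = min_size)
  if (nrow(ref$fr_regions) == 0) {
    stop("no CSM-FRs in the full cohort; persistence undefined")
  }
  if (length(excluded_sample_ids) == 0) return(1.0)
  kept <- mutations[!(mutations$sample_id %in% excluded_sample_ids), ,
                    drop = FALSE]
  det <- detect_regions(kept, gap_bp = gap_bp, min_size = min_size)
  region_recall(ref$fr_regions, det$fr_regions)$recall
}
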