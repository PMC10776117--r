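#' Cluster mutations by genomic distance
#'
#' A mutation cluster is three or more calls on the same chromosome whose
#' mutual distances are closer than the gap threshold, implemented as
#' consecutive-gap single linkage: positions are sorted per chromosome and
#' adjacent calls chain together whenever their gap is strictly below
#' `gap_bp`. Maximal chains with at least `min_size` members are returned;
#' every call belongs to at most one cluster. Calls from different samples at
#' the same or nearby positions each count as one member.
#'
#' @param mutations Mutation table with `chrom` and `pos` (and optionally
#'   `group` for later classification).
#' @param gap_bp Strict upper bound on adjacent gaps (default 5000, i.e.
#'   "closer than 5 kb").
#' @param min_size Minimum members per cluster (default 3).
#' @return A `csmfr_clustering` list: `members` (input rows, position-sorted,
#'   with `cluster_id`, NA when unclustered) and `clusters` (one row per
#'   cluster: `cluster_id`, `chrom`, `start`, `end`, `n_members`).
#' @export
cluster_mutations <- function(mutations, gap_bp = 5000, min_size = 3) {
  if (gap_bp <= 0) stop("gap_bp must be positive")
  if (min_size < 1) stop("min_size must be >= 1")
  m <- mutations[order(mutations$chrom, mutations$pos), , drop = FALSE]
  rownames(m) <- NULL
  n <- nrow(m)
  if (n == 0) {
    m$cluster_id <- integer(0)
    return(structure(list(members = m, clusters = empty_cluster_table()),
                     class = "csmfr_clustering"))
  }
  new_chain <- c(TRUE, diff(m$pos) >= gap_bp | m$chrom[-1] != m$chrom[-n])
  chain <- cumsum(new_chain)
  sizes <- tabulate(chain)
  keep <- sizes[chain] >= min_size
  # renumber surviving chains 1..k in genomic order
  ids <- match(chain, sort(unique(chain[keep])))
  ids[!keep] <- NA_integer_
  m$cluster_id <- ids
  cl <- if (any(keep)) {
    idx <- split(which(keep), ids[keep])
    data.frame(
      cluster_id = as.integer(names(idx)),
      chrom = vapply(idx, function(i) m$chrom[i[1]], character(1)),
      start = vapply(idx, function(i) min(m$pos[i]), numeric(1)),
      end = vapply(idx, function(i) max(m$pos[i]), numeric(1)),
      n_members = lengths(idx),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else empty_cluster_table()
  structure(list(members = m, clusters = cl), class = "csmfr_clustering")
}

empty_cluster_table <- function() {
  data.frame(cluster_id = integer(0), chrom = character(0), start = numeric(0),
             end = numeric(0), n_members = integer(0), stringsAsFactors = FALSE)
}

#' Classify clusters by group composition
#'
#' Clusters containing mutations merely from younger controls are CSM-FRs
#' (the region is variable in YCs but mutation-free in centenarians); clusters
#' containing only centenarian mutations are CSM-CRs; clusters with both
#' groups are kept as MIXED rather than discarded.
#'
#' @param clustering A `csmfr_clustering` whose members carry `group` labels
#'   (CEN or YC).
#' @return The clustering with `clusters` gaining `n_cen`, `n_yc` and `cls`
#'   (`CSM_FR` / `CSM_CR` / `MIXED`) columns.
#' @export
classify_clusters <- function(clustering) {
  m <- clustering$members
  cl <- clustering$clusters
  if (is.null(m$group)) stop("members must carry a `group` column")
  validate_groups(m$group)
  in_cl <- !is.na(m$cluster_id)
  n_cen <- integer(nrow(cl)); n_yc <- integer(nrow(cl))
  if (any(in_cl)) {
    tab <- table(factor(m$cluster_id[in_cl], levels = cl$cluster_id),
                 factor(m$group[in_cl], levels = c("CEN", "YC")))
    n_cen <- as.integer(tab[, "CEN"])
    n_yc <- as.integer(tab[, "YC"])
  }
  cl$n_cen <- n_cen
  cl$n_yc <- n_yc
  cl$cls <- ifelse(n_cen == 0, "CSM_FR", ifelse(n_yc == 0, "CSM_CR", "MIXED"))
  clustering$clusters <- cl
  clustering
}

#' Convert a cluster to its genomic region
#'
#' The region spans the member positions (min to max), optionally padded and
#' clipped to chromosome bounds; width = end - start + 1.
#'
#' @param clusters Cluster table rows (with `chrom`, `start`, `end`, and
#'   optionally `cls`).
#' @param padding_bp Symmetric padding in bp (default 0).
#' @param genome Optional genome used to clip the padded ends.
#' @return Region data.frame with a `width` column.
#' @export
cluster_to_region <- function(clusters, padding_bp = 0, genome = NULL) {
  out <- data.frame(
    chrom = clusters$chrom,
    start = pmax(1, clusters$start - padding_bp),
    end = clusters$end + padding_bp,
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    genome <- assert_genome(genome)
    out$end <- pmin(out$end, genome_lengths(genome)[out$chrom])
  }
  out$width <- out$end - out$start + 1
  for (col in intersect(c("cls", "n_members", "n_cen", "n_yc"), names(clusters))) {
    out[[col]] <- clusters[[col]]
  }
  rownames(out) <- NULL
  out
}

#' Detect and classify group-exclusive mutation cluster regions
#'
#' Composition of [cluster_mutations()], [classify_clusters()] and
#' [cluster_to_region()]: the full CSM-FR / CSM-CR detection step.
#'
#' @inheritParams cluster_mutations
#' @param padding_bp Padding applied when converting clusters to regions.
#' @param genome Optional genome for clipping.
#' @return A `csmfr_regions` list: `fr_regions`, `cr_regions`, `mixed_regions`
#'   (region tables), `clusters` (all classified clusters), and `stats` with
#'   `n_clusters`, `n_fr`, `n_cr`, `n_mixed`, `mean_width_fr`, `mean_width_cr`
#'   and `frac_above_min` (fraction of clusters with more than `min_size`
#'   members).
#' @export
detect_regions <- function(mutations, gap_bp = 5000, min_size = 3,
                           padding_bp = 0, genome = NULL) {
  clustering <- classify_clusters(cluster_mutations(mutations, gap_bp, min_size))
  cl <- clustering$clusters
  regions <- cluster_to_region(cl, padding_bp = padding_bp, genome = genome)
  fr <- regions[regions$cls == "CSM_FR", , drop = FALSE]
  cr <- regions[regions$cls == "CSM_CR", , drop = FALSE]
  mixed <- regions[regions$cls == "MIXED", , drop = FALSE]
  rownames(fr) <- rownames(cr) <- rownames(mixed) <- NULL
  structure(list(
    fr_regions = fr, cr_regions = cr, mixed_regions = mixed,
    clusters = cl, clustering = clustering,
    stats = list(
      n_clusters = nrow(cl), n_fr = nrow(fr), n_cr = nrow(cr),
      n_mixed = nrow(mixed),
      mean_width_fr = if (nrow(fr)) mean(fr$width) else NA_real_,
      mean_width_cr = if (nrow(cr)) mean(cr$width) else NA_real_,
      frac_above_min = if (nrow(cl)) mean(cl$n_members > min_size) else NA_real_
    )
  ), class = "csmfr_regions")
}

#' @export
print.csmfr_regions <- function(x, ...) {
  s <- x$stats
  cat("mutation cluster regions:", s$n_clusters, "clusters ->",
      s$n_fr, "CSM-FR,", s$n_cr, "CSM-CR,", s$n_mixed, "mixed\n")
  if (!is.na(s$mean_width_fr)) {
    cat(sprintf("mean CSM-FR width: %.0f bp\n", s$mean_width_fr))
  }
  invisible(x)
}
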