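#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage parameter. Input is either a cohort directory written
#' by [write_cohort()] (`input_dir`) or an in-memory `csmfr_cohort`
#' (`cohort`). The config is validated up front and a YAML copy is written
#' into the output directory for provenance.
#'
#' @param out_dir Output directory.
#' @param input_dir Cohort directory (ignored when `cohort` is given).
#' @param cohort Optional in-memory `csmfr_cohort`.
#' @param filter A `csmfr_filterconfig`.
#' @param gap_bp,min_size Clustering parameters.
#' @param n_reps Permutation replicates.
#' @param seed Global seed; stages use [child_seeds()] of it.
#' @param excluded_sample_ids Samples for the exclusion-persistence check
#'   (e.g. clonal-hematopoiesis carriers); empty to skip.
#' @return A `csmfr_pipeconfig` list.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, cohort = NULL,
                            filter = filter_config(), gap_bp = 5000,
                            min_size = 3, n_reps = 1000, seed = 1L,
                            excluded_sample_ids = character(0)) {
  if (is.null(cohort)) {
    if (is.null(input_dir)) stop("either `input_dir` or `cohort` is required")
    if (!dir.exists(input_dir)) stop("missing input path: ", input_dir)
  }
  structure(list(out_dir = out_dir, input_dir = input_dir, cohort = cohort,
                 filter = filter, gap_bp = gap_bp, min_size = min_size,
                 n_reps = n_reps, seed = as.integer(seed),
                 excluded_sample_ids = excluded_sample_ids),
            class = "csmfr_pipeconfig")
}

pipe_log <- function(quiet, ...) if (!quiet) message("[csmfr] ", ...)

#' Run the full analysis pipeline
#'
#' Stages, in order: variant filtering (eight criteria), cluster detection and
#' CSM-FR/CSM-CR classification, enrichment tests against every cohort track,
#' cohort statistics (burden, deleterious ratios, partition Fisher tests), and
#' robustness checks (threshold sensitivity, leave-one-out recall, optional
#' sample-exclusion persistence). Each stage logs its counts; outputs are
#' written as TSV/BED under `config$out_dir` together with a YAML provenance
#' copy of the configuration. Fully deterministic given the seed.
#'
#' @param config A `csmfr_pipeconfig`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every stage's result objects.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "csmfr_pipeconfig")) {
    stop("`config` must come from pipeline_config()")
  }
  cohort <- config$cohort %||% read_cohort(config$input_dir)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out)
  prov <- config[setdiff(names(config), c("cohort", "filter"))]
  prov$filter <- config$filter[setdiff(names(config$filter), "superdups")]
  yaml::write_yaml(prov, file.path(out, "pipeline_config.yaml"))
  seeds <- child_seeds(config$seed, 4)

  # stage 1: filtering
  flt <- apply_filters(cohort$mutations, config$filter)
  pipe_log(quiet, "filter: ", flt$n_input, " calls -> ", nrow(flt$retained),
           " retained (", sum(flt$rejections), " rejected)")
  write_mutations(flt$retained, file.path(out, "mutations_filtered.tsv"))
  utils::write.table(
    data.frame(criterion = names(flt$rejections), rejected = flt$rejections),
    file.path(out, "filter_rejections.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 2: cluster detection
  det <- detect_regions(flt$retained, gap_bp = config$gap_bp,
                        min_size = config$min_size, genome = cohort$genome)
  pipe_log(quiet, "cluster: ", det$stats$n_clusters, " clusters -> ",
           det$stats$n_fr, " CSM-FR, ", det$stats$n_cr, " CSM-CR, ",
           det$stats$n_mixed, " mixed")
  write_bed(det$fr_regions, file.path(out, "csm_fr.bed"))
  write_bed(det$cr_regions, file.path(out, "csm_cr.bed"))
  utils::write.table(det$clusters, file.path(out, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 3: enrichment against every track
  enrich <- NULL
  if (length(cohort$tracks) && nrow(det$fr_regions)) {
    rows <- lapply(names(cohort$tracks), function(nm) {
      pt <- permutation_test(det$fr_regions, track = cohort$tracks[[nm]],
                             genome = cohort$genome, n_reps = config$n_reps,
                             seed = seeds[1])
      fis <- if (nrow(det$cr_regions)) {
        fisher_region_class_comparison(
          count_overlapping_regions(det$fr_regions, cohort$tracks[[nm]]),
          nrow(det$fr_regions),
          count_overlapping_regions(det$cr_regions, cohort$tracks[[nm]]),
          nrow(det$cr_regions))
      } else list(odds_ratio = NA_real_, p = NA_real_)
      data.frame(track = nm, observed = pt$observed,
                 null_mean = mean(pt$null_values), perm_p = pt$empirical_p,
                 fr_vs_cr_or = fis$odds_ratio, fr_vs_cr_p = fis$p,
                 stringsAsFactors = FALSE)
    })
    enrich <- do.call(rbind, rows)
    utils::write.table(enrich, file.path(out, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pipe_log(quiet, "enrich: ", nrow(enrich), " track(s) tested")
  }

  # stage 4: cohort statistics
  burden <- burden_summary(flt$retained, cohort$samples)
  delrat <- suppressWarnings(deleterious_ratio(flt$retained, cohort$samples))
  stats_tab <- data.frame(
    statistic = c("mean_burden_cen", "mean_burden_yc", "burden_wilcoxon_p",
                  "deleterious_ratio_cen", "deleterious_ratio_yc",
                  "deleterious_wilcoxon_p"),
    value = c(burden$group_means["CEN"], burden$group_means["YC"],
              burden$wilcoxon_p, delrat$group_ratios["CEN"],
              delrat$group_ratios["YC"], delrat$wilcoxon_p)
  )
  utils::write.table(stats_tab, file.path(out, "cohort_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pipe_log(quiet, "stats: mean burden CEN ",
           round(burden$group_means["CEN"], 1), ", YC ",
           round(burden$group_means["YC"], 1))

  # stage 5: robustness
  robust <- NULL
  if (nrow(det$fr_regions)) {
    thr <- threshold_sensitivity(flt$retained, reference_gap = config$gap_bp,
                                 min_size = config$min_size)
    loo <- leave_one_out_recall(flt$retained, cohort$samples,
                                gap_bp = config$gap_bp,
                                min_size = config$min_size)
    persist <- if (length(config$excluded_sample_ids)) {
      exclusion_persistence(flt$retained, cohort$samples,
                            config$excluded_sample_ids,
                            gap_bp = config$gap_bp,
                            min_size = config$min_size)
    } else NA_real_
    utils::write.table(thr, file.path(out, "threshold_sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    robust <- list(threshold = thr, loo = loo, persistence = persist)
    utils::write.table(
      data.frame(statistic = c("loo_mean_recall", "exclusion_persistence"),
                 value = c(loo$mean_recall, persist)),
      file.path(out, "robustness.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    pipe_log(quiet, "robustness: leave-one-out mean recall ",
             round(loo$mean_recall, 4))
  }

  invisible(list(cohort = cohort, filter = flt, regions = det,
                 enrichment = enrich, burden = burden,
                 deleterious = delrat, robustness = robust,
                 out_dir = out))
}
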