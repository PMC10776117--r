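# Shared study configuration for the analysis scripts.
#
# Two synthetic cohorts stand in for the restricted-access human data, both
# 73 CEN + 51 YC samples on the 3 x 10 Mb toy genome:
#   * burden cohort  — Poisson burdens 950 / 881 SSBS per sample, used for
#     burden, VAF and deleteriousness statistics (per-bp density is far above
#     the human genome's, so it is not used for cluster detection);
#   * cluster cohort — sparse background (0.5 SSBS per sample, expected
#     spurious clusters << 1) with 5 planted YC-only regions (true CSM-FRs),
#     7 planted CEN-only regions (true CSM-CRs) and a regulatory track
#     enriched over the planted CSM-FRs at odds ratio 25.

library(csmfr)

STUDY_SEED <- 20240901L

burden_cohort_config <- function() {
  simulation_config(seed = child_seeds(STUDY_SEED, 2)[1])
}

cluster_cohort_config <- function() {
  simulation_config(
    burden_mean_cen = 0.5, burden_mean_yc = 0.5,
    n_planted_fr = 5, n_planted_cr = 7, planted_muts_per_region = 4,
    track_specs = list(
      regulatory = list(density = 0.05, mean_width = 1000,
                        enrich_or = 25, enrich_cls = "CSM_FR"),
      heterochromatin = list(density = 0.3, mean_width = 5000)
    ),
    seed = child_seeds(STUDY_SEED, 2)[2]
  )
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
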