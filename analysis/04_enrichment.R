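#!/usr/bin/env Rscript
# Are the detected CSM-FRs preferentially located in functional tracks?
# Randomized-region permutation tests against each simulated track, Fisher
# comparison against CSM-CRs, DSM coverage, and deleteriousness of YC
# mutations inside CSM-FRs.

source("analysis/00_config.R")

cohort <- read_cohort("results/cohort")
flt <- apply_filters(cohort$mutations)
det <- detect_regions(flt$retained, genome = cohort$genome)
seeds <- child_seeds(STUDY_SEED + 4L, 4)

rows <- lapply(names(cohort$tracks), function(nm) {
  pt <- permutation_test(det$fr_regions, track = cohort$tracks[[nm]],
                         genome = cohort$genome, n_reps = 999,
                         seed = seeds[1])
  fis <- fisher_region_class_comparison(
    count_overlapping_regions(det$fr_regions, cohort$tracks[[nm]]),
    nrow(det$fr_regions),
    count_overlapping_regions(det$cr_regions, cohort$tracks[[nm]]),
    nrow(det$cr_regions))
  message(sprintf(
    "%s: observed %d/%d CSM-FRs in track (null mean %.2f) perm p = %.3f; FR-vs-CR OR %.2f, Fisher p = %.3f",
    nm, pt$observed, nrow(det$fr_regions), mean(pt$null_values),
    pt$empirical_p, fis$odds_ratio, fis$p))
  data.frame(track = nm, observed = pt$observed,
             null_mean = mean(pt$null_values), perm_p = pt$empirical_p,
             fr_vs_cr_or = fis$odds_ratio, fr_vs_cr_p = fis$p)
})
write_tsv(do.call(rbind, rows), file.path(results_dir(), "enrichment.tsv"))

# synthetic disease-susceptibility catalogue: 300 random positions plus one
# inside every true CSM-FR, to give the coverage statistics planted signal
truth_fr <- cohort$truth[cohort$truth$cls == "CSM_FR", ]
dsms <- withr::with_seed(seeds[2], rbind(
  data.frame(chrom = sample(cohort$genome$chrom, 300, replace = TRUE,
                            prob = cohort$genome$length),
             pos = sample.int(1e7, 300)),
  data.frame(chrom = truth_fr$chrom,
             pos = floor((truth_fr$start + truth_fr$end) / 2))
))
cov <- dsm_coverage(det$fr_regions, dsms)
pt_dsm <- permutation_test(
  det$fr_regions, genome = cohort$genome, n_reps = 999, seed = seeds[3],
  stat_fn = function(r) dsm_coverage(r, dsms)$n_dsms_covered)
message(sprintf(
  "DSMs: %d covered by CSM-FRs, %d/%d CSM-FRs contain one; perm p = %.3f",
  cov$n_dsms_covered, cov$n_regions_with_dsm, nrow(det$fr_regions),
  pt_dsm$empirical_p))

# deleterious YC mutations inside CSM-FRs vs random YC mutation draws
yc <- flt$retained[flt$retained$group == "YC", ]
del <- deleterious_mutation_enrichment(yc, det$fr_regions, n_reps = 999,
                                       seed = seeds[4])
message(sprintf(
  "deleterious YC mutations in CSM-FRs: observed %d (null mean %.2f), p = %.3f",
  del$observed, mean(del$null_values), del$empirical_p))
write_tsv(data.frame(
  statistic = c("dsms_covered", "fr_with_dsm", "dsm_perm_p",
                "deleterious_in_fr", "deleterious_perm_p"),
  value = c(cov$n_dsms_covered, cov$n_regions_with_dsm, pt_dsm$empirical_p,
            del$observed, del$empirical_p)),
  file.path(results_dir(), "dsm_deleterious.tsv"))
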