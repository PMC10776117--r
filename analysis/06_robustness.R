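#!/usr/bin/env Rscript
# Stability of CSM-FR detection: distance-threshold sensitivity,
# leave-one-out recall, and persistence after excluding flagged samples
# (the analog of removing putative clonal-hematopoiesis carriers).

source("analysis/00_config.R")

cohort <- read_cohort("results/cohort")
flt <- apply_filters(cohort$mutations)

thr <- threshold_sensitivity(flt$retained,
                             thresholds = c(3000, 4000, 5000, 6000, 8000,
                                            10000))
print(thr)
write_tsv(thr, file.path(results_dir(), "threshold_sensitivity.tsv"))

loo <- leave_one_out_recall(flt$retained, cohort$samples)
message(sprintf(
  "leave-one-out: mean CSM-FR recall %.4f over %d samples (min %.2f)",
  loo$mean_recall, length(loo$per_sample), min(loo$per_sample)))

excluded <- head(cohort$samples$sample_id[cohort$samples$group == "CEN"], 6)
persist <- exclusion_persistence(flt$retained, cohort$samples, excluded)
message(sprintf(
  "excluding 6 flagged CEN samples: %.2f%% of CSM-FRs persist",
  100 * persist))

write_tsv(data.frame(
  statistic = c("loo_mean_recall", "exclusion_persistence"),
  value = c(loo$mean_recall, persist)),
  file.path(results_dir(), "robustness.tsv"))
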