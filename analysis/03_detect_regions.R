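#!/usr/bin/env Rscript
# Detect mutation clusters (>= 3 calls, adjacent gaps < 5 kb), classify them
# into CSM-FRs / CSM-CRs and compare against the planted truth.

source("analysis/00_config.R")

cohort <- read_cohort("results/cohort")
flt <- apply_filters(cohort$mutations)
det <- detect_regions(flt$retained, genome = cohort$genome)
print(det)

write_bed(det$fr_regions, file.path(results_dir(), "csm_fr.bed"))
write_bed(det$cr_regions, file.path(results_dir(), "csm_cr.bed"))
write_tsv(det$clusters, file.path(results_dir(), "clusters.tsv"))

truth_fr <- cohort$truth[cohort$truth$cls == "CSM_FR", ]
truth_cr <- cohort$truth[cohort$truth$cls == "CSM_CR", ]
message(sprintf(
  "planted-region recovery: FR %d/%d (recall %.2f), CR %d/%d (recall %.2f)",
  det$stats$n_fr, nrow(truth_fr),
  region_recall(truth_fr, det$fr_regions)$recall,
  det$stats$n_cr, nrow(truth_cr),
  region_recall(truth_cr, det$cr_regions)$recall))
message(sprintf("mean widths: CSM-FR %.0f bp, CSM-CR %.0f bp",
                det$stats$mean_width_fr, det$stats$mean_width_cr))
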