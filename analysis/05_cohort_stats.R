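#!/usr/bin/env Rscript
# Cohort-level descriptive statistics on the burden-scale cohort: per-sample
# burden and group comparison, burden-age correlation, deleterious-mutation
# ratios, mutation distribution across a genomic partition, and the
# 96-context trinucleotide spectrum on a sequenced toy chromosome.

source("analysis/00_config.R")

cohort <- simulate_cohort(burden_cohort_config())
flt <- apply_filters(cohort$mutations)
seeds <- child_seeds(STUDY_SEED + 5L, 3)

b <- burden_summary(flt$retained, cohort$samples)
message(sprintf("burden: CEN %.1f vs YC %.1f per sample, Wilcoxon p = %.3g",
                b$group_means["CEN"], b$group_means["YC"], b$wilcoxon_p))

yc <- b$per_sample[b$per_sample$group == "YC", ]
ages <- cohort$samples$age[match(yc$sample_id, cohort$samples$sample_id)]
corr <- burden_age_correlation(yc$burden, ages)
message(sprintf(
  "YC burden-age Pearson r = %.3f (p = %.3f, n = %d); the generator draws burden independent of age, so r is expected near 0",
  corr$r, corr$p, corr$n))

dl <- deleterious_ratio(flt$retained, cohort$samples)
message(sprintf(
  "deleterious ratio (CADD > 15 or FATHMM damaging): CEN %.4f vs YC %.4f, Wilcoxon p = %.3f",
  dl$group_ratios["CEN"], dl$group_ratios["YC"], dl$wilcoxon_p))

# genomic-partition Fisher tests against a simulated compartment-like track
partition <- simulate_tracks(
  cohort$genome,
  list(compartment_A = list(density = 0.4, mean_width = 50000),
       essential_genes = list(density = 0.05, mean_width = 20000)),
  seed = seeds[1])
pf <- partition_fisher(flt$retained, partition)
print(pf)
write_tsv(pf, file.path(results_dir(), "partition_fisher.tsv"))

# trinucleotide spectrum on a 50 kb sequenced chromosome
spec_genome <- genome_spec("chrS", 50000)
seqs <- simulate_genome_sequence(spec_genome, seed = seeds[2])
muts <- withr::with_seed(seeds[3], {
  pos <- sort(sample(2:49999, 1000))
  base <- substring(as.character(seqs[[1]]), pos, pos)
  data.frame(chrom = "chrS", pos = pos, ref = base,
             alt = vapply(base, function(r)
               sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1)),
             stringsAsFactors = FALSE)
})
sp <- trinucleotide_spectrum(muts, seqs)
print(sp)
write_tsv(data.frame(context = names(sp$counts), count = unname(sp$counts),
                     fraction = unname(sp$fractions)),
          file.path(results_dir(), "trinucleotide_spectrum.tsv"))

write_tsv(data.frame(
  statistic = c("mean_burden_cen", "mean_burden_yc", "burden_wilcoxon_p",
                "yc_age_r", "yc_age_p", "deleterious_ratio_cen",
                "deleterious_ratio_yc", "deleterious_wilcoxon_p"),
  value = c(b$group_means["CEN"], b$group_means["YC"], b$wilcoxon_p,
            corr$r, corr$p, dl$group_ratios["CEN"], dl$group_ratios["YC"],
            dl$wilcoxon_p)),
  file.path(results_dir(), "cohort_stats.tsv"))
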