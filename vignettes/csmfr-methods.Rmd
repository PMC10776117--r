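---
title: "Methods: detecting group-exclusive somatic mutation cluster regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting group-exclusive somatic mutation cluster regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmfr)
```

## The question and the design

Centenarians carry a lifetime's load of blood somatic mutations, yet reach
extreme age in good health. One way this could happen is spatial: if certain
genomic regions are kept mutation-free in long-lived individuals while
accumulating mutations in the general population, those regions are
candidates for loci whose integrity matters for survival. `csmfr` implements
the full analysis chain for testing this idea in a two-group cohort design —
centenarians (CEN) versus younger controls (YC) — from raw per-sample somatic
single-base-substitution (SSBS) calls to classified cluster regions and their
functional characterization:

1. **Filtering** — dual-caller consensus plus an eight-criterion somatic
   filter producing the analysis-ready SSBS set.
2. **Clustering** — detection of mutation clusters by genomic distance, and
   classification of group-exclusive clusters: clusters containing only YC
   mutations are *CSM-FRs* (centenarian somatic-mutation-free regions;
   variable in controls, spared in centenarians) and clusters containing only
   CEN mutations are *CSM-CRs*.
3. **Enrichment** — randomized-region permutation tests and Fisher's exact
   tests asking whether CSM-FRs preferentially overlap functional tracks
   (regulatory elements, disease-susceptibility mutations, DNA repair
   hotspots) and whether mutations falling inside them are preferentially
   deleterious.
4. **Cohort statistics** — per-sample burden, age correlation, deleterious
   ratios, partition tests, trinucleotide spectra.
5. **Robustness** — distance-threshold sensitivity, leave-one-out recall,
   and persistence after excluding flagged samples.

Because the motivating human data are restricted-access, the package ships a
synthetic cohort generator that emulates the study design and plants
group-exclusive clusters as ground truth; every stage is validated against
that truth or against independent brute-force oracles.

## Filtering model

A call is retained iff **all** of the following hold, checked in this order
(the order matters only for bookkeeping: each rejected call is attributed to
the first criterion it fails, while the retained set itself is
order-independent):

1. `FILTER == "PASS"`;
2. chromosome in the allowed set (autosomes and X — the design cohorts are
   all-female, so X is treated like an autosome throughout);
3. position not covered by the segmental-duplication (SuperDups) track;
4. VAF `< 0.5`, where VAF is the ratio of mutant to all mapped reads;
5. depth in `[20, 120]`;
6. at least 3 reads supporting the alternative allele;
7. population (gnomAD-style popmax) allele frequency `< 0.01`;
8. site observed in at most one cohort individual (distinct individuals, not
   call records, are counted).

Boundary conventions follow the wording of the criteria: the depth bounds are
inclusive ("not less than ... not more than"), the VAF and population-AF
bounds strict ("less than"). A missing population-frequency annotation is
treated as AF 0: absence from a population database cannot establish that a
variant is common. Multi-allelic records are split into biallelic SNV
candidates before filtering and non-SNV alleles are discarded. Criterion 8
counts distinct carriers of the identical (chrom, pos, ref, alt) site; when
one individual shows a site through both callers it still counts once.

Filtering is idempotent and monotone: re-filtering retained output removes
nothing, and loosening any single threshold can only grow the retained set.
Both properties are enforced by tests.

## Cluster model

A mutation cluster is **three or more calls on one chromosome whose mutual
distances are closer than 5 kb**. "Mutual distances" is ambiguous between a
consecutive-gap rule and an all-pairs (diameter) rule; `csmfr` implements
**consecutive-gap single linkage**: positions are sorted and adjacent calls
chain whenever their gap is strictly below `gap_bp`. The diameter reading
would cap cluster width at the threshold itself, which is inconsistent with
multi-kilobase clusters of three or more members that the consecutive-gap
convention (standard for clustered-mutation detection) naturally produces;
the threshold is exposed as a parameter and the sensitivity analysis re-runs
detection at 3, 4, 6, 8 and 10 kb. The inequality is strict ("closer than
5 kb"), so an exact 5000 bp gap breaks a chain — tested at the boundary.

Calls from different samples at the same position each count as one member; a
cluster may therefore be driven by a single individual, which is exactly what
the leave-one-out analysis quantifies rather than something to silently
prevent. Cluster regions span the member positions with zero padding (the
only rule consistent with reporting a mean region width without a padding
convention); padding and clipping to chromosome ends are available as
options. Classification is exhaustive: every cluster is exactly one of
`CSM_FR` (no CEN members), `CSM_CR` (no YC members) or `MIXED`, and mixed
clusters are returned, not dropped.

The minimum cluster size (`min_size = 3`) is a parameter; `detect_regions()`
reports the fraction of clusters exceeding it for any run, since the choice
of 3 over 2 trades recall for a lower false-positive rate.

## Enrichment model

The null model for "are CSM-FRs preferentially located in track X?" is
**width- and count-matched random placement**: one random region per observed
region, with the observed width multiset preserved exactly, each placed
uniformly over all valid start positions genome-wide (chromosome chosen
proportional to its number of valid starts; an option keeps each template's
own chromosome instead). No gap/blacklist exclusion mask is applied — the
minimal fair null absent a stated masking rule. Random regions may overlap
each other, as independent draws should.

The test statistic defaults to the number of regions with at least one base
of overlap with the track ("located in"); any statistic of a region set can
be substituted, e.g. the number of disease-susceptibility mutations (DSMs)
covered. The empirical p-value uses add-one smoothing,

$$p = \frac{1 + \#\{T_{\text{null}} \ge T_{\text{obs}}\}}{n_{\text{reps}} + 1},$$

so p is never exactly zero and is valid (super-uniform) under the null; the
default is 1000 replicates. Group comparisons of overlap (CSM-FR vs CSM-CR)
use two-sided Fisher's exact tests on the 2x2 in/out table; the reported
odds ratio is the sample cross-product ratio.

A mutation is "deleterious" when its CADD PHRED score exceeds 15 or its
FATHMM-MKL class is damaging; each predictor is also available separately.
The deleterious-enrichment test compares the observed number of deleterious
YC mutations inside CSM-FRs with draws of equally many YC mutations sampled
uniformly without replacement — a count that is exactly hypergeometric, and
drawn as such.

## Cohort statistics

Burden comparisons use the two-sided Wilcoxon rank-sum test (exact for small
untied samples, tie-corrected normal approximation otherwise); burden-age
relations use Pearson correlation with the t-distribution p-value.
Mutation-distribution tests across genomic partitions (compartments,
ChromHMM-style segments, transcription activity, essential genes, regulatory
classes) pool counts across samples into per-group 2x2 tables for Fisher's
exact test — proportions of pooled counts are what such figures display — and
a per-sample variant (Wilcoxon on per-sample proportions) is available as an
option.

Trinucleotide spectra map each SSBS to one of the 96 pyrimidine-centric
context classes; purine-reference mutations are reverse-complemented first.
The reference allele of every call is checked against the FASTA and
mismatches are a hard error naming the offending records. Fractions sum to 1
and the spectrum is invariant under reverse-complementing the whole input,
both enforced by tests.

## Robustness checks

A reference region is "recovered" by a re-detected set when any test region
overlaps it by at least one base; no reciprocal-overlap fraction is part of
the definition, but a minimum-overlap fraction is exposed as an option.
Threshold sensitivity re-runs detection at alternative gaps and reports
recall of the reference-gap CSM-FRs. Leave-one-out drops each sample in turn;
sample exclusion (e.g. of putative clonal-hematopoiesis carriers, which are
identified upstream from a curated variant list and supplied as metadata)
reports the fraction of CSM-FRs that persist. Excluding an entire group is an
error, and self-recall at the reference threshold is exactly 1 by
construction — both tested.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 73 CEN and 51 YC samples,
per-sample background burden Poisson with means 950 and 881, CEN ages
N(100.5, 3.7) and YC ages N(60.3, 7.8) years, on a toy genome of three 10 Mb
chromosomes (small enough for brute-force oracles, large enough for sparse
clustering). Planted ground truth consists of `n_planted_fr` YC-only regions
and `n_planted_cr` CEN-only regions (defaults 5 and 7, width 3500 bp — near
the few-kb scale at which detected cluster regions live — with 4 mutations
each, assigned to distinct samples because cluster evidence aggregates across
individuals).

Distributional choices the data do not pin down are conventions, chosen once:

* **VAF** per call is Beta(2, 18) (mean 0.1) in both groups — bounded,
  right-skewed, and typical of blood somatic VAF; the shapes are per-group
  parameters.
* **Depth** is uniform on [20, 120] and the alt-read count is
  Binomial(depth, VAF) **clamped to [3, (depth-1)/2]**, so generated calls
  sit inside the filter envelope and planted truth survives filtering
  unchanged — the generator's job is to provide clean ground truth for the
  pipeline, not to model caller error.
* **Deleteriousness** is planted by rate (5% background, 20% inside planted
  regions by default), realized as a CADD PHRED draw above/below 15 with a
  concordant FATHMM class.
* **Background placement** is uniform per chromosome (probability
  proportional to length). Background draws of the opposite group landing
  inside a planted region *or within 5 kb of it* are rejected and resampled:
  without the flanking buffer, an opposite-group mutation within chaining
  distance would merge into the planted cluster and flip its class to MIXED,
  making the truth labels themselves random. Same-group background near
  planted regions is allowed — it only extends a cluster's span.

Annotation tracks are simulated per chromosome as
`n = round(density * L / mean_width)` non-overlapping intervals with widths
`1 + Poisson(mean_width - 1)`, placed by uniform stick-breaking of the
residual gap space. This makes total coverage analytically tractable (mean
`n * mean_width`, variance `n * (mean_width - 1)`), which the tests exploit.
Optionally a track is enriched over planted regions at a configurable odds
ratio: an interval is force-placed over a planted region's midpoint with the
probability that lifts its hit odds from the background density `p0` to
`p1 = OR * p0 / (1 - p0 + OR * p0)`; `p0` is approximated by the track
density (a point-hit approximation, adequate for regions much narrower than
the chromosome). At odds ratio 1 nothing is added.

All randomness flows from a single integer seed, expanded into per-stage
child seeds as successive draws of `sample.int(.Machine$integer.max - 1)`
under the parent seed (`child_seeds()`), so any stage is reproducible in
isolation and identical configurations are byte-identical.

### What the generator does and does not emulate

It reproduces the cohort structure, burden scale, group-exclusive cluster
geometry, VAF/depth bookkeeping and annotation-overlap structure — the
features the pipeline's correctness depends on. It does **not** simulate
reads or caller error (calls are taken as given), trinucleotide signature
biases (spectra are exercised on arbitrary contexts), burden overdispersion
between individuals (real blood cohorts are more variable than Poisson, so
synthetic group comparisons are anti-conservative relative to real data),
burden-age trends (burden is drawn independent of age; the correlation
machinery is tested on constructed data), or linkage between deleteriousness
and genomic position beyond the planted rates. Passing tests therefore
demonstrate that the pipeline's logic is correct on data of the designed
structure, not that any biological conclusion transfers to real cohorts.

## Problem sizes and numerical choices

The test-suite and analysis scripts choose sizes that keep brute-force
oracles exact and runs quick while preserving the study's sample structure:

* Cluster-detection analyses use the full 73 + 51 samples with a sparse
  background (0.5-1 mutations per sample on 30 Mb), so that the expected
  number of spurious background clusters is far below 1 and planted-region
  recovery is exact by construction.
* Burden/deleteriousness analyses use the full Poisson burdens (950/881;
  ~114k calls), where per-bp density is irrelevant.
* Permutation tests default to 999-1000 replicates; the calibration test
  uses 200 independent repeats at 999 replicates against the binomial 99%
  band for the rejection rate at level 0.05.
* Fisher p-values are checked against an explicit log-space hypergeometric
  tail sum (at the standard two-sided rule that includes all tables with
  probability up to the observed one, within 1e-7 relative slack) to 1e-12,
  exhaustively for small tables.
* Ties in rank tests fall back to the tie-corrected normal approximation;
  fully tied comparisons carry no evidence and return p = 1.
* Degenerate inputs are errors where silence would mislead (zero depth,
  empty reference region sets, zero-variance correlations, excluding an
  entire group) and warnings where work can proceed (zero-mutation samples
  excluded from ratio comparisons, empty partition categories skipped,
  unknown chromosome names rejected under the chromosome criterion).

## Worked example

```{r example, eval = FALSE}
library(csmfr)

cfg <- simulation_config(
  burden_mean_cen = 0.5, burden_mean_yc = 0.5,
  n_planted_fr = 5, n_planted_cr = 7, planted_muts_per_region = 4,
  track_specs = list(regulatory = list(density = 0.05, mean_width = 1000,
                                       enrich_or = 25, enrich_cls = "CSM_FR")),
  seed = 42)
cohort <- simulate_cohort(cfg)

flt <- apply_filters(count_cohort_occurrence(cohort$mutations))
det <- detect_regions(flt$retained, genome = cohort$genome)
det

region_recall(cohort$truth[cohort$truth$cls == "CSM_FR", ], det$fr_regions)
permutation_test(det$fr_regions, track = cohort$tracks$regulatory,
                 genome = cohort$genome, n_reps = 999, seed = 1)
leave_one_out_recall(flt$retained, cohort$samples)$mean_recall
```

The numbered scripts under `analysis/` run this workflow end to end on the
two study-scale synthetic cohorts and write their tables under `results/`.

## Known limitations

* The consecutive-gap reading of "mutual distances" is a documented choice;
  an all-pairs-diameter variant would require only a different chaining rule
  but is not implemented.
* The randomization null has no mappability/blacklist masking and no
  GC- or chromatin-matching; on real genomes those covariates matter.
* Clonal-hematopoiesis carrier identification is consumed as metadata, not
  computed.
* Mutational-signature decomposition, clonality inference and
  coverage-based sensitivity estimation are out of scope; the package stops
  at the spectrum itself.
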