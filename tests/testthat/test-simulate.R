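small_config <- function(seed = 5, ...) {
  simulation_config(n_cen = 6, n_yc = 5, burden_mean_cen = 30,
                    burden_mean_yc = 30, n_planted_fr = 2, n_planted_cr = 2,
                    seed = seed, ...)
}

test_that("zero burden and no planted regions give an empty cohort", {
  cfg <- simulation_config(burden_mean_cen = 0, burden_mean_yc = 0,
                           n_planted_fr = 0, n_planted_cr = 0, seed = 1)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$mutations), 0)
  expect_equal(nrow(co$samples), 73 + 51)
})

test_that("identical config and seed reproduce the cohort exactly", {
  a <- simulate_cohort(small_config())
  b <- simulate_cohort(small_config())
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)

  c2 <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("simulated cohorts satisfy their structural invariants", {
  co <- simulate_cohort(small_config())
  m <- co$mutations
  expect_true(all(m$sample_id %in% co$samples$sample_id))
  expect_true(all(m$pos >= 1))
  lens <- stats::setNames(co$genome$length, co$genome$chrom)
  expect_true(all(m$pos <= lens[m$chrom]))
  expect_true(all(m$alt_reads <= m$depth))
  expect_equal(m$vaf, m$alt_reads / m$depth)
  expect_true(all(m$ref != m$alt))

  # planted mutations lie inside their regions, from the right group only
  for (i in seq_len(nrow(co$truth))) {
    pm <- m[!is.na(m$region_id) & m$region_id == co$truth$region_id[i], ]
    expect_gte(nrow(pm), 3)
    expect_true(all(pm$chrom == co$truth$chrom[i]))
    expect_true(all(pm$pos >= co$truth$start[i] & pm$pos <= co$truth$end[i]))
    expect_true(all(pm$group ==
                      if (co$truth$cls[i] == "CSM_FR") "YC" else "CEN"))
    expect_lt(max(diff(sort(pm$pos))), 5000)
    # default: planted members come from distinct samples
    expect_equal(anyDuplicated(pm$sample_id), 0)
  }

  # background mutations never land in opposite-class planted regions
  bg <- m[!m$planted, ]
  tr_gr <- regions_to_granges(co$truth)
  bg_gr <- regions_to_granges(
    data.frame(chrom = bg$chrom, start = bg$pos, end = bg$pos))
  ov <- GenomicRanges::findOverlaps(bg_gr, tr_gr)
  if (length(ov)) {
    cls_hit <- co$truth$cls[S4Vectors::subjectHits(ov)]
    grp_hit <- bg$group[S4Vectors::queryHits(ov)]
    expect_true(all(ifelse(cls_hit == "CSM_FR", grp_hit == "YC",
                           grp_hit == "CEN")))
  }

  # planted regions are mutually disjoint
  expect_equal(sum(GenomicRanges::countOverlaps(tr_gr, tr_gr)), nrow(co$truth))
})

test_that("per-sample burden matches the configured Poisson means within 5%", {
  cfg <- simulation_config(n_cen = 60, n_yc = 60, burden_mean_cen = 200,
                           burden_mean_yc = 100, n_planted_fr = 0,
                           n_planted_cr = 0, seed = 2)
  co <- simulate_cohort(cfg)
  b <- burden_summary(co$mutations, co$samples)
  expect_lt(abs(b$group_means["CEN"] / 200 - 1), 0.05)
  expect_lt(abs(b$group_means["YC"] / 100 - 1), 0.05)
})

test_that("oversized planted configurations are rejected at construction", {
  expect_error(simulation_config(genome = genome_spec("chr1", 1e4),
                                 n_planted_fr = 2, n_planted_cr = 2,
                                 planted_width_bp = 3500),
               "cannot fit")
  expect_error(simulation_config(genome = genome_spec("chr1", 1e3),
                                 n_planted_fr = 1, n_planted_cr = 0,
                                 planted_width_bp = 2000),
               "cannot fit")
  expect_error(simulation_config(n_planted_fr = 1, planted_muts_per_region = 2),
               "planted_muts_per_region")
})

test_that("track density 0 gives an empty track; coverage tracks its expectation", {
  g <- genome_spec("chr1", 1e7)
  empty <- simulate_tracks(g, list(t = list(density = 0, mean_width = 1000)),
                           seed = 1)
  expect_equal(length(empty$t), 0)

  expect_error(simulate_tracks(g, list(t = list(density = 1.2)), seed = 1),
               "density")

  # n = 1000 intervals, widths 1 + Poisson(999): coverage mean 1e6, sd
  # sqrt(1000 * 999) ~ 1000 (before the non-overlap merge, which only removes
  # double counting and cannot inflate coverage)
  for (seed in 1:5) {
    tr <- simulate_tracks(g, list(t = list(density = 0.1, mean_width = 1000)),
                          seed = seed)
    covered <- sum(GenomicRanges::width(tr$t))
    expect_lt(abs(covered - 1e6), 3 * sqrt(1000 * 999) + 1)
    # intervals are non-overlapping and within bounds
    expect_true(all(GenomicRanges::start(tr$t) >= 1))
    expect_true(all(GenomicRanges::end(tr$t) <= 1e7))
  }
})

test_that("planted-enrichment odds ratio 1 adds nothing beyond background", {
  g <- genome_spec("chr1", 1e7)
  planted <- data.frame(chrom = "chr1", start = (1:5) * 1e6,
                        end = (1:5) * 1e6 + 3499)
  base <- simulate_tracks(g, list(t = list(density = 0.05, mean_width = 500,
                                           enrich_or = 1)),
                          seed = 3, planted_regions = planted)
  no_planted <- simulate_tracks(g, list(t = list(density = 0.05,
                                                 mean_width = 500)),
                                seed = 3)
  expect_identical(granges_to_regions(base$t), granges_to_regions(no_planted$t))

  # a large odds ratio makes planted regions overlap the track far more often
  hits <- function(or, seed) {
    tr <- simulate_tracks(g, list(t = list(density = 0.05, mean_width = 500,
                                           enrich_or = or)),
                          seed = seed, planted_regions = planted)
    count_overlapping_regions(planted, tr$t)
  }
  h1 <- mean(vapply(1:20, function(s) hits(1, s), numeric(1)))
  h50 <- mean(vapply(1:20, function(s) hits(50, s), numeric(1)))
  expect_gt(h50, h1)
})

test_that("writing and re-reading a cohort is lossless", {
  co <- simulate_cohort(small_config(track_specs = list(
    reg = list(density = 0.02, mean_width = 400))))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  for (col in c("sample_id", "group", "chrom", "ref", "alt",
                "depth", "alt_reads", "fathmm_class", "planted")) {
    expect_identical(unname(back$mutations[[col]]),
                     unname(co$mutations[[col]]))
  }
  for (col in c("pos", "cadd_phred", "popmax_af")) {
    expect_equal(unname(back$mutations[[col]]),
                 unname(co$mutations[[col]]),
                 ignore_attr = TRUE, tolerance = 0)
  }
  expect_equal(back$mutations$vaf, co$mutations$vaf)
  expect_identical(back$samples, co$samples)
  expect_equal(back$truth[, c("chrom", "start", "end", "cls")],
               co$truth[, c("chrom", "start", "end", "cls")])
  expect_equal(granges_to_regions(back$tracks$reg)[, c("chrom", "start", "end")],
               granges_to_regions(co$tracks$reg)[, c("chrom", "start", "end")])
})

test_that("truth regions are written as 0-based half-open BED", {
  co <- simulate_cohort(small_config())
  d <- withr::local_tempdir()
  write_cohort(co, d)
  raw <- read.table(file.path(d, "truth.bed"), sep = "\t")
  expect_equal(raw$V2, co$truth$start - 1)
  expect_equal(raw$V3, co$truth$end)
})
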