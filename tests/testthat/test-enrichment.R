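random_regions_fixture <- function(seed, n = 50, genome = toy_genome(),
                                   max_width = 2000) {
  withr::with_seed(seed, {
    chrom <- sample(genome$chrom, n, replace = TRUE)
    start <- sample.int(9e5, n)
    width <- sample.int(max_width, n)
    data.frame(chrom = chrom, start = start, end = start + width - 1,
               stringsAsFactors = FALSE)
  })
}

test_that("random regions preserve the template width multiset and the seed", {
  g <- genome_spec(c("chr1", "chr2"), c(1e7, 5e6))
  templates <- data.frame(chrom = "chr1", start = c(1000, 5000),
                          end = c(2000, 7000) - 1)
  got <- sample_random_regions(g, templates, seed = 42)
  expect_setequal(got$width, c(1000, 2000))
  expect_identical(got, sample_random_regions(g, templates, seed = 42))
  expect_false(identical(got, sample_random_regions(g, templates, seed = 43)))

  wide <- data.frame(chrom = "chr1", start = 1, end = 2e7)
  expect_error(sample_random_regions(g, wide, seed = 1), "wider than every")
})

test_that("per-base hit probability of a fixed target matches the closed form", {
  # one 1 kb template on a single 1 Mb chromosome; a fixed 1 kb target.
  # placements overlapping the target: starts in [target_start - w + 1,
  # target_end], intersected with the valid range [1, L - w + 1]
  g <- genome_spec("chr1", 1e6)
  template <- data.frame(chrom = "chr1", start = 1, end = 1000)
  target <- data.frame(chrom = "chr1", start = 500001, end = 501000)
  w <- 1000; L <- 1e6
  p_hit <- (1000 + w - 1) / (L - w + 1)
  hits <- vapply(1:2000, function(s) {
    count_overlapping_regions(sample_random_regions(g, template, seed = s),
                              target)
  }, numeric(1))
  mc_se <- sqrt(p_hit * (1 - p_hit) / 2000)
  expect_lt(abs(mean(hits) - p_hit), 4 * mc_se)
})

test_that("overlap counting equals the brute-force all-pairs oracle", {
  expect_equal(count_overlapping_regions(
    data.frame(chrom = "chr1", start = 1, end = 100),
    data.frame(chrom = "chr1", start = 200, end = 300)), 0)
  expect_equal(count_overlapping_regions(
    data.frame(chrom = "chr1", start = 200, end = 300),
    data.frame(chrom = "chr1", start = 200, end = 300)), 1)

  for (seed in 1:5) {
    regions <- random_regions_fixture(seed)
    track <- random_regions_fixture(seed + 100, n = 30)
    expect_equal(count_overlapping_regions(regions, track),
                 overlap_count_oracle(regions, track))
  }
})

test_that("empirical p follows the add-one rule and its boundary cases", {
  g <- toy_genome()
  regions <- random_regions_fixture(1, n = 10)
  # track covering everything: observed equals every null value -> p = 1
  full <- data.frame(chrom = g$chrom, start = 1, end = g$length)
  pt <- permutation_test(regions, track = full, genome = g, n_reps = 99,
                         seed = 1)
  expect_equal(pt$observed, 10)
  expect_true(all(pt$null_values == 10))
  expect_equal(pt$empirical_p, 1)

  # near-empty track, depletion tail: add-one rule mirrored over null <= obs
  none <- data.frame(chrom = "chr1", start = 999999, end = 999999)
  pt2 <- permutation_test(regions, track = none, genome = g, n_reps = 99,
                          seed = 1, tail = "less")
  expect_equal(pt2$observed, 0)
  expect_equal(pt2$empirical_p,
               (1 + sum(pt2$null_values <= 0)) / 100)

  expect_gt(permutation_test(regions, track = full, genome = g, n_reps = 999,
                             seed = 1)$empirical_p, 0)
  expect_length(pt$null_values, 99)
})

test_that("a caller-supplied statistic drives the permutation null", {
  g <- toy_genome()
  regions <- random_regions_fixture(3, n = 20)
  dsms <- data.frame(chrom = "chr1", pos = seq(1000, 9e5, by = 5000))
  pt <- permutation_test(regions, genome = g, n_reps = 199, seed = 9,
                         stat_fn = function(r) dsm_coverage(r, dsms)$n_dsms_covered)
  expect_equal(pt$observed, dsm_coverage(regions, dsms)$n_dsms_covered)
  expect_length(pt$null_values, 199)
  expect_true(pt$empirical_p > 0 && pt$empirical_p <= 1)
})

test_that("Fisher comparison of region classes matches closed forms", {
  expect_equal(fisher_region_class_comparison(1, 2, 1, 2)$p, 1.0)

  res <- fisher_region_class_comparison(10, 10, 0, 10)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)

  or <- fisher_region_class_comparison(8, 10, 3, 10)$odds_ratio
  expect_equal(or, (8 * 7) / (2 * 3))

  expect_error(fisher_region_class_comparison(0, 0, 1, 2), "zero-total")
  expect_error(fisher_region_class_comparison(3, 2, 1, 2), "counts")
})

test_that("DSM coverage counts points and covered regions, matching enumeration", {
  regions <- data.frame(chrom = "chr1", start = c(100, 1000), end = c(200, 2000))
  expect_equal(dsm_coverage(regions, data.frame(chrom = character(0),
                                                pos = numeric(0))),
               list(n_dsms_covered = 0L, n_regions_with_dsm = 0L))
  got <- dsm_coverage(regions, data.frame(chrom = "chr1",
                                          pos = c(150, 160, 170, 5000)))
  expect_equal(got$n_dsms_covered, 3L)
  expect_equal(got$n_regions_with_dsm, 1L)

  for (seed in 1:5) {
    regions <- random_regions_fixture(seed, n = 25)
    pts <- withr::with_seed(seed + 50, data.frame(
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
      pos = sample.int(1e6, 40)))
    inside <- vapply(seq_len(nrow(pts)), function(i) {
      any(regions$chrom == pts$chrom[i] & regions$start <= pts$pos[i] &
            regions$end >= pts$pos[i])
    }, logical(1))
    covered <- vapply(seq_len(nrow(regions)), function(i) {
      any(pts$chrom == regions$chrom[i] & pts$pos >= regions$start[i] &
            pts$pos <= regions$end[i])
    }, logical(1))
    got <- dsm_coverage(regions, pts)
    expect_equal(got$n_dsms_covered, sum(inside))
    expect_equal(got$n_regions_with_dsm, sum(covered))
  }
})

test_that("deleterious YC-mutation enrichment has the hypergeometric null", {
  frs <- data.frame(chrom = "chr1", start = 1000, end = 6000)
  yc <- data.frame(chrom = "chr1", pos = seq(1500, 99500, by = 1000),
                   cadd_phred = 0, fathmm_class = "nondamaging",
                   stringsAsFactors = FALSE)
  # all deleterious: every null equals the in-FR sample size, p = 1
  all_del <- yc; all_del$cadd_phred <- 30
  res <- deleterious_mutation_enrichment(all_del, frs, n_reps = 99, seed = 1)
  k <- sum(yc$pos >= 1000 & yc$pos <= 6000)
  expect_equal(res$observed, k)
  expect_true(all(res$null_values == k))
  expect_equal(res$empirical_p, 1)

  # none deleterious: observed 0, p = 1
  res0 <- deleterious_mutation_enrichment(yc, frs, n_reps = 99, seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$empirical_p, 1)

  # null replicate mean approaches sample_size * global deleterious fraction
  mixed <- yc
  mixed$cadd_phred <- rep(c(30, 0), length.out = nrow(yc))
  res_m <- deleterious_mutation_enrichment(mixed, frs, n_reps = 4000, seed = 2)
  frac <- mean(is_deleterious(mixed))
  expect_equal(mean(res_m$null_values), k * frac, tolerance = 0.15)
})

test_that("deleterious flags honor CADD, FATHMM and their union", {
  m <- data.frame(cadd_phred = c(20, 10, NA, 15),
                  fathmm_class = c("nondamaging", "damaging", NA, "nondamaging"))
  expect_equal(is_deleterious(m, "cadd"), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(is_deleterious(m, "fathmm"), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(is_deleterious(m, "any"), c(TRUE, TRUE, FALSE, FALSE))
})
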