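toy_metadata <- function(burdens_cen, burdens_yc) {
  data.frame(
    sample_id = c(sprintf("C%d", seq_along(burdens_cen)),
                  sprintf("Y%d", seq_along(burdens_yc))),
    group = rep(c("CEN", "YC"), c(length(burdens_cen), length(burdens_yc))),
    age = c(rep(100, length(burdens_cen)), rep(60, length(burdens_yc))),
    stringsAsFactors = FALSE
  )
}

mutations_for_burdens <- function(metadata, burdens) {
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    if (burdens[i] == 0) return(NULL)
    data.frame(sample_id = metadata$sample_id[i], group = metadata$group[i],
               chrom = "chr1", pos = seq_len(burdens[i]) * 100,
               cadd_phred = 0, fathmm_class = "nondamaging",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("Wilcoxon burden comparison matches rank-split enumeration", {
  md <- toy_metadata(burdens_cen = c(1, 2, 3), burdens_yc = c(4, 5, 6))
  m <- mutations_for_burdens(md, c(1, 2, 3, 4, 5, 6))
  b <- burden_summary(m, md)
  expect_equal(b$wilcoxon_p, 0.1)
  expect_equal(b$wilcoxon_p, wilcoxon_enum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(b$group_means, c(CEN = 2, YC = 5))

  # identical groups: p = 1
  md2 <- toy_metadata(c(5, 6, 7), c(5, 6, 7))
  m2 <- mutations_for_burdens(md2, c(5, 6, 7, 5, 6, 7))
  expect_equal(burden_summary(m2, md2)$wilcoxon_p, 1)

  # zero-burden samples are included
  md3 <- toy_metadata(c(0, 2), c(3, 4))
  m3 <- mutations_for_burdens(md3, c(0, 2, 3, 4))
  expect_equal(burden_summary(m3, md3)$per_sample$burden, c(0, 2, 3, 4))

  expect_error(burden_summary(m, md[md$group == "CEN", ]), "0 samples")
})

test_that("Wilcoxon agrees with enumeration on random small samples", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x <- sample.int(1000, 5)
      y <- sample.int(1000, 6)
    })
    md <- toy_metadata(x, y)
    m <- mutations_for_burdens(md, c(x, y))
    expect_equal(burden_summary(m, md)$wilcoxon_p, wilcoxon_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("burden-age correlation recovers exact linear relations", {
  expect_equal(burden_age_correlation(c(10, 20, 30, 40), c(1, 2, 3, 4))$r, 1)
  expect_equal(burden_age_correlation(c(3, 2, 1), c(1, 2, 3))$r, -1)
  expect_error(burden_age_correlation(c(5, 5, 5), c(1, 2, 3)), "zero variance")
  expect_error(burden_age_correlation(c(1, 2), c(1, 2)), "at least 3")

  # independent burdens: r centered at 0 over replicates
  rs <- vapply(1:200, function(s) {
    withr::with_seed(s, burden_age_correlation(rnorm(20), rnorm(20))$r)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 / sqrt(19 * 200))
})

test_that("deleterious ratios cover the degenerate and simulated cases", {
  md <- toy_metadata(c(3, 3), c(3, 3))
  m <- mutations_for_burdens(md, rep(3, 4))
  m$cadd_phred <- 30
  res <- deleterious_ratio(m, md)
  expect_equal(unname(res$group_ratios), c(1, 1))
  expect_equal(res$wilcoxon_p, 1)

  m$cadd_phred <- 0
  expect_equal(unname(deleterious_ratio(m, md)$group_ratios), c(0, 0))

  md0 <- toy_metadata(c(3, 0), c(3, 3))
  m0 <- mutations_for_burdens(md0, c(3, 0, 3, 3))
  expect_warning(res0 <- deleterious_ratio(m0, md0), "zero mutations")
  expect_true(is.na(res0$per_sample$ratio[2]))

  # simulator rates are recovered within binomial error
  cfg <- simulation_config(n_cen = 40, n_yc = 40, burden_mean_cen = 100,
                           burden_mean_yc = 100, n_planted_fr = 0,
                           n_planted_cr = 0,
                           deleterious_rate_background = 0.1, seed = 8)
  co <- simulate_cohort(cfg)
  res_sim <- deleterious_ratio(co$mutations, co$samples)
  n_per_group <- 40 * 100
  tol <- 4 * sqrt(0.1 * 0.9 / n_per_group)
  expect_lt(abs(res_sim$group_ratios["CEN"] - 0.1), tol)
  expect_lt(abs(res_sim$group_ratios["YC"] - 0.1), tol)
})

test_that("partition Fisher tests match the hypergeometric oracle", {
  md <- toy_metadata(rep(1, 4), rep(1, 4))
  # balanced: equal in-category proportions -> p = 1
  m <- rbind(
    mutations_for_burdens(md, rep(1, 8))
  )
  m$compartment <- rep(c("A", "B"), 4)
  res <- partition_fisher(m, "compartment")
  expect_equal(res$p, c(1, 1))

  # pooled-count table equals the closed-form oracle
  m2 <- data.frame(
    sample_id = "X", group = rep(c("CEN", "YC"), c(1000, 1000)),
    chrom = "chr1", pos = 1:2000,
    cat = c(rep("in", 100), rep("out", 900), rep("in", 200), rep("out", 800)),
    stringsAsFactors = FALSE
  )
  res2 <- partition_fisher(m2, "cat")
  want <- fisher_oracle_p(100, 900, 200, 800)
  expect_equal(res2$p[res2$category == "in"], want, tolerance = 1e-12)

  # track-based membership: mutations inside vs outside a GRanges category
  m3 <- mutations_for_burdens(md, rep(2, 8))
  track <- list(reg = data.frame(chrom = "chr1", start = 1, end = 150))
  res3 <- partition_fisher(m3, track)
  expect_equal(res3$cen_in + res3$cen_out, sum(m3$group == "CEN"))
  expect_equal(res3$p, 1)  # identical composition in both groups

  # all mutations in one category: degenerate table, p = 1
  m4 <- m3
  m4$lab <- "only"
  res4 <- partition_fisher(m4, "lab")
  expect_equal(res4$p, 1)

  # empty category is skipped with a warning
  emptyt <- list(void = data.frame(chrom = "chr2", start = 1, end = 2))
  expect_warning(res5 <- partition_fisher(m3, emptyt), "empty partition")
  expect_equal(nrow(res5), 0)
})

test_that("trinucleotide spectrum maps contexts with strand collapse", {
  ref <- Biostrings::DNAStringSet(c(chrT = "AACAGG"))
  # C>A at position 3: context ACA
  m <- data.frame(chrom = "chrT", pos = 3, ref = "C", alt = "A",
                  stringsAsFactors = FALSE)
  sp <- trinucleotide_spectrum(m, ref)
  expect_equal(unname(sp$fractions["A[C>A]A"]), 1)
  expect_equal(sp$n, 1L)

  # G>T at a site whose reverse-complement context is ACA maps identically:
  # TGT on the forward strand, G>T  ->  ACA, C>A
  ref2 <- Biostrings::DNAStringSet(c(chrT = "ATGTAA"))
  m2 <- data.frame(chrom = "chrT", pos = 3, ref = "G", alt = "T",
                   stringsAsFactors = FALSE)
  sp2 <- trinucleotide_spectrum(m2, ref2)
  expect_equal(unname(sp2$fractions["A[C>A]A"]), 1)

  # ref-mismatch is an error naming the offending site
  m_bad <- data.frame(chrom = "chrT", pos = 3, ref = "G", alt = "T",
                      stringsAsFactors = FALSE)
  expect_error(trinucleotide_spectrum(m_bad, ref), "mismatch.*chrT:3")
})

test_that("spectrum normalizes to 1 and is invariant under strand involution", {
  g <- genome_spec("chrA", 20000)
  seqs <- simulate_genome_sequence(g, seed = 4)
  withr::with_seed(9, pos <- sort(sample(2:19999, 500)))
  base <- substring(as.character(seqs[[1]]), pos, pos)
  alt <- vapply(base, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  m <- data.frame(chrom = "chrA", pos = pos, ref = base, alt = alt,
                  stringsAsFactors = FALSE)
  sp <- trinucleotide_spectrum(m, seqs)
  expect_equal(sum(sp$fractions), 1, tolerance = 1e-12)
  expect_equal(sum(sp$counts), nrow(m))

  # reverse-complementing the reference and alleles leaves the spectrum fixed
  rc_seq <- Biostrings::reverseComplement(seqs[[1]])
  rc <- function(x) chartr("ACGT", "TGCA", x)
  m_rc <- data.frame(chrom = "chrA", pos = 20000 + 1 - pos,
                     ref = rc(base), alt = rc(alt), stringsAsFactors = FALSE)
  sp_rc <- trinucleotide_spectrum(m_rc, Biostrings::DNAStringSet(
    stats::setNames(list(rc_seq), "chrA")))
  expect_equal(sp_rc$counts, sp$counts)

  # uniform positions on an i.i.d. uniform reference with uniform alt choice
  # spread mass ~1/6 over each of the six substitution types
  sub_type <- sub("^.\\[(.>.)\\].$", "\\1", names(sp$fractions))
  by_type <- tapply(sp$fractions, sub_type, sum)
  tol <- 4 * sqrt((1 / 6) * (5 / 6) / 500)
  expect_true(all(abs(by_type - 1 / 6) < tol))
})
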