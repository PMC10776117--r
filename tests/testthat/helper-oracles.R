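# Independent brute-force oracles and fixture builders shared across tests.

# O(n^2) single-linkage clustering oracle: build the graph whose edges join
# consecutive sorted positions closer than gap_bp, take connected components,
# keep components of size >= min_size. Returns a list of sorted position
# vectors per cluster, in genomic order, for a single chromosome.
brute_force_clusters <- function(pos, gap_bp = 5000, min_size = 3) {
  pos <- sort(pos)
  n <- length(pos)
  if (n == 0) return(list())
  comp <- seq_len(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (pos[i + 1] - pos[i] < gap_bp) {
        comp[comp == comp[i + 1]] <- comp[i]
      }
    }
  }
  out <- lapply(split(seq_len(n), comp), function(i) pos[i])
  out <- out[vapply(out, length, 1L) >= min_size]
  out[order(vapply(out, min, numeric(1)))]
}

# two-sided Fisher exact p for a 2x2 table, by explicit hypergeometric tail
# sum in log space (lchoose), using the standard rule that includes every
# table whose probability is <= the observed one (up to 1e-7 relative slack)
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[x == a] * (1 + 1e-7)])
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all rank splits
wilcoxon_enum_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  splits <- utils::combn(n, length(x))
  w_all <- apply(splits, 2, function(i) sum(r[i])) -
    length(x) * (length(x) + 1) / 2
  mu <- length(x) * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# O(n*m) all-pairs overlap oracle for 1-based inclusive regions
overlap_count_oracle <- function(regions, track) {
  hits <- 0L
  for (i in seq_len(nrow(regions))) {
    found <- FALSE
    for (j in seq_len(nrow(track))) {
      if (regions$chrom[i] == track$chrom[j] &&
          regions$start[i] <= track$end[j] &&
          regions$end[i] >= track$start[j]) {
        found <- TRUE
        break
      }
    }
    hits <- hits + found
  }
  hits
}

# hand-built filter fixture: 8 records violating exactly one criterion each
# (in criterion order) + 4 clean records, all cohort_site_count preassigned
make_filter_fixture <- function() {
  clean <- function(id, chrom = "chr1", pos) {
    data.frame(sample_id = id, group = "YC", chrom = chrom, pos = pos,
               ref = "A", alt = "T", depth = 40L, alt_reads = 8L,
               vaf = 0.2, filter_flag = "PASS", popmax_af = 0,
               cadd_phred = 5, fathmm_class = "nondamaging",
               cohort_site_count = 1L, stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, lapply(1:12, function(i) clean("S1", pos = i * 100000)))
  m$sample_id <- sprintf("S%02d", 1:12)
  m$filter_flag[1] <- "germline"        # (1) not PASS
  m$chrom[2] <- "chrUn_gl000220"        # (2) not autosome/X
  m$pos[3] <- 5000500                   # (3) inside superdups (see track below)
  m$vaf[4] <- 0.5                       # (4) VAF not < 0.5
  m$alt_reads[4] <- 20L
  m$depth[5] <- 19L                     # (5) depth below 20
  m$vaf[5] <- 8 / 19
  m$alt_reads[6] <- 2L                  # (6) fewer than 3 alt reads
  m$vaf[6] <- 2 / 40
  m$popmax_af[7] <- 0.02                # (7) common in gnomAD
  m$cohort_site_count[8] <- 2L          # (8) recurrent in the cohort
  superdups <- data.frame(chrom = "chr1", start = 5000000, end = 5001000,
                          stringsAsFactors = FALSE)
  list(mutations = m, superdups = superdups)
}

# tiny deterministic cohort with fully hand-controlled cluster structure:
# `spec` rows give chrom, base position, member count, group pattern
make_toy_cohort_mutations <- function(spec, step = 1000) {
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    k <- spec$k[i]
    groups <- strsplit(spec$groups[i], "")[[1]]
    groups <- ifelse(groups == "C", "CEN", "YC")
    stopifnot(length(groups) == k)
    samples <- spec$samples[i]
    sids <- strsplit(samples, ",")[[1]]
    data.frame(
      sample_id = sids, group = groups, chrom = spec$chrom[i],
      pos = spec$base[i] + (seq_len(k) - 1) * step,
      ref = "C", alt = "T", depth = 50L, alt_reads = 10L, vaf = 0.2,
      filter_flag = "PASS", popmax_af = 0, cadd_phred = 1,
      fathmm_class = "nondamaging", stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

toy_genome <- function() genome_spec(c("chr1", "chr2"), c(1e6, 1e6))
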