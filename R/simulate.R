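#' Configuration for the synthetic two-group cohort generator
#'
#' The defaults encode the study design the pipeline targets: 73 centenarians
#' (CEN) and 51 younger controls (YC), all female, with Poisson background
#' burdens of 950 and 881 SSBS per sample respectively, on a three-chromosome
#' 10 Mb toy genome. Group-exclusive mutation clusters are planted as ground
#' truth: `n_planted_fr` regions receiving only YC mutations (future CSM-FRs)
#' and `n_planted_cr` regions receiving only CEN mutations (CSM-CRs).
#'
#' @param genome A `csmfr_genome`; default [default_genome()].
#' @param n_cen,n_yc Sample counts per group.
#' @param burden_mean_cen,burden_mean_yc Poisson mean background mutations per
#'   sample.
#' @param age_mean_cen,age_sd_cen,age_mean_yc,age_sd_yc Normal age parameters
#'   per group (years).
#' @param n_planted_fr,n_planted_cr Numbers of planted YC-only / CEN-only
#'   cluster regions.
#' @param planted_width_bp Width of each planted region (bp). Must stay below
#'   the clustering gap so planted members always chain.
#' @param planted_muts_per_region Mutations planted per region (>= 3).
#' @param vaf_beta_cen,vaf_beta_yc Beta shape parameters `c(alpha, beta)` for
#'   the latent per-call VAF in each group; default Beta(2, 18), mean 0.1.
#' @param depth_range Min/max simulated read depth.
#' @param deleterious_rate_background,deleterious_rate_planted Probability a
#'   background / planted mutation is simulated as deleterious (CADD PHRED
#'   > 15 and FATHMM damaging).
#' @param track_specs Named list of annotation-track specifications passed to
#'   [simulate_tracks()]; `NULL` for no tracks.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated `csmfr_simconfig` list.
#' @export
simulation_config <- function(genome = default_genome(),
                              n_cen = 73, n_yc = 51,
                              burden_mean_cen = 950, burden_mean_yc = 881,
                              age_mean_cen = 100.5, age_sd_cen = 3.7,
                              age_mean_yc = 60.3, age_sd_yc = 7.8,
                              n_planted_fr = 5, n_planted_cr = 7,
                              planted_width_bp = 3500,
                              planted_muts_per_region = 4,
                              vaf_beta_cen = c(2, 18), vaf_beta_yc = c(2, 18),
                              depth_range = c(20, 120),
                              deleterious_rate_background = 0.05,
                              deleterious_rate_planted = 0.2,
                              track_specs = NULL,
                              seed = 1L) {
  genome <- assert_genome(genome)
  cfg <- list(
    genome = genome, n_cen = n_cen, n_yc = n_yc,
    burden_mean_cen = burden_mean_cen, burden_mean_yc = burden_mean_yc,
    age_mean_cen = age_mean_cen, age_sd_cen = age_sd_cen,
    age_mean_yc = age_mean_yc, age_sd_yc = age_sd_yc,
    n_planted_fr = n_planted_fr, n_planted_cr = n_planted_cr,
    planted_width_bp = planted_width_bp,
    planted_muts_per_region = planted_muts_per_region,
    vaf_beta_cen = vaf_beta_cen, vaf_beta_yc = vaf_beta_yc,
    depth_range = depth_range,
    deleterious_rate_background = deleterious_rate_background,
    deleterious_rate_planted = deleterious_rate_planted,
    track_specs = track_specs, seed = as.integer(seed)
  )
  counts <- c(cfg$n_cen, cfg$n_yc, cfg$n_planted_fr, cfg$n_planted_cr,
              cfg$burden_mean_cen, cfg$burden_mean_yc)
  if (any(counts < 0)) stop("all counts and burden means must be >= 0")
  if ((cfg$n_planted_fr > 0 || cfg$n_planted_cr > 0) &&
      cfg$planted_muts_per_region < 3) {
    stop("planted_muts_per_region must be >= 3 when regions are planted")
  }
  if (cfg$planted_width_bp < cfg$planted_muts_per_region) {
    stop("planted_width_bp too small for planted_muts_per_region distinct positions")
  }
  if (cfg$n_planted_fr > 0 && cfg$n_yc == 0) stop("planted FRs require YC samples")
  if (cfg$n_planted_cr > 0 && cfg$n_cen == 0) stop("planted CRs require CEN samples")
  n_regions <- cfg$n_planted_fr + cfg$n_planted_cr
  if (n_regions * cfg$planted_width_bp > 0.5 * sum(genome$length)) {
    stop("planted regions cannot fit in the genome: ",
         "total planted width exceeds half the genome")
  }
  if (cfg$planted_width_bp > max(genome$length)) {
    stop("planted regions cannot fit in the genome: wider than every chromosome")
  }
  if (cfg$depth_range[1] < 1 || cfg$depth_range[2] < cfg$depth_range[1]) {
    stop("invalid depth_range")
  }
  structure(cfg, class = "csmfr_simconfig")
}

# sample chromosome index proportional to number of valid start positions
sample_chrom_idx <- function(genome, n, width = 1) {
  valid <- pmax(genome$length - width + 1, 0)
  if (sum(valid) == 0) stop("no chromosome can hold a region of width ", width)
  sample.int(nrow(genome), n, replace = TRUE, prob = valid)
}

place_disjoint_regions <- function(genome, n, width) {
  if (n == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                       stringsAsFactors = FALSE)
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > 1000L * n) {
      stop("planted regions cannot fit in the genome without overlap")
    }
    ci <- sample_chrom_idx(genome, 1, width)
    start <- sample.int(genome$length[ci] - width + 1, 1)
    end <- start + width - 1
    same <- placed$chrom == genome$chrom[ci]
    if (any(same & placed$start <= end & placed$end >= start)) next
    placed <- rbind(placed, data.frame(chrom = genome$chrom[ci], start = start,
                                       end = end, stringsAsFactors = FALSE))
  }
  placed
}

# positions within [start, end], all adjacent gaps < max_gap
sample_clustered_positions <- function(start, end, k, max_gap = 5000) {
  width <- end - start + 1
  for (i in 1:100) {
    pos <- sort(sample.int(width, k)) + start - 1
    if (k == 1 || max(diff(pos)) < max_gap) return(pos)
  }
  stop("could not place ", k, " positions with adjacent gaps < ", max_gap,
       " in a region of width ", width)
}

simulate_call_fields <- function(n, group, cfg, deleterious_rate) {
  shapes <- if (identical(group, "CEN")) cfg$vaf_beta_cen else cfg$vaf_beta_yc
  depth <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n, replace = TRUE)
  vaf_latent <- stats::rbeta(n, shapes[1], shapes[2])
  # clamp alt support into the filter envelope (>= 3 reads, VAF < 0.5) so the
  # generator's truth labels survive the variant filter unchanged
  alt <- stats::rbinom(n, depth, vaf_latent)
  alt <- as.integer(pmin(pmax(alt, 3), floor((depth - 1) / 2)))
  depth <- as.integer(depth)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt_allele <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  del <- stats::runif(n) < deleterious_rate
  data.frame(
    ref = ref, alt = alt_allele, depth = depth, alt_reads = alt,
    vaf = alt / depth, filter_flag = "PASS", popmax_af = 0,
    cadd_phred = round(ifelse(del, 15 + stats::runif(n, 0.5, 25),
                              stats::runif(n, 0, 14.5)), 3),
    fathmm_class = ifelse(del, "damaging", "nondamaging"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a two-group somatic-mutation cohort with planted clusters
#'
#' Background mutations are placed uniformly per chromosome (chromosome chosen
#' proportional to length), with per-sample counts Poisson-distributed around
#' the group mean. Planted regions receive `planted_muts_per_region` mutations
#' each, drawn only from YC samples (FR regions) or only from CEN samples
#' (CR regions), assigned to distinct samples where possible, with adjacent
#' gaps below 5 kb so each planted region forms one detectable cluster.
#' Background mutations falling inside a planted region of the opposite
#' class, or within chaining distance (5 kb) of one, are rejected and
#' resampled, keeping truth labels unambiguous. Fully reproducible from
#' `config$seed`.
#'
#' @param config A `csmfr_simconfig` from [simulation_config()].
#' @return A `csmfr_cohort` list: `mutations` (one row per call), `samples`
#'   (metadata), `truth` (planted regions with `cls`), `tracks` (named list of
#'   `GRanges`, possibly empty), `genome`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "csmfr_simconfig")) {
    stop("`config` must come from simulation_config()")
  }
  cfg <- config
  genome <- cfg$genome
  seeds <- child_seeds(cfg$seed, 4)

  samples <- withr::with_seed(seeds[1], {
    ids <- c(sprintf("CEN%03d", seq_len(cfg$n_cen)),
             sprintf("YC%03d", seq_len(cfg$n_yc)))
    grp <- c(rep("CEN", cfg$n_cen), rep("YC", cfg$n_yc))
    age <- round(c(stats::rnorm(cfg$n_cen, cfg$age_mean_cen, cfg$age_sd_cen),
                   stats::rnorm(cfg$n_yc, cfg$age_mean_yc, cfg$age_sd_yc)), 1)
    data.frame(sample_id = ids, group = grp, age = age, stringsAsFactors = FALSE)
  })

  truth <- withr::with_seed(seeds[2], {
    tr <- place_disjoint_regions(genome, cfg$n_planted_fr + cfg$n_planted_cr,
                                 cfg$planted_width_bp)
    if (nrow(tr)) {
      tr$cls <- rep(c("CSM_FR", "CSM_CR"), c(cfg$n_planted_fr, cfg$n_planted_cr))
      tr$region_id <- sprintf("planted_%02d", seq_len(nrow(tr)))
    } else {
      tr$cls <- character(0); tr$region_id <- character(0)
    }
    tr
  })

  planted <- withr::with_seed(seeds[3], {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      grp <- if (truth$cls[i] == "CSM_FR") "YC" else "CEN"
      pool <- samples$sample_id[samples$group == grp]
      k <- cfg$planted_muts_per_region
      pos <- sample_clustered_positions(truth$start[i], truth$end[i], k)
      ids <- if (k <= length(pool)) sample(pool, k) else
        sample(pool, k, replace = TRUE)
      cbind(
        data.frame(sample_id = ids, group = grp, chrom = truth$chrom[i],
                   pos = pos, stringsAsFactors = FALSE),
        simulate_call_fields(k, grp, cfg, cfg$deleterious_rate_planted),
        data.frame(planted = TRUE, region_id = truth$region_id[i],
                   stringsAsFactors = FALSE)
      )
    })
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  background <- withr::with_seed(seeds[4], {
    counts <- stats::rpois(
      nrow(samples),
      ifelse(samples$group == "CEN", cfg$burden_mean_cen, cfg$burden_mean_yc)
    )
    n <- sum(counts)
    if (n == 0) NULL else {
      sid <- rep(samples$sample_id, counts)
      grp <- rep(samples$group, counts)
      ci <- sample_chrom_idx(genome, n)
      pos <- floor(stats::runif(n) * genome$length[ci]) + 1
      # resample draws landing inside (or within chaining distance of) an
      # opposite-class planted region, so planted clusters stay group-pure
      buf <- 5000
      forbidden <- function(grp, chrom, pos) {
        bad <- rep(FALSE, length(pos))
        for (i in seq_len(nrow(truth))) {
          opp <- if (truth$cls[i] == "CSM_FR") "CEN" else "YC"
          bad <- bad | (grp == opp & chrom == truth$chrom[i] &
                          pos >= truth$start[i] - buf &
                          pos <= truth$end[i] + buf)
        }
        bad
      }
      bad <- forbidden(grp, genome$chrom[ci], pos)
      while (any(bad)) {
        ci[bad] <- sample_chrom_idx(genome, sum(bad))
        pos[bad] <- floor(stats::runif(sum(bad)) * genome$length[ci[bad]]) + 1
        bad <- forbidden(grp, genome$chrom[ci], pos)
      }
      fields <- simulate_call_fields(n, "CEN", cfg, cfg$deleterious_rate_background)
      yc <- which(grp == "YC")
      if (length(yc)) {
        fields[yc, ] <- simulate_call_fields(length(yc), "YC", cfg,
                                             cfg$deleterious_rate_background)
      }
      cbind(
        data.frame(sample_id = sid, group = grp, chrom = genome$chrom[ci],
                   pos = pos, stringsAsFactors = FALSE),
        fields,
        data.frame(planted = FALSE, region_id = NA_character_,
                   stringsAsFactors = FALSE)
      )
    }
  })

  mutations <- rbind(planted, background)
  if (is.null(mutations)) {
    mutations <- cbind(empty_mutation_table(),
                       data.frame(group = character(0), popmax_af = numeric(0),
                                  cadd_phred = numeric(0),
                                  fathmm_class = character(0),
                                  planted = logical(0),
                                  region_id = character(0)))
  }
  mutations <- mutations[order(mutations$sample_id, mutations$chrom,
                               mutations$pos), ]
  rownames(mutations) <- NULL

  tracks <- if (is.null(cfg$track_specs)) list() else
    simulate_tracks(genome, cfg$track_specs, seed = child_seeds(cfg$seed, 5)[5],
                    planted_regions = truth)

  structure(
    list(mutations = mutations, samples = samples, truth = truth,
         tracks = tracks, genome = genome, config = cfg),
    class = "csmfr_cohort"
  )
}

#' @export
print.csmfr_cohort <- function(x, ...) {
  cat("csmfr synthetic cohort:",
      sum(x$samples$group == "CEN"), "CEN +",
      sum(x$samples$group == "YC"), "YC samples;",
      nrow(x$mutations), "mutations;",
      sum(x$truth$cls == "CSM_FR"), "planted FR +",
      sum(x$truth$cls == "CSM_CR"), "planted CR regions;",
      length(x$tracks), "tracks\n")
  invisible(x)
}

#' Simulate non-overlapping annotation tracks
#'
#' Each track covers approximately `density` of the genome: per chromosome,
#' `n = round(density * L / mean_width)` intervals with widths
#' `1 + Poisson(mean_width - 1)` are placed by uniform stick-breaking of the
#' residual gap space, so intervals never overlap and total coverage has mean
#' `n * mean_width` and variance `n * (mean_width - 1)`. Optionally, planted
#' regions are enriched at a configurable odds ratio: an extra interval is
#' force-placed over a planted region's midpoint with the probability that
#' lifts its hit odds from the background density to the requested ratio.
#'
#' @param genome A `csmfr_genome`.
#' @param track_specs Named list; each element a list with `density` (genome
#'   fraction in \[0, 1\]), `mean_width` (bp, > 1) and optionally `enrich_or`
#'   (odds ratio of planted-region overlap, default 1 = no enrichment) and
#'   `enrich_cls` (restrict the enrichment to planted regions of one class,
#'   e.g. `"CSM_FR"`; default all).
#' @param seed Integer seed.
#' @param planted_regions Optional region table (e.g. the cohort `truth`) to
#'   enrich. With `enrich_or = 1` it is ignored.
#' @return Named list of `GRanges`, one per track.
#' @export
simulate_tracks <- function(genome, track_specs, seed, planted_regions = NULL) {
  genome <- assert_genome(genome)
  if (is.null(names(track_specs)) || any(names(track_specs) == "")) {
    stop("track_specs must be a named list")
  }
  seeds <- child_seeds(seed, length(track_specs))
  out <- lapply(seq_along(track_specs), function(ti) {
    spec <- track_specs[[ti]]
    density <- spec$density
    if (is.null(density) || density < 0 || density > 1) {
      stop("track density must lie in [0, 1]")
    }
    mean_width <- spec$mean_width %||% 1000
    enrich_or <- spec$enrich_or %||% 1
    withr::with_seed(seeds[ti], {
      per_chrom <- lapply(seq_len(nrow(genome)), function(ci) {
        L <- genome$length[ci]
        n <- round(density * L / mean_width)
        if (n == 0) return(NULL)
        widths <- 1 + stats::rpois(n, mean_width - 1)
        if (sum(widths) >= L) stop("requested track coverage too high for ",
                                   genome$chrom[ci])
        gaps <- diff(c(0, sort(stats::runif(n, 0, L - sum(widths)))))
        starts <- floor(cumsum(gaps)) + c(0, cumsum(widths))[seq_len(n)] + 1
        data.frame(chrom = genome$chrom[ci], start = starts,
                   end = starts + widths - 1, stringsAsFactors = FALSE)
      })
      iv <- do.call(rbind, per_chrom)
      if (is.null(iv)) iv <- data.frame(chrom = character(0), start = numeric(0),
                                        end = numeric(0), stringsAsFactors = FALSE)
      if (!is.null(spec$enrich_cls) && !is.null(planted_regions$cls)) {
        planted_regions <- planted_regions[
          planted_regions$cls %in% spec$enrich_cls, , drop = FALSE]
      }
      if (enrich_or != 1 && !is.null(planted_regions) && nrow(planted_regions)) {
        p0 <- min(density, 0.99)
        p1 <- enrich_or * p0 / (1 - p0 + enrich_or * p0)
        p_extra <- max(0, (p1 - p0) / (1 - p0))
        hit <- stats::runif(nrow(planted_regions)) < p_extra
        if (any(hit)) {
          mid <- floor((planted_regions$start + planted_regions$end) / 2)[hit]
          chrom <- planted_regions$chrom[hit]
          L <- genome_lengths(genome)[chrom]
          half <- floor(mean_width / 2)
          iv <- rbind(iv, data.frame(
            chrom = chrom,
            start = pmax(1, mid - half),
            end = pmin(L, mid + half),
            stringsAsFactors = FALSE
          ))
        }
      }
      GenomicRanges::reduce(regions_to_granges(iv, genome = genome))
    })
  })
  stats::setNames(out, names(track_specs))
}

#' Write a simulated cohort to disk
#'
#' One VCF per sample (including zero-burden samples), one BED per track, TSV
#' sample metadata, a BED of planted truth regions (class in the name column)
#' and a TSV of per-variant annotations (gnomAD-style popmax AF, CADD PHRED,
#' FATHMM class). [read_cohort()] inverts this exactly for position, alleles,
#' depth, alt count, sample, group and annotations.
#'
#' @param dataset A `csmfr_cohort`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(dataset, out_dir) {
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  ok <- dir.exists(file.path(out_dir, "vcf"))
  if (!ok) stop("cannot create output directory: ", out_dir)
  utils::write.table(dataset$genome, file.path(out_dir, "genome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_metadata(dataset$samples, file.path(out_dir, "metadata.tsv"))
  for (sid in dataset$samples$sample_id) {
    m <- dataset$mutations[dataset$mutations$sample_id == sid, , drop = FALSE]
    write_sample_vcf(m, file.path(out_dir, "vcf", paste0(sid, ".vcf")),
                     genome = dataset$genome, sample_id = sid)
  }
  ann <- dataset$mutations[, c("sample_id", "chrom", "pos", "ref", "alt",
                               "popmax_af", "cadd_phred", "fathmm_class",
                               "planted", "region_id")]
  utils::write.table(ann, file.path(out_dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(dataset$truth, file.path(out_dir, "truth.bed"))
  if (length(dataset$tracks)) {
    dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
    for (nm in names(dataset$tracks)) {
      write_bed(granges_to_regions(dataset$tracks[[nm]]),
                file.path(out_dir, "tracks", paste0(nm, ".bed")))
    }
  }
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `csmfr_cohort` (without the generating config).
#' @export
read_cohort <- function(dir) {
  genome <- do.call(genome_spec, unname(utils::read.delim(
    file.path(dir, "genome.tsv"), stringsAsFactors = FALSE)))
  samples <- read_metadata(file.path(dir, "metadata.tsv"))
  muts <- do.call(rbind, lapply(samples$sample_id, function(sid) {
    read_vcf(file.path(dir, "vcf", paste0(sid, ".vcf")), sample_id = sid)
  }))
  muts$group <- samples$group[match(muts$sample_id, samples$sample_id)]
  ann_path <- file.path(dir, "annotations.tsv")
  if (file.exists(ann_path)) {
    ann <- utils::read.delim(ann_path, stringsAsFactors = FALSE)
    key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt)
    i <- match(key(muts), key(ann))
    for (col in setdiff(names(ann), c("sample_id", "chrom", "pos", "ref", "alt"))) {
      muts[[col]] <- ann[[col]][i]
    }
  }
  muts <- muts[order(muts$sample_id, muts$chrom, muts$pos), ]
  rownames(muts) <- NULL
  truth_path <- file.path(dir, "truth.bed")
  truth <- if (file.exists(truth_path) && file.size(truth_path) > 0) {
    tr <- read_bed(truth_path)
    names(tr)[names(tr) == "name"] <- "cls"
    tr
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               cls = character(0), stringsAsFactors = FALSE)
  }
  track_files <- list.files(file.path(dir, "tracks"), pattern = "\\.bed$",
                            full.names = TRUE)
  tracks <- read_tracks(stats::setNames(track_files,
                                        sub("\\.bed$", "", basename(track_files))),
                        genome = genome)
  structure(list(mutations = muts, samples = samples, truth = truth,
                 tracks = tracks, genome = genome, config = NULL),
            class = "csmfr_cohort")
}
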