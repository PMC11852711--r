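# Synthetic cohort generator: libraries, cohorts, counts, reads, MS tables.

test_that("generated libraries satisfy the motif invariants", {
  cfg <- sim_config(n_aptamers = 30L, n_families = 2L, fraction_in_families = 1 / 3,
                    family_motif_length = 8L, variable_region_length = 20L,
                    collision_guard = 8L, seed = 1L)
  lib <- generate_library(cfg)
  apt <- lib$aptamers
  expect_equal(nrow(apt), 30L)
  expect_false(anyDuplicated(apt$sequence) > 0)
  expect_true(all(nchar(apt$sequence) == 20L))

  in_fam <- !is.na(apt$family_id)
  expect_equal(sum(in_fam), 10L)
  # every family member carries its motif verbatim
  expect_true(all(mapply(grepl, apt$motif[in_fam], apt$sequence[in_fam],
                         MoreArgs = list(fixed = TRUE))))
  # singletons carry no planted motif
  motifs <- unique(apt$motif[in_fam])
  for (m in motifs) {
    expect_false(any(grepl(m, apt$sequence[!in_fam], fixed = TRUE)))
  }
})

test_that("library generation is deterministic in the seed", {
  cfg <- sim_config(n_aptamers = 20L, n_families = 2L, fraction_in_families = 0.5,
                    seed = 42L)
  expect_identical(generate_library(cfg), generate_library(cfg))
  cfg2 <- sim_config(n_aptamers = 20L, n_families = 2L, fraction_in_families = 0.5,
                     seed = 43L)
  expect_false(identical(generate_library(cfg)$aptamers$sequence,
                         generate_library(cfg2)$aptamers$sequence))
})

test_that("a familyless library shares no long substrings across sequences", {
  cfg <- sim_config(n_aptamers = 50L, n_families = 0L, fraction_in_families = 0,
                    seed = 9L)
  lib <- generate_library(cfg)
  seqs <- lib$aptamers$sequence
  # brute-force pairwise scan at the guard length
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in (i + 1L):length(seqs)) {
      expect_lt(brute_lcs_length(seqs[i], seqs[j]), 12L)
    }
  }
})

test_that("cohorts map fibrosis stages to groups and keep covariates positive", {
  expect_equal(map_fibrosis_group(c(0, 1, 2, 3, 4)),
               c("F0", "F1_2", "F1_2", "F3_4", "F3_4"))
  expect_error(map_fibrosis_group(5), "0\\.\\.4")

  cfg <- sim_config(group_sizes = c(healthy = 200L, MASLD_no_SH = 400L, MASH = 400L),
                    seed = 11L)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 1000L)
  expect_equal(as.vector(table(coh$steatohepatitis_group)[c("healthy", "MASLD_no_SH", "MASH")]),
               c(200L, 400L, 400L))
  expect_identical(coh$fibrosis_group, map_fibrosis_group(coh$fibrosis_stage))
  expect_true(all(coh$AST > 0))
  expect_true(all(coh$ALT > 0))
  expect_true(all(coh$platelets > 0))
  expect_true(all(coh$library_size > 0))
  # healthy controls have no fibrosis
  expect_true(all(coh$fibrosis_stage[coh$steatohepatitis_group == "healthy"] == 0L))
  expect_identical(coh, generate_cohort(cfg))
})

test_that("simulated counts follow the generative means in the Poisson limit", {
  cfg <- sim_config(n_aptamers = 40L, n_families = 2L, fraction_in_families = 0.25,
                    group_sizes = c(healthy = 0L, MASLD_no_SH = 200L, MASH = 0L),
                    nb_dispersion = 0, library_size_range = c(5e4, 5e4),
                    seed = 3L)
  b <- simulate_bundle(cfg)
  p <- b$truth$expected_proportions[1L, ]  # identical across this one-group cohort
  mu <- 5e4 * p
  obs <- colMeans(b$counts$counts)
  se <- sqrt(mu / 200)
  expect_true(all(abs(obs - mu) < 3 * se + 1e-9))
})

test_that("null effects give balanced groups and counts are reproducible", {
  cfg <- small_config(seed = 5L, effect_log2fc = 0)
  b <- simulate_bundle(cfg)
  expect_identical(b$counts$counts,
                   simulate_counts(b$lib, b$cohort, cfg)$counts)
  ab <- normalize_log2cpm(b$counts)
  ctr <- default_contrast(b$cohort)
  d <- colMeans(ab[ctr$samples_B, ]) - colMeans(ab[ctr$samples_A, ])
  expect_lt(abs(mean(d)), 0.25)
  expect_length(b$truth$discriminative, 0L)
})

test_that("simulated reads reproduce counts exactly at error rate zero", {
  cfg <- sim_config(n_aptamers = 5L, n_families = 0L, fraction_in_families = 0,
                    group_sizes = c(healthy = 0L, MASLD_no_SH = 2L, MASH = 0L),
                    seed = 2L)
  lib <- generate_library(cfg)
  counts <- apta_counts(matrix(c(3L, 0L, 1L, 2L, 0L,
                                 0L, 4L, 0L, 0L, 1L), 2L, 5L, byrow = TRUE),
                        sample_ids = c("s1", "s2"),
                        aptamer_ids = lib$aptamers$aptamer_id)
  out <- withr::local_tempdir()
  paths <- simulate_reads(counts, lib, cfg, out)
  lines <- readLines(paths[["s1"]])
  expect_length(lines, 4L * 6L)
  reads <- lines[seq(2L, length(lines), by = 4L)]
  seq1 <- lib$aptamers$sequence[1L]
  expect_equal(sum(grepl(seq1, reads, fixed = TRUE)), 3L)
  expect_true(all(startsWith(reads, cfg$primer_5p)))
  expect_true(all(endsWith(reads, cfg$primer_3p)))
})

test_that("the sequencing error rate produces the configured base error fraction", {
  cfg <- sim_config(n_aptamers = 25L, n_families = 0L, fraction_in_families = 0,
                    group_sizes = c(healthy = 0L, MASLD_no_SH = 1L, MASH = 0L),
                    library_size_range = c(2000, 2000),
                    sequencing_error_rate = 0.01, seed = 8L)
  lib <- generate_library(cfg)
  coh <- generate_cohort(cfg)
  counts <- simulate_counts(lib, coh, cfg)
  out <- withr::local_tempdir()
  paths <- simulate_reads(counts, lib, cfg, out)
  lines <- readLines(paths[[1L]])
  reads <- lines[seq(2L, length(lines), by = 4L)]
  truth <- paste0(cfg$primer_5p,
                  rep(lib$aptamers$sequence, times = counts$counts[1L, ]),
                  cfg$primer_3p)
  n_diff <- sum(mapply(function(r, t) {
    sum(utf8ToInt(r) != utf8ToInt(t))
  }, reads, truth))
  n_bases <- sum(nchar(truth))
  expect_gt(n_bases, 1e5)
  # 99% binomial bounds around rate 0.01
  bounds <- qbinom(c(0.005, 0.995), n_bases, 0.01)
  expect_gte(n_diff, bounds[1L])
  expect_lte(n_diff, bounds[2L])
})

test_that("MS tables are non-negative with positive run totals and a noiseless table is fully recoverable", {
  truth <- stats::setNames(rep(c("CFH", "FN1", "ITIH2"), length.out = 12L),
                           sprintf("apt_%02d", 1:12))
  ms0 <- simulate_ms_table(truth, noise_sd = 0, dominant_share = c(0.6, 0.6),
                           seed = 4L)
  expect_true(all(ms0$intensities >= 0))
  expect_true(all(colSums(ms0$intensities) > 0))
  expect_equal(nrow(ms0$run_info), 36L)
  assigned <- assign_targets(normalize_and_aggregate(ms0))
  expect_identical(stats::setNames(assigned$primary_target, assigned$aptamer_id),
                   truth[assigned$aptamer_id])
})
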