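# Normalization, alignment, OLS, BH and panel selection.

test_that("log2-CPM follows the stated formula and its invariances", {
  mat <- matrix(c(0L, 1000L, 999000L,
                  0L, 2000L, 1998000L), 2L, 3L, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  ab <- normalize_log2cpm(apta_counts(mat))
  expect_equal(ab["s1", "a"], 0)                      # zero count -> log2(1) = 0
  expect_equal(ab["s1", "b"], log2(1000 + 1))          # 1000 of 1e6 -> ~9.9672
  expect_equal(round(ab["s1", "b"], 4), 9.9672)
  # doubling all counts in a sample leaves CPM values unchanged
  expect_equal(ab["s1", ], ab["s2", ])

  zero <- apta_counts(matrix(c(0L, 0L, 0L, 4L), 2L, 2L, byrow = TRUE,
                             dimnames = list(c("s1", "s2"), c("a", "b"))))
  expect_error(normalize_log2cpm(zero), "s1")
})

test_that("median alignment removes a common per-sample offset", {
  set.seed(42)
  base <- matrix(rnorm(200, 8, 1), 10L, 20L,
                 dimnames = list(sprintf("s%d", 1:10), sprintf("a%d", 1:20)))
  shift <- seq(-1, 1, length.out = 10L)
  shifted <- base + shift
  ref <- apply(base, 2L, median)
  aligned <- align_abundance(shifted, reference = ref)
  # the per-sample offsets absorb the injected shift on top of the base ones
  expect_equal(unname(attr(aligned, "size_log2")),
               unname(shift + attr(align_abundance(base, ref), "size_log2")))
  # alignment of the shifted matrix equals alignment of the clean one
  expect_equal(unclass(aligned), unclass(align_abundance(base, ref)),
               ignore_attr = TRUE)
})

test_that("median dichotomization splits at the cutoff with at-or-above going positive", {
  meta <- data.frame(sample_id = sprintf("s%d", 1:4), LDL = c(2, 3, 4, 5))
  ctr <- dichotomize_by_median(meta, "LDL")
  expect_equal(ctr$cutoff, 3.5)
  expect_equal(ctr$samples_A, c("s1", "s2"))
  expect_equal(ctr$samples_B, c("s3", "s4"))
  # value exactly at the cutoff goes to level_B
  meta2 <- data.frame(sample_id = sprintf("s%d", 1:3), v = c(1, 2, 3))
  ctr2 <- dichotomize_by_median(meta2, "v")
  expect_true("s2" %in% ctr2$samples_B)
  # a fixed (training) cutoff can be applied elsewhere
  ctr3 <- dichotomize_by_median(meta, "LDL", cutoff = 2.5)
  expect_equal(ctr3$cutoff, 2.5)
  expect_equal(ctr3$samples_A, "s1")
  expect_equal(length(ctr3$samples_B), 3L)
  meta$LDL <- NA_real_
  expect_error(dichotomize_by_median(meta, "LDL"), "non-missing")
})

test_that("two-group OLS equals the textbook pooled t-test", {
  ab <- matrix(c(1, 2, 3, 3, 4, 5), 6L, 1L,
               dimnames = list(sprintf("s%d", 1:6), "a"))
  ctr <- new_test_contrast(sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  fit <- fit_two_group_ols(ab, ctr)
  expect_equal(fit$coefficient, 2.0)

  set.seed(11)
  for (i in 1:25) {
    nA <- sample(3:12, 1L)
    nB <- sample(3:12, 1L)
    m <- matrix(rnorm((nA + nB) * 4L), nA + nB, 4L,
                dimnames = list(sprintf("s%d", seq_len(nA + nB)),
                                sprintf("a%d", 1:4)))
    ctr <- new_test_contrast(rownames(m)[seq_len(nA)], rownames(m)[nA + seq_len(nB)])
    fit <- fit_two_group_ols(m, ctr)
    for (j in 1:4) {
      tt <- t.test(m[ctr$samples_B, j], m[ctr$samples_A, j], var.equal = TRUE)
      expect_equal(fit$coefficient[j], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
      expect_lt(abs(fit$p_value[j] - tt$p.value), 1e-10)
    }
  }
})

test_that("OLS handles degenerate variance and group-swap antisymmetry", {
  ab <- matrix(c(1, 1, 2, 2, 5, 5, 5, 5), 4L, 2L,
               dimnames = list(sprintf("s%d", 1:4), c("a", "b")))
  ctr <- new_test_contrast(c("s1", "s2"), c("s3", "s4"))
  fit <- fit_two_group_ols(ab, ctr)
  expect_equal(fit$p_value[1L], 0)     # zero variance, nonzero coefficient
  expect_equal(fit$p_value[2L], 1)     # identical groups
  expect_equal(fit$coefficient[2L], 0)

  set.seed(3)
  m <- matrix(rnorm(40), 10L, 4L,
              dimnames = list(sprintf("s%d", 1:10), sprintf("a%d", 1:4)))
  f1 <- fit_two_group_ols(m, new_test_contrast(rownames(m)[1:5], rownames(m)[6:10]))
  f2 <- fit_two_group_ols(m, new_test_contrast(rownames(m)[6:10], rownames(m)[1:5]))
  expect_equal(f1$coefficient, -f2$coefficient)
  expect_equal(f1$p_value, f2$p_value)
  expect_error(fit_two_group_ols(m, new_test_contrast(rownames(m)[1], rownames(m)[2:10])),
               ">= 2 samples")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:200) {
    m <- sample(1:50, 1L)
    p <- round(runif(m), 3)
    adj <- adjust_bh(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("panel membership applies both the coefficient and significance thresholds", {
  res <- data.frame(
    aptamer_id = c("a", "b", "c", "d"),
    coefficient = c(0.30, 0.30, -0.40, 0.10),
    std_error = 0.1,
    p_value = c(0.0005, 0.01, 0.0005, 0.0001)
  )
  # p_adjusted: BH over the 4 p-values
  pan <- select_panel(res, panel_config(alpha = 0.05, coef_threshold = 0.25))
  expect_true(all(c("a", "c") %in% pan$members))
  expect_false("d" %in% pan$members)  # significant p but coefficient below 0.25
  expect_equal(pan$n_up >= 1L && pan$n_down == 1L, TRUE)
  expect_equal(pan$table$direction[pan$table$aptamer_id == "c"], "down")
  # above-alpha adjusted p excludes
  res2 <- data.frame(aptamer_id = "a", coefficient = 0.3, std_error = 0.1,
                     p_value = 0.06)
  expect_length(select_panel(res2)$members, 0L)
})

test_that("two-pass selection recovers planted families without compositional false positives", {
  cfg <- sim_config(seed = 77L)
  b <- simulate_bundle(cfg)
  top <- select_top_k(b$counts, rank_aptamers(b$counts), 500L)
  sel <- select_discriminative(top, default_contrast(b$cohort))
  truth <- b$truth$discriminative
  sens <- mean(truth %in% sel$panel$members)
  fdr <- if (length(sel$panel$members)) mean(!sel$panel$members %in% truth) else 0
  expect_gt(sens, 0.7)
  expect_lt(fdr, 0.2)
  expect_true(all(sel$invariant %in% top$aptamer_ids))
  expect_gt(length(sel$invariant), 400L)
})
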