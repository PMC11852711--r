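# PC1 panel scoring, DeLong AUC, Wilcoxon tests, AUC bands, clinical scores
# and the evaluation table.

make_ab <- function(mat) {
  dimnames(mat) <- list(sprintf("s%d", seq_len(nrow(mat))),
                        sprintf("a%d", seq_len(ncol(mat))))
  mat
}

test_that("PC1 fitting captures rank-1 geometry with the disease-ward orientation", {
  t_ <- c(-2, -1, 0, 1, 2, 3)
  ab <- make_ab(cbind(1 + 2 * t_, 3 - t_))  # data on a line
  model <- fit_panel_projection(ab, c("a1", "a2"), positive = c("s5", "s6"))
  expect_equal(sqrt(sum(model$loading^2)), 1)
  # loading parallel to the line direction (2, -1)/sqrt(5)
  expect_equal(abs(sum(model$loading * c(2, -1) / sqrt(5))), 1, tolerance = 1e-12)
  scores <- project_scores(model, ab)
  # PC1 variance equals total variance for rank-1 data
  expect_equal(var(scores), sum(apply(ab, 2L, var)))
  # positive class scores higher on average
  expect_gt(mean(scores[c("s5", "s6")]), mean(scores[c("s1", "s2")]))
})

test_that("PC1 score variance equals the top eigenvalue of the training covariance", {
  set.seed(5)
  ab <- make_ab(matrix(rnorm(120), 20L, 6L) %*% diag(c(3, 2, 1, 1, 1, 1)))
  model <- fit_panel_projection(ab, colnames(ab), positive = rownames(ab)[1:10])
  scores <- project_scores(model, ab)
  ev <- eigen(cov(ab), symmetric = TRUE)$values
  expect_equal(var(scores), ev[1L], tolerance = 1e-10)
  # duplicating every training sample changes neither center nor loading
  dup <- rbind(ab, ab)
  rownames(dup) <- sprintf("s%d", 1:40)
  model2 <- fit_panel_projection(dup, colnames(ab), positive = rownames(dup)[c(1:10, 21:30)])
  expect_equal(model2$center, model$center)
  expect_equal(abs(sum(model2$loading * model$loading)), 1, tolerance = 1e-10)
})

test_that("projection is centered, linear and reproduces fit-time scores", {
  set.seed(8)
  ab <- make_ab(matrix(rnorm(60), 12L, 5L))
  model <- fit_panel_projection(ab, colnames(ab), positive = rownames(ab)[1:6])
  scores <- project_scores(model, ab)
  expect_equal(mean(scores), 0, tolerance = 1e-12)   # training scores center at 0
  # a sample equal to the center vector scores 0
  center_row <- make_ab(matrix(model$center, 1L, 5L))
  expect_equal(unname(project_scores(model, center_row)), 0, tolerance = 1e-12)
  # adding a constant to one member column shifts scores by c * loading * sign
  ab2 <- ab
  ab2[, 2L] <- ab2[, 2L] + 1.5
  shift <- project_scores(model, ab2) - scores
  expect_equal(unname(shift),
               rep(unname(1.5 * model$loading[2L] * model$orientation), nrow(ab)),
               tolerance = 1e-12)
  expect_error(project_scores(model, ab[, -2L]), "absent")
  expect_error(fit_panel_projection(make_ab(matrix(1, 4L, 2L)), c("a1", "a2"),
                                    positive = c("s1", "s2")), "rank 0")
})

test_that("DeLong AUC matches brute-force pair counting with its symmetries", {
  res <- auc_delong(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(res$auc, 0.75)

  set.seed(23)
  for (i in 1:40) {
    n <- sample(4:30, 1L)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    scores <- sample(round(rnorm(n), 1))  # ties likely
    res <- auc_delong(scores, labels)
    expect_equal(res$auc, auc_oracle(scores, labels))
    flipped <- auc_delong(scores, !labels)
    expect_equal(flipped$auc, 1 - res$auc)
    expect_equal(flipped$variance, res$variance)
    expect_true(res$ci_low <= res$auc && res$auc <= res$ci_high)
    expect_true(res$ci_low >= 0 && res$ci_high <= 1)
  }

  sep <- auc_delong(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$auc, 1)
  expect_equal(sep$variance, 0)
  expect_equal(c(sep$ci_low, sep$ci_high), c(1, 1))
  expect_error(auc_delong(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("DeLong variance and CI agree with the pROC reference implementation", {
  set.seed(47)
  for (i in 1:10) {
    scores <- rnorm(60)
    labels <- rep(c(0L, 1L), each = 30L)
    scores[labels == 1L] <- scores[labels == 1L] + runif(1, 0, 2)
    res <- auc_delong(scores, labels == 1L)
    roc <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    ci <- pROC::ci.auc(roc, method = "delong")
    expect_equal(res$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
    expect_equal(res$variance, as.numeric(pROC::var(roc, method = "delong")),
                 tolerance = 1e-10)
    # pROC uses qnorm(0.975) where this package uses the conventional 1.96
    expect_equal(res$ci_low, max(0, ci[1L]), tolerance = 1e-4)
    expect_equal(res$ci_high, min(1, ci[3L]), tolerance = 1e-4)
  }
})

test_that("AUC and Wilcoxon p are invariant under monotone score transforms", {
  set.seed(31)
  scores <- rnorm(30)
  labels <- rep(c(TRUE, FALSE), 15L)
  mono <- function(x) exp(3 * x) + 2
  expect_equal(auc_delong(mono(scores), labels)$auc,
               auc_delong(scores, labels)$auc)
  expect_equal(wilcoxon_test(mono(scores[labels]), mono(scores[!labels]))$p_value,
               wilcoxon_test(scores[labels], scores[!labels])$p_value)
})

test_that("Wilcoxon test uses exact enumeration for small untied samples", {
  res <- wilcoxon_test(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3)   # 2 / choose(4, 2)
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # agrees with stats::wilcox.test on larger samples
  set.seed(2)
  a <- rnorm(25)
  b <- rnorm(25, 0.7)
  expect_equal(wilcoxon_test(a, b)$p_value,
               stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
})

test_that("AUC qualification bands resolve boundaries upward", {
  expect_equal(classify_auc(0.83), "excellent")
  expect_equal(classify_auc(0.72), "acceptable")
  expect_equal(classify_auc(0.50), "below_acceptable")
  expect_equal(classify_auc(c(0.70, 0.80, 0.90, 1.0)),
               c("acceptable", "excellent", "outstanding", "outstanding"))
  expect_error(classify_auc(1.2), "\\[0, 1\\]")
})

test_that("clinical comparator scores follow the standard formulas", {
  meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                     age = c(50, 60, 40), AST = c(25, 40, 30),
                     ALT = c(30, 40, 50), platelets = c(250, NA, 200))
  cs <- clinical_scores(meta)
  expect_equal(round(cs$fib4[1L], 4), 0.9129)
  expect_equal(cs$ast_alt_ratio[2L], 1.0)
  expect_true(is.na(cs$fib4[2L]))          # missing platelets -> missing FIB-4
  expect_false(is.na(cs$ast_alt_ratio[2L]))
  meta$ALT[1L] <- 0
  expect_error(clinical_scores(meta), "s1")
})

test_that("evaluation tables preserve N/A rows and detect planted effects", {
  cfg <- sim_config(seed = 55L, effect_log2fc = 2.0,
                    group_sizes = c(healthy = 0L, MASLD_no_SH = 20L, MASH = 20L))
  b <- simulate_bundle(cfg)
  top <- select_top_k(b$counts, rank_aptamers(b$counts), 500L)
  ctr <- default_contrast(b$cohort)
  sel <- select_discriminative(top, ctr)
  model <- fit_panel_projection(sel$abundance, sel$panel, positive = ctr$samples_B)
  cohorts <- list(dev = list(abundance = sel$abundance, metadata = b$cohort),
                  dev_again = list(abundance = sel$abundance, metadata = b$cohort))
  comparisons <- list(
    noSH_vs_MASH = list(variable = "steatohepatitis_group",
                        level_A = "MASLD_no_SH", level_B = "MASH"),
    healthy_vs_noSH = list(variable = "steatohepatitis_group",
                           level_A = "healthy", level_B = "MASLD_no_SH")
  )
  ev <- evaluate_comparisons(model, cohorts, comparisons)
  expect_equal(nrow(ev), 4L)  # every cohort x comparison, N/A rows included
  strong <- ev[ev$cohort == "dev" & ev$comparison == "noSH_vs_MASH", ]
  expect_gte(strong$auc, 0.9)
  na_row <- ev[ev$cohort == "dev" & ev$comparison == "healthy_vs_noSH", ]
  expect_true(is.na(na_row$auc))
  expect_equal(na_row$note, "empty class")  # no healthy samples in this cohort
  # identical cohorts under two names give identical rows
  expect_equal(ev[ev$cohort == "dev", -1L], ev[ev$cohort == "dev_again", -1L],
               ignore_attr = TRUE)
})

test_that("permuted labels give a null AUC distribution centered at one half", {
  cfg <- sim_config(seed = 66L, effect_log2fc = 0,
                    group_sizes = c(healthy = 0L, MASLD_no_SH = 40L, MASH = 40L))
  b <- simulate_bundle(cfg)
  top <- select_top_k(b$counts, rank_aptamers(b$counts), 100L)
  ab <- normalize_log2cpm(top)
  model <- fit_panel_projection(ab, colnames(ab)[1:20],
                                positive = b$cohort$sample_id[b$cohort$steatohepatitis_group == "MASH"])
  scores <- project_scores(model, ab)
  set.seed(1)
  aucs <- replicate(200, {
    auc_delong(scores, sample(rep(c(TRUE, FALSE), each = 40L)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
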