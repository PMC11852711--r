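# PC1 panel scoring (train once, apply anywhere), Mann-Whitney AUC with
# DeLong variance and confidence intervals, Wilcoxon tests, comparator
# clinical scores and the cohort x comparison evaluation table.

#' Fit the panel's PC1 scoring model
#'
#' Centers the panel submatrix at the training column means and takes the
#' first right singular vector of the centered matrix as the loading (unit
#' Euclidean norm, columns unscaled). The orientation sign is chosen so the
#' positive (disease-ward) class has the higher mean training score; when the
#' class means are exactly equal the first nonzero loading component is
#' forced positive.
#'
#' @param abundance A log2-CPM [normalize_log2cpm()] matrix containing the
#'   training samples.
#' @param panel An `apta_panel` or a character vector of member aptamer ids.
#' @param positive Sample ids (or a logical vector over the matrix rows) of
#'   the training positive class; all other training samples form the
#'   negative class.
#' @param samples Optional training sample ids (default: all rows).
#' @param scale Standardize columns to unit variance before the SVD
#'   (default FALSE: log2-CPM columns are left unscaled).
#' @return An object of class `panel_model`: `members`, `center`, `scale`,
#'   `loading` (unit norm), `orientation` (+1/-1).
#' @export
fit_panel_projection <- function(abundance, panel, positive, samples = NULL,
                                 scale = FALSE) {
  members <- if (inherits(panel, "apta_panel")) panel$members else as.character(panel)
  if (length(members) < 1L) stopf("panel has no members")
  missing <- setdiff(members, colnames(abundance))
  if (length(missing)) stopf("panel member %s absent from abundance matrix", missing[1])
  samples <- samples %||% rownames(abundance)
  if (length(samples) < 2L) stopf("need >= 2 training samples")
  sub <- abundance[samples, members, drop = FALSE]

  if (is.logical(positive)) {
    if (length(positive) != length(samples)) stopf("logical 'positive' must match samples")
    pos <- samples[positive]
  } else {
    pos <- intersect(as.character(positive), samples)
  }
  neg <- setdiff(samples, pos)
  if (length(pos) < 1L || length(neg) < 1L) {
    stopf("training samples must contain both classes")
  }

  center <- colMeans(sub)
  C <- sweep(sub, 2L, center)
  scl <- rep(1, length(members))
  if (isTRUE(scale)) {
    scl <- apply(C, 2L, stats::sd)
    if (any(scl == 0)) stopf("cannot scale: constant column %s",
                             members[which(scl == 0)[1]])
    C <- sweep(C, 2L, scl, "/")
  }
  sv <- svd(C)
  if (max(sv$d) <= 0) stopf("training submatrix has rank 0 (all columns constant)")
  loading <- sv$v[, 1L]
  scores <- drop(C %*% loading)
  d <- mean(scores[match(pos, samples)]) - mean(scores[match(neg, samples)])
  orientation <- if (d > 0) 1 else if (d < 0) -1 else {
    nz <- loading[loading != 0][1]
    if (nz >= 0) 1 else -1
  }
  structure(
    list(members = members,
         center = stats::setNames(center, members),
         scale = stats::setNames(scl, members),
         scaled = isTRUE(scale),
         loading = stats::setNames(loading, members),
         orientation = orientation),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("panel_model: %d members, orientation %+d%s\n",
              length(x$members), x$orientation,
              if (x$scaled) ", scaled" else ""))
  invisible(x)
}

#' Project samples onto the panel's PC1 score
#'
#' `score = <row - center, loading> * orientation` using the training center
#' and loading, making the score deployable across cohorts. Projecting the
#' training cohort reproduces the fit-time scores exactly.
#'
#' @param model A [fit_panel_projection()] result.
#' @param abundance A log2-CPM matrix containing all panel members.
#' @return Named numeric vector of per-sample scores.
#' @export
project_scores <- function(model, abundance) {
  stopifnot(inherits(model, "panel_model"))
  missing <- setdiff(model$members, colnames(abundance))
  if (length(missing)) {
    stopf("panel member %s absent from abundance matrix; represent missing aptamers as zero counts upstream",
          missing[1])
  }
  sub <- abundance[, model$members, drop = FALSE]
  C <- sweep(sub, 2L, model$center)
  if (model$scaled) C <- sweep(C, 2L, model$scale, "/")
  stats::setNames(drop(C %*% model$loading) * model$orientation, rownames(abundance))
}

#' Mann-Whitney AUC with DeLong variance and 95% CI
#'
#' The AUC is the mean over all (positive, negative) score pairs of
#' `[pos > neg] + 0.5 [pos == neg]`. The variance is DeLong's
#' placement-value estimator `var(V10)/n_pos + var(V01)/n_neg` and the 95%
#' CI is the Wald interval `auc +/- 1.96 sqrt(var)` clipped to \[0, 1\];
#' degenerate variance 0 collapses the CI to a point.
#'
#' @param scores Numeric score vector.
#' @param labels Logical (TRUE = positive) or two-level vector aligned with
#'   `scores`; factors/characters use the second sorted level as positive
#'   unless logical.
#' @return An object of class `auc_result`: `auc`, `variance`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`.
#' @export
auc_delong <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  if (!is.logical(labels)) {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2L) stopf("labels must contain exactly two classes, got %d", length(lev))
    labels <- as.character(labels) == lev[2L]
  }
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) < 1L || length(neg) < 1L) stopf("both classes must be non-empty")
  M <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  auc <- mean(M)
  v10 <- rowMeans(M)   # placement values of positives
  v01 <- colMeans(M)   # placement values of negatives
  var_part <- function(v) if (length(v) > 1L) stats::var(v) / length(v) else 0
  variance <- var_part(v10) + var_part(v01)
  half <- 1.96 * sqrt(variance)
  structure(
    list(auc = auc, variance = variance,
         ci_low = max(0, auc - half), ci_high = min(1, auc + half),
         n_pos = length(pos), n_neg = length(neg)),
    class = "auc_result"
  )
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), n_pos %d, n_neg %d\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when the pooled sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Convention for the null center: when the
#' Mann-Whitney U statistic sits exactly at `n_A n_B / 2` (e.g. identical
#' multisets) the two-sided p-value is 1.
#'
#' @param a,b Numeric score vectors for the two groups.
#' @return A list with `statistic` (the rank-sum W as in
#'   [stats::wilcox.test()]) and `p_value`.
#' @export
wilcoxon_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 1L || length(b) < 1L) stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  p <- ht$p.value
  if (abs(u - length(a) * length(b) / 2) < 1e-9) p <- 1
  list(statistic = unname(ht$statistic), p_value = min(p, 1))
}

#' Qualify an AUC value
#'
#' Bands: below 0.70 `below_acceptable`, 0.70 to below 0.80 `acceptable`,
#' 0.80 to below 0.90 `excellent`, 0.90 and above `outstanding` (boundary
#' ties resolve upward).
#'
#' @param auc AUC value(s) in \[0, 1\].
#' @return Character vector of labels.
#' @export
classify_auc <- function(auc) {
  if (any(is.na(auc) | auc < 0 | auc > 1)) stopf("auc must lie in [0, 1]")
  cut_labels <- c("below_acceptable", "acceptable", "excellent", "outstanding")
  idx <- findInterval(auc, c(0.70, 0.80, 0.90)) + 1L
  cut_labels[idx]
}

#' Comparator clinical scores
#'
#' FIB-4 = (age \[years\] x AST \[U/L\]) / (platelets \[1e9/L\] x sqrt(ALT
#' \[U/L\])) and the AST/ALT ratio. Missing inputs give missing outputs
#' (never silent zeros); non-positive ALT or platelet values are an error.
#'
#' @param metadata Metadata data frame with `sample_id` and (some of) `age`,
#'   `AST`, `ALT`, `platelets`.
#' @return Data frame with `sample_id`, `fib4`, `ast_alt_ratio`.
#' @export
clinical_scores <- function(metadata) {
  n <- nrow(metadata)
  get <- function(col) if (col %in% names(metadata)) metadata[[col]] else rep(NA_real_, n)
  age <- get("age"); ast <- get("AST"); alt <- get("ALT"); plt <- get("platelets")
  bad_alt <- !is.na(alt) & alt <= 0
  if (any(bad_alt)) stopf("non-positive ALT for sample %s", metadata$sample_id[which(bad_alt)[1]])
  bad_plt <- !is.na(plt) & plt <= 0
  if (any(bad_plt)) stopf("non-positive platelets for sample %s", metadata$sample_id[which(bad_plt)[1]])
  data.frame(
    sample_id = metadata$sample_id,
    fib4 = age * ast / (plt * sqrt(alt)),
    ast_alt_ratio = ast / alt,
    stringsAsFactors = FALSE
  )
}

resolve_comparison <- function(metadata, comparison) {
  if (!is.null(comparison$cutoff) || isTRUE(comparison$dichotomize)) {
    dichotomize_by_median(metadata, comparison$variable, cutoff = comparison$cutoff)
  } else {
    make_contrast(metadata, comparison$variable, comparison$level_A, comparison$level_B)
  }
}

#' Evaluate a panel model across cohorts and comparisons
#'
#' One row per cohort x comparison, with the PC1 DeLong AUC (95% CI), the
#' Wilcoxon p-value and the qualitative AUC label. Comparisons that cannot
#' be formed in a cohort (an empty class, a missing variable) are preserved
#' as N/A rows with the reason, never dropped.
#'
#' @param model A [fit_panel_projection()] result.
#' @param cohorts Named list; each element a list with `abundance` (log2-CPM
#'   matrix) and `metadata` (data frame).
#' @param comparisons Named list of comparison specs: either
#'   `list(variable, level_A, level_B)` or `list(variable, cutoff)` /
#'   `list(variable, dichotomize = TRUE)` for a median split.
#' @return A data frame with columns `cohort`, `comparison`, `n_A`, `n_B`,
#'   `auc`, `ci_low`, `ci_high`, `auc_label`, `wilcoxon_p`, `note`.
#' @export
evaluate_comparisons <- function(model, cohorts, comparisons) {
  stopifnot(inherits(model, "panel_model"))
  if (is.null(names(cohorts)) || is.null(names(comparisons))) {
    stopf("cohorts and comparisons must be named lists")
  }
  rows <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    scores <- project_scores(model, co$abundance)
    for (pn in names(comparisons)) {
      row <- data.frame(cohort = cn, comparison = pn, n_A = NA_integer_,
                        n_B = NA_integer_, auc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, auc_label = NA_character_,
                        wilcoxon_p = NA_real_, note = "",
                        stringsAsFactors = FALSE)
      ctr <- tryCatch(resolve_comparison(co$metadata, comparisons[[pn]]),
                      error = function(e) conditionMessage(e))
      if (is.character(ctr)) {
        row$note <- if (grepl("non-empty", ctr)) "empty class" else ctr
        rows[[length(rows) + 1L]] <- row
        next
      }
      a_ids <- intersect(ctr$samples_A, names(scores))
      b_ids <- intersect(ctr$samples_B, names(scores))
      if (length(a_ids) < 1L || length(b_ids) < 1L) {
        row$note <- "empty class"
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- auc_delong(c(scores[a_ids], scores[b_ids]),
                        c(rep(FALSE, length(a_ids)), rep(TRUE, length(b_ids))))
      wt <- wilcoxon_test(scores[a_ids], scores[b_ids])
      row$n_A <- length(a_ids)
      row$n_B <- length(b_ids)
      row$auc <- res$auc
      row$ci_low <- res$ci_low
      row$ci_high <- res$ci_high
      row$auc_label <- classify_auc(res$auc)
      row$wilcoxon_p <- wt$p_value
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
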