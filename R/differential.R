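# Normalization, per-aptamer two-group OLS, BH adjustment and panel
# selection: the discriminative-aptamer discovery stage.

#' Panel selection configuration
#'
#' Houses the discovery thresholds: the abundance cutoff (500 most abundant
#' aptamers), the absolute log2 regression-coefficient threshold (0.25) and
#' the BH-adjusted significance level (0.05).
#'
#' @param top_k Abundance cutoff.
#' @param coef_threshold Minimal absolute log2 coefficient.
#' @param alpha BH-adjusted p-value threshold.
#' @param pseudocount Pseudocount added on the CPM scale before log2.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(top_k = 500L, coef_threshold = 0.25, alpha = 0.05,
                         pseudocount = 1.0) {
  if (top_k < 1L) stopf("top_k must be positive")
  if (coef_threshold <= 0) stopf("coef_threshold must be > 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  structure(list(top_k = as.integer(top_k), coef_threshold = coef_threshold,
                 alpha = alpha, pseudocount = pseudocount),
            class = "panel_config")
}

#' Log2 counts-per-million normalization
#'
#' `value = log2(count / effective_total * 1e6 + pseudocount)`. CPM removes
#' library-size differences between samples and the pseudocount resolves the
#' zero-count problem; with the default pseudocount 1 a zero count maps to
#' exactly 0. `method = "total"` (the default) uses the raw sample totals as
#' stated; `method = "tmm"` multiplies them by trimmed-mean-of-M-values
#' scaling factors ([edgeR::calcNormFactors()]). Compositional shifts —
#' when a coordinated subset of aptamers changes and drags every other CPM
#' value with it — are handled separately by [align_abundance()].
#'
#' @param x An [apta_counts] object; every sample total must be > 0.
#' @param pseudocount Pseudocount on the CPM scale (default 1).
#' @param method `"total"` (raw sample totals, default) or `"tmm"`
#'   (effective library sizes).
#' @return A samples x aptamers numeric matrix of class `abundance_matrix`
#'   with attributes `pseudocount` and `method`.
#' @export
normalize_log2cpm <- function(x, pseudocount = 1.0, method = c("total", "tmm")) {
  stopifnot(inherits(x, "apta_counts"))
  method <- match.arg(method)
  totals <- rowSums(x$counts)
  if (any(totals <= 0)) {
    stopf("sample %s has zero total count; cannot normalize",
          x$sample_ids[which(totals <= 0)[1]])
  }
  if (method == "tmm" && nrow(x$counts) > 1L) {
    factors <- edgeR::calcNormFactors(t(x$counts), method = "TMM")
    totals <- totals * factors
  }
  m <- log2(x$counts / totals * 1e6 + pseudocount)
  dimnames(m) <- list(x$sample_ids, x$aptamer_ids)
  structure(m, pseudocount = pseudocount, method = method,
            class = c("abundance_matrix", "matrix", "array"))
}

#' Median-ratio alignment of a log2-CPM matrix to a reference profile
#'
#' Per sample, subtracts the median deviation of the sample's log2-CPM
#' values from a per-aptamer reference profile, computed over an invariant
#' (assumed non-differential) aptamer set. This removes compositional
#' shifts: when a coordinated subset of aptamers rises, CPM values of all
#' other aptamers fall in concert, and the unweighted median over invariant
#' aptamers recovers that common offset robustly (heavy-tailed pools defeat
#' count-weighted scaling-factor estimators here). Pass the training
#' reference to align an external cohort onto the training scale.
#'
#' @param abundance A [normalize_log2cpm()] matrix.
#' @param reference Per-aptamer reference profile (named numeric); default
#'   the column medians of `abundance`.
#' @param invariant Aptamer ids over which the per-sample median deviation
#'   is computed; default all columns.
#' @return The aligned matrix with attributes `reference`, `invariant`
#'   and `size_log2` (the per-sample subtracted offsets).
#' @export
align_abundance <- function(abundance, reference = NULL, invariant = NULL) {
  if (is.null(reference)) {
    reference <- apply(abundance, 2L, stats::median)
  }
  invariant <- invariant %||% colnames(abundance)
  invariant <- intersect(invariant, intersect(colnames(abundance), names(reference)))
  if (length(invariant) < 1L) stopf("no invariant aptamers shared with the reference")
  dev <- sweep(abundance[, invariant, drop = FALSE], 2L, reference[invariant])
  size <- apply(dev, 1L, stats::median)
  out <- abundance - size
  attributes(out) <- attributes(abundance)
  structure(out, reference = reference, invariant = invariant,
            size_log2 = size)
}

#' Two-pass discriminative panel selection
#'
#' Composes the selection stage end to end on a (top-K filtered) count
#' matrix: log2-CPM normalization, compositional alignment, per-aptamer OLS,
#' BH adjustment and thresholding. Selection runs twice: the first pass
#' aligns on all aptamers and selects a provisional panel; the second pass
#' re-aligns on the non-selected (invariant) aptamers only, so a
#' one-directional differential subset cannot bias the per-sample offsets,
#' and reselects. The returned alignment reference and invariant set allow
#' external cohorts to be placed on the same scale.
#'
#' @param x An [apta_counts] object (already abundance-filtered).
#' @param contrast An `apta_contrast`.
#' @param config A [panel_config()].
#' @return A list: `panel` (the final [select_panel()] result), `abundance`
#'   (the aligned log2-CPM matrix the panel was selected on), `reference`
#'   (per-aptamer alignment profile), `invariant` (aptamer ids used for the
#'   final alignment).
#' @export
select_discriminative <- function(x, contrast, config = panel_config()) {
  stopifnot(inherits(x, "apta_counts"))
  ab <- normalize_log2cpm(x, config$pseudocount)
  reference <- apply(ab, 2L, stats::median)
  ab1 <- align_abundance(ab, reference)
  pass1 <- select_panel(fit_two_group_ols(ab1, contrast), config, contrast)
  invariant <- setdiff(colnames(ab), pass1$members)
  if (length(invariant) < 1L) invariant <- colnames(ab)
  ab2 <- align_abundance(ab, reference, invariant)
  panel <- select_panel(fit_two_group_ols(ab2, contrast), config, contrast)
  list(panel = panel, abundance = ab2, reference = reference,
       invariant = invariant)
}

new_contrast <- function(variable, level_A, level_B, samples_A, samples_B,
                         cutoff = NULL) {
  if (length(samples_A) < 1L || length(samples_B) < 1L) {
    stopf("contrast %s: both groups must be non-empty (A: %d, B: %d)",
          variable, length(samples_A), length(samples_B))
  }
  if (length(intersect(samples_A, samples_B))) stopf("contrast groups overlap")
  structure(list(variable = variable, level_A = level_A, level_B = level_B,
                 samples_A = samples_A, samples_B = samples_B, cutoff = cutoff),
            class = "apta_contrast")
}

#' @export
print.apta_contrast <- function(x, ...) {
  cat(sprintf("contrast %s: %s (n=%d) vs %s (n=%d)%s\n", x$variable,
              x$level_A, length(x$samples_A), x$level_B, length(x$samples_B),
              if (is.null(x$cutoff)) "" else sprintf(" [cutoff %g]", x$cutoff)))
  invisible(x)
}

#' Two-group contrast from categorical metadata levels
#'
#' `level_B` is the positive / disease-ward level. Samples at neither level
#' are excluded.
#'
#' @param metadata Metadata data frame.
#' @param variable Metadata column name.
#' @param level_A,level_B Factor levels defining the groups.
#' @return An `apta_contrast` with per-group sample ids.
#' @export
make_contrast <- function(metadata, variable, level_A, level_B) {
  if (!variable %in% names(metadata)) stopf("unknown metadata variable '%s'", variable)
  v <- as.character(metadata[[variable]])
  new_contrast(variable, level_A, level_B,
               samples_A = metadata$sample_id[!is.na(v) & v == level_A],
               samples_B = metadata$sample_id[!is.na(v) & v == level_B])
}

#' Dichotomize a numeric variable at its (training) median
#'
#' Splits samples at the median of the non-missing values: `level_A` below
#' the cutoff, `level_B` at or above it (values exactly at the cutoff go to
#' `level_B`). Pass a pre-computed `cutoff` to apply a training-cohort median
#' to another cohort.
#'
#' @param metadata Metadata data frame.
#' @param variable Numeric metadata column name.
#' @param cutoff Optional fixed cutoff; defaults to the median of the
#'   non-missing values in `metadata`.
#' @return An `apta_contrast` with the cutoff recorded.
#' @export
dichotomize_by_median <- function(metadata, variable, cutoff = NULL) {
  if (!variable %in% names(metadata)) stopf("unknown metadata variable '%s'", variable)
  v <- metadata[[variable]]
  if (!is.numeric(v)) stopf("variable '%s' is not numeric", variable)
  if (is.null(cutoff)) {
    obs <- v[!is.na(v)]
    if (length(obs) < 2L) stopf("variable '%s' has fewer than 2 non-missing values", variable)
    cutoff <- stats::median(obs)
  }
  new_contrast(variable,
               level_A = sprintf("%s<%g", variable, cutoff),
               level_B = sprintf("%s>=%g", variable, cutoff),
               samples_A = metadata$sample_id[!is.na(v) & v < cutoff],
               samples_B = metadata$sample_id[!is.na(v) & v >= cutoff],
               cutoff = cutoff)
}

#' Per-aptamer two-group OLS fit
#'
#' For each aptamer, ordinary least squares of the log2-CPM abundance on an
#' intercept plus an indicator of `level_B`. The coefficient equals the
#' difference of group means (B minus A); the two-sided p-value comes from
#' the t statistic on the coefficient with `n_A + n_B - 2` residual degrees
#' of freedom, identical to a pooled-variance two-sample t-test. When the
#' residual variance is exactly zero the convention is p = 0 for a nonzero
#' coefficient and p = 1 otherwise.
#'
#' @param abundance An [normalize_log2cpm()] matrix.
#' @param contrast An `apta_contrast`; both groups need >= 2 samples present
#'   in the matrix.
#' @return A data frame with columns `aptamer_id`, `coefficient`,
#'   `std_error`, `p_value`.
#' @export
fit_two_group_ols <- function(abundance, contrast) {
  stopifnot(inherits(contrast, "apta_contrast"))
  a_ids <- intersect(contrast$samples_A, rownames(abundance))
  b_ids <- intersect(contrast$samples_B, rownames(abundance))
  nA <- length(a_ids)
  nB <- length(b_ids)
  if (nA < 2L || nB < 2L) {
    stopf("contrast %s: both groups need >= 2 samples in the matrix (A: %d, B: %d)",
          contrast$variable, nA, nB)
  }
  A <- abundance[a_ids, , drop = FALSE]
  B <- abundance[b_ids, , drop = FALSE]
  mA <- colMeans(A)
  mB <- colMeans(B)
  coef <- mB - mA
  ssA <- colSums(sweep(A, 2L, mA)^2)
  ssB <- colSums(sweep(B, 2L, mB)^2)
  df <- nA + nB - 2L
  s2 <- (ssA + ssB) / df
  se <- sqrt(s2 * (1 / nA + 1 / nB))
  p <- 2 * stats::pt(-abs(coef / se), df)
  zero_var <- s2 <= 0
  if (any(zero_var)) {
    se[zero_var] <- 0
    p[zero_var] <- ifelse(coef[zero_var] != 0, 0, 1)
  }
  data.frame(aptamer_id = colnames(abundance),
             coefficient = unname(coef),
             std_error = unname(se),
             p_value = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; validates that inputs lie in \[0, 1\] and
#' delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select the discriminative aptamer panel
#'
#' An aptamer is a panel member when its BH-adjusted p-value is at most
#' `alpha` and its absolute log2 coefficient is at least `coef_threshold`.
#' Direction `up` means higher abundance in `level_B` (positive
#' coefficient).
#'
#' @param results A [fit_two_group_ols()] data frame.
#' @param config A [panel_config()].
#' @param contrast Optional `apta_contrast` recorded on the panel.
#' @return An object of class `apta_panel`: `members`, `n_up`, `n_down`,
#'   `contrast`, and `table` (the volcano table with `coefficient`,
#'   `p_value`, `p_adjusted`, `neg_log10_p_adjusted`, `significant`,
#'   `direction`).
#' @export
select_panel <- function(results, config = panel_config(), contrast = NULL) {
  stopifnot(inherits(config, "panel_config"))
  tab <- results
  tab$p_adjusted <- adjust_bh(tab$p_value)
  tab$significant <- abs(tab$coefficient) >= config$coef_threshold &
    tab$p_adjusted <= config$alpha
  tab$direction <- ifelse(tab$coefficient > 0, "up", "down")
  tab$neg_log10_p_adjusted <- -log10(pmax(tab$p_adjusted, .Machine$double.xmin))
  members <- tab$aptamer_id[tab$significant]
  structure(
    list(members = members,
         n_up = sum(tab$significant & tab$direction == "up"),
         n_down = sum(tab$significant & tab$direction == "down"),
         contrast = contrast,
         config = config,
         table = tab),
    class = "apta_panel"
  )
}

#' @export
print.apta_panel <- function(x, ...) {
  cat(sprintf("apta_panel: %d members (%d up, %d down) of %d tested\n",
              length(x$members), x$n_up, x$n_down, nrow(x$table)))
  if (!is.null(x$contrast)) print(x$contrast)
  invisible(x)
}
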