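# Abundance ranking, zero-vs-rank missingness profile, top-K cutoff and
# sample-level QC by grouping variables.

#' Rank aptamers by total count
#'
#' Rank 1 is the aptamer with the highest total count across all samples;
#' ties are broken lexicographically by aptamer id so the ranking is
#' deterministic.
#'
#' @param x An [apta_counts] object.
#' @return A data frame (class `abundance_ranking`) ordered by rank with
#'   columns `aptamer_id`, `total_count`, `rank`, `n_zero_samples`.
#' @export
rank_aptamers <- function(x) {
  stopifnot(inherits(x, "apta_counts"))
  if (ncol(x$counts) < 1L) stopf("count matrix has no aptamers")
  totals <- colSums(x$counts)
  zeros <- colSums(x$counts == 0L)
  ord <- order(-totals, x$aptamer_ids)
  out <- data.frame(
    aptamer_id = x$aptamer_ids[ord],
    total_count = unname(totals[ord]),
    rank = seq_along(ord),
    n_zero_samples = unname(zeros[ord]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("abundance_ranking", "data.frame")
  out
}

#' Zero-count profile against abundance rank
#'
#' Emits the number of zero samples per aptamer ordered by rank, plus a
#' suggested abundance cutoff: the rank that maximizes the forward
#' difference of a moving-average-smoothed zero curve (the "steep increase
#' in zeros"). The suggestion is diagnostic only; panel selection uses the
#' configured top-K.
#'
#' @param x An [apta_counts] object.
#' @param ranking The matching [rank_aptamers()] result.
#' @param window Moving-average window (default 25); `window = 1` means no
#'   smoothing.
#' @return A list with `profile` (data frame `rank`, `n_zero_samples`,
#'   `smoothed`) and `suggested_cutoff` (integer rank; `n_aptamers` when the
#'   curve never increases).
#' @export
zero_profile <- function(x, ranking, window = 25L) {
  stopifnot(inherits(x, "apta_counts"), inherits(ranking, "abundance_ranking"))
  if (!identical(sort(ranking$aptamer_id), sort(x$aptamer_ids))) {
    stopf("ranking does not match the count matrix")
  }
  z <- ranking$n_zero_samples
  n <- length(z)
  h <- max(0L, (as.integer(window) - 1L) %/% 2L)
  cs <- cumsum(c(0, z))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  suggested <- n
  if (n > 1L) {
    d <- diff(smoothed)
    if (max(d) > 0) suggested <- which.max(d)
  }
  list(profile = data.frame(rank = ranking$rank,
                            n_zero_samples = z,
                            smoothed = smoothed),
       suggested_cutoff = as.integer(suggested))
}

#' Restrict a count matrix to the top-K most abundant aptamers
#'
#' Columns of the result are in rank order (rank 1 first); the sample set is
#' unchanged. The study default is `k = 500`.
#'
#' @param x An [apta_counts] object.
#' @param ranking The matching [rank_aptamers()] result.
#' @param k Number of top-ranked aptamers to keep (1 <= k <= n_aptamers).
#' @return An [apta_counts] restricted to ranks 1..k.
#' @export
select_top_k <- function(x, ranking, k = 500L) {
  stopifnot(inherits(x, "apta_counts"), inherits(ranking, "abundance_ranking"))
  k <- as.integer(k)
  if (k < 1L || k > ncol(x$counts)) {
    stopf("k = %d out of range 1..%d", k, ncol(x$counts))
  }
  keep <- ranking$aptamer_id[seq_len(k)]
  apta_counts(x$counts[, keep, drop = FALSE],
              sample_ids = x$sample_ids, aptamer_ids = keep,
              sequences = if (!is.null(x$sequences)) x$sequences[keep])
}

#' QC summary of per-sample total counts by grouping variables
#'
#' For each grouping variable and group, summarizes the per-sample library
#' sizes (total counts) and flags samples whose total lies outside the Tukey
#' fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of their group. Flags are advisory:
#' nothing is excluded automatically. Single-sample groups are skipped (IQR
#' undefined).
#'
#' @param x An [apta_counts] object.
#' @param metadata Metadata data frame with a `sample_id` column covering the
#'   samples of `x`.
#' @param grouping_variables Character vector of metadata column names.
#' @return A list with `summary` (variable, group, n, q1, median, q3) and
#'   `flags` (variable, group, sample_id, total_count).
#' @export
qc_sample_summary <- function(x, metadata, grouping_variables) {
  stopifnot(inherits(x, "apta_counts"))
  unknown <- setdiff(grouping_variables, names(metadata))
  if (length(unknown)) stopf("unknown grouping variable '%s'", unknown[1])
  meta <- metadata[match(x$sample_ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stopf("metadata missing sample %s",
          x$sample_ids[which(is.na(meta$sample_id))[1]])
  }
  totals <- rowSums(x$counts)
  summaries <- list()
  flags <- list()
  for (v in grouping_variables) {
    groups <- split(seq_along(totals), as.character(meta[[v]]))
    for (g in names(groups)) {
      idx <- groups[[g]]
      tg <- totals[idx]
      q <- stats::quantile(tg, c(0.25, 0.5, 0.75), names = FALSE)
      summaries[[length(summaries) + 1L]] <- data.frame(
        variable = v, group = g, n = length(idx),
        q1 = q[1], median = q[2], q3 = q[3], stringsAsFactors = FALSE)
      if (length(idx) < 2L) next
      iqr <- q[3] - q[1]
      out <- tg < q[1] - 1.5 * iqr | tg > q[3] + 1.5 * iqr
      if (any(out)) {
        flags[[length(flags) + 1L]] <- data.frame(
          variable = v, group = g,
          sample_id = x$sample_ids[idx][out],
          total_count = unname(tg[out]), stringsAsFactors = FALSE)
      }
    }
  }
  empty_flags <- data.frame(variable = character(0), group = character(0),
                            sample_id = character(0), total_count = numeric(0),
                            stringsAsFactors = FALSE)
  list(summary = do.call(rbind, summaries),
       flags = if (length(flags)) do.call(rbind, flags) else empty_flags)
}
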