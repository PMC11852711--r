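# MS pull-down intensity normalization and most-probable-target assignment.

#' MS pull-down intensity table
#'
#' Proteins x runs intensity matrix where each run is one replicate
#' pull-down of one aptamer (three replicates expected).
#'
#' @param intensities Non-negative numeric matrix, proteins as rows, runs as
#'   columns.
#' @param run_info Data frame with one row per run: `aptamer_id`,
#'   `replicate`.
#' @return An object of class `ms_intensity_table`.
#' @export
ms_intensity_table <- function(intensities, run_info) {
  intensities <- as.matrix(intensities)
  if (anyNA(intensities) || any(intensities < 0)) {
    stopf("intensities must be non-negative and complete")
  }
  if (nrow(run_info) != ncol(intensities)) {
    stopf("run_info rows (%d) must match intensity columns (%d)",
          nrow(run_info), ncol(intensities))
  }
  if (!all(c("aptamer_id", "replicate") %in% names(run_info))) {
    stopf("run_info needs columns aptamer_id, replicate")
  }
  if (is.null(rownames(intensities))) stopf("intensities need protein row names")
  structure(list(intensities = intensities, run_info = run_info),
            class = "ms_intensity_table")
}

#' @export
print.ms_intensity_table <- function(x, ...) {
  cat(sprintf("ms_intensity_table: %d proteins x %d runs (%d aptamers)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$run_info$aptamer_id))))
  invisible(x)
}

#' Normalize pull-down intensities and aggregate per aptamer
#'
#' Per run, each protein's intensity is converted to percent of the run's
#' total signal; per aptamer, the percent is averaged over the replicate
#' runs; the mean percent is log2 transformed after flooring at
#' `floor_percent` (default 0.01%) to avoid minus infinity for absent
#' proteins. Aggregation order is percent per run, then mean over the
#' triplicate, then log2.
#'
#' @param table An [ms_intensity_table()].
#' @param floor_percent Lower floor applied to the mean percent before log2.
#' @return An object of class `ms_target_profile`: `mean_percent` and
#'   `log2_percent` (proteins x aptamers matrices) plus `floor_percent`.
#' @export
normalize_and_aggregate <- function(table, floor_percent = 0.01) {
  stopifnot(inherits(table, "ms_intensity_table"))
  if (floor_percent <= 0) stopf("floor_percent must be > 0")
  totals <- colSums(table$intensities)
  if (any(totals <= 0)) {
    stopf("run %s has zero total intensity",
          colnames(table$intensities)[which(totals <= 0)[1]])
  }
  percent <- sweep(table$intensities, 2L, totals, "/") * 100
  aptamers <- unique(table$run_info$aptamer_id)
  mean_percent <- vapply(aptamers, function(a) {
    rowMeans(percent[, table$run_info$aptamer_id == a, drop = FALSE])
  }, numeric(nrow(percent)))
  dimnames(mean_percent) <- list(rownames(table$intensities), aptamers)
  structure(
    list(mean_percent = mean_percent,
         log2_percent = log2(pmax(mean_percent, floor_percent)),
         floor_percent = floor_percent),
    class = "ms_target_profile"
  )
}

#' Assign each aptamer its most probable protein target
#'
#' The primary target is the protein with the highest mean percent of total
#' intensity (ties resolve to the lexicographically smallest protein id). A
#' secondary target is reported when the runner-up binds a comparable
#' amount, i.e. its log2 mean percent is within `comparability_log2_margin`
#' of the primary's (default 1.0 = within 2-fold); such dual assignments are
#' rendered as `"primary/secondary"`.
#'
#' @param profile A [normalize_and_aggregate()] result.
#' @param comparability_log2_margin Log2 margin for dual targets.
#' @return A data frame with one row per aptamer: `aptamer_id`,
#'   `primary_target`, `secondary_target` (NA when not comparable),
#'   `probable_target`, `primary_mean_percent`, `secondary_mean_percent`,
#'   `comparable`.
#' @export
assign_targets <- function(profile, comparability_log2_margin = 1.0) {
  stopifnot(inherits(profile, "ms_target_profile"))
  if (comparability_log2_margin < 0) stopf("comparability margin must be >= 0")
  mp <- profile$mean_percent
  lp <- profile$log2_percent
  proteins <- rownames(mp)
  rows <- lapply(colnames(mp), function(a) {
    o <- order(-mp[, a], proteins)
    primary <- proteins[o[1L]]
    second <- if (length(o) > 1L) proteins[o[2L]] else NA_character_
    comparable <- !is.na(second) &&
      (lp[primary, a] - lp[second, a]) <= comparability_log2_margin
    data.frame(
      aptamer_id = a,
      primary_target = primary,
      secondary_target = if (comparable) second else NA_character_,
      probable_target = if (comparable) paste(primary, second, sep = "/") else primary,
      primary_mean_percent = mp[primary, a],
      secondary_mean_percent = if (is.na(second)) NA_real_ else mp[second, a],
      comparable = comparable,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write an MS intensity table (TSV)
#'
#' On-disk format: first column `protein_id`, remaining columns one per run
#' named `<aptamer_id>_r<replicate>`.
#'
#' @param path File path.
#' @return `read_ms_table` returns an [ms_intensity_table()];
#'   `write_ms_table` returns the path invisibly.
#' @export
read_ms_table <- function(path) {
  if (!file.exists(path)) stopf("MS table not found: '%s'", path)
  df <- utils::read.delim(path, check.names = FALSE, quote = "")
  if (names(df)[1] != "protein_id") stopf("MS table must start with a 'protein_id' column")
  runs <- names(df)[-1]
  m <- regmatches(runs, regexec("^(.+)_r([0-9]+)$", runs))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stopf("run column '%s' does not match '<aptamer>_r<replicate>'",
                      runs[which(bad)[1]])
  run_info <- data.frame(
    aptamer_id = vapply(m, `[`, character(1), 2L),
    replicate = as.integer(vapply(m, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  intens <- as.matrix(df[, -1, drop = FALSE])
  rownames(intens) <- df$protein_id
  ms_intensity_table(intens, run_info)
}

#' @rdname read_ms_table
#' @param table An [ms_intensity_table()].
#' @export
write_ms_table <- function(table, path) {
  stopifnot(inherits(table, "ms_intensity_table"))
  df <- data.frame(protein_id = rownames(table$intensities),
                   table$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
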