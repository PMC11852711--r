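# Sequenced aptamer-pool reads -> samples x aptamers count matrix, plus
# robust TSV I/O for count matrices and sample metadata.

#' Samples-by-aptamers count matrix
#'
#' The pipeline's central container: a non-negative integer matrix with
#' samples as rows and aptamers as columns, optionally carrying the aptamer
#' variable-region sequences.
#'
#' @param counts Integer matrix (samples x aptamers), all entries >= 0.
#' @param sample_ids,aptamer_ids Unique identifiers; default to existing
#'   dimnames.
#' @param sequences Optional named character vector mapping aptamer ids to
#'   variable-region sequences.
#' @return An object of class `apta_counts`.
#' @export
apta_counts <- function(counts, sample_ids = rownames(counts),
                        aptamer_ids = colnames(counts), sequences = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(nrow(counts)))
  if (is.null(aptamer_ids)) aptamer_ids <- sprintf("apt_%d", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  aptamer_ids <- as.character(aptamer_ids)
  if (length(sample_ids) != nrow(counts)) stopf("sample_ids length mismatch")
  if (length(aptamer_ids) != ncol(counts)) stopf("aptamer_ids length mismatch")
  if (anyDuplicated(sample_ids)) stopf("duplicate sample_id: %s", sample_ids[duplicated(sample_ids)][1])
  if (anyDuplicated(aptamer_ids)) stopf("duplicate aptamer_id: %s", aptamer_ids[duplicated(aptamer_ids)][1])
  storage.mode(counts) <- "integer"
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0L)) stopf("counts must be non-negative")
  dimnames(counts) <- list(sample_ids, aptamer_ids)
  if (!is.null(sequences)) {
    missing <- setdiff(aptamer_ids, names(sequences))
    if (length(missing)) stopf("sequences missing for aptamer %s", missing[1])
    sequences <- sequences[aptamer_ids]
  }
  structure(
    list(counts = counts, sample_ids = sample_ids, aptamer_ids = aptamer_ids,
         sequences = sequences),
    class = "apta_counts"
  )
}

#' @export
print.apta_counts <- function(x, ...) {
  cat(sprintf("apta_counts: %d samples x %d aptamers, total %.3g reads%s\n",
              nrow(x$counts), ncol(x$counts), sum(as.numeric(x$counts)),
              if (is.null(x$sequences)) "" else " (with sequences)"))
  invisible(x)
}

#' @export
dim.apta_counts <- function(x) dim(x$counts)

#' Primer configuration for read trimming
#'
#' @param primer_5p,primer_3p Constant flank sequences (non-empty).
#' @param max_mismatches Hamming-distance budget per flank (default 0: exact
#'   prefix/suffix match).
#' @param region_length Expected variable-region length.
#' @param length_tolerance Allowed deviation of the trimmed region length.
#' @return An object of class `primer_config`.
#' @export
primer_config <- function(primer_5p, primer_3p, max_mismatches = 0L,
                          region_length, length_tolerance = 0L) {
  primer_5p <- normalize_sequence(primer_5p)
  primer_3p <- normalize_sequence(primer_3p)
  if (!nzchar(primer_5p) || !nzchar(primer_3p)) stopf("primers must be non-empty")
  if (max_mismatches < 0L || length_tolerance < 0L) stopf("tolerances must be >= 0")
  if (region_length < 1L) stopf("region_length must be positive")
  structure(list(primer_5p = primer_5p, primer_3p = primer_3p,
                 max_mismatches = as.integer(max_mismatches),
                 region_length = as.integer(region_length),
                 length_tolerance = as.integer(length_tolerance)),
            class = "primer_config")
}

hamming <- function(a, b) {
  # equal-length strings
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b, USE.NAMES = FALSE)
}

# Locate the first structurally malformed record for error reporting.
diagnose_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stopf("malformed FASTQ '%s': truncated record %d (file has %d lines)",
          path, n %/% 4L + 1L, n)
  }
  for (rec in seq_len(n %/% 4L)) {
    i <- (rec - 1L) * 4L
    if (!startsWith(lines[i + 1L], "@")) {
      stopf("malformed FASTQ '%s': record %d header does not start with '@'", path, rec)
    }
    if (!startsWith(lines[i + 3L], "+")) {
      stopf("malformed FASTQ '%s': record %d separator does not start with '+'", path, rec)
    }
    if (nchar(lines[i + 2L]) != nchar(lines[i + 4L])) {
      stopf("malformed FASTQ '%s': record %d sequence/quality length mismatch", path, rec)
    }
  }
  invisible(TRUE)
}

#' Trim primer flanks from pool reads
#'
#' Reads whose 5' and 3' flanks match the primers (within the Hamming
#' mismatch budget) and whose enclosed region length is within tolerance are
#' trimmed to the variable region; all others are discarded and tallied in
#' the parse report by reason (`no_5p`, `no_3p`, `bad_length`). Sequences are
#' case-folded to uppercase with U mapped to T.
#'
#' @param fastq_path Path to a FASTQ file (Phred+33, 4-line records).
#' @param primers A [primer_config()].
#' @return A list with `sequences` (character vector of retained
#'   variable-region sequences, one per retained read) and `report` (totals
#'   and per-reason discard counts).
#' @export
parse_pool_reads <- function(fastq_path, primers) {
  stopifnot(inherits(primers, "primer_config"))
  if (!file.exists(fastq_path)) stopf("FASTQ file not found: '%s'", fastq_path)
  if (file.size(fastq_path) == 0L) {
    return(list(sequences = character(0),
                report = list(total = 0L, retained = 0L, no_5p = 0L,
                              no_3p = 0L, bad_length = 0L)))
  }
  diagnose_fastq(fastq_path)  # record-level structural validation
  reads <- tryCatch(
    as.character(Biostrings::readBStringSet(fastq_path, format = "fastq")),
    error = function(e) {
      stopf("malformed FASTQ '%s': %s", fastq_path, conditionMessage(e))
    }
  )
  reads <- chartr("U", "T", toupper(unname(reads)))
  p5 <- primers$primer_5p
  p3 <- primers$primer_3p
  n5 <- nchar(p5)
  n3 <- nchar(p3)
  len <- nchar(reads)

  long_enough <- len >= n5 + n3
  if (primers$max_mismatches == 0L) {
    has5 <- long_enough & startsWith(reads, p5)
  } else {
    has5 <- long_enough
    has5[long_enough] <- hamming(substr(reads[long_enough], 1L, n5), p5) <=
      primers$max_mismatches
  }
  has3 <- rep(FALSE, length(reads))
  cand <- long_enough & has5
  if (any(cand)) {
    suffix <- substr(reads[cand], len[cand] - n3 + 1L, len[cand])
    has3[cand] <- if (primers$max_mismatches == 0L) suffix == p3 else
      hamming(suffix, p3) <= primers$max_mismatches
  }
  region <- rep(NA_character_, length(reads))
  keep0 <- has5 & has3
  region[keep0] <- substr(reads[keep0], n5 + 1L, len[keep0] - n3)
  good_len <- keep0 & !is.na(region) &
    abs(nchar(region) - primers$region_length) <= primers$length_tolerance

  report <- list(
    total = length(reads),
    retained = sum(good_len),
    no_5p = sum(!has5 | !long_enough),
    no_3p = sum((has5 & long_enough) & !has3),
    bad_length = sum(keep0 & !good_len)
  )
  list(sequences = region[good_len], report = report)
}

#' Build a count matrix from per-sample sequence multisets
#'
#' One column per distinct variable-region sequence observed in any sample;
#' entries are per-sample multiplicities (absent sequence = 0). Aptamer ids
#' are assigned deterministically as `apt_<rank>` after ranking sequences by
#' total count across samples, descending, ties broken lexicographically by
#' sequence.
#'
#' @param sample_seqs Named list: sample id -> character vector of retained
#'   variable-region sequences (a multiset).
#' @return An [apta_counts] object carrying the sequences.
#' @export
build_count_matrix <- function(sample_seqs) {
  if (length(sample_seqs) < 1L || is.null(names(sample_seqs))) {
    stopf("sample_seqs must be a non-empty named list")
  }
  sample_ids <- names(sample_seqs)
  all_seqs <- sort(unique(unlist(sample_seqs, use.names = FALSE)))
  mat <- matrix(0L, length(sample_ids), length(all_seqs),
                dimnames = list(sample_ids, all_seqs))
  for (s in sample_ids) {
    tab <- table(sample_seqs[[s]])
    if (length(tab)) mat[s, names(tab)] <- as.integer(tab)
  }
  totals <- colSums(mat)
  ord <- order(-totals, all_seqs)
  mat <- mat[, ord, drop = FALSE]
  seqs <- all_seqs[ord]
  ids <- sprintf("apt_%0*d", max(1L, nchar(length(seqs))), seq_along(seqs))
  apta_counts(mat, sample_ids = sample_ids, aptamer_ids = ids,
              sequences = stats::setNames(seqs, ids))
}

#' Read / write a count table (TSV)
#'
#' The on-disk format is a TSV with header `sample_id` followed by aptamer
#' ids, one row per sample, integer cells. `write_count_table` followed by
#' `read_count_table` is the identity on valid matrices, and rewriting a
#' read table reproduces the file byte for byte.
#'
#' @param path File path.
#' @param sequences Optional named character vector of aptamer sequences to
#'   attach to the matrix on read.
#' @return `read_count_table` returns an [apta_counts]; `write_count_table`
#'   returns the path invisibly.
#' @export
read_count_table <- function(path, sequences = NULL) {
  if (!file.exists(path)) stopf("count table not found: '%s'", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) stopf("count table '%s' is empty (no header)", path)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stopf("ragged count table '%s': row %d has %d fields, expected %d",
          path, bad, nf[bad], nf[1])
  }
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          quote = "")
  if (names(df)[1] != "sample_id") stopf("count table must start with a 'sample_id' column")
  apt_ids <- names(df)[-1]
  if (anyDuplicated(apt_ids)) stopf("duplicate aptamer_id in header: %s",
                                    apt_ids[duplicated(apt_ids)][1])
  sample_ids <- df$sample_id
  if (anyDuplicated(sample_ids)) stopf("duplicate sample_id: %s",
                                       sample_ids[duplicated(sample_ids)][1])
  n <- nrow(df)
  mat <- matrix(0L, n, length(apt_ids), dimnames = list(sample_ids, apt_ids))
  for (j in seq_along(apt_ids)) {
    cell <- df[[j + 1L]]
    bad <- !grepl("^[0-9]+$", cell)
    if (any(bad)) {
      i <- which(bad)[1]
      stopf("non-integer count '%s' at row %d (sample %s), column '%s'",
            cell[i], i, sample_ids[i], apt_ids[j])
    }
    mat[, j] <- as.integer(cell)
  }
  apta_counts(mat, sequences = sequences)
}

#' @rdname read_count_table
#' @param x An [apta_counts] object.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "apta_counts"))
  header <- paste(c("sample_id", x$aptamer_ids), collapse = "\t")
  rows <- vapply(seq_along(x$sample_ids), function(i) {
    paste(c(x$sample_ids[i], x$counts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

SH_GROUPS <- c("healthy", "MASLD_no_SH", "MASH")

#' Read / write sample metadata (TSV)
#'
#' Required columns: `sample_id`, `steatohepatitis_group`,
#' `fibrosis_stage`; clinical columns (`sex`, `age`, `BMI`, `LDL`, `sCD163`,
#' `AST`, `ALT`, `platelets`, `metabolic_syndrome`, `library_size`, `cohort`)
#' are optional and may contain `NA`. Group labels are whitespace-trimmed and
#' matched case-insensitively against `healthy`, `MASLD_no_SH`, `MASH`; the
#' fibrosis group is derived from the stage.
#'
#' @param path File path.
#' @return `read_metadata` returns a validated metadata data frame;
#'   `write_metadata` returns the path invisibly.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: '%s'", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = "NA")
  required <- c("sample_id", "steatohepatitis_group", "fibrosis_stage")
  missing <- setdiff(required, names(df))
  if (length(missing)) stopf("metadata missing required column '%s'", missing[1])
  df$sample_id <- trimws(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stopf("duplicate sample_id: %s", df$sample_id[duplicated(df$sample_id)][1])
  }

  grp <- trimws(df$steatohepatitis_group)
  idx <- match(tolower(grp), tolower(SH_GROUPS))
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stopf("unknown steatohepatitis_group '%s' for sample %s", grp[i], df$sample_id[i])
  }
  df$steatohepatitis_group <- SH_GROUPS[idx]

  stage <- suppressWarnings(as.integer(trimws(df$fibrosis_stage)))
  bad <- is.na(stage) | stage < 0L | stage > 4L
  if (any(bad)) {
    i <- which(bad)[1]
    stopf("invalid fibrosis_stage '%s' for sample %s (must be 0..4)",
          df$fibrosis_stage[i], df$sample_id[i])
  }
  df$fibrosis_stage <- stage
  df$fibrosis_group <- map_fibrosis_group(stage)

  numeric_cols <- c("age", "BMI", "LDL", "sCD163", "AST", "ALT", "platelets",
                    "library_size")
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.na(df[[col]]) & is.na(v)
    if (any(bad)) {
      i <- which(bad)[1]
      stopf("non-numeric %s '%s' for sample %s", col, df[[col]][i], df$sample_id[i])
    }
    df[[col]] <- v
  }
  for (col in intersect(c("AST", "ALT", "platelets", "library_size"), names(df))) {
    bad <- !is.na(df[[col]]) & df[[col]] <= 0
    if (any(bad)) {
      stopf("%s must be > 0 when present (sample %s)", col,
            df$sample_id[which(bad)[1]])
    }
  }
  if ("metabolic_syndrome" %in% names(df)) {
    df$metabolic_syndrome <- as.logical(df$metabolic_syndrome)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_metadata
#' @param metadata A metadata data frame.
#' @export
write_metadata <- function(metadata, path) {
  df <- metadata
  for (col in names(df)) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), "NA", as.character(v))
  }
  lines <- c(paste(names(df), collapse = "\t"),
             apply(df, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
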