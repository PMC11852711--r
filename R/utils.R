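stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

#' Enumerate the distinct k-mers of a sequence
#' @noRd
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq(k, n)))
}

normalize_sequence <- function(s) {
  chartr("U", "T", toupper(trimws(s)))
}

check_dna_alphabet <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stopf("%s %d contains characters outside {A,C,G,T}", what, which(bad)[1])
  }
  invisible(seqs)
}
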