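# Shared fixtures: small simulation configs and convenience wrappers.

small_config <- function(seed = 1L, ...) {
  sim_config(n_aptamers = 60L, n_families = 3L, fraction_in_families = 0.25,
             group_sizes = c(healthy = 0L, MASLD_no_SH = 8L, MASH = 8L),
             library_size_range = c(2e4, 4e4), seed = seed, ...)
}

# contrast directly from two sample-id vectors (B is the positive level)
new_test_contrast <- function(a, b) {
  make_contrast(data.frame(sample_id = c(a, b),
                           grp = rep(c("A", "B"), c(length(a), length(b))),
                           stringsAsFactors = FALSE),
                "grp", "A", "B")
}

default_contrast <- function(cohort) {
  make_contrast(cohort, "steatohepatitis_group", "MASLD_no_SH", "MASH")
}

simulate_bundle <- function(config) {
  lib <- generate_library(config)
  cohort <- generate_cohort(config)
  counts <- simulate_counts(lib, cohort, config)
  list(lib = lib, cohort = cohort, counts = counts,
       truth = attr(counts, "truth"))
}

# brute-force BH step-up oracle, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o]
  for (k in seq_len(m)) {
    q[k] <- min(pmin(1, (m / seq(k, m)) * sorted[seq(k, m)]))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive pairwise AUC oracle (ties count one half)
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (x in pos) for (y in neg) total <- total + (x > y) + 0.5 * (x == y)
  total / (length(pos) * length(neg))
}

# brute-force longest common substring by enumerating all substrings of a
brute_lcs_length <- function(a, b) {
  best <- 0L
  na <- nchar(a)
  for (i in seq_len(na)) {
    for (j in i:na) {
      if (j - i + 1L <= best) next
      if (grepl(substr(a, i, j), b, fixed = TRUE)) best <- j - i + 1L
    }
  }
  best
}
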