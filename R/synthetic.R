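# Synthetic cohort generator: aptamer libraries, cohorts, count matrices,
# FASTQ reads and MS pull-down tables with planted, known ground truth.
# Seed streams: seed+0 library, seed+1 cohort, seed+2 counts, seed+3 reads.

#' Generate a synthetic post-selection aptamer library
#'
#' Produces `n_aptamers` unique DNA sequences (sequencing reads cDNA, so the
#' RNA aptamers are represented in the A/C/G/T alphabet). A configured
#' fraction of aptamers is partitioned into families whose members all carry
#' the family's planted motif verbatim at a random offset; the remaining
#' aptamers are singletons containing no planted motif. A k-mer collision
#' guard (rejection sampling) ensures no two sequences share any substring of
#' the guard length other than planted motifs, so the family partition is
#' exactly recoverable by substring clustering. Baseline log2 abundances are
#' i.i.d. normal (log-normal abundances); members of discriminative families
#' share the configured effect size on the configured contrast.
#'
#' @param config A [sim_config()].
#' @return An object of class `aptamer_library`: a list with `aptamers` (a
#'   data frame with columns `aptamer_id`, `sequence`, `family_id`, `motif`,
#'   `baseline_log2`, `effect_log2fc`), `effect_contrast`, and `config`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_aptamers
  L <- config$variable_region_length
  mlen <- config$family_motif_length
  k <- min(config$collision_guard, if (config$n_families > 0L) mlen else config$collision_guard)

  n_fam <- config$n_families
  n_in_fam <- round(config$fraction_in_families * n)
  if (n_fam == 0L || n_in_fam < 2L) {
    n_fam <- 0L
    n_in_fam <- 0L
  }
  fam_sizes <- integer(0)
  if (n_fam > 0L) {
    base <- n_in_fam %/% n_fam
    rem <- n_in_fam %% n_fam
    fam_sizes <- base + as.integer(seq_len(n_fam) <= rem)
    if (any(fam_sizes < 2L)) {
      stopf("family configuration leaves a family with < 2 members (%d aptamers over %d families)",
            n_in_fam, n_fam)
    }
  }

  # Tagged k-mer registry: each guard-length k-mer maps to the family that
  # owns it, or "G" for background/singleton k-mers. A candidate may reuse a
  # k-mer only when the k-mer overlaps its own planted motif occurrence and
  # is owned by its own family (sharing that is expected by design); any
  # other reuse would create a spurious substring link between sequences of
  # different families, so the candidate is rejected and redrawn.
  registry <- new.env(hash = TRUE, parent = emptyenv())
  tag_of <- function(km) if (exists(km, envir = registry, inherits = FALSE))
    get(km, envir = registry, inherits = FALSE) else NA_character_

  draw_until <- function(gen, ok, max_tries = 10000L) {
    for (i in seq_len(max_tries)) {
      cand <- gen()
      if (ok(cand)) return(cand)
    }
    stopf("could not generate a collision-free sequence after %d tries", max_tries)
  }

  # candidate acceptance/registration; overlap_range = positions (1-based,
  # inclusive) of the candidate's own motif occurrence, NULL for singletons
  admit <- function(s, fam_tag, overlap_range = NULL) {
    starts <- seq_len(nchar(s) - k + 1L)
    kms <- substring(s, starts, starts + k - 1L)
    overlaps_own <- if (is.null(overlap_range)) rep(FALSE, length(starts)) else
      starts <= overlap_range[2L] & (starts + k - 1L) >= overlap_range[1L]
    tags <- vapply(kms, tag_of, character(1), USE.NAMES = FALSE)
    hit <- !is.na(tags)
    if (any(hit & !(overlaps_own & tags == fam_tag))) return(FALSE)
    for (i in which(!hit)) {
      assign(kms[i], if (overlaps_own[i]) fam_tag else "G", envir = registry)
    }
    TRUE
  }

  # family motifs: their own k-mers must be globally fresh
  motifs <- character(n_fam)
  for (f in seq_len(n_fam)) {
    fam_tag <- sprintf("fam_%02d", f)
    motifs[f] <- draw_until(
      function() random_dna(mlen),
      function(m) {
        if (any(!is.na(vapply(seq_kmers(m, k), tag_of, character(1))))) return(FALSE)
        for (km in seq_kmers(m, k)) assign(km, fam_tag, envir = registry)
        TRUE
      }
    )
  }

  seqs <- character(n)
  family_id <- rep(NA_character_, n)
  motif_of <- rep(NA_character_, n)
  idx <- 1L
  for (f in seq_len(n_fam)) {
    fam <- sprintf("fam_%02d", f)
    motif <- motifs[f]
    for (m in seq_len(fam_sizes[f])) {
      offset <- NA_integer_
      s <- draw_until(
        function() {
          offset <<- sample.int(L - mlen + 1L, 1L) - 1L
          bg <- random_dna(L - mlen)
          paste0(substr(bg, 1L, offset), motif,
                 substr(bg, offset + 1L, L - mlen))
        },
        function(s) admit(s, fam, overlap_range = c(offset + 1L, offset + mlen))
      )
      seqs[idx] <- s
      family_id[idx] <- fam
      motif_of[idx] <- motif
      idx <- idx + 1L
    }
  }
  while (idx <= n) {
    seqs[idx] <- draw_until(
      function() random_dna(L),
      function(s) admit(s, "G")
    )
    idx <- idx + 1L
  }

  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  n_disc <- ceiling(config$fraction_discriminative_families * n_fam)
  disc_fams <- if (n_disc > 0) sprintf("fam_%02d", seq_len(n_disc)) else character(0)
  effect <- ifelse(!is.na(family_id) & family_id %in% disc_fams,
                   config$effect_log2fc, 0)

  aptamers <- data.frame(
    aptamer_id = sprintf("apt_%0*d", nchar(n), seq_len(n)),
    sequence = seqs,
    family_id = family_id,
    motif = motif_of,
    baseline_log2 = baseline,
    effect_log2fc = effect,
    stringsAsFactors = FALSE
  )
  structure(
    list(aptamers = aptamers,
         effect_contrast = config$effect_contrast,
         config = config),
    class = "aptamer_library"
  )
}

#' @export
print.aptamer_library <- function(x, ...) {
  a <- x$aptamers
  cat(sprintf("aptamer_library: %d aptamers (%d in %d families), %d with planted effect on %s\n",
              nrow(a), sum(!is.na(a$family_id)),
              length(unique(stats::na.omit(a$family_id))),
              sum(a$effect_log2fc != 0), x$effect_contrast))
  invisible(x)
}

#' Map Kleiner fibrosis stage to the analysis fibrosis group
#'
#' Stage 0 maps to `F0`, stages 1 and 2 to `F1_2`, stages 3 and 4 to `F3_4`.
#'
#' @param stage Integer vector of fibrosis stages in 0..4.
#' @return Character vector of fibrosis groups.
#' @export
map_fibrosis_group <- function(stage) {
  stage <- as.integer(stage)
  if (any(is.na(stage) | stage < 0L | stage > 4L)) {
    stopf("fibrosis stage must lie in 0..4")
  }
  c("F0", "F1_2", "F1_2", "F3_4", "F3_4")[stage + 1L]
}

#' Generate a synthetic cohort with clinical covariates
#'
#' Samples are labelled by steatohepatitis group per `config$group_sizes`;
#' fibrosis stages are drawn per group (healthy controls are F0; the MASH
#' group skews toward advanced fibrosis) and mapped deterministically to
#' fibrosis groups. Clinical covariates (age, BMI, LDL, sCD163, AST, ALT,
#' platelets, metabolic syndrome) are drawn from distributions loosely
#' matching a MASLD population, with mild severity shifts in the MASH group.
#'
#' @param config A [sim_config()].
#' @return A data frame of per-sample metadata (one row per sample).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  gs <- config$group_sizes
  groups <- rep(names(gs), times = gs)
  n <- length(groups)
  if (n < 1L) stopf("cohort must contain at least one sample")

  stage_probs <- list(
    healthy      = c(1, 0, 0, 0, 0),
    MASLD_no_SH  = c(0.50, 0.25, 0.15, 0.07, 0.03),
    MASH         = c(0.12, 0.18, 0.25, 0.28, 0.17)
  )
  stage <- vapply(groups, function(g) {
    sample(0:4, 1L, prob = stage_probs[[g]])
  }, integer(1))

  is_mash <- groups == "MASH"
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  meta <- data.frame(
    sample_id = sprintf("S%0*d", nchar(n), seq_len(n)),
    cohort = "synthetic",
    steatohepatitis_group = groups,
    fibrosis_stage = stage,
    fibrosis_group = map_fibrosis_group(stage),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.65, 0.35)),
    age = round(clip(stats::rnorm(n, 45, 11), 18, 75)),
    BMI = round(clip(stats::rnorm(n, 31, 5), 18, 55), 1),
    LDL = round(clip(stats::rnorm(n, 3.3, 0.9), 0.5, 8), 2),
    sCD163 = round(stats::rlnorm(n, log(1.8) + 0.25 * is_mash, 0.35), 2),
    AST = round(stats::rlnorm(n, log(40) + 0.30 * is_mash, 0.45), 1),
    ALT = round(stats::rlnorm(n, log(55) + 0.25 * is_mash, 0.50), 1),
    platelets = round(clip(stats::rnorm(n, 250, 60), 50, 600)),
    metabolic_syndrome = stats::rbinom(n, 1, 0.25 + 0.3 * is_mash) == 1,
    library_size = round(stats::runif(n, config$library_size_range[1],
                                      config$library_size_range[2])),
    stringsAsFactors = FALSE
  )
  rownames(meta) <- NULL
  meta
}

contrast_indicator <- function(metadata, contrast) {
  switch(contrast,
    MASH = metadata$steatohepatitis_group == "MASH",
    F3_4 = metadata$fibrosis_group == "F3_4",
    metabolic_syndrome = as.logical(metadata$metabolic_syndrome),
    stopf("unknown effect contrast '%s'", contrast)
  )
}

#' Simulate a samples-by-aptamers count matrix
#'
#' Counts for aptamer i in sample j are negative binomial with mean
#' `library_size_j * p_ij` and dispersion phi, where
#' `p_ij` is proportional to `2^(baseline_i + effect_i * x_j)` normalized over
#' aptamers and `x_j` is the sample's indicator for the configured effect
#' contrast. With `nb_dispersion = 0` counts are Poisson.
#'
#' @param library An [generate_library()] result.
#' @param cohort A metadata data frame from [generate_cohort()].
#' @param config A [sim_config()].
#' @return An [apta_counts] object (samples x aptamers) carrying the library
#'   sequences and a `truth` attribute with the planted per-aptamer effects.
#' @export
simulate_counts <- function(library, cohort, config) {
  stopifnot(inherits(library, "aptamer_library"))
  if (nrow(library$aptamers) == 0L || nrow(cohort) == 0L) {
    stopf("library and cohort must be non-empty")
  }
  set.seed(config$seed + 2L)
  apt <- library$aptamers
  x <- as.numeric(contrast_indicator(cohort, library$effect_contrast))
  log2mu <- matrix(apt$baseline_log2, nrow(cohort), nrow(apt), byrow = TRUE) +
    outer(x, apt$effect_log2fc)
  w <- 2^log2mu
  p <- w / rowSums(w)
  mu <- p * cohort$library_size
  phi <- config$nb_dispersion
  counts <- if (phi > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
           nrow(cohort), nrow(apt))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow(cohort), nrow(apt))
  }
  obj <- apta_counts(counts,
                     sample_ids = cohort$sample_id,
                     aptamer_ids = apt$aptamer_id,
                     sequences = stats::setNames(apt$sequence, apt$aptamer_id))
  attr(obj, "truth") <- list(
    contrast = library$effect_contrast,
    effect_log2fc = stats::setNames(apt$effect_log2fc, apt$aptamer_id),
    discriminative = apt$aptamer_id[apt$effect_log2fc != 0],
    expected_proportions = p
  )
  obj
}

mutate_bases <- function(reads, rate) {
  vapply(reads, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write per-sample FASTQ files for a simulated count matrix
#'
#' Each read is `primer_5p + variable region + primer_3p` with a constant
#' Phred+33 quality string; read multiplicities equal the count matrix
#' exactly when `sequencing_error_rate = 0`.
#'
#' @param counts An [apta_counts] object whose aptamer ids resolve to
#'   sequences in `library`.
#' @param library The [generate_library()] result the counts came from.
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if missing); one
#'   `<sample_id>.fastq` per sample.
#' @return Invisibly, the named vector of written file paths.
#' @export
simulate_reads <- function(counts, library, config, out_dir) {
  stopifnot(inherits(counts, "apta_counts"), inherits(library, "aptamer_library"))
  set.seed(config$seed + 3L)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stopf("cannot create output directory '%s'", out_dir)
  }
  apt <- library$aptamers
  seq_of <- stats::setNames(apt$sequence, apt$aptamer_id)
  missing <- setdiff(colnames(counts$counts), names(seq_of))
  if (length(missing)) stopf("counts contain aptamers absent from library: %s", missing[1])

  paths <- character(nrow(counts$counts))
  names(paths) <- counts$sample_ids
  for (j in seq_along(counts$sample_ids)) {
    sid <- counts$sample_ids[j]
    cnt <- counts$counts[j, ]
    regions <- rep(seq_of[colnames(counts$counts)], times = cnt)
    reads <- paste0(config$primer_5p, regions, config$primer_3p)
    if (config$sequencing_error_rate > 0 && length(reads)) {
      reads <- mutate_bases(reads, config$sequencing_error_rate)
    }
    path <- file.path(out_dir, paste0(sid, ".fastq"))
    con <- file(path, open = "wt")
    ok <- tryCatch({
      if (length(reads)) {
        ids <- sprintf("@%s_read%d", sid, seq_along(reads))
        qual <- strrep("I", nchar(reads))
        writeLines(rbind(ids, reads, "+", qual), con)
      }
      TRUE
    }, error = function(e) {
      stopf("failed writing FASTQ '%s': %s", path, conditionMessage(e))
    }, finally = close(con))
    paths[j] <- path
  }
  invisible(paths)
}

#' Simulate a triplicate MS pull-down intensity table
#'
#' For each aptamer the true target protein receives a dominant share of the
#' run's total intensity (drawn uniformly from `dominant_share`), the
#' remainder is Dirichlet-spread over the other proteins, and each of the
#' three replicate runs applies independent multiplicative log-normal noise
#' per protein.
#'
#' @param truth Named character vector mapping aptamer ids to their true
#'   target protein id.
#' @param n_background_proteins Number of non-target background proteins.
#' @param noise_sd Standard deviation of the log-normal replicate noise (log
#'   scale).
#' @param dominant_share Range (min, max) of the true target's intensity
#'   share.
#' @param seed Integer seed.
#' @return An [ms_intensity_table] with three replicate runs per aptamer and
#'   a `truth` attribute.
#' @export
simulate_ms_table <- function(truth, n_background_proteins = 30L,
                              noise_sd = 0.5, dominant_share = c(0.4, 0.7),
                              seed = 1L) {
  if (length(truth) < 1L || is.null(names(truth))) {
    stopf("truth must be a named aptamer -> protein map")
  }
  set.seed(as.integer(seed))
  proteins <- sort(unique(c(unname(truth),
                            sprintf("BG_%03d", seq_len(n_background_proteins)))))
  aptamers <- names(truth)
  n_runs <- 3L * length(aptamers)
  run_info <- data.frame(
    aptamer_id = rep(aptamers, each = 3L),
    replicate = rep(1:3, times = length(aptamers)),
    stringsAsFactors = FALSE
  )
  intens <- matrix(0, length(proteins), n_runs,
                   dimnames = list(proteins,
                                   sprintf("%s_r%d", run_info$aptamer_id, run_info$replicate)))
  for (i in seq_along(aptamers)) {
    target <- truth[[aptamers[i]]]
    s <- stats::runif(1, dominant_share[1], dominant_share[2])
    others <- setdiff(proteins, target)
    bg <- stats::rgamma(length(others), shape = 1)
    base <- stats::setNames(numeric(length(proteins)), proteins)
    base[target] <- s
    base[others] <- (1 - s) * bg / sum(bg)
    for (r in 1:3) {
      noise <- exp(stats::rnorm(length(proteins), 0, noise_sd))
      intens[, (i - 1L) * 3L + r] <- 1e7 * base * noise
    }
  }
  obj <- ms_intensity_table(intens, run_info)
  attr(obj, "truth") <- truth
  obj
}
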