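#' Simulation configuration for the synthetic cohort generator
#'
#' Collects every knob of the synthetic-data module in one validated object.
#' The defaults describe the study conditions the package is exercised under:
#' a post-selection aptamer pool of 500 sequences in which 10 families of 5
#' aptamers (10% of the pool) carry a planted group effect of 1 log2 unit on
#' the steatohepatitis contrast, negative-binomial count noise with common
#' dispersion 0.3, and two groups of 40 samples each (a development-cohort
#' style design with no healthy controls).
#'
#' @param n_aptamers Number of distinct aptamers in the library.
#' @param n_families Number of planted sequence families.
#' @param fraction_in_families Fraction of aptamers that belong to a family
#'   (the remainder are singletons with no planted motif).
#' @param fraction_discriminative_families Fraction of families that carry the
#'   planted group effect.
#' @param family_motif_length Length (nt) of the exact motif shared by all
#'   members of a family.
#' @param variable_region_length Length (nt) of the variable region of every
#'   aptamer.
#' @param primer_5p,primer_3p Constant flank sequences added to every read.
#' @param group_sizes Named integer vector of samples per steatohepatitis
#'   group (`healthy`, `MASLD_no_SH`, `MASH`).
#' @param baseline_log2_mean,baseline_log2_sd Parameters of the normal
#'   distribution of per-aptamer baseline log2 abundance (a log-normal
#'   abundance profile, reproducing a steep rank-abundance curve).
#' @param effect_log2fc Planted log2 fold change for members of discriminative
#'   families on `effect_contrast`.
#' @param effect_contrast Which sample indicator the effect acts on: `"MASH"`
#'   (steatohepatitis group), `"F3_4"` (advanced fibrosis) or
#'   `"metabolic_syndrome"`.
#' @param nb_dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param library_size_range Range (min, max) of per-sample total read counts,
#'   drawn uniformly.
#' @param sequencing_error_rate Per-base substitution rate applied when
#'   writing reads; default 0 so read-count round trips are exact.
#' @param collision_guard No two generated sequences share any substring of
#'   this length except planted motifs (rejection sampling); guarantees the
#'   planted family partition is exactly recoverable by substring clustering
#'   at thresholds down to this length. Internally capped at
#'   `family_motif_length`.
#' @param seed Integer seed; fixes all generator randomness end to end.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_aptamers = 500L,
                       n_families = 10L,
                       fraction_in_families = 0.1,
                       fraction_discriminative_families = 1.0,
                       family_motif_length = 16L,
                       variable_region_length = 40L,
                       primer_5p = "GGGAGACAAGAATAAACGCT",
                       primer_3p = "TTCGACAGGAGGCTCACAAC",
                       group_sizes = c(healthy = 0L, MASLD_no_SH = 40L, MASH = 40L),
                       baseline_log2_mean = 0,
                       baseline_log2_sd = 2,
                       effect_log2fc = 1.0,
                       effect_contrast = "MASH",
                       nb_dispersion = 0.3,
                       library_size_range = c(5e4, 2e5),
                       sequencing_error_rate = 0,
                       collision_guard = 12L,
                       seed = 1L) {
  cfg <- list(
    n_aptamers = as.integer(n_aptamers),
    n_families = as.integer(n_families),
    fraction_in_families = fraction_in_families,
    fraction_discriminative_families = fraction_discriminative_families,
    family_motif_length = as.integer(family_motif_length),
    variable_region_length = as.integer(variable_region_length),
    primer_5p = normalize_sequence(primer_5p),
    primer_3p = normalize_sequence(primer_3p),
    group_sizes = group_sizes,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    effect_log2fc = effect_log2fc,
    effect_contrast = effect_contrast,
    nb_dispersion = nb_dispersion,
    library_size_range = as.numeric(library_size_range),
    sequencing_error_rate = sequencing_error_rate,
    collision_guard = as.integer(collision_guard),
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_aptamers < 1L) stopf("n_aptamers must be positive")
    if (n_families < 0L) stopf("n_families must be >= 0")
    if (variable_region_length < 1L) stopf("variable_region_length must be positive")
    if (family_motif_length < 1L) stopf("family_motif_length must be positive")
    if (n_families > 0L && family_motif_length >= variable_region_length) {
      stopf("family_motif_length (%d) must be smaller than variable_region_length (%d)",
            family_motif_length, variable_region_length)
    }
    if (fraction_in_families < 0 || fraction_in_families > 1) {
      stopf("fraction_in_families must lie in [0, 1]")
    }
    if (fraction_discriminative_families < 0 || fraction_discriminative_families > 1) {
      stopf("fraction_discriminative_families must lie in [0, 1]")
    }
    if (!nzchar(primer_5p) || !nzchar(primer_3p)) stopf("primers must be non-empty")
    if (any(group_sizes < 0)) stopf("group sizes must be >= 0")
    if (sum(group_sizes) < 1) stopf("cohort must contain at least one sample")
    if (baseline_log2_sd < 0) stopf("baseline_log2_sd must be >= 0")
    if (nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
    if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
        diff(library_size_range) < 0) {
      stopf("library_size_range must be an increasing positive pair")
    }
    if (sequencing_error_rate < 0 || sequencing_error_rate > 1) {
      stopf("sequencing_error_rate must lie in [0, 1]")
    }
    if (collision_guard < 4L) stopf("collision_guard must be >= 4")
    if (!effect_contrast %in% c("MASH", "F3_4", "metabolic_syndrome")) {
      stopf("effect_contrast must be one of MASH, F3_4, metabolic_syndrome")
    }
  })
  # guard feasibility: generated k-mers must be sparse in 4^k space
  k <- min(cfg$collision_guard, if (cfg$n_families > 0L) cfg$family_motif_length else cfg$collision_guard)
  n_kmers <- cfg$n_aptamers * (cfg$variable_region_length - k + 1)
  if (n_kmers > 0.25 * 4^k) {
    stopf("collision guard infeasible: %d sequences of %d nt saturate the %d-mer space",
          cfg$n_aptamers, cfg$variable_region_length, k)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d aptamers (%d families, motif %d nt) x %d samples, seed %d\n",
              x$n_aptamers, x$n_families, x$family_motif_length,
              sum(x$group_sizes), x$seed))
  invisible(x)
}
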