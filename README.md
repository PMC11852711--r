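# aptapanel

Aptamer pool profiling for biomarker panel selection and scoring.

## The problem

Profiling a plasma proteome with an enriched pool of RNA aptamers turns a
binding assay into a sequencing experiment: each plasma sample is incubated
with the selected pool, bound aptamers are sequenced, and the per-aptamer
read count reflects how much of each aptamer's protein epitope the sample
carries. Downstream of sequencing, the analytical task is to find the
aptamers whose abundance separates clinical groups — for example patients
with metabolic dysfunction-associated steatotic liver disease (MASLD)
without steatohepatitis versus those with steatohepatitis (MASH), or
histological fibrosis stages F0 versus F3–4 — to turn those aptamers into a
deployable one-number score per sample, and to find out which plasma
proteins the discriminative aptamers actually bind.

`aptapanel` implements that downstream pipeline for analysts working with
sequenced aptamer-pool data:

1. **Counting** — collapse primer-flanked FASTQ reads to a samples ×
   aptamers count matrix (`parse_pool_reads()`, `build_count_matrix()`), or
   read a precomputed count TSV.
2. **Abundance filtering** — rank aptamers by total count, inspect the
   zeros-versus-rank profile, keep the top K (default 500) most abundant
   aptamers, and run boxplot-style QC of per-sample totals
   (`rank_aptamers()`, `zero_profile()`, `select_top_k()`,
   `qc_sample_summary()`).
3. **Panel selection** — log2 counts-per-million normalization with a
   pseudocount, median-ratio compositional alignment, per-aptamer ordinary
   least squares (OLS) regression on the group indicator, and
   Benjamini–Hochberg correction. An aptamer joins the panel when its
   BH-adjusted p ≤ 0.05 and |log2 coefficient| ≥ 0.25
   (`select_discriminative()`).
4. **PC1 scoring** — the panel's first principal component, fitted once on
   the training cohort (center + unit loading + orientation) and projected
   onto any cohort; group separation is evaluated with Wilcoxon rank tests
   and the Mann–Whitney AUC with DeLong 95% confidence intervals
   (`fit_panel_projection()`, `project_scores()`, `auc_delong()`), with the
   usual qualification bands (acceptable 0.70–0.80, excellent 0.80–0.90,
   outstanding ≥ 0.90).
5. **Aptamer families** — single-linkage clustering of aptamers that share
   an exact sequence motif of ≥ 12 nt, with the most abundant family member
   as representative (`cluster_families()`, `select_representatives()`).
6. **Target assignment** — mass-spectrometry pull-down intensities are
   converted to percent of total signal per run, averaged over triplicates,
   log2-transformed, and each aptamer is assigned the protein with the
   highest mean percent as most probable target, reporting dual targets
   within 2-fold (`normalize_and_aggregate()`, `assign_targets()`).

Because real plasma/sequencing cohorts of this kind are rarely public, the
package ships a first-class synthetic-cohort generator with planted ground
truth (`sim_config()`, `generate_library()`, `generate_cohort()`,
`simulate_counts()`, `simulate_reads()`, `simulate_ms_table()`): aptamer
families sharing exact motifs, log-normal baseline abundances,
negative-binomial counts with group effects planted at family level,
clinical covariates (including FIB-4 and AST/ALT comparator inputs), and
triplicate MS intensity tables with a dominant true target. Every pipeline
stage is tested against this known truth.

## The core statistics

Per aptamer, for groups A and B on the log2 scale, OLS of abundance on an
intercept plus the B indicator gives coefficient
`b = mean(B) − mean(A)` and the two-sided p-value of the pooled-variance t
statistic with `n_A + n_B − 2` degrees of freedom. BH adjustment is the
step-up rule `q(k) = min_{j≥k} (m/j) p(j)`. The panel score is
`s = ⟨x − c, v⟩ · o` with training center `c`, first right singular vector
`v` (‖v‖₂ = 1) and orientation `o ∈ {±1}` chosen so the disease-ward class
scores higher. The AUC is the Mann–Whitney statistic (ties counted ½) with
DeLong's placement-value variance `var(V₁₀)/n₊ + var(V₀₁)/n₋` and the Wald
95% CI `auc ± 1.96·√V`, clipped to [0, 1].

## Worked example

```r
library(aptapanel)

cfg    <- sim_config(seed = 42)          # 500 aptamers, 10 planted families, 40 vs 40
lib    <- generate_library(cfg)
cohort <- generate_cohort(cfg)
counts <- simulate_counts(lib, cohort, cfg)

top      <- select_top_k(counts, rank_aptamers(counts), 500)
contrast <- make_contrast(cohort, "steatohepatitis_group", "MASLD_no_SH", "MASH")
sel      <- select_discriminative(top, contrast)
sel$panel
#> apta_panel: 52 members (48 up, 4 down) of 500 tested
#> contrast steatohepatitis_group: MASLD_no_SH (n=40) vs MASH (n=40)

model  <- fit_panel_projection(sel$abundance, sel$panel, positive = contrast$samples_B)
scores <- project_scores(model, sel$abundance)
auc_delong(scores, cohort$steatohepatitis_group == "MASH")
#> AUC 1.000 (95% CI 1.000-1.000), n_pos 40, n_neg 40

cluster_families(setNames(lib$aptamers$sequence,
                          lib$aptamers$aptamer_id)[sel$panel$members], 12)
#> aptamer_families: 52 aptamers in 15 families (10 multi-member, 5 singletons) at motif >= 12 nt

mean(attr(counts, "truth")$discriminative %in% sel$panel$members)
#> [1] 0.94
```

The 52-member panel recovers 94% of the 50 planted discriminative aptamers
at this seed; the PC1 score separates the two simulated groups completely
(the planted log2 effect of 1.0 per family member is strong relative to the
negative-binomial noise at these library sizes); and the panel members
collapse back into the planted sequence families.

A full run — ingestion, QC, filtering, selection, scoring, cross-cohort
evaluation, families and MS targets, with TSV artifacts and a JSON manifest
— is driven by `run_pipeline()` and a YAML config (see
`?pipeline_config`), or from a shell via the thin wrapper
`inst/scripts/aptapanel.R` (`simulate` and `run` subcommands).

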