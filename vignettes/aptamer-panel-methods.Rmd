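---
title: "Methods: aptamer pool profiling, panel selection and scoring"
author: "aptapanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aptamer pool profiling, panel selection and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptapanel)
```

## Overview

`aptapanel` analyses sequenced aptamer pools used to profile the plasma
proteome. A pool of RNA aptamers enriched by several rounds of selection
against pooled plasma is incubated with each sample; the sequencing read
count of each aptamer reflects the abundance of its protein epitope in that
sample. The pipeline ranks aptamers by abundance, keeps the most abundant
set, selects a discriminative panel for a clinical contrast by per-aptamer
regression, condenses the panel to a one-dimensional principal-component
score per sample, evaluates stratification by AUC with DeLong confidence
intervals, groups aptamers into sequence families, and assigns each family
a most probable protein target from pull-down mass spectrometry.

This vignette documents the statistical model, the tunable parameters and
their defaults, the synthetic-data generator the test suite relies on, and
the numerical and design choices made where the problem left the design
open.

## Counting and abundance filtering

Reads have the form `5' primer + variable region + 3' primer`. Parsing
(`parse_pool_reads()`) requires both flanks (exact prefix/suffix match by
default; a Hamming mismatch budget per flank is available) and a variable
region of the expected length (tolerance 0 by default); everything else is
discarded and tallied by reason (`no_5p`, `no_3p`, `bad_length`). Sequences
are uppercased and U is mapped to T: aptamers are RNA but sequencing reads
cDNA, and one alphabet avoids U/T mismatches throughout. Reads whose region
length deviates are discarded rather than padded — the simplest rule, and
the report makes the loss visible.

`build_count_matrix()` gives one column per distinct variable-region
sequence; aptamer identifiers are assigned as `apt_<rank>` after ranking by
total count (ties broken lexicographically by sequence), so identifiers are
deterministic across runs and machines.

Aptamers are then ranked by total count over all samples
(`rank_aptamers()`; ties again break lexicographically). The
zeros-versus-rank curve (`zero_profile()`) shows where counts become too
sparse to normalize meaningfully; the suggested cutoff is the rank
maximizing the forward difference of a moving-average smoothed curve
(window 25). The suggestion is a diagnostic only: selection uses the
configured `top_k` (default 500), because a visual knee is not a
reproducible quantity. QC (`qc_sample_summary()`) summarizes per-sample
totals within groups and flags samples outside the Tukey fences
Q1 − 1.5·IQR, Q3 + 1.5·IQR; flags are advisory and nothing is excluded
automatically — exclusion is an explicit analyst decision.

## Normalization and compositional alignment

Counts are transformed to `log2(count / total * 1e6 + pseudocount)` with
pseudocount 1 on the CPM scale (`normalize_log2cpm()`): CPM removes
library-size differences, the pseudocount handles zeros, and on the log2
scale the panel threshold "|coefficient| ≥ 0.25" reads directly as a
fold-change bound. TMM effective library sizes are available as an option.

Relative abundances are compositional: when a subset of aptamers rises in
one group, the CPM of every other aptamer falls in concert. Under the
generator's default conditions (10% of aptamers doubling in one group) this
shift reaches 0.1–0.2 log2 units — large enough to push null aptamers past
the 0.25 coefficient threshold and inflate the false discovery rate several
fold. Standard scaling-factor estimators (TMM, relative log expression,
upper quartile) under-correct here: their count-based precision weights
concentrate on a handful of extremely abundant aptamers whose
overdispersion the weights do not model. `align_abundance()` therefore
subtracts, per sample, the *unweighted median* deviation of the sample's
log2-CPM values from a reference profile (the per-aptamer median), computed
over an invariant aptamer set.

One pass is not quite enough: a one-directional differential subset
contaminates even the median (10% contamination moves it by roughly 0.05
here). `select_discriminative()` therefore runs selection twice — pass one
aligns on all aptamers and selects a provisional panel; pass two re-aligns
using only the non-selected (invariant) aptamers and reselects. On null
data pass one selects (almost) nothing, so the procedure reduces to plain
median alignment and inherits its calibration. The alignment reference and
invariant set are returned so external cohorts can be placed on exactly
the training scale before projection.

## Panel selection

For a two-group contrast (the positive, disease-ward group is `level_B`),
each aptamer is fitted by OLS on an intercept plus the group indicator. The
coefficient is the difference of group means on the log2 scale and the
p-value is the two-sided t test on the coefficient with
`n_A + n_B − 2` residual degrees of freedom — numerically identical to a
pooled-variance two-sample t test, which the test suite asserts to 1e-10.
With exactly zero residual variance the convention is p = 0 for a nonzero
coefficient and p = 1 otherwise. Benjamini–Hochberg adjustment is applied
within one contrast across the filtered (top-K) aptamers. An aptamer is a
panel member when `p_adjusted ≤ alpha` (default 0.05) **and**
`|coefficient| ≥ coef_threshold` (default 0.25). Numeric clinical variables
(e.g. LDL, sCD163) are dichotomized at the training-cohort median, values
at the cutoff going to the positive side; the cutoff is recorded so it can
be applied unchanged to other cohorts.

Three-level groupings (steatohepatitis status, fibrosis groups F0 / F1–2 /
F3–4, derived deterministically from stages 0 / 1–2 / 3–4) are handled as
pairwise contrasts on the relevant sample subsets.

## PC1 scoring and evaluation

The panel score is the first principal component of the panel submatrix:
center at the training column means, take the first right singular vector
(unit Euclidean norm) of the centered matrix, and orient so the positive
class has the higher mean training score (if class means tie exactly, the
first nonzero loading component is forced positive — PC sign is otherwise
arbitrary). Columns are left unscaled by default since log2-CPM values are
already on a common scale; unit-variance scaling is an option. Projection
uses the training center and loading everywhere (`project_scores()`), so
the score is a deployable quantity: training-cohort projection reproduces
fit-time scores exactly, and external cohorts are first median-aligned to
the training reference (previous section).

Evaluation (`evaluate_comparisons()`) produces one row per cohort ×
comparison with the Mann–Whitney AUC (ties ½), DeLong placement-value
variance `var(V10)/n_pos + var(V01)/n_neg`, the Wald 95% CI clipped to
[0, 1] (a degenerate zero variance collapses the CI to a point), a
two-sided Wilcoxon rank-sum p-value, and a qualitative band: below 0.70
below-acceptable, 0.70–0.80 acceptable, 0.80–0.90 excellent, ≥ 0.90
outstanding, boundaries resolving upward (0.80 is "excellent"). A
comparison that cannot be formed in a cohort — typically an empty class,
such as no advanced-fibrosis samples — yields an N/A row with the reason,
never a dropped row. The Wilcoxon test enumerates exactly when the pooled
size is ≤ 20 without ties, otherwise it uses the normal approximation with
tie and continuity corrections; when the U statistic sits exactly at the
null center (identical score multisets) the two-sided p is reported as 1.

Comparator clinical scores are computed from metadata:
FIB-4 = age·AST / (platelets·√ALT) and the AST/ALT ratio; missing inputs
propagate to missing outputs, never silent zeros. They feed `auc_delong()`
as generic score columns, exactly like sCD163 or CK18 values supplied in
the metadata.

## Aptamer families and MS target assignment

Two aptamers belong to the same family when they share an exact substring
of at least `min_motif_length` nt (default 12; "extended sequence motif"
operationalized as an exact match — deterministic and directly testable);
families are the connected components of the sharing graph
(single-linkage). Clustering must run on variable regions only: constant
primer flanks would link everything. Each family reports a witness motif (a
longest common substring over its links) and its most abundant member as
representative (ties: lexicographically smallest sequence). Since sharing
a k-mer is equivalent to sharing a substring of length ≥ k, the
implementation indexes k-mers rather than computing all-pairs longest
common substrings.

MS pull-down intensities (proteins × triplicate runs per aptamer) are
normalized per run to percent of total signal, averaged over the
triplicate, and log2-transformed after flooring at 0.01% (the floor only
prevents −∞ for absent proteins and is recorded in the output). The
aggregation order is percent → mean → log2, in that order. The most
probable target is the protein with the highest mean percent; a runner-up
within a log2 margin of 1.0 (2-fold) is reported as a dual target
("primary/secondary"). The margin quantifies "comparable binding" and is
configurable.

## The synthetic-cohort generator

No public data exist for this assay type, so the generator *defines* the
study conditions the package is validated under:

| parameter | default | rationale |
|---|---|---|
| `n_aptamers` | 500 | the post-filter analysis set size |
| `n_families` × members | 10 × 5 | 10% of the pool in planted families |
| `family_motif_length` | 16 nt | "extended" motif, comfortably above the clustering threshold 12 |
| `variable_region_length` | 40 nt | typical variable-region length |
| `baseline_log2` | N(0, 2) | log-normal abundances give the steep rank-abundance curve of enriched pools |
| `effect_log2fc` | 1.0 | planted per-family group effect (MASH contrast) |
| `nb_dispersion` | 0.3 | overdispersed counts, variance = mu + 0.3·mu² |
| `group_sizes` | 0 / 40 / 40 | development-cohort style: no healthy controls |
| `library_size_range` | 5e4–2e5 | per-sample totals, uniform |
| `sequencing_error_rate` | 0 | read round-trips are exact by default |

Counts for aptamer i in sample j are negative binomial with mean
`library_size_j · p_ij`, where `p_ij ∝ 2^(baseline_i + effect_i·x_j)`
normalized over aptamers and `x_j` the sample's contrast indicator. Effects
are planted at family level because family members are assumed to bind the
same epitope, making biological signal family-coherent. Clinical
covariates are drawn from distributions loosely matching a MASLD
population, with mild severity shifts in the MASH group; fibrosis stages
are drawn per group and mapped 0→F0, 1–2→F1–2, 3–4→F3–4.

Two generator details matter for interpretation:

* **Collision guard.** Independent random 40-mers share a 12-mer more often
  than intuition suggests (about 6 expected sharing pairs among 500
  sequences), which would make the planted family partition unrecoverable
  in a seed-dependent way. The generator rejection-samples so that no two
  sequences share any guard-length (default 12 nt) substring except planted
  motifs; within-family sharing that overlaps a member's own motif is
  exempt, since it cannot change the partition. Family recovery is
  therefore exactly testable (adjusted Rand index 1).
* **What the generator does not emulate.** SELEX enrichment dynamics across
  rounds, batch effects between cohorts, sequencing error structure beyond
  uniform substitutions, aptamer cross-hybridization, and degenerate or
  approximate motifs. Tests passing on synthetic data therefore demonstrate
  the pipeline's statistical behaviour under a known generative model, not
  performance on real plasma cohorts.

The MS simulator gives the true target a dominant share (uniform 0.4–0.7)
of each run's intensity, spreads the rest over background proteins by a
Dirichlet draw, and applies log-normal noise (sd 0.5) per protein per
replicate — enough separation that assignment accuracy is expected near
100%, degrading gracefully as `noise_sd` grows.

## Numerical choices and degenerate inputs

* All randomness in the generator is a pure function of `seed`; the
  stages use fixed offsets of the seed so library, cohort, counts and reads
  have independent streams.
* Ties: abundance ranks and representatives break lexicographically;
  `argmax` ties in target assignment take the lexicographically smallest
  protein id; AUC and Wilcoxon count ties as ½.
* Degenerate inputs: a header-only count table is a valid 0-sample matrix;
  zero-total samples and zero-total MS runs are errors naming the
  offender; a rank-0 (all-constant) training submatrix is an error;
  single-sample QC groups are skipped, not flagged; an empty panel is
  allowed and reported, not an error.
* Determinism: every tabular output is sorted by stable keys, and
  `run_pipeline()` reruns byte-identically for a fixed config (the manifest
  records the config hash and seed).

## Problem sizes in the test suite

The suite validates calibration with 50 null cohorts and recovery with 20
planted cohorts of 500 aptamers × 80 samples, DeLong coverage with 500
binormal replicates (40 vs 40, true AUC 0.8), and the statistical core
against brute-force oracles (pooled t test, step-up BH on 1000 random
vectors, exhaustive AUC pair counting up to n = 30). These sizes keep the
whole suite under a few minutes while leaving Monte-Carlo error well below
the asserted margins.

## Known limitations

* Per-aptamer OLS uses no covariates (age, sex, BMI are not adjusted for);
  group contrasts are marginal.
* Exact-substring families cannot capture degenerate motifs; a single
  shared 12-mer links two otherwise unrelated aptamers (single linkage is
  deliberately permissive).
* The DeLong CI is the Wald form with clipping; near AUC = 1 it is known to
  undercover, which is visible at the lower edge of the coverage band.
* MS assignment operates on protein-level intensity tables; peptide
  identification and protein inference are upstream of this package.
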