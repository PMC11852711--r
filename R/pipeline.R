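# End-to-end orchestration: configuration, staged execution, stable TSV
# outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Can be
#' constructed programmatically or loaded from YAML with
#' [read_pipeline_config()].
#'
#' @param cohorts Named list; each element `list(counts = <tsv>, metadata =
#'   <tsv>, role = "development"|"evaluation")`. Exactly one cohort must have
#'   the development (training) role.
#' @param panels Named list of training contrast specs (`list(variable,
#'   level_A, level_B)` or `list(variable, dichotomize = TRUE)`), one
#'   discriminative panel is selected and scored per entry.
#' @param comparisons Named list of evaluation comparison specs (same shape
#'   as `panels`); every panel is evaluated on every cohort x comparison.
#' @param selection A [panel_config()].
#' @param sequences Optional TSV path (`aptamer_id`, `sequence`) enabling the
#'   family-clustering stage when counts come from a table rather than
#'   FASTQ.
#' @param ms_table Optional MS intensity TSV path enabling the
#'   target-assignment stage.
#' @param min_motif_length Family clustering threshold (nt).
#' @param ms_margin,ms_floor_percent Target-assignment parameters.
#' @param qc_variables Metadata columns for the QC stage.
#' @param out_dir Output directory for the TSV/JSON artifacts.
#' @param seed Integer seed recorded in the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts, panels, comparisons,
                            selection = panel_config(),
                            sequences = NULL, ms_table = NULL,
                            min_motif_length = 12L, ms_margin = 1.0,
                            ms_floor_percent = 0.01,
                            qc_variables = c("steatohepatitis_group", "fibrosis_group", "sex"),
                            out_dir = "aptapanel_out", seed = 1L) {
  if (length(cohorts) < 1L || is.null(names(cohorts))) stopf("cohorts must be a named list")
  roles <- vapply(cohorts, function(co) co$role %||% "evaluation", character(1))
  if (sum(roles == "development") != 1L) {
    stopf("exactly one cohort must have role 'development', found %d",
          sum(roles == "development"))
  }
  if (length(panels) < 1L || is.null(names(panels))) stopf("panels must be a named list")
  if (length(comparisons) < 1L || is.null(names(comparisons))) {
    stopf("comparisons must be a named list")
  }
  structure(
    list(cohorts = cohorts, panels = panels, comparisons = comparisons,
         selection = selection, sequences = sequences, ms_table = ms_table,
         min_motif_length = as.integer(min_motif_length),
         ms_margin = ms_margin, ms_floor_percent = ms_floor_percent,
         qc_variables = qc_variables, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file with the fields above.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: '%s'", path)
  y <- yaml::read_yaml(path)
  sel <- y$selection %||% list()
  pipeline_config(
    cohorts = y$cohorts,
    panels = y$panels,
    comparisons = y$comparisons,
    selection = panel_config(
      top_k = sel$top_k %||% 500L,
      coef_threshold = sel$coef_threshold %||% 0.25,
      alpha = sel$alpha %||% 0.05,
      pseudocount = sel$pseudocount %||% 1.0),
    sequences = y$sequences,
    ms_table = y$ms_table,
    min_motif_length = y$min_motif_length %||% 12L,
    ms_margin = y$ms_margin %||% 1.0,
    ms_floor_percent = y$ms_floor_percent %||% 0.01,
    qc_variables = unlist(y$qc_variables) %||%
      c("steatohepatitis_group", "fibrosis_group", "sex"),
    out_dir = y$out_dir %||% "aptapanel_out",
    seed = y$seed %||% 1L
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' Stages, in order: count and metadata ingestion for every cohort; QC
#' summaries; abundance ranking, zero profile and top-K filtering on the
#' development cohort; per-panel differential selection (OLS + BH) on the
#' development cohort; PC1 model fit per panel; evaluation of every panel on
#' every cohort x comparison (N/A rows preserved); family clustering and
#' representative selection over the panel members (when sequences are
#' available); MS target assignment (when an MS table is configured).
#' Writes stable TSV artifacts plus a JSON run manifest (config hash, seed,
#' package and R versions) to `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list bundle with every intermediate result
#'   (`cohorts`, `qc`, `ranking`, `panels`, `models`, `evaluation`,
#'   `families`, `representatives`, `targets`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stopf("cannot create output directory '%s'", out_dir)
  }

  sequences <- NULL
  if (!is.null(config$sequences)) {
    sequences <- stage("sequences", {
      df <- utils::read.delim(config$sequences, colClasses = "character")
      stats::setNames(normalize_sequence(df$sequence), df$aptamer_id)
    })
  }

  cohorts <- stage("ingest", {
    lapply(config$cohorts, function(co) {
      counts <- read_count_table(co$counts, sequences = sequences)
      metadata <- read_metadata(co$metadata)
      missing <- setdiff(counts$sample_ids, metadata$sample_id)
      if (length(missing)) stopf("sample %s has counts but no metadata", missing[1])
      list(counts = counts, metadata = metadata, role = co$role %||% "evaluation")
    })
  })
  dev_name <- names(cohorts)[vapply(cohorts, `[[`, character(1), "role") == "development"]
  dev <- cohorts[[dev_name]]
  message(sprintf("[ingest] %d cohorts; development = %s (%d samples x %d aptamers)",
                  length(cohorts), dev_name, nrow(dev$counts$counts),
                  ncol(dev$counts$counts)))

  qc <- stage("qc", {
    vars <- intersect(config$qc_variables, names(dev$metadata))
    qc_sample_summary(dev$counts, dev$metadata, vars)
  })
  write_tsv(qc$summary, file.path(out_dir, "qc_summary.tsv"))
  write_tsv(qc$flags, file.path(out_dir, "qc_flags.tsv"))
  message(sprintf("[qc] %d advisory outlier flags", nrow(qc$flags)))

  filtered <- stage("abundance_filter", {
    ranking <- rank_aptamers(dev$counts)
    zp <- zero_profile(dev$counts, ranking)
    k <- min(config$selection$top_k, nrow(ranking))
    list(ranking = ranking, zero_profile = zp,
         counts = select_top_k(dev$counts, ranking, k))
  })
  write_tsv(filtered$ranking, file.path(out_dir, "abundance_ranking.tsv"))
  message(sprintf("[abundance_filter] kept top %d of %d aptamers (knee suggestion: %d)",
                  ncol(filtered$counts$counts), nrow(filtered$ranking),
                  filtered$zero_profile$suggested_cutoff))

  raw_eval <- lapply(cohorts, function(co) {
    keep <- intersect(filtered$counts$aptamer_ids, co$counts$aptamer_ids)
    sub <- apta_counts(co$counts$counts[, keep, drop = FALSE],
                       sequences = if (!is.null(co$counts$sequences)) co$counts$sequences[keep])
    list(abundance = normalize_log2cpm(sub, config$selection$pseudocount),
         metadata = co$metadata)
  })

  panels <- list()
  models <- list()
  evaluations <- list()
  for (pn in names(config$panels)) {
    sel <- stage(paste0("select_panel:", pn), {
      ctr <- resolve_comparison(dev$metadata, config$panels[[pn]])
      select_discriminative(filtered$counts, ctr, config$selection)
    })
    panel <- sel$panel
    dev_ab <- sel$abundance
    panels[[pn]] <- panel
    write_tsv(panel$table, file.path(out_dir, sprintf("volcano_%s.tsv", pn)))
    write_tsv(data.frame(aptamer_id = panel$members),
              file.path(out_dir, sprintf("panel_%s.tsv", pn)))
    message(sprintf("[select_panel:%s] %d members (%d up, %d down)",
                    pn, length(panel$members), panel$n_up, panel$n_down))
    if (length(panel$members) == 0L) {
      message(sprintf("[select_panel:%s] empty panel; scoring skipped", pn))
      next
    }

    model <- stage(paste0("fit_model:", pn), {
      fit_panel_projection(dev_ab, panel, positive = panel$contrast$samples_B,
                           samples = intersect(rownames(dev_ab),
                                               c(panel$contrast$samples_A,
                                                 panel$contrast$samples_B)))
    })
    models[[pn]] <- model
    scores <- project_scores(model, dev_ab)
    write_tsv(data.frame(sample_id = names(scores), pc1_score = unname(scores)),
              file.path(out_dir, sprintf("scores_%s_%s.tsv", pn, dev_name)))

    ev <- stage(paste0("evaluate:", pn), {
      eval_cohorts <- lapply(raw_eval, function(co) {
        list(abundance = align_abundance(co$abundance, sel$reference,
                                         sel$invariant),
             metadata = co$metadata)
      })
      evaluate_comparisons(model, eval_cohorts, config$comparisons)
    })
    ev <- cbind(panel = pn, ev)
    evaluations[[pn]] <- ev
  }
  evaluation <- if (length(evaluations)) do.call(rbind, evaluations) else NULL
  if (!is.null(evaluation)) {
    write_tsv(evaluation, file.path(out_dir, "evaluation.tsv"))
    message(sprintf("[evaluate] %d rows (%d N/A)",
                    nrow(evaluation), sum(is.na(evaluation$auc))))
  }

  families <- NULL
  representatives <- NULL
  panel_union <- unique(unlist(lapply(panels, `[[`, "members")))
  if (!is.null(dev$counts$sequences) && length(panel_union)) {
    families <- stage("families", {
      cluster_families(dev$counts$sequences[panel_union], config$min_motif_length)
    })
    representatives <- stage("representatives", {
      select_representatives(families, dev$counts)
    })
    write_tsv(merge(families$assignments, families$families, by = "family_id"),
              file.path(out_dir, "families.tsv"))
    write_tsv(data.frame(family_id = names(representatives),
                         representative = unname(representatives)),
              file.path(out_dir, "representatives.tsv"))
    message(sprintf("[families] %d panel aptamers -> %d families",
                    nrow(families$assignments), nrow(families$families)))
  }

  targets <- NULL
  if (!is.null(config$ms_table)) {
    targets <- stage("ms_assign", {
      tab <- read_ms_table(config$ms_table)
      profile <- normalize_and_aggregate(tab, config$ms_floor_percent)
      assign_targets(profile, config$ms_margin)
    })
    write_tsv(targets, file.path(out_dir, "targets.tsv"))
    message(sprintf("[ms_assign] %d aptamers assigned (%d dual targets)",
                    nrow(targets), sum(targets$comparable)))
  }

  manifest <- stage("manifest", {
    cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                                 auto_unbox = TRUE, force = TRUE, digits = NA)
    tmp <- tempfile()
    writeLines(cfg_json, tmp)
    list(
      package = "aptapanel",
      package_version = as.character(utils::packageVersion("aptapanel")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config_hash = unname(tools::md5sum(tmp)),
      panel_sizes = lapply(panels, function(p) length(p$members))
    )
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohorts = cohorts, qc = qc, ranking = filtered$ranking,
                 zero_profile = filtered$zero_profile, panels = panels,
                 models = models, evaluation = evaluation,
                 families = families, representatives = representatives,
                 targets = targets, manifest = manifest))
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates a library, cohort, count matrix and MS pull-down table from one
#' [sim_config()] and writes them in the pipeline's input formats:
#' `counts.tsv`, `metadata.tsv`, `sequences.tsv`, `library.tsv` (full ground
#' truth), `ms_table.tsv`, `ms_truth.tsv`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param fastq Also write per-sample FASTQ files under `out_dir/fastq`.
#' @return Invisibly, a named list of file paths.
#' @export
write_simulation_bundle <- function(config, out_dir, fastq = FALSE) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stopf("cannot create output directory '%s'", out_dir)
  }
  lib <- generate_library(config)
  cohort <- generate_cohort(config)
  counts <- simulate_counts(lib, cohort, config)
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    sequences = file.path(out_dir, "sequences.tsv"),
    library = file.path(out_dir, "library.tsv"),
    ms_table = file.path(out_dir, "ms_table.tsv"),
    ms_truth = file.path(out_dir, "ms_truth.tsv")
  )
  write_count_table(counts, paths$counts)
  write_metadata(cohort, paths$metadata)
  write_tsv(data.frame(aptamer_id = lib$aptamers$aptamer_id,
                       sequence = lib$aptamers$sequence),
            paths$sequences)
  write_tsv(lib$aptamers, paths$library)

  fams <- unique(stats::na.omit(lib$aptamers$family_id))
  protein_names <- c("CFH", "C4BPA", "FN1", "IGHG3", "ITIH2")
  if (length(fams)) {
    reps <- vapply(fams, function(f) {
      members <- lib$aptamers$aptamer_id[lib$aptamers$family_id %in% f]
      members[which.max(colSums(counts$counts[, members, drop = FALSE]))]
    }, character(1))
    truth <- stats::setNames(
      rep_len(protein_names, length(reps)), unname(reps))
    ms <- simulate_ms_table(truth, seed = config$seed + 4L)
    write_ms_table(ms, paths$ms_table)
    write_tsv(data.frame(aptamer_id = names(truth), protein_id = unname(truth)),
              paths$ms_truth)
  }
  if (fastq) {
    paths$fastq_dir <- file.path(out_dir, "fastq")
    simulate_reads(counts, lib, config, paths$fastq_dir)
  }
  invisible(paths)
}
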