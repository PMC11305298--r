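#' Build a pipeline configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()].
#' Inputs are the four TSV tables written by the `write_*` functions plus
#' an optional GMT collection; a cohort simulated in memory can be passed
#' directly to [run_pipeline()] instead via the `cohort` argument.
#'
#' @param expression,annotation paths to the expression matrix and sample
#'   annotation TSVs (required for the skin stages).
#' @param serum path to a serum panel TSV (optional stage).
#' @param qpcr path to a raw qPCR Ct table TSV (optional stage).
#' @param gene_sets path to a GMT file (optional enrichment/GSVA stages).
#' @param out_dir directory for result tables and the run report.
#' @param fc_min,fdr_max signature selection thresholds.
#' @param stability_floor minimum |mean baseline delta| for a stable
#'   percent-improvement denominator.
#' @param scar_arm arm in which the molecular scar is evaluated.
#' @param improvement_thresholds percent-improvement cutoffs summarized.
#' @param ancova_week follow-up week for the between-arm serum contrast.
#' @param lloq_policy below-LLOQ handling, see [apply_lloq_policy()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, annotation = NULL,
                            serum = NULL, qpcr = NULL, gene_sets = NULL,
                            out_dir = ".",
                            fc_min = 1.5, fdr_max = 0.05,
                            stability_floor = 0.1,
                            scar_arm = "GUS",
                            improvement_thresholds = c(75, 90),
                            ancova_week = 24,
                            lloq_policy = "half") {
  cfg <- list(expression = expression, annotation = annotation,
              serum = serum, qpcr = qpcr, gene_sets = gene_sets,
              out_dir = out_dir,
              fc_min = fc_min, fdr_max = fdr_max,
              stability_floor = stability_floor,
              scar_arm = scar_arm,
              improvement_thresholds = improvement_thresholds,
              ancova_week = ancova_week,
              lloq_policy = lloq_policy)
  if (!is.numeric(cfg$fc_min) || cfg$fc_min < 1) {
    stop_validation("fc_min must be a number >= 1")
  }
  if (!is.numeric(cfg$fdr_max) || cfg$fdr_max <= 0 || cfg$fdr_max > 1) {
    stop_validation("fdr_max must lie in (0, 1]")
  }
  if (!is.numeric(cfg$stability_floor) || cfg$stability_floor < 0) {
    stop_validation("stability_floor must be >= 0")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; relative input paths are resolved against
#' the configuration file's directory.
#'
#' @param path `.yml`/`.yaml` or `.json` configuration file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("config file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_validation("config file must be .yaml/.yml or .json")
  }
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop_validation(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  for (key in c("expression", "annotation", "serum", "qpcr", "gene_sets")) {
    p <- raw[[key]]
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) raw[[key]] <- file.path(base, p)
  }
  do.call(pipeline_config, raw)
}

write_stage_tsv <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  readr::write_tsv(df, path)
  path
}

#' Run the end-to-end pharmacodynamic analysis pipeline
#'
#' Stages, each skipped cleanly when its inputs are absent:
#' \enumerate{
#'   \item \strong{signature}: paired lesional/nonlesional differential
#'     expression and signature selection;
#'   \item \strong{improvement}: per-gene percent improvement, arm/week
#'     summaries and overlap counts;
#'   \item \strong{scar}: residual disease expression in healed lesional
#'     skin of `scar_arm`;
#'   \item \strong{enrichment}: hypergeometric over-representation of the
#'     signature in the GMT collection plus per-set improvement;
#'   \item \strong{gsva}: sample-level set scores and the paired
#'     lesional/nonlesional contrast;
#'   \item \strong{serum}: baseline case-control, within-arm change and
#'     the between-arm ANCOVA at `ancova_week`;
#'   \item \strong{qpcr}: delta-Ct normalization and fold-change tables.
#' }
#' Every stage writes a TSV under `out_dir` and the whole run is described
#' by `run_report.json`. All computations are deterministic: rerunning on
#' the same inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()] (or path accepted by
#'   [read_pipeline_config()]).
#' @param cohort optional in-memory cohort from
#'   [simulate_expression_cohort()]; overrides the `expression` and
#'   `annotation` paths.
#' @return invisibly, a list of stage results plus `report` (also written
#'   to `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop_validation("config must be a pipeline_config or a path to one")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  report <- list(package_version = as.character(utils::packageVersion("psopd")),
                 r_version = as.character(getRversion()),
                 config = unclass(config),
                 stages = list(), outputs = character())
  add_output <- function(path) {
    report$outputs <<- c(report$outputs, basename(path))
  }

  # --- skin expression stages ------------------------------------------
  expr <- annot <- NULL
  if (!is.null(cohort)) {
    expr <- cohort$expr
    annot <- cohort$annot
  } else if (!is.null(config$expression)) {
    if (is.null(config$annotation)) {
      stop_validation("an expression matrix requires a sample annotation")
    }
    expr <- read_expression_matrix(config$expression)
    annot <- read_sample_annotation(config$annotation)
  }

  signature <- NULL
  if (!is.null(expr)) {
    de <- paired_lesional_de(expr, annot)
    signature <- select_signature(de, fc_min = config$fc_min,
                                  fdr_max = config$fdr_max)
    add_output(write_stage_tsv(de, config$out_dir, "differential_expression"))
    add_output(write_stage_tsv(tidy(signature), config$out_dir, "signature"))
    results$differential_expression <- de
    results$signature <- signature
    report$stages$signature <- list(
      n_features = nrow(de), n_signature = nrow(signature$features))

    records <- gene_improvement(expr, annot, signature,
                                stability_floor = config$stability_floor)
    summ <- improvement_summary(records,
                                thresholds = config$improvement_thresholds)
    add_output(write_stage_tsv(records, config$out_dir, "gene_improvement"))
    add_output(write_stage_tsv(summ, config$out_dir, "improvement_summary"))
    results$gene_improvement <- records
    results$improvement_summary <- summ
    report$stages$improvement <- list(
      arms = sort(unique(records$arm)), weeks = sort(unique(records$week)))

    healed <- annot[annot$arm == config$scar_arm & annot$tissue == "LS" &
                      annot$week > 0 & annot$pasi100, , drop = FALSE]
    if (nrow(healed) >= 2) {
      scar <- molecular_scar(expr, annot, signature, arm = config$scar_arm,
                             fc_min = config$fc_min,
                             stability_floor = config$stability_floor)
      add_output(write_stage_tsv(tidy(scar), config$out_dir, "molecular_scar"))
      results$scar <- scar
      report$stages$scar <- list(arm = config$scar_arm,
                                 n_healed_samples = length(scar$healed_sample_ids),
                                 n_scar_features = length(scar$scar_feature_ids))
    } else {
      report$stages$scar <- list(skipped = "fewer than 2 healed lesional samples")
    }

    if (!is.null(config$gene_sets)) {
      collection <- read_gmt(config$gene_sets)
      enr <- hypergeometric_enrichment(signature_feature_ids(signature),
                                       collection, rownames(as_expression_matrix(expr)))
      selected <- select_enriched(enr)
      add_output(write_stage_tsv(enr, config$out_dir, "enrichment"))
      results$enrichment <- enr
      results$enriched_sets <- selected
      report$stages$enrichment <- list(n_sets = nrow(enr),
                                       n_selected = nrow(selected))
      if (nrow(selected)) {
        set_pi <- set_improvement(records, collection[selected$set_name])
        add_output(write_stage_tsv(set_pi, config$out_dir, "set_improvement"))
        results$set_improvement <- set_pi
      }

      scores <- gsva_scores(expr, collection)
      diffs <- gsva_differential(scores, annot)
      add_output(write_stage_tsv(tidy(scores), config$out_dir, "gsva_scores"))
      add_output(write_stage_tsv(diffs, config$out_dir, "gsva_differential"))
      results$gsva_scores <- scores
      results$gsva_differential <- diffs
      report$stages$gsva <- list(n_sets = nrow(scores), n_samples = ncol(scores))
    }
  }

  # --- serum stage ------------------------------------------------------
  if (!is.null(config$serum)) {
    panel <- read_serum_panel(config$serum)
    cc <- baseline_case_control(panel, lloq_policy = config$lloq_policy)
    add_output(write_stage_tsv(cc, config$out_dir, "serum_case_control"))
    results$serum_case_control <- cc
    arms <- setdiff(unique(panel$group), "HC")
    weeks <- sort(setdiff(unique(panel$week), 0))
    if (length(weeks)) {
      wc <- within_arm_change(panel, arm = arms, week = weeks,
                              lloq_policy = config$lloq_policy)
      add_output(write_stage_tsv(wc, config$out_dir, "serum_within_arm"))
      results$serum_within_arm <- wc
    }
    if (config$ancova_week %in% weeks &&
        all(c("GUS", "ADA") %in% arms)) {
      an <- between_arm_ancova(panel, week = config$ancova_week,
                               lloq_policy = config$lloq_policy)
      add_output(write_stage_tsv(an, config$out_dir, "serum_ancova"))
      results$serum_ancova <- an
    }
    report$stages$serum <- list(n_analytes = length(unique(panel$analyte)),
                                arms = sort(arms), weeks = weeks)
  }

  # --- qPCR stage -------------------------------------------------------
  if (!is.null(config$qpcr)) {
    ct <- read_qpcr_table(config$qpcr)
    norm <- normalize_delta_ct(ct)
    fcs <- qpcr_fold_changes(norm)
    add_output(write_stage_tsv(norm, config$out_dir, "qpcr_normalized"))
    add_output(write_stage_tsv(fcs, config$out_dir, "qpcr_fold_changes"))
    results$qpcr_normalized <- norm
    results$qpcr_fold_changes <- fcs
    report$stages$qpcr <- list(n_genes = length(unique(fcs$gene)))
  }

  if (!length(report$stages)) {
    stop_validation("configuration enables no pipeline stage")
  }
  report_path <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  results$report <- report
  invisible(results)
}
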