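## End-to-end orchestration: configuration, staged artifacts, run
## manifest, reproducible reports. Stage artifacts are files, so any
## stage can be re-run and inspected independently.

PIPELINE_STAGES <- c("simulate", "qc", "screen", "validate", "model-train",
                     "model-eval", "report", "all")

default_run_config <- function() {
  list(
    out_dir = "seroscreen-run",
    seed = 1L,
    paths = list(layout = NULL, scans_dir = NULL, manifest = NULL),
    sim = unclass(sim_config()),
    screening = list(range_lo = 1000, range_hi = 24000, rpd_max = 30,
                     pass_fraction = 0.90, presence_z = 3, snr_min = 13,
                     fold_min = 2.5, min_case_positive = 2,
                     max_control_positive = 0),
    diagnostics = list(controls = "all"),
    model = list(cv_folds = 4L, target_specificity = 0.90,
                 n_case_train = 120L, n_control_train = 120L)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Build a pipeline run configuration
#'
#' Starts from the package defaults (which mirror the per-stage function
#' defaults) and overlays user settings from a YAML file or a nested
#' list. Unknown keys are rejected.
#'
#' @param config `NULL` (defaults), a path to a YAML file, or a nested
#'   list.
#' @param seed optional seed override.
#' @param out_dir optional output-directory override.
#' @return list of class `run_config`.
#' @export
run_config <- function(config = NULL, seed = NULL, out_dir = NULL) {
  cfg <- default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg$sim$seed <- cfg$seed
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  hashed <- unclass(cfg)
  hashed$out_dir <- NULL  # the hash identifies the analysis, not its location
  saved <- serialize(hashed, NULL, version = 2L)
  writeBin(saved, tmp)
  unname(tools::md5sum(tmp))
}

pipe_log <- function(level, verbosity, ...) {
  if (verbosity != "quiet")
    message(sprintf("[%s] %s", level, paste0(...)))
}

artifact <- function(cfg, ...) file.path(cfg$out_dir, ...)

require_artifact <- function(cfg, file, produced_by) {
  p <- artifact(cfg, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run the '", produced_by,
         "' stage first")
  p
}

load_cohort_files <- function(cfg) {
  layout <- read_layout(require_artifact(cfg, "layout.gal", "simulate"))
  manifest <- read_manifest(require_artifact(cfg, "manifest.tsv", "simulate"))
  scan_dir <- artifact(cfg, "scans")
  files <- list.files(scan_dir, pattern = "\\.gpr$", full.names = TRUE)
  if (!length(files))
    stop("missing artifact 'scans/': run the 'simulate' stage first")
  scans <- lapply(files, read_scan, layout = layout)
  names(scans) <- vapply(scans, function(s) s$sample_id, character(1))
  list(layout = layout, manifest = manifest, scans = scans)
}

stage_simulate <- function(cfg, verbosity) {
  sim <- do.call(sim_config, cfg$sim)
  cohort <- simulate_cohort(sim)
  write_cohort(cohort, cfg$out_dir)
  qc <- simulate_qc_profile(sim, n_scans = 1L)
  write_scan(qc[[1]], cohort$layout, artifact(cfg, "qc_scan.gpr"))
  pipe_log("info", verbosity, "simulate: ", length(cohort$scans),
           " scans, ", sim$n_probes, " probes")
  invisible(cohort)
}

stage_qc <- function(cfg, verbosity) {
  layout <- read_layout(require_artifact(cfg, "layout.gal", "simulate"))
  qc_scan <- read_scan(require_artifact(cfg, "qc_scan.gpr", "simulate"), layout)
  sc <- cfg$screening
  rep <- qc_array(qc_scan, layout, sc$range_lo, sc$range_hi, sc$rpd_max,
                  sc$pass_fraction)
  write_qc_report(rep, artifact(cfg, "qc_report.txt"))
  pipe_log("info", verbosity, sprintf("qc: in-range %.3f, rpd-ok %.3f (%s)",
                                      rep$fraction_in_range, rep$fraction_rpd_ok,
                                      if (rep$passed) "pass" else "fail"))
  invisible(rep)
}

stage_screen <- function(cfg, verbosity) {
  co <- load_cohort_files(cfg)
  man <- co$manifest
  sc <- cfg$screening
  blank <- co$scans[[man$sample_id[man$role == "blank"][1]]]
  secondary <- co$scans[[man$sample_id[man$role == "secondary-only"][1]]]
  pooled_scan <- co$scans[[man$sample_id[man$role == "pooled-control"][1]]]
  serum_ids <- man$sample_id[man$role %in% c("case", "control")]
  hits <- call_hits_cohort(co$scans[serum_ids], blank, secondary, co$layout,
                           presence_z = sc$presence_z)
  mat <- build_intensity_matrix(co$scans[serum_ids], co$layout, man)
  pooled_agg <- aggregate_duplicates(pooled_scan, co$layout)
  pooled <- stats::setNames(pooled_agg$net, pooled_agg$probe_id)
  cand <- select_candidates(hits, mat, pooled, man, sc$snr_min, sc$fold_min,
                            sc$min_case_positive, sc$max_control_positive)
  write_table_tsv(hits, artifact(cfg, "hits.tsv"))
  write_table_tsv(cand, artifact(cfg, "candidates.tsv"))
  pipe_log("info", verbosity, "screen: ", nrow(cand), " candidate antigens")
  invisible(cand)
}

stage_validate <- function(cfg, verbosity) {
  co <- load_cohort_files(cfg)
  cand <- utils::read.delim(require_artifact(cfg, "candidates.tsv", "screen"),
                            stringsAsFactors = FALSE)
  man <- co$manifest
  serum_ids <- man$sample_id[man$role %in% c("case", "control")]
  mat <- build_intensity_matrix(co$scans[serum_ids], co$layout, man)
  probes <- if (nrow(cand)) cand$probe_id else mat$probe_ids
  panel <- antibody_panel_report(mat, man, co$layout, probes,
                                 controls = cfg$diagnostics$controls)
  write_table_tsv(panel, artifact(cfg, "panel_report.tsv"))
  grid <- correlate_clinical(mat, man, probes,
                             c("esr", "crp", "rf", "igg", "das28", "sjc",
                               "tjc", "shs"),
                             samples = man$sample_id[man$role == "case"])
  write_table_tsv(grid, artifact(cfg, "clinical_correlations.tsv"))
  emb <- embed_cohort(mat, man, seed = cfg$seed)
  write_table_tsv(emb, artifact(cfg, "embedding.tsv"))
  pipe_log("info", verbosity, "validate: panel of ", nrow(panel), " antigens")
  invisible(panel)
}

model_features <- function(mat, probes) {
  x <- log10(pmax(mat$net[, probes, drop = FALSE], 1))
  x[is.na(x)] <- 0
  x
}

stage_model_train <- function(cfg, verbosity) {
  co <- load_cohort_files(cfg)
  cand <- utils::read.delim(require_artifact(cfg, "candidates.tsv", "screen"),
                            stringsAsFactors = FALSE)
  if (!nrow(cand)) stop("no candidate antigens: cannot train a model")
  man <- co$manifest
  serum_ids <- man$sample_id[man$role %in% c("case", "control")]
  mat <- build_intensity_matrix(co$scans[serum_ids], co$layout, man)
  case_ids <- man$sample_id[man$role == "case"]
  control_ids <- man$sample_id[man$role == "control"]
  # distinct derived seed: reusing the simulation seed verbatim would
  # replay the generator's own subject-sampling draws
  sp <- split_cohort(case_ids, control_ids, cfg$model$n_case_train,
                     cfg$model$n_control_train, seed = cfg$seed + 101L)
  x <- model_features(mat, cand$probe_id)
  train_ids <- c(sp$train$cases, sp$train$controls)
  y_train <- ifelse(train_ids %in% case_ids, "case", "control")
  mc <- model_config(cv_folds = cfg$model$cv_folds,
                     target_specificity = cfg$model$target_specificity,
                     seed = cfg$seed)
  model <- train_ra_model(x[train_ids, , drop = FALSE], y_train, mc)
  write_model(model, artifact(cfg, "model.json"))
  split_df <- data.frame(sample_id = c(train_ids, sp$test$cases, sp$test$controls),
                         set = c(rep("train", length(train_ids)),
                                 rep("test", length(sp$test$cases) +
                                       length(sp$test$controls))),
                         stringsAsFactors = FALSE)
  write_table_tsv(split_df, artifact(cfg, "split.tsv"))
  pipe_log("info", verbosity,
           sprintf("model-train: %d features, CV AUROC %.3f",
                   length(model$features), model$cv$auc_pooled))
  invisible(model)
}

stage_model_eval <- function(cfg, verbosity) {
  co <- load_cohort_files(cfg)
  model <- read_model(require_artifact(cfg, "model.json", "model-train"))
  split_df <- utils::read.delim(require_artifact(cfg, "split.tsv", "model-train"),
                                stringsAsFactors = FALSE)
  man <- co$manifest
  serum_ids <- man$sample_id[man$role %in% c("case", "control")]
  mat <- build_intensity_matrix(co$scans[serum_ids], co$layout, man)
  x <- model_features(mat, model$features)
  test_ids <- split_df$sample_id[split_df$set == "test"]
  y <- ifelse(man$role[match(test_ids, man$sample_id)] == "case",
              "case", "control")
  acpa <- man$acpa_status[match(test_ids, man$sample_id)]
  ev <- evaluate_model(model, x[test_ids, , drop = FALSE], y, acpa)
  out <- data.frame(metric = c("auroc", "sensitivity", "specificity",
                               "sensitivity_acpa_pos", "sensitivity_acpa_neg",
                               "n_case", "n_control", "threshold"),
                    value = c(ev$auroc, ev$sensitivity, ev$specificity,
                              ev$sensitivity_acpa_pos, ev$sensitivity_acpa_neg,
                              ev$n_case, ev$n_control, ev$threshold),
                    stringsAsFactors = FALSE)
  write_table_tsv(out, artifact(cfg, "eval_report.tsv"))
  pipe_log("info", verbosity,
           sprintf("model-eval: AUROC %.3f, sens %.3f / spec %.3f",
                   ev$auroc, ev$sensitivity, ev$specificity))
  invisible(ev)
}

stage_report <- function(cfg, verbosity) {
  require_artifact(cfg, "panel_report.tsv", "validate")
  require_artifact(cfg, "eval_report.tsv", "model-eval")
  manifest_lines <- c(
    paste0("config_hash=", config_hash(cfg)),
    paste0("seed=", cfg$seed),
    paste0("package_version=", as.character(utils::packageVersion("seroscreen"))),
    paste0("stages=", paste(setdiff(PIPELINE_STAGES, "all"), collapse = ",")))
  writeLines(manifest_lines, artifact(cfg, "run_manifest.txt"))
  pipe_log("info", verbosity, "report: run manifest written")
  invisible(artifact(cfg, "run_manifest.txt"))
}

#' Run the screening-and-diagnostics pipeline
#'
#' Each stage reads its upstream artifacts from `config$out_dir` and
#' writes its own tables there, so stages are independently re-runnable;
#' `"all"` chains every stage in order. Re-running with an identical
#' configuration and seed reproduces byte-identical tables.
#'
#' @param subcommand one of `simulate`, `qc`, `screen`, `validate`,
#'   `model-train`, `model-eval`, `report`, `all`.
#' @param config a [run_config()] (or anything accepted by it).
#' @param verbosity `"info"` (default) or `"quiet"`.
#' @return the last stage's result, invisibly.
#' @export
run_pipeline <- function(subcommand = "all", config = NULL,
                         verbosity = c("info", "quiet")) {
  subcommand <- match.arg(subcommand, PIPELINE_STAGES)
  verbosity <- match.arg(verbosity)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (subcommand == "all")
    c("simulate", "qc", "screen", "validate", "model-train", "model-eval",
      "report")
  else subcommand
  res <- NULL
  for (st in stages)
    res <- switch(st,
                  simulate = stage_simulate(cfg, verbosity),
                  qc = stage_qc(cfg, verbosity),
                  screen = stage_screen(cfg, verbosity),
                  validate = stage_validate(cfg, verbosity),
                  `model-train` = stage_model_train(cfg, verbosity),
                  `model-eval` = stage_model_eval(cfg, verbosity),
                  report = stage_report(cfg, verbosity))
  invisible(res)
}
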