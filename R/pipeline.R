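# Pipeline orchestration: simulate -> extract -> select -> evaluate as
# composable file-based stages with a YAML config, logging and one global
# seed fanned out per stage. Every report embeds the configuration and seed
# it was produced with, so any output can be regenerated.

#' Pipeline run configuration
#'
#' Defaults follow the package defaults (quantization 5 bits, 64 histogram
#' bins, LBP 8/1, 10-fold selection and evaluation, 100 trees,
#' paper-faithful evaluation). A YAML file and an override list are merged
#' over the defaults.
#'
#' @param path Optional YAML config file.
#' @param overrides Optional named list merged last.
#' @return A nested list of class `rad_run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L,
    paths = list(data_dir = "cohort", table = "features.csv",
                 out_dir = "results"),
    features = list(bits = 5L, n_bins = 64L, lbp_p = 8L, lbp_r = 1L),
    cohort = list(n_cases = 91L, prevalence = 0.43,
                  dre_prob = c(0.2, 0.7),
                  pirads_probs = list(c(0.70, 0.27, 0.03),
                                      c(0.13, 0.28, 0.59)),
                  effect = 1),
    selection = list(inner_folds = 10L, n_trees = 100L, stall_limit = 5L),
    evaluation = list(folds = 10L, n_trees = 100L, mode = "paper-faithful")
  )
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "rad_run_config")
}

cfg_feature_config <- function(cfg) {
  feature_config(bits = cfg$features$bits, n_bins = cfg$features$n_bins,
                 lbp_p = cfg$features$lbp_p, lbp_r = cfg$features$lbp_r)
}

log_msg <- function(...) message(sprintf(...))

#' Pipeline stage: simulate a cohort to disk
#'
#' @param cfg A [run_config()].
#' @param force Overwrite an existing output directory.
#' @return The manifest, invisibly.
#' @export
cmd_simulate <- function(cfg = run_config(), force = FALSE) {
  sp <- cohort_spec(n_cases = cfg$cohort$n_cases,
                    prevalence = cfg$cohort$prevalence,
                    dre_prob = cfg$cohort$dre_prob,
                    pirads_probs = do.call(rbind, cfg$cohort$pirads_probs),
                    seed = cfg$seed)
  pp <- phantom_params(effect = cfg$cohort$effect)
  cohort <- generate_cohort(sp, pp)
  man <- write_cohort(cohort, cfg$paths$data_dir, force = force)
  log_msg("simulate: wrote %d files to %s", length(man$files),
          cfg$paths$data_dir)
  invisible(man)
}

#' Pipeline stage: extract the cohort feature table from files
#'
#' Reads `clinical.csv` (columns `case_id`, `dre`, `pirads_max` and either
#' `label` or `gleason`) and the per-case NIfTI volume/mask triples from
#' the data directory, extracts all features and writes the feature-table
#' CSV.
#'
#' @param cfg A [run_config()].
#' @return The feature tibble, invisibly.
#' @export
cmd_extract <- function(cfg = run_config()) {
  dir <- cfg$paths$data_dir
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) abort(sprintf("missing %s", clin_path))
  clinical <- readr::read_csv(clin_path, show_col_types = FALSE,
                              progress = FALSE)
  if (!"label" %in% names(clinical)) {
    if (!"gleason" %in% names(clinical))
      abort("clinical.csv needs a `label` or `gleason` column")
    clinical$label <- binarize_gleason(clinical$gleason)
  }
  fc <- cfg_feature_config(cfg)
  rows <- lapply(seq_len(nrow(clinical)), function(i) {
    id <- clinical$case_id[i]
    paths <- file.path(dir, sprintf("%s_%s.nii.gz", id, c("t2", "adc", "mask")))
    for (p in paths[1:2])
      if (!file.exists(p)) abort(sprintf("case %s: missing volume %s", id, p))
    if (!file.exists(paths[3]))
      abort(sprintf("case %s: missing mask %s", id, paths[3]))
    t2 <- load_volume(paths[1], "T2W", id)
    adc <- load_volume(paths[2], "ADC", id)
    mask <- load_mask(paths[3], t2)
    row <- assemble_case(extract_voi(t2, mask), extract_voi(adc, mask),
                         clinical[i, c("case_id", "dre", "pirads_max")],
                         fc, label = clinical$label[i])
    log_msg("extract: %s (%d features)", id, ncol(row) - 2L)
    row
  })
  table <- bind_rows(rows)
  write_cohort_table(table, cfg$paths$table)
  log_msg("extract: wrote %s (%d x %d)", cfg$paths$table, nrow(table),
          ncol(table))
  invisible(table)
}

#' Pipeline stage: wrapper feature selection
#'
#' @param cfg A [run_config()].
#' @param table Optional in-memory feature tibble; read from
#'   `cfg$paths$table` when missing.
#' @return The [`rad_selection`][best_first_select], invisibly; the report
#'   (selected names, trace, config, seed) is written as JSON to the output
#'   directory.
#' @export
cmd_select <- function(cfg = run_config(), table = NULL) {
  if (is.null(table)) table <- read_cohort_table(cfg$paths$table)
  sc <- selection_config(inner_folds = cfg$selection$inner_folds,
                         n_trees = cfg$selection$n_trees,
                         stall_limit = cfg$selection$stall_limit,
                         seed = cfg$seed)
  sel <- best_first_select(table, sc)
  dir.create(cfg$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(cfg$paths$out_dir, "selection.json")
  jsonlite::write_json(
    list(selected = sel$selected, best_score = sel$best_score,
         trace = sel$trace, config = unclass(sc)),
    out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("select: %d features (inner-CV accuracy %.3f) -> %s",
          length(sel$selected), sel$best_score, out)
  invisible(sel)
}

#' Pipeline stage: cross-validated evaluation
#'
#' In paper-faithful mode an existing `selection.json` in the output
#' directory is reused when present; nested mode always re-selects inside
#' each outer fold.
#'
#' @param cfg A [run_config()].
#' @param table Optional in-memory feature tibble.
#' @return The `rad_eval` report, invisibly; metrics (JSON) and ROC
#'   coordinates (CSV) are written to the output directory.
#' @export
cmd_evaluate <- function(cfg = run_config(), table = NULL) {
  if (is.null(table)) table <- read_cohort_table(cfg$paths$table)
  sc <- selection_config(inner_folds = cfg$selection$inner_folds,
                         n_trees = cfg$selection$n_trees,
                         stall_limit = cfg$selection$stall_limit,
                         seed = cfg$seed)
  mode <- cfg$evaluation$mode
  selection <- NULL
  sel_path <- file.path(cfg$paths$out_dir, "selection.json")
  if (mode == "paper-faithful" && file.exists(sel_path)) {
    sj <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
    selection <- structure(list(selected = sj$selected,
                                best_score = sj$best_score,
                                trace = as_tibble(sj$trace), config = sc),
                           class = "rad_selection")
  }
  ev <- evaluate_cohort(table, mode = mode, selection = selection,
                        sel_config = sc, folds = cfg$evaluation$folds,
                        seed = cfg$seed, n_trees = cfg$evaluation$n_trees)
  dir.create(cfg$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    mode = ev$mode, seed = cfg$seed, folds = cfg$evaluation$folds,
    pooled_out_of_fold = TRUE,
    best_cutoff = ev$best_cutoff, metrics = ev$metrics,
    confusion = as.list(ev$confusion),
    selected = if (!is.null(ev$selection)) ev$selection$selected,
    fold_subsets = ev$fold_subsets,
    config = unclass(cfg)
  )
  jsonlite::write_json(report, file.path(cfg$paths$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_csv(ev$roc$points, file.path(cfg$paths$out_dir, "roc.csv"))
  log_msg("evaluate (%s): AUC %.3f, accuracy %.3f -> %s", ev$mode,
          ev$metrics$estimate[1], ev$metrics$estimate[2], cfg$paths$out_dir)
  invisible(ev)
}

#' Run the full pipeline
#'
#' `simulate -> extract -> select -> evaluate` under one configuration.
#'
#' @param cfg A [run_config()].
#' @param force Overwrite existing outputs.
#' @return The `rad_eval` report, invisibly.
#' @export
cmd_run_all <- function(cfg = run_config(), force = FALSE) {
  cmd_simulate(cfg, force = force)
  table <- cmd_extract(cfg)
  cmd_select(cfg, table)
  cmd_evaluate(cfg, table)
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `extract`, `select`, `evaluate` or `run-all` with
#' flags `--config`, `--seed`, `--out`, `--data-dir`, `--table`, `--mode`,
#' `--force`. Installed as the `radtex` script under `inst/cli/`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Invisibly, the result of the dispatched stage.
#' @export
radtex_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    abort("usage: radtex <simulate|extract|select|evaluate|run-all> [flags]")
  command <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--data-dir", type = "character", default = NULL,
                          dest = "data_dir"),
    optparse::make_option("--table", type = "character", default = NULL),
    optparse::make_option("--mode", type = "character", default = NULL),
    optparse::make_option("--force", action = "store_true", default = FALSE)
  ))
  opt <- optparse::parse_args(parser, args = args[-1])
  ov <- list()
  if (!is.null(opt$seed)) ov$seed <- opt$seed
  if (!is.null(opt$out)) ov$paths$out_dir <- opt$out
  if (!is.null(opt$data_dir)) ov$paths$data_dir <- opt$data_dir
  if (!is.null(opt$table)) ov$paths$table <- opt$table
  if (!is.null(opt$mode)) ov$evaluation$mode <- opt$mode
  cfg <- run_config(opt$config, ov)
  switch(command,
    "simulate" = cmd_simulate(cfg, force = opt$force),
    "extract" = cmd_extract(cfg),
    "select" = cmd_select(cfg),
    "evaluate" = cmd_evaluate(cfg),
    "run-all" = cmd_run_all(cfg, force = opt$force),
    abort(sprintf("unknown command: %s", command))
  )
}
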