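# File-based pipeline commands: generate -> train -> score -> evaluate.
# Each command reads and writes plain files (NIfTI, CSV, JSON, RDS
# checkpoints) so stages can be re-run independently; every stochastic
# component consumes a seed derived from one global seed.

check_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stop("output directory ", out_dir,
         " is not empty; use force = TRUE to overwrite", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

write_manifest <- function(out_dir, what, config, seed) {
  manifest <- list(command = what, seed = seed,
                   config = config[setdiff(names(config), "")],
                   config_hash = hash_object(config))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = 12,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Generate a phantom dataset on disk
#'
#' Writes one NIfTI slice per image, a metadata CSV (subject_id, stage,
#' severity_s, split, path) and a manifest recording the configuration
#' hash and seed.
#'
#' @param out_dir output directory.
#' @param config a [phantom_config()].
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the metadata table.
#' @export
cmd_generate <- function(out_dir, config = phantom_config(), force = FALSE) {
  check_out_dir(out_dir, force)
  data <- generate_phantom_dataset(config)
  meta <- write_dataset(data, out_dir)
  write_manifest(out_dir, "generate", unclass(config), config$seed)
  invisible(meta)
}

#' Train an encoder on a dataset directory
#'
#' @param data_dir directory written by [cmd_generate()] (or
#'   [write_dataset()]).
#' @param out_dir output directory for `checkpoint.rds` and
#'   `loss_history.csv`.
#' @param encoder an [encoder_config()].
#' @param training a [train_config()].
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the loss history data.frame.
#' @export
cmd_train <- function(data_dir, out_dir, encoder = encoder_config(),
                      training = train_config(), force = FALSE) {
  check_out_dir(out_dir, force)
  data <- read_dataset(data_dir)
  fit <- train_encoder(build_encoder(encoder), data, training)
  save_encoder(fit$encoder, file.path(out_dir, "checkpoint.rds"))
  utils::write.csv(fit$history, file.path(out_dir, "loss_history.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "train",
                 c(unclass(encoder), unclass(training)), training$seed)
  invisible(fit$history)
}

#' Score the test split of a dataset with a trained checkpoint
#'
#' Builds the healthy-baseline panel from the training split, scores every
#' test image, and writes `scores.csv` plus `panel.json` (panel subject ids
#' and selection seed).
#'
#' @param data_dir dataset directory.
#' @param checkpoint path to a checkpoint written by [cmd_train()].
#' @param out_dir output directory.
#' @param panel_seed seed for the baseline-panel draw.
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the scores data.frame.
#' @export
cmd_score <- function(data_dir, checkpoint, out_dir, panel_seed = 1L,
                      force = FALSE) {
  if (!file.exists(checkpoint)) {
    stop("checkpoint not found: ", checkpoint, call. = FALSE)
  }
  check_out_dir(out_dir, force)
  data <- read_dataset(data_dir)
  enc <- load_encoder(checkpoint)
  panel <- build_baseline_panel(data, enc, seed = panel_seed)
  scores <- score_dataset(dataset_split(data, "test"), enc, panel)
  write_scores(scores, file.path(out_dir, "scores.csv"))
  writeLines(jsonlite::toJSON(list(subject_ids = panel$subject_ids,
                                   seed = panel$seed,
                                   stage = rep("NC", length(panel$subject_ids))),
                              auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "panel.json"))
  invisible(scores)
}

#' Evaluate a scores CSV and write the report
#'
#' Writes `report.json` plus flat CSV tables (correlation, t-tests,
#' two-class and three-class metrics, dispersion, Pareto bins). Rerunning
#' on the same CSV is byte-identical.
#'
#' @param scores_csv path to a scores CSV with `score` and `stage` columns.
#' @param out_dir output directory.
#' @param force overwrite a non-empty output directory.
#' @return invisibly, the `odss_eval` report.
#' @export
cmd_evaluate <- function(scores_csv, out_dir, force = FALSE) {
  scores <- read_scores(scores_csv)
  if (!"stage" %in% names(scores)) {
    stop("scores file has no `stage` column: ", scores_csv, call. = FALSE)
  }
  check_out_dir(out_dir, force)
  report <- evaluate_scores(scores)
  write_eval_report(report, file.path(out_dir, "report.json"))
  utils::write.csv(
    data.frame(metric = c("pearson", "spearman"),
               signed = c(report$correlation$pearson,
                          report$correlation$spearman),
               percent = c(report$correlation$pearson_pct,
                           report$correlation$spearman_pct)),
    file.path(out_dir, "correlation.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(pair = names(report$ttests), p_value = unname(report$ttests)),
    file.path(out_dir, "ttests.csv"), row.names = FALSE)
  utils::write.csv(
    do.call(rbind, lapply(names(report$binary), function(nm) {
      b <- report$binary[[nm]]
      data.frame(task = nm, sensitivity = b$sensitivity,
                 specificity = b$specificity, accuracy = b$accuracy,
                 threshold = b$threshold)
    })),
    file.path(out_dir, "twoclass.csv"), row.names = FALSE)
  utils::write.csv(report$threeclass$per_stage,
                   file.path(out_dir, "threeclass.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$dispersion),
                   file.path(out_dir, "dispersion.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(bin_lo = report$pareto$bin_edges[-length(report$pareto$bin_edges)],
               bin_hi = report$pareto$bin_edges[-1],
               frequency = report$pareto$frequencies,
               cumulative_percent = report$pareto$cumulative_percent),
    file.path(out_dir, "pareto.csv"), row.names = FALSE)
  invisible(report)
}

#' Run the whole pipeline under one global seed
#'
#' generate -> train -> score -> evaluate, with every stage's seed derived
#' deterministically from `seed`. Two invocations with the same seed and
#' configuration produce byte-identical `report.json`.
#'
#' @param out_dir root output directory (subdirectories `data`, `model`,
#'   `scores`, `eval`).
#' @param seed global integer seed.
#' @param phantom a [phantom_config()]; its `seed` field is overridden by
#'   the derived seed.
#' @param encoder an [encoder_config()]; seed likewise derived.
#' @param training a [train_config()]; seed likewise derived.
#' @param force overwrite existing outputs.
#' @return invisibly, a list: paths of the four stage directories and the
#'   `odss_eval` report.
#' @export
run_odss_pipeline <- function(out_dir, seed = 1L,
                              phantom = phantom_config(),
                              encoder = encoder_config(),
                              training = train_config(),
                              force = FALSE) {
  phantom$seed <- derive_seed(seed, "pipeline-phantom")
  encoder$seed <- derive_seed(seed, "pipeline-encoder")
  training$seed <- derive_seed(seed, "pipeline-train")
  dirs <- file.path(out_dir, c("data", "model", "scores", "eval"))
  names(dirs) <- c("data", "model", "scores", "eval")
  cmd_generate(dirs[["data"]], phantom, force = force)
  cmd_train(dirs[["data"]], dirs[["model"]], encoder, training, force = force)
  cmd_score(dirs[["data"]], file.path(dirs[["model"]], "checkpoint.rds"),
            dirs[["scores"]], panel_seed = derive_seed(seed, "pipeline-panel"),
            force = force)
  report <- cmd_evaluate(file.path(dirs[["scores"]], "scores.csv"),
                         dirs[["eval"]], force = force)
  invisible(list(dirs = as.list(dirs), report = report))
}
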