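#' Read a delimited signal file
#'
#' Expects a header and two numeric columns (time and value, e.g.
#' `time_s, ppg`). Values round-trip at full precision through
#' [write_ppg_dataset()].
#'
#' @param path File path (comma- or tab-delimited).
#' @return Tibble with columns `time_s`, `value`.
#' @export
read_signal_file <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) abort_input(sprintf("'%s': empty signal file (need a header and data).", path))
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- strsplit(lines[-1], sep, fixed = TRUE)
  bad_len <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad_len) > 0) {
    abort_input(sprintf("'%s': malformed row at line %d.", path, bad_len[1] + 1L))
  }
  t <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2)))
  bad <- which(is.na(t) | is.na(v))
  if (length(bad) > 0) {
    abort_input(sprintf("'%s': non-numeric value at line %d.", path, bad[1] + 1L))
  }
  tibble::tibble(time_s = t, value = v)
}

#' Write / read pooled predictions as delimited text
#'
#' The on-disk format is long: one row per (window, target) with columns
#' `window_id`, `fold`, `target`, `estimate`, `reference`, full precision.
#' The reader returns the wide per-window form used by [evaluate_report()].
#'
#' @param predictions Wide predictions tibble (`window_id`, optionally `fold`,
#'   `sbp`, `dbp`, `sbp_hat`, `dbp_hat`).
#' @param path Output path.
#' @return `path` (write) / wide predictions tibble (read).
#' @export
write_predictions <- function(predictions, path) {
  fold <- if ("fold" %in% names(predictions)) predictions$fold else NA_integer_
  long <- dplyr::bind_rows(
    tibble::tibble(window_id = predictions$window_id, fold = fold, target = "sbp",
                   estimate = predictions$sbp_hat, reference = predictions$sbp),
    tibble::tibble(window_id = predictions$window_id, fold = fold, target = "dbp",
                   estimate = predictions$dbp_hat, reference = predictions$dbp)
  )
  long$estimate <- format(long$estimate, digits = 17, trim = TRUE, scientific = FALSE)
  long$reference <- format(long$reference, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("file '%s' does not exist.", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("window_id", "target", "estimate", "reference")
  if (!all(needed %in% names(df))) abort_input("predictions file is missing required columns.")
  wide_est <- tidyr::pivot_wider(df, id_cols = dplyr::any_of(c("window_id", "fold")),
                                 names_from = "target",
                                 values_from = c("estimate", "reference"))
  tibble::tibble(
    window_id = wide_est$window_id,
    fold = if ("fold" %in% names(wide_est)) wide_est$fold else NA_integer_,
    sbp = wide_est$reference_sbp, dbp = wide_est$reference_dbp,
    sbp_hat = wide_est$estimate_sbp, dbp_hat = wide_est$estimate_dbp
  )
}

#' Default pipeline configuration
#'
#' A nested configuration covering every stage: `sim` ([sim_config()]),
#' `filter` ([filter_spec()]), `segment` (window length and overlap),
#' `render` ([render_spec()]), `backbone` ([backbone_config()]), `fusion`
#' ([mhca_config()]) and `train` ([train_config()]), plus a global `seed`
#' that every stage seed is derived from unless overridden in its block.
#'
#' @param seed Global seed.
#' @param ... Named lists overriding fields of individual blocks, e.g.
#'   `sim = list(n_records = 8)`.
#' @return A list of class `pipeline_config` of fully-validated block configs.
#' @export
pipeline_config <- function(seed = 0L, ...) {
  over <- list(...)
  blocks <- list(
    sim = list(), filter = list(), segment = list(), render = list(),
    backbone = list(), fusion = list(), train = list(),
    evaluate = list(n_boot = 1000L, alpha = 0.05)
  )
  for (nm in names(over)) {
    if (!nm %in% names(blocks)) abort_config(sprintf("unknown pipeline block '%s'.", nm))
    blocks[[nm]] <- utils::modifyList(blocks[[nm]], over[[nm]])
  }
  build <- function(fn, args, defaults = list()) do.call(fn, utils::modifyList(defaults, args))
  cfg <- list(
    seed = as.integer(seed),
    sim = build(sim_config, blocks$sim, list(seed = derive_seed(seed, 1L))),
    filter = build(filter_spec, blocks$filter),
    segment = utils::modifyList(list(window_s = 15, overlap_frac = 2 / 3), blocks$segment),
    render = build(render_spec, blocks$render),
    backbone = build(backbone_config, blocks$backbone, list(seed = derive_seed(seed, 2L))),
    fusion = build(mhca_config, blocks$fusion, list(seed = derive_seed(seed, 3L))),
    train = build(train_config, blocks$train, list(seed = derive_seed(seed, 4L))),
    evaluate = blocks$evaluate
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain any subset of the blocks accepted by
#' [pipeline_config()] plus a top-level `seed`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("config file '%s' does not exist.", path))
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 0L
  raw$seed <- NULL
  do.call(pipeline_config, c(list(seed = seed), raw))
}

stage_fresh <- function(meta_path, hash, outputs) {
  if (!file.exists(meta_path) || !all(file.exists(outputs))) return(FALSE)
  meta <- tryCatch(jsonlite::read_json(meta_path), error = function(e) NULL)
  identical(meta$hash, hash)
}

write_stage_meta <- function(meta_path, hash, outputs) {
  jsonlite::write_json(
    list(hash = hash, outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)), outputs)),
         time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    meta_path, auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, cross-validated training/prediction and
#' evaluation, writing all artifacts under `out_dir`. Each stage is
#' idempotent: it is skipped when its outputs exist and were produced under
#' the same configuration (content-hash check), so deleting a late output
#' re-runs only the stages from that point on. A run manifest listing every
#' stage output with its file hash is written last.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The run manifest (named list), invisibly. Artifacts:
#'   `data/` (signals + manifest), `windows.rds`, `predictions.csv`,
#'   `report.json`, `run_manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) abort_config("`config` must be a `pipeline_config`.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, hash, outputs, fun) {
    meta_path <- file.path(out_dir, paste0(".", name, ".json"))
    if (stage_fresh(meta_path, hash, outputs)) {
      inform(sprintf("[%s] up to date, skipped.", name))
      return(invisible(NULL))
    }
    st <- Sys.time()
    fun()
    write_stage_meta(meta_path, hash, outputs)
    inform(sprintf("[%s] done in %.1f s.", name, as.numeric(difftime(Sys.time(), st, units = "secs"))))
  }

  data_dir <- file.path(out_dir, "data")
  h_sim <- config_hash(unclass(config$sim))
  stage("simulate", h_sim, file.path(data_dir, "manifest.json"), function() {
    recs <- simulate_ppg_dataset(config$sim)
    write_ppg_dataset(recs, data_dir)
    inform(sprintf("[simulate] %d records x %.0f s at %g Hz.",
                   nrow(recs), config$sim$record_duration, config$sim$sampling_rate))
  })

  win_path <- file.path(out_dir, "windows.rds")
  h_win <- config_hash(list(h_sim, unclass(config$filter), config$segment))
  stage("preprocess", h_win, win_path, function() {
    recs <- read_ppg_dataset(data_dir)
    windows <- make_windows(recs, config$filter, config$segment$window_s, config$segment$overlap_frac)
    saveRDS(windows, win_path)
    inform(sprintf("[preprocess] %d windows from %d records.", nrow(windows), nrow(recs)))
  })

  pred_path <- file.path(out_dir, "predictions.csv")
  h_train <- config_hash(list(h_win, unclass(config$render), unclass(config$backbone),
                              unclass(config$fusion), unclass(config$train)))
  stage("train", h_train, pred_path, function() {
    windows <- readRDS(win_path)
    cv <- kfold_evaluate(windows, config$backbone, config$fusion, config$render, config$train)
    write_predictions(cv$predictions, pred_path)
    inform(sprintf("[train] %d folds, %d pooled predictions.",
                   config$train$k_folds, nrow(cv$predictions)))
  })

  report_path <- file.path(out_dir, "report.json")
  h_eval <- config_hash(list(h_train, config$evaluate, config$seed))
  stage("evaluate", h_eval, report_path, function() {
    preds <- read_predictions(pred_path)
    report <- evaluate_report(preds, n_boot = config$evaluate$n_boot,
                              alpha = config$evaluate$alpha,
                              seed = derive_seed(config$seed, 5L))
    write_report_json(report, report_path)
    print(report)
  })

  outputs <- c(file.path(data_dir, "manifest.json"), win_path, pred_path, report_path)
  manifest <- list(
    config_hash = config_hash(rapply(unclass(config), identity, how = "list")),
    seed = config$seed,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)), basename(outputs))),
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
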