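#' Serialize an experiment configuration to YAML
#'
#' An experiment config bundles the stage configs plus paths, variant and
#' master seed, and round-trips losslessly through YAML so any run can be
#' reproduced from its config file and seed alone.
#'
#' @param config named list of stage configs (classes are preserved on read).
#' @param path output YAML path.
#' @return Invisibly, `path`.
#' @export
write_experiment_config <- function(config, path) {
  ser <- lapply(config, function(x)
    if (is.list(x)) c(unclass(x), list(.class = class(x)[1])) else x)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#' @param path YAML path written by [write_experiment_config()].
#' @return The configuration list with stage-config classes restored.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    if (is.list(x) && !is.null(x$.class)) {
      cl <- x$.class; x$.class <- NULL
      structure(x, class = cl)
    } else x
  })
}

config_hash <- function(config) {
  # order-stable hash of the deparsed config; embedded in every artifact
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_report <- function(report, path, master_seed, config) {
  out <- list(config_hash = config_hash(config), master_seed = master_seed,
              pooled = unclass(report$pooled),
              per_fold = lapply(report$per_fold, unclass))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

write_predictions_csv <- function(preds, path) {
  utils::write.csv(
    data.frame(subject = preds$subject, round = preds$round,
               window_start_s = preds$start_s, estimate = preds$estimate),
    path, row.names = FALSE)
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate   --n-subjects N --seed S --out-dir DIR [--round-s SEC]",
    "             [--session-s SEC] [--exam-s SEC]",
    "  preprocess --data-dir DIR --out-dir DIR",
    "  evaluate   --data-dir DIR --out-dir DIR --variant V --seed S",
    "             [--folds K] [--epochs E] [--width W] [--lstm H]",
    "  benchmark  --data-dir DIR --out-dir DIR --seed S [--folds K]",
    "             [--epochs E] [--width W] [--lstm H]",
    sep = "\n")
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    if (!startsWith(argv[i], "--"))
      stop("unexpected argument '", argv[i], "'\n", cli_usage())
    key <- sub("^--", "", argv[i])
    if (i + 1L > length(argv)) stop("flag --", key, " needs a value")
    flags[[gsub("-", "_", key)]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

cli_net_config <- function(flags) {
  w <- as.integer(flags$width %||% "8")
  network_config(r_filters1 = w, r_filters2 = 2L * w, s_filters1 = w,
                 s_filters2 = 2L * w, task_head = 4L * w,
                 lstm = as.integer(flags$lstm %||% "16"),
                 fusion = 4L * w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_one_variant <- function(ws, variant, flags, master_seed) {
  subjects <- unique(ws$meta$subject)
  k <- as.integer(flags$folds %||% "0")
  folds <- if (k >= 2) grouped_folds(subjects, k, seed = master_seed)
           else loso_folds(subjects)
  tcfg <- train_config(epochs = as.integer(flags$epochs %||% "35"),
                       learning_rate = as.numeric(flags$lr %||% "3e-3"),
                       seed = stage_seed(master_seed, "finetune"))
  run_experiment(ws, variant, folds, cli_net_config(flags), tcfg,
                 stft = stft_config())
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher tying the stages into reproducible shell runs:
#' `simulate` writes a synthetic cohort as CSV+JSON; `preprocess` turns a
#' cohort directory into a persisted window set; `evaluate` cross-validates
#' one model variant and writes predictions CSV + report JSON; `benchmark`
#' runs all seven variants over the same folds and writes a comparison
#' table. Every artifact embeds the config hash and master seed.
#'
#' @param argv character vector of command-line arguments (subcommand first).
#' @return Exit code, 0 on success (invisibly).
#' @export
run_cli <- function(argv) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(if (length(argv) == 0) 1L else 0L))
  }
  cmd <- argv[1]
  if (!cmd %in% c("simulate", "preprocess", "evaluate", "benchmark")) {
    message("unknown subcommand '", cmd, "'\n", cli_usage())
    return(invisible(1L))
  }
  flags <- parse_flags(argv[-1])
  seed <- as.integer(flags$seed %||% "1")
  t0 <- Sys.time()
  log_line <- function(stage, ...) {
    message(jsonlite::toJSON(list(stage = stage, seed = seed,
                                  elapsed_s = round(as.numeric(
                                    difftime(Sys.time(), t0, units = "secs")), 2),
                                  ...), auto_unbox = TRUE))
  }

  if (cmd == "simulate") {
    cfg <- cohort_config(
      n_subjects = as.integer(flags$n_subjects %||% "4"),
      round_duration_s = as.numeric(flags$round_s %||% "600"),
      session_duration_s = as.numeric(flags$session_s %||% "1800"),
      exam_s = as.numeric(flags$exam_s %||% "30"),
      seed = stage_seed(seed, "simulate"))
    recs <- simulate_cohort(cfg)
    write_cohort(recs, flags$out_dir %||% ".")
    log_line("simulate", n_subjects = cfg$n_subjects,
             config_hash = config_hash(list(cohort = cfg)))
    return(invisible(0L))
  }

  if (cmd == "preprocess") {
    recs <- read_cohort(flags$data_dir %||% ".")
    ws <- preprocess_cohort(recs)
    dir.create(flags$out_dir %||% ".", recursive = TRUE, showWarnings = FALSE)
    saveRDS(ws, file.path(flags$out_dir %||% ".", "windows.rds"))
    log_line("preprocess", n_windows = nrow(ws$meta))
    return(invisible(0L))
  }

  # evaluate / benchmark start from a cohort directory
  recs <- read_cohort(flags$data_dir %||% ".")
  ws <- preprocess_cohort(recs)
  out_dir <- flags$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (cmd == "evaluate") {
    variant <- flags$variant %||% "cnn_multi_lstm"
    res <- run_one_variant(ws, variant, flags, seed)
    write_predictions_csv(res$predictions,
                          file.path(out_dir, paste0(variant, "_predictions.csv")))
    write_report(res, file.path(out_dir, paste0(variant, "_report.json")),
                 seed, flags[setdiff(names(flags), c("out_dir", "data_dir"))])
    log_line("evaluate", variant = variant, r = res$pooled$r,
             MAE = res$pooled$MAE)
    return(invisible(0L))
  }

  rows <- lapply(MODEL_VARIANTS, function(v) {
    res <- run_one_variant(ws, v, flags, seed)
    log_line("benchmark", variant = v, r = res$pooled$r, MAE = res$pooled$MAE)
    data.frame(variant = v, r = res$pooled$r, R2 = res$pooled$R2,
               MAE = res$pooled$MAE, RMSE = res$pooled$RMSE,
               n_rounds = res$pooled$n)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "benchmark.csv"), row.names = FALSE)
  log_line("benchmark", done = TRUE)
  invisible(0L)
}
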