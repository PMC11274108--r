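#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is that subject alone and its
#' training set is every other subject, so test sets are disjoint and
#' exhaustive and no identity leaks across the split.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @return List of folds, each a list with `train_ids` and `test_ids`.
#' @export
loso_folds <- function(subject_ids) {
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (length(subject_ids) < 2) stop("need at least 2 subjects")
  lapply(subject_ids, function(s)
    list(train_ids = setdiff(subject_ids, s), test_ids = s))
}

#' Grouped k-fold subject splits
#'
#' Subjects (never windows) are partitioned into `k` folds; each fold's
#' subjects form the test set once. A scaled-down stand-in for full
#' leave-one-subject-out when training cost matters.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return List of folds, each a list with `train_ids` and `test_ids`.
#' @export
grouped_folds <- function(subject_ids, k = 3L, seed = 1L) {
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  stopifnot(k >= 2, k <= length(subject_ids))
  set.seed(seed)
  shuffled <- sample(subject_ids)
  grp <- rep(seq_len(k), length.out = length(shuffled))
  lapply(seq_len(k), function(i)
    list(train_ids = sort(shuffled[grp != i]),
         test_ids = sort(shuffled[grp == i])))
}

#' Average per-window estimates within rounds
#'
#' The round, not the window, is the clinical unit: per-round estimates are
#' the arithmetic means of the round's window estimates, paired with the
#' round's clinical score. Rounds with zero windows are dropped with a
#' warning.
#'
#' @param estimates numeric vector of per-window estimates.
#' @param meta data.frame with `subject`, `round`, `updrs`, `med_state` and
#'   optionally `activity` aligned with `estimates`.
#' @return data.frame with one row per (subject, round): `estimate`, `updrs`,
#'   `med_state`, `n_windows`.
#' @export
round_average <- function(estimates, meta) {
  stopifnot(length(estimates) == nrow(meta))
  key <- interaction(meta$subject, meta$round, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    idx <- which(key == k)
    data.frame(subject = meta$subject[idx[1]], round = meta$round[idx[1]],
               estimate = mean(estimates[idx]), updrs = meta$updrs[idx[1]],
               med_state = meta$med_state[idx[1]], n_windows = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$subject, out$round), , drop = FALSE]
}

#' Round-level agreement metrics
#'
#' Pearson correlation (two-sided p via the t transform), coefficient of
#' determination `R2 = 1 - SS_res/SS_tot`, mean absolute error and root mean
#' squared error between clinical scores and estimates.
#'
#' @param y clinical scores.
#' @param y_hat estimates.
#' @return List of class `metrics_report` with `r`, `p_value`, `R2`, `MAE`,
#'   `RMSE`, `n`.
#' @export
compute_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  if (stats::sd(y) < 1e-12) {
    return(structure(list(r = NA_real_, p_value = NA_real_,
                          R2 = NA_real_, MAE = mean(abs(y - y_hat)),
                          RMSE = sqrt(mean((y - y_hat)^2)), n = length(y),
                          flag = "zero-variance clinical scores"),
                     class = "metrics_report"))
  }
  p_val <- if (length(y) >= 3 && stats::sd(y_hat) > 1e-12)
    suppressWarnings(stats::cor.test(y, y_hat, method = "pearson")$p.value)
  else NA_real_
  structure(list(r = suppressWarnings(stats::cor(y, y_hat)),
                 p_value = p_val,
                 R2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2),
                 MAE = mean(abs(y - y_hat)),
                 RMSE = sqrt(mean((y - y_hat)^2)),
                 n = length(y), flag = NULL),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("rounds: %d  r = %.3f (p = %.3g)  R2 = %.3f  MAE = %.2f  RMSE = %.2f\n",
              x$n, x$r, x$p_value, x$R2, x$MAE, x$RMSE))
  invisible(x)
}

#' Metrics by group (activity, medication state, subject)
#'
#' Splits a prediction table by a grouping key and reports metrics per group.
#' For medication-state grouping the per-subject MAE median and IQR are also
#' reported. Groups with fewer than 2 rounds are flagged with undefined
#' correlation metrics.
#'
#' @param pred data.frame of per-round predictions with columns `estimate`,
#'   `updrs` and the grouping key.
#' @param group_key one of `"activity"`, `"med_state"`, `"subject"`.
#' @return Named list of `metrics_report` objects (plus `mae_median`/
#'   `mae_iqr` for med_state grouping).
#' @export
grouped_metrics <- function(pred, group_key = c("med_state", "activity",
                                                "subject")) {
  group_key <- match.arg(group_key)
  if (!group_key %in% names(pred)) stop("group key not present in metadata")
  out <- list()
  for (g in sort(unique(pred[[group_key]]))) {
    sub <- pred[pred[[group_key]] == g, , drop = FALSE]
    if (nrow(sub) < 2) {
      rep <- structure(list(r = NA_real_, p_value = NA_real_, R2 = NA_real_,
                            MAE = mean(abs(sub$updrs - sub$estimate)),
                            RMSE = sqrt(mean((sub$updrs - sub$estimate)^2)),
                            n = nrow(sub), flag = "fewer than 2 rounds"),
                       class = "metrics_report")
    } else {
      rep <- compute_metrics(sub$updrs, sub$estimate)
    }
    if (group_key == "med_state" && "subject" %in% names(pred)) {
      per_subj <- vapply(split(sub, sub$subject), function(d)
        mean(abs(d$updrs - d$estimate)), numeric(1))
      rep$mae_median <- stats::median(per_subj)
      rep$mae_iqr <- stats::IQR(per_subj)
    }
    out[[as.character(g)]] <- rep
  }
  out
}

# Audit that nothing of the test subjects leaked into training structures.
audit_no_leakage <- function(fold, train_meta, norm, val_subjects = NULL) {
  leaks <- intersect(unique(train_meta$subject), fold$test_ids)
  if (length(leaks) > 0)
    stop("leakage: test subject(s) in training windows: ",
         paste(leaks, collapse = ", "))
  if (length(intersect(norm$fitted_on, fold$test_ids)) > 0)
    stop("leakage: normalization statistics saw a test subject")
  if (!is.null(val_subjects) &&
      length(intersect(val_subjects, fold$test_ids)) > 0)
    stop("leakage: validation split contains a test subject")
  invisible(TRUE)
}

#' Run a cross-validated experiment for one model variant
#'
#' For each fold: fit the input normalizer on the training subjects only; for
#' the self-supervised variant, build the pretext dataset from training
#' windows, pretrain, and transfer/freeze into the target network; fine-tune
#' (or train the supervised variant from scratch) on the training windows;
#' predict the held-out subjects' windows; average within rounds. Pooled
#' metrics are computed over the concatenated held-out rounds of all folds,
#' and per-fold reports are returned alongside.
#'
#' @param ws a `window_set` for the whole cohort (unnormalized).
#' @param variant a model variant (see [build_model()]).
#' @param folds list of folds from [loso_folds()] or [grouped_folds()].
#' @param net_config a [network_config()].
#' @param tcfg a [train_config()]; per-fold seeds are derived from its seed.
#' @param lcfg a [loss_config()].
#' @param transform a [transform_config()] (self-supervised variant only).
#' @param stft the [stft_config()] the window set was built with (used to
#'   recompute spectrograms of transformed windows).
#' @param pretrain_epochs optional cap on pretraining epochs (defaults to
#'   `tcfg$epochs`).
#' @return List with `predictions` (per-window), `rounds` (per-round table),
#'   `pooled` (a `metrics_report`), `per_fold` (list of reports) and
#'   `history` (per-fold train histories).
#' @export
run_experiment <- function(ws, variant, folds, net_config = network_config(),
                           tcfg = train_config(), lcfg = loss_config(),
                           transform = transform_config(),
                           stft = stft_config(), pretrain_epochs = NULL) {
  stopifnot(variant %in% MODEL_VARIANTS)
  input <- list(len = dim(ws$x_r)[2], ch = dim(ws$x_r)[3],
                fbins = dim(ws$x_s)[2], frames = dim(ws$x_s)[3])
  preds <- NULL; per_fold <- list(); histories <- list()
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    fold_seed <- as.integer((tcfg$seed + 104729 * fi) %% (2^31 - 1))
    tr <- subset_window_set(ws, ws$meta$subject %in% fold$train_ids)
    te <- subset_window_set(ws, ws$meta$subject %in% fold$test_ids)
    norm <- fit_normalizer(tr)
    audit_no_leakage(fold, tr$meta, norm)
    trn <- apply_normalizer(tr, norm)
    ten <- apply_normalizer(te, norm)
    tcfg_f <- tcfg; tcfg_f$seed <- fold_seed

    if (variant == "mssl_cnn_multi_lstm") {
      tcfg_p <- tcfg_f
      if (!is.null(pretrain_epochs)) tcfg_p$epochs <- as.integer(pretrain_epochs)
      tf <- transform
      tf$rng_seed <- fold_seed
      ssl_data <- build_ssl_dataset(trn, tf, stft)
      pt <- pretrain(ssl_data, net_config, tcfg_p, lcfg, input)
      model <- build_model(variant, net_config, input, seed = fold_seed)
      model <- transfer_and_freeze(pt$weights, model)
      histories[[fi]] <- list(pretrain = pt$history)
    } else {
      model <- build_model(variant, net_config, input, seed = fold_seed)
      histories[[fi]] <- list()
    }
    ft <- finetune(model, trn, tcfg_f, lcfg)
    histories[[fi]]$finetune <- ft$history
    est <- predict_window_set(ft$model, ten)
    p <- cbind(te$meta, estimate = est, fold = fi)
    preds <- rbind(preds, p)
    rd <- round_average(est, te$meta)
    per_fold[[fi]] <- if (nrow(rd) >= 2) compute_metrics(rd$updrs, rd$estimate)
                      else NULL
  }
  rounds <- round_average(preds$estimate, preds)
  list(predictions = preds, rounds = rounds,
       pooled = compute_metrics(rounds$updrs, rounds$estimate),
       per_fold = per_fold, history = histories)
}
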