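test_that("LOSO folds are disjoint, exhaustive and leak-free", {
  ids <- sprintf("S%02d", 1:24)
  folds <- loso_folds(ids)
  expect_length(folds, 24)
  test_ids <- vapply(folds, `[[`, character(1), "test_ids")
  expect_setequal(test_ids, ids)
  expect_false(anyDuplicated(test_ids) > 0)
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$test_ids), ids)
  }
  expect_error(loso_folds(c("a", "a", "b")), "duplicate")
  expect_error(loso_folds("a"), "at least 2")
})

test_that("grouped folds partition subjects, never windows", {
  ids <- sprintf("S%02d", 1:8)
  folds <- grouped_folds(ids, 3, seed = 5)
  expect_length(folds, 3)
  expect_setequal(unlist(lapply(folds, `[[`, "test_ids")), ids)
  for (f in folds)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
})

test_that("round averaging is the arithmetic mean per round", {
  meta <- data.frame(subject = "A", round = c(1, 1, 1, 2, 2, 3),
                     updrs = c(20, 20, 20, 10, 10, 5),
                     med_state = c("OFF", "OFF", "OFF", "ON", "ON", "ON"))
  rd <- round_average(c(10, 20, 30, 4, 6, 10), meta)
  expect_equal(rd$estimate, c(20, 5, 10))
  expect_equal(rd$updrs, c(20, 10, 5))
  expect_equal(rd$n_windows, c(3, 2, 1))
  # permutation of window order leaves round means unchanged
  perm <- c(3, 1, 6, 2, 5, 4)
  rd2 <- round_average(c(10, 20, 30, 4, 6, 10)[perm], meta[perm, ])
  expect_equal(rd2$estimate, rd$estimate)
})

test_that("agreement metrics match hand computations", {
  m <- compute_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(m$r, 1); expect_equal(m$R2, 1); expect_equal(m$MAE, 0)
  # constant prediction at the mean -> R2 = 0
  y <- c(2, 4, 6, 8)
  m0 <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(m0$R2, 0)
  # y = (0,1,2), y_hat = (0,2,4): SS_res = 5, SS_tot = 2
  m1 <- compute_metrics(c(0, 1, 2), c(0, 2, 4))
  expect_equal(m1$r, 1)
  expect_equal(m1$MAE, 1)
  expect_equal(m1$R2, -1.5)
  expect_gte(m1$RMSE, m1$MAE)  # Jensen
  # zero-variance clinical scores are flagged, not crashed
  mz <- compute_metrics(c(3, 3, 3), c(1, 2, 3))
  expect_true(is.na(mz$r))
  expect_match(mz$flag, "zero-variance")
})

test_that("grouped metrics split correctly and flag tiny groups", {
  pred <- data.frame(subject = rep(c("A", "B"), each = 4),
                     round = rep(1:4, 2),
                     estimate = c(10, 12, 20, 22, 11, 13, 21, 23),
                     updrs = c(10, 12, 20, 22, 11, 13, 21, 23),
                     med_state = rep(c("OFF", "ON", "ON", "ON"), 2))
  g <- grouped_metrics(pred, "med_state")
  expect_setequal(names(g), c("OFF", "ON"))
  expect_equal(g$ON$MAE, 0)
  expect_equal(g$OFF$MAE, 0)
  expect_true(!is.null(g$ON$mae_median))
  # identical group copies yield identical reports
  pred2 <- pred; pred2$med_state <- rep(c("X", "Y"), 4)
  g2 <- grouped_metrics(pred2, "med_state")
  expect_equal(g2$X$MAE, g2$Y$MAE)
  expect_error(grouped_metrics(pred[, -5], "med_state"), "not present")
})

test_that("pooled window-level MAE equals the count-weighted group mean", {
  set.seed(12)
  est <- stats::runif(30, 0, 50)
  y <- stats::runif(30, 0, 50)
  grp <- sample(c("a", "b", "c"), 30, replace = TRUE)
  pooled <- mean(abs(y - est))
  per <- vapply(split(seq_len(30), grp), function(i) mean(abs(y[i] - est[i])),
                numeric(1))
  wts <- table(grp)[names(per)]
  expect_equal(sum(per * as.numeric(wts)) / 30, pooled)
})

test_that("the leakage audit rejects contaminated folds", {
  ws <- small_cohort_ws(n_subjects = 3, round_s = 30, exam_s = 0)
  ids <- unique(ws$meta$subject)
  fold <- list(train_ids = ids[1:2], test_ids = ids[3])
  tr <- subset_window_set(ws, ws$meta$subject %in% fold$train_ids)
  norm <- fit_normalizer(tr)
  audit <- asNamespace("msslwear")$audit_no_leakage
  expect_true(audit(fold, tr$meta, norm))
  # training windows from the held-out subject
  expect_error(audit(fold, ws$meta, norm), "training windows")
  # normalizer fitted on everything
  expect_error(audit(fold, tr$meta, fit_normalizer(ws)), "normalization")
  # validation split containing the test subject
  expect_error(audit(fold, tr$meta, norm, val_subjects = ids[3]),
               "validation split")
})

test_that("a cross-validated experiment is reproducible and leak-audited", {
  ws <- small_cohort_ws(n_subjects = 4, round_s = 30, exam_s = 0, seed = 41)
  folds <- grouped_folds(unique(ws$meta$subject), 2, seed = 3)
  tcfg <- train_config(epochs = 2, learning_rate = 3e-3, seed = 13)
  res <- run_experiment(ws, "cnn1d", folds, small_net_config(), tcfg,
                        stft = train_stft())
  # pooled table covers every round of every subject exactly once
  expect_equal(nrow(res$rounds),
               nrow(unique(ws$meta[, c("subject", "round")])))
  expect_equal(sort(unique(res$predictions$subject)),
               sort(unique(ws$meta$subject)))
  # determinism under a fixed seed
  res2 <- run_experiment(ws, "cnn1d", folds, small_net_config(), tcfg,
                         stft = train_stft())
  expect_equal(res$pooled$r, res2$pooled$r, tolerance = 1e-12)
  expect_equal(res$predictions$estimate, res2$predictions$estimate,
               tolerance = 1e-12)
})
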