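test_that("multi-shared-task loss matches its closed forms", {
  lc <- loss_config(positive_weight = 1)
  # single task, single sample, y = 1, P = 0.5 -> -log(0.5)
  expect_equal(ssl_loss(matrix(1), matrix(0.5), lc), 0.6931472,
               tolerance = 1e-5)
  # perfect predictions at the clipping boundary -> ~ 0
  y <- matrix(c(1, 0, 0, 1, 0, 1), 2, 3)
  expect_lt(ssl_loss(y, y, lc), 1e-5)
  # linearity in the task weights: doubling alpha_1 doubles task 1's share
  P <- matrix(stats::runif(6, 0.2, 0.8), 2, 3)
  l1 <- ssl_loss(y, P, loss_config(alphas = c(1, 1, 1), positive_weight = 1))
  l2 <- ssl_loss(y, P, loss_config(alphas = c(2, 1, 1), positive_weight = 1))
  task1 <- ssl_loss(y[, 1, drop = FALSE], P[, 1, drop = FALSE],
                    loss_config(alphas = 1, positive_weight = 1))
  expect_equal(l2 - l1, task1, tolerance = 1e-12)
  expect_error(ssl_loss(y, P[, 1:2]), "identical dimensions")
  # non-negative always
  expect_gte(ssl_loss(y, P, loss_config()), 0)
})

test_that("Huber loss matches quadratic and linear branches exactly", {
  expect_equal(huber_loss(0, 0, 1), 0)
  expect_equal(huber_loss(0.5, 0, 1), 0.125)  # quadratic branch: r^2/2
  expect_equal(huber_loss(3, 0, 1), 2.5)      # linear branch: 1*(3 - 0.5)
  # continuity and differentiability at |r| = delta
  d <- 1; e <- 1e-6
  expect_equal(huber_loss(d + e, 0, d), huber_loss(d - e, 0, d),
               tolerance = 1e-5)
  g_plus <- (huber_loss(d + 2 * e, 0, d) - huber_loss(d, 0, d)) / (2 * e)
  g_minus <- (huber_loss(d, 0, d) - huber_loss(d - 2 * e, 0, d)) / (2 * e)
  expect_equal(g_plus, g_minus, tolerance = 1e-4)
  # bounded above by half squared error, equality iff |r| <= delta
  r <- seq(-4, 4, by = 0.25)
  h <- vapply(r, function(ri) huber_loss(ri, 0, 1), numeric(1))
  expect_true(all(h <= r^2 / 2 + 1e-12))
  expect_equal(h[abs(r) <= 1], (r^2 / 2)[abs(r) <= 1])
  expect_true(all(h[abs(r) > 1] < (r^2 / 2)[abs(r) > 1]))
})

test_that("pretraining reduces the pretext loss and learns above chance", {
  ws <- small_cohort_ws(n_subjects = 3, round_s = 40, exam_s = 0, seed = 33)
  norm <- fit_normalizer(ws)
  ds <- build_ssl_dataset(apply_normalizer(ws, norm),
                          transform_config(rng_seed = 2), train_stft())
  input <- list(len = 320L, ch = 6L, fbins = dim(ws$x_s)[2],
                frames = dim(ws$x_s)[3])
  tcfg <- train_config(epochs = 4, learning_rate = 1e-3, seed = 8)
  pt <- pretrain(ds, small_net_config(), tcfg, loss_config(), input)
  h <- pt$history
  expect_lt(utils::tail(h$train_loss, 1), h$train_loss[1])
  acc <- h$val_metric[[length(h$val_metric)]]
  expect_true(all(acc > 0.5))
  # identical seed and data reproduce the history exactly
  pt2 <- pretrain(ds, small_net_config(), tcfg, loss_config(), input)
  expect_identical(pt$history, pt2$history)
  # degenerate labels are refused
  ds_bad <- ds
  ds_bad$y_p[, 2] <- 0
  expect_error(pretrain(ds_bad, small_net_config(), tcfg, loss_config(),
                        input), "single class")
})

test_that("fine-tuning respects frozen tensors and improves on the fresh head", {
  ws <- small_cohort_ws(n_subjects = 3, round_s = 40, exam_s = 0, seed = 34)
  norm <- fit_normalizer(ws)
  wsn <- apply_normalizer(ws, norm)
  input <- list(len = 320L, ch = 6L, fbins = dim(ws$x_s)[2],
                frames = dim(ws$x_s)[3])
  cfg <- small_net_config()
  tcfg <- train_config(epochs = 5, learning_rate = 3e-3, seed = 9)
  ssl <- build_ssl_network(cfg, input, seed = 9)
  model <- transfer_and_freeze(ssl, build_model("mssl_cnn_multi_lstm", cfg,
                                                input, seed = 10))
  untrained_mae <- {
    est0 <- target_forward(model, wsn$x_r, wsn$x_s)
    mean(abs(wsn$meta$updrs - est0))
  }
  ft <- finetune(model, wsn, tcfg, loss_config())
  # frozen first blocks bit-identical through training
  for (k in model$frozen)
    expect_identical(ft$model$params[[k]], model$params[[k]])
  # trainable blocks moved
  expect_gt(sum((ft$model$params$convR_b2_W - model$params$convR_b2_W)^2), 0)
  # validation MAE beats the untrained head
  expect_lt(min(unlist(ft$history$val_metric)), untrained_mae)
  # label broadcast: every window of a round carries the round's score
  rd <- ws$meta[ws$meta$round == 1 & ws$meta$subject == ws$meta$subject[1], ]
  expect_equal(length(unique(rd$updrs)), 1L)
  wsn_na <- wsn
  wsn_na$meta$updrs <- NA
  expect_error(finetune(model, wsn_na, tcfg), "no labelled rounds")
})

test_that("finite-difference perturbation of a frozen tensor changes the loss", {
  # freezing masks the update, not the gradient path
  ns <- asNamespace("msslwear")
  cfg <- tiny_net_config()
  ssl <- build_ssl_network(cfg, tiny_input, seed = 4)
  m <- transfer_and_freeze(ssl, build_model("mssl_cnn_multi_lstm", cfg,
                                            tiny_input, seed = 5))
  set.seed(6)
  x_r <- array(stats::rnorm(2 * 20 * 6), c(2, 20, 6))
  x_s <- array(stats::rnorm(2 * 9 * 11 * 6), c(2, 9, 11, 6))
  y <- c(1, -1)
  loss_at <- function(mm) huber_loss(y, as.numeric(
    ns$net_fwd(mm, x_r, x_s, train = FALSE)$out), 1)
  base <- loss_at(m)
  m2 <- m
  m2$params$convR_b1_W[1] <- m2$params$convR_b1_W[1] + 0.5
  expect_false(isTRUE(all.equal(base, loss_at(m2))))
})
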