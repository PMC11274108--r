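test_that("default configuration carries the published hyperparameters", {
  cfg <- network_config()
  expect_equal(cfg$r_filters1, 64L);  expect_equal(cfg$r_kernel1, 32L)
  expect_equal(cfg$r_pool_size, 16L); expect_equal(cfg$r_pool_stride, 4L)
  expect_equal(cfg$r_dropout1, 0.1);  expect_equal(cfg$r_dropout2, 0.2)
  expect_equal(cfg$r_filters2, 128L); expect_equal(cfg$r_kernel2, 8L)
  expect_equal(cfg$s_filters1, 64L);  expect_equal(cfg$s_kernel1, c(5L, 5L))
  expect_equal(cfg$s_pool, c(2L, 2L))
  expect_equal(cfg$s_dropout1, 0.1);  expect_equal(cfg$s_dropout2, 0.1)
  expect_equal(cfg$s_filters2, 128L); expect_equal(cfg$s_kernel2, c(3L, 3L))
  expect_equal(cfg$task_head, 128L);  expect_equal(cfg$n_tasks, 3L)
  expect_equal(cfg$lstm, 128L);       expect_equal(cfg$lstm_dropout, 0.1)
  expect_equal(cfg$fusion, 256L)
  tc <- train_config()
  expect_equal(tc$epochs, 35L); expect_equal(tc$batch_size, 32L)
  expect_equal(tc$learning_rate, 1e-4); expect_equal(tc$val_fraction, 0.2)
})

test_that("branch shape chains match the published arithmetic", {
  m <- build_model("cnn_multi_lstm", network_config(), seed = 1)
  for (i in 1:3) {
    x_r <- array(stats::rnorm(2 * 320 * 6), c(2, 320, 6))
    x_s <- array(stats::rnorm(2 * 33 * 43 * 6), c(2, 33, 43, 6))
    expect_equal(dim(conv_r_forward(m, x_r, "seq")), c(2, 77, 128))
    expect_equal(dim(conv_r_forward(m, x_r, "pooled")), c(2, 128))
    expect_equal(dim(conv_s_forward(m, x_s, "seq")), c(2, 21, 128))
    expect_equal(dim(conv_s_forward(m, x_s, "pooled")), c(2, 128))
  }
  expect_error(conv_r_forward(m, array(0, c(2, 100, 6))), "raw input")
  expect_error(conv_s_forward(m, array(0, c(2, 10, 43, 6))), "spectrogram input")
})

test_that("compiled convolutions agree with the pure-R reference", {
  ns <- asNamespace("msslwear")
  set.seed(31)
  for (i in 1:5) {
    x <- array(stats::rnorm(3 * 25 * 4), c(3, 25, 4))
    W <- array(stats::rnorm(7 * 4 * 5), c(7, 4, 5)); b <- stats::rnorm(5)
    expect_equal(ns$conv1d_fwd(x, W, b)$out, ns$conv1d_fwd_ref(x, W, b),
                 tolerance = 1e-12)
    x2 <- array(stats::rnorm(2 * 12 * 15 * 3), c(2, 12, 15, 3))
    W2 <- array(stats::rnorm(5 * 3 * 3 * 4), c(5, 3, 3, 4)); b2 <- stats::rnorm(4)
    expect_equal(ns$conv2d_fwd(x2, W2, b2)$out, ns$conv2d_fwd_ref(x2, W2, b2),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences on every architecture", {
  ns <- asNamespace("msslwear")
  cfg <- tiny_net_config()
  set.seed(42)
  N <- 3
  x_r <- array(stats::rnorm(N * 20 * 6), c(N, 20, 6))
  x_s <- array(stats::rnorm(N * 9 * 11 * 6), c(N, 9, 11, 6))

  check_grads <- function(model, lossfn, n_per_tensor = 3) {
    fw <- ns$net_fwd(model, x_r, x_s, train = TRUE)
    lg <- lossfn(fw$out)
    grads <- ns$net_bwd(model, fw$cache, lg$dout)
    for (nm in names(grads)) {
      p <- model$params[[nm]]
      for (i in sample(length(p), min(n_per_tensor, length(p)))) {
        eps <- 1e-5
        m1 <- model; m1$params[[nm]][i] <- p[i] + eps
        m2 <- model; m2$params[[nm]][i] <- p[i] - eps
        num <- (lossfn(ns$net_fwd(m1, x_r, x_s, TRUE)$out)$loss -
                  lossfn(ns$net_fwd(m2, x_r, x_s, TRUE)$out)$loss) / (2 * eps)
        ana <- grads[[nm]][i]
        expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
      }
    }
  }

  lcfg <- loss_config(positive_weight = 2, alphas = c(1, 0.7, 1.3))
  y_p <- diag(3)
  check_grads(build_ssl_network(cfg, tiny_input, seed = 7),
              function(P) list(loss = ssl_loss(y_p, P, lcfg),
                               dout = ns$ssl_loss_grad_z(y_p, P, lcfg)))
  y <- c(0.3, -1.2, 2.0)
  reg_loss <- function(o) list(
    loss = huber_loss(y, as.numeric(o), 1),
    dout = matrix(ns$huber_grad_yhat(y, as.numeric(o), 1), ncol = 1))
  for (v in c("cnn1d", "cnn2d", "cnn_multi", "cnn1d_lstm", "cnn2d_lstm",
              "cnn_multi_lstm"))
    check_grads(build_model(v, cfg, tiny_input, seed = 5), reg_loss)
})

test_that("pretext head probabilities behave like sigmoids over shared features", {
  cfg <- tiny_net_config()
  m <- build_ssl_network(cfg, tiny_input, seed = 3)
  x_r <- array(stats::rnorm(4 * 20 * 6), c(4, 20, 6))
  x_s <- array(stats::rnorm(4 * 9 * 11 * 6), c(4, 9, 11, 6))
  P <- ssl_forward(m, x_r, x_s)
  expect_true(all(P > 0 & P < 1))
  # zero weights -> exactly 0.5 everywhere
  m0 <- m
  for (nm in names(m0$params)) m0$params[[nm]][] <- 0
  expect_true(all(ssl_forward(m0, x_r, x_s) == 0.5))
  # task heads are disjoint after the trunk: task-1 loss has zero gradient
  # w.r.t. task-2 head weights
  ns <- asNamespace("msslwear")
  fw <- ns$net_fwd(m, x_r, x_s, train = TRUE)
  dZ <- matrix(0, 4, 3); dZ[, 1] <- 1
  g <- ns$net_bwd(m, fw$cache, dZ)
  expect_true(all(g$task2_W1 == 0))
  expect_true(all(g$task3_W2 == 0))
  expect_false(all(g$task1_W1 == 0))
})

test_that("target network yields one finite deterministic scalar per window", {
  cfg <- tiny_net_config()
  m <- build_model("cnn_multi_lstm", cfg, tiny_input, seed = 2)
  x_r <- array(stats::rnorm(4 * 20 * 6), c(4, 20, 6))
  x_s <- array(stats::rnorm(4 * 9 * 11 * 6), c(4, 9, 11, 6))
  y1 <- target_forward(m, x_r, x_s)
  expect_length(y1, 4)
  expect_true(all(is.finite(y1)))
  # inference is deterministic (dropout off) and batch-order independent
  expect_identical(y1, target_forward(m, x_r, x_s))
  expect_equal(target_forward(m, x_r[c(2, 1, 4, 3), , , drop = FALSE],
                              x_s[c(2, 1, 4, 3), , , , drop = FALSE]),
               y1[c(2, 1, 4, 3)], tolerance = 1e-12)
  # zero-weight network outputs exactly the (zero) output bias
  m0 <- m
  for (nm in names(m0$params)) m0$params[[nm]][] <- 0
  expect_true(all(target_forward(m0, x_r, x_s) == 0))
})

test_that("every variant constructs and single-input variants reject the other input", {
  cfg <- tiny_net_config()
  for (v in c("cnn1d", "cnn2d", "cnn_multi", "cnn1d_lstm", "cnn2d_lstm",
              "cnn_multi_lstm", "mssl_cnn_multi_lstm")) {
    m <- build_model(v, cfg, tiny_input, seed = 1)
    expect_s3_class(m, "mssl_model")
  }
  expect_error(build_model("vgg", cfg, tiny_input), "unknown variant")
  # shared branch definitions: the multichannel model contains the raw
  # branch keys of the single-input model
  k1 <- names(build_model("cnn1d_lstm", cfg, tiny_input, seed = 1)$params)
  km <- names(build_model("cnn_multi_lstm", cfg, tiny_input, seed = 1)$params)
  expect_true(all(grep("^convR|^lstmR", k1, value = TRUE) %in% km))
  # parameter count is a pure function of the configuration
  expect_equal(param_count(build_model("cnn_multi_lstm", cfg, tiny_input, 1)),
               param_count(build_model("cnn_multi_lstm", cfg, tiny_input, 99)))
})

test_that("transfer copies convolutional weights and freezing masks updates", {
  cfg <- tiny_net_config()
  ssl <- build_ssl_network(cfg, tiny_input, seed = 11)
  tgt <- build_model("mssl_cnn_multi_lstm", cfg, tiny_input, seed = 12)
  tr <- transfer_and_freeze(ssl, tgt)
  for (k in grep("^conv", names(tr$params), value = TRUE))
    expect_identical(tr$params[[k]], ssl$params[[k]])
  expect_setequal(tr$frozen, c("convR_b1_W", "convR_b1_b",
                               "convS_b1_W", "convS_b1_b"))
  # one optimizer step with nonzero gradients: frozen unchanged, rest moved
  ns <- asNamespace("msslwear")
  x_r <- array(stats::rnorm(3 * 20 * 6), c(3, 20, 6))
  x_s <- array(stats::rnorm(3 * 9 * 11 * 6), c(3, 9, 11, 6))
  fw <- ns$net_fwd(tr, x_r, x_s, train = TRUE)
  g <- ns$net_bwd(tr, fw$cache, matrix(c(1, -1, 0.5), ncol = 1))
  st <- ns$adam_init(tr$params)
  upd <- ns$adam_step(tr$params, g, st, 0.01, tr$frozen)
  expect_identical(upd$params$convR_b1_W, tr$params$convR_b1_W)
  expect_identical(upd$params$convS_b1_W, tr$params$convS_b1_W)
  expect_gt(sum((upd$params$convR_b2_W - tr$params$convR_b2_W)^2), 0)
  expect_equal(sum(!names(tr$params) %in% tr$frozen),
               length(tr$params) - 4L)
  # key mismatch is reported with the missing keys
  bad <- ssl$params[!grepl("convS_b1", names(ssl$params))]
  expect_error(transfer_and_freeze(bad, tgt), "convS_b1")
})
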