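MODEL_VARIANTS <- c("cnn1d", "cnn2d", "cnn_multi", "cnn1d_lstm", "cnn2d_lstm",
                    "cnn_multi_lstm", "mssl_cnn_multi_lstm")

glorot <- function(...) {
  d <- c(...)
  fan_in <- prod(d[-length(d)]); fan_out <- prod(d[-(length(d) - 1)]) / d[1]
  if (length(d) == 2) { fan_in <- d[1]; fan_out <- d[2] }
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(d), -lim, lim), d)
}

lstm_init <- function(D, H) {
  b <- numeric(4 * H)
  b[H + 1:H] <- 1  # forget-gate bias at 1, standard LSTM practice
  list(Wx = glorot(D, 4 * H), Wh = glorot(H, 4 * H), b = b)
}

variant_uses <- function(variant) {
  list(r = !startsWith(variant, "cnn2d"),
       s = !startsWith(variant, "cnn1d"),
       lstm = grepl("lstm", variant))
}

conv_params <- function(cfg, C) {
  list(convR_b1_W = glorot(cfg$r_kernel1, C, cfg$r_filters1),
       convR_b1_b = numeric(cfg$r_filters1),
       convR_b2_W = glorot(cfg$r_kernel2, cfg$r_filters1, cfg$r_filters2),
       convR_b2_b = numeric(cfg$r_filters2),
       convS_b1_W = glorot(cfg$s_kernel1[1], cfg$s_kernel1[2], C, cfg$s_filters1),
       convS_b1_b = numeric(cfg$s_filters1),
       convS_b2_W = glorot(cfg$s_kernel2[1], cfg$s_kernel2[2], cfg$s_filters1,
                           cfg$s_filters2),
       convS_b2_b = numeric(cfg$s_filters2))
}

fused_dim <- function(cfg, use, per_branch) {
  n_branches <- sum(use$r, use$s)
  if (cfg$fusion_op == "concat") n_branches * per_branch else per_branch
}

#' Build a model of a given architecture variant
#'
#' Seven variants share the same branch definitions: single-input 1D (raw
#' signal) and 2D (spectrogram) CNNs and CNN-LSTMs, their multichannel
#' fusions, and the multichannel CNN-LSTM used as the target network of the
#' self-supervised route (`mssl_cnn_multi_lstm`, architecturally identical to
#' `cnn_multi_lstm` but pretrained and partially frozen by
#' [transfer_and_freeze()]). CNN variants regress from globally pooled branch
#' features; CNN-LSTM variants feed the branches' intra-window sequence
#' outputs (raw branch: pooled conv time axis, 77 steps; spectrogram branch:
#' frequency-averaged frames, 21 steps) into one LSTM per branch, fuse the
#' final states, and regress through a dense layer to a single unbounded
#' linear output.
#'
#' @param variant one of
#'   `r paste0('"', paste(MODEL_VARIANTS, collapse = '", "'), '"')`.
#' @param config a [network_config()].
#' @param input list with `len`, `ch` (raw window), `fbins`, `frames`
#'   (spectrogram).
#' @param seed initialization seed.
#' @return A list of class `mssl_model` with `params`, `frozen`, `variant`,
#'   `config`, `input`.
#' @export
build_model <- function(variant, config = network_config(),
                        input = list(len = 320L, ch = 6L, fbins = 33L,
                                     frames = 43L),
                        seed = 1L) {
  if (!variant %in% MODEL_VARIANTS)
    stop("unknown variant '", variant, "'; expected one of: ",
         paste(MODEL_VARIANTS, collapse = ", "))
  use <- variant_uses(variant)
  set.seed(seed)
  params <- conv_params(config, input$ch)
  if (!use$r) params <- params[!grepl("^convR", names(params))]
  if (!use$s) params <- params[!grepl("^convS", names(params))]
  if (use$lstm) {
    if (use$r) {
      l <- lstm_init(config$r_filters2, config$lstm)
      params$lstmR_Wx <- l$Wx; params$lstmR_Wh <- l$Wh; params$lstmR_b <- l$b
    }
    if (use$s) {
      l <- lstm_init(config$s_filters2, config$lstm)
      params$lstmS_Wx <- l$Wx; params$lstmS_Wh <- l$Wh; params$lstmS_b <- l$b
    }
    fin <- fused_dim(config, use, config$lstm)
  } else {
    if (use$r && use$s && config$fusion_op == "add" &&
        config$r_filters2 != config$s_filters2)
      stop("additive fusion requires equal branch widths")
    fin <- (if (use$r) config$r_filters2 else 0) +
           (if (use$s) config$s_filters2 else 0)
    if (use$r && use$s && config$fusion_op == "add") fin <- config$r_filters2
  }
  params$fusion_W <- glorot(fin, config$fusion)
  params$fusion_b <- numeric(config$fusion)
  params$out_W <- glorot(config$fusion, 1L)
  params$out_b <- 0
  structure(list(variant = variant, config = config, input = input,
                 params = params, frozen = character(0),
                 target_scale = NULL),
            class = "mssl_model")
}

#' Build the multi-shared-task self-supervised network
#'
#' The pretext network: both convolutional branches in pooled mode (global
#' average pooling on the raw branch, global max pooling on the spectrogram
#' branch), their features fused, and one shared dense+sigmoid head per
#' transformation-recognition task.
#'
#' @inheritParams build_model
#' @return A list of class `mssl_model` with `variant = "ssl"`.
#' @export
build_ssl_network <- function(config = network_config(),
                              input = list(len = 320L, ch = 6L, fbins = 33L,
                                           frames = 43L),
                              seed = 1L) {
  set.seed(seed)
  params <- conv_params(config, input$ch)
  fin <- if (config$fusion_op == "concat")
    config$r_filters2 + config$s_filters2 else config$r_filters2
  for (t in seq_len(config$n_tasks)) {
    params[[paste0("task", t, "_W1")]] <- glorot(fin, config$task_head)
    params[[paste0("task", t, "_b1")]] <- numeric(config$task_head)
    params[[paste0("task", t, "_W2")]] <- glorot(config$task_head, 1L)
    params[[paste0("task", t, "_b2")]] <- 0
  }
  structure(list(variant = "ssl", config = config, input = input,
                 params = params, frozen = character(0),
                 target_scale = NULL),
            class = "mssl_model")
}

# ---- branch forward / backward ----------------------------------------

branch_r_fwd <- function(params, x, cfg, mode = c("pooled", "seq"),
                         train = FALSE) {
  mode <- match.arg(mode)
  c1 <- conv1d_fwd(x, params$convR_b1_W, params$convR_b1_b)
  r1 <- relu_fwd(c1$out)
  p1 <- maxpool1d_fwd(r1$out, cfg$r_pool_size, cfg$r_pool_stride)
  d1 <- dropout_fwd(p1$out, cfg$r_dropout1, train)
  c2 <- conv1d_fwd(d1$out, params$convR_b2_W, params$convR_b2_b)
  r2 <- relu_fwd(c2$out)
  d2 <- dropout_fwd(r2$out, cfg$r_dropout2, train)
  if (mode == "pooled") {
    g <- gap1d_fwd(d2$out)
    out <- g$out; gcache <- g$cache
  } else {
    out <- d2$out; gcache <- NULL
  }
  list(out = out, cache = list(c1 = c1$cache, r1 = r1$cache, p1 = p1$cache,
                               d1 = d1$cache, c2 = c2$cache, r2 = r2$cache,
                               d2 = d2$cache, g = gcache, mode = mode))
}

branch_r_bwd <- function(cache, dout) {
  d <- if (cache$mode == "pooled") gap1d_bwd(cache$g, dout) else dout
  d <- dropout_bwd(cache$d2, d)
  d <- relu_bwd(cache$r2, d)
  b2 <- conv1d_bwd(cache$c2, d)
  d <- dropout_bwd(cache$d1, b2$dx)
  d <- maxpool1d_bwd(cache$p1, d)
  d <- relu_bwd(cache$r1, d)
  b1 <- conv1d_bwd(cache$c1, d)
  list(grads = list(convR_b1_W = b1$dW, convR_b1_b = b1$db,
                    convR_b2_W = b2$dW, convR_b2_b = b2$db),
       dx = b1$dx)
}

branch_s_fwd <- function(params, x, cfg, mode = c("pooled", "seq"),
                         train = FALSE) {
  mode <- match.arg(mode)
  c1 <- conv2d_fwd(x, params$convS_b1_W, params$convS_b1_b)
  r1 <- relu_fwd(c1$out)
  p1 <- maxpool2d_fwd(r1$out, cfg$s_pool, cfg$s_pool)
  d1 <- dropout_fwd(p1$out, cfg$s_dropout1, train)
  c2 <- conv2d_fwd(d1$out, params$convS_b2_W, params$convS_b2_b)
  r2 <- relu_fwd(c2$out)
  d2 <- dropout_fwd(r2$out, cfg$s_dropout2, train)
  if (mode == "pooled") {
    g <- gmp2d_fwd(d2$out)
  } else {
    g <- freqmean_fwd(d2$out)
  }
  list(out = g$out, cache = list(c1 = c1$cache, r1 = r1$cache, p1 = p1$cache,
                                 d1 = d1$cache, c2 = c2$cache, r2 = r2$cache,
                                 d2 = d2$cache, g = g$cache, mode = mode))
}

branch_s_bwd <- function(cache, dout) {
  d <- if (cache$mode == "pooled") gmp2d_bwd(cache$g, dout)
       else freqmean_bwd(cache$g, dout)
  d <- dropout_bwd(cache$d2, d)
  d <- relu_bwd(cache$r2, d)
  b2 <- conv2d_bwd(cache$c2, d)
  d <- dropout_bwd(cache$d1, b2$dx)
  d <- maxpool2d_bwd(cache$p1, d)
  d <- relu_bwd(cache$r1, d)
  b1 <- conv2d_bwd(cache$c1, d)
  list(grads = list(convS_b1_W = b1$dW, convS_b1_b = b1$db,
                    convS_b2_W = b2$dW, convS_b2_b = b2$db),
       dx = b1$dx)
}

#' Raw-signal branch features (ConvR)
#'
#' @param model an `mssl_model` with a raw branch.
#' @param x_r array `N x len x ch` of (normalized) raw windows.
#' @param mode `"pooled"` (global average pooling, pretext mode) or `"seq"`
#'   (sequence output for the LSTM, target mode).
#' @return `N x filters2` matrix (pooled) or `N x steps x filters2` array.
#' @export
conv_r_forward <- function(model, x_r, mode = c("pooled", "seq")) {
  check_r_input(model, x_r)
  branch_r_fwd(model$params, x_r, model$config, match.arg(mode))$out
}

#' Spectrogram branch features (ConvS)
#'
#' @param model an `mssl_model` with a spectrogram branch.
#' @param x_s array `N x fbins x frames x ch` of (scaled) spectrograms.
#' @param mode `"pooled"` (global max pooling) or `"seq"`
#'   (frequency-averaged frame sequence).
#' @return `N x filters2` matrix (pooled) or `N x frames' x filters2` array.
#' @export
conv_s_forward <- function(model, x_s, mode = c("pooled", "seq")) {
  check_s_input(model, x_s)
  branch_s_fwd(model$params, x_s, model$config, match.arg(mode))$out
}

check_r_input <- function(model, x_r) {
  d <- dim(x_r)
  if (length(d) != 3 || d[2] != model$input$len || d[3] != model$input$ch)
    stop("raw input must be N x ", model$input$len, " x ", model$input$ch,
         ", got ", paste(d, collapse = " x "))
}
check_s_input <- function(model, x_s) {
  d <- dim(x_s)
  if (length(d) != 4 || d[2] != model$input$fbins ||
      d[3] != model$input$frames || d[4] != model$input$ch)
    stop("spectrogram input must be N x ", model$input$fbins, " x ",
         model$input$frames, " x ", model$input$ch, ", got ",
         paste(d, collapse = " x "))
}

fuse_fwd <- function(fr, fs, op) {
  if (is.null(fs)) return(list(out = fr, which = "r"))
  if (is.null(fr)) return(list(out = fs, which = "s"))
  if (op == "concat") list(out = cbind(fr, fs), which = "both")
  else list(out = fr + fs, which = "both_add")
}

fuse_bwd <- function(d, which, nr) {
  switch(which,
         r = list(dr = d, ds = NULL),
         s = list(dr = NULL, ds = d),
         both = list(dr = d[, seq_len(nr), drop = FALSE],
                     ds = d[, -seq_len(nr), drop = FALSE]),
         both_add = list(dr = d, ds = d))
}

# ---- full network forward / backward ----------------------------------

# SSL network: pooled branches -> fusion -> per-task dense+sigmoid heads.
# Returns probabilities P (N x n_tasks); backward consumes dZ, the gradient
# w.r.t. the pre-sigmoid logits.
ssl_fwd <- function(model, x_r, x_s, train = FALSE) {
  cfg <- model$config; p <- model$params
  br <- branch_r_fwd(p, x_r, cfg, "pooled", train)
  bs <- branch_s_fwd(p, x_s, cfg, "pooled", train)
  fu <- fuse_fwd(br$out, bs$out, cfg$fusion_op)
  heads <- vector("list", cfg$n_tasks)
  P <- matrix(0, nrow(fu$out), cfg$n_tasks)
  for (t in seq_len(cfg$n_tasks)) {
    h1 <- dense_fwd(fu$out, p[[paste0("task", t, "_W1")]],
                    p[[paste0("task", t, "_b1")]])
    a1 <- relu_fwd(h1$out)
    h2 <- dense_fwd(a1$out, p[[paste0("task", t, "_W2")]],
                    p[[paste0("task", t, "_b2")]])
    P[, t] <- sigmoid(h2$out)
    heads[[t]] <- list(h1 = h1$cache, a1 = a1$cache, h2 = h2$cache)
  }
  list(out = P, cache = list(br = br$cache, bs = bs$cache, fu = fu,
                             heads = heads, nr = ncol(br$out)))
}

ssl_bwd <- function(model, cache, dZ) {
  cfg <- model$config
  grads <- list()
  dfu <- matrix(0, nrow(dZ), ncol(cache$fu$out))
  for (t in seq_len(cfg$n_tasks)) {
    hc <- cache$heads[[t]]
    b2 <- dense_bwd(hc$h2, dZ[, t, drop = FALSE])
    da <- relu_bwd(hc$a1, b2$dx)
    b1 <- dense_bwd(hc$h1, da)
    grads[[paste0("task", t, "_W1")]] <- b1$dW
    grads[[paste0("task", t, "_b1")]] <- b1$db
    grads[[paste0("task", t, "_W2")]] <- b2$dW
    grads[[paste0("task", t, "_b2")]] <- b2$db
    dfu <- dfu + b1$dx
  }
  sp <- fuse_bwd(dfu, cache$fu$which, cache$nr)
  gr <- branch_r_bwd(cache$br, sp$dr)
  gs <- branch_s_bwd(cache$bs, sp$ds)
  c(grads, gr$grads, gs$grads)
}

# Regression networks (all seven variants). Returns y_hat (N x 1); backward
# consumes dy (N x 1).
reg_fwd <- function(model, x_r, x_s, train = FALSE) {
  cfg <- model$config; p <- model$params
  use <- variant_uses(model$variant)
  br <- bs <- NULL; lr <- ls <- NULL; dr <- ds <- NULL
  fr <- fs <- NULL
  if (use$r) {
    br <- branch_r_fwd(p, x_r, cfg, if (use$lstm) "seq" else "pooled", train)
    fr <- br$out
    if (use$lstm) {
      dr <- dropout_fwd(br$out, cfg$lstm_dropout, train)
      lr <- lstm_fwd(dr$out, p$lstmR_Wx, p$lstmR_Wh, p$lstmR_b)
      fr <- lr$out
    }
  }
  if (use$s) {
    bs <- branch_s_fwd(p, x_s, cfg, if (use$lstm) "seq" else "pooled", train)
    fs <- bs$out
    if (use$lstm) {
      ds <- dropout_fwd(bs$out, cfg$lstm_dropout, train)
      ls <- lstm_fwd(ds$out, p$lstmS_Wx, p$lstmS_Wh, p$lstmS_b)
      fs <- ls$out
    }
  }
  fu <- fuse_fwd(fr, fs, cfg$fusion_op)
  f1 <- dense_fwd(fu$out, p$fusion_W, p$fusion_b)
  a1 <- relu_fwd(f1$out)
  o <- dense_fwd(a1$out, p$out_W, p$out_b)
  list(out = o$out,
       cache = list(br = if (use$r) br$cache, bs = if (use$s) bs$cache,
                    dr = if (use$r && use$lstm) dr$cache,
                    ds = if (use$s && use$lstm) ds$cache,
                    lr = if (use$r && use$lstm) lr$cache,
                    ls = if (use$s && use$lstm) ls$cache,
                    fu = fu, f1 = f1$cache, a1 = a1$cache, o = o$cache,
                    nr = if (!is.null(fr)) ncol(fr) else 0L, use = use))
}

reg_bwd <- function(model, cache, dy) {
  use <- cache$use
  grads <- list()
  bo <- dense_bwd(cache$o, dy)
  grads$out_W <- bo$dW; grads$out_b <- bo$db
  da <- relu_bwd(cache$a1, bo$dx)
  bf <- dense_bwd(cache$f1, da)
  grads$fusion_W <- bf$dW; grads$fusion_b <- bf$db
  sp <- fuse_bwd(bf$dx, cache$fu$which, cache$nr)
  if (use$r) {
    d <- sp$dr
    if (use$lstm) {
      lb <- lstm_bwd(cache$lr, d)
      grads$lstmR_Wx <- lb$dWx; grads$lstmR_Wh <- lb$dWh; grads$lstmR_b <- lb$db
      d <- dropout_bwd(cache$dr, lb$dx)
    }
    gr <- branch_r_bwd(cache$br, d)
    grads <- c(grads, gr$grads)
  }
  if (use$s) {
    d <- sp$ds
    if (use$lstm) {
      lb <- lstm_bwd(cache$ls, d)
      grads$lstmS_Wx <- lb$dWx; grads$lstmS_Wh <- lb$dWh; grads$lstmS_b <- lb$db
      d <- dropout_bwd(cache$ds, lb$dx)
    }
    gs <- branch_s_bwd(cache$bs, d)
    grads <- c(grads, gs$grads)
  }
  grads
}

net_fwd <- function(model, x_r, x_s, train = FALSE) {
  if (model$variant == "ssl") ssl_fwd(model, x_r, x_s, train)
  else reg_fwd(model, x_r, x_s, train)
}

net_bwd <- function(model, cache, dout) {
  if (model$variant == "ssl") ssl_bwd(model, cache, dout)
  else reg_bwd(model, cache, dout)
}

#' Pretext-task probabilities for a batch
#'
#' @param model an `mssl_model` built by [build_ssl_network()].
#' @param x_r,x_s normalized raw windows and spectrograms.
#' @return `N x n_tasks` matrix of per-task transformation probabilities.
#' @export
ssl_forward <- function(model, x_r, x_s) {
  stopifnot(model$variant == "ssl")
  ssl_fwd(model, x_r, x_s, train = FALSE)$out
}

#' UPDRS estimates for a batch of windows
#'
#' Inference-mode forward pass (dropout off); estimates are mapped back to
#' the clinical scale when the model was fine-tuned on standardized targets.
#'
#' @param model a fitted regression `mssl_model`.
#' @param x_r,x_s normalized raw windows and spectrograms (either may be
#'   ignored by single-input variants).
#' @param batch_size forward-pass batch size.
#' @return Numeric vector of per-window estimates.
#' @export
target_forward <- function(model, x_r, x_s, batch_size = 64L) {
  stopifnot(model$variant != "ssl")
  use <- variant_uses(model$variant)
  n <- if (use$r) dim(x_r)[1] else dim(x_s)[1]
  out <- numeric(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    out[b] <- reg_fwd(model,
                      if (use$r) x_r[b, , , drop = FALSE],
                      if (use$s) x_s[b, , , , drop = FALSE],
                      train = FALSE)$out
  }
  if (!is.null(model$target_scale))
    out <- out * model$target_scale$sd + model$target_scale$mu
  out
}

#' Transfer pretrained convolutional weights and freeze the first blocks
#'
#' Copies the convolutional-branch weights of a pretrained self-supervised
#' network into a target network and marks the first block of each branch as
#' frozen; frozen tensors are never updated by the optimizer during
#' fine-tuning, while second blocks remain trainable. LSTM, fusion and
#' output layers keep their fresh initialization.
#'
#' @param ssl_weights parameter list of a pretrained SSL network (or an
#'   `mssl_model`, whose `$params` are used).
#' @param target_model an `mssl_model` regression network.
#' @param freeze_blocks which convolutional blocks to freeze.
#' @return The target model with transferred weights and a `frozen` key set.
#' @export
transfer_and_freeze <- function(ssl_weights, target_model,
                                freeze_blocks = "b1") {
  if (inherits(ssl_weights, "mssl_model")) ssl_weights <- ssl_weights$params
  conv_keys <- grep("^conv[RS]_b[12]_", names(target_model$params),
                    value = TRUE)
  missing <- setdiff(conv_keys, names(ssl_weights))
  if (length(missing) > 0)
    stop("SSL bundle is missing convolutional key(s): ",
         paste(missing, collapse = ", "))
  for (k in conv_keys) {
    if (!identical(dim(target_model$params[[k]]), dim(ssl_weights[[k]])) &&
        length(target_model$params[[k]]) != length(ssl_weights[[k]]))
      stop("shape mismatch for transferred key ", k)
    target_model$params[[k]] <- ssl_weights[[k]]
  }
  target_model$frozen <- unlist(lapply(freeze_blocks, function(b)
    grep(paste0("^conv[RS]_", b, "_"), conv_keys, value = TRUE)))
  target_model
}

#' Total parameter count of a model
#' @param model an `mssl_model`.
#' @return Integer number of scalar parameters.
#' @export
param_count <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}
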