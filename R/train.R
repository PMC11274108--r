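#' Multi-shared-task self-supervised loss
#'
#' Weighted sum over pretext tasks of per-task binary cross-entropies:
#' `L = sum_t alpha_t * mean_n -[w_pos*y*log(P) + (1-y)*log(1-P)]`,
#' with probabilities clipped to `[eps, 1-eps]`. `w_pos` counteracts the 3:1
#' negative:positive imbalance each head sees when every window contributes
#' one original and three singly-transformed samples.
#'
#' @param y_p `N x T` binary pseudo-label matrix.
#' @param P `N x T` matrix of predicted probabilities.
#' @param config a [loss_config()].
#' @return Scalar loss.
#' @export
ssl_loss <- function(y_p, P, config = loss_config()) {
  if (!all(dim(y_p) == dim(P)))
    stop("y_p and P must have identical dimensions")
  eps <- config$prob_clip_eps
  Pc <- pmin(pmax(P, eps), 1 - eps)
  w <- config$positive_weight
  total <- 0
  for (t in seq_len(ncol(P))) {
    bce <- -(w * y_p[, t] * log(Pc[, t]) + (1 - y_p[, t]) * log(1 - Pc[, t]))
    total <- total + config$alphas[t] * mean(bce)
  }
  total
}

# Gradient of ssl_loss w.r.t. the pre-sigmoid logits (N x T).
ssl_loss_grad_z <- function(y_p, P, config) {
  n <- nrow(P)
  w <- config$positive_weight
  dZ <- matrix(0, n, ncol(P))
  for (t in seq_len(ncol(P)))
    dZ[, t] <- config$alphas[t] / n *
      (w * y_p[, t] * (P[, t] - 1) + (1 - y_p[, t]) * P[, t])
  dZ
}

#' Huber regression loss
#'
#' Quadratic for residuals within `delta`, linear beyond:
#' `0.5*r^2` if `|r| <= delta`, else `delta*(|r| - 0.5*delta)`; averaged over
#' the batch. Robust to outlying windows during fine-tuning.
#'
#' @param y,y_hat observed and estimated scores.
#' @param delta transition point between quadratic and linear behavior.
#' @return Scalar loss (batch mean).
#' @export
huber_loss <- function(y, y_hat, delta = 1) {
  r <- y - y_hat
  a <- abs(r)
  mean(ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta)))
}

# Gradient of huber_loss w.r.t. y_hat (length-N vector / batch mean).
huber_grad_yhat <- function(y, y_hat, delta = 1) {
  r <- y - y_hat
  -pmin(pmax(r, -delta), delta) / length(r)
}

# Subject-stratified validation split: within each subject, a val_fraction
# share of samples goes to validation, so both splits see every subject but
# no window is shared.
stratified_val_split <- function(subjects, val_fraction) {
  val <- integer(0)
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    k <- max(1L, round(length(idx) * val_fraction))
    if (length(idx) <= 1) next
    val <- c(val, sample(idx, min(k, length(idx) - 1L)))
  }
  if (length(val) == 0) val <- sample(seq_along(subjects), 1)
  sort(val)
}

slice_batch <- function(data, idx, use) {
  list(x_r = if (use$r) data$x_r[idx, , , drop = FALSE],
       x_s = if (use$s) data$x_s[idx, , , , drop = FALSE])
}

# Shared minibatch training engine for the SSL and regression objectives.
fit_network <- function(model, data, objective = c("ssl", "regression"),
                        tcfg = train_config(), lcfg = loss_config(),
                        verbose = FALSE) {
  objective <- match.arg(objective)
  use <- if (model$variant == "ssl") list(r = TRUE, s = TRUE, lstm = FALSE)
         else variant_uses(model$variant)
  set.seed(tcfg$seed)
  n <- length(data$subject)
  val_idx <- stratified_val_split(data$subject, tcfg$val_fraction)
  tr_idx <- setdiff(seq_len(n), val_idx)

  if (objective == "regression") {
    y <- data$y
    mu <- mean(y[tr_idx]); sdv <- max(stats::sd(y[tr_idx]), 1e-6)
    model$target_scale <- list(mu = mu, sd = sdv)
    ys <- (y - mu) / sdv
  }

  state <- adam_init(model$params)
  lr <- tcfg$learning_rate
  best_val <- Inf; best_params <- model$params
  bad <- 0L; lr_bad <- 0L
  hist <- list(train_loss = numeric(0), val_loss = numeric(0),
               val_metric = list(), lr = numeric(0), stop_epoch = NA_integer_)

  eval_split <- function(idx) {
    loss <- 0; m <- NULL; nb <- 0L
    P_all <- NULL; yhat_all <- NULL
    for (b in split(idx, ceiling(seq_along(idx) / tcfg$batch_size))) {
      xb <- slice_batch(data, b, use)
      fw <- net_fwd(model, xb$x_r, xb$x_s, train = FALSE)
      if (objective == "ssl") {
        loss <- loss + ssl_loss(data$y_p[b, , drop = FALSE], fw$out, lcfg) *
          length(b)
        P_all <- rbind(P_all, fw$out)
      } else {
        loss <- loss + huber_loss(ys[b], as.numeric(fw$out), lcfg$huber_delta) *
          length(b)
        yhat_all <- c(yhat_all, as.numeric(fw$out))
      }
    }
    if (objective == "ssl") {
      acc <- vapply(seq_len(ncol(P_all)), function(t)
        mean((P_all[, t] > 0.5) == (data$y_p[idx, t] == 1)), numeric(1))
      list(loss = loss / length(idx), metric = acc)
    } else {
      mae <- mean(abs(y[idx] - (yhat_all * sdv + mu)))
      list(loss = loss / length(idx), metric = mae)
    }
  }

  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample(tr_idx)
    tl <- 0
    for (b in split(ord, ceiling(seq_along(ord) / tcfg$batch_size))) {
      xb <- slice_batch(data, b, use)
      fw <- net_fwd(model, xb$x_r, xb$x_s, train = TRUE)
      if (objective == "ssl") {
        yb <- data$y_p[b, , drop = FALSE]
        tl <- tl + ssl_loss(yb, fw$out, lcfg) * length(b)
        dout <- ssl_loss_grad_z(yb, fw$out, lcfg)
      } else {
        yhat <- as.numeric(fw$out)
        tl <- tl + huber_loss(ys[b], yhat, lcfg$huber_delta) * length(b)
        dout <- matrix(huber_grad_yhat(ys[b], yhat, lcfg$huber_delta), ncol = 1)
      }
      grads <- net_bwd(model, fw$cache, dout)
      upd <- adam_step(model$params, grads, state, lr, model$frozen)
      model$params <- upd$params; state <- upd$state
    }
    vs <- eval_split(val_idx)
    hist$train_loss <- c(hist$train_loss, tl / length(tr_idx))
    hist$val_loss <- c(hist$val_loss, vs$loss)
    hist$val_metric[[epoch]] <- vs$metric
    hist$lr <- c(hist$lr, lr)
    if (verbose)
      message(sprintf("epoch %d train %.4f val %.4f lr %.2g", epoch,
                      utils::tail(hist$train_loss, 1), vs$loss, lr))
    if (vs$loss < best_val - 1e-6) {
      best_val <- vs$loss; best_params <- model$params
      bad <- 0L; lr_bad <- 0L
    } else {
      bad <- bad + 1L; lr_bad <- lr_bad + 1L
      if (lr_bad >= tcfg$lr_patience) {
        lr <- max(lr * tcfg$lr_factor, tcfg$lr_min)
        lr_bad <- 0L
      }
      if (bad >= tcfg$early_stop_patience) {
        hist$stop_epoch <- epoch
        break
      }
    }
  }
  if (is.na(hist$stop_epoch)) hist$stop_epoch <- length(hist$train_loss)
  model$params <- best_params
  list(model = model, history = hist)
}

#' Pretrain the self-supervised network on pretext tasks
#'
#' Minimizes the multi-shared-task loss with Adam over the transformation
#' recognition dataset, using a subject-stratified 20% validation split,
#' early stopping on validation loss and reduce-on-plateau learning-rate
#' scheduling; the best-validation weights are returned.
#'
#' @param ssl_dataset an `ssl_dataset` from [build_ssl_dataset()]
#'   (normalized).
#' @param net_config a [network_config()].
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @param input input shape list (see [build_model()]).
#' @return List with `weights` (named parameter tensors of the best epoch),
#'   `history` (a train history) and `model` (the fitted SSL network).
#' @export
pretrain <- function(ssl_dataset, net_config = network_config(),
                     tcfg = train_config(), lcfg = loss_config(),
                     input = list(len = 320L, ch = 6L, fbins = 33L,
                                  frames = 43L)) {
  if (length(ssl_dataset$t) == 0) stop("empty SSL dataset")
  for (t in seq_len(ncol(ssl_dataset$y_p)))
    if (length(unique(ssl_dataset$y_p[, t])) < 2)
      stop("pretext task ", t, " has a single class; cannot pretrain")
  model <- build_ssl_network(net_config, input, seed = tcfg$seed)
  fit <- fit_network(model, ssl_dataset, "ssl", tcfg, lcfg)
  list(weights = fit$model$params, history = fit$history, model = fit$model)
}

#' Fine-tune (or train) a regression network on labelled windows
#'
#' Minimizes the Huber loss with Adam under the same epoch/batch/early-stop
#' regime as pretraining. Every window's target is its round's clinical
#' score; targets are standardized internally on the training split (Huber
#' `delta` then acts on the standardized residual) and estimates are mapped
#' back to the clinical scale at prediction time. Frozen tensors (after
#' [transfer_and_freeze()]) are never updated.
#'
#' @param model an `mssl_model` regression network (optionally transferred
#'   and frozen).
#' @param ws a normalized `window_set` whose `meta$updrs` provides labels.
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @return List with `model` (fitted), `weights` and `history`.
#' @export
finetune <- function(model, ws, tcfg = train_config(), lcfg = loss_config()) {
  y <- ws$meta$updrs
  keep <- !is.na(y)
  if (!any(keep)) stop("no labelled rounds to fine-tune on")
  data <- list(x_r = ws$x_r[keep, , , drop = FALSE],
               x_s = ws$x_s[keep, , , , drop = FALSE],
               y = as.numeric(y[keep]), subject = ws$meta$subject[keep])
  fit <- fit_network(model, data, "regression", tcfg, lcfg)
  list(model = fit$model, weights = fit$model$params, history = fit$history)
}

#' Per-window estimates for a window set
#' @param model a fitted regression `mssl_model`.
#' @param ws a normalized `window_set`.
#' @return Numeric vector of per-window estimates on the clinical scale.
#' @export
predict_window_set <- function(model, ws) {
  target_forward(model, ws$x_r, ws$x_s)
}
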