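#' Training configuration
#'
#' The training regime shared by all model variants: AdamW, mini-batches of
#' 8, up to 20 epochs, early stopping with patience 3, base learning rate
#' 5e-4 under a linear warmup/decay schedule. The four mode tags bind the
#' published per-mode settings -- warmup ratio SMSTL 0.3, MMSTL 0.35, SMMTL
#' 0.35, MMMTL 0.25; dropout SMSTL 0.2, all others 0.1 (SM = single
#' modality, MM = multimodal; STL/MTL = single-/multitask learning).
#' Explicit arguments override the mode defaults.
#'
#' @param mode Optional tag in `SMSTL`, `MMSTL`, `SMMTL`, `MMMTL` selecting
#'   default warmup ratio and dropout.
#' @param epochs,patience,batch_size,learning_rate,weight_decay Training
#'   regime; weight decay is decoupled (AdamW) and applied to weight
#'   matrices only.
#' @param warmup_ratio Fraction of total optimizer steps spent ramping the
#'   learning rate linearly from 0 to its base value.
#' @param dropout Dropout probability after each encoder activation.
#' @param validation_fraction Fraction of the training portion carved out
#'   (stratified by the joint labels) as the early-stopping validation set.
#' @param seed Integer seed covering initialization, batch order and
#'   dropout; identical seeds give bitwise-identical runs.
#' @return A `psymtl_train_config`.
#' @export
train_config <- function(mode = NULL, epochs = 20L, patience = 3L,
                         batch_size = 8L, learning_rate = 5e-4,
                         warmup_ratio = NULL, dropout = NULL,
                         weight_decay = 0.01, validation_fraction = 1 / 9,
                         seed = 1L) {
  defaults <- list(SMSTL = c(warmup = 0.30, dropout = 0.2),
                   MMSTL = c(warmup = 0.35, dropout = 0.1),
                   SMMTL = c(warmup = 0.35, dropout = 0.1),
                   MMMTL = c(warmup = 0.25, dropout = 0.1))
  if (!is.null(mode)) {
    mode <- match.arg(mode, names(defaults))
    if (is.null(warmup_ratio)) warmup_ratio <- defaults[[mode]][["warmup"]]
    if (is.null(dropout)) dropout <- defaults[[mode]][["dropout"]]
  }
  if (is.null(warmup_ratio)) warmup_ratio <- 0.3
  if (is.null(dropout)) dropout <- 0.1
  stopifnot(epochs >= 1, patience >= 1, batch_size >= 1, learning_rate >= 0,
            warmup_ratio > 0, warmup_ratio < 1, dropout >= 0, dropout < 1,
            weight_decay >= 0, validation_fraction > 0,
            validation_fraction < 1)
  structure(list(mode = mode, epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, warmup_ratio = warmup_ratio,
                 dropout = dropout, weight_decay = weight_decay,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "psymtl_train_config")
}

#' Linear warmup / linear decay learning-rate multiplier
#'
#' Ramps linearly from 0 at step 0 to 1 at `warmup_ratio * total_steps`,
#' then decays linearly back to 0 at `total_steps`. The schedule is defined
#' over the total planned optimizer steps of a run
#' (`ceiling(n_train / batch_size) * epochs`).
#'
#' @param step Current optimizer step, 0-based, in \[0, total_steps\].
#' @param total_steps Total planned steps (> 0).
#' @param warmup_ratio Warmup fraction in (0, 1).
#' @return Multiplier in \[0, 1\].
#' @export
lr_multiplier <- function(step, total_steps, warmup_ratio) {
  if (total_steps <= 0) stop("total_steps must be positive", call. = FALSE)
  stopifnot(warmup_ratio > 0, warmup_ratio < 1, step >= 0, step <= total_steps)
  warm <- warmup_ratio * total_steps
  ifelse(step <= warm, step / warm, (total_steps - step) / (total_steps - warm))
}

#' Early-stopping bookkeeping over a validation-loss trace
#'
#' Patience-based rule: training stops after `patience` consecutive epochs
#' without strict improvement over the best validation loss seen so far;
#' the parameters returned by the trainers are always those of the best
#' epoch.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return List with `stop_epoch`, `best_epoch`, and `reason`
#'   (`"early_stopped"` or `"completed"`).
#' @export
early_stop_trace <- function(val_losses, patience) {
  best <- Inf; best_epoch <- 0L; stall <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience)
        return(list(stop_epoch = e, best_epoch = best_epoch,
                    reason = "early_stopped"))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch,
       reason = "completed")
}

# ---- AdamW ------------------------------------------------------------

adam_zero_like <- function(x) {
  if (is.list(x)) lapply(x, adam_zero_like) else x * 0
}

# one decoupled-weight-decay Adam update on a single tensor
adamw_update <- function(p, g, m, v, lr, t, wd,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
  list(p = p, m = m, v = v)
}

# ---- trainer ----------------------------------------------------------

# stratified index split: carve a validation fraction out of 1..n by strata
stratified_holdout <- function(strata, fraction) {
  val <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    k <- max(1L, round(length(idx) * fraction))
    if (k >= length(idx)) k <- length(idx) - 1L
    if (k > 0) val <- c(val, sample(idx, k))
  }
  sort(val)
}

joint_strata <- function(yd, ys) paste(yd, ys, sep = "/")

#' Train a single-task model
#'
#' Trains the shared-encoder architecture with one task head against the
#' task's cross-entropy. A stratified `validation_fraction` of the supplied
#' data is held out to monitor total validation loss for early stopping;
#' the returned parameters are those of the best validation epoch. The run
#' is deterministic given `cfg$seed`.
#'
#' @param dataset A [psymtl_dataset()].
#' @param task `"ds"` or `"sr"`; must match `spec$task`.
#' @param spec A [model_spec()] with task mode `stl_ds` or `stl_sr`.
#' @param cfg A [train_config()].
#' @return A `psymtl_fit`: list with the trained `net`, a `history` data
#'   frame (per-epoch train/validation losses, validation accuracies, task
#'   variances for multitask runs), `stop_epoch`, `best_epoch`, `reason`.
#' @export
train_stl <- function(dataset, task = c("ds", "sr"), spec, cfg) {
  task <- match.arg(task)
  if (spec$task != paste0("stl_", task))
    stop(sprintf("spec task mode '%s' does not match task '%s'",
                 spec$task, task), call. = FALSE)
  train_network(dataset, spec, cfg)
}

#' Train the multitask model
#'
#' Trains the shared encoder and both task heads jointly against the
#' uncertainty-weighted composite loss; the two log-variances are
#' optimized by the same AdamW steps as the network weights (no weight
#' decay on them) and their per-epoch trajectory is recorded in the
#' history.
#'
#' @inheritParams train_stl
#' @param spec A [model_spec()] with task mode `mtl`.
#' @return A `psymtl_fit`; `fit$uncertainty` holds the final
#'   [uncertainty_params()].
#' @export
train_mtl <- function(dataset, spec, cfg) {
  if (spec$task != "mtl")
    stop("spec task mode must be 'mtl'", call. = FALSE)
  train_network(dataset, spec, cfg)
}

train_network <- function(dataset, spec, cfg) {
  stopifnot(inherits(dataset, "psymtl_dataset"),
            inherits(spec, "psymtl_model_spec"),
            inherits(cfg, "psymtl_train_config"))
  tasks <- spec_tasks(spec)
  X <- model_matrix(dataset, spec$modality)
  yd <- as.integer(ds_labels(dataset))
  ys <- as.integer(sr_labels(dataset))
  for (tk in tasks) {
    y <- if (tk == "ds") yd else ys
    if (length(unique(y)) < n_classes(tk))
      stop(sprintf("stratification error: task '%s' is missing a class in the training data", tk),
           call. = FALSE)
  }
  with_seed(cfg$seed, {
    strat <- switch(spec$task, mtl = joint_strata(yd, ys), stl_ds = yd,
                    stl_sr = ys)
    val_idx <- stratified_holdout(strat, cfg$validation_fraction)
    tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
    for (tk in tasks) {
      y <- if (tk == "ds") yd else ys
      if (length(unique(y[tr_idx])) < n_classes(tk))
        stop(sprintf("stratification error: task '%s' lost a class to the validation split", tk),
             call. = FALSE)
    }
    net <- init_model(spec, ncol(X))
    n_tr <- length(tr_idx)
    steps_per_epoch <- ceiling(n_tr / cfg$batch_size)
    total_steps <- steps_per_epoch * cfg$epochs
    m_state <- list(layers = adam_zero_like(net$layers),
                    heads = adam_zero_like(net$heads),
                    s = if (!is.null(net$s)) net$s * 0)
    v_state <- m_state
    step <- 0L
    best <- list(loss = Inf, net = net, epoch = 0L)
    hist <- list()
    stall <- 0L; stop_epoch <- cfg$epochs; reason <- "completed"
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample(tr_idx)
      batch_losses <- numeric(0)
      for (b in seq_len(steps_per_epoch)) {
        bi <- perm[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, n_tr)]
        lr <- cfg$learning_rate * lr_multiplier(step, total_steps,
                                                cfg$warmup_ratio)
        step <- step + 1L
        upd <- train_step(net, X[bi, , drop = FALSE], yd[bi], ys[bi],
                          lr, step, cfg, m_state, v_state)
        net <- upd$net
        m_state <- upd$m_state
        v_state <- upd$v_state
        batch_losses <- c(batch_losses, upd$loss)
      }
      ev <- evaluate_split(net, X[val_idx, , drop = FALSE], yd[val_idx],
                           ys[val_idx])
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = mean(batch_losses), val_loss = ev$loss,
        val_acc_ds = ev$acc["ds"] %|NA|% NA_real_,
        val_acc_sr = ev$acc["sr"] %|NA|% NA_real_,
        sigma2_ds = if (!is.null(net$s)) exp(net$s[["ds"]]) else NA_real_,
        sigma2_sr = if (!is.null(net$s)) exp(net$s[["sr"]]) else NA_real_)
      if (ev$loss < best$loss) {
        best <- list(loss = ev$loss, net = net, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) {
          stop_epoch <- epoch; reason <- "early_stopped"
          break
        }
      }
      stop_epoch <- epoch
    }
    history <- do.call(rbind, hist)
    fit <- structure(list(net = best$net, history = history,
                          stop_epoch = stop_epoch, best_epoch = best$epoch,
                          reason = reason, cfg = cfg,
                          val_idx = val_idx),
                     class = "psymtl_fit")
    if (spec$task == "mtl")
      fit$uncertainty <- uncertainty_params(best$net$s[["ds"]],
                                            best$net$s[["sr"]])
    fit
  })
}

`%|NA|%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else unname(a)

# one mini-batch forward/backward/AdamW step; pure in (net, optimizer
# state), returns the updated copies.
train_step <- function(net, Xb, ydb, ysb, lr, t, cfg, m_state, v_state) {
  fw <- net_forward(net, Xb, training = TRUE, dropout = cfg$dropout)
  B <- nrow(Xb)
  dlogits <- list()
  if (net$spec$task == "mtl") {
    L_d <- ce_mean(fw$probs$ds, ydb)
    L_s <- ce_mean(fw$probs$sr, ysb)
    w_d <- exp(-net$s[["ds"]]) / 2
    w_s <- exp(-net$s[["sr"]]) / 2
    loss <- auto_weighted_total(L_d, L_s,
                                uncertainty_params(net$s[["ds"]], net$s[["sr"]]))
    dlogits$ds <- w_d * (fw$probs$ds - onehot(ydb, 3L)) / B
    dlogits$sr <- w_s * (fw$probs$sr - onehot(ysb, 2L)) / B
    gs <- c(ds = -w_d * L_d + 1, sr = -w_s * L_s + 1)
  } else {
    tk <- spec_tasks(net$spec)
    y <- if (tk == "ds") ydb else ysb
    loss <- ce_mean(fw$probs[[tk]], y)
    dlogits[[tk]] <- (fw$probs[[tk]] - onehot(y, n_classes(tk))) / B
    gs <- NULL
  }
  gr <- net_backward(net, fw, dlogits)
  # parameter updates (weight decay on weight matrices only)
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      if (is.null(gr$layers[[l]][[nm]])) next
      wd <- if (nm == "W") cfg$weight_decay else 0
      u <- adamw_update(net$layers[[l]][[nm]], gr$layers[[l]][[nm]],
                        m_state$layers[[l]][[nm]], v_state$layers[[l]][[nm]],
                        lr, t, wd)
      net$layers[[l]][[nm]] <- u$p
      m_state$layers[[l]][[nm]] <- u$m
      v_state$layers[[l]][[nm]] <- u$v
    }
    # running batch-norm statistics (momentum 0.1, unbiased variance)
    if (net$spec$batch_norm) {
      bs <- fw$batch_stats[[l]]
      vv <- if (bs$B > 1) bs$var * bs$B / (bs$B - 1) else bs$var
      net$layers[[l]]$run_mean <- 0.9 * net$layers[[l]]$run_mean + 0.1 * bs$mean
      net$layers[[l]]$run_var <- 0.9 * net$layers[[l]]$run_var + 0.1 * vv
    }
  }
  for (k in names(net$heads)) {
    for (nm in c("W", "b")) {
      wd <- if (nm == "W") cfg$weight_decay else 0
      u <- adamw_update(net$heads[[k]][[nm]], gr$heads[[k]][[nm]],
                        m_state$heads[[k]][[nm]], v_state$heads[[k]][[nm]],
                        lr, t, wd)
      net$heads[[k]][[nm]] <- u$p
      m_state$heads[[k]][[nm]] <- u$m
      v_state$heads[[k]][[nm]] <- u$v
    }
  }
  if (!is.null(gs)) {
    u <- adamw_update(net$s, gs, m_state$s, v_state$s, lr, t, wd = 0)
    net$s <- u$p
    m_state$s <- u$m
    v_state$s <- u$v
  }
  list(net = net, loss = loss, m_state = m_state, v_state = v_state)
}

onehot <- function(y, C) {
  M <- matrix(0, length(y), C)
  M[cbind(seq_along(y), y)] <- 1
  M
}

# evaluation-mode loss/accuracy on a held-out split
evaluate_split <- function(net, Xv, ydv, ysv) {
  probs <- net_forward(net, Xv, training = FALSE)$probs
  acc <- c(ds = NA_real_, sr = NA_real_)
  if (net$spec$task == "mtl") {
    L_d <- ce_mean(probs$ds, ydv)
    L_s <- ce_mean(probs$sr, ysv)
    loss <- auto_weighted_total(L_d, L_s,
                                uncertainty_params(net$s[["ds"]], net$s[["sr"]]))
    acc["ds"] <- mean(max.col(probs$ds) == ydv)
    acc["sr"] <- mean(max.col(probs$sr) == ysv)
  } else {
    tk <- spec_tasks(net$spec)
    y <- if (tk == "ds") ydv else ysv
    loss <- ce_mean(probs[[tk]], y)
    acc[tk] <- mean(max.col(probs[[tk]]) == y)
  }
  list(loss = loss, acc = acc)
}

#' @export
print.psymtl_fit <- function(x, ...) {
  cat(sprintf("psymtl_fit: %s/%s, stopped at epoch %d (%s), best epoch %d\n",
              x$net$spec$modality, x$net$spec$task, x$stop_epoch, x$reason,
              x$best_epoch))
  invisible(x)
}
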