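#' Early fusion of audio and text embeddings
#'
#' Feature-level fusion by concatenation: the fused vector carries the
#' audio coordinates first, then the text coordinates, both in their
#' original order. Concatenation is injective for fixed dimensions and
#' avoids the information cancellation that sums or products can cause.
#'
#' @param xa Finite numeric audio embedding.
#' @param xt Finite numeric text embedding.
#' @return Numeric vector of length `length(xa) + length(xt)`.
#' @examples
#' fuse(c(1, 2), 3)  # c(1, 2, 3)
#' @export
fuse <- function(xa, xt) {
  if (!all(is.finite(xa)) || !all(is.finite(xt)))
    stop("embeddings must be finite", call. = FALSE)
  c(as.numeric(xa), as.numeric(xt))
}

#' Architecture specification for the shared-encoder network
#'
#' The network is a fully connected encoder shared by all tasks (hard
#' parameter sharing) followed by one linear softmax head per task. Every
#' non-classifier linear layer is followed by batch normalization and a
#' rectified linear activation; dropout (probability set at training time)
#' is applied after each encoder activation. Single-task variants use the
#' identical encoder with one head, so single- vs multitask differences
#' are attributable to the training objective alone.
#'
#' @param modality `"fused"` (audio then text, concatenated),
#'   `"audio_only"`, or `"text_only"`.
#' @param task `"mtl"` (both heads), `"stl_ds"` (3-class severity head), or
#'   `"stl_sr"` (binary risk head).
#' @param hidden Strictly decreasing positive integer widths of the encoder
#'   layers; the last entry is the shared representation width H.
#' @param batch_norm Apply batch normalization to encoder layers.
#' @return A `psymtl_model_spec`.
#' @export
model_spec <- function(modality = c("fused", "audio_only", "text_only"),
                       task = c("mtl", "stl_ds", "stl_sr"),
                       hidden = c(256L, 64L), batch_norm = TRUE) {
  modality <- match.arg(modality)
  task <- match.arg(task)
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || any(hidden <= 0))
    stop("hidden widths must be positive integers", call. = FALSE)
  if (length(hidden) > 1 && any(diff(hidden) >= 0))
    stop("hidden widths must be strictly decreasing", call. = FALSE)
  structure(list(modality = modality, task = task, hidden = hidden,
                 batch_norm = isTRUE(batch_norm)),
            class = "psymtl_model_spec")
}

spec_tasks <- function(spec) {
  switch(spec$task, mtl = c("ds", "sr"), stl_ds = "ds", stl_sr = "sr")
}

n_classes <- function(task) if (task == "ds") 3L else 2L

# design matrix for a dataset under a modality mode
model_matrix <- function(dataset, modality) {
  switch(modality,
         audio_only = dataset$audio,
         text_only = dataset$text,
         fused = cbind(dataset$audio, dataset$text))
}

#' Initialize network parameters
#'
#' Seeded uniform fan-in initialization (`U(-1/sqrt(fan_in),
#' 1/sqrt(fan_in))`) for all weights and biases; batch-norm scale/shift
#' start at 1/0 with running statistics 0/1; multitask log-variances start
#' at 0. If `seed` is `NULL`, draws come from the current RNG stream
#' (used by the trainer, which seeds the whole run once).
#'
#' @param spec A [model_spec()].
#' @param input_dim Width of the (fused) input; must exceed the first
#'   hidden width.
#' @param seed Optional integer seed.
#' @return A `psymtl_network`.
#' @export
init_model <- function(spec, input_dim, seed = NULL) {
  stopifnot(inherits(spec, "psymtl_model_spec"))
  if (input_dim <= spec$hidden[1])
    stop(sprintf("input width (%d) must exceed the first encoder width (%d)",
                 input_dim, spec$hidden[1]), call. = FALSE)
  build <- function() {
    dims <- c(input_dim, spec$hidden)
    layers <- lapply(seq_along(spec$hidden), function(l) {
      d_in <- dims[l]; d_out <- dims[l + 1]
      bound <- 1 / sqrt(d_in)
      list(W = matrix(stats::runif(d_in * d_out, -bound, bound), d_in, d_out),
           b = stats::runif(d_out, -bound, bound),
           gamma = rep(1, d_out), beta = rep(0, d_out),
           run_mean = rep(0, d_out), run_var = rep(1, d_out))
    })
    H <- spec$hidden[length(spec$hidden)]
    heads <- lapply(stats::setNames(nm = spec_tasks(spec)), function(task) {
      C <- n_classes(task)
      bound <- 1 / sqrt(H)
      list(W = matrix(stats::runif(H * C, -bound, bound), H, C),
           b = stats::runif(C, -bound, bound))
    })
    s <- if (spec$task == "mtl") c(ds = 0, sr = 0) else NULL
    structure(list(spec = spec, input_dim = as.integer(input_dim),
                   layers = layers, heads = heads, s = s),
              class = "psymtl_network")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @export
print.psymtl_network <- function(x, ...) {
  cat(sprintf("psymtl_network: %s/%s, %d -> %s -> heads [%s]\n",
              x$spec$modality, x$spec$task, x$input_dim,
              paste(x$spec$hidden, collapse = " -> "),
              paste(names(x$heads), collapse = ", ")))
  invisible(x)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass. In training mode batch statistics are used for batch norm
# and dropout masks are drawn from the current RNG stream; in evaluation
# mode running statistics are used and dropout is off, so inference is
# deterministic. Returns probabilities plus the caches backprop needs.
net_forward <- function(net, X, training = FALSE, dropout = 0) {
  bn_eps <- 1e-5
  A <- X
  caches <- vector("list", length(net$layers))
  batch_stats <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- sweep(A %*% ly$W, 2, ly$b, "+")
    if (net$spec$batch_norm) {
      if (training) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
        batch_stats[[l]] <- list(mean = mu, var = v, B = nrow(Z))
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      invstd <- 1 / sqrt(v + bn_eps)
      Xhat <- sweep(sweep(Z, 2, mu), 2, invstd, "*")
      Y <- sweep(sweep(Xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    } else {
      invstd <- NULL; Xhat <- NULL
      Y <- Z
    }
    Aout <- Y * (Y > 0)
    mask <- NULL
    if (training && dropout > 0) {
      keep <- 1 - dropout
      mask <- matrix(stats::rbinom(length(Aout), 1L, keep),
                     nrow(Aout)) / keep
      Aout <- Aout * mask
    }
    caches[[l]] <- list(A_in = A, Xhat = Xhat, invstd = invstd, Y = Y,
                        mask = mask)
    A <- Aout
  }
  logits <- lapply(net$heads, function(h) sweep(A %*% h$W, 2, h$b, "+"))
  list(probs = lapply(logits, softmax_rows), logits = logits, H = A,
       caches = caches, batch_stats = batch_stats)
}

# Backward pass: dlogits is a named list (subset of heads) of gradients of
# the scalar loss w.r.t. each head's logits. Returns gradients matching the
# network's parameter structure.
net_backward <- function(net, fw, dlogits) {
  gheads <- lapply(stats::setNames(nm = names(net$heads)), function(k) {
    if (is.null(dlogits[[k]])) {
      list(W = matrix(0, nrow(net$heads[[k]]$W), ncol(net$heads[[k]]$W)),
           b = rep(0, length(net$heads[[k]]$b)))
    } else {
      list(W = crossprod(fw$H, dlogits[[k]]), b = colSums(dlogits[[k]]))
    }
  })
  dA <- 0
  for (k in names(dlogits)) dA <- dA + dlogits[[k]] %*% t(net$heads[[k]]$W)
  glayers <- vector("list", length(net$layers))
  for (l in rev(seq_along(net$layers))) {
    cc <- fw$caches[[l]]
    if (!is.null(cc$mask)) dA <- dA * cc$mask
    dY <- dA * (cc$Y > 0)
    if (net$spec$batch_norm) {
      dgamma <- colSums(dY * cc$Xhat)
      dbeta <- colSums(dY)
      dXhat <- sweep(dY, 2, net$layers[[l]]$gamma, "*")
      B <- nrow(dY)
      dZ <- sweep(B * dXhat -
                    matrix(colSums(dXhat), B, ncol(dY), byrow = TRUE) -
                    sweep(cc$Xhat, 2, colSums(dXhat * cc$Xhat), "*"),
                  2, cc$invstd / B, "*")
    } else {
      dgamma <- NULL; dbeta <- NULL
      dZ <- dY
    }
    glayers[[l]] <- list(W = crossprod(cc$A_in, dZ), b = colSums(dZ),
                         gamma = dgamma, beta = dbeta)
    dA <- tcrossprod(dZ, net$layers[[l]]$W)
  }
  list(layers = glayers, heads = gheads)
}

#' Deterministic inference forward pass
#'
#' Evaluation-mode forward pass: dropout off, batch normalization using the
#' stored running statistics. Two calls on identical input agree bitwise.
#'
#' @param net A `psymtl_network` (from [init_model()] or a trainer).
#' @param X Numeric matrix (or single vector) whose width matches the
#'   network's input width under its modality mode.
#' @return Named list with one row-stochastic probability matrix per task
#'   head (`ds`: n x 3, `sr`: n x 2).
#' @export
model_forward <- function(net, X) {
  stopifnot(inherits(net, "psymtl_network"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$input_dim)
    stop(sprintf("input width %d does not match network input width %d",
                 ncol(X), net$input_dim), call. = FALSE)
  if (!all(is.finite(X))) stop("input contains non-finite values", call. = FALSE)
  net_forward(net, X, training = FALSE)$probs
}

#' Predict task probabilities for a dataset
#'
#' @param object A trained `psymtl_fit` (see [train_stl()], [train_mtl()]).
#' @param dataset A [psymtl_dataset()].
#' @param ... Unused.
#' @return Named list of probability matrices, one per task head.
#' @export
predict.psymtl_fit <- function(object, dataset, ...) {
  model_forward(object$net, model_matrix(dataset, object$net$spec$modality))
}
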