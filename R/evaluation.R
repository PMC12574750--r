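#' Confusion-matrix metrics
#'
#' Computes accuracy, recall, precision, specificity and F1 from predicted
#' and true labels. In `binary` mode the metrics are computed against the
#' positive class (for the risk task, `moderate_high`); in `macro` mode
#' each metric is the unweighted mean of its one-vs-rest value over the
#' classes (accuracy remains overall agreement). F1 is 0 by convention
#' when precision + recall = 0; precision (or specificity) is 0 when its
#' denominator is 0.
#'
#' @param y_true,y_pred Equal-length label vectors (factors or values
#'   coercible to a common factor).
#' @param mode `"binary"` or `"macro"`.
#' @param positive For binary mode, the positive level; defaults to the
#'   last level of `y_true`.
#' @return Named list: `accuracy`, `recall`, `precision`, `specificity`,
#'   `f1`, plus the `mode`.
#' @export
confusion_metrics <- function(y_true, y_pred, mode = c("binary", "macro"),
                              positive = NULL) {
  mode <- match.arg(mode)
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  lev <- if (is.factor(y_true)) levels(y_true) else sort(unique(c(y_true, y_pred)))
  y_true <- factor(y_true, levels = lev)
  y_pred <- factor(y_pred, levels = lev)
  if (anyNA(y_pred)) stop("y_pred contains labels outside the class set",
                          call. = FALSE)
  acc <- mean(y_true == y_pred)
  ovr <- function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(recall = rec, precision = prec, specificity = spec, f1 = f1)
  }
  if (mode == "binary") {
    if (length(lev) != 2) stop("binary mode requires exactly two classes",
                               call. = FALSE)
    if (is.null(positive)) positive <- lev[2]
    m <- ovr(positive)
  } else {
    m <- rowMeans(vapply(lev, ovr, numeric(4)))
  }
  list(accuracy = acc, recall = unname(m["recall"]),
       precision = unname(m["precision"]),
       specificity = unname(m["specificity"]), f1 = unname(m["f1"]),
       mode = mode)
}

#' Binary AUC (Mann--Whitney, midrank ties)
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, ties counted one half -- computed from midranks, which
#' is exactly equivalent to brute-force pair counting.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary labels (0/1, logical, or a two-level factor whose
#'   second level is positive).
#' @return AUC in \[0, 1\].
#' @export
auc_binary <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined metric: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Macro-averaged one-vs-rest multiclass AUC
#'
#' Unweighted mean of the per-class one-vs-rest binary AUCs, each using
#' that class's predicted-probability column as the score. All classes
#' must be present in `labels`.
#'
#' @param prob_matrix n x C matrix of row-stochastic class probabilities.
#' @param labels Length-n labels in `1..C` (or a factor with C levels).
#' @return Macro AUC in \[0, 1\].
#' @export
auc_macro_ovr <- function(prob_matrix, labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  C <- ncol(prob_matrix)
  if (length(labels) != nrow(prob_matrix))
    stop("labels must match prob_matrix rows", call. = FALSE)
  present <- sort(unique(labels))
  if (!setequal(present, seq_len(C)))
    stop("undefined metric: all ", C, " classes must be present",
         call. = FALSE)
  mean(vapply(seq_len(C), function(cl) {
    auc_binary(prob_matrix[, cl], as.integer(labels == cl))
  }, numeric(1)))
}

#' Stratified fold assignment
#'
#' Partitions `1..n` into `k` folds whose sizes differ by at most one.
#' Stratification is by the joint (severity, risk) label so both tasks see
#' every class in every fold where possible; if some joint stratum has
#' fewer members than `k` the assignment falls back to severity-only
#' stratification, then to an unstratified shuffle, warning at each
#' degradation.
#'
#' @param ds Severity labels (any vector).
#' @param sr Risk labels, or `NULL` for severity-only stratification.
#' @param k Number of folds.
#' @param seed Integer seed; identical seeds reproduce the assignment.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(ds, sr = NULL, k = 10L, seed = 1L) {
  n <- length(ds)
  if (k > n) stop("k must not exceed the number of subjects", call. = FALSE)
  strata <- if (is.null(sr)) as.character(ds) else joint_strata(ds, sr)
  if (!is.null(sr) && min(table(strata)) < k) {
    warning("a joint stratum has fewer members than k; falling back to severity-only stratification",
            call. = FALSE)
    strata <- as.character(ds)
  }
  if (min(table(strata)) < k && length(unique(strata)) > 1) {
    warning("a stratum has fewer members than k; falling back to unstratified folds",
            call. = FALSE)
    strata <- rep("all", n)
  }
  with_seed(seed, {
    fold <- integer(n)
    cursor <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
      cursor <- cursor + length(idx)
    }
    fold
  })
}

#' k-fold cross-validation of a model configuration
#'
#' Stratified k-fold evaluation: for each fold, the model is trained from
#' scratch on the other k-1 folds (with its own internal validation split
#' for early stopping -- no test subject ever influences training) and
#' evaluated on the held-out fold. Severity metrics are macro-averaged over
#' the three classes with macro one-vs-rest AUC; risk metrics use the
#' positive class (`moderate_high`) with binary AUC. Per-fold training
#' seeds are derived deterministically from `(cfg$seed, fold)`.
#'
#' @param dataset A [psymtl_dataset()].
#' @param spec A [model_spec()].
#' @param cfg A [train_config()].
#' @param k Number of folds (default 10).
#' @return A `psymtl_cv`: `folds` (per-fold, per-task metric rows), `means`
#'   (per-task arithmetic means over folds), `assignment`
#'   (subject_id -> fold), `k`.
#' @export
cross_validate <- function(dataset, spec, cfg, k = 10L) {
  n <- nrow(dataset$scores)
  if (k > n) stop("k must not exceed the number of subjects", call. = FALSE)
  fold <- make_folds(ds_labels(dataset), sr_labels(dataset), k = k,
                     seed = cfg$seed)
  rows <- list()
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    cfg_f <- cfg
    cfg_f$seed <- fold_seed(cfg$seed, f)
    fit <- if (spec$task == "mtl") {
      train_mtl(dataset[train_idx], spec, cfg_f)
    } else {
      train_stl(dataset[train_idx], spec_tasks(spec), spec, cfg_f)
    }
    probs <- predict(fit, dataset[test_idx])
    rows[[f]] <- fold_metrics(probs, dataset[test_idx], f)
  }
  folds <- do.call(rbind, rows)
  num <- c("accuracy", "recall", "precision", "specificity", "f1", "auc")
  means <- do.call(rbind, lapply(split(folds, folds$task), function(d) {
    out <- d[1, c("task", num)]
    out[num] <- lapply(d[num], mean, na.rm = TRUE)
    out
  }))
  rownames(means) <- NULL
  structure(list(folds = folds, means = means,
                 assignment = data.frame(subject_id = dataset$scores$subject_id,
                                         fold = fold,
                                         stringsAsFactors = FALSE),
                 k = k, spec = spec, cfg = cfg),
            class = "psymtl_cv")
}

fold_seed <- function(seed, fold) (abs(seed) %% 1000000L) * 1000L + fold

fold_metrics <- function(probs, test_data, f) {
  out <- list()
  if (!is.null(probs$ds)) {
    y <- as.integer(ds_labels(test_data))
    pred <- max.col(probs$ds)
    cm <- confusion_metrics(factor(y, 1:3), factor(pred, 1:3), mode = "macro")
    auc <- if (length(unique(y)) == 3) auc_macro_ovr(probs$ds, y) else NA_real_
    out$ds <- data.frame(fold = f, task = "ds", accuracy = cm$accuracy,
                         recall = cm$recall, precision = cm$precision,
                         specificity = cm$specificity, f1 = cm$f1, auc = auc)
  }
  if (!is.null(probs$sr)) {
    y <- as.integer(sr_labels(test_data))
    pred <- max.col(probs$sr)
    cm <- confusion_metrics(factor(y, 1:2), factor(pred, 1:2),
                            mode = "binary", positive = "2")
    auc <- if (length(unique(y)) == 2) auc_binary(probs$sr[, 2],
                                                  as.integer(y == 2)) else NA_real_
    out$sr <- data.frame(fold = f, task = "sr", accuracy = cm$accuracy,
                         recall = cm$recall, precision = cm$precision,
                         specificity = cm$specificity, f1 = cm$f1, auc = auc)
  }
  do.call(rbind, out)
}

#' @export
print.psymtl_cv <- function(x, ...) {
  cat(sprintf("psymtl_cv: %d folds, %s/%s\n", x$k, x$spec$modality,
              x$spec$task))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Single-task vs multitask comparison table
#'
#' Joins matched single-task and multitask AUC rows on
#' (task, modality, embedding) and reports `improvement = mtl - stl`.
#' Negative improvements (negative transfer) are reported as negative --
#' degradation under joint training is a finding, not an error.
#'
#' @param stl,mtl Data frames with columns `task`, `modality`, `embedding`,
#'   `auc`; row keys must match one-to-one.
#' @return Data frame with columns `task`, `modality`, `embedding`,
#'   `stl_auc`, `mtl_auc`, `improvement`.
#' @export
compare_stl_mtl <- function(stl, mtl) {
  req <- c("task", "modality", "embedding", "auc")
  stopifnot(all(req %in% names(stl)), all(req %in% names(mtl)))
  key <- function(d) paste(d$task, d$modality, d$embedding, sep = "|")
  ks <- key(stl); km <- key(mtl)
  unmatched <- c(setdiff(ks, km), setdiff(km, ks))
  if (length(unmatched))
    stop("unmatched comparison keys: ", paste(unmatched, collapse = "; "),
         call. = FALSE)
  mtl <- mtl[match(ks, km), ]
  data.frame(task = stl$task, modality = stl$modality,
             embedding = stl$embedding, stl_auc = stl$auc, mtl_auc = mtl$auc,
             improvement = mtl$auc - stl$auc, stringsAsFactors = FALSE)
}
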