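test_that("confusion metrics match hand-counted matrices", {
  # binary: TP=1 FN=1 FP=0 TN=2
  m <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), mode = "binary",
                         positive = "1")
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 1.0)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$f1, 2 / 3)
  # perfect predictions
  p <- confusion_metrics(c(1, 2, 3, 1), c(1, 2, 3, 1), mode = "macro")
  expect_true(all(unlist(p[c("accuracy", "recall", "precision",
                             "specificity", "f1")]) == 1))
  # all predictions class 1 on balanced 3-class truth: macro recall 1/3
  q <- confusion_metrics(rep(1:3, each = 4), rep(1, 12), mode = "macro")
  expect_equal(q$recall, 1 / 3)
  expect_equal(q$accuracy, 1 / 3)
  # zero-division conventions
  z <- confusion_metrics(c(1, 1, 0), c(0, 0, 0), mode = "binary",
                         positive = "1")
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
})

test_that("binary AUC matches its defining cases and handles ties by midrank", {
  expect_equal(auc_binary(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_binary(rep(0.3, 10), rep(0:1, 5)), 0.5)
  expect_equal(auc_binary(1:10, c(rep(0, 5), rep(1, 5))), 1.0)
  expect_equal(auc_binary(1:10, c(rep(1, 5), rep(0, 5))), 0.0)
  expect_error(auc_binary(1:4, rep(1, 4)), "both classes")
})

test_that("rank-based AUC equals brute-force pair counting on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    expect_equal(auc_binary(scores, labels), auc_pairs(scores, labels))
  }
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:20) {
    n <- 40
    labels <- c(rep(0, 15), rep(1, 25))
    scores <- rnorm(n) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_binary(scores, labels), ref)
  }
})

test_that("macro one-vs-rest AUC averages per-class pairwise counts", {
  # one-hot rows matching labels
  y <- c(1, 2, 3, 1, 2, 3)
  P <- diag(3)[y, ]
  expect_equal(auc_macro_ovr(P, y), 1.0)
  # identical rows: pure ties
  expect_equal(auc_macro_ovr(matrix(1 / 3, 6, 3), y), 0.5)
  # 6-subject toy vs brute force per class
  set.seed(5)
  P2 <- t(apply(matrix(rexp(18), 6), 1, function(r) r / sum(r)))
  manual <- mean(vapply(1:3, function(cl) {
    auc_pairs(P2[, cl], as.integer(y == cl))
  }, numeric(1)))
  expect_equal(auc_macro_ovr(P2, y), manual)
  expect_error(auc_macro_ovr(P2[1:2, ], y[1:2]), "classes")
})

test_that("fold assignment partitions the cohort evenly and reproducibly", {
  d <- generate_cohort(synthetic_config(n = 200, Da = 4, Dt = 4, seed = 2))
  f <- suppressWarnings(make_folds(ds_labels(d), sr_labels(d), k = 10, seed = 5))
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 20))               # exactly 20 per fold
  expect_identical(f, suppressWarnings(
    make_folds(ds_labels(d), sr_labels(d), k = 10, seed = 5)))
  f2 <- suppressWarnings(make_folds(ds_labels(d), sr_labels(d), k = 10, seed = 6))
  expect_false(identical(f, f2))
  # every fold sees every severity class (stratification)
  for (k in 1:10)
    expect_equal(sort(unique(as.integer(ds_labels(d))[f == k])), 1:3)
  expect_error(make_folds(1:5, NULL, k = 10), "exceed")
})

test_that("fold sizes differ by at most one for awkward n", {
  for (n in c(23, 57, 101)) {
    f <- suppressWarnings(
      make_folds(sample(1:3, n, replace = TRUE), NULL, k = 7, seed = 1))
    expect_lte(diff(range(table(factor(f, 1:7)))), 1)
  }
  # the degradation itself warns
  expect_warning(make_folds(rep(1:2, c(3, 20)), NULL, k = 5, seed = 1),
                 "fewer members")
})

test_that("cross-validation isolates folds and averages within fold range", {
  d <- small_cohort(n = 90, seed = 8)
  cv <- suppressWarnings(
    cross_validate(d, tiny_spec(hidden = c(8, 4)), fast_cfg(seed = 4), k = 3))
  expect_equal(sort(unique(cv$assignment$fold)), 1:3)
  expect_equal(nrow(cv$assignment), 90)
  # union of test folds = full dataset, pairwise disjoint by construction
  expect_setequal(cv$assignment$subject_id, d$scores$subject_id)
  for (task in c("ds", "sr")) {
    fl <- cv$folds[cv$folds$task == task, ]
    mn <- cv$means[cv$means$task == task, ]
    for (col in c("accuracy", "recall", "auc")) {
      vals <- fl[[col]][!is.na(fl[[col]])]
      expect_gte(mn[[col]], min(vals) - 1e-12)
      expect_lte(mn[[col]], max(vals) + 1e-12)
      expect_equal(mn[[col]], mean(vals))
    }
  }
  # same seed reproduces the whole result
  cv2 <- suppressWarnings(
    cross_validate(d, tiny_spec(hidden = c(8, 4)), fast_cfg(seed = 4), k = 3))
  expect_identical(cv$folds, cv2$folds)
})

test_that("the comparison table subtracts mean AUCs and keeps negative transfer visible", {
  stl <- data.frame(task = c("ds", "sr"), modality = "fused",
                    embedding = "stub", auc = c(0.80, 0.85))
  mtl <- data.frame(task = c("ds", "sr"), modality = "fused",
                    embedding = "stub", auc = c(0.85, 0.80))
  tab <- compare_stl_mtl(stl, mtl)
  expect_equal(tab$improvement, c(0.05, -0.05), tolerance = 1e-12)
  expect_equal(tab$improvement, tab$mtl_auc - tab$stl_auc)
  # identical inputs: zero improvement everywhere
  expect_true(all(compare_stl_mtl(stl, stl)$improvement == 0))
  # unmatched keys are listed
  mtl2 <- mtl; mtl2$embedding <- c("stub", "other")
  expect_error(compare_stl_mtl(stl, mtl2), "sr|fused|other")
})
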