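test_that("the learning-rate schedule ramps linearly up then decays to zero", {
  expect_equal(lr_multiplier(0, 100, 0.25), 0)
  expect_equal(lr_multiplier(25, 100, 0.25), 1)
  expect_equal(lr_multiplier(50, 100, 0.25), 2 / 3)
  expect_equal(lr_multiplier(100, 100, 0.25), 0)
  expect_equal(lr_multiplier(15, 100, 0.3), 0.5)
  steps <- 0:200
  m <- lr_multiplier(steps, 200, 0.35)
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(which.max(m) - 1, 0.35 * 200)
  expect_error(lr_multiplier(0, 0, 0.3), "positive")
})

test_that("early stopping fires after `patience` flat epochs and keeps the best epoch", {
  # plateau from epoch 2: improvements at 1,2 then three flat epochs
  trace <- c(1.0, 0.6, 0.6, 0.6, 0.6, 0.6)
  out <- early_stop_trace(trace, patience = 3)
  expect_equal(out$stop_epoch, 5L)
  expect_equal(out$best_epoch, 2L)
  expect_equal(out$reason, "early_stopped")
  # strictly improving sequence runs to completion
  out2 <- early_stop_trace(seq(1, 0.1, length.out = 8), patience = 3)
  expect_equal(out2$reason, "completed")
  expect_equal(out2$best_epoch, 8L)
  # non-consecutive stalls reset the counter
  out3 <- early_stop_trace(c(1, 0.9, 0.95, 0.8, 0.85, 0.9, 0.87), patience = 3)
  expect_equal(out3$stop_epoch, 7L)
  expect_equal(out3$best_epoch, 4L)
})

test_that("table-bound mode defaults follow the published regime", {
  expect_equal(train_config("SMSTL")$warmup_ratio, 0.3)
  expect_equal(train_config("SMSTL")$dropout, 0.2)
  expect_equal(train_config("MMSTL")$warmup_ratio, 0.35)
  expect_equal(train_config("SMMTL")$warmup_ratio, 0.35)
  expect_equal(train_config("MMMTL")$warmup_ratio, 0.25)
  expect_equal(train_config("MMMTL")$dropout, 0.1)
  cfg <- train_config("MMMTL", dropout = 0.5)  # explicit override wins
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$epochs, 20L)
  expect_equal(cfg$patience, 3L)
  expect_equal(cfg$batch_size, 8L)
  expect_equal(cfg$learning_rate, 5e-4)
})

test_that("zero learning rate is a no-op on weights and task variances", {
  d <- small_cohort(n = 60, seed = 2)
  spec <- tiny_spec(hidden = c(8, 4))
  cfg <- fast_cfg(seed = 3, epochs = 3, learning_rate = 0)
  fit <- train_mtl(d, spec, cfg)
  # learnable parameters after 3 epochs equal those after 1 epoch (both
  # equal the initialization); only batch-norm running statistics move
  fit1 <- train_mtl(d, spec, fast_cfg(seed = 3, epochs = 1, learning_rate = 0))
  weights <- function(net) list(
    lapply(net$layers, function(l) l[c("W", "b", "gamma", "beta")]),
    net$heads, net$s)
  expect_identical(weights(fit$net), weights(fit1$net))
  expect_equal(fit$net$s, c(ds = 0, sr = 0))
  expect_equal(unique(fit$history$sigma2_ds), 1)
  expect_equal(unique(fit$history$sigma2_sr), 1)
})

test_that("training is bitwise deterministic given the seed", {
  d <- small_cohort(n = 80, seed = 6)
  spec <- tiny_spec(task = "stl_sr", hidden = c(8, 4))
  cfg <- fast_cfg(seed = 11, epochs = 4)
  f1 <- train_stl(d, "sr", spec, cfg)
  f2 <- train_stl(d, "sr", spec, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net, f2$net)
  f3 <- train_stl(d, "sr", spec, fast_cfg(seed = 12, epochs = 4))
  expect_false(identical(f1$net$layers[[1]]$W, f3$net$layers[[1]]$W))
})

test_that("separable data is learned to a perfect training-set AUC", {
  d <- generate_cohort(synthetic_config(n = 400, Da = 24, Dt = 16,
                                        snr_audio = 10, snr_text = 10,
                                        seed = 21))
  spec <- model_spec("fused", "stl_sr", hidden = c(16, 8))
  fit <- train_stl(d, "sr", spec, train_config(mode = "MMSTL", seed = 5))
  p <- predict(fit, d)
  expect_equal(auc_binary(p$sr[, 2], as.integer(sr_labels(d)) == 2), 1.0)
})

test_that("early stopping returns parameters from the best validation epoch", {
  d <- small_cohort(n = 100, seed = 13, snr = 0.3)  # noisy: stalls happen
  fit <- train_mtl(d, tiny_spec(hidden = c(8, 4)),
                   train_config(epochs = 20, seed = 7))
  expect_true(fit$reason %in% c("early_stopped", "completed"))
  expect_equal(fit$history$val_loss[fit$best_epoch],
               min(fit$history$val_loss))
  if (fit$reason == "early_stopped")
    expect_equal(fit$stop_epoch, nrow(fit$history))
  # history bookkeeping matches the standalone early-stop rule
  es <- early_stop_trace(fit$history$val_loss, patience = 3)
  expect_equal(fit$best_epoch, es$best_epoch)
  expect_equal(fit$stop_epoch, es$stop_epoch)
})

test_that("a task with a missing class raises a stratification error", {
  d <- small_cohort(n = 40, seed = 3)
  d$scores$sad_persons <- rep(1L, 40)  # all low risk
  expect_error(train_stl(d, "sr", tiny_spec(task = "stl_sr", hidden = c(8, 4)),
                         fast_cfg()), "stratification")
})

test_that("one noisy task earns the larger learned variance", {
  res <- uncertainty_experiment(seeds = 1:3)
  expect_true(all(res$sigma2_sr > 0))
  expect_gte(sum(res$sigma2_sr > res$sigma2_ds), 2)
})
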