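test_that("pearson chi-square matches the base-R oracle without correction", {
  set.seed(2)
  for (i in 1:20) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    m <- matrix(rpois(r * c, 20) + 1, r, c)
    ours <- pearson_chi2(m)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p, ref$p.value)
  }
})

test_that("2x2 statistic equals the closed form N(ad-bc)^2/(margins product)", {
  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rpois(4, 30) + 1, 2, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    closed <- sum(m) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(pearson_chi2(m)$statistic, closed)
  }
})

test_that("chi-square is invariant to permutation and transposition, zero on proportional rows", {
  m <- matrix(c(29, 9, 21, 68, 21, 52), nrow = 2, byrow = TRUE)
  base <- pearson_chi2(m)$statistic
  expect_equal(pearson_chi2(m[, c(3, 1, 2)])$statistic, base)
  expect_equal(pearson_chi2(m[c(2, 1), ])$statistic, base)
  expect_equal(pearson_chi2(t(m))$statistic, base)
  prop <- rbind(c(10, 20, 30), c(5, 10, 15))
  expect_equal(pearson_chi2(prop)$statistic, 0)
  expect_equal(pearson_chi2(prop)$p, 1)
  u <- matrix(10, 2, 2)
  expect_equal(pearson_chi2(u)$df, 1L)
  expect_equal(pearson_chi2(u)$p, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 1, 2), 2)), "degenerate")
  expect_error(pearson_chi2(matrix(1:3, 1)), "2x2")
})

test_that("packaged cohort tables reproduce the published p-values at printed precision", {
  tabs <- demographic_tables()
  expect_equal(round(pearson_chi2(tabs$ds$sex)$p, 2), 0.99)
  expect_equal(round(pearson_chi2(tabs$ds$occupation)$p, 2), 0.01)
  expect_equal(round(pearson_chi2(tabs$ds$marriage)$p, 3), 0.001)
  expect_equal(round(pearson_chi2(tabs$sr$sex)$p, 2), 0.09)
  expect_equal(round(pearson_chi2(tabs$sr$occupation)$p, 2), 0.02)
  expect_lt(pearson_chi2(tabs$ds$education)$p, 0.001)
  expect_lt(pearson_chi2(tabs$sr$education)$p, 0.001)
  expect_lt(pearson_chi2(tabs$sr$marriage)$p, 0.001)
  # group sizes as tabulated
  expect_equal(unname(colSums(tabs$ds$sex)), c(97, 30, 73))
  expect_equal(unname(colSums(tabs$sr$sex)), c(110, 90))
})

test_that("Welch t from summaries matches the formula oracle and base R on raw data", {
  out <- welch_t(summary_group(45, 16.7, 110), summary_group(42, 19.3, 90))
  expect_equal(out$t, 1.1612, tolerance = 1e-4)
  expect_equal(out$p, 0.247, tolerance = 1e-3)
  # equal groups: t = 0, p = 1
  eq <- welch_t(summary_group(5, 2, 30), summary_group(5, 2, 30))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # doubling n at fixed means/sds decreases p when means differ
  p1 <- welch_t(summary_group(45, 16.7, 110), summary_group(42, 19.3, 90))$p
  p2 <- welch_t(summary_group(45, 16.7, 220), summary_group(42, 19.3, 180))$p
  expect_lt(p2, p1)
  # against t.test on raw vectors whose summaries we feed in
  set.seed(9)
  a <- rnorm(40, 1); b <- rnorm(35, 0.4, 1.6)
  ref <- stats::t.test(a, b)
  ours <- welch_t(summary_group(mean(a), sd(a), 40),
                  summary_group(mean(b), sd(b), 35))
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value)
  expect_error(welch_t(summary_group(1, 1, 1), summary_group(0, 1, 5)),
               "n >= 2")
})

test_that("summary-statistic ANOVA matches oracles and the two-group t identity", {
  # identical groups: F = 0, p = 1
  g <- summary_group(10, 2, 20)
  expect_equal(anova_oneway_from_summary(list(g, g, g))$F, 0)
  expect_equal(anova_oneway_from_summary(list(g, g, g))$p, 1)
  # two groups: F equals the squared pooled-variance t
  a <- summary_group(3, 1.5, 12); b <- summary_group(4.1, 1.2, 15)
  out2 <- anova_oneway_from_summary(list(a, b))
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  t_pooled <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  expect_equal(out2$F, t_pooled^2, tolerance = 1e-12)
  # three-group case vs aov() on expanded samples with matching summaries
  make_group <- function(mean, sd, n) {
    x <- scale(seq_len(n))          # exact mean 0, sd 1
    as.numeric(x * sd + mean)
  }
  xs <- list(make_group(0, 1, 10), make_group(0, 1, 10), make_group(1, 1, 10))
  df <- data.frame(y = unlist(xs), g = factor(rep(1:3, each = 10)))
  ref <- summary(stats::aov(y ~ g, df))[[1]]
  ours <- anova_oneway_from_summary(lapply(xs, function(x) {
    summary_group(mean(x), sd(x), length(x))
  }))
  expect_equal(ours$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(ours$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("the cohort report tabulates demographics with test p-values", {
  d <- small_cohort(n = 150, seed = 12)
  rep_ds <- cohort_report(d$scores, by = "ds")
  expect_true(all(c("sex", "age") %in% rep_ds$variable))
  p_sex <- rep_ds$p[rep_ds$variable == "sex"][1]
  ref <- pearson_chi2(unclass(table(d$scores$sex, ds_labels(d))))$p
  expect_equal(p_sex, ref)
  rep_sr <- cohort_report(d$scores, by = "sr")
  expect_true(any(rep_sr$variable == "age"))
})
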