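#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic `sum((O-E)^2/E)` with expected counts from
#' the product of margins over the grand total, `df = (r-1)(c-1)`, p-value
#' from the upper chi-square tail. No Yates continuity correction is
#' applied anywhere in the package: the cohort tables it targets were
#' tested without it, and for 2x2 tables the statistic then equals the
#' closed form `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param table Numeric matrix of nonnegative counts, at least 2x2.
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' pearson_chi2(matrix(c(64, 33, 13, 17, 33, 40), nrow = 2))
#' @export
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (any(m < 0) || any(!is.finite(m)))
    stop("counts must be nonnegative and finite", call. = FALSE)
  N <- sum(m)
  if (N <= 0) stop("degenerate table: total count is zero", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  E <- outer(rs, cs) / N
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Summary statistics for one group
#'
#' Container for group-level age summaries (mean in years, SD, group size)
#' used by the summary-statistic tests; raw per-subject values are not
#' required.
#'
#' @param mean,sd,n Group mean, standard deviation (>= 0), size (>= 1).
#' @return A `psymtl_summary_group`.
#' @export
summary_group <- function(mean, sd, n) {
  stopifnot(is.finite(mean), sd >= 0, n >= 1)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n = as.integer(n)), class = "psymtl_summary_group")
}

#' Welch two-sample t test from group summaries
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of
#' freedom, computed from group means, SDs and sizes; two-sided p-value.
#'
#' @param a,b [summary_group()] objects, each with `n >= 2`.
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_t(summary_group(45, 16.7, 110), summary_group(42, 19.3, 90))
#' @export
welch_t <- function(a, b) {
  stopifnot(inherits(a, "psymtl_summary_group"),
            inherits(b, "psymtl_summary_group"))
  if (a$n < 2 || b$n < 2) stop("each group needs n >= 2", call. = FALSE)
  if (a$sd == 0 && b$sd == 0 && a$mean != b$mean)
    stop("zero variance in both groups with unequal means", call. = FALSE)
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  se2 <- va + vb
  if (se2 == 0) return(list(t = 0, df = a$n + b$n - 2, p = 1))
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way ANOVA from group summaries
#'
#' Reconstructs between- and within-group sums of squares from means, SDs
#' and sizes: `SSB = sum(n_g (m_g - m)^2)`, `SSW = sum((n_g - 1) s_g^2)`;
#' `F = (SSB/(G-1)) / (SSW/(N-G))` with the upper-tail p-value. With two
#' groups, F equals the square of the pooled-variance t statistic.
#'
#' @param groups List of at least two [summary_group()]s, each `n >= 2`.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway_from_summary <- function(groups) {
  stopifnot(length(groups) >= 2,
            all(vapply(groups, inherits, logical(1), "psymtl_summary_group")))
  ns <- vapply(groups, `[[`, numeric(1), "n")
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  ms <- vapply(groups, `[[`, numeric(1), "mean")
  sds <- vapply(groups, `[[`, numeric(1), "sd")
  N <- sum(ns); G <- length(groups)
  gm <- sum(ns * ms) / N
  ssb <- sum(ns * (ms - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = G - 1L, df2 = N - G, p = 1))
    stop("zero within-group variance with unequal means", call. = FALSE)
  }
  F <- (ssb / (G - 1)) / (ssw / (N - G))
  list(F = F, df1 = G - 1L, df2 = as.integer(N - G),
       p = stats::pf(F, G - 1, N - G, lower.tail = FALSE))
}

#' Packaged cohort demographic tables
#'
#' Loads the packaged contingency tables and age summaries describing the
#' 200-subject clinical cohort this package emulates: sex, education,
#' occupation and marriage cross-tabulated against the three severity
#' groups and against the two risk groups, plus group-level age
#' mean/SD/n. Shipped as plain CSV under `extdata/demographics/`.
#'
#' @return A list with elements `ds` and `sr`, each containing named count
#'   matrices (`sex`, `education`, `occupation`, `marriage`) and an `age`
#'   data frame (`group`, `mean`, `sd`, `n`).
#' @export
demographic_tables <- function() {
  root <- system.file("extdata", "demographics", package = "psymtl",
                      mustWork = TRUE)
  read_tab <- function(f) {
    df <- utils::read.csv(file.path(root, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  read_age <- function(f) utils::read.csv(file.path(root, f),
                                          check.names = FALSE)
  out <- list()
  for (grp in c("ds", "sr")) {
    out[[grp]] <- list(sex = read_tab(paste0(grp, "_sex.csv")),
                       education = read_tab(paste0(grp, "_education.csv")),
                       occupation = read_tab(paste0(grp, "_occupation.csv")),
                       marriage = read_tab(paste0(grp, "_marriage.csv")),
                       age = read_age(paste0(grp, "_age.csv")))
  }
  out
}

#' Demographic group-comparison report for a labels table
#'
#' Builds a cohort-characteristics report from a raw labels table:
#' categorical demographics (`sex`, `education`, `occupation`, `marriage`,
#' whichever are present) are cross-tabulated against the derived severity
#' groups (3 levels) or risk groups (2 levels) and tested with the
#' uncorrected Pearson chi-square; `age`, if present, is compared with a
#' one-way ANOVA across severity groups or a Welch t test across risk
#' groups.
#'
#' @param labels Data frame with `hamd17`, `sad_persons` and demographic
#'   columns.
#' @param by `"ds"` or `"sr"`: which task's groups to compare.
#' @return Data frame with one row per (variable, level) holding counts
#'   and percentages per group, plus the variable-level p-value.
#' @export
cohort_report <- function(labels, by = c("ds", "sr")) {
  by <- match.arg(by)
  grp <- if (by == "ds") ds_label_from_hamd(labels$hamd17)
         else sr_label_from_sadpersons(labels$sad_persons)
  rows <- list()
  for (v in intersect(c("sex", "education", "occupation", "marriage"),
                      names(labels))) {
    tab <- table(labels[[v]], grp)
    p <- tryCatch(pearson_chi2(unclass(tab))$p, error = function(e) NA_real_)
    counts <- as.data.frame.matrix(tab)
    pct <- round(100 * sweep(as.matrix(counts), 2, colSums(counts), "/"), 1)
    rows[[v]] <- data.frame(variable = v, level = rownames(counts),
                            counts, check.names = FALSE,
                            p = c(p, rep(NA_real_, nrow(counts) - 1)))
    names(rows[[v]])[3:(2 + ncol(counts))] <- paste0("n_", colnames(counts))
    rows[[v]][paste0("pct_", colnames(counts))] <- as.data.frame(pct)
  }
  if ("age" %in% names(labels)) {
    gs <- lapply(split(labels$age, grp), function(x) {
      summary_group(mean(x), stats::sd(x), length(x))
    })
    p_age <- if (by == "ds") anova_oneway_from_summary(gs)$p
             else welch_t(gs[[1]], gs[[2]])$p
    age_row <- data.frame(variable = "age", level = "mean (sd)", p = p_age)
    for (g in names(gs))
      age_row[paste0("n_", g)] <- sprintf("%.1f (%.1f)", gs[[g]]$mean,
                                          gs[[g]]$sd)
    rows$age <- age_row
  }
  out <- do.call(rbind, lapply(rows, function(d) {
    d[setdiff(unique(unlist(lapply(rows, names))), names(d))] <- NA
    d
  }))
  rownames(out) <- NULL
  out
}
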