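#' Depression-severity label from a HAMD-17 total score
#'
#' Maps Hamilton Depression Rating Scale (17-item) totals to the three
#' ordinal severity levels used throughout the package: scores 0--7 are
#' `none`, 8--23 are `low_moderate` (the low and moderate bands are a single
#' class), and 24--52 are `high`.
#'
#' @param score Integer vector of HAMD-17 totals, each in \[0, 52\].
#' @return An ordered factor with levels `none < low_moderate < high`.
#' @examples
#' ds_label_from_hamd(c(0, 7, 8, 23, 24, 52))
#' @export
ds_label_from_hamd <- function(score) {
  check_integer_range(score, 0L, 52L, "hamd17")
  cut(as.integer(score), breaks = c(-1L, 7L, 23L, 52L),
      labels = ds_levels(), ordered_result = TRUE)
}

#' Suicide-risk label from a SAD PERSONS total score
#'
#' Scores 0--3 map to `low`, 4--10 to `moderate_high` (moderate and high
#' risk bands are a single class). `moderate_high` is the positive class in
#' every binary metric this package reports.
#'
#' @param score Integer vector of SAD PERSONS totals, each in \[0, 10\].
#' @return A factor with levels `low`, `moderate_high`.
#' @examples
#' sr_label_from_sadpersons(c(0, 3, 4, 10))
#' @export
sr_label_from_sadpersons <- function(score) {
  check_integer_range(score, 0L, 10L, "sad_persons")
  factor(ifelse(as.integer(score) >= 4L, "moderate_high", "low"),
         levels = sr_levels())
}

ds_levels <- function() c("none", "low_moderate", "high")
sr_levels <- function() c("low", "moderate_high")

# integer score bands per class, used by the generator's back-fill
ds_score_bands <- function() list(none = c(0L, 7L), low_moderate = c(8L, 23L),
                                  high = c(24L, 52L))
sr_score_bands <- function() list(low = c(0L, 3L), moderate_high = c(4L, 10L))

check_integer_range <- function(x, lo, hi, what) {
  if (length(x) == 0) stop(what, ": empty score vector", call. = FALSE)
  if (anyNA(x) || any(x != round(x)))
    stop(what, ": scores must be integers without missing values", call. = FALSE)
  bad <- x < lo | x > hi
  if (any(bad))
    stop(sprintf("%s: score %s outside [%d, %d]", what,
                 paste(x[bad], collapse = ", "), lo, hi), call. = FALSE)
  invisible(x)
}

#' Construct a cohort dataset
#'
#' A `psymtl_dataset` bundles, for `n` subjects: an `n x Da` audio-embedding
#' matrix, an `n x Dt` text-embedding matrix, and a scores data frame with
#' columns `subject_id`, `hamd17`, `sad_persons` plus any demographic
#' columns (`sex`, `age`, `education`, `occupation`, `marriage`). Severity
#' and risk labels are always derived on demand from the stored scores
#' (single source of truth), never stored redundantly.
#'
#' @param audio Numeric matrix, one row per subject.
#' @param text Numeric matrix, one row per subject.
#' @param scores Data frame with `subject_id`, `hamd17`, `sad_persons` and
#'   optional demographic columns.
#' @return An object of class `psymtl_dataset`.
#' @export
psymtl_dataset <- function(audio, text, scores) {
  audio <- as.matrix(audio); text <- as.matrix(text)
  storage.mode(audio) <- "double"; storage.mode(text) <- "double"
  n <- nrow(scores)
  if (nrow(audio) != n || nrow(text) != n)
    stop("audio/text/scores disagree on the number of subjects", call. = FALSE)
  req <- c("subject_id", "hamd17", "sad_persons")
  miss <- setdiff(req, names(scores))
  if (length(miss))
    stop("scores table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- as.character(scores$subject_id)
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (n > 0) {
    check_integer_range(scores$hamd17, 0L, 52L, "hamd17")
    check_integer_range(scores$sad_persons, 0L, 10L, "sad_persons")
    if (!all(is.finite(audio))) stop("audio embeddings contain non-finite values",
                                     call. = FALSE)
    if (!all(is.finite(text))) stop("text embeddings contain non-finite values",
                                    call. = FALSE)
  }
  rownames(audio) <- ids; rownames(text) <- ids
  scores$subject_id <- ids
  structure(list(audio = audio, text = text,
                 scores = as.data.frame(scores, stringsAsFactors = FALSE),
                 Da = ncol(audio), Dt = ncol(text)),
            class = "psymtl_dataset")
}

#' @export
print.psymtl_dataset <- function(x, ...) {
  cat(sprintf("psymtl_dataset: %d subjects, Da=%d, Dt=%d\n",
              nrow(x$scores), x$Da, x$Dt))
  if (nrow(x$scores) > 0) {
    cat("  DS classes:", paste(sprintf("%s=%d", ds_levels(),
        tabulate(as.integer(ds_labels(x)), 3L)), collapse = " "), "\n")
    cat("  SR classes:", paste(sprintf("%s=%d", sr_levels(),
        tabulate(as.integer(sr_labels(x)), 2L)), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
`[.psymtl_dataset` <- function(x, i, ...) {
  psymtl_dataset(x$audio[i, , drop = FALSE], x$text[i, , drop = FALSE],
                 x$scores[i, , drop = FALSE])
}

#' Derived task labels of a dataset
#'
#' @param dataset A [psymtl_dataset()].
#' @return `ds_labels()`: ordered severity factor; `sr_labels()`: binary
#'   risk factor (positive class `moderate_high`).
#' @export
ds_labels <- function(dataset) ds_label_from_hamd(dataset$scores$hamd17)

#' @rdname ds_labels
#' @export
sr_labels <- function(dataset) sr_label_from_sadpersons(dataset$scores$sad_persons)

#' Load a cohort from delimited tables
#'
#' Reads the package's three standard tables -- audio embeddings, text
#' embeddings, labels -- and joins them by `subject_id`. Embedding tables
#' are CSV/TSV with a header, first column `subject_id`, remaining columns
#' numeric. The labels table is a CSV with `subject_id`, `hamd17`,
#' `sad_persons` and optional demographic columns. Row order follows the
#' labels table.
#'
#' @param audio_path,text_path,labels_path File paths.
#' @return A [psymtl_dataset()].
#' @export
load_dataset <- function(audio_path, text_path, labels_path) {
  audio <- read_embedding_table(audio_path)
  text <- read_embedding_table(text_path)
  labels <- as.data.frame(data.table::fread(labels_path, header = TRUE))
  if (!"subject_id" %in% names(labels))
    stop(basename(labels_path), ": missing subject_id column", call. = FALSE)
  labels$subject_id <- as.character(labels$subject_id)
  ids <- labels$subject_id
  for (tb in list(list(m = audio, p = audio_path), list(m = text, p = text_path))) {
    missing_ids <- setdiff(ids, rownames(tb$m))
    extra_ids <- setdiff(rownames(tb$m), ids)
    if (length(missing_ids) || length(extra_ids))
      stop(sprintf("%s: subject_id mismatch (missing: %s; extra: %s)",
                   basename(tb$p),
                   paste(missing_ids, collapse = ",") %||% "",
                   paste(extra_ids, collapse = ",") %||% ""), call. = FALSE)
  }
  psymtl_dataset(audio[ids, , drop = FALSE], text[ids, , drop = FALSE], labels)
}

read_embedding_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L))
  df <- as.data.frame(dt)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_row <- which(apply(df[, -1, drop = FALSE], 1,
                           function(r) anyNA(suppressWarnings(as.numeric(r)))))[1]
    stop(sprintf("%s: non-numeric token in row %d", basename(path), bad_row),
         call. = FALSE)
  }
  if (!all(is.finite(m))) {
    bad_row <- which(!apply(is.finite(m), 1, all))[1]
    stop(sprintf("%s: non-finite value in row %d", basename(path), bad_row),
         call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Write a cohort to the three standard tables
#'
#' Inverse of [load_dataset()]: writes `audio.csv`, `text.csv`, `labels.csv`
#' under `dir`. Round-trips losslessly up to floating-point text precision
#' (values are written with 17 significant digits).
#'
#' @param dataset A [psymtl_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("audio.csv", "text.csv", "labels.csv"))
  write_embedding_table(dataset$audio, paths[1], "a")
  write_embedding_table(dataset$text, paths[2], "t")
  data.table::fwrite(dataset$scores, paths[3])
  invisible(paths)
}

write_embedding_table <- function(m, path, prefix) {
  df <- data.frame(subject_id = rownames(m), stringsAsFactors = FALSE)
  cols <- as.data.frame(m)
  names(cols) <- paste0(prefix, seq_len(ncol(m)))
  data.table::fwrite(cbind(df, cols), path)
}

`%||%` <- function(a, b) if (length(a) == 0 || (length(a) == 1 && a == "")) b else a
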