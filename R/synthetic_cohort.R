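#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study cohort the framework targets: 200 subjects,
#' severity class proportions 106/21/73 out of 200, risk-positive proportion
#' 90/200, 1024-dimensional audio embeddings and 768-dimensional text
#' embeddings. `rho` is the latent cross-task correlation driving the
#' co-occurrence of depression severity and suicide risk (default 0.7, a
#' strong clinical association); `snr_audio`/`snr_text` scale the
#' class-mean signal relative to unit-variance isotropic noise.
#'
#' @param n Subject count.
#' @param Da,Dt Audio / text embedding dimensions.
#' @param ds_proportions Length-3 vector of severity class proportions
#'   (none, low_moderate, high); must sum to 1.
#' @param sr_proportion_positive Proportion in the positive (moderate/high)
#'   risk class.
#' @param rho Latent correlation between the severity and risk factors,
#'   in \[0, 1\].
#' @param snr_audio,snr_text Nonnegative signal-to-noise ratios.
#' @param seed Integer RNG seed; the same seed reproduces the cohort
#'   bit for bit.
#' @return A `psymtl_synth_config` list.
#' @export
synthetic_config <- function(n = 200L, Da = 1024L, Dt = 768L,
                             ds_proportions = c(106, 21, 73) / 200,
                             sr_proportion_positive = 90 / 200,
                             rho = 0.7, snr_audio = 1, snr_text = 1,
                             seed = 1L) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (Da < 1 || Dt < 1) stop("Da and Dt must be positive", call. = FALSE)
  if (length(ds_proportions) != 3 || any(ds_proportions < 0) ||
      abs(sum(ds_proportions) - 1) > 1e-12)
    stop("ds_proportions must be 3 nonnegative values summing to 1",
         call. = FALSE)
  if (sr_proportion_positive <= 0 || sr_proportion_positive >= 1)
    stop("sr_proportion_positive must be in (0, 1)", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (snr_audio < 0 || snr_text < 0) stop("SNRs must be nonnegative",
                                          call. = FALSE)
  structure(list(n = as.integer(n), Da = as.integer(Da), Dt = as.integer(Dt),
                 ds_proportions = as.numeric(ds_proportions),
                 sr_proportion_positive = as.numeric(sr_proportion_positive),
                 rho = as.numeric(rho), snr_audio = as.numeric(snr_audio),
                 snr_text = as.numeric(snr_text), seed = as.integer(seed)),
            class = "psymtl_synth_config")
}

#' Generate a synthetic cohort
#'
#' Latent-threshold (probit-style) construction of correlated ordinal and
#' binary task labels, with class-informative noisy embeddings:
#' \enumerate{
#'   \item latent severity `u_i ~ N(0,1)`; severity class by the two
#'     standard-normal quantile cut points matching `ds_proportions`;
#'   \item latent risk `v_i = rho*u_i + sqrt(1-rho^2)*e_i`, `e_i ~ N(0,1)`;
#'     risk positive when `v_i` exceeds the
#'     `(1 - sr_proportion_positive)` normal quantile;
#'   \item questionnaire scores back-filled uniformly from the integer band
#'     of the assigned class (labels, not scores, drive the models);
#'   \item per modality, one unit-norm mean vector per severity class and
#'     one per risk class (drawn once per seed); a subject's embedding is
#'     `snr * (mu_DS[class] + mu_SR[class])` plus isotropic unit-variance
#'     Gaussian noise.
#' }
#' Simple demographics (`sex`, `age`) are attached so the cohort-report
#' tooling has something to tabulate; they carry no embedding signal.
#'
#' @param cfg A [synthetic_config()].
#' @return A [psymtl_dataset()] of `cfg$n` subjects.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "psymtl_synth_config"))
  with_seed(cfg$seed, {
    n <- cfg$n
    mu <- list(
      audio_ds = class_means(3L, cfg$Da), audio_sr = class_means(2L, cfg$Da),
      text_ds = class_means(3L, cfg$Dt), text_sr = class_means(2L, cfg$Dt))
    if (n == 0) {
      scores <- data.frame(subject_id = character(0), hamd17 = integer(0),
                           sad_persons = integer(0), sex = character(0),
                           age = integer(0))
      psymtl_dataset(matrix(0, 0, cfg$Da), matrix(0, 0, cfg$Dt), scores)
    } else {
    u <- stats::rnorm(n)
    cuts <- stats::qnorm(cumsum(cfg$ds_proportions)[1:2])
    ds <- findInterval(u, cuts) + 1L                     # 1..3
    e <- stats::rnorm(n)
    v <- cfg$rho * u + sqrt(1 - cfg$rho^2) * e
    sr <- as.integer(v > stats::qnorm(1 - cfg$sr_proportion_positive)) + 1L
    hamd <- sample_band(ds, ds_score_bands())
    sadp <- sample_band(sr, sr_score_bands())
    audio <- cfg$snr_audio * (mu$audio_ds[ds, , drop = FALSE] +
                              mu$audio_sr[sr, , drop = FALSE]) +
      matrix(stats::rnorm(n * cfg$Da), n, cfg$Da)
    text <- cfg$snr_text * (mu$text_ds[ds, , drop = FALSE] +
                            mu$text_sr[sr, , drop = FALSE]) +
      matrix(stats::rnorm(n * cfg$Dt), n, cfg$Dt)
    scores <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      hamd17 = hamd, sad_persons = sadp,
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.3, 0.7)),
      age = pmin(90L, pmax(18L, as.integer(round(stats::rnorm(n, 44, 17))))),
      stringsAsFactors = FALSE)
    psymtl_dataset(audio, text, scores)
    }
  })
}

class_means <- function(k, d) {
  m <- matrix(stats::rnorm(k * d), k, d)
  m / sqrt(rowSums(m^2))
}

sample_band <- function(class_idx, bands) {
  vapply(class_idx, function(k) {
    b <- bands[[k]]
    as.integer(sample(b[1]:b[2], 1L))
  }, integer(1))
}

#' Cramér's V between two categorical label vectors
#'
#' Association strength derived from the uncorrected Pearson chi-square of
#' the cross-tabulation: `V = sqrt(chi2 / (n * (min(r, c) - 1)))`, in
#' \[0, 1\]. Used as a diagnostic for the cross-task association that
#' motivates multitask training.
#'
#' @param ds_labels,sr_labels Equal-length label vectors (factors or
#'   atomic); each must show at least two distinct observed categories.
#' @return A scalar in \[0, 1\].
#' @export
association_strength <- function(ds_labels, sr_labels) {
  if (length(ds_labels) != length(sr_labels))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(droplevels(factor(ds_labels)), droplevels(factor(sr_labels)))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate input: fewer than two observed categories on one axis",
         call. = FALSE)
  chi2 <- pearson_chi2(unclass(tab))$statistic
  v <- sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1)))
  min(1, v)  # guard FP overshoot on perfect association
}

#' Inject label noise into one task of a cohort
#'
#' Reassigns a fraction of subjects' questionnaire scores so the affected
#' task's derived label flips to a different class drawn uniformly among
#' the other classes; scores are re-sampled within the new class band. Used
#' to construct "noisier task" conditions for uncertainty-weighting and
#' transfer experiments.
#'
#' @param dataset A [psymtl_dataset()].
#' @param task `"ds"` or `"sr"`.
#' @param fraction Fraction of subjects to corrupt, in \[0, 1\].
#' @param seed Integer seed for the corruption draw.
#' @return A new [psymtl_dataset()] with modified scores.
#' @export
corrupt_labels <- function(dataset, task = c("ds", "sr"), fraction, seed = 1L) {
  task <- match.arg(task)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(dataset$scores)
  with_seed(seed, {
    idx <- sample(n, size = round(fraction * n))
    scores <- dataset$scores
    if (task == "ds") {
      cur <- as.integer(ds_label_from_hamd(scores$hamd17))
      new <- vapply(cur[idx], function(k) sample(setdiff(1:3, k), 1L), integer(1))
      scores$hamd17[idx] <- sample_band(new, ds_score_bands())
    } else {
      cur <- as.integer(sr_label_from_sadpersons(scores$sad_persons))
      new <- 3L - cur[idx]
      scores$sad_persons[idx] <- sample_band(new, sr_score_bands())
    }
    psymtl_dataset(dataset$audio, dataset$text, scores)
  })
}

# evaluate code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
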