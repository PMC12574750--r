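# shared fixtures: small cohorts and brute-force oracles, built in code

small_cohort <- function(n = 120, seed = 1, rho = 0.7, snr = 1,
                         Da = 24, Dt = 16) {
  generate_cohort(synthetic_config(n = n, Da = Da, Dt = Dt, rho = rho,
                                   snr_audio = snr, snr_text = snr,
                                   seed = seed))
}

tiny_spec <- function(task = "mtl", modality = "fused", hidden = c(12, 6)) {
  model_spec(modality, task, hidden = hidden)
}

fast_cfg <- function(seed = 1, epochs = 6, mode = NULL, ...) {
  train_config(mode = mode, epochs = epochs, seed = seed, ...)
}

# brute-force pairwise AUC: count positive-negative pairs directly
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# scores table consistent with the target label bands and counts
scores_for_counts <- function(ds_counts = c(106, 21, 73),
                              sr_counts = c(110, 90)) {
  hamd <- rep(c(3L, 15L, 30L), ds_counts)
  sadp <- rep(c(2L, 6L), sr_counts)
  data.frame(subject_id = sprintf("P%03d", seq_len(sum(ds_counts))),
             hamd17 = hamd, sad_persons = sadp, stringsAsFactors = FALSE)
}
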