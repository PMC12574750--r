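---
title: "Multimodal multitask severity and risk prediction: models, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal multitask severity and risk prediction: models, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Depression severity (DS) and suicide risk (SR) are assessed in clinics with
structured questionnaires: the 17-item Hamilton Depression Rating Scale
(HAMD-17, integer total 0–52) and the SAD PERSONS checklist (integer total
0–10). The two conditions co-occur strongly, which makes their joint
prediction from a patient's speech — the audio signal and its transcript —
a natural multitask problem. `psymtl` implements that joint predictor as a
reusable, fully tested package: DS is a three-level ordinal classification
(`none` for HAMD-17 0–7, `low_moderate` for 8–23, `high` for ≥24) and SR a
binary one (`low` for SAD PERSONS 0–3, `moderate_high` — the positive
class — for ≥4). Low and moderate depression form one class, as do moderate
and high suicide risk; scores are stored and labels always derived on
demand, so the score table is the single source of truth.

Inputs are per-subject embedding vectors from pretrained speech and language
encoders (by convention 1024-dimensional audio, 768-dimensional text),
supplied as delimited tables. The encoders themselves are out of scope: the
package consumes their outputs and ships only a deterministic extraction
*stub* that enforces the input contract (mono 16 kHz PCM, trimmed/padded to
6.25 s = 100,000 samples; transcripts tokenized to 512 tokens) so pipelines
can be exercised end to end without multi-gigabyte models.

## The model

Fusion is early and by concatenation, `x = xa ⊕ xt`: simple, injective for
fixed dimensions, and free of the cancellation risks of sums or products.
The fused vector feeds a fully connected encoder shared by both tasks
(*hard parameter sharing*); each task owns only a small linear softmax
head. Encoder layers use batch normalization and rectified linear
activations (classifier heads do not), with dropout after each encoder
activation. Single-task (STL) variants use the identical encoder with one
head, so any STL-vs-MTL difference is attributable to the training
objective rather than capacity.

The encoder depth and widths are not fixed by the problem; the default is
two hidden layers of 256 and 64 units for the full-size 1792-dimensional
fused input, configurable via `model_spec()`. Widths must decrease strictly
from the input width — the encoder's job is compression into a shared
representation.

### The composite loss

Each task contributes a cross-entropy loss (probabilities floored at
`1e-12` before the log). Multitask training combines them with learnable
homoscedastic task uncertainties rather than hand-tuned weights:

$$L_\mathrm{total} = \frac{1}{2\sigma_d^2} L_d + \frac{1}{2\sigma_s^2} L_s
  + \log \sigma_d^2 + \log \sigma_s^2 .$$

We parameterize and learn $s = \log\sigma^2$ (initialized at 0, i.e.
$\sigma^2 = 1$, so the loss starts as the plain half-sum), which guarantees
positivity and matches the printed $\log\sigma^2$ regularizers exactly;
some literature variants use $\tfrac12\log\sigma^2$, which we deliberately
do not. For a fixed task loss $L$, the per-task minimizer is
$\sigma^2 = L/2$ — a noisier task (persistently larger loss) earns a larger
variance and hence a smaller effective weight. The uncertainty parameters
are optimized by the same optimizer steps as the network weights, with no
weight decay on them.

### Training regime

All variants train with AdamW (decoupled weight decay 0.01 on weight
matrices only), mini-batches of 8 with reshuffling each epoch and the last
short batch kept, up to 20 epochs, base learning rate 5e-4 under a linear
warmup / linear decay schedule, and early stopping with patience 3. The
four mode tags bind published per-mode settings: warmup ratio 0.3 (SMSTL),
0.35 (MMSTL, SMMTL), 0.25 (MMMTL); dropout 0.2 (SMSTL) and 0.1 otherwise.

Three details are underdetermined by the regime as published, and are fixed
here as package choices:

* **Early-stopping signal.** Patience needs a monitored quantity. We carve
  a stratified 1/9 of the training portion as a validation split and
  monitor total validation loss; the returned parameters are always those
  of the best validation epoch. The 1/9 fraction leaves any outer test
  fold untouched.
* **Schedule horizon.** The warmup ratio is interpreted over total planned
  optimizer steps, `ceiling(n_train / 8) * 20`; early stopping simply cuts
  the tail off.
* **Determinism.** One run seed covers initialization (uniform fan-in),
  the validation split, batch order and dropout masks; inference always
  uses batch-norm running statistics (momentum 0.1), so two
  evaluation-mode passes agree bitwise and whole training runs are
  reproducible bit for bit.

## Evaluation

The metric suite is accuracy, recall, precision, specificity, F1 and AUC.
SR metrics use the positive class (`moderate_high`); DS metrics are
macro-averaged one-vs-rest, including specificity (TN/(TN+FP) per class,
averaged) and macro AUC (unweighted mean of the three one-vs-rest AUCs,
each scored by that class's probability column). Binary AUC is the
Mann–Whitney probability with midrank tie handling, exactly equivalent to
brute-force pair counting — the test suite asserts the equivalence
instance by instance. F1 is 0 when precision and recall are both 0.

Cross-validation is 10-fold. Folds are stratified by the joint (DS, SR)
label so both tasks see every class per fold where possible, falling back
to DS-only stratification and then to unstratified folds (with warnings)
when strata are smaller than k; fold sizes never differ by more than one.
Per-fold training seeds derive deterministically from the run seed and the
fold index. The comparison harness (`compare_stl_mtl()`) subtracts mean
STL from mean MTL AUC per (task, modality, embedding) row and reports
negative improvements as negative: negative transfer is a finding.

## The synthetic cohort generator

The study cohort the framework targets is private, so the generator is a
first-class module rather than a test fixture. It emulates the cohort's
statistical structure with a latent-threshold (probit-style) construction:

1. latent severity $u_i \sim N(0,1)$; DS class from the two standard-normal
   quantile cut points matching the class proportions (defaults 106/21/73
   out of 200);
2. latent risk $v_i = \rho u_i + \sqrt{1-\rho^2}\, e_i$; SR positive when
   $v_i$ exceeds the quantile matching the positive proportion (default
   90/200). $\rho$ is the single knob for the DS–SR co-occurrence that
   motivates multitask learning; the default 0.7 encodes the strong
   clinical association between depression severity and suicide risk.
3. questionnaire scores back-filled uniformly within the assigned class's
   integer band (any within-band distribution is consistent with the label
   definitions; labels, not scores, drive the models);
4. embeddings per modality: one unit-norm mean vector per DS class and one
   per SR class, drawn once per seed; a subject's embedding is
   `snr * (mu_DS + mu_SR)` plus isotropic unit-variance Gaussian noise.
   The additive per-task means give each task its own signal while leaving
   cross-task transfer controlled solely by $\rho$; the SNR scalars
   separate geometry from difficulty (defaults 1.0, which puts held-out
   AUCs in the realistic 0.75–0.9 band at the default cohort size).

Two consequences matter for experiment design. First, the class-mean
geometry is drawn per seed: train and test data must come from the *same*
generated cohort (split after generation), never from two seeds. Second,
the generator emulates class-conditional mean structure only — it does not
reproduce the heavy-tailed, anisotropic, cross-modality-correlated
geometry of real pretrained embeddings, nor demographic confounding
(generated sex/age carry no embedding signal). Passing tests therefore
demonstrate that the machinery is correct and that multitask effects move
in the predicted directions, not that clinical AUC levels are attainable.

## The packaged transfer experiments

`transfer_experiment()` fixes the package's scaled-down multitask
benchmark: per seed, one cohort of 800 subjects (32/24-dimensional
embeddings, encoder 16→8) is split 400 train / 400 test; 30% of training
SR labels are flipped, making SR the noisier task; STL and MTL models train
under the published regime and are compared by held-out AUC. With
$\rho = 0.9$ and SNR 0.7 the noisy task is learnable but degraded (STL AUC
roughly 0.55–0.6), and joint training with the clean, strongly correlated
DS task recovers part of the loss — the median improvement across 10 seeds
is reliably positive. With $\rho = 0$ and clean labels the tasks share
nothing, and the same harness shows negative transfer: a substantial
fraction of seed-task pairs have MTL below STL. These operating points
were chosen once, during design, so that the mechanism under test is
expressed rather than drowned (a regime where STL sits at chance shows
nothing); they are stated here precisely so they are not mistaken for
tuned values.

`uncertainty_experiment()` probes the loss weighting the same way: with
40% label noise on SR only (n = 400), the learned $\sigma_s^2$ ends above
$\sigma_d^2$ in nearly all seeded replicates — the noisier task is
down-weighted, which is the entire point of the weighting.

The problem sizes above (and the small dimensions used throughout the test
suite) are the package's chosen experiment scale: large enough for the
effects to be stable across seed bases, small enough that the full suite
and the acceptance script each run in a couple of minutes on one core.

## Cohort statistics

`pearson_chi2()`, `welch_t()` and `anova_oneway_from_summary()` reproduce
demographic group comparisons from count tables and summary statistics
(raw ages are typically unavailable; the summary-statistic route is
exact). No continuity correction is applied anywhere: the packaged cohort
tables' published p-values (sex .99/.09, occupation .01/.02, marriage
.001) match the uncorrected Pearson statistic, and the package validates
against exactly those values. Two published values resist reconstruction
from the rounded summaries they accompany: the three-group age comparison
(printed .048; one-way ANOVA from the rounded summaries gives .065, and no
pairwise Welch test gives .048 either) and the two-group age comparison
(printed .26; Welch from rounded summaries gives .247). Both tools are
provided; neither is asserted against the unreachable value — rounding of
the published means/SDs suffices to explain the gaps. One related
bookkeeping note: the severity group sizes in the packaged demographic
tables (97/30/73) differ from the label counts used for the generator
defaults (106/21/73); both groupings circulate for this cohort and the
package represents each where it is used, without resolving the
discrepancy.

## Degenerate inputs and numerical conventions

* Probabilities are floored at `1e-12` inside every log; softmax subtracts
  the row maximum before exponentiation.
* Batch norm uses `eps = 1e-5`; a size-1 trailing batch degenerates to
  zero batch variance and is handled by the epsilon (kept, as the regime
  keeps short batches).
* AUC requires both classes; macro AUC requires all three — absence raises
  an undefined-metric error rather than a silent default, and
  cross-validation records `NA` for a fold whose test split lost a class
  (stratification makes this rare).
* Chi-square on a table with a zero margin, Cramér's V on a single
  observed category, and scores outside their questionnaire ranges all
  raise immediate, named errors.
* `n = 0` cohorts, empty metric inputs and `k > n` fold requests fail (or
  return empty structures) explicitly.

## Known limitations

The generator's Gaussian, isotropic, mean-shift world is far simpler than
pretrained-embedding space; absolute metric levels here do not transfer to
clinical data. The uncertainty-weighted loss learns slowly at the regime's
20-epoch horizon, so learned variances move little from 1 — their ordering
(noisy above clean) is the reliable signal, not their magnitude. Real
embedding extraction, denoising and silence trimming are upstream of the
package's contract and are represented only by the documented stub.
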