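#' Cross-entropy of a single prediction
#'
#' `-sum(y * log(y_hat))` for a one-hot target, i.e. minus the log of the
#' probability assigned to the true class. Probabilities are floored at
#' `1e-12` before the log so a hard zero on the true class yields a large
#' finite loss rather than `Inf`.
#'
#' @param y One-hot numeric vector of length C.
#' @param y_hat Probability vector of length C (entries in \[0,1\], summing
#'   to 1 within 1e-6).
#' @return Nonnegative scalar.
#' @examples
#' cross_entropy(c(1, 0, 0), c(0.7, 0.2, 0.1))  # -log(0.7)
#' @export
cross_entropy <- function(y, y_hat) {
  if (length(y) != length(y_hat))
    stop("y and y_hat must have the same length", call. = FALSE)
  if (sum(y == 1) != 1 || sum(y == 0) != length(y) - 1)
    stop("y must be one-hot", call. = FALSE)
  if (any(y_hat < -1e-9) || abs(sum(y_hat) - 1) > 1e-6)
    stop("y_hat must lie on the probability simplex", call. = FALSE)
  -log(max(y_hat[y == 1], 1e-12))
}

# mean cross-entropy of a batch: P is n x C row-stochastic, yidx in 1..C
ce_mean <- function(P, yidx) {
  p_true <- P[cbind(seq_len(nrow(P)), yidx)]
  mean(-log(pmax(p_true, 1e-12)))
}

#' Learnable homoscedastic-uncertainty parameters
#'
#' Stores `s = log(sigma^2)` for each task rather than `sigma` itself, so
#' positivity of the task variances is guaranteed by construction and the
#' `log(sigma^2)` regularizer terms of the composite loss are exactly `s`.
#' Both start at 0 (`sigma^2 = 1`), i.e. the composite loss begins as the
#' plain half-sum of the task losses.
#'
#' @param s_d,s_s Initial log-variances for the severity and risk tasks.
#' @return A `psymtl_uncertainty` list with elements `s_d`, `s_s`.
#' @export
uncertainty_params <- function(s_d = 0, s_s = 0) {
  stopifnot(is.finite(s_d), is.finite(s_s))
  structure(list(s_d = as.numeric(s_d), s_s = as.numeric(s_s)),
            class = "psymtl_uncertainty")
}

#' @export
print.psymtl_uncertainty <- function(x, ...) {
  cat(sprintf("uncertainty params: sigma2_d = %.4f, sigma2_s = %.4f\n",
              exp(x$s_d), exp(x$s_s)))
  invisible(x)
}

#' Uncertainty-weighted composite multitask loss
#'
#' Combines the two task losses with learnable per-task variances:
#' `L_total = L_d / (2*sigma_d^2) + L_s / (2*sigma_s^2)
#'           + log(sigma_d^2) + log(sigma_s^2)`,
#' computed as `exp(-s)*L/2 + s` per task with `s = log(sigma^2)`. A task
#' with larger learned variance (higher homoscedastic uncertainty)
#' contributes with a smaller effective weight; the `log` terms stop the
#' variances from growing without bound. For fixed `L > 0` the per-task
#' minimizer is `sigma^2 = L/2`.
#'
#' @param L_d,L_s Nonnegative task losses (severity, risk).
#' @param params An [uncertainty_params()].
#' @return Scalar total loss (may be negative through the log terms).
#' @examples
#' auto_weighted_total(1, 2, uncertainty_params())     # 0.5 * (1 + 2)
#' auto_weighted_total(1, 2, uncertainty_params(log(2), log(0.5)))
#' @export
auto_weighted_total <- function(L_d, L_s, params) {
  stopifnot(inherits(params, "psymtl_uncertainty"),
            is.finite(L_d), is.finite(L_s))
  exp(-params$s_d) * L_d / 2 + params$s_d +
    exp(-params$s_s) * L_s / 2 + params$s_s
}
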