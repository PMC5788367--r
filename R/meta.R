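Z95 <- 1.959964

#' Back-derive a log-scale standard error from a reported OR and 95% CI
#'
#' For a Wald CI symmetric on the log scale,
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`. This is how
#' group-level medians of ORs and CI bounds are turned into study effects
#' for pooling.
#'
#' @param or_hat Reported odds ratio (> 0), with
#'   `ci_low <= or_hat <= ci_high`.
#' @param ci_low,ci_high Reported 95% CI bounds (> 0).
#' @return Positive standard error on the log-OR scale.
#' @export
#' @examples
#' se_from_ci(1.1, 0.4, 3.4)
se_from_ci <- function(or_hat, ci_low, ci_high) {
  if (any(c(or_hat, ci_low, ci_high) <= 0) || any(ci_low > or_hat) ||
      any(or_hat > ci_high))
    stop("need 0 < ci_low <= or_hat <= ci_high", call. = FALSE)
  se <- (log(ci_high) - log(ci_low)) / (2 * Z95)
  if (any(se <= 0))
    stop("degenerate CI (zero width): se must be > 0", call. = FALSE)
  se
}

#' Higgins I-squared from Cochran's Q
#'
#' `I2 = max(0, (Q - df) / Q) * 100`, with `I2 = 0` when `Q = 0`.
#' Heterogeneity at or below 60% is labelled mild/moderate, above 60%
#' substantial.
#'
#' @param q Cochran's Q statistic (>= 0).
#' @param df Degrees of freedom (number of studies minus one, >= 1).
#' @return List with `i2_percent` in \[0, 100\] and `band`
#'   (`"mild/moderate"` or `"substantial"`).
#' @export
#' @examples
#' higgins_i2(2, 1)
higgins_i2 <- function(q, df) {
  stopifnot(is.numeric(q), q >= 0)
  if (!is.numeric(df) || df < 1 || df != round(df))
    stop("df must be a positive integer", call. = FALSE)
  i2 <- if (q == 0) 0 else max(0, (q - df) / q) * 100
  list(i2_percent = i2,
       band = if (i2 > 60) "substantial" else "mild/moderate")
}

#' Inverse-variance fixed-effects meta-analysis of odds ratios
#'
#' Pools study log-ORs with weights `1/se^2`; the pooled standard error is
#' `1/sqrt(sum(w))`, the CI is Wald on the log scale, Cochran's Q is the
#' weighted sum of squared deviations from the pooled effect, and I² is
#' the Higgins statistic with clamping at 0. Study standard errors may be
#' supplied directly or back-derived from reported CIs via
#' [se_from_ci()].
#'
#' @param or_hat Study odds ratios (> 0).
#' @param ci_low,ci_high Study 95% CI bounds; used to derive standard
#'   errors when `se` is not given.
#' @param se Optional log-scale standard errors (overrides the CIs).
#' @param labels Optional study labels.
#' @return An object of class `cow_meta`: list with `pooled_or`, `ci_low`,
#'   `ci_high`, `pooled_log_or`, `pooled_se`, `q`, `df`, `i2_percent`,
#'   `band`, `n_studies`, `studies` (the input effects).
#' @export
#' @examples
#' # pooling two group-level estimates for one outcome
#' pool_fixed(c(2.9, 2.7), c(1.7, 1.4), c(5.2, 5.1),
#'            labels = c("group1", "group2"))
pool_fixed <- function(or_hat, ci_low = NULL, ci_high = NULL, se = NULL,
                       labels = NULL) {
  if (!length(or_hat)) stop("need at least one study", call. = FALSE)
  if (is.null(se)) {
    if (is.null(ci_low) || is.null(ci_high))
      stop("supply either se or both CI bounds", call. = FALSE)
    se <- mapply(se_from_ci, or_hat, ci_low, ci_high)
  }
  stopifnot(length(se) == length(or_hat), all(se > 0), all(or_hat > 0))
  b <- log(or_hat)
  w <- 1 / se^2
  pooled <- sum(w * b) / sum(w)
  pse <- 1 / sqrt(sum(w))
  q <- sum(w * (b - pooled)^2)
  df <- length(b) - 1L
  het <- if (df >= 1) higgins_i2(q, df)
  else list(i2_percent = 0, band = "mild/moderate")
  structure(list(pooled_or = exp(pooled),
                 ci_low = exp(pooled - Z95 * pse),
                 ci_high = exp(pooled + Z95 * pse),
                 pooled_log_or = pooled, pooled_se = pse,
                 q = q, df = df, i2_percent = het$i2_percent,
                 band = het$band, n_studies = length(b),
                 studies = data.frame(
                   label = if (is.null(labels))
                     paste0("study", seq_along(b)) else labels,
                   log_or = b, se = se)),
            class = "cow_meta")
}

#' @export
print.cow_meta <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Fixed-effects meta-analysis (%d studies)\n  pooled OR %.*f (95%% CI %.*f-%.*f)\n  Q = %.3f on %d df, I2 = %.1f%% (%s heterogeneity)\n",
    x$n_studies, digits, x$pooled_or, digits, x$ci_low, digits, x$ci_high,
    x$q, x$df, x$i2_percent, x$band))
  invisible(x)
}
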