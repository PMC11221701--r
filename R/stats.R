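# Group-comparison statistics and effect sizes used on the phase metrics.

.cohens_d_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(NA_real_)
  (mean(a) - mean(b)) / sp
}

#' Two-sample comparison of a phase metric
#'
#' Welch's t test (Satterthwaite degrees of freedom) by default, with
#' pooled-SD Cohen's d and the 95% CI of the mean difference. With
#' `normality_gate = TRUE` the Shapiro-Wilk test is run on both samples
#' first and a Student (pooled-variance) t test is used when neither
#' sample departs from normality, mirroring the convention of gating the
#' test choice on a normality check.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param normality_gate Use Shapiro-Wilk to choose between Student and
#'   Welch.
#' @param alpha Significance level of the normality gate.
#' @return A list of class `"reach_test"`: statistic, df, p, effect_size_d,
#'   ci95, method.
#' @export
welch_t <- function(a, b, normality_gate = FALSE, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  pooled <- FALSE
  if (normality_gate) {
    p_norm <- c(stats::shapiro.test(a)$p.value,
                stats::shapiro.test(b)$p.value)
    pooled <- all(p_norm > alpha)
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value,
                 effect_size_d = .cohens_d_pooled(a, b),
                 ci95 = unname(tt$conf.int),
                 method = if (pooled) "student_t" else "welch_t"),
            class = "reach_test")
}

#' Paired comparison across time points within a group
#'
#' Paired t test on the differences; effect size is mean(diff)/sd(diff).
#' A nonzero constant difference (zero SD) is flagged as degenerate.
#'
#' @param pre,post Numeric samples of equal length (n >= 2).
#' @return A list of class `"reach_test"` (see [welch_t()]); `degenerate`
#'   is TRUE when the difference has zero variance.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  if (length(pre) < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(structure(list(statistic = if (all(d == 0)) 0 else NA_real_,
                          df = length(d) - 1, p = NA_real_,
                          effect_size_d = NA_real_,
                          ci95 = c(mean(d), mean(d)),
                          method = "paired_t", degenerate = TRUE),
                     class = "reach_test"))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 effect_size_d = mean(d) / stats::sd(d),
                 ci95 = unname(tt$conf.int),
                 method = "paired_t", degenerate = FALSE),
            class = "reach_test")
}

#' @export
print.reach_test <- function(x, ...) {
  cat(sprintf("<reach_test> %s: t(%.3g) = %.3f, p = %.4g, d = %.3f\n",
              x$method, x$df, x$statistic, x$p, x$effect_size_d))
  cat(sprintf("  95%% CI [%.3f, %.3f]\n", x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Regression of late learning change on early change
#'
#' Ordinary least-squares regression testing whether the change in hand
#' angle over the remainder of the learning block is predicted by the
#' change from late baseline to early learning.
#'
#' @param early_change Per-subject early change (predictor).
#' @param late_change Per-subject late change (response).
#' @return A list: r2, p (slope test), slope, intercept, n.
#' @export
change_regression <- function(early_change, late_change) {
  if (length(early_change) != length(late_change) ||
      length(early_change) < 3)
    stop("need equal-length samples with n >= 3", call. = FALSE)
  if (stats::var(early_change) == 0)
    stop("zero-variance predictor", call. = FALSE)
  fit <- stats::lm(late_change ~ early_change)
  sm <- summary(fit)
  list(r2 = sm$r.squared,
       p = sm$coefficients["early_change", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)["early_change"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       n = length(early_change))
}
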