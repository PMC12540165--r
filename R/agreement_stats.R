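#' Shapiro-Wilk normality test
#'
#' Normality gate for the modality-comparison battery (Royston's
#' approximation, as implemented in `stats::shapiro.test`).
#'
#' @param values numeric sample, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (diff(range(values)) == 0)
    stop(errorCondition("constant sample: Shapiro-Wilk undefined",
                        class = "stenocfd_degenerate_input"))
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Paired two-group comparison with a normality gate
#'
#' Tests paired differences with Shapiro-Wilk; normally distributed
#' differences (p >= alpha) use a paired t-test, otherwise the Wilcoxon
#' signed-rank test (zero differences dropped per Wilcoxon's convention,
#' exact null enumeration for small samples without ties, normal
#' approximation with continuity correction otherwise).
#'
#' Differences that are zero to within double-precision noise (below
#' `1e-12` of the measurement scale) are treated as exact zeros, so pairs
#' identical up to numerical round-off are degenerate rather than randomly
#' signed.
#'
#' @param a,b paired measurements (equal length >= 3).
#' @param alpha normality-gate level (default 0.05).
#' @return List with `test_name`, `statistic`, `p_value`,
#'   `mean_difference`, `normality_p` and `degenerate` flag.
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("paired samples must have equal length >= 3", call. = FALSE)
  d <- a - b
  scale <- max(abs(c(a, b)), na.rm = TRUE)
  d[abs(d) <= 1e-12 * scale] <- 0
  if (all(d == 0))
    return(list(test_name = "degenerate", statistic = NA_real_, p_value = 1,
                mean_difference = 0, normality_p = NA_real_, degenerate = TRUE))
  norm_p <- tryCatch(shapiro_wilk(d)$p, stenocfd_degenerate_input = function(e) 0)
  if (norm_p >= alpha) {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(test_name = "paired t", statistic = unname(tt$statistic),
         p_value = tt$p.value, mean_difference = mean(d),
         normality_p = norm_p, degenerate = FALSE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              correct = TRUE))
    list(test_name = "wilcoxon signed-rank", statistic = unname(wt$statistic),
         p_value = wt$p.value, mean_difference = mean(d),
         normality_p = norm_p, degenerate = FALSE)
  }
}

#' Kruskal-Wallis comparison among groups
#'
#' Rank-based k-group comparison with tie correction; chi-squared p-value
#' on k - 1 degrees of freedom.
#'
#' @param groups list of numeric samples (>= 2 groups, total n >= 5).
#' @return List with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required", call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 1L) || sum(ns) < 5L)
    stop("each group needs n >= 1 and total n >= 5", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  if (diff(range(pooled)) == 0)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), ns))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Bland-Altman bias and 95\% limits of agreement
#'
#' Mean difference `a - b` and limits of agreement `bias +/- 1.96 * SD` of
#' the paired differences.
#'
#' @param a,b paired measurements (equal length >= 3).
#' @return List with `mean_difference`, `loa_lower`, `loa_upper`,
#'   `sd_difference`, and plot data (`means`, `differences`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("paired samples must have equal length >= 3", call. = FALSE)
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  list(mean_difference = bias,
       loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_difference = s,
       means = (a + b) / 2, differences = d)
}

#' Absolute-agreement intraclass correlation ICC(2,1)
#'
#' Single-measure absolute-agreement ICC from the two-way random-effects
#' ANOVA decomposition,
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))}
#' with an F-based 95\% confidence interval (McGraw & Wong).
#'
#' @param a,b paired measurements by the two raters/modalities (n >= 3).
#' @param conf confidence level (default 0.95).
#' @return An object of class `agreement_result`: list with `icc`,
#'   `icc_ci_lower`, `icc_ci_upper`, and the mean squares `ms_rows`,
#'   `ms_cols`, `ms_error`.
#' @export
icc_absolute <- function(a, b, conf = 0.95) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("ICC(2,1) requires two equal-length samples with n >= 3", call. = FALSE)
  x <- cbind(a, b)
  n <- nrow(x); k <- 2L
  if (diff(range(x)) == 0)
    stop(errorCondition("zero total variance: ICC undefined",
                        class = "stenocfd_degenerate_input"))
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # F-based CI (McGraw & Wong 1996, case A-1)
  alpha <- 1 - conf
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) * (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, icc_ci_lower = lower, icc_ci_upper = upper,
                 ms_rows = msr, ms_cols = msc, ms_error = mse),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<ICC(2,1)> %.3f (95%% CI %.3f-%.3f)\n",
              x$icc, x$icc_ci_lower, x$icc_ci_upper))
  invisible(x)
}

#' One-row agreement summary for a parameter across two modalities
#'
#' Combines the paired comparison, Bland-Altman and ICC(2,1) into the row
#' format of the agreement output table.
#'
#' @param a,b paired measurements.
#' @param parameter parameter name.
#' @param alpha normality-gate level.
#' @return One-row data frame: `parameter`, `mean_diff`, `loa_lower`,
#'   `loa_upper`, `icc`, `icc_ci_lower`, `icc_ci_upper`, `test`, `p`.
#' @export
agreement_summary <- function(a, b, parameter, alpha = 0.05) {
  ba <- bland_altman(a, b)
  icc <- tryCatch(icc_absolute(a, b),
                  stenocfd_degenerate_input = function(e)
                    list(icc = if (all(a == b)) 1 else NA_real_,
                         icc_ci_lower = NA_real_, icc_ci_upper = NA_real_))
  pc <- paired_compare(a, b, alpha)
  data.frame(parameter = parameter,
             mean_diff = ba$mean_difference,
             loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
             icc = icc$icc, icc_ci_lower = icc$icc_ci_lower,
             icc_ci_upper = icc$icc_ci_upper,
             test = pc$test_name, p = pc$p_value,
             stringsAsFactors = FALSE)
}

#' Distribution-aware summary string
#'
#' Formats a sample as `mean (SD)` when the Shapiro-Wilk gate accepts
#' normality and `median [Q1, Q3]` otherwise, mirroring the reporting
#' convention of the comparison tables.
#'
#' @param values numeric sample.
#' @param alpha normality-gate level.
#' @param digits significant digits.
#' @return A character scalar.
#' @export
summarize_distribution <- function(values, alpha = 0.05, digits = 4) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || diff(range(values)) == 0)
    return(sprintf("%.*g (degenerate)", digits, mean(values)))
  p <- shapiro_wilk(values)$p
  if (p >= alpha) {
    sprintf("%.*g (%.*g)", digits, mean(values), digits, stats::sd(values))
  } else {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.*g [%.*g, %.*g]", digits, q[2], digits, q[1], digits, q[3])
  }
}
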