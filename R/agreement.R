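#' Systematic measurement bias between two methods
#'
#' One-sample t-test of paired differences against zero: the group-level
#' "equivalent estimates" criterion of method-agreement guidelines.
#'
#' @param diffs paired differences (method A minus method B), kcal/min.
#' @param conf_level confidence level for the bias CI.
#' @return list: `bias`, `ci` (length 2), `t`, `df`, `p`, `n`. With zero
#'   variance and nonzero mean the t statistic is infinite and `p` is
#'   reported as 0 with a warning; an all-equal-to-zero sample gives
#'   `t = 0`, `p = 1`, CI collapsed at 0.
#' @export
mean_bias <- function(diffs, conf_level = 0.95) {
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 2L) stop_invalid("need at least 2 differences")
  m <- mean(diffs)
  if (stats::sd(diffs) == 0) {
    if (m != 0)
      warning("degenerate zero-variance differences with nonzero mean; ",
              "t is infinite", call. = FALSE)
    return(list(bias = m, ci = c(m, m),
                t = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1L, p = if (m == 0) 1 else 0, n = n))
  }
  tt <- stats::t.test(diffs, mu = 0, conf.level = conf_level)
  list(bias = m, ci = as.numeric(tt$conf.int),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = n)
}

#' Bland-Altman 95% limits of agreement
#'
#' `bias +/- 1.96 x SD` of the paired differences (sample SD, n-1
#' denominator), the classic absolute-agreement interval.
#'
#' @param diffs paired differences.
#' @param multiplier normal quantile; 1.96 by convention.
#' @return list: `bias`, `sd`, `loa_lower`, `loa_upper`.
#' @export
limits_of_agreement <- function(diffs, multiplier = 1.96) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2L) stop_invalid("need at least 2 differences")
  m <- mean(diffs); s <- stats::sd(diffs)
  list(bias = m, sd = s,
       loa_lower = m - multiplier * s, loa_upper = m + multiplier * s)
}

#' Pearson correlation between two methods
#'
#' @param a,b paired measurements (equal length, n >= 3, both nonconstant).
#' @return list: `r`, `p` (two-sided, t-transform), `n`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("'a' and 'b' must be equal length")
  if (length(a) < 3L) stop_invalid("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_invalid("correlation undefined: constant input")
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Two-way random-effects absolute-agreement ICC, single measures
#'
#' ICC(A,1) from the two-way mean squares of a complete subjects-by-methods
#' table (rows = subjects, columns = methods):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' Unlike consistency ICCs it penalises systematic between-method offsets,
#' which is why it accompanies Pearson r in validation batteries.
#'
#' @param x numeric matrix or data frame, subjects in rows, methods in
#'   columns (k >= 2, n >= 3, no missing cells).
#' @return list: `icc`, mean squares (`msr`, `msc`, `mse`), `n`, `k`.
#' @export
icc_absolute <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_invalid("incomplete table: missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop_invalid("need at least 3 subjects")
  if (k < 2L) stop_invalid("need at least 2 methods")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Does activity intensity level affect measurement bias?
#'
#' One-way ANOVA of paired differences across intensity levels, followed by
#' least-significant-difference pairwise comparisons (two-sample t with the
#' ANOVA pooled variance) whose p-values are Bonferroni-corrected by
#' multiplying by the number of pairs N(N-1)/2 and capping at 1.
#'
#' @param diffs paired differences.
#' @param level factor (or coercible) of intensity levels, same length.
#' @return list of class `bias_anova`: `F`, `df` (numerator, denominator),
#'   `p`, per-level means `level_means`, and `pairwise` data frame with raw
#'   and Bonferroni-adjusted p-values. Levels with fewer than 2
#'   observations are excluded with a warning.
#' @export
bias_anova_by_level <- function(diffs, level) {
  diffs <- as.numeric(diffs)
  level <- factor(level)
  if (length(diffs) != length(level)) stop_invalid("length mismatch")
  cnt <- table(level)
  bad <- names(cnt)[cnt < 2L]
  if (length(bad)) {
    warning("excluding level(s) with < 2 observations: ",
            paste(bad, collapse = ", "), call. = FALSE)
    keep <- !(level %in% bad)
    diffs <- diffs[keep]; level <- droplevels(level[keep])
  }
  if (nlevels(level) < 2L) stop_invalid("need at least 2 usable levels")
  fit <- stats::lm(diffs ~ level)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  means <- tapply(diffs, level, mean)
  ns <- tapply(diffs, level, length)
  lv <- levels(level)
  pairs <- utils::combn(lv, 2L)
  n_pairs <- ncol(pairs)
  p_raw <- numeric(n_pairs); est <- numeric(n_pairs)
  for (j in seq_len(n_pairs)) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    est[j] <- means[[i1]] - means[[i2]]
    se <- sqrt(mse * (1 / ns[[i1]] + 1 / ns[[i2]]))
    p_raw[j] <- 2 * stats::pt(abs(est[j] / se), df_err, lower.tail = FALSE)
  }
  pairwise <- data.frame(level_a = pairs[1L, ], level_b = pairs[2L, ],
                         diff = est, p_raw = p_raw,
                         p_adj = pmin(1, p_raw * n_pairs))
  structure(list(F = an["level", "F value"],
                 df = c(an["level", "Df"], df_err),
                 p = an["level", "Pr(>F)"],
                 level_means = data.frame(level = lv,
                                          n = as.vector(ns[lv]),
                                          bias = as.vector(means[lv])),
                 pairwise = pairwise),
            class = "bias_anova")
}

#' @export
print.bias_anova <- function(x, ...) {
  cat(sprintf("Bias-by-level ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$df[1L], x$df[2L], x$F, x$p))
  print(x$level_means, row.names = FALSE)
  cat("Bonferroni-corrected pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-individual measurement biases
#'
#' Group-level agreement can mask offsetting individual biases; this
#' tabulates each participant's mean difference, sorted by magnitude.
#'
#' @param diffs paired differences.
#' @param participant participant id, same length.
#' @return data frame (`participant`, `n`, `bias`) sorted by |bias|
#'   decreasing.
#' @export
per_individual_biases <- function(diffs, participant) {
  if (length(diffs) != length(participant)) stop_invalid("length mismatch")
  participant <- factor(participant)
  out <- data.frame(participant = levels(participant),
                    n = as.vector(table(participant)),
                    bias = as.vector(tapply(as.numeric(diffs), participant, mean)))
  out[order(abs(out$bias), decreasing = TRUE), , drop = FALSE]
}

#' Time-synchronized group-level measurement pattern
#'
#' Per protocol minute, the mean across participants for each method —
#' the "pattern agreement" view that exposes physiological lag at bout
#' transitions.
#'
#' @param x long data frame with columns `participant`, `minute`, `method`,
#'   `value`.
#' @param min_participants minutes covered by fewer participants than this
#'   are flagged (`flagged = TRUE`), not dropped.
#' @return data frame: `minute`, `method`, `mean`, `n`, `flagged`.
#' @export
time_synchronized_group_pattern <- function(x, min_participants = 1L) {
  req <- c("participant", "minute", "method", "value")
  if (!all(req %in% names(x)))
    stop_invalid("'x' must have columns ", paste(req, collapse = ", "))
  agg <- stats::aggregate(value ~ minute + method, data = x, FUN = mean)
  n <- stats::aggregate(value ~ minute + method, data = x, FUN = length)
  out <- data.frame(minute = agg$minute, method = agg$method,
                    mean = agg$value, n = n$value)
  out$flagged <- out$n < min_participants
  out[order(out$method, out$minute), , drop = FALSE]
}

#' Full agreement battery for one method pair
#'
#' Runs the complete validation-statistics battery on paired measurements:
#' systematic-bias t-test, Bland-Altman limits of agreement, Pearson
#' correlation, absolute-agreement ICC, and (when levels are supplied)
#' bias-by-intensity ANOVA with Bonferroni pairwise comparisons, plus
#' per-individual biases when participant ids are supplied.
#'
#' @param a,b paired measurements (method A, method B), kcal/min.
#' @param level optional intensity level per pair.
#' @param participant optional participant id per pair. The ICC table uses
#'   participant means when ids are given (subjects x methods), else raw
#'   pairs as rows.
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(a, b, level = NULL, participant = NULL) {
  if (length(a) != length(b)) stop_invalid("'a' and 'b' must be equal length")
  d <- as.numeric(a) - as.numeric(b)
  icc_tab <- if (!is.null(participant)) {
    cbind(a = tapply(a, factor(participant), mean),
          b = tapply(b, factor(participant), mean))
  } else cbind(a = a, b = b)
  rep <- list(
    n = length(a),
    bias = mean_bias(d),
    loa = limits_of_agreement(d),
    pearson = pearson_r(a, b),
    icc = if (nrow(icc_tab) >= 3L) icc_absolute(icc_tab),
    by_level = if (!is.null(level) && nlevels(factor(level)) >= 2L)
      bias_anova_by_level(d, level),
    individual = if (!is.null(participant)) per_individual_biases(d, participant))
  class(rep) <- "agreement_report"
  rep
}

#' @export
print.agreement_report <- function(x, ...) {
  b <- x$bias
  cat(sprintf("Agreement report (n = %d pairs)\n", x$n))
  cat(sprintf("  bias = %.2f [%.2f to %.2f] kcal/min, t(%s) = %.2f, p = %.3g\n",
              b$bias, b$ci[1L], b$ci[2L], format(b$df), b$t, b$p))
  cat(sprintf("  95%% LoA: %.2f to %.2f kcal/min\n",
              x$loa$loa_lower, x$loa$loa_upper))
  cat(sprintf("  Pearson r = %.2f (p = %.3g)", x$pearson$r, x$pearson$p))
  if (!is.null(x$icc)) cat(sprintf(", ICC(A,1) = %.2f", x$icc$icc))
  cat("\n")
  if (!is.null(x$by_level)) {
    cat("\n"); print(x$by_level)
  }
  invisible(x)
}
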