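## Two-group comparison of per-subject features: per-group one-sample
## Kolmogorov-Smirnov normality screen, then a pooled Student's t-test when
## both groups pass or a Mann-Whitney U test otherwise. Group summaries use
## the sample (divide-by-(n-1)) SD, as printed in cohort tables; all
## p-values are two-tailed and no multiple-testing correction is applied.

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' KS statistic against a normal with the sample's own mean and SD,
#' p-value from the asymptotic KS distribution. `method = "lilliefors"`
#' applies the Lilliefors correction for the estimated parameters instead.
#' A constant sample returns p = 0 (flagged with a warning): it is
#' certainly non-normal for screening purposes.
#'
#' @param values numeric vector, n >= 4.
#' @param method `"asymptotic"` (default) or `"lilliefors"`.
#' @return Two-sided p-value.
#' @export
ks_normality <- function(values, method = c("asymptotic", "lilliefors")) {
  method <- match.arg(method)
  if (length(values) < 4L) stop("normality screen needs n >= 4", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("constant sample: normality p-value set to 0", call. = FALSE)
    return(0)
  }
  if (method == "lilliefors") {
    return(unname(nortest::lillie.test(values)$p.value))
  }
  suppressWarnings(  # ties warning: feature values can coincide
    unname(stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value))
}

#' Two-sample Student's t-test on raw values
#'
#' Pooled-variance two-sample t (df = n_a + n_b - 2), two-tailed; set
#' `welch = TRUE` for the unequal-variance variant.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param welch use the Welch (unequal-variance) form.
#' @return List with `statistic`, `df`, `p`.
#' @export
student_t <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    stop("zero pooled variance: t statistic undefined", call. = FALSE)
  }
  ht <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Student's t-test from group summary statistics
#'
#' The pooled two-sample t computed from (n, mean, sample SD) alone —
#' exactly what a printed "mean ± SD" table provides. Identical to
#' [student_t()] on any raw samples having those summaries.
#'
#' @param n_a,mean_a,sd_a,n_b,mean_b,sd_b group summaries (sample SD,
#'   divide-by-(n-1)).
#' @param welch use the Welch form with Welch-Satterthwaite df.
#' @return List with `statistic`, `df`, `p`.
#' @export
#' @examples
#' # age comparison: 19 cases 33.79 +/- 9.97 vs 20 controls 32.745 +/- 8.50
#' summary_student_t(19, 33.79, 9.97, 20, 32.745, 8.50)$p
summary_student_t <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b,
                              welch = FALSE) {
  if (n_a < 2L || n_b < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd_a == 0 && sd_b == 0) {
    stop("zero pooled variance: t statistic undefined", call. = FALSE)
  }
  if (welch) {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  t <- (mean_a - mean_b) / se
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling: exact enumeration when
#' n_a + n_b <= 12 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections. U is reported for
#' the first group (swapping groups maps U to n_a * n_b - U, p unchanged).
#'
#' @param values_a,values_b numeric vectors (each n >= 1).
#' @return List with `statistic` (U) and `p` (two-tailed).
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) < 1L || length(values_b) < 1L) {
    stop("each group needs n >= 1", call. = FALSE)
  }
  ties <- any(duplicated(c(values_a, values_b)))
  exact <- (length(values_a) + length(values_b) <= 12L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

## display names for the comparison rows, in canonical table order
feature_display_names <- function() {
  c(mean = "Mean", sd = "Standard deviation", min = "Minimum",
    max = "Maximum", median = "Median", variance = "Variance",
    entropy = "Entropy", size_pct_lower = "Size %Lower",
    size_pct_upper = "Size %Upper", size_pct_mean = "Size %Mean",
    kurtosis = "Kurtosis", skewness = "Skewness", uniformity = "Uniformity",
    area_cm2 = "Area (cm2)")
}

#' Compare two cohorts feature by feature
#'
#' For each of the 14 features: a KS normality screen on each group; if
#' both groups pass (p > 0.05) the groups are compared with the pooled
#' Student's t-test, otherwise with the Mann-Whitney U test. Rows follow
#' the canonical table order. No multiple-testing correction is applied.
#'
#' @param feature_table data frame with `group` (values `control` /
#'   `case`) and the feature columns (see [write_feature_table()]).
#' @param alpha two-tailed significance level.
#' @param ks_method normality screen variant, see [ks_normality()].
#' @param welch use the Welch t variant when the t-test is selected.
#' @return A `cohort_comparison` data frame: one row per feature with group
#'   summaries (sample SD), `test_used`, `statistic`, `df`, `p_two_tailed`,
#'   `significant`.
#' @export
compare_cohorts <- function(feature_table, alpha = 0.05,
                            ks_method = "asymptotic", welch = FALSE) {
  if (!"group" %in% names(feature_table)) {
    stop("feature table lacks a 'group' column", call. = FALSE)
  }
  groups <- unique(feature_table$group)
  if (!setequal(groups, c("control", "case"))) {
    stop("group column must contain exactly 'control' and 'case'", call. = FALSE)
  }
  missing <- setdiff(feature_columns(), names(feature_table))
  if (length(missing)) {
    stop(sprintf("feature table lacks columns: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  ctrl <- feature_table[feature_table$group == "control", , drop = FALSE]
  case <- feature_table[feature_table$group == "case", , drop = FALSE]
  if (nrow(ctrl) < 2L || nrow(case) < 2L) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  rows <- lapply(feature_columns(), function(fc) {
    xa <- case[[fc]]; xb <- ctrl[[fc]]   # case - control direction
    ok <- is.finite(xa) & !is.na(xa)
    xa <- xa[ok]; xb <- xb[is.finite(xb) & !is.na(xb)]
    base <- data.frame(
      feature = unname(feature_display_names()[fc]), feature_key = fc,
      n_control = length(xb), mean_control = mean(xb), sd_control = stats::sd(xb),
      n_case = length(xa), mean_case = mean(xa), sd_case = stats::sd(xa),
      stringsAsFactors = FALSE)
    if (length(xa) < 4L || length(xb) < 4L || stats::sd(xa) == 0 || stats::sd(xb) == 0) {
      normal <- FALSE   # too few / degenerate: rank test
    } else {
      normal <- ks_normality(xa, method = ks_method) > 0.05 &&
                ks_normality(xb, method = ks_method) > 0.05
    }
    res <- if (normal) {
      tt <- student_t(xa, xb, welch = welch)
      data.frame(test_used = "student_t", statistic = tt$statistic,
                 df = tt$df, p_two_tailed = tt$p, stringsAsFactors = FALSE)
    } else {
      mw <- mann_whitney(xa, xb)
      data.frame(test_used = "mann_whitney", statistic = mw$statistic,
                 df = NA_real_, p_two_tailed = mw$p, stringsAsFactors = FALSE)
    }
    cbind(base, res)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_two_tailed < alpha
  structure(out, alpha = alpha, class = c("cohort_comparison", "data.frame"))
}

#' @export
print.cohort_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Two-group feature comparison (alpha = %g, two-tailed)\n",
              attr(x, "alpha")))
  df <- data.frame(
    feature = x$feature,
    control = sprintf("%.2f ± %.2f", x$mean_control, x$sd_control),
    case = sprintf("%.2f ± %.2f", x$mean_case, x$sd_case),
    test = x$test_used,
    p = signif(x$p_two_tailed, digits),
    sig = ifelse(x$significant, "*", ""))
  print(df, row.names = FALSE)
  cat("KS screen selects pooled t (both groups normal) or Mann-Whitney U.\n")
  cat("No multiple-testing correction applied.\n")
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param comparison a `cohort_comparison` from [compare_cohorts()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(comparison, path) {
  df <- as.data.frame(comparison)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA, formatC(v, digits = 15, format = "g")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}
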