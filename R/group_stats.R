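#' Descriptive statistics with a choice of SD convention
#'
#' Mean and standard deviation of a numeric vector. The default SD divides the
#' summed squared deviations by `n` ("population"), which is the convention
#' that reproduces the published cohort's tabulated mean +/- SD values; the
#' usual `n - 1` ("sample") divisor is available for inference-oriented use.
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @param sd_mode `"population"` (divide by n, default) or `"sample"`.
#' @return One-row tibble: `n`, `mean`, `sd`, `sd_mode`.
#' @examples
#' describe_values(c(1, 2, 3))            # sd = sqrt(2/3)
#' describe_values(c(1, 2, 3), "sample")  # sd = 1
#' @export
describe_values <- function(values, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) {
    qrsqtc_abort("cannot describe an empty vector", "qrsqtc_domain_error")
  }
  m <- mean(values)
  s <- if (n == 1) 0 else {
    ss <- sum((values - m)^2)
    sqrt(ss / if (sd_mode == "population") n else n - 1)
  }
  tibble::tibble(n = n, mean = m, sd = s, sd_mode = sd_mode)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] returning a tidy one-row tibble.
#'
#' @param values Numeric vector with 3 <= n <= 5000.
#' @return Tibble with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    qrsqtc_abort("Shapiro-Wilk requires 3 <= n <= 5000", "qrsqtc_domain_error")
  }
  r <- shapiro.test(values)
  tibble::tibble(statistic = unname(r$statistic), p_value = r$p.value)
}

#' Brown-Forsythe test of equal variances (two groups)
#'
#' Levene-type test on absolute deviations from the group medians: a one-way
#' ANOVA of \eqn{z_{ij} = |x_{ij} - \tilde x_i|} on group. Robust to
#' non-normality, which is why it is the usual gate before a pooled-variance
#' t-test on small clinical cohorts. When both groups are constant the test is
#' degenerate and `F = 0`, `p = 1` is returned by convention.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2 (NAs dropped).
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
brown_forsythe <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    qrsqtc_abort("Brown-Forsythe requires n >= 2 in each group",
                 "qrsqtc_domain_error")
  }
  z <- c(abs(group_a - median(group_a)), abs(group_b - median(group_b)))
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  df1 <- 1L
  df2 <- length(z) - 2L
  if (all(z == z[1])) {
    return(tibble::tibble(statistic = 0, df1 = df1, df2 = df2, p_value = 1))
  }
  tab <- anova(lm(z ~ g))
  tibble::tibble(
    statistic = tab[["F value"]][1],
    df1 = tab[["Df"]][1],
    df2 = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Pooled-variance two-sample t-test
#'
#' Student's unpaired t-test with pooled variance (equal variances assumed;
#' the Brown-Forsythe gate justifies the pooling on this cohort), two-tailed,
#' with `df = n_a + n_b - 2`. Delegates to [stats::t.test()] except in the
#' zero-variance degenerate cases: identical constant groups give `t = 0`,
#' `p = 1`; constant groups with different means are an error. Welch's
#' unequal-variance test is available via `var_equal = FALSE` for sensitivity
#' analysis.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2 (NAs dropped).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return Tibble with `statistic` (t, sign follows `group_a - group_b`),
#'   `df`, `p_value` (two-tailed).
#' @export
pooled_t_test <- function(group_a, group_b, var_equal = TRUE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) {
    qrsqtc_abort("t-test requires n >= 2 in each group", "qrsqtc_domain_error")
  }
  pooled_ss <- sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)
  if (pooled_ss == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(tibble::tibble(statistic = 0, df = na + nb - 2, p_value = 1))
    }
    qrsqtc_abort("zero pooled variance with unequal means", "qrsqtc_domain_error")
  }
  r <- t.test(group_a, group_b, var.equal = var_equal)
  tibble::tibble(
    statistic = unname(r$statistic),
    df = unname(r$parameter),
    p_value = r$p.value
  )
}

comparison_variables <- c("ratio", "qrs_ms", "qtc_ms", "hr_bpm")

#' Compare VT/VF outcome groups on one ECG variable
#'
#' Runs the full small-cohort pipeline on one variable split by the VT/VF
#' outcome: per-group descriptives (population SD), Shapiro-Wilk normality per
#' group, Brown-Forsythe equal-variance test, and the two-tailed pooled
#' t-test, with significance declared at `alpha`.
#'
#' For `variable = "ratio"` the QRS/QTc values are, by default, the ratios
#' rounded half-up to 2 decimals (`ratio_digits = 2`) — i.e. the values as
#' they were tabulated and analysed in the source publication; pass
#' `ratio_digits = NULL` for full precision (group means agree at printed
#' precision either way).
#'
#' @param cohort A cohort tibble with both outcomes represented, n >= 3 each.
#' @param variable One of `"ratio"`, `"qrs_ms"`, `"qtc_ms"`, `"hr_bpm"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param sd_mode SD convention for the descriptives, see [describe_values()].
#' @param ratio_digits Rounding for the ratio column, see [cohort_ratio()].
#' @return A `group_comparison` object; use [tidy()] for the per-group
#'   descriptives and [glance()] for a one-row summary.
#' @examples
#' cmp <- compare_groups(load_cohort(), "ratio")
#' glance(cmp)$p_value   # < 0.0005
#' @export
compare_groups <- function(cohort, variable = comparison_variables,
                           alpha = 0.05, sd_mode = "population",
                           ratio_digits = 2) {
  variable <- match.arg(variable)
  cohort <- validate_cohort(cohort)
  values <- if (variable == "ratio") {
    cohort_ratio(cohort, digits = ratio_digits)
  } else {
    cohort[[variable]]
  }
  yes <- values[cohort$vt_vf]
  no <- values[!cohort$vt_vf]
  if (length(yes) < 3) {
    qrsqtc_abort("vt_vf = TRUE group has fewer than 3 cases", "qrsqtc_domain_error")
  }
  if (length(no) < 3) {
    qrsqtc_abort("vt_vf = FALSE group has fewer than 3 cases", "qrsqtc_domain_error")
  }
  des_yes <- describe_values(yes, sd_mode)
  des_no <- describe_values(no, sd_mode)
  sw_yes <- shapiro_wilk(yes)
  sw_no <- shapiro_wilk(no)
  bf <- brown_forsythe(yes, no)
  tt <- pooled_t_test(yes, no)
  structure(
    list(
      variable = variable,
      alpha = alpha,
      data = tibble::tibble(
        group = rep(c("vt_vf", "no_vt_vf"), c(length(yes), length(no))),
        value = c(yes, no)
      ),
      groups = dplyr::bind_rows(
        dplyr::mutate(des_yes, group = "vt_vf",
                      shapiro_w = sw_yes$statistic, shapiro_p = sw_yes$p_value),
        dplyr::mutate(des_no, group = "no_vt_vf",
                      shapiro_w = sw_no$statistic, shapiro_p = sw_no$p_value)
      ),
      brown_forsythe = bf,
      t_test = tt,
      significant = tt$p_value < alpha
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  g <- glance(x)
  cat("Two-group comparison of", x$variable, "by VT/VF outcome\n")
  cat(sprintf("  vt_vf:    n = %d, mean = %.4g, sd = %.4g\n",
              g$n_yes, g$mean_yes, g$sd_yes))
  cat(sprintf("  no vt_vf: n = %d, mean = %.4g, sd = %.4g\n",
              g$n_no, g$mean_no, g$sd_no))
  cat(sprintf("  Shapiro-Wilk p: %.3f / %.3f;  Brown-Forsythe p: %.3f\n",
              g$shapiro_p_yes, g$shapiro_p_no, g$brown_forsythe_p))
  cat(sprintf("  pooled t = %.3f, df = %d, two-tailed p = %.3g (%ssignificant at alpha = %g)\n",
              g$statistic, g$df, g$p_value,
              if (g$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  dplyr::select(
    dplyr::mutate(x$groups, variable = x$variable),
    "variable", "group", "n", "mean", "sd", "sd_mode", "shapiro_w", "shapiro_p"
  )
}

#' @rdname compare_groups
#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  g <- x$groups
  yes <- g[g$group == "vt_vf", ]
  no <- g[g$group == "no_vt_vf", ]
  tibble::tibble(
    variable = x$variable,
    n_yes = yes$n, mean_yes = yes$mean, sd_yes = yes$sd,
    n_no = no$n, mean_no = no$mean, sd_no = no$sd,
    shapiro_p_yes = yes$shapiro_p, shapiro_p_no = no$shapiro_p,
    brown_forsythe_p = x$brown_forsythe$p_value,
    statistic = x$t_test$statistic,
    df = as.integer(x$t_test$df),
    p_value = x$t_test$p_value,
    significant = x$significant
  )
}

#' Compare the outcome groups on all four ECG variables
#'
#' @inheritParams compare_groups
#' @param variables Variables to compare (default all four).
#' @return A tibble with one [glance()] row per variable.
#' @export
compare_all_groups <- function(cohort, variables = comparison_variables,
                               alpha = 0.05, sd_mode = "population",
                               ratio_digits = 2) {
  purrr::map_dfr(variables, function(v) {
    glance(compare_groups(cohort, v, alpha = alpha, sd_mode = sd_mode,
                          ratio_digits = ratio_digits))
  })
}

#' Box-plot summary (median, quartiles, 5th/95th percentiles)
#'
#' The five-number summary used in the cohort's figures: solid line at the
#' median, box from the 25th to the 75th percentile, error bars at the 5th and
#' 95th. Percentiles use the linear-interpolation convention
#' ([stats::quantile()] type 7).
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @return One-row tibble: `median`, `p25`, `p75`, `p5`, `p95`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    qrsqtc_abort("cannot summarise an empty vector", "qrsqtc_domain_error")
  }
  q <- quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  tibble::tibble(median = q[3], p25 = q[2], p75 = q[4], p5 = q[1], p95 = q[5])
}
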