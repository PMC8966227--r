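variable_labels <- c(
  ratio = "QRS/QTc",
  qrs_ms = "QRS (ms)",
  qtc_ms = "QTc (ms)",
  hr_bpm = "Heart rate (bpm)"
)

#' Box-plot of one ECG variable by VT/VF outcome
#'
#' Reproduces the cohort figures' convention: solid line at the median, box
#' from the 25th to the 75th percentile, error bars at the 5th and 95th
#' percentiles, with the individual cases overplotted.
#'
#' @inheritParams compare_groups
#' @return A ggplot object.
#' @examples
#' plot_group_summary(load_cohort(), "ratio")
#' @export
plot_group_summary <- function(cohort, variable = comparison_variables,
                               ratio_digits = 2) {
  variable <- match.arg(variable)
  cohort <- validate_cohort(cohort)
  values <- if (variable == "ratio") {
    cohort_ratio(cohort, digits = ratio_digits)
  } else {
    cohort[[variable]]
  }
  df <- tibble::tibble(
    group = factor(ifelse(cohort$vt_vf, "VT/VF", "No VT/VF"),
                   levels = c("No VT/VF", "VT/VF")),
    value = values
  )
  summ <- dplyr::reframe(dplyr::group_by(df, .data$group),
                         boxplot_summary(.data$value))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$p5, ymax = .data$p95), width = 0.15
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$p25, ymax = .data$p75),
      width = 0.5, fill = "grey90"
    ) +
    ggplot2::geom_jitter(
      data = df, ggplot2::aes(x = .data$group, y = .data$value),
      width = 0.08, height = 0, size = 1.8, alpha = 0.7
    ) +
    ggplot2::labs(x = NULL, y = variable_labels[[variable]]) +
    ggplot2::theme_classic()
}

#' ROC-style plot of a threshold sweep
#'
#' @param sweep A tibble from [threshold_sweep()].
#' @return A ggplot object of sensitivity against 1 - specificity.
#' @export
plot_roc <- function(sweep) {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_classic()
}

#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, ...) {
  df <- object$data
  df$group <- factor(ifelse(df$group == "vt_vf", "VT/VF", "No VT/VF"),
                     levels = c("No VT/VF", "VT/VF"))
  summ <- dplyr::reframe(dplyr::group_by(df, .data$group),
                         boxplot_summary(.data$value))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$p5, ymax = .data$p95), width = 0.15
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$p25, ymax = .data$p75),
      width = 0.5, fill = "grey90"
    ) +
    ggplot2::geom_jitter(
      data = df, ggplot2::aes(x = .data$group, y = .data$value),
      width = 0.08, height = 0, size = 1.8, alpha = 0.7
    ) +
    ggplot2::labs(x = NULL, y = variable_labels[[object$variable]],
                  subtitle = sprintf("pooled t, two-tailed p = %.3g",
                                     object$t_test$p_value)) +
    ggplot2::theme_classic()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ecg_waveform <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(time_s = object$time_s,
                                 voltage = object$voltage),
                  ggplot2::aes(x = .data$time_s, y = .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (a.u.)") +
    ggplot2::theme_classic()
}
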