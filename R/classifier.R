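#' Threshold risk classification by QRS/QTc
#'
#' Classifies ratios against a risk threshold with a strict-inequality rule:
#' a case is predicted high risk when `ratio < threshold`; a ratio exactly at
#' the threshold is low risk. The default threshold of 0.2 is imported from
#' the hypothermia literature where QRS/QTc below 0.2 marked increased risk of
#' cardiac arrest; it is not fitted to this cohort.
#'
#' @param ratio Positive QRS/QTc value(s).
#' @param threshold Positive risk threshold (default 0.2).
#' @return Tibble with `ratio`, `threshold`, `predicted_high_risk`.
#' @examples
#' classify_risk(c(0.19, 0.20, 0.17))$predicted_high_risk # TRUE FALSE TRUE
#' @export
classify_risk <- function(ratio, threshold = 0.2) {
  if (any(ratio <= 0) || threshold <= 0) {
    qrsqtc_abort("ratio and threshold must be positive", "qrsqtc_domain_error")
  }
  tibble::tibble(
    ratio = ratio,
    threshold = threshold,
    predicted_high_risk = ratio < threshold
  )
}

#' Evaluate the threshold classifier against observed VT/VF
#'
#' Confusion counts of the strict `ratio < threshold` rule over a cohort,
#' treating observed VT/VF as the positive class. With only one outcome
#' present the counts are still returned but the undefined rate is `NA`. By
#' default the tabulated 2-decimal ratios are used (see [cohort_ratio()]).
#'
#' @param cohort A cohort tibble.
#' @param threshold Risk threshold, see [classify_risk()].
#' @param ratio_digits Ratio rounding convention, see [cohort_ratio()].
#' @return A `classifier_eval` object with fields `threshold`, `tp`, `fn`,
#'   `fp`, `tn`, `sensitivity`, `specificity`; [tidy()] returns them as a
#'   one-row tibble.
#' @examples
#' ev <- evaluate_classifier(load_cohort(), threshold = 0.2)
#' c(ev$tp, ev$fn, ev$fp, ev$tn) # 7 0 1 8
#' @export
evaluate_classifier <- function(cohort, threshold = 0.2, ratio_digits = 2) {
  cohort <- validate_cohort(cohort)
  pred <- classify_risk(cohort_ratio(cohort, digits = ratio_digits),
                        threshold)$predicted_high_risk
  obs <- cohort$vt_vf
  tp <- sum(pred & obs)
  fn <- sum(!pred & obs)
  fp <- sum(pred & !obs)
  tn <- sum(!pred & !obs)
  structure(
    list(
      threshold = threshold,
      tp = tp, fn = fn, fp = fp, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ),
    class = "classifier_eval"
  )
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("QRS/QTc threshold classifier (high risk if ratio < %g)\n",
              x$threshold))
  cat(sprintf("  tp = %d, fn = %d, fp = %d, tn = %d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity = %.3f, specificity = %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x A `classifier_eval` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.classifier_eval <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    tp = x$tp, fn = x$fn, fp = x$fp, tn = x$tn,
    sensitivity = x$sensitivity, specificity = x$specificity
  )
}

#' Sensitivity/specificity sweep over thresholds
#'
#' Evaluates the classifier at each threshold; sensitivity is non-decreasing
#' and specificity non-increasing in the threshold, so the points trace an ROC
#' curve.
#'
#' @inheritParams evaluate_classifier
#' @param thresholds Numeric vector of positive thresholds (may be empty).
#' @return Tibble with one row per threshold: `threshold`, `tp`, `fn`, `fp`,
#'   `tn`, `sensitivity`, `specificity`.
#' @export
threshold_sweep <- function(cohort, thresholds, ratio_digits = 2) {
  purrr::map_dfr(thresholds, function(th) {
    tidy(evaluate_classifier(cohort, threshold = th, ratio_digits = ratio_digits))
  })
}
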