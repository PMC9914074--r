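#' Classification accuracy in percent
#'
#' @param preds,truths equal-length vectors of event labels.
#' @return `100 * correct / n`.
#' @examples
#' accuracy(c("urine", "stool"), c("urine", "urine")) # 50
#' @export
accuracy <- function(preds, truths) {
  if (length(preds) != length(truths) || length(preds) < 1L) {
    stop("preds and truths must have equal length >= 1", call. = FALSE)
  }
  100 * mean(as_event_label(preds) == as_event_label(truths))
}

#' McNemar's paired chi-square test for two classifiers
#'
#' Compares the accuracy of two classifiers evaluated on the same trials
#' from the discordant-pair counts: `b` trials where only the second
#' classifier is right, `c` trials where only the first is. The
#' continuity-corrected statistic is `(|b - c| - 1)^2 / (b + c)` (the
#' uncorrected variant `(b - c)^2 / (b + c)` is available with
#' `correct = FALSE`); significance is assessed against the chi-square
#' critical value 3.841 at alpha = 0.05. With no discordant pairs the test
#' is not applicable.
#'
#' @param b,c non-negative discordant-pair counts.
#' @param correct apply the continuity correction (default).
#' @param alpha significance level (only 1 df is used).
#' @return list with `statistic`, `applicable`, `significant`, `b`, `c`.
#' @examples
#' paired_chi2(1, 9)  # statistic 4.9, significant
#' @export
paired_chi2 <- function(b, c, correct = TRUE, alpha = 0.05) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    return(list(statistic = NA_real_, applicable = FALSE, significant = FALSE,
                b = b, c = c))
  }
  stat <- if (correct) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
  crit <- stats::qchisq(1 - alpha, df = 1)
  list(statistic = stat, applicable = TRUE, significant = stat > crit,
       b = b, c = c)
}

#' Confusion matrix over the four excretion events
#'
#' @param preds,truths equal-length label vectors.
#' @return a 4x4 integer matrix, rows = truth, columns = prediction, in
#'   canonical A, B, C, D (urine, stool, both, none) order.
#' @export
confusion_matrix <- function(preds, truths) {
  if (length(preds) != length(truths)) {
    stop("preds and truths must have equal length", call. = FALSE)
  }
  lv <- event_labels()
  table(truth = factor(as_event_label(truths), levels = lv),
        prediction = factor(as_event_label(preds), levels = lv))
}

#' Paired comparison report for fused vs direct classification
#'
#' Bundles the accuracies, confusion matrices and the McNemar paired
#' chi-square verdict for the evidence-fusion pipeline against the direct
#' threshold baseline on the same labelled trials.
#'
#' @param truth,fused,direct equal-length event-label vectors.
#' @param correct continuity correction for [paired_chi2()].
#' @return an object of class `comparison_report`: list with `n`,
#'   `accuracy_fused`, `accuracy_direct` (percent), discordant counts `b`
#'   (fused wrong, direct right) and `c` (fused right, direct wrong),
#'   `chi2` (the [paired_chi2()] result) and both confusion matrices.
#' @export
comparison_report <- function(truth, fused, direct, correct = TRUE) {
  truth <- as_event_label(truth)
  fused <- as_event_label(fused)
  direct <- as_event_label(direct)
  b <- sum(fused != truth & direct == truth)
  cc <- sum(fused == truth & direct != truth)
  structure(list(
    n = length(truth),
    accuracy_fused = accuracy(fused, truth),
    accuracy_direct = accuracy(direct, truth),
    b = b, c = cc,
    chi2 = paired_chi2(b, cc, correct = correct),
    confusion_fused = confusion_matrix(fused, truth),
    confusion_direct = confusion_matrix(direct, truth)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison report> n = %d\n", x$n))
  cat(sprintf("  fused accuracy:  %.2f%%\n", x$accuracy_fused))
  cat(sprintf("  direct accuracy: %.2f%%\n", x$accuracy_direct))
  cat(sprintf("  discordant pairs: b = %d (only direct right), c = %d (only fused right)\n",
              x$b, x$c))
  if (x$chi2$applicable) {
    cat(sprintf("  McNemar chi-square = %.3f (%ssignificant at 0.05)\n",
                x$chi2$statistic, if (x$chi2$significant) "" else "not "))
  } else {
    cat("  McNemar chi-square: not applicable (no discordant pairs)\n")
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report a [comparison_report()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  x <- list(n = report$n,
            accuracy_fused = report$accuracy_fused,
            accuracy_direct = report$accuracy_direct,
            b = report$b, c = report$c,
            chi2 = report$chi2$statistic,
            chi2_applicable = report$chi2$applicable,
            significant_at_0.05 = report$chi2$significant,
            confusion_fused = unclass(report$confusion_fused),
            confusion_direct = unclass(report$confusion_direct))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
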