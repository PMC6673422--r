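# Classification metrics for the three-direction task and hit-rate
# evaluation of cecum estimates.

#' 3x3 confusion matrix for the three-direction task
#'
#' Rows index the output (predicted) class, columns the target (true) class,
#' both in the order insertion, withdrawal, stop.
#'
#' @param counts 3x3 matrix of non-negative counts.
#' @return A `confusion_matrix3` with derived `row_sums`, `column_sums`,
#'   `total`.
#' @export
confusion_matrix3 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3))) stop("counts must be 3x3")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(predicted = DIRECTION_LEVELS, true = DIRECTION_LEVELS)
  structure(list(counts = counts, row_sums = rowSums(counts),
                 column_sums = colSums(counts), total = sum(counts)),
            class = "confusion_matrix3")
}

#' @export
print.confusion_matrix3 <- function(x, ...) {
  cat("<confusion_matrix3> rows = predicted, columns = true\n")
  print(x$counts)
  cat("total:", x$total, "\n")
  invisible(x)
}

#' Read / write a confusion matrix as CSV
#'
#' The CSV has a header row and a leading class-name column, classes in the
#' order insertion, withdrawal, stop; rows are predicted, columns true.
#'
#' @param path CSV file path.
#' @return A [confusion_matrix3].
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  confusion_matrix3(as.matrix(df[DIRECTION_LEVELS, DIRECTION_LEVELS]))
}

#' @rdname read_confusion_csv
#' @param cm A [confusion_matrix3] to write.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$counts), path)
  invisible(path)
}

#' Per-class and overall classification metrics
#'
#' For class c: recall = diagonal / column sum (fraction of true-c samples
#' recovered), precision = diagonal / row sum (fraction of predicted-c
#' samples correct), F1 = harmonic mean of the two; overall accuracy =
#' trace / total. A class absent from the truth (zero column sum) has recall
#' 0, one never predicted (zero row sum) has precision 0; both emit a
#' warning.
#'
#' @param cm A [confusion_matrix3] (or plain 3x3 matrix).
#' @return List with `per_class` (data frame: class, recall, precision, f1)
#'   and `overall_accuracy`.
#' @export
compute_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix3")) cm <- confusion_matrix3(cm)
  if (cm$total == 0) stop("empty confusion matrix")
  dg <- diag(cm$counts)
  if (any(cm$column_sums == 0) || any(cm$row_sums == 0))
    warning("class with zero row or column sum; its metric is reported as 0")
  recall <- ifelse(cm$column_sums > 0, dg / cm$column_sums, 0)
  precision <- ifelse(cm$row_sums > 0, dg / cm$row_sums, 0)
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  list(per_class = data.frame(class = DIRECTION_LEVELS, recall = unname(recall),
                              precision = unname(precision), f1 = unname(f1)),
       overall_accuracy = sum(dg) / cm$total)
}

#' Did a cecum estimate hit the true cecum time?
#'
#' A hit means the true cecum lies within the +/- t/2 interval around the
#' estimate.
#'
#' @param estimate A [cecum_estimate] (or a numeric time in seconds).
#' @param truth_time True cecum time (seconds).
#' @param t Interval width in seconds (> 0).
#' @return Logical.
#' @export
cecum_hit <- function(estimate, truth_time, t) {
  if (t <= 0) stop("t must be > 0")
  est_time <- if (inherits(estimate, "cecum_estimate")) estimate$time else estimate
  if (is.na(est_time)) return(FALSE)
  abs(est_time - truth_time) <= t / 2
}

#' Cecum-discovery accuracy as a function of the window width t
#'
#' Runs [locate_cecum()] on each signal at each t and reports the fraction of
#' estimates that hit the true cecum time.
#'
#' @param signals List of elements, each a list with `signal` (a
#'   [direction_signal]) and `truth_time` (seconds).
#' @param t_values Numeric vector of window widths (seconds).
#' @return Data frame with columns `t` and `accuracy`.
#' @export
accuracy_vs_t <- function(signals, t_values = c(10, 20, 30)) {
  if (length(signals) == 0 || length(t_values) == 0) stop("empty input")
  acc <- vapply(t_values, function(t) {
    hits <- vapply(signals, function(s) {
      est <- locate_cecum(s$signal, t)
      cecum_hit(est, s$truth_time, t)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  data.frame(t = t_values, accuracy = acc)
}
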