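#' Confusion counts from per-examination predictions
#'
#' Tallies true/false positives and negatives with high grade as the
#' positive class. `TP + FP + TN + FN` always equals the number of
#' examinations.
#'
#' @param predictions Character vector of predicted labels
#'   (`"high"`/`"low"`).
#' @param labels Character vector of ground-truth labels, same length.
#' @return An object of class `confusion_counts` (fields `TP`, `FP`, `TN`,
#'   `FN`).
#' @examples
#' confusion_from_predictions(c("high", "low"), c("high", "high"))
#' @export
confusion_from_predictions <- function(predictions, labels) {
  assert_that(length(predictions) == length(labels),
              "predictions and labels differ in length")
  assert_that(length(predictions) > 0, "no examinations to tally")
  assert_that(all(predictions %in% label_levels) &&
                all(labels %in% label_levels),
              "values must be 'high' or 'low'")
  confusion_counts(
    TP = sum(predictions == "high" & labels == "high"),
    FP = sum(predictions == "high" & labels == "low"),
    TN = sum(predictions == "low" & labels == "low"),
    FN = sum(predictions == "low" & labels == "high")
  )
}

#' Construct confusion counts directly
#'
#' @param TP,FP,TN,FN Nonnegative integer counts; positive = high grade.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  for (v in list(TP, FP, TN, FN)) {
    assert_that(is_count(v), "counts must be nonnegative integers")
  }
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 TN = as.integer(TN), FN = as.integer(FN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' Diagnostic metrics from confusion counts
#'
#' Computes, as percentages: accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)` and
#' negative predictive value `TN/(TN+FN)`. Full precision is retained in
#' `value`; `display` carries the nearest-integer rounding used in reports.
#' A metric with a zero denominator is explicitly `NA` and flagged
#' undefined — never silently 0.
#'
#' @param counts A `confusion_counts`.
#' @return A tibble of class `cle_metrics` with columns `metric`, `value`
#'   (percent, full precision), `display` (rounded percent) and `defined`;
#'   the counts are attached as an attribute.
#' @examples
#' compute_metrics(confusion_counts(TP = 18, FP = 5, TN = 15, FN = 0))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  assert_that(n > 0, "total count must be positive")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  vals <- c(
    accuracy    = 100 * (counts$TP + counts$TN) / n,
    sensitivity = ratio(counts$TP, counts$TP + counts$FN),
    specificity = ratio(counts$TN, counts$TN + counts$FP),
    ppv         = ratio(counts$TP, counts$TP + counts$FP),
    npv         = ratio(counts$TN, counts$TN + counts$FN)
  )
  out <- tibble::tibble(
    metric = names(vals),
    value = unname(vals),
    display = round_display(unname(vals)),
    defined = !is.na(vals)
  )
  class(out) <- c("cle_metrics", class(out))
  attr(out, "counts") <- counts
  out
}

#' Average per-split accuracies into an overall figure
#'
#' Arithmetic mean of split percentages, the aggregation used when an
#' experiment is repeated over several random train/test splits. Display
#' rounding is to the nearest integer percent.
#'
#' @param split_accuracies Nonempty numeric vector of percentages.
#' @return Scalar mean (full precision); round with [round_display()] for
#'   reporting.
#' @examples
#' aggregate_splits(c(82, 75, 76)) # 77.67, displays as 78
#' @export
aggregate_splits <- function(split_accuracies) {
  assert_that(is.numeric(split_accuracies) && length(split_accuracies) > 0,
              "split_accuracies must be a nonempty numeric vector")
  mean(split_accuracies)
}

#' Display rounding for reported percentages
#'
#' Round-half-up to `digits` decimals, the convention used when percentages
#' are printed in report tables (base `round()` is round-half-even, which
#' would turn 87.5 into 88 but 86.5 into 86).
#'
#' @param x Numeric.
#' @param digits Decimal digits to keep (default 0).
#' @return Rounded numeric.
#' @examples
#' round_display(86.84) # 87
#' round_display(74.285, 1) # 74.3
#' @export
round_display <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Export a confusion matrix as figure and CSV
#'
#' Writes a 2x2 CSV (rows = prediction, columns = ground truth, matching the
#' conventional orientation with truth on the x-axis) and returns a ggplot2
#' heatmap whose fill intensity encodes the cell count. When `out_path` is
#' given, the CSV is written to `<out_path>.csv` and the figure to
#' `<out_path>.png`.
#'
#' @param counts A `confusion_counts`.
#' @param out_path Optional path prefix for the CSV/PNG pair.
#' @return The ggplot object, invisibly when writing files.
#' @export
export_confusion_matrix <- function(counts, out_path = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  m <- confusion_matrix_table(counts)
  df <- tibble::tibble(
    truth = factor(rep(colnames(m), each = 2), levels = c("high", "low")),
    prediction = factor(rep(rownames(m), 2), levels = c("low", "high")),
    count = as.vector(m)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$prediction,
                                        fill = .data$count)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166AC") +
    ggplot2::labs(x = "Ground truth", y = "Prediction", fill = "Count") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    utils::write.csv(as.data.frame(m),
                     paste0(out_path, ".csv"), row.names = TRUE)
    ggplot2::ggsave(paste0(out_path, ".png"), p, width = 4, height = 3.5,
                    dpi = 150)
    return(invisible(p))
  }
  p
}

# 2x2 matrix: rows = prediction (high, low), cols = ground truth (high, low).
confusion_matrix_table <- function(counts) {
  m <- matrix(c(counts$TP, counts$FN, counts$FP, counts$TN), 2, 2)
  dimnames(m) <- list(prediction = c("high", "low"),
                      truth = c("high", "low"))
  m
}

#' Read back a confusion matrix CSV
#'
#' Inverse of the CSV side of [export_confusion_matrix()].
#'
#' @param path Path to the CSV (including extension).
#' @return A `confusion_counts`.
#' @export
read_confusion_matrix <- function(path) {
  m <- utils::read.csv(path, row.names = 1)
  confusion_counts(TP = m["high", "high"], FP = m["high", "low"],
                   TN = m["low", "low"], FN = m["low", "high"])
}

#' Tidy a metrics report
#'
#' @param x A `cle_metrics` tibble.
#' @param ... Unused.
#' @return The underlying tibble (metric, value, display, defined).
#' @export
tidy.cle_metrics <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cle_metrics")
  out
}

#' One-row summary of a metrics report
#'
#' @param x A `cle_metrics` tibble.
#' @param ... Unused.
#' @return One-row tibble with one column per metric (full-precision
#'   percentages) plus `n`.
#' @export
glance.cle_metrics <- function(x, ...) {
  counts <- attr(x, "counts")
  out <- tibble::as_tibble(as.list(stats::setNames(x$value, x$metric)))
  out$n <- counts$TP + counts$FP + counts$TN + counts$FN
  out
}
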