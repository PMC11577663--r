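#' Assign semantic labels to checkbox detections
#'
#' The chart's checkboxes are arranged in columns, so labels are assigned
#' geometrically: sort all detections by x-center, take the first c1 for the
#' left-most column (c1 = that column's label count), sort those by y-center
#' and zip with the column's labels top to bottom; repeat for the remaining
#' columns. The method presumes a complete detection set, so a detection
#' count different from the layout's expected count is an error (strict
#' count policy: better to reject a sheet than to silently misalign every
#' label). A lenient mode exists behind `strict = FALSE` as an extension: it
#' assigns the nearest detections per column and marks the record, but it is
#' not the evaluated default.
#'
#' @param detections box tibble with labels `"checked"`/`"unchecked"`.
#' @param layout a `chart_layout` (supplies `checkbox_columns` and
#'   `expected_checkbox_count`).
#' @param strict error on count mismatch (default) or fall back to
#'   nearest-template assignment.
#' @return A tibble `label`, `column`, `checked` in schema order.
#' @export
assign_checkbox_labels <- function(detections, layout, strict = TRUE) {
  expected <- layout$expected_checkbox_count
  if (strict && nrow(detections) != expected) {
    stop("checkbox count mismatch: detected ", nrow(detections),
         " boxes but the layout expects ", expected, call. = FALSE)
  }
  remaining <- dplyr::arrange(detections, .data$x_center)
  out <- list()
  for (col in layout$checkbox_columns) {
    take <- min(length(col$labels), nrow(remaining))
    grp <- remaining[seq_len(take), , drop = FALSE]
    remaining <- remaining[setdiff(seq_len(nrow(remaining)), seq_len(take)), ,
                           drop = FALSE]
    grp <- dplyr::arrange(grp, .data$y_center)
    out[[col$name]] <- tibble::tibble(
      label = col$labels,
      column = col$name,
      checked = c(grp$label == "checked",
                  rep(NA, length(col$labels) - take))
    )
  }
  dplyr::bind_rows(out)
}

#' Binary metrics for checkbox inference
#'
#' Accuracy, precision, recall and F1 with "checked" as the positive class.
#' Precision is `NA` when nothing is predicted positive; F1 uses the
#' `2TP / (2TP + FP + FN)` form so it stays defined (0) in that case.
#'
#' @param predicted,truth tibbles with columns `label`, `checked` over the
#'   same label set.
#' @return A one-row tibble `accuracy`, `precision`, `recall`, `f1`.
#' @export
checkbox_metrics <- function(predicted, truth) {
  if (!setequal(predicted$label, truth$label)) {
    stop("predicted and truth label sets differ", call. = FALSE)
  }
  m <- dplyr::inner_join(predicted[, c("label", "checked")],
                         truth[, c("label", "checked")],
                         by = "label", suffix = c("_pred", "_true"))
  tp <- sum(m$checked_pred & m$checked_true)
  fp <- sum(m$checked_pred & !m$checked_true)
  fn <- sum(!m$checked_pred & m$checked_true)
  tn <- sum(!m$checked_pred & !m$checked_true)
  tibble::tibble(
    accuracy = (tp + tn) / nrow(m),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    f1 = if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  )
}
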