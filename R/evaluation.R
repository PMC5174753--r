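#' Observed-vs-predicted contingency table
#'
#' @param observed,predicted equal-length binary 0/1 vectors (non-empty).
#' @return Object of class `contingency` with counts `tp` (observed 1,
#'   predicted 1), `fn`, `fp`, `tn`.
#' @export
contingency <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch", call. = FALSE)
  if (length(observed) == 0) stop("empty vectors", call. = FALSE)
  structure(list(tp = sum(observed == 1 & predicted == 1),
                 fn = sum(observed == 1 & predicted == 0),
                 fp = sum(observed == 0 & predicted == 1),
                 tn = sum(observed == 0 & predicted == 0)),
            class = "contingency")
}

#' Sensitivity, specificity and diagnostic accuracy
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`,
#' `accuracy = (tp + tn) / n`.  Each proportion is also reported as an
#' integer percentage with half-up rounding (the convention of printed
#' clinical tables, e.g. 73.51% -> 74%).  A metric with a zero denominator
#' is reported as `NA`.
#'
#' @param table a [contingency()] table, or a list with fields
#'   `tp`, `fn`, `fp`, `tn`.
#' @return Object of class `metrics_report` with the three proportions and
#'   their `*_pct` integer versions.
#' @export
classification_metrics <- function(table) {
  tp <- table$tp; fn <- table$fn; fp <- table$fp; tn <- table$tn
  n <- tp + fn + fp + tn
  if (n == 0) stop("empty table", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 sensitivity_pct = round_half_up(100 * sens),
                 specificity_pct = round_half_up(100 * spec),
                 accuracy_pct = round_half_up(100 * acc),
                 n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d: sensitivity %s%%, specificity %s%%, accuracy %s%%\n",
              x$n, format(x$sensitivity_pct), format(x$specificity_pct),
              format(x$accuracy_pct)))
  invisible(x)
}

#' Render an observed-vs-predicted report
#'
#' Aligned text mirroring a clinical cross-tabulation: observed rows,
#' predicted columns, row percentages, and a diagnosis-accuracy line.
#'
#' @param table a [contingency()] table.
#' @return Character vector of report lines.
#' @export
format_contingency <- function(table) {
  m <- classification_metrics(table)
  c(sprintf("%-10s %8s %8s %8s", "Observed", "Pred yes", "Pred no", "Total"),
    sprintf("%-10s %8s %8s %8d", "Yes",
            sprintf("%d (%d%%)", table$tp, m$sensitivity_pct),
            sprintf("%d (%d%%)", table$fn, 100 - m$sensitivity_pct),
            table$tp + table$fn),
    sprintf("%-10s %8s %8s %8d", "No",
            sprintf("%d (%d%%)", table$fp, 100 - m$specificity_pct),
            sprintf("%d (%d%%)", table$tn, m$specificity_pct),
            table$fp + table$tn),
    sprintf("%-10s %8d %8d %8d", "Total", table$tp + table$fp,
            table$fn + table$tn, m$n),
    sprintf("Diagnosis accuracy: %d%%", m$accuracy_pct))
}
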