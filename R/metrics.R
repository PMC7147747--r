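#' Confusion matrix of true vs predicted classes
#'
#' @param true_labels Character vector of true classes.
#' @param predicted Character vector of predicted classes, same length.
#' @param scheme A [grade_scheme()]; both label vectors must be drawn from
#'   its classes, and rows/columns are ordered as `scheme$classes`.
#' @return An object of class `confusion_matrix`: a K x K integer matrix
#'   (rows = true class, columns = predicted class) with the scheme attached
#'   as attribute `scheme`.
#' @examples
#' sch <- grade_scheme(c("Healthy", "Diseased"))
#' confusion(c("Healthy", "Healthy", "Healthy", "Diseased"),
#'           c("Healthy", "Diseased", "Healthy", "Diseased"), sch)
#' @export
confusion <- function(true_labels, predicted, scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  if (length(true_labels) != length(predicted))
    stop("true and predicted label vectors differ in length", call. = FALSE)
  unknown <- setdiff(unique(c(true_labels, predicted)), scheme$classes)
  if (length(unknown))
    stop("label(s) outside the scheme: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  lv <- scheme$classes
  m <- table(factor(true_labels, levels = lv),
             factor(predicted, levels = lv))
  m <- matrix(as.integer(m), nrow = length(lv),
              dimnames = list(true = lv, predicted = lv))
  structure(m, scheme = scheme, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest screening metrics from a confusion matrix
#'
#' For each class `c` the one-vs-rest reduction takes
#' `TP = counts[c, c]`, `FN = rowsum(c) - TP`, `FP = colsum(c) - TP` and
#' `TN` as the remainder, then applies the screening definitions:
#' sensitivity `TP / (TP + FN)` (true positive rate), specificity
#' `TN / (TN + FP)` (true negative rate), positive predictive value
#' `TP / (TP + FP)`, negative predictive value `TN / (TN + FN)`, and
#' `F1 = 2 * PPV * sensitivity / (PPV + sensitivity)`. Overall accuracy is
#' the matrix trace over the grand total. Any metric whose denominator is
#' zero is reported as `NA` (undefined), never as an error, and is excluded
#' from aggregate summaries.
#'
#' @param cm A [confusion()] matrix with a positive grand total.
#' @return An object of class `metrics_report`: a data.frame with one row
#'   per class and columns `class, sensitivity, specificity, ppv, npv, f1`,
#'   plus attributes `accuracy` and `scheme`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  scheme <- attr(cm, "scheme")
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  classes <- scheme$classes
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f1 <- f1_score(ppv, sens)
  rep <- data.frame(class = classes, sensitivity = unname(sens),
                    specificity = unname(spec), ppv = unname(ppv),
                    npv = unname(npv), f1 = unname(f1),
                    stringsAsFactors = FALSE)
  structure(rep, accuracy = sum(tp) / n, scheme = scheme,
            class = c("metrics_report", "data.frame"))
}

#' F1 score from PPV and sensitivity
#'
#' Harmonic mean `2 * PPV * sensitivity / (PPV + sensitivity)`; `NA` when
#' either input is `NA` or the denominator is zero.
#'
#' @param ppv,sensitivity Numeric vectors in \[0, 1\].
#' @return Numeric vector.
#' @examples
#' f1_score(0.9005, 0.9665)  # 0.9323 at 4 decimal places
#' @export
f1_score <- function(ppv, sensitivity) {
  out <- ifelse(!is.na(ppv) & !is.na(sensitivity) & (ppv + sensitivity) > 0,
                2 * ppv * sensitivity / (ppv + sensitivity), NA_real_)
  out
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(format_metrics(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Accuracy of a metrics report
#'
#' @param report A `metrics_report`.
#' @return Overall accuracy (trace over grand total).
#' @export
accuracy <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  attr(report, "accuracy")
}

#' Format a metrics report as an aligned plain-text table
#'
#' Rows follow the screening-report convention: accuracy first, then
#' per-class Sensitivity, Specificity, F1 Score, PPV and NPV blocks. Values
#' are printed to 4 decimal places; undefined metrics print as `--`.
#'
#' @param report A `metrics_report` (or a named list of them, one column
#'   each).
#' @param digits Decimal places (default 4).
#' @return Character vector of lines.
#' @export
format_metrics <- function(report, digits = 4) {
  reports <- if (inherits(report, "metrics_report"))
    stats::setNames(list(report), "") else report
  stopifnot(all(vapply(reports, inherits, logical(1), "metrics_report")))
  classes <- reports[[1]]$class
  rows <- c("accuracy",
            paste("Sensitivity", classes), paste("Specificity", classes),
            paste("F1 Score", classes), paste("PPV", classes),
            paste("NPV", classes))
  cell <- function(v) ifelse(is.na(v), "--", formatC(v, digits = digits,
                                                     format = "f"))
  col_for <- function(rep) {
    c(cell(accuracy(rep)), cell(rep$sensitivity), cell(rep$specificity),
      cell(rep$f1), cell(rep$ppv), cell(rep$npv))
  }
  cols <- vapply(reports, col_for, character(length(rows)))
  cols <- matrix(cols, nrow = length(rows),
                 dimnames = list(rows, names(reports)))
  widths <- pmax(nchar(colnames(cols)), apply(nchar(cols), 2, max))
  header <- paste(c(formatC("", width = max(nchar(rows))),
                    mapply(formatC, colnames(cols), width = widths)),
                  collapse = "  ")
  body <- vapply(seq_along(rows), function(i) {
    paste(c(formatC(rows[i], width = max(nchar(rows)), flag = "-"),
            mapply(formatC, cols[i, ], width = widths)), collapse = "  ")
  }, character(1))
  c(header, body)
}

#' Write a metrics report as CSV
#'
#' @param report A `metrics_report`.
#' @param path Output CSV path; the accuracy is written as an extra row with
#'   class `"(overall)"`.
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  df <- as.data.frame(report)
  df <- rbind(df, data.frame(class = "(overall)",
                             sensitivity = NA, specificity = NA,
                             ppv = NA, npv = NA, f1 = NA))
  df$accuracy <- c(rep(NA, nrow(df) - 1), accuracy(report))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
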