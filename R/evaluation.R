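#' Truth-by-prediction confusion table
#'
#' @param truth Named character vector of true class labels, or a
#'   `prediction_run` (whose `true` column is used).
#' @param predicted Named character vector of predicted labels; omitted
#'   when `truth` is a `prediction_run`.
#' @param classes Ordered class list; defaults to the classes present.
#' @return A `confusion_table`: K x K integer matrix `counts[true, pred]`
#'   with classes in the given order.
#' @export
confusion_table <- function(truth, predicted = NULL, classes = NULL) {
  if (inherits(truth, "prediction_run")) {
    run <- truth
    truth <- stats::setNames(run$true, run$genome_id)
    predicted <- stats::setNames(run$predicted, run$genome_id)
  }
  if (is.null(names(truth)) || is.null(names(predicted)))
    stop("truth and predicted must be named by genome id", call. = FALSE)
  missing <- setdiff(names(truth), names(predicted))
  if (length(missing))
    stop("genome(s) missing a prediction: ",
         paste(missing, collapse = ", "), call. = FALSE)
  predicted <- predicted[names(truth)]
  if (is.null(classes))
    classes <- sort(unique(c(truth, predicted)))
  ct <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(ct), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_table", "matrix"))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> (rows: true, cols: predicted)\n")
  print(unclass(x))
  pct <- column_percentages(x)
  cat("per-class correct (% of true-class column): ",
      paste(colnames(x), paste0(diag(pct), "%"), sep = " ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Percent of each true class receiving each prediction
#'
#' Percentages are computed per true class (count over the class total)
#' and rounded half-up to integers.
#'
#' @param ct A `confusion_table`.
#' @return Integer matrix, same shape, columns = true classes as in the
#'   published layout (prediction rows by true-class columns).
#' @export
column_percentages <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  totals <- rowSums(ct)               # per true class
  pct <- t(ct) / rep(totals, each = ncol(ct)) * 100
  round_half_up(pct)
}

round_half_up <- function(x) {
  out <- floor(x + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Collapse a K-class confusion table to one-vs-rest binary counts
#'
#' Forces the classes into two — the positive class and every other class.
#'
#' @param ct A `confusion_table`.
#' @param positive_class One of the table's classes.
#' @return A `binary_counts` list: `TP`, `FP`, `FN`, `TN`.
#' @export
collapse_one_vs_rest <- function(ct, positive_class) {
  stopifnot(inherits(ct, "confusion_table"))
  if (!(positive_class %in% rownames(ct)))
    stop("unknown class: ", positive_class, call. = FALSE)
  pos <- positive_class
  tp <- ct[pos, pos]
  fn <- sum(ct[pos, ]) - tp
  fp <- sum(ct[, pos]) - tp
  tn <- sum(ct) - tp - fn - fp
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "binary_counts")
}

#' Matthews Correlation Coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#' [-1, 1]; 1 is perfect prediction, 0 the random expectation. Any zero
#' factor in the denominator gives MCC 0 by convention.
#'
#' @param bc A `binary_counts` (from [collapse_one_vs_rest()]) or a list
#'   with elements `TP`, `FP`, `FN`, `TN`.
#' @return A single numeric value.
#' @export
mcc <- function(bc) {
  tp <- as.numeric(bc$TP); fp <- as.numeric(bc$FP)
  fn <- as.numeric(bc$FN); tn <- as.numeric(bc$TN)
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' One-vs-rest MCC for every class of a confusion table
#'
#' @param ct A `confusion_table`.
#' @return Named numeric vector, one MCC per class.
#' @export
mcc_per_class <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  vapply(rownames(ct), function(cl) mcc(collapse_one_vs_rest(ct, cl)),
         numeric(1L))
}

#' Overall misclassification rate
#'
#' @param ct A `confusion_table`.
#' @return `1 - trace/total`, the fraction of genomes predicted wrongly.
#' @export
misclassification_rate <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  total <- sum(ct)
  if (total == 0) stop("empty confusion table", call. = FALSE)
  1 - sum(diag(ct)) / total
}

#' Write an evaluation report
#'
#' A TSV with the per-class one-vs-rest MCCs, the misclassification rate,
#' and the confusion table with per-true-class percentages.
#'
#' @param ct A `confusion_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(ct, path) {
  stopifnot(inherits(ct, "confusion_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-class one-vs-rest MCC", con)
  writeLines("class\tMCC", con)
  m <- mcc_per_class(ct)
  writeLines(paste(names(m), sprintf("%.4f", m), sep = "\t"), con)
  writeLines(sprintf("misclassification_rate\t%.4f",
                     misclassification_rate(ct)), con)
  writeLines("# confusion table: rows = predicted, columns = true class", con)
  pct <- column_percentages(ct)
  writeLines(paste(c("prediction", rownames(ct)), collapse = "\t"), con)
  for (p in colnames(ct))
    writeLines(paste(c(p, paste0(ct[, p], " (", pct[p, ], "%)")),
                     collapse = "\t"), con)
  invisible(path)
}
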