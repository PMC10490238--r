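# Multiclass evaluation: one-vs-rest confusion counts, overall accuracy,
# per-class F1 and macro-F1, balanced accuracy, and the per-stage report.

#' One-vs-rest confusion counts per stage
#'
#' Computes TP, FP, TN, FN for each of the five stages, treating each
#' stage in turn as the positive class.
#'
#' @param y_true,y_pred Character vectors of stage names (see
#'   [stage_levels()]), equal length, at least one element.
#' @return Object of class `confusion_counts`: a list with `table`
#'   (5 x 4 matrix of TP/FP/TN/FN, rows named by stage), `n` (total
#'   samples) and `n_classes` (always 5).
#' @examples
#' confusion_counts(c("W", "N1"), c("N1", "W"))
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  lv <- stage_levels()
  if (!all(y_true %in% lv) || !all(y_pred %in% lv)) {
    stop("labels must be among ", paste(lv, collapse = ", "))
  }
  n <- length(y_true)
  tab <- t(vapply(lv, function(s) {
    tp <- sum(y_true == s & y_pred == s)
    fp <- sum(y_true != s & y_pred == s)
    fn <- sum(y_true == s & y_pred != s)
    c(TP = tp, FP = fp, TN = n - tp - fp - fn, FN = fn)
  }, numeric(4)))
  structure(list(table = tab, n = n, n_classes = length(lv)),
            class = "confusion_counts")
}

#' Overall accuracy from confusion counts
#'
#' Sum of per-class true positives over the total sample count.
#'
#' @param counts A [confusion_counts()] object.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0L) stop("no samples")
  sum(counts$table[, "TP"]) / counts$n
}

#' Per-class F1 and macro-F1
#'
#' Per class, precision = TP/(TP+FP) and recall = TP/(TP+FN); F1 is
#' their harmonic mean, set to 0 when precision or recall is undefined
#' (zero denominator). Macro-F1 is the unweighted mean over all five
#' stages, including stages absent from the evaluation set.
#'
#' @param counts A [confusion_counts()] object.
#' @return List with `macro_f1`, and per-stage vectors `f1`,
#'   `precision`, `recall` named by stage.
#' @export
macro_f1 <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n == 0L) stop("no samples")
  tab <- counts$table
  pre <- ifelse(tab[, "TP"] + tab[, "FP"] > 0,
                tab[, "TP"] / (tab[, "TP"] + tab[, "FP"]), 0)
  rec <- ifelse(tab[, "TP"] + tab[, "FN"] > 0,
                tab[, "TP"] / (tab[, "TP"] + tab[, "FN"]), 0)
  f1 <- ifelse(pre + rec > 0, 2 * pre * rec / (pre + rec), 0)
  list(macro_f1 = mean(f1), f1 = f1, precision = pre, recall = rec)
}

#' Balanced accuracy (mean per-class recall)
#'
#' Averaged only over stages that occur in the reference labels, so a
#' stage missing from a fold does not drag the mean to zero.
#'
#' @param counts A [confusion_counts()] object.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tab <- counts$table
  present <- tab[, "TP"] + tab[, "FN"] > 0
  rec <- tab[present, "TP"] / (tab[present, "TP"] + tab[present, "FN"])
  mean(rec)
}

#' Evaluation report in the per-stage table layout
#'
#' One row per stage (precision, recall, F1) plus overall accuracy,
#' macro-F1 and balanced accuracy, optionally written as CSV.
#'
#' @param y_true,y_pred Stage name vectors, equal length.
#' @param file Optional path; when given the report data frame is also
#'   written as CSV.
#' @return Invisibly for `file`, otherwise visibly: a list with
#'   `summary` (accuracy, macro_f1, balanced_accuracy) and `per_stage`
#'   (data frame with stage, precision, recall, f1).
#' @export
metrics_report <- function(y_true, y_pred, file = NULL) {
  cc <- confusion_counts(y_true, y_pred)
  mf <- macro_f1(cc)
  rep <- list(
    summary = c(accuracy = accuracy(cc), macro_f1 = mf$macro_f1,
                balanced_accuracy = balanced_accuracy(cc)),
    per_stage = data.frame(stage = stage_levels(),
                           precision = unname(mf$precision),
                           recall = unname(mf$recall),
                           f1 = unname(mf$f1))
  )
  if (!is.null(file)) {
    hdr <- data.frame(stage = names(rep$summary),
                      precision = NA_real_, recall = NA_real_,
                      f1 = unname(rep$summary))
    utils::write.csv(rbind(hdr, rep$per_stage), file, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
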