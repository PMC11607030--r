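# Multiclass evaluation: confusion matrix, mean accuracy (micro),
# macro-averaged precision (mAP) and recall (mAR), and the F1 score as
# their harmonic mean.

#' Evaluate predictions against labels
#'
#' `mAcc` is the fraction of correct predictions (micro accuracy); `mAP`
#' and `mAR` are unweighted means over classes of per-class precision and
#' recall; `f1 = 2 mAP mAR / (mAP + mAR)`. Classes absent from both
#' labels and predictions are excluded from the macro means; a class
#' never predicted contributes precision 0 (with a warning).
#'
#' @param predictions,labels equal-length vectors (character or factor).
#' @param classes class set defining the confusion-matrix order; default
#'   the union of observed values.
#' @param macro_acc also report the mean of per-class accuracies
#'   (identical to mAR on this definition) as `mAcc_macro`.
#' @return an `eval_report`: list with `confusion` (rows = true,
#'   cols = predicted), `mAcc`, `mAP`, `mAR`, `f1`, `n_patches`.
#' @export
evaluate_predictions <- function(predictions, labels, classes = NULL,
                                 macro_acc = FALSE) {
  if (length(predictions) == 0L || length(labels) == 0L)
    stop("empty predictions or labels")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(c(predictions, labels)))
  cm <- table(factor(labels, levels = classes),
              factor(predictions, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")

  present <- rowSums(cm) > 0 | colSums(cm) > 0
  tp <- diag(cm)[present]
  pred_n <- colSums(cm)[present]
  true_n <- rowSums(cm)[present]
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  if (any(pred_n == 0))
    warning("class(es) never predicted: precision counted as 0 for ",
            paste(names(pred_n)[pred_n == 0], collapse = ", "))
  rec <- ifelse(true_n > 0, tp / true_n, 0)

  mAcc <- sum(diag(cm)) / sum(cm)
  mAP <- mean(prec)
  mAR <- mean(rec)
  rep <- structure(
    list(confusion = cm, mAcc = mAcc, mAP = mAP, mAR = mAR,
         f1 = f1_from_pr(mAP, mAR), n_patches = sum(cm),
         per_class = data.frame(class = names(prec), precision = prec,
                                recall = rec, support = as.integer(true_n),
                                row.names = NULL)),
    class = "eval_report"
  )
  if (macro_acc) rep$mAcc_macro <- mean(rec[true_n > 0])
  rep
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("<eval_report> n = %d | mAcc %.4f, mAP %.4f, mAR %.4f, F1 %.4f\n",
              x$n_patches, x$mAcc, x$mAP, x$mAR, x$f1))
  print(x$confusion)
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`; defined as 0 (with attribute
#' `degenerate = TRUE`) when `p + r = 0`.
#'
#' @param p,r precision and recall in \[0, 1\] (vectorized).
#' @return F1 value(s).
#' @export
f1_from_pr <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  out <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  if (any(p + r == 0)) attr(out, "degenerate") <- TRUE
  out
}

#' Mean and sample standard deviation across test-set accuracies
#'
#' @param maccs numeric vector of per-test-set accuracies.
#' @return list with `mean` and `sd` (the n-1 denominator standard
#'   deviation; `NA` with a message when only one value is given).
#' @export
summarize_across_testsets <- function(maccs) {
  stopifnot(length(maccs) >= 1, all(is.finite(maccs)))
  s <- if (length(maccs) >= 2) stats::sd(maccs) else {
    message("standard deviation undefined for a single value")
    NA_real_
  }
  list(mean = mean(maccs), sd = s)
}
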