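# Confusion-matrix metrics, chance-corrected agreement and the
# window-size selection procedure (GAM-smoothed performance curve with
# difference-quotient slopes and a smallest-window preference).

#' Confusion matrix of truth versus predicted labels
#'
#' Rows are the observed (true) classes, columns the predicted classes.
#' Predictions in the rejection class are kept as an extra predicted
#' column — rejected items are never true members of any behaviour class.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Optional class ordering; defaults to the sorted union of
#'   the non-reject labels seen.
#' @param reject Rejection class name (default `"other"`).
#' @return Integer matrix of class `"confusion_matrix"` with attributes
#'   `classes` (behaviour classes) and `reject`.
#' @export
confusion <- function(truth, predicted, classes = NULL, reject = "other") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (is.null(classes))
    classes <- sort(unique(c(truth, setdiff(predicted, reject))))
  pred_levels <- classes
  if (reject %in% predicted) pred_levels <- c(classes, reject)
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = pred_levels))
  cm <- unclass(cm)
  dimnames(cm) <- list(truth = classes, predicted = pred_levels)
  structure(cm, class = "confusion_matrix", classes = classes,
            reject = reject)
}

cm_total <- function(cm) sum(cm)

cm_cell <- function(cm, i, j) {
  if (j %in% colnames(cm)) cm[i, j] else 0
}

#' Per-class recall, precision and accuracy
#'
#' One-vs-rest derivation of TP/FP/FN/TN per behaviour class:
#' recall = TP/(TP+FN), precision = TP/(TP+FP),
#' accuracy = (TP+TN)/total. Undefined ratios (zero denominator) are
#' reported as 0 and flagged. Accuracy is reported for completeness but
#' is dominated by the majority class under strong imbalance and is not
#' used for model selection here.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with columns `class`, `recall`, `precision`,
#'   `accuracy`, `recall_defined`, `precision_defined`.
#' @export
per_class_metrics <- function(cm) {
  total <- cm_total(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- attr(cm, "classes")
  out <- lapply(classes, function(cl) {
    tp <- cm_cell(cm, cl, cl)
    fn <- sum(cm[cl, ]) - tp
    fp <- if (cl %in% colnames(cm)) sum(cm[, cl]) - tp else 0
    tn <- total - tp - fn - fp
    rec_def <- (tp + fn) > 0
    pre_def <- (tp + fp) > 0
    data.frame(class = cl,
               recall = if (rec_def) tp / (tp + fn) else 0,
               precision = if (pre_def) tp / (tp + fp) else 0,
               accuracy = (tp + tn) / total,
               recall_defined = rec_def,
               precision_defined = pre_def,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohen's kappa from a confusion matrix
#'
#' kappa = (po - pe) / (1 - pe), with observed agreement po = trace/n.
#' The default chance agreement is the standard multiclass marginal
#' product pe = sum_c (rowsum_c/n)(colsum_c/n). An alternative variant
#' replacing the truth marginal by (TP_c + TN_c) is exposed behind
#' `chance = "tn_product"`; the marginal product is the conventional
#' two-rater definition and is the package default.
#'
#' @param cm A [confusion()] matrix.
#' @param chance `"margins"` (standard) or `"tn_product"`.
#' @return Scalar in \[-1, 1\].
#' @export
cohens_kappa <- function(cm, chance = c("margins", "tn_product")) {
  chance <- match.arg(chance)
  n <- cm_total(cm)
  if (n == 0) stop("empty confusion matrix")
  classes <- attr(cm, "classes")
  po <- sum(vapply(classes, function(cl) cm_cell(cm, cl, cl), numeric(1))) / n
  pe <- if (chance == "margins") {
    sum(vapply(classes, function(cl) {
      colsum <- if (cl %in% colnames(cm)) sum(cm[, cl]) else 0
      (sum(cm[cl, ]) / n) * (colsum / n)
    }, numeric(1)))
  } else {
    sum(vapply(classes, function(cl) {
      tp <- cm_cell(cm, cl, cl)
      fn <- sum(cm[cl, ]) - tp
      fp <- if (cl %in% colnames(cm)) sum(cm[, cl]) - tp else 0
      tn <- n - tp - fn - fp
      ((tp + tn) / n) * ((tp + fp) / n)
    }, numeric(1)))
  }
  if (abs(1 - pe) < .Machine$double.eps)
    stop("undefined kappa: chance agreement equals 1")
  (po - pe) / (1 - pe)
}

#' Proportion of rejected ("other") predictions
#' @param predicted Character vector of predicted classes.
#' @param reject Rejection class name.
#' @return Fraction in \[0, 1\].
#' @export
other_proportion <- function(predicted, reject = "other") {
  if (length(predicted) == 0) return(0)
  mean(predicted == reject)
}

#' Full performance report for a labelled evaluation
#'
#' @param truth,predicted Equal-length label vectors (predicted may
#'   contain the rejection class).
#' @param classes Optional class ordering.
#' @param reject Rejection class name.
#' @return Object of class `"performance_report"`: confusion matrix,
#'   per-class metric table, Cohen's kappa, rejected proportion and the
#'   combined selection score.
#' @export
performance_report <- function(truth, predicted, classes = NULL,
                               reject = "other") {
  cm <- confusion(truth, predicted, classes = classes, reject = reject)
  metrics <- per_class_metrics(cm)
  rep <- structure(list(confusion = cm, metrics = metrics,
                        kappa = cohens_kappa(cm),
                        other_proportion = other_proportion(predicted,
                                                            reject)),
                   class = "performance_report")
  rep$selection_score <- selection_score(rep)
  rep
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Performance report\n")
  print(x$metrics[c("class", "recall", "precision", "accuracy")],
        row.names = FALSE, digits = 3)
  cat(sprintf("kappa = %.3f | other proportion = %.3f | selection score = %.3f\n",
              x$kappa, x$other_proportion, x$selection_score))
  invisible(x)
}

#' Combined model-selection score
#'
#' The mean of three quantities on a common \[0, 1\] scale: the mean
#' per-class recall, the mean per-class precision, and one minus the
#' proportion of rejected assignments. Accuracy is deliberately excluded:
#' under strong class imbalance it mostly reflects the majority class.
#'
#' @param report A [performance_report()], or a list with elements
#'   `recall` (vector), `precision` (vector) and `other_proportion`.
#' @return Scalar in \[0, 1\].
#' @examples
#' selection_score(list(recall = 0.8, precision = 0.6,
#'                      other_proportion = 0.1))  # (0.8+0.6+0.9)/3
#' @export
selection_score <- function(report) {
  if (inherits(report, "performance_report")) {
    rec <- report$metrics$recall
    pre <- report$metrics$precision
    oth <- report$other_proportion
  } else {
    rec <- report$recall; pre <- report$precision
    oth <- report$other_proportion
  }
  mean(c(mean(rec), mean(pre), 1 - oth))
}

#' Sweep window sizes and record window-level performance
#'
#' For each candidate window size: the labelled bursts are split 70/30 at
#' burst level (the same split seed throughout the sweep), both partitions
#' are expanded with the moving window, the classifier is trained on the
#' training windows and evaluated on the test windows (each window one
#' item, thresholded classes including the rejection class), and the
#' combined [selection_score()] is recorded.
#'
#' @param bursts Labelled `acc_bursts`.
#' @param sizes Integer vector of window sizes (default 20..110).
#' @param spec A [model_spec()].
#' @param train_frac Training fraction (default 0.7).
#' @param tau Rejection threshold applied to window probabilities.
#' @param seed Split seed (training uses `spec$seed`).
#' @return Data frame of class `"window_size_curve"`: `size`, `score`,
#'   `mean_recall`, `mean_precision`, `other_proportion`.
#' @export
sweep_window_sizes <- function(bursts, sizes = 20:110,
                               spec = model_spec("ann"), train_frac = 0.7,
                               tau = 0.7, seed = 1L) {
  if (any(sizes > min(bursts$meta$n)))
    stop("window size exceeds burst length")
  split <- stratified_split(bursts, train_frac = train_frac, seed = seed)
  rows <- lapply(sizes, function(w) {
    plan <- window_plan(w)
    tr <- expand(split$train, plan)
    te <- expand(split$test, plan)
    model <- train_model(tr, tr$label, spec)
    pred <- apply_threshold(predict_probs(model, te), tau = tau)
    rep <- performance_report(te$label, pred)
    data.frame(size = w, score = rep$selection_score,
               mean_recall = mean(rep$metrics$recall),
               mean_precision = mean(rep$metrics$precision),
               other_proportion = rep$other_proportion)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_size_curve", class(out))
  out
}

#' Smooth a window-size curve and select the working window
#'
#' Fits a penalized cubic regression spline (a GAM with basis dimension
#' `basis_dim`, smoothing parameter by generalized cross-validation) to
#' the raw scores, computes difference-quotient slopes of the fitted
#' values (central differences at interior sizes, one-sided at the ends,
#' on the fitted curve normalized to \[0, 1\]), and returns the smallest
#' window size whose fitted value lies within `slope_tol` of the fitted
#' maximum (on the normalized scale) and whose slope magnitude is at most
#' `slope_tol`. A performance plateau therefore resolves to its smallest
#' member; if no size satisfies both conditions (e.g. a strictly rising
#' curve), the size of the fitted maximum is returned.
#'
#' @param curve A [sweep_window_sizes()] result, or any data frame with
#'   columns `size` and `score` (>= 4 rows).
#' @param basis_dim GAM basis dimension (default 40), capped at the
#'   number of distinct sizes minus 1.
#' @param slope_tol Tolerance on the normalized score scale
#'   (default 1e-3).
#' @return List with `chosen` (integer size), `curve` (data frame adding
#'   `fitted` and `slope`), and the fitted `gam` object.
#' @export
smooth_and_select <- function(curve, basis_dim = 40, slope_tol = 1e-3) {
  df <- as.data.frame(curve)[c("size", "score")]
  df <- df[order(df$size), ]
  n <- nrow(df)
  if (n < 4) stop("fit error: need at least 4 points")
  k <- min(basis_dim, n - 1)
  fit <- mgcv::gam(score ~ s(size, k = k), data = df, method = "GCV.Cp")
  fitted <- as.numeric(stats::predict(fit, df))
  rng <- diff(range(fitted))
  # a fitted range at numerical noise level is a plateau, not structure
  flat <- rng <= 1e-9 * max(abs(fitted), 1)
  yn <- if (flat) rep(0, n) else (fitted - min(fitted)) / rng
  x <- df$size
  slope <- numeric(n)
  if (n >= 2) {
    slope[1] <- (yn[2] - yn[1]) / (x[2] - x[1])
    slope[n] <- (yn[n] - yn[n - 1]) / (x[n] - x[n - 1])
    if (n > 2) {
      i <- 2:(n - 1)
      slope[i] <- (yn[i + 1] - yn[i - 1]) / (x[i + 1] - x[i - 1])
    }
  }
  qualifies <- yn >= max(yn) - slope_tol & abs(slope) <= slope_tol
  chosen <- if (any(qualifies)) x[which(qualifies)[1]]
            else x[which.max(yn)[1]]
  df$fitted <- fitted
  df$slope <- slope
  list(chosen = as.integer(chosen), curve = df, fit = fit)
}
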