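# Evaluation battery: confusion matrices, TPR/FPR/precision/recall/F1, ROC
# with trapezoidal AUC, stratified 60/20/20 splits, leave-one-subject-out
# cross-validation with +/- 1 SD outlier flagging, and per-confounder
# misclassification attribution for the 16-class analysis.

#' Split indices into train / test / evaluation subsets
#'
#' Sizes are the nearest-integer rounding of the proportions with any
#' remainder absorbed by the first (training) subset, so they always sum to
#' `n`; at n = 1054 with the default 60/20/20 this yields 632/211/211.
#' When labels are supplied the split is stratified: the rule is applied
#' within each class, so subset class proportions match the data within one
#' item per class.
#'
#' @param n total number of items, or a vector of class labels (stratified).
#' @param proportions train/test/evaluation fractions, summing to 1.
#' @param seed integer seed for the shuffle.
#' @return list of integer index vectors `train`, `test`, `evaluation`;
#'   disjoint and exhaustive.
#' @examples
#' lengths(splitDataset(1054, seed = 1))  # 632 211 211
#' @export
splitDataset <- function(n, proportions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1")
  if (length(proportions) != 3L) stop("expected 3 proportions")
  labels <- NULL
  if (length(n) > 1L || is.character(n) || is.factor(n)) {
    labels <- as.character(n)
    n <- length(labels)
  }
  if (n < 3L) stop("need at least 3 items to split")
  sizes_for <- function(m) {
    s <- round(proportions * m)
    s[1] <- s[1] + (m - sum(s))
    s
  }
  with_seed(seed, {
    if (is.null(labels)) {
      idx <- sample.int(n)
      s <- sizes_for(n)
      list(train = sort(idx[seq_len(s[1])]),
           test = sort(idx[s[1] + seq_len(s[2])]),
           evaluation = sort(idx[s[1] + s[2] + seq_len(s[3])]))
    } else {
      out <- list(train = integer(), test = integer(),
                  evaluation = integer())
      for (cl in unique(labels)) {
        ci <- which(labels == cl)
        ci <- ci[sample.int(length(ci))]
        s <- sizes_for(length(ci))
        out$train <- c(out$train, ci[seq_len(s[1])])
        out$test <- c(out$test, ci[s[1] + seq_len(s[2])])
        out$evaluation <- c(out$evaluation, ci[s[1] + s[2] + seq_len(s[3])])
      }
      lapply(out, sort)
    }
  })
}

#' Confusion matrix
#'
#' @param truth,predicted equal-length label vectors.
#' @param classes class name ordering (default: sorted union).
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @examples
#' confusion(c("a", "b", "b"), c("a", "b", "a"))
#' @export
confusion <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Binary classification rates from a confusion matrix
#'
#' Reduces the matrix one-vs-rest against `positive` and reports
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), precision = TP/(TP+FP),
#' recall = TPR and F1 = 2*precision*recall/(precision+recall).
#' Zero-denominator cases are defined as 0.
#'
#' @param cm confusion matrix from [confusion()].
#' @param positive name of the positive class.
#' @return named numeric vector `tpr, fpr, precision, recall, f1` plus the
#'   raw `tp, fp, fn, tn` cells.
#' @examples
#' cm <- confusion(rep(c("smoking", "other"), c(10, 10)),
#'                 rep(c("smoking", "other", "smoking", "other"),
#'                     c(9, 1, 1, 9)))
#' classRates(cm, "smoking")
#' @export
classRates <- function(cm, positive) {
  if (!positive %in% rownames(cm)) stop("positive class not in matrix")
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp
  tn <- sum(cm) - tp - fn - fp
  div <- function(a, b) if (b == 0) 0 else a / b
  tpr <- div(tp, tp + fn)
  fpr <- div(fp, fp + tn)
  precision <- div(tp, tp + fp)
  f1 <- if (precision + tpr == 0) 0 else 2 * precision * tpr / (precision + tpr)
  c(tpr = tpr, fpr = fpr, precision = precision, recall = tpr, f1 = f1,
    tp = tp, fp = fp, fn = fn, tn = tn)
}

#' ROC curve with trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique positive-class scores (plus
#' +Inf so the curve starts at (0,0)) and integrates TPR over FPR with the
#' trapezoidal rule. Tied scores enter the curve as a single group, so the
#' trapezoid between tied groups counts concordant ties as one half — the
#' AUC equals the Mann-Whitney probability that a positive outranks a
#' negative (ties counted 1/2).
#'
#' @param scores positive-class probabilities or scores.
#' @param truth logical (or 0/1) vector, TRUE for the positive class.
#' @return list with `points` (data.frame `fpr, tpr`, FPR non-decreasing,
#'   endpoints (0,0) and (1,1)) and `auc`.
#' @examples
#' rocCurve(c(.9, .8, .3, .2), c(TRUE, TRUE, FALSE, FALSE))$auc  # 1
#' @export
rocCurve <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  nPos <- sum(truth)
  nNeg <- sum(!truth)
  if (nPos == 0 || nNeg == 0)
    stop("need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  # cumulative counts at each distinct threshold
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(y)
  fpCum <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tpCum[last] / nPos)
  fpr <- c(0, fpCum[last] / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per participant: the fold's model is trained on every other
#' participant's windows and scored on the held-out participant
#' (window-level accuracy). Reports per-participant accuracy, their mean and
#' SD, and flags outliers beyond mean +/- 1 SD.
#'
#' @param windows a labeled [SensorWindows-class] with `participant_id`.
#' @param modelFactory zero-argument function returning a fresh untrained
#'   [CRSModel-class].
#' @param tc a [trainConfig()].
#' @param verbose print per-fold progress.
#' @return A [LosoReport-class].
#' @export
loso <- function(windows, modelFactory, tc = trainConfig(), verbose = FALSE) {
  stopifnot(is(windows, "SensorWindows"))
  parts <- unique(windows$participant_id)
  if (length(parts) < 2L)
    stop("leave-one-subject-out needs at least 2 participants")
  acc <- numeric(length(parts))
  names(acc) <- parts
  folds <- list()
  for (i in seq_along(parts)) {
    p <- parts[i]
    testIdx <- which(windows$participant_id == p)
    trainIdx <- which(windows$participant_id != p)
    stopifnot(length(intersect(testIdx, trainIdx)) == 0L)
    m <- modelFactory()
    m <- trainModel(m, windows[, trainIdx], tc)
    truthLab <- .window_targets(m, windows[, testIdx])
    pred <- classify(m, windows[, testIdx])
    acc[i] <- mean(m@classes[truthLab$idx + 1L] == pred$label)
    folds[[i]] <- list(participant = p, nTest = length(testIdx),
                       accuracy = acc[i])
    if (verbose)
      message(sprintf("fold %d/%d (%s): accuracy %.3f",
                      i, length(parts), p, acc[i]))
  }
  new("LosoReport", perParticipant = acc, meanAccuracy = mean(acc),
      sdAccuracy = stats::sd(acc), outliers = flagOutliers(acc),
      folds = folds)
}

#' Flag accuracy outliers beyond one SD from the mean
#'
#' @param accuracies named numeric vector of per-participant accuracies.
#' @return names (or indices) of entries with value greater or less than
#'   1 SD from the mean.
#' @examples
#' flagOutliers(c(a = .9, b = .88, c = .91, d = .5))
#' @export
flagOutliers <- function(accuracies) {
  m <- mean(accuracies)
  s <- stats::sd(accuracies)
  out <- which(accuracies > m + s | accuracies < m - s)
  if (is.null(names(accuracies))) out else names(accuracies)[out]
}

#' Per-confounder smoking misclassification attribution
#'
#' From a multi-class confusion matrix, reports for every non-smoking
#' gesture the row-normalized rate at which it is predicted as smoking
#' (a source of false smoking alerts) and the rate at which true smoking is
#' predicted as that gesture (missed detections attributed to it).
#'
#' @param cm K x K confusion matrix with class names, K >= 2.
#' @param smokingClass name of the smoking class (default `"smoking"`).
#' @return data.frame with columns `gesture`, `predicted_as_smoking_rate`,
#'   `smoking_predicted_as_rate`.
#' @export
confoundAttribution <- function(cm, smokingClass = "smoking") {
  if (!smokingClass %in% rownames(cm)) stop("smoking class not in matrix")
  others <- setdiff(rownames(cm), smokingClass)
  rowTot <- rowSums(cm)
  asSmoke <- ifelse(rowTot[others] == 0, 0,
                    cm[others, smokingClass] / rowTot[others])
  smokeAs <- if (rowTot[smokingClass] == 0) rep(0, length(others))
             else cm[smokingClass, others] / rowTot[smokingClass]
  data.frame(
    gesture = others,
    predicted_as_smoking_rate = as.numeric(asSmoke),
    smoking_predicted_as_rate = as.numeric(smokeAs),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Full 2-class evaluation report
#'
#' Convenience wrapper combining the confusion matrix, TPR/FPR/precision/
#' recall/F1 and the ROC/AUC for a scored window set.
#'
#' @param truth logical vector (TRUE = smoking).
#' @param scores smoking-class probabilities.
#' @param threshold decision threshold on the smoking probability.
#' @return list with `confusion`, `rates`, `roc`.
#' @export
evalReport <- function(truth, scores, threshold = 0.5) {
  lab <- ifelse(as.logical(truth), "smoking", "non_smoking")
  pred <- ifelse(scores >= threshold, "smoking", "non_smoking")
  cm <- confusion(lab, pred, classes = c("non_smoking", "smoking"))
  list(confusion = cm, rates = classRates(cm, "smoking"),
       roc = rocCurve(scores, truth))
}
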