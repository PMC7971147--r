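#' Jaccard index of two binary arrays
#'
#' Intersection over union of the foreground pixel sets. Two empty
#' foregrounds agree perfectly and score 1.
#'
#' @param prediction,truth Binary arrays of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_index <- function(prediction, truth) {
  check_same_shape(prediction, truth)
  if (!is_binary_array(prediction) || !is_binary_array(truth))
    stop("contract error: inputs must be binary", call. = FALSE)
  inter <- sum(prediction * truth)
  uni <- sum((prediction + truth) > 0)
  if (uni == 0) 1 else inter / uni
}

#' Pixel-level agreement metrics
#'
#' Mean absolute error, mean relative error (`|p-t| / (|t| + 1e-8)`),
#' pixel-wise Pearson correlation over the flattened arrays, and — when
#' both arrays are binary — pixel accuracy. A constant truth makes the
#' Pearson correlation undefined; it is reported as `NA`.
#'
#' @param prediction,truth Arrays of the same shape.
#' @return Named list: `accuracy` (or `NA` for non-binary input),
#'   `mean_absolute_error`, `mean_relative_error`, `pearson_r`.
#' @export
pixel_metrics <- function(prediction, truth) {
  check_same_shape(prediction, truth)
  p <- as.vector(prediction); t <- as.vector(truth)
  mae <- mean(abs(p - t))
  mre <- mean(abs(p - t) / (abs(t) + 1e-8))
  r <- if (stats::sd(t) == 0 || stats::sd(p) == 0) NA_real_ else
    stats::cor(p, t)
  acc <- if (is_binary_array(p) && is_binary_array(t)) mean(p == t) else
    NA_real_
  list(accuracy = acc, mean_absolute_error = mae,
       mean_relative_error = mre, pearson_r = r)
}

#' Classification evaluation report
#'
#' Confusion matrix (row = truth, column = prediction), macro Jaccard index
#' over classes of the hard label assignment, mean absolute and squared
#' error of the probability vectors against one-hot truth, ROC points by
#' threshold sweep on the positive-class probability and trapezoidal AUC
#' (binary directly, multi-class macro one-vs-rest).
#'
#' @param predictions Matrix `N x K` of class probabilities (or a list of
#'   probability vectors).
#' @param truths Integer vector of 0-based true class indices.
#' @return List: `jaccard`, `mae`, `mse`, `auc`, `confusion_matrix`,
#'   `roc_points`.
#' @export
classification_report <- function(predictions, truths) {
  if (is.list(predictions)) predictions <- do.call(rbind, predictions)
  if (length(truths) == 0L || nrow(predictions) == 0L)
    stop("contract error: empty input", call. = FALSE)
  if (nrow(predictions) != length(truths))
    stop("contract error: predictions and truths differ in length",
         call. = FALSE)
  K <- ncol(predictions)
  pred_lab <- max.col(predictions, ties.method = "first") - 1L
  cm <- matrix(0L, K, K,
               dimnames = list(truth = 0:(K - 1L), prediction = 0:(K - 1L)))
  for (i in seq_along(truths))
    cm[truths[i] + 1L, pred_lab[i] + 1L] <- cm[truths[i] + 1L,
                                               pred_lab[i] + 1L] + 1L
  jac <- mean(vapply(seq_len(K) - 1L, function(k) {
    inter <- sum(pred_lab == k & truths == k)
    uni <- sum(pred_lab == k | truths == k)
    if (uni == 0) 1 else inter / uni
  }, 0))
  onehot <- matrix(0, length(truths), K)
  onehot[cbind(seq_along(truths), truths + 1L)] <- 1
  mae <- mean(abs(predictions - onehot))
  mse <- mean((predictions - onehot)^2)
  if (K == 2L) {
    roc <- roc_curve(predictions[, 2L], as.integer(truths == 1L))
    auc <- roc$auc
    roc_points <- roc$points
  } else {
    rocs <- lapply(seq_len(K) - 1L, function(k)
      roc_curve(predictions[, k + 1L], as.integer(truths == k)))
    auc <- mean(vapply(rocs, function(r) r$auc, 0))
    roc_points <- lapply(rocs, function(r) r$points)
  }
  list(jaccard = jac, mae = mae, mse = mse, auc = auc,
       confusion_matrix = cm, roc_points = roc_points)
}

# ROC by sweeping a threshold over the scores; AUC by the trapezoidal rule.
roc_curve <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    return(list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                auc = NA_real_))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last point of each tie group
  tpr <- c(0, tp[keep] / np)
  fpr <- c(0, fp[keep] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Bootstrap distribution of a per-image metric
#'
#' Each round draws `ceiling(fraction * n)` values without replacement and
#' records their median, following the subsample-half protocol; the
#' round-medians, their median and the 25/75 percentiles are returned.
#' Results are a deterministic function of the values, the settings and the
#' seed, independent of input ordering.
#'
#' @param values Non-empty numeric vector of per-image metric values.
#' @param n_rounds Number of rounds (default 100).
#' @param fraction Subsample fraction in (0, 1]; default 0.5.
#' @param seed Integer seed.
#' @return List: `medians` (length `n_rounds`), `median`, `q25`, `q75`.
#' @export
bootstrap_metric <- function(values, n_rounds = 100L, fraction = 0.5,
                             seed = 1L) {
  if (length(values) == 0L)
    stop("contract error: empty value list", call. = FALSE)
  if (!(fraction > 0 && fraction <= 1))
    stop("parameter error: fraction must be in (0, 1]", call. = FALSE)
  values <- sort(values)
  m <- ceiling(fraction * length(values))
  meds <- with_local_seed(seed, {
    vapply(seq_len(n_rounds), function(i)
      median(values[sample(length(values), m)]), 0)
  })
  list(medians = meds, median = median(meds),
       q25 = unname(quantile(meds, 0.25)),
       q75 = unname(quantile(meds, 0.75)))
}

#' Signed over/under-prediction error map
#'
#' `+1` marks over-predicted pixels (predicted foreground absent from the
#' truth), `-1` under-predicted ones, `0` agreement.
#'
#' @param prediction,truth Binary arrays of the same shape.
#' @return Integer array in `{-1, 0, +1}`.
#' @export
error_map <- function(prediction, truth) {
  check_same_shape(prediction, truth)
  if (!is_binary_array(prediction) || !is_binary_array(truth))
    stop("contract error: inputs must be binary", call. = FALSE)
  prediction - truth
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("contract error: shape mismatch", call. = FALSE)
  invisible(TRUE)
}
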