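#' Otsu threshold of a probability map
#'
#' The threshold maximizing the between-class variance over a 256-bin
#' histogram of the map's value range. Candidate thresholds are the 255
#' interior bin edges; class statistics use exact per-bin pixel sums, and a
#' pixel belongs to the lower class iff its value is strictly below the
#' edge. A constant map yields an all-background mask with the constant
#' reported as the threshold.
#'
#' @param map Numeric array with values in `[0, 1]`.
#' @return List with `threshold` and binary `mask` (`map > threshold`).
#' @export
otsu_threshold <- function(map) {
  rng <- range(map)
  if (rng[2] - rng[1] <= 0)
    return(list(threshold = rng[1], mask = array(0, dim(map) %||% length(map))))
  nb <- 256L
  width <- (rng[2] - rng[1]) / nb
  bin <- pmin(floor((map - rng[1]) / width) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)
  sums <- vapply(split(as.vector(map), factor(bin, levels = seq_len(nb))),
                 sum, 0)
  n <- length(map); total <- sum(map)
  n0 <- cumsum(counts)[seq_len(nb - 1L)]
  s0 <- cumsum(sums)[seq_len(nb - 1L)]
  n1 <- n - n0; s1 <- total - s0
  valid <- n0 > 0 & n1 > 0
  bcv <- rep(-Inf, nb - 1L)
  bcv[valid] <- (n0[valid] * n1[valid]) *
    (s0[valid] / n0[valid] - s1[valid] / n1[valid])^2
  k <- which.max(bcv)
  thr <- rng[1] + k * width
  list(threshold = thr, mask = (map > thr) * 1)
}

#' Monte-Carlo-dropout sampling
#'
#' Runs `T` stochastic forward passes with dropout enabled at inference,
#' each with an independent dropout mask, emulating an ensemble of `T`
#' models.
#'
#' @param net A trained `dl_network` with dropout units.
#' @param image A single sample array.
#' @param T Number of passes (default 20).
#' @return List of `T` predictions.
#' @export
mc_dropout_predict <- function(net, image, T = 20L) {
  if (!net_has_dropout(net))
    stop("contract error: model has no dropout units", call. = FALSE)
  if (T < 2L) stop("contract error: T must be >= 2", call. = FALSE)
  lapply(seq_len(T), function(i) predict(net, image, dropout = TRUE))
}

#' Per-pixel uncertainty from stochastic passes
#'
#' The uncertainty map is the per-pixel population standard deviation of
#' the predictions across passes; the scalar summary `u` is the mean of the
#' map over all pixels.
#'
#' @param passes List of >= 2 prediction arrays of identical shape.
#' @return List with `map` and `u`.
#' @export
pixel_uncertainty <- function(passes) {
  if (length(passes) < 2L)
    stop("contract error: need at least 2 passes", call. = FALSE)
  d0 <- dim(passes[[1L]]) %||% length(passes[[1L]])
  for (p in passes)
    if (!identical(dim(p) %||% length(p), d0))
      stop("contract error: passes have different shapes", call. = FALSE)
  Tn <- length(passes)
  # shift by the first pass for numerical stability: identical passes give
  # an exactly-zero map
  devs <- lapply(passes, function(p) p - passes[[1L]])
  m <- Reduce(`+`, devs) / Tn
  v <- Reduce(`+`, lapply(devs, function(d) (d - m)^2)) / Tn
  v[v < 0] <- 0
  map <- sqrt(v)
  list(map = map, u = mean(map))
}

#' Classification uncertainty score on the unit interval
#'
#' Normalized predictive entropy of the mean softmax vector across passes:
#' 0 for a repeated one-hot prediction, 1 when the mean is uniform over
#' classes.
#'
#' @param passes List of >= 2 probability vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
classification_uncertainty <- function(passes) {
  if (length(passes) < 2L)
    stop("contract error: need at least 2 passes", call. = FALSE)
  k <- length(passes[[1L]])
  for (p in passes)
    if (length(p) != k)
      stop("contract error: probability vectors of unequal length",
           call. = FALSE)
  pbar <- Reduce(`+`, passes) / length(passes)
  pbar <- pbar / sum(pbar)
  nz <- pbar > 0
  h <- -sum(pbar[nz] * log(pbar[nz]))
  min(1, h / log(k))
}

#' Compare uncertainty scores of correct vs incorrect predictions
#'
#' Two-sided Mann-Whitney rank test. The returned `U` counts pairs
#' `(a, b)`, `a` from `correct` and `b` from `incorrect`, with `a < b`,
#' plus half the ties.
#'
#' @param correct,incorrect Non-empty numeric vectors of uncertainty scores.
#' @return List with `U` and `p_value`.
#' @export
compare_uncertainty_distributions <- function(correct, incorrect) {
  if (length(correct) == 0L || length(incorrect) == 0L)
    stop("contract error: both score lists must be non-empty", call. = FALSE)
  r <- rank(c(incorrect, correct))
  n_i <- length(incorrect)
  U <- sum(r[seq_len(n_i)]) - n_i * (n_i + 1) / 2
  p <- suppressWarnings(
    stats::wilcox.test(correct, incorrect, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)$p.value)
  list(U = U, p_value = p)
}

#' Predict the test set and write results
#'
#' One deterministic (dropout-off) prediction per test sample. Semantic
#' outputs are saved both as the continuous probability map and as the
#' Otsu-thresholded binary mask; regression outputs as 32-bit float TIFF;
#' classification predictions are appended to a results CSV (one row per
#' image with the per-class probabilities). Shape-incompatible images are
#' skipped with a warning.
#'
#' @param net Trained `dl_network`.
#' @param test List of samples (`list(id=, x=, ...)`).
#' @param task Task enum.
#' @param outdir Results directory.
#' @param class_levels Class label names (classification).
#' @return Invisible list of per-sample predictions plus file inventory.
#' @export
predict_test_set <- function(net, test, task, outdir,
                             class_levels = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  preds <- list(); files <- character(0)
  rows <- list()
  for (s in test) {
    out <- tryCatch(net_predict_sample(net, s$x, dropout = FALSE),
                    error = function(e) e)
    if (inherits(out, "error")) {
      warning("skipping ", s$id, ": ", conditionMessage(out), call. = FALSE)
      next
    }
    if (task == "classification") {
      probs <- as.numeric(out)
      lab <- (class_levels %||% as.character(seq_along(probs) - 1L))[
        which.max(probs)]
      row <- c(list(filename = s$id, predicted_label = lab),
               stats::setNames(as.list(probs),
                               paste0("prob_",
                                      class_levels %||%
                                        (seq_along(probs) - 1L))))
      rows[[length(rows) + 1L]] <- row
      preds[[s$id]] <- probs
    } else if (task %in% c("semantic_segmentation", "instance_segmentation")) {
      ot <- otsu_threshold(out)
      base <- tools::file_path_sans_ext(s$id)
      files <- c(files,
                 write_prediction(paste0(base, "_prob"), out, outdir),
                 write_prediction(paste0(base, "_mask"), ot$mask, outdir))
      preds[[s$id]] <- list(prob = out, mask = ot$mask,
                            threshold = ot$threshold)
    } else {
      files <- c(files, write_prediction(s$id, clip01(out), outdir))
      preds[[s$id]] <- out
    }
  }
  csv <- NULL
  if (task == "classification" && length(rows)) {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    csv <- file.path(outdir, "results.csv")
    utils::write.csv(df, csv, row.names = FALSE)
    files <- c(files, csv)
  }
  invisible(list(predictions = preds, files = files, results_csv = csv))
}
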