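#' Quantitative and visual evaluation of test-set predictions
#'
#' Computes the per-image metric table for the task, aggregates
#' (median, 25/75 percentiles), bootstrap distributions, and renders the
#' standard figures (side-by-side panels, error maps, metric boxplots for
#' image tasks; confusion matrix and ROC curve for classification).
#' Numeric tables are always written alongside the figures.
#'
#' @param predictions For image tasks, named list (by identifier) of
#'   predictions as returned by [predict_test_set()]; for classification a
#'   probability matrix.
#' @param truths For image tasks, named list of ground-truth arrays; for
#'   classification an integer vector of 0-based class indices.
#' @param task Task enum.
#' @param outdir Evaluation output directory.
#' @param n_rounds,fraction,seed Bootstrap settings (see
#'   [bootstrap_metric()]).
#' @param n_panels Number of example side-by-side panels to render.
#' @return An `evaluation_report` (invisible): per-image table, aggregates,
#'   bootstrap summaries and figure paths.
#' @export
evaluate_predictions <- function(predictions, truths, task, outdir,
                                 n_rounds = 100L, fraction = 0.5, seed = 1L,
                                 n_panels = 3L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  figures <- character(0)
  if (task == "classification") {
    rep <- classification_report(predictions, truths)
    summary <- list(jaccard = rep$jaccard, mae = rep$mae, mse = rep$mse,
                    auc = rep$auc)
    utils::write.csv(as.data.frame(rep$confusion_matrix),
                     file.path(outdir, "confusion_matrix.csv"))
    pts <- if (is.data.frame(rep$roc_points)) rep$roc_points else
      rep$roc_points[[1L]]
    utils::write.csv(pts, file.path(outdir, "roc_points.csv"),
                     row.names = FALSE)
    figures <- c(plot_confusion_matrix(rep$confusion_matrix,
                                       file.path(outdir, "confusion_matrix.png")),
                 plot_roc(pts, rep$auc, file.path(outdir, "roc_curve.png")))
    jsonlite::write_json(summary, file.path(outdir, "metrics_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    out <- structure(list(task = task, per_image = NULL, summary = summary,
                          confusion_matrix = rep$confusion_matrix,
                          bootstrap = NULL, figures = figures),
                     class = "evaluation_report")
    return(invisible(out))
  }
  binary <- task %in% c("semantic_segmentation", "instance_segmentation")
  rows <- lapply(names(predictions), function(id) {
    pred <- predictions[[id]]
    p <- if (is.list(pred)) (if (binary) pred$mask else pred$prob) else pred
    t <- truths[[id]]
    pm <- pixel_metrics(p, t)
    jac <- if (binary && is_binary_array(t)) jaccard_index(p, t) else NA_real_
    data.frame(identifier = id, jaccard = jac, accuracy = pm$accuracy,
               mean_absolute_error = pm$mean_absolute_error,
               mean_relative_error = pm$mean_relative_error,
               pearson_r = pm$pearson_r)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(outdir, "metrics_per_image.csv"),
                   row.names = FALSE)
  metric_cols <- c("jaccard", "accuracy", "mean_absolute_error",
                   "mean_relative_error", "pearson_r")
  aggregate <- list(); boots <- list()
  for (mc in metric_cols) {
    v <- tab[[mc]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    aggregate[[mc]] <- list(median = median(v),
                            q25 = unname(quantile(v, 0.25)),
                            q75 = unname(quantile(v, 0.75)))
    bs <- bootstrap_metric(v, n_rounds = n_rounds, fraction = fraction,
                           seed = seed)
    boots[[mc]] <- bs
    utils::write.csv(data.frame(round = seq_along(bs$medians),
                                median = bs$medians),
                     file.path(outdir, paste0("bootstrap_", mc, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(aggregate, file.path(outdir, "metrics_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  # figures
  figures <- c(figures,
               plot_metric_boxplots(tab, metric_cols,
                                    file.path(outdir, "metrics_boxplot.png")))
  ids <- utils::head(names(predictions), n_panels)
  for (id in ids) {
    pred <- predictions[[id]]
    p <- if (is.list(pred)) (if (binary) pred$mask else pred$prob) else pred
    figures <- c(figures,
                 plot_panel(id, truths[[id]], p, binary,
                            file.path(outdir,
                                      paste0("panel_",
                                             tools::file_path_sans_ext(id),
                                             ".png"))))
  }
  invisible(structure(list(task = task, per_image = tab,
                           summary = aggregate, bootstrap = boots,
                           figures = figures),
                      class = "evaluation_report"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>", x$task, "\n")
  if (!is.null(x$per_image))
    cat("  images:", nrow(x$per_image), "\n")
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    if (is.list(s))
      cat(sprintf("  %s: median %.4f [%.4f, %.4f]\n", nm, s$median,
                  s$q25, s$q75))
    else cat(sprintf("  %s: %.4f\n", nm, s))
  }
  invisible(x)
}

as_plot_matrix <- function(x) {
  m <- drop(x)
  if (length(dim(m)) == 3L) m <- m[1, , ]   # first slice of a stack
  m
}

plot_panel <- function(id, truth, pred, binary, path) {
  grDevices::png(path, width = 900, height = 320)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  show_img <- function(m, main)
    graphics::image(t(m)[, nrow(m):1, drop = FALSE], axes = FALSE,
                    col = grDevices::gray(seq(0, 1, length.out = 256)),
                    main = main)
  tm <- as_plot_matrix(truth); pm <- as_plot_matrix(pred)
  show_img(tm, paste("groundtruth:", id))
  show_img(pm, "prediction")
  if (binary && is_binary_array(tm) && is_binary_array(pm)) {
    em <- error_map(pm, tm)
    graphics::image(t(em)[, nrow(em):1, drop = FALSE], axes = FALSE,
                    zlim = c(-1, 1),
                    col = grDevices::hcl.colors(3, "Blue-Red"),
                    main = "error map (over/under)")
  } else {
    show_img(abs(pm - tm), "absolute error")
  }
  path
}

plot_metric_boxplots <- function(tab, metric_cols, path) {
  keep <- metric_cols[vapply(metric_cols, function(mc)
    any(!is.na(tab[[mc]])), TRUE)]
  grDevices::png(path, width = 200 * length(keep) + 100, height = 400)
  on.exit(grDevices::dev.off())
  graphics::boxplot(tab[keep], las = 2, main = "per-image metrics")
  path
}

plot_confusion_matrix <- function(cm, path) {
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  k <- nrow(cm)
  graphics::image(seq_len(k), seq_len(k), t(cm[k:1, , drop = FALSE]),
                  axes = FALSE, xlab = "prediction", ylab = "truth",
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  main = "confusion matrix")
  graphics::axis(1, at = seq_len(k), labels = colnames(cm))
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(cm)))
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k - i + 1, cm[i, j])
  path
}

plot_roc <- function(points, auc, path) {
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  graphics::plot(points$fpr, points$tpr, type = "l", lwd = 2,
       xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("ROC (AUC = %.3f)", auc))
  graphics::abline(0, 1, lty = 2)
  path
}
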