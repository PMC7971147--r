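# End-to-end orchestration: load -> split -> augment -> train -> predict ->
# uncertainty -> evaluate, all driven by a pipeline_config, with one logfile
# per run.

# Advanced settings (documented extension block of the configuration).
adv_defaults <- list(
  unet_depth = 3L, unet_filters = 16L, dropout_rate = 0.25,
  classifier_variant = "resnet_lite", classifier_dropout = 0.5,
  classifier_dropout_stage = 0.2,
  learning_rate = 1e-4, patience = NULL, min_delta = 1e-5,
  mc_passes = 20L, normalization = "minmax", val_fraction = 0.2,
  min_confidence = 0.5, n_bootstrap = 100L, bootstrap_fraction = 0.5,
  save_augmented_examples = 0L, augmentation_params = list())

resolve_advanced <- function(advanced) {
  unknown <- setdiff(names(advanced), names(adv_defaults))
  if (length(unknown))
    stop("configuration error: unknown advanced key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  utils::modifyList(adv_defaults, advanced)
}

# Predict one sample, slice-wise for 3D stacks (attr "stack").
net_predict_sample <- function(net, x, dropout = FALSE) {
  if (isTRUE(attr(x, "stack"))) {
    nd <- length(dim(x))
    out <- array(0, dim(x)[1:3])
    for (z in seq_len(dim(x)[1])) {
      slice <- if (nd == 3L) x[z, , ] else x[z, , , ]
      out[z, , ] <- drop(predict(net, slice, dropout = dropout))
    }
    attr(out, "stack") <- TRUE
    return(out)
  }
  predict(net, x, dropout = dropout)
}

# Load one dataset split into sample lists. Image labels are binarized for
# segmentation tasks; 3D training stacks are expanded into 2D slices while
# test stacks stay whole (predictions are reassembled).
load_split <- function(folder, task, resize_to, normalization,
                       expand_stacks, class_levels = NULL) {
  label_kind <- if (task == "classification") "csv" else "image"
  ids <- discover_pairs(folder, label_kind)
  binary <- task %in% c("semantic_segmentation", "instance_segmentation")
  if (task == "classification") {
    labs <- read_label_table(folder)
    class_levels <- class_levels %||% sort(unique(unname(labs)))
    samples <- lapply(ids, function(id) {
      x <- normalize_image(load_image(file.path(folder, "image", id)),
                           mode = normalization)
      if (!is.null(resize_to)) x <- resize_array(x, resize_to, "bilinear")
      y <- match(labs[[id]], class_levels) - 1L
      list(id = id, x = x, y = y)
    })
    return(list(samples = samples, class_levels = class_levels))
  }
  samples <- list()
  for (id in ids) {
    x <- normalize_image(load_image(file.path(folder, "image", id)),
                         mode = normalization)
    y <- load_image(file.path(folder, "groundtruth", id))
    if (binary) y <- (y > max(y) / 2) * 1 else if (max(y) > 1)
      y <- normalize_image(y)
    if (!is.null(resize_to)) {
      rp <- resize_pair(x, y, resize_to, label_is_mask = binary)
      x <- rp$image; y <- rp$label
    }
    is_stack <- is_stack_array(x)
    if (is_stack && expand_stacks) {
      for (z in seq_len(dim(x)[1])) {
        xz <- slice_z(x, z); yz <- slice_z(y, z)
        samples[[length(samples) + 1L]] <-
          list(id = sprintf("%s#z%02d", id, z), x = xz, y = yz)
      }
    } else {
      if (is_stack) { attr(x, "stack") <- TRUE; attr(y, "stack") <- TRUE }
      samples[[length(samples) + 1L]] <- list(id = id, x = x, y = y)
    }
  }
  list(samples = samples, class_levels = NULL)
}

# A 3D array is a z-stack when its leading axis is the page axis
# (trailing axis <= 4 would be channels of a 2D image).
is_stack_array <- function(x) {
  nd <- length(dim(x))
  nd == 4L || (nd == 3L && dim(x)[3] > 4L)
}

slice_z <- function(x, z) {
  if (length(dim(x)) == 3L) x[z, , ] else x[z, , , ]
}

#' Run the full pipeline for a configuration
#'
#' Executes the training workflow end to end: (i) model initialization,
#' optionally from pre-trained weights matched layer by layer; (ii) data
#' import, normalization, 20 percent validation split, shuffling and online
#' augmentation; (iii) Adam training with early stopping and best-model
#' checkpointing; (iv) prediction of the test set; (v) optional
#' Monte-Carlo-dropout uncertainty; followed by optional automatic
#' evaluation. Every run writes one logfile
#' (`<data_path>/logs/pipeline_log.txt`) with a machine-readable JSON
#' footer.
#'
#' @param config A `pipeline_config` (see [pipeline_config()],
#'   [parse_config()]).
#' @return A `dl_run` with the trained network, training history, weight
#'   manifest, prediction inventory, uncertainty results and evaluation
#'   report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  adv <- resolve_advanced(config$advanced)
  seed_everything(config$seed)
  root <- config$data_path
  task <- config$task
  tr <- load_split(file.path(root, "train"), task, config$resize_to,
                   adv$normalization, expand_stacks = TRUE)
  te <- load_split(file.path(root, "test"), task, config$resize_to,
                   adv$normalization, expand_stacks = FALSE,
                   class_levels = tr$class_levels)
  train_samples <- tr$samples
  if (length(train_samples) < 2L)
    stop("data error: need at least 2 training samples", call. = FALSE)
  ids <- vapply(train_samples, function(s) s$id, "")
  split <- split_validation(ids, fraction = adv$val_fraction,
                            seed = config$seed)
  by_id <- stats::setNames(train_samples, ids)
  train_set <- by_id[split$train]
  val_set <- by_id[split$validation]

  in_ch <- {
    x1 <- train_set[[1L]]$x
    if (length(dim(x1)) == 3L && dim(x1)[3] <= 4L) dim(x1)[3] else 1L
  }
  net <- if (task == "classification") {
    n_cls <- length(tr$class_levels)
    if (config$n_classes != n_cls)
      warning("n_classes = ", config$n_classes, " but labels.csv contains ",
              n_cls, " classes; using ", n_cls, call. = FALSE)
    b <- build_classifier(input_channels = in_ch, n_classes = n_cls,
                          variant = adv$classifier_variant,
                          dropout_rate = adv$classifier_dropout,
                          dropout_rate_stage = adv$classifier_dropout_stage)
    b$spec$class_levels <- tr$class_levels
    b
  } else {
    build_unet(input_channels = in_ch, base_filters = adv$unet_filters,
               depth = adv$unet_depth, dropout_rate = adv$dropout_rate,
               head = if (task == "regression") "linear" else "sigmoid")
  }

  manifest <- NULL
  if (!is.null(config$pretrained_weights_path)) {
    lw <- load_matching_weights(net, config$pretrained_weights_path)
    net <- lw$net
    manifest <- lw$manifest
  }

  augment <- NULL
  if (length(config$augmentations))
    augment <- augmentation_spec(config$augmentations,
                                 adv$augmentation_params)
  if (!is.null(augment) && adv$save_augmented_examples > 0L)
    save_augmented_examples(augment, train_set, adv$save_augmented_examples,
                            file.path(root, "augmented_examples"))

  binary_labels <- task %in% c("semantic_segmentation",
                               "instance_segmentation")
  state <- train_model(net, train_set, val_set, config$loss_name,
                       epochs = config$epochs,
                       batch_size = config$batch_size,
                       learning_rate = adv$learning_rate,
                       patience = adv$patience, min_delta = adv$min_delta,
                       augment = augment,
                       spatial_labels = task != "classification",
                       binary_labels = binary_labels,
                       log_dir = file.path(root, "logs"))
  net <- state$net

  results_dir <- file.path(root, "results")
  pred <- predict_test_set(net, te$samples, task, results_dir,
                           class_levels = tr$class_levels)
  instances <- NULL
  if (task == "instance_segmentation") {
    instances <- lapply(te$samples, function(s)
      detect_and_segment_instances(net, s$x,
                                   min_confidence = adv$min_confidence))
    names(instances) <- vapply(te$samples, function(s) s$id, "")
    counts <- data.frame(filename = names(instances),
                         n_instances = vapply(instances, length, 1L))
    utils::write.csv(counts, file.path(results_dir, "instance_counts.csv"),
                     row.names = FALSE)
    for (id in names(instances)) {
      inst <- instances[[id]]
      base <- tools::file_path_sans_ext(id)
      for (k in seq_along(inst))
        write_prediction(sprintf("%s_instance_%02d", base, k),
                         inst[[k]]$mask, results_dir)
    }
  }

  uncertainty <- NULL
  if (config$compute_uncertainty)
    uncertainty <- run_uncertainty(net, te$samples, task, results_dir,
                                   T = adv$mc_passes,
                                   class_levels = tr$class_levels,
                                   results_csv = pred$results_csv)

  report <- NULL
  if (config$auto_evaluate) {
    eval_dir <- file.path(root, "evaluation")
    if (task == "classification") {
      probs <- do.call(rbind, pred$predictions[
        vapply(te$samples, function(s) s$id, "")])
      truths <- vapply(te$samples, function(s) s$y, 0L)
      report <- evaluate_predictions(probs, truths, task, eval_dir,
                                     n_rounds = adv$n_bootstrap,
                                     fraction = adv$bootstrap_fraction,
                                     seed = config$seed)
    } else {
      truths <- stats::setNames(lapply(te$samples, function(s) s$y),
                                vapply(te$samples, function(s) s$id, ""))
      report <- evaluate_predictions(pred$predictions, truths, task,
                                     eval_dir,
                                     n_rounds = adv$n_bootstrap,
                                     fraction = adv$bootstrap_fraction,
                                     seed = config$seed)
    }
  }

  log_path <- write_run_log(root, config, adv, state, manifest, pred,
                            uncertainty, report)
  structure(list(config = config, advanced = adv, net = net,
                 train_state = state, weight_manifest = manifest,
                 predictions = pred, instances = instances,
                 uncertainty = uncertainty, evaluation = report,
                 log_path = log_path,
                 class_levels = tr$class_levels),
            class = "dl_run")
}

# Monte-Carlo-dropout uncertainty for the test set; maps for image tasks,
# a trailing `uncertainty` column in the results CSV for classification.
run_uncertainty <- function(net, test, task, results_dir, T = 20L,
                            class_levels = NULL, results_csv = NULL) {
  if (task == "classification") {
    scores <- vapply(test, function(s) {
      passes <- lapply(seq_len(T), function(i)
        as.numeric(predict(net, s$x, dropout = TRUE)))
      classification_uncertainty(passes)
    }, 0)
    names(scores) <- vapply(test, function(s) s$id, "")
    if (!is.null(results_csv) && file.exists(results_csv)) {
      df <- utils::read.csv(results_csv, stringsAsFactors = FALSE)
      df$uncertainty <- unname(scores[df$filename])
      utils::write.csv(df, results_csv, row.names = FALSE)
    }
    return(list(scores = scores, T = T))
  }
  maps <- list(); u <- numeric(0)
  for (s in test) {
    passes <- lapply(seq_len(T), function(i)
      net_predict_sample(net, s$x, dropout = TRUE))
    passes <- lapply(passes, function(p) { attr(p, "stack") <- NULL; p })
    pu <- pixel_uncertainty(passes)
    base <- tools::file_path_sans_ext(s$id)
    write_prediction(paste0("uncertainty_", base), clip01(pu$map),
                     results_dir)
    maps[[s$id]] <- pu$map
    u[s$id] <- pu$u
  }
  utils::write.csv(data.frame(filename = names(u),
                              average_pixel_uncertainty = unname(u)),
                   file.path(results_dir, "uncertainty_summary.csv"),
                   row.names = FALSE)
  list(maps = maps, average_pixel_uncertainty = u, T = T)
}

# One logfile per run: human-readable body, machine-readable JSON footer.
write_run_log <- function(root, config, adv, state, manifest, pred,
                          uncertainty, report) {
  dir.create(file.path(root, "logs"), recursive = TRUE, showWarnings = FALSE)
  path <- file.path(root, "logs", "pipeline_log.txt")
  lines <- c("bioimagedl pipeline run",
             paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             "",
             "configuration:",
             paste0("  task: ", config$task),
             paste0("  seed: ", config$seed),
             paste0("  data_path: ", config$data_path),
             paste0("  batch_size: ", config$batch_size,
                    "  epochs: ", config$epochs,
                    "  loss: ", config$loss_name),
             paste0("  augmentations: ",
                    if (length(config$augmentations))
                      paste(config$augmentations, collapse = ", ")
                    else "(none)"),
             "",
             if (!is.null(manifest)) manifest_lines(manifest) else
               "no pre-trained weights requested",
             "",
             sprintf("training: %d epochs run, best epoch %d (val loss %.6g)",
                     state$epochs_run, state$best_epoch, state$best_val_loss),
             "per-epoch losses (train, validation):",
             sprintf("  epoch %3d: %.6f  %.6f",
                     seq_along(state$train_losses), state$train_losses,
                     state$val_losses),
             "",
             "output files:",
             paste0("  ", pred$files))
  footer <- list(
    config = unclass(config)[c("task", "seed", "batch_size", "epochs",
                               "loss_name", "n_classes",
                               "compute_uncertainty", "auto_evaluate")],
    seed = config$seed,
    epochs_run = state$epochs_run,
    best_epoch = state$best_epoch,
    train_losses = state$train_losses,
    val_losses = state$val_losses,
    batch_order = state$batch_order,
    weights_loaded = if (!is.null(manifest)) manifest$loaded$layer else
      character(0),
    weights_skipped = if (!is.null(manifest)) manifest$skipped$layer else
      character(0),
    files = pred$files)
  writeLines(c(lines, "", "JSON-FOOTER:",
               jsonlite::toJSON(footer, auto_unbox = TRUE, digits = NA)),
             path)
  path
}

#' Read the machine-readable footer of a pipeline logfile
#' @param path Logfile path (`.../logs/pipeline_log.txt`).
#' @return Parsed footer list.
#' @export
read_run_log <- function(path) {
  lines <- readLines(path)
  i <- which(lines == "JSON-FOOTER:")
  jsonlite::fromJSON(paste(lines[(i + 1L):length(lines)], collapse = "\n"),
                     simplifyVector = TRUE)
}

#' @export
print.dl_run <- function(x, ...) {
  cat("<dl_run>", x$config$task, "\n")
  print(x$train_state)
  if (!is.null(x$evaluation)) print(x$evaluation)
  cat("  log:", x$log_path, "\n")
  invisible(x)
}

#' @export
summary.dl_run <- function(object, ...) print(object)

#' Plot the training history of a run
#' @param x A `dl_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dl_run <- function(x, ...) {
  st <- x$train_state
  graphics::plot(seq_along(st$train_losses), st$train_losses, type = "l",
                 lwd = 2, xlab = "epoch", ylab = "loss",
                 ylim = range(c(st$train_losses, st$val_losses)), ...)
  graphics::lines(seq_along(st$val_losses), st$val_losses, lwd = 2, lty = 2)
  graphics::abline(v = st$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   lwd = 2, bty = "n")
  invisible(x)
}
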