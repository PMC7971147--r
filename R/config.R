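# The twelve user-settable pipeline parameters, their JSON aliases and
# validation. Only the task and the data path are mandatory; everything
# else has a documented default.

TASKS <- c("semantic_segmentation", "instance_segmentation", "regression",
           "classification")
LOSSES <- c("binary_crossentropy", "categorical_crossentropy", "mse",
            "instance_composite")

# canonical name -> accepted JSON keys (first alias = canonical)
CONFIG_KEYS <- list(
  task = c("task", "use_algorithm"),
  seed = c("seed"),
  data_path = c("data_path", "path"),
  pretrained_weights_path = c("pretrained_weights_path"),
  batch_size = c("batch_size", "batchsize"),
  epochs = c("epochs", "Iterations_Over_Dataset", "iterations_over_dataset"),
  augmentations = c("augmentations", "data_augmentations"),
  loss_name = c("loss_name", "loss_function"),
  n_classes = c("n_classes", "num_classes"),
  resize_to = c("resize_to", "image_size"),
  compute_uncertainty = c("compute_uncertainty", "calculate_uncertainty"),
  auto_evaluate = c("auto_evaluate", "evaluation"))

default_loss <- function(task)
  switch(task,
         semantic_segmentation = "binary_crossentropy",
         instance_segmentation = "instance_composite",
         regression = "mse",
         classification = "categorical_crossentropy")

#' Build a validated pipeline configuration
#'
#' Exactly the twelve pipeline parameters are accepted (unknown keys are
#' rejected); only `task` and `data_path` are mandatory. An optional
#' `advanced` block carries the documented extension settings (network
#' size, learning rate, augmentation parameter overrides, number of
#' Monte-Carlo passes, ...). Defaults: `seed = 1`, `batch_size = 1`,
#' `epochs = 100`, no augmentations, loss chosen by task, `n_classes = 2`,
#' no resize, `compute_uncertainty = FALSE`, `auto_evaluate = TRUE`, no
#' pre-trained weights.
#'
#' @param task One of `"semantic_segmentation"`, `"instance_segmentation"`,
#'   `"regression"`, `"classification"`.
#' @param data_path Project directory with `train/` and `test/` folders.
#' @param seed Reproducibility seed for the whole run.
#' @param pretrained_weights_path Optional weight archive for transfer
#'   learning.
#' @param batch_size,epochs Training schedule (both >= 1).
#' @param augmentations Character vector of augmentation operator names.
#' @param loss_name Loss enum; default depends on the task.
#' @param n_classes Number of classes (semantic segmentation supports
#'   exactly two: background vs foreground).
#' @param resize_to Optional `c(H, W)` to resize images during import.
#' @param compute_uncertainty Run Monte-Carlo-dropout uncertainty after
#'   prediction?
#' @param auto_evaluate Run the quantitative evaluation after prediction?
#' @param advanced Named list of extension settings.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(task, data_path, seed = 1L,
                            pretrained_weights_path = NULL,
                            batch_size = 1L, epochs = 100L,
                            augmentations = character(0),
                            loss_name = NULL, n_classes = 2L,
                            resize_to = NULL,
                            compute_uncertainty = FALSE,
                            auto_evaluate = TRUE,
                            advanced = list()) {
  if (missing(task) || is.null(task))
    stop("configuration error: missing mandatory key `task`", call. = FALSE)
  if (missing(data_path) || is.null(data_path))
    stop("configuration error: missing mandatory key `data_path`",
         call. = FALSE)
  if (!task %in% TASKS)
    stop("configuration error: invalid task \"", task,
         "\"; allowed values: ", paste(TASKS, collapse = ", "),
         call. = FALSE)
  loss_name <- loss_name %||% default_loss(task)
  if (!loss_name %in% LOSSES)
    stop("configuration error: invalid loss \"", loss_name,
         "\"; allowed values: ", paste(LOSSES, collapse = ", "),
         call. = FALSE)
  batch_size <- as.integer(batch_size)
  epochs <- as.integer(epochs)
  n_classes <- as.integer(n_classes)
  if (is.na(batch_size) || batch_size < 1L)
    stop("configuration error: batch_size must be >= 1", call. = FALSE)
  if (is.na(epochs) || epochs < 1L)
    stop("configuration error: epochs must be >= 1", call. = FALSE)
  if (n_classes < 1L)
    stop("configuration error: n_classes must be positive", call. = FALSE)
  if (task == "semantic_segmentation" && n_classes != 2L)
    stop("configuration error: semantic segmentation supports exactly two ",
         "classes (background vs. foreground); got n_classes = ", n_classes,
         call. = FALSE)
  if (length(augmentations)) {
    augmentation_spec(as.character(augmentations))  # validates names
    augmentations <- as.character(augmentations)
  } else augmentations <- character(0)
  if (!is.null(resize_to)) {
    resize_to <- as.integer(resize_to)
    if (length(resize_to) == 1L) resize_to <- rep(resize_to, 2L)
    if (any(is.na(resize_to)) || any(resize_to <= 0L))
      stop("configuration error: resize_to must be positive dimensions",
           call. = FALSE)
  }
  structure(list(task = task, seed = as.integer(seed),
                 data_path = data_path,
                 pretrained_weights_path = pretrained_weights_path,
                 batch_size = batch_size, epochs = epochs,
                 augmentations = augmentations, loss_name = loss_name,
                 n_classes = n_classes, resize_to = resize_to,
                 compute_uncertainty = isTRUE(compute_uncertainty),
                 auto_evaluate = isTRUE(auto_evaluate),
                 advanced = advanced),
            class = "pipeline_config")
}

#' Parse a JSON configuration file
#'
#' Accepts the canonical key names and their familiar aliases
#' (`use_algorithm`, `path`, `batchsize`, `Iterations_Over_Dataset`, ...).
#' Unknown keys are rejected with an error naming the offender.
#'
#' @param path Path to a JSON file.
#' @return A validated `pipeline_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path))
    stop("configuration error: file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(unlist(CONFIG_KEYS), "advanced")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  args <- list()
  for (canon in names(CONFIG_KEYS)) {
    hits <- intersect(CONFIG_KEYS[[canon]], names(raw))
    if (length(hits) > 1L)
      stop("configuration error: duplicate settings for `", canon, "`: ",
           paste(hits, collapse = ", "), call. = FALSE)
    if (length(hits) == 1L) args[[canon]] <- raw[[hits]]
  }
  if (!is.null(raw$advanced)) args$advanced <- as.list(raw$advanced)
  do.call(pipeline_config, args)
}

#' Serialize a configuration back to JSON
#'
#' `parse_config(serialize_config(cfg))` reproduces `cfg`.
#'
#' @param config A `pipeline_config`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, TRUE)]
  if (!length(x$augmentations)) x$augmentations <- NULL
  if (!length(x$advanced)) x$advanced <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  task:", x$task, "| seed:", x$seed, "\n")
  cat("  data_path:", x$data_path, "\n")
  cat("  batch_size:", x$batch_size, "| epochs:", x$epochs,
      "| loss:", x$loss_name, "| n_classes:", x$n_classes, "\n")
  cat("  augmentations:",
      if (length(x$augmentations)) paste(x$augmentations, collapse = ", ")
      else "(none)", "\n")
  cat("  resize_to:", if (is.null(x$resize_to)) "(none)" else
    paste(x$resize_to, collapse = "x"),
    "| uncertainty:", x$compute_uncertainty,
    "| evaluate:", x$auto_evaluate, "\n")
  if (!is.null(x$pretrained_weights_path))
    cat("  pretrained weights:", x$pretrained_weights_path, "\n")
  invisible(x)
}
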