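#' Save network weights as a flat name/tensor archive
#'
#' The archive stores every parameter tensor under its layer name together
#' with a header of shapes, so weights can later be matched into any model
#' by name and shape (transfer learning).
#'
#' @param net A `dl_network` (or a bare named list of parameter arrays).
#' @param path Output file path (conventionally `.weights`).
#' @return `path`, invisibly.
#' @export
save_weights <- function(net, path) {
  params <- if (inherits(net, "dl_network")) net$params else net
  header <- lapply(params, function(p) as.integer(dim(p) %||% length(p)))
  saveRDS(list(format = "bioimagedl-weights-v1", header = header,
               tensors = params),
          path)
  invisible(path)
}

#' Load stored weights into a model by layer compatibility
#'
#' Matching happens at layer granularity: the kernel and bias tensors of a
#' layer (`<layer>_W`, `<layer>_b`) are loaded together, and only when every
#' tensor of that layer exists in the model with exactly matching name and
#' shape; otherwise the whole layer is skipped. Mismatches never raise: the
#' returned manifest reports both lists tensor by tensor, and the pipeline
#' echoes it into the logfile.
#'
#' @param net A `dl_network`.
#' @param weights_path Path to an archive written by [save_weights()].
#' @return List with `net` (weights applied) and `manifest`, a
#'   `weight_manifest` with `loaded` and `skipped` data frames covering every
#'   stored entry.
#' @export
load_matching_weights <- function(net, weights_path) {
  if (!file.exists(weights_path))
    stop("I/O error: weights file not found: ", weights_path, call. = FALSE)
  arch <- tryCatch(readRDS(weights_path), error = function(e)
    stop("I/O error reading weights ", weights_path, ": ",
         conditionMessage(e), call. = FALSE))
  tensors <- arch$tensors %||% list()
  shp <- function(p) as.integer(dim(p) %||% length(p))
  layer_of <- function(nm) sub("_(W|b)$", "", nm)
  tensor_ok <- vapply(names(tensors), function(nm) {
    !is.null(net$params[[nm]]) &&
      identical(shp(net$params[[nm]]), shp(tensors[[nm]]))
  }, TRUE)
  layer_ok <- tapply(tensor_ok, layer_of(names(tensors)), all)
  loaded <- list(); skipped <- list()
  for (nm in names(tensors)) {
    stored_shape <- shp(tensors[[nm]])
    if (isTRUE(layer_ok[[layer_of(nm)]])) {
      net$params[[nm]] <- tensors[[nm]]
      loaded[[nm]] <- stored_shape
    } else {
      model_shape <- if (is.null(net$params[[nm]])) "absent" else
        paste(shp(net$params[[nm]]), collapse = "x")
      skipped[[nm]] <- list(stored = stored_shape, model = model_shape)
    }
  }
  manifest <- structure(
    list(loaded = data.frame(
           layer = names(loaded),
           shape = vapply(loaded, paste, "", collapse = "x"),
           row.names = NULL),
         skipped = data.frame(
           layer = names(skipped),
           stored_shape = vapply(skipped, function(s)
             paste(s$stored, collapse = "x"), ""),
           model_shape = vapply(skipped, function(s)
             if (identical(s$model, "absent")) "absent" else s$model, ""),
           row.names = NULL),
         n_stored = length(tensors)),
    class = "weight_manifest")
  list(net = net, manifest = manifest)
}

#' @export
print.weight_manifest <- function(x, ...) {
  cat("<weight_manifest>", nrow(x$loaded), "loaded,",
      nrow(x$skipped), "skipped of", x$n_stored, "stored tensors\n")
  if (nrow(x$loaded)) {
    cat("loaded:\n")
    print(x$loaded, row.names = FALSE)
  }
  if (nrow(x$skipped)) {
    cat("skipped:\n")
    print(x$skipped, row.names = FALSE)
  }
  invisible(x)
}

# Render the manifest as plain text lines for the logfile.
manifest_lines <- function(m) {
  c(paste0("weights loaded (", nrow(m$loaded), "):"),
    if (nrow(m$loaded))
      paste0("  + ", m$loaded$layer, " [", m$loaded$shape, "]"),
    paste0("weights skipped (", nrow(m$skipped), "):"),
    if (nrow(m$skipped))
      paste0("  - ", m$skipped$layer, " stored [", m$skipped$stored_shape,
             "] model [", m$skipped$model_shape, "]"))
}
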