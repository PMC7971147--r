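#' Create instance-level ground truth from a binary semantic mask
#'
#' Each connected foreground component becomes one instance
#' (8-connectivity in 2D, 26-connectivity in 3D). Instance masks are
#' pairwise disjoint and their union reproduces the input foreground.
#'
#' @param mask Binary array (`{0,1}`), 2D or 3D.
#' @return An `instance_set`: list of instances, each with `mask`
#'   (binary array), `bbox` (per-dimension index ranges) and `confidence`.
#' @export
masks_from_semantic <- function(mask) {
  if (!is_binary_array(mask))
    stop("contract error: mask must be binary {0,1}", call. = FALSE)
  mask <- as.array(mask * 1)
  lab <- cpp_label_components(mask)
  instance_set_from_labels(lab, confidence = rep(1, max(lab)))
}

# Build an instance_set from a labeled array and per-label confidences.
instance_set_from_labels <- function(lab, confidence) {
  n <- max(lab)
  instances <- vector("list", n)
  dims <- dim(lab)
  for (k in seq_len(n)) {
    m <- (lab == k) * 1
    idx <- which(lab == k, arr.ind = TRUE)
    if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1L)
    bbox <- apply(idx, 2L, range)
    instances[[k]] <- list(mask = m, bbox = bbox,
                           confidence = confidence[k])
  }
  structure(instances, class = "instance_set")
}

#' Detect and segment object instances in an image
#'
#' Reference instance backend: the semantic network predicts a foreground
#' probability map, Otsu's method binarizes it, and connected components
#' become instances. Each instance carries its bounding box and a
#' confidence equal to the mean predicted foreground probability inside the
#' component; components whose confidence falls below `min_confidence` are
#' discarded (this makes near-blank predictions yield an empty set).
#' Instances are returned sorted by descending confidence.
#'
#' @param net Trained semantic `dl_network`.
#' @param image Sample array.
#' @param min_confidence Minimum mean foreground probability (default 0.5).
#' @return An `instance_set` (possibly empty).
#' @export
detect_and_segment_instances <- function(net, image, min_confidence = 0.5) {
  prob <- predict(net, image, dropout = FALSE)
  if (max(prob) - min(prob) <= 1e-6)
    return(structure(list(), class = "instance_set"))
  ot <- otsu_threshold(prob)
  lab <- cpp_label_components(as.array(ot$mask))
  n <- max(lab)
  if (n == 0L) return(structure(list(), class = "instance_set"))
  conf <- vapply(seq_len(n), function(k) mean(prob[lab == k]), 0)
  keep <- which(conf >= min_confidence)
  if (length(keep) == 0L) return(structure(list(), class = "instance_set"))
  relab <- array(0L, dim(lab))
  for (j in seq_along(keep)) relab[lab == keep[j]] <- j
  out <- instance_set_from_labels(relab, confidence = conf[keep])
  out[order(vapply(out, function(i) i$confidence, 0), decreasing = TRUE)] |>
    structure(class = "instance_set")
}

#' @export
print.instance_set <- function(x, ...) {
  cat("<instance_set>", length(x), "instance(s)\n")
  for (k in seq_along(x))
    cat(sprintf("  #%d: %d px, confidence %.3f\n", k, sum(x[[k]]$mask),
                x[[k]]$confidence))
  invisible(x)
}
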