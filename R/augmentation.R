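# Paired online augmentation. Spatial operators (flips, zoom, rotation) are
# applied with the identical geometric map to image and image-valued label
# (labels with nearest-neighbour resampling so masks stay binary); color
# operators touch the image only.

AUG_SPATIAL <- c("horizontal_flip", "vertical_flip", "zoom", "rotation")
AUG_COLOR <- c("contrast", "brightness", "poisson_noise", "feature_scaling",
               "mean_std_normalization", "resampling", "gamma_shift")

#' Define an augmentation specification
#'
#' @param operators Character vector of operator names (subset of the
#'   spatial operators `horizontal_flip`, `vertical_flip`, `zoom`,
#'   `rotation` and color operators `contrast`, `brightness`,
#'   `poisson_noise`, `feature_scaling`, `mean_std_normalization`,
#'   `resampling`, `gamma_shift`).
#' @param params Optional named list overriding per-operator parameter
#'   ranges, e.g. `list(rotation = list(range = c(-30, 30)))`. Each operator
#'   also accepts a `p` entry (application probability, default 0.5).
#' @return An `augmentation_spec`.
#' @export
augmentation_spec <- function(operators = character(0), params = list()) {
  unknown <- setdiff(operators, c(AUG_SPATIAL, AUG_COLOR))
  if (length(unknown))
    stop("configuration error: unknown augmentation operator(s): ",
         paste(unknown, collapse = ", "), "; allowed: ",
         paste(c(AUG_SPATIAL, AUG_COLOR), collapse = ", "), call. = FALSE)
  defaults <- list(
    horizontal_flip = list(p = 0.5),
    vertical_flip = list(p = 0.5),
    zoom = list(p = 0.5, range = c(0.9, 1.1)),
    rotation = list(p = 0.5, range = c(-20, 20)),
    contrast = list(p = 0.5, range = c(0.8, 1.25)),
    brightness = list(p = 0.5, range = c(-0.1, 0.1)),
    poisson_noise = list(p = 0.5, scale = 255),
    feature_scaling = list(p = 0.5),
    mean_std_normalization = list(p = 0.5),
    resampling = list(p = 0.5, range = c(1, 2)),
    gamma_shift = list(p = 0.5, range = c(0.7, 1.4)))
  for (op in names(params)) {
    if (!op %in% names(defaults))
      stop("configuration error: unknown augmentation operator: ", op,
           call. = FALSE)
    defaults[[op]] <- utils::modifyList(defaults[[op]], params[[op]])
  }
  structure(list(operators = operators, params = defaults),
            class = "augmentation_spec")
}

#' Sample a concrete transform from a specification
#'
#' Each enabled operator is independently included with its probability and
#' its parameters drawn from the configured range, using the current RNG
#' stream. The result is a plain, serializable list so drawn augmentations
#' can be inspected and saved.
#'
#' @param spec An [augmentation_spec()].
#' @return List of concrete operator descriptors (class
#'   `augmentation_transform`).
#' @export
sample_transform <- function(spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  ops <- list()
  for (op in spec$operators) {
    pr <- spec$params[[op]]
    if (runif(1) >= pr$p) next
    d <- list(op = op)
    if (op %in% c("zoom", "rotation", "contrast", "brightness",
                  "gamma_shift", "resampling"))
      d$value <- runif(1, pr$range[1], pr$range[2])
    if (op == "poisson_noise") d$scale <- pr$scale
    ops[[length(ops) + 1L]] <- d
  }
  structure(ops, class = "augmentation_transform")
}

#' Apply the spatial part of a transform to an image/label pair
#'
#' The identical geometric map is applied to both arrays; the label is
#' resampled with nearest-neighbour and, for binary labels, re-binarized.
#' Output shape equals input shape (zoom and rotation crop or pad back).
#'
#' @param transform A sampled [sample_transform()] result.
#' @param image `(H,W)` or `(H,W,C)` array.
#' @param label Array of the same spatial shape.
#' @param binary_label Re-binarize the label after interpolation?
#' @return List with transformed `image` and `label`.
#' @export
apply_spatial <- function(transform, image, label, binary_label = TRUE) {
  if (!is.null(label) &&
      !identical(dim(image)[1:2], dim(label)[1:2]))
    stop("contract error: image and label spatial shapes differ",
         call. = FALSE)
  for (d in transform) {
    if (!d$op %in% AUG_SPATIAL) next
    image <- spatial_op(d, image, "bilinear")
    if (!is.null(label)) {
      label <- spatial_op(d, label, "none")
      if (binary_label) label <- (label > 0.5) * 1
    }
  }
  list(image = image, label = label)
}

# One geometric operator applied to all channels of `x`.
spatial_op <- function(d, x, filter) {
  per_channel <- function(f) {
    if (length(dim(x)) == 3L) {
      for (c in seq_len(dim(x)[3])) x[, , c] <- f(x[, , c])
      x
    } else f(x)
  }
  switch(d$op,
         horizontal_flip = per_channel(function(m) m[, rev(seq_len(ncol(m)))]),
         vertical_flip = per_channel(function(m) m[rev(seq_len(nrow(m))), ]),
         rotation = per_channel(function(m)
           as.array(EBImage::rotate(m, d$value, filter = filter,
                                    output.dim = dim(m), bg.col = 0))),
         zoom = per_channel(function(m) zoom_op(m, d$value, filter)),
         x)
}

# Zoom keeping the canvas size: scale, then center-crop or zero-pad back.
zoom_op <- function(m, factor, filter) {
  H <- nrow(m); W <- ncol(m)
  Hn <- max(1L, round(H * factor)); Wn <- max(1L, round(W * factor))
  z <- as.array(EBImage::resize(m, w = Hn, h = Wn, filter = filter))
  out <- matrix(0, H, W)
  if (Hn >= H) {
    off_h <- (Hn - H) %/% 2L; off_w <- (Wn - W) %/% 2L
    out <- z[off_h + seq_len(H), off_w + seq_len(W)]
  } else {
    off_h <- (H - Hn) %/% 2L; off_w <- (W - Wn) %/% 2L
    out[off_h + seq_len(Hn), off_w + seq_len(Wn)] <- z
  }
  out
}

#' Apply the color part of a transform to an image
#'
#' Labels are never touched by color operators. Outputs are clipped back to
#' `[0,1]` except `mean_std_normalization`, which z-scores the image (zero
#' mean, unit variance).
#'
#' @param transform A sampled [sample_transform()] result.
#' @param image Array with values in `[0,1]`.
#' @return Transformed image array.
#' @export
apply_color <- function(transform, image) {
  for (d in transform) {
    if (!d$op %in% AUG_COLOR) next
    image <- switch(d$op,
      contrast = clip01((image - 0.5) * d$value + 0.5),
      brightness = clip01(image + d$value),
      poisson_noise = {
        counts <- rpois(length(image), lambda = as.vector(image) * d$scale)
        clip01(array(counts / d$scale, dim(image)))
      },
      feature_scaling = normalize_image(image),
      mean_std_normalization = {
        s <- sd(image)
        if (s == 0) image - mean(image) else (image - mean(image)) / s
      },
      resampling = {
        f <- d$value
        dn <- c(max(1L, round(nrow(image) / f)), max(1L, round(ncol(image) / f)))
        down <- resize_array(image, dn, "bilinear")
        resize_array(down, dim(image)[1:2], "bilinear")
      },
      gamma_shift = {
        if (d$value <= 0)
          stop("parameter error: gamma must be positive", call. = FALSE)
        clip01(image)^d$value
      },
      image)
  }
  image
}

# Full online augmentation of one sample: draw a transform, apply spatial
# part to image+label and color part to the image.
augment_sample <- function(spec, image, label = NULL, binary_label = TRUE) {
  tr <- sample_transform(spec)
  sp <- apply_spatial(tr, image, label, binary_label = binary_label)
  list(image = apply_color(tr, sp$image), label = sp$label, transform = tr)
}

#' Write augmented example pairs for visual inspection
#'
#' @param spec An [augmentation_spec()].
#' @param samples List of `list(id=, x=, y=)` samples.
#' @param k Number of augmented examples to write.
#' @param outdir Output directory.
#' @return Paths of written files, invisibly.
#' @export
save_augmented_examples <- function(spec, samples, k, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_len(min(k, length(samples)))) {
    s <- samples[[i]]
    a <- augment_sample(spec, s$x, if (is.array(s$y)) s$y else NULL)
    base <- tools::file_path_sans_ext(s$id)
    paths <- c(paths,
               write_prediction(paste0(base, "_aug_image"),
                                clip01(drop(a$image)), outdir))
    if (!is.null(a$label))
      paths <- c(paths,
                 write_prediction(paste0(base, "_aug_label"),
                                  drop(a$label), outdir))
  }
  invisible(paths)
}
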