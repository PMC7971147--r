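#' Discover image/label pairs by filename
#'
#' Input and ground-truth images must carry the same filename (including the
#' file ending). For image-labelled tasks the pair partner is looked up in
#' the `groundtruth/` subfolder; for classification it is a row of
#' `groundtruth/labels.csv` (header `filename,label`). Matching is exact and
#' case-sensitive.
#'
#' @param folder Dataset split folder containing an `image/` subfolder and
#'   either a `groundtruth/` image subfolder or `groundtruth/labels.csv`.
#' @param label_kind `"image"` for image-valued labels, `"csv"` for
#'   classification labels.
#' @return Sorted character vector of paired identifiers (filenames).
#' @export
discover_pairs <- function(folder, label_kind = c("image", "csv")) {
  label_kind <- match.arg(label_kind)
  img_dir <- file.path(folder, "image")
  if (!dir.exists(img_dir))
    stop("data error: no image/ subfolder in ", folder, call. = FALSE)
  imgs <- sort(list.files(img_dir, pattern = "\\.(tif|tiff|png)$"))
  if (length(imgs) == 0L)
    stop("data error: no images found in ", img_dir, call. = FALSE)
  if (label_kind == "image") {
    gt_dir <- file.path(folder, "groundtruth")
    if (!dir.exists(gt_dir))
      stop("data error: no groundtruth/ subfolder in ", folder, call. = FALSE)
    labs <- sort(list.files(gt_dir, pattern = "\\.(tif|tiff|png)$"))
  } else {
    csv <- file.path(folder, "groundtruth", "labels.csv")
    if (!file.exists(csv))
      stop("data error: missing ", csv, call. = FALSE)
    tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
    if (!all(c("filename", "label") %in% names(tab)))
      stop("data error: labels.csv must have columns filename,label",
           call. = FALSE)
    labs <- sort(unique(tab$filename))
  }
  missing_lab <- setdiff(imgs, labs)
  if (length(missing_lab))
    stop("pairing error: no label found for image(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  if (label_kind == "image") {
    missing_img <- setdiff(labs, imgs)
    if (length(missing_img))
      stop("pairing error: no image found for label(s): ",
           paste(missing_img, collapse = ", "), call. = FALSE)
  }
  sort(imgs)
}

#' Read the classification label table of a split folder
#' @param folder Split folder (`.../train` or `.../test`).
#' @return Named character vector, names = filenames.
#' @export
read_label_table <- function(folder) {
  tab <- utils::read.csv(file.path(folder, "groundtruth", "labels.csv"),
                         stringsAsFactors = FALSE)
  stats::setNames(as.character(tab$label), tab$filename)
}

#' Load a 2D image or 3D stack from TIFF or PNG
#'
#' Raw stored values are returned as doubles without normalization
#' (`uint8` stays 0..255, `uint16` 0..65535). Multi-page TIFFs become
#' `(Z, H, W)` or `(Z, H, W, C)` stacks; single images `(H, W)` or `(H, W, C)`.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric array of raw pixel values.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                      error = function(e)
                        stop("I/O error reading ", path, ": ", conditionMessage(e),
                             call. = FALSE))
    pages <- lapply(pages, function(p) {
      # readTIFF scales to [0,1]; undo for 8/16-bit integer data. 32-bit
      # data holds unit-interval reals already.
      bits <- attr(p, "bits.per.sample") %||% 8L
      out <- unclass(p) * if (bits <= 16L) (2^bits - 1) else 1
      attributes(out) <- list(dim = dim(p))
      out
    })
    if (length(pages) == 1L) return(pages[[1L]])
    d <- dim(pages[[1L]])
    out <- array(0, c(length(pages), d))
    for (z in seq_along(pages)) {
      if (!identical(dim(pages[[z]]), d))
        stop("I/O error: pages of ", path, " differ in shape", call. = FALSE)
      if (length(d) == 2L) out[z, , ] <- pages[[z]] else out[z, , , ] <- pages[[z]]
    }
    out
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e)
                      stop("I/O error reading ", path, ": ", conditionMessage(e),
                           call. = FALSE))
    info <- attr(img, "info")
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    out <- unclass(img) * (2^depth - 1)  # undo readPNG's [0,1] scaling
    attr(out, "info") <- NULL
    out
  } else {
    stop("I/O error: unsupported file type: ", path, call. = FALSE)
  }
}

#' Normalize an image to the unit interval
#'
#' Default is per-image min-max scaling; `mode = "fixed"` divides by the
#' dtype ceiling inferred from the value range instead (intensity-comparable
#' studies). A constant image maps to all zeros.
#'
#' @param image Numeric array.
#' @param mode `"minmax"` (default) or `"fixed"`.
#' @return Array with values in `[0, 1]`.
#' @export
normalize_image <- function(image, mode = c("minmax", "fixed")) {
  mode <- match.arg(mode)
  if (mode == "minmax") {
    rng <- range(image)
    if (rng[2] - rng[1] <= 0) return(array(0, dim(image) %||% length(image)))
    (image - rng[1]) / (rng[2] - rng[1])
  } else {
    mx <- max(image)
    ceiling_val <- if (mx <= 1) 1 else if (mx <= 255) 255 else 65535
    clip01(image / ceiling_val)
  }
}

#' Split identifiers into training and validation sets
#'
#' Membership is a deterministic function of the (sorted) identifiers, the
#' fraction and the seed, independent of input ordering and of the caller's
#' RNG state. The validation size is `max(1, round(fraction * n))`; the
#' remaining training identifiers are returned shuffled.
#'
#' @param ids Character vector of sample identifiers.
#' @param fraction Validation fraction in (0, 1); default 0.2.
#' @param seed Integer seed.
#' @return List with elements `train` and `validation`.
#' @export
split_validation <- function(ids, fraction = 0.2, seed = 1) {
  if (length(ids) < 2L)
    stop("data error: need at least 2 samples to hold out validation data",
         call. = FALSE)
  if (!(fraction > 0 && fraction < 1))
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  ids <- sort(ids)
  n_val <- max(1L, round(fraction * length(ids)))
  with_local_seed(seed, {
    val_idx <- sample(length(ids), n_val)
    train <- sample(ids[-val_idx])  # shuffled training order
    list(train = train, validation = ids[val_idx])
  })
}

#' Resize an image/label pair
#'
#' Images and continuous (regression) labels are resized with bilinear
#' interpolation, mask labels with nearest-neighbour so they stay binary;
#' class labels pass through unchanged. 3D stacks are resized slice-wise.
#'
#' @param image Image array (`(H,W)`, `(H,W,C)`, `(Z,H,W)` or `(Z,H,W,C)`).
#' @param label Image-valued label of the same spatial shape, or a class label.
#' @param target Integer vector `c(H, W)`.
#' @param label_is_mask Should the label be treated as a binary mask?
#' @return List with resized `image` and `label`.
#' @export
resize_pair <- function(image, label = NULL, target, label_is_mask = TRUE) {
  if (any(target <= 0)) stop("target dimensions must be positive", call. = FALSE)
  img <- resize_array(image, target, "bilinear")
  lab <- label
  if (!is.null(label) && (is.matrix(label) || is.array(label))) {
    lab <- resize_array(label, target,
                        if (label_is_mask) "none" else "bilinear")
    if (label_is_mask) lab <- (lab > 0.5) * 1
  }
  list(image = img, label = lab)
}

# Resize the trailing-two spatial dims of a 2D image / 3D stack.
# `filter` follows EBImage: "bilinear" or "none" (nearest).
resize_array <- function(x, target, filter = "bilinear") {
  nd <- length(dim(x) %||% 0)
  rs2 <- function(m) as.array(EBImage::resize(m, w = target[1], h = target[2],
                                              filter = filter))
  if (nd == 2L) return(rs2(x))
  if (nd == 3L) {
    # ambiguity: (H,W,C) small trailing dim = channels, else (Z,H,W) stack
    if (dim(x)[3] <= 4L) {
      out <- array(0, c(target, dim(x)[3]))
      for (c in seq_len(dim(x)[3])) out[, , c] <- rs2(x[, , c])
      return(out)
    }
    out <- array(0, c(dim(x)[1], target))
    for (z in seq_len(dim(x)[1])) out[z, , ] <- rs2(x[z, , ])
    return(out)
  }
  if (nd == 4L) {
    out <- array(0, c(dim(x)[1], target, dim(x)[4]))
    for (z in seq_len(dim(x)[1]))
      for (c in seq_len(dim(x)[4])) out[z, , c] <- rs2(x[z, , c])
    return(out)
  }
  stop("unsupported array rank for resize: ", nd, call. = FALSE)
}

#' Write a prediction as a TIFF image or stack
#'
#' Binary masks are stored as 8-bit `{0, 255}`; continuous outputs as 32-bit
#' float. 3D predictions (`(Z,H,W)`) become multi-page TIFFs. The base
#' filename of the originating input is kept.
#'
#' @param identifier Output filename (extension replaced with `.tif`).
#' @param prediction Array with values in `[0,1]` (continuous) or `{0,1}`.
#' @param outdir Output directory (created if needed).
#' @return The written file path, invisibly.
#' @export
write_prediction <- function(identifier, prediction, outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("I/O error: cannot create ", outdir, call. = FALSE)
  fn <- file.path(outdir, paste0(tools::file_path_sans_ext(identifier), ".tif"))
  binary <- is_binary_array(prediction)
  bits <- if (binary) 8L else 32L
  prediction <- clip01(prediction)
  nd <- length(dim(prediction) %||% 0)
  if (nd == 3L) {
    # (Z,H,W) stack -> multi-page
    pages <- lapply(seq_len(dim(prediction)[1]), function(z) prediction[z, , ])
    tiff::writeTIFF(pages, fn, bits.per.sample = bits)
  } else {
    tiff::writeTIFF(prediction, fn, bits.per.sample = bits)
  }
  invisible(fn)
}
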