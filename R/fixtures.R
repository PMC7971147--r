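# Synthetic desk-scale datasets with exact ground truth: bright blob
# ("nucleus") scenes on a noisy background, written in the pipeline's folder
# layout so every stage runs without external data.

#' Parameters of the synthetic blob scenes
#'
#' Defaults emulate nucleus-like microscopy at desk scale: 64x64 images,
#' 1-6 blobs of radius 4-9 px, foreground mean 0.8 on background 0.2 with
#' Gaussian noise sd 0.08. With `overlap_allowed = FALSE` blob masks are
#' kept disjoint with a 2 px gap, so instance counts are unambiguous.
#'
#' @param size Image side length in pixels.
#' @param n_blobs Integer range `c(min, max)` of blobs per image.
#' @param radius Range `c(min, max)` of blob radii in pixels.
#' @param fg,bg Foreground / background mean intensities.
#' @param noise_sd Gaussian noise standard deviation.
#' @param overlap_allowed May blobs overlap?
#' @return A `blob_scene_params` list.
#' @export
blob_scene_params <- function(size = 64L, n_blobs = c(1L, 6L),
                              radius = c(4, 9), fg = 0.8, bg = 0.2,
                              noise_sd = 0.08, overlap_allowed = FALSE) {
  structure(list(size = size, n_blobs = n_blobs, radius = radius, fg = fg,
                 bg = bg, noise_sd = noise_sd,
                 overlap_allowed = overlap_allowed),
            class = "blob_scene_params")
}

# Draw one scene: returns image, binary mask, blob table. Ground truth is
# analytic: mask pixel = 1 iff the pixel center lies within a blob disk.
make_blob_scene <- function(params) {
  sz <- params$size
  k <- sample(params$n_blobs[1]:params$n_blobs[2], 1L)
  centers <- matrix(0, 0, 2); radii <- numeric(0)
  tries <- 0L
  while (length(radii) < k && tries < 200L) {
    tries <- tries + 1L
    r <- runif(1, params$radius[1], params$radius[2])
    cx <- runif(1, r + 1, sz - r)
    cy <- runif(1, r + 1, sz - r)
    if (!params$overlap_allowed && length(radii) > 0) {
      dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (any(dd < radii + r + 2)) next  # 2 px gap keeps instances disjoint
    }
    centers <- rbind(centers, c(cx, cy)); radii <- c(radii, r)
  }
  k <- length(radii)
  gx <- matrix(seq_len(sz), sz, sz)
  gy <- t(gx)
  mask <- matrix(0, sz, sz)
  for (i in seq_len(k))
    mask <- mask | ((gx - centers[i, 1])^2 + (gy - centers[i, 2])^2 <=
                      radii[i]^2)
  mask <- mask * 1
  img <- params$bg + (params$fg - params$bg) * mask +
    rnorm(sz * sz, 0, params$noise_sd)
  list(image = clip01(matrix(img, sz, sz)), mask = mask,
       centers = centers, radii = radii, count = k)
}

# Continuous "staining" target: a Gaussian ridge along each blob boundary
# (nuclear-envelope-like ring), computed from the noiseless geometry.
ring_target <- function(scene, sigma = 1.5) {
  sz <- nrow(scene$mask)
  gx <- matrix(seq_len(sz), sz, sz)
  gy <- t(gx)
  target <- matrix(0, sz, sz)
  for (i in seq_along(scene$radii)) {
    d <- sqrt((gx - scene$centers[i, 1])^2 + (gy - scene$centers[i, 2])^2)
    target <- pmax(target, exp(-(d - scene$radii[i])^2 / (2 * sigma^2)))
  }
  target
}

write_img16 <- function(x, path) tiff::writeTIFF(x, path, bits.per.sample = 16L)

#' Generate a synthetic semantic-segmentation dataset
#'
#' Writes `train/` and `test/` folders (each with `image/` and
#' `groundtruth/`) of blob scenes with exact binary masks, and a
#' `manifest.json` recording the planted blob counts and centers.
#'
#' @param params A [blob_scene_params()].
#' @param n_train,n_test Number of image/mask pairs per split.
#' @param outdir Dataset root directory.
#' @return The manifest (invisible): per-image truth records.
#' @export
generate_segmentation_dataset <- function(params = blob_scene_params(),
                                          n_train = 20L, n_test = 5L,
                                          outdir) {
  gen <- function(split, n) {
    img_dir <- file.path(outdir, split, "image")
    gt_dir <- file.path(outdir, split, "groundtruth")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(gt_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(img_dir)) stop("I/O error: cannot create ", img_dir,
                                   call. = FALSE)
    lapply(seq_len(n), function(i) {
      s <- make_blob_scene(params)
      fn <- sprintf("%s_%03d.tif", split, i)
      write_img16(s$image, file.path(img_dir, fn))
      tiff::writeTIFF(s$mask, file.path(gt_dir, fn), bits.per.sample = 8L)
      list(filename = fn, split = split, count = s$count,
           centers = s$centers)
    })
  }
  manifest <- list(task = "semantic_segmentation",
                   params = unclass(params),
                   train = gen("train", n_train), test = gen("test", n_test))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a synthetic pixel-wise regression dataset
#'
#' Input images are noisy blob scenes; the continuous target is a
#' deterministic ring ("envelope") around each blob boundary computed from
#' the noiseless geometry, so a consistent input-to-staining mapping exists
#' for the network to learn. With `stacks = TRUE`, 3D multi-page stacks are
#' emitted (blobs span 3-5 of 8 slices).
#'
#' @inheritParams generate_segmentation_dataset
#' @param stacks Emit 3D stacks instead of 2D images?
#' @param n_slices Number of z slices per stack when `stacks = TRUE`.
#' @return The manifest (invisible).
#' @export
generate_regression_dataset <- function(params = blob_scene_params(),
                                        n_train = 20L, n_test = 5L,
                                        outdir, stacks = FALSE,
                                        n_slices = 8L) {
  gen <- function(split, n) {
    img_dir <- file.path(outdir, split, "image")
    gt_dir <- file.path(outdir, split, "groundtruth")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(gt_dir, recursive = TRUE, showWarnings = FALSE)
    lapply(seq_len(n), function(i) {
      fn <- sprintf("%s_%03d.tif", split, i)
      if (!stacks) {
        s <- make_blob_scene(params)
        tg <- ring_target(s)
        write_img16(s$image, file.path(img_dir, fn))
        tiff::writeTIFF(tg, file.path(gt_dir, fn), bits.per.sample = 32L)
        return(list(filename = fn, split = split, count = s$count))
      }
      z0 <- sample(seq_len(n_slices - 2L), 1L)
      extent <- sample(3:5, 1L)
      s <- make_blob_scene(params)
      tg <- ring_target(s)
      pages_img <- list(); pages_tg <- list()
      for (z in seq_len(n_slices)) {
        active <- z >= z0 && z < z0 + extent
        pages_img[[z]] <- if (active) s$image else
          clip01(matrix(params$bg + rnorm(params$size^2, 0, params$noise_sd),
                        params$size, params$size))
        pages_tg[[z]] <- if (active) tg else matrix(0, params$size, params$size)
      }
      tiff::writeTIFF(pages_img, file.path(img_dir, fn),
                      bits.per.sample = 16L)
      tiff::writeTIFF(pages_tg, file.path(gt_dir, fn), bits.per.sample = 32L)
      list(filename = fn, split = split, count = s$count, z0 = z0,
           extent = extent)
    })
  }
  manifest <- list(task = "regression", params = unclass(params),
                   stacks = stacks,
                   train = gen("train", n_train), test = gen("test", n_test))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a synthetic two-or-more-class classification dataset
#'
#' Class `k` images carry `round(k * separation)` additional blobs on top of
#' the base count range, a learnable morphological difference;
#' `separation = 0` makes the class-conditional distributions identical.
#' Labels are written to `groundtruth/labels.csv` (`filename,label`).
#'
#' @param n_per_class Training images per class.
#' @param n_test_per_class Test images per class.
#' @param separation Blob-count shift between consecutive classes (>= 0).
#' @param n_classes Number of classes (>= 2).
#' @param params A [blob_scene_params()]; the blob-count range is used as
#'   the class-0 base range.
#' @param outdir Dataset root directory.
#' @return The manifest (invisible).
#' @export
generate_classification_dataset <- function(n_per_class = 50L,
                                            n_test_per_class = 10L,
                                            separation = 6,
                                            n_classes = 2L,
                                            params = blob_scene_params(
                                              n_blobs = c(2L, 4L)),
                                            outdir) {
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (n_classes < 2L) stop("need at least two classes", call. = FALSE)
  gen <- function(split, n_each) {
    img_dir <- file.path(outdir, split, "image")
    gt_dir <- file.path(outdir, split, "groundtruth")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(gt_dir, recursive = TRUE, showWarnings = FALSE)
    recs <- list()
    for (k in seq_len(n_classes) - 1L) {
      pk <- params
      pk$n_blobs <- params$n_blobs + round(k * separation)
      for (i in seq_len(n_each)) {
        s <- make_blob_scene(pk)
        fn <- sprintf("%s_c%d_%03d.tif", split, k, i)
        write_img16(s$image, file.path(img_dir, fn))
        recs[[length(recs) + 1L]] <- list(filename = fn, label = k,
                                          split = split, count = s$count)
      }
    }
    df <- data.frame(filename = vapply(recs, `[[`, "", "filename"),
                     label = vapply(recs, `[[`, 0, "label"))
    utils::write.csv(df, file.path(gt_dir, "labels.csv"), row.names = FALSE)
    recs
  }
  manifest <- list(task = "classification", n_classes = n_classes,
                   separation = separation, params = unclass(params),
                   train = gen("train", n_per_class),
                   test = gen("test", n_test_per_class))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Corrupt images to emulate out-of-distribution inputs
#'
#' Applies severity-scaled heavy Gaussian blur, contrast inversion and
#' additive noise. Severity 0 returns the inputs bitwise unchanged; the
#' corruption is drawn from the current RNG stream, hence seed-reproducible.
#'
#' @param images List of 2D image arrays (or a single array).
#' @param severity Corruption strength in `[0, 1]`.
#' @return Corrupted images in the same structure.
#' @export
corrupt_images <- function(images, severity) {
  if (severity < 0 || severity > 1)
    stop("severity must be in [0, 1]", call. = FALSE)
  single <- !is.list(images)
  if (single) images <- list(images)
  out <- lapply(images, function(x) {
    if (severity == 0) return(x)
    y <- x
    sigma <- 3 * severity
    y <- as.array(EBImage::gblur(y, sigma = sigma))
    y <- (1 - severity) * y + severity * (1 - y)   # contrast inversion
    y <- y + rnorm(length(y), 0, 0.2 * severity)
    clip01(array(y, dim(x)))
  })
  if (single) out[[1L]] else out
}
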