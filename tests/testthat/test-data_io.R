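make_pair_folders <- function(imgs, labs, label_kind = "image") {
  root <- tempfile("pairs")
  dir.create(file.path(root, "image"), recursive = TRUE)
  m <- matrix(runif(16), 4, 4)
  for (f in imgs) tiff::writeTIFF(m, file.path(root, "image", f))
  if (label_kind == "image") {
    dir.create(file.path(root, "groundtruth"), recursive = TRUE)
    for (f in labs) tiff::writeTIFF(m, file.path(root, "groundtruth", f))
  } else {
    dir.create(file.path(root, "groundtruth"), recursive = TRUE)
    write.csv(data.frame(filename = labs, label = seq_along(labs)),
              file.path(root, "groundtruth", "labels.csv"),
              row.names = FALSE)
  }
  root
}

test_that("pairing matches identical filenames and is case-sensitive", {
  root <- make_pair_folders(c("a.tif", "b.tif"), c("a.tif", "b.tif"))
  expect_equal(discover_pairs(root, "image"), c("a.tif", "b.tif"))
  root <- make_pair_folders("a.tif", "A.tif")
  expect_error(discover_pairs(root, "image"), "pairing error.*a.tif")
  root <- make_pair_folders(c("a.tif", "b.tif"), "a.tif")
  expect_error(discover_pairs(root, "image"), "pairing error.*b.tif")
  empty <- tempfile(); dir.create(file.path(empty, "image"), recursive = TRUE)
  expect_error(discover_pairs(empty, "image"), "data error")
})

test_that("classification pairing uses the labels CSV", {
  root <- make_pair_folders("x.tif", "x.tif", label_kind = "csv")
  expect_equal(discover_pairs(root, "csv"), "x.tif")
  root <- make_pair_folders(c("x.tif", "y.tif"), "x.tif", label_kind = "csv")
  expect_error(discover_pairs(root, "csv"), "pairing error.*y.tif")
})

test_that("images load as raw values with the documented shapes", {
  tf <- tempfile(fileext = ".tif")
  m <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  tiff::writeTIFF(m, tf, bits.per.sample = 16L)
  x <- load_image(tf)
  expect_equal(dim(x), c(64, 64))
  expect_gt(max(x), 2)  # raw 16-bit values, not normalized
  # 8-page stack
  tiff::writeTIFF(replicate(8, m, simplify = FALSE), tf,
                  bits.per.sample = 16L)
  x <- load_image(tf)
  expect_equal(dim(x), c(8, 64, 64))
  # RGB PNG keeps channels and undoes readPNG's scaling
  pf <- tempfile(fileext = ".png")
  png::writePNG(array(runif(32 * 32 * 3), c(32, 32, 3)), pf)
  x <- load_image(pf)
  expect_equal(dim(x), c(32, 32, 3))
  expect_gt(max(x), 2)
  expect_error(load_image(tempfile(fileext = ".tif")), "I/O error")
})

test_that("normalization scales to [0,1] and zeroes constant images", {
  x <- matrix(c(0, 255, 100, 30), 2, 2)
  expect_equal(normalize_image(x), x / 255)
  expect_equal(normalize_image(matrix(7, 3, 3)), array(0, c(3, 3)))
  x <- matrix(c(100, 1100, 600, 350), 2, 2)
  expect_equal(normalize_image(x), (x - 100) / 1000)
  expect_equal(normalize_image(matrix(c(0, 128, 255, 64), 2, 2),
                               mode = "fixed"),
               matrix(c(0, 128, 255, 64), 2, 2) / 255)
})

test_that("validation split sizes, determinism and order-invariance hold", {
  ids <- sprintf("img_%02d.tif", 1:10)
  sp <- split_validation(ids, 0.2, seed = 5)
  expect_length(sp$validation, 2L)
  expect_length(sp$train, 8L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_length(split_validation(sprintf("%d.tif", 1:5), 0.2, 1)$validation,
                1L)
  sp2 <- split_validation(ids, 0.2, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- split_validation(rev(ids), 0.2, seed = 5)   # order-invariant
  expect_identical(sp, sp3)
  expect_false(identical(sp, split_validation(ids, 0.2, seed = 6)))
  expect_error(split_validation("one.tif", 0.2, 1), "data error")
})

test_that("resizing interpolates images smoothly and masks nearest", {
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  rp <- resize_pair(img, mask, c(32L, 32L), label_is_mask = TRUE)
  expect_equal(dim(rp$image), c(32, 32))
  expect_true(all(rp$label %in% c(0, 1)))
  up <- resize_pair(img, img, c(128L, 128L), label_is_mask = FALSE)
  expect_equal(dim(up$image), c(128, 128))
  expect_false(all(up$label %in% c(0, 1)))  # continuous label stays smooth
  rp2 <- resize_pair(img, label = 1L, c(32L, 32L))
  expect_identical(rp2$label, 1L)  # class labels unchanged
})

test_that("prediction write/load round trip preserves shape and values", {
  out <- tempfile("preds")
  mask <- matrix(rbinom(64 * 64, 1, 0.4), 64, 64)
  f <- write_prediction("m.tif", mask, out)
  back <- load_image(f)
  expect_true(all(back %in% c(0, 255)))  # binary convention on disk
  expect_equal((back > 0) * 1, mask)
  cont <- matrix(runif(32 * 32), 32, 32)
  back <- load_image(write_prediction("c.tif", cont, out))
  expect_equal(back, cont, tolerance = 1e-6)
  stack <- array(runif(8 * 16 * 16), c(8, 16, 16))
  back <- load_image(write_prediction("s.tif", stack, out))
  expect_equal(dim(back), c(8, 16, 16))
  expect_equal(back, stack, tolerance = 1e-6)
})
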