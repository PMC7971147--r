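test_that("segmentation fixtures write exact paired files and truth", {
  td <- tempfile("fix")
  seed_everything(71)
  man <- generate_segmentation_dataset(blob_scene_params(),
                                       n_train = 20L, n_test = 3L,
                                       outdir = td)
  imgs <- list.files(file.path(td, "train", "image"))
  gts <- list.files(file.path(td, "train", "groundtruth"))
  expect_length(imgs, 20L)
  expect_identical(imgs, gts)   # matching filenames
  expect_length(man$test, 3L)
  # mask equals planted truth: foreground fraction moderate, count matches
  for (rec in man$train[1:5]) {
    m <- load_image(file.path(td, "train", "groundtruth", rec$filename))
    m <- (m > 0) * 1
    frac <- mean(m)
    expect_gt(frac, 0); expect_lt(frac, 0.5)
    expect_equal(oracle_flood_count(m), rec$count)
  }
})

test_that("regeneration with the same seed is bitwise reproducible", {
  t1 <- tempfile(); t2 <- tempfile()
  seed_everything(72)
  generate_regression_dataset(n_train = 3L, n_test = 1L, outdir = t1)
  seed_everything(72)
  generate_regression_dataset(n_train = 3L, n_test = 1L, outdir = t2)
  f <- list.files(file.path(t1, "train", "groundtruth"), full.names = TRUE)[1]
  g <- list.files(file.path(t2, "train", "groundtruth"), full.names = TRUE)[1]
  expect_identical(load_image(f), load_image(g))
})

test_that("ring targets live on blob boundaries and stay in [0,1]", {
  seed_everything(73)
  p <- blob_scene_params()
  s <- bioimagedl:::make_blob_scene(p)
  tg <- bioimagedl:::ring_target(s)
  expect_true(all(tg >= 0 & tg <= 1))
  # boundary band: pixels whose distance to a blob edge is < 1 px
  sz <- p$size
  gx <- matrix(seq_len(sz), sz, sz); gy <- t(gx)
  band <- matrix(FALSE, sz, sz)
  for (i in seq_along(s$radii)) {
    d <- sqrt((gx - s$centers[i, 1])^2 + (gy - s$centers[i, 2])^2)
    band <- band | abs(d - s$radii[i]) < 1
  }
  expect_gt(mean(tg[band]), mean(tg[!band]))
})

test_that("3D regression stacks exercise the multi-page pathway", {
  td <- tempfile("stack")
  seed_everything(74)
  generate_regression_dataset(n_train = 2L, n_test = 1L, outdir = td,
                              stacks = TRUE)
  x <- load_image(list.files(file.path(td, "train", "image"),
                             full.names = TRUE)[1])
  expect_equal(dim(x), c(8, 64, 64))
})

test_that("classification fixtures separate classes by construction", {
  td <- tempfile("cls")
  seed_everything(75)
  man <- generate_classification_dataset(n_per_class = 10L,
                                         n_test_per_class = 3L,
                                         separation = 6, outdir = td)
  csv <- read.csv(file.path(td, "train", "groundtruth", "labels.csv"))
  expect_equal(nrow(csv), 20L)
  expect_length(list.files(file.path(td, "train", "image")), 20L)
  counts <- vapply(man$train, `[[`, 0, "count")
  labels <- vapply(man$train, `[[`, 0, "label")
  # large separation: a blob-count threshold classifies perfectly
  thr <- max(counts[labels == 0])
  expect_true(all(counts[labels == 1] > thr))
})

test_that("zero separation yields identically distributed classes", {
  seed_everything(76)
  td <- tempfile("cls0")
  man <- generate_classification_dataset(n_per_class = 5L,
                                         n_test_per_class = 2L,
                                         separation = 0, outdir = td)
  counts <- vapply(man$train, `[[`, 0, "count")
  labels <- vapply(man$train, `[[`, 0, "label")
  rng <- blob_scene_params(n_blobs = c(2L, 4L))$n_blobs
  expect_true(all(counts >= rng[1] & counts <= rng[2]))
})

test_that("corruption is identity at severity 0 and seeded above", {
  seed_everything(77)
  imgs <- lapply(1:3, function(i) matrix(runif(64 * 64), 64, 64))
  expect_identical(corrupt_images(imgs, 0), imgs)
  seed_everything(78)
  a <- corrupt_images(imgs, 1)
  seed_everything(78)
  b <- corrupt_images(imgs, 1)
  expect_identical(a, b)
  expect_false(identical(a, imgs))
  expect_true(all(vapply(a, function(x) all(x >= 0 & x <= 1), TRUE)))
  expect_error(corrupt_images(imgs, 2), "severity")
})
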