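test_that("the U-Net preserves spatial shape across depths and odd sizes", {
  seed_everything(31)
  for (depth in 2:3) {
    for (sz in list(c(32L, 32L), c(17L, 23L))) {
      net <- build_unet(base_filters = 4L, depth = depth)
      x <- array(runif(prod(sz)), c(sz, 1, 1))
      out <- bioimagedl:::net_forward(net, x)$out
      expect_equal(dim(out)[1:2], sz)
      expect_true(all(out > 0 & out < 1))  # sigmoid head
    }
  }
  net <- build_unet(base_filters = 4L, depth = 2L, auto_pad = FALSE)
  expect_error(bioimagedl:::net_forward(net,
                                        array(runif(17 * 23), c(17, 23, 1, 1))),
               "shape error")
})

test_that("the linear regression head is unbounded and dropout-0 is deterministic", {
  seed_everything(32)
  net <- build_unet(base_filters = 4L, depth = 2L, head = "linear",
                    dropout_rate = 0)
  # scale a weight up so outputs leave (0,1)
  net$params$head_W <- net$params$head_W * 50
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  out <- bioimagedl:::net_forward(net, x)$out
  expect_true(any(out < 0 | out > 1))
  p1 <- predict(net, x[, , , 1], dropout = TRUE)
  p2 <- predict(net, x[, , , 1], dropout = TRUE)
  expect_identical(p1, p2)  # no noise source at rate 0
})

test_that("classifier outputs are probability vectors for 2 and 15 classes", {
  seed_everything(33)
  for (k in c(2L, 15L)) {
    net <- build_classifier(n_classes = k)
    x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
    out <- bioimagedl:::net_forward(net, x)$out
    expect_equal(dim(out), c(2L, k))
    expect_equal(rowSums(out), c(1, 1), tolerance = 1e-6)
  }
  expect_error(build_classifier(n_classes = 1L), "n_classes")
  net <- build_classifier(n_classes = 3L)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(predict(net, x[, , , 1]), predict(net, x[, , , 1]))
})

test_that("the full-depth residual layout builds and runs forward", {
  seed_everything(34)
  net <- build_classifier(n_classes = 4L, variant = "resnet50")
  conv_layers <- grep("_W$", names(net$params), value = TRUE)
  expect_equal(length(grep("_c[0-9]_W$|stem_W|fc_W", conv_layers)), 50L)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  out <- bioimagedl:::net_forward(net, x)$out
  expect_equal(sum(out), 1, tolerance = 1e-6)
})

test_that("weight matching loads by name+shape and reports everything", {
  seed_everything(35)
  net <- build_unet(base_filters = 4L, depth = 2L)
  wf <- tempfile(fileext = ".weights")
  save_weights(net, wf)
  # identical architecture: everything loads
  net2 <- build_unet(base_filters = 4L, depth = 2L)
  res <- load_matching_weights(net2, wf)
  expect_equal(nrow(res$manifest$loaded), length(net$params))
  expect_equal(nrow(res$manifest$skipped), 0L)
  for (nm in names(net$params))
    expect_identical(res$net$params[[nm]], net$params[[nm]])
  # doubled filters: every shape differs, everything is skipped
  net3 <- build_unet(base_filters = 8L, depth = 2L)
  res3 <- load_matching_weights(net3, wf)
  expect_equal(nrow(res3$manifest$loaded), 0L)
  expect_equal(nrow(res3$manifest$skipped), length(net$params))
  expect_equal(res3$manifest$n_stored,
               nrow(res3$manifest$loaded) + nrow(res3$manifest$skipped))
  # partial match: classifier backbone transfers across head sizes
  c15 <- build_classifier(n_classes = 15L)
  wf2 <- tempfile(fileext = ".weights")
  save_weights(c15, wf2)
  c2 <- build_classifier(n_classes = 2L)
  res4 <- load_matching_weights(c2, wf2)
  expect_true(all(c("fc_W", "fc_b") %in% res4$manifest$skipped$layer))
  expect_true("stem_W" %in% res4$manifest$loaded$layer)
  # empty archive: nothing loads, random init kept
  wf3 <- tempfile(fileext = ".weights")
  save_weights(list(), wf3)
  res5 <- load_matching_weights(net2, wf3)
  expect_equal(nrow(res5$manifest$loaded), 0L)
  expect_error(load_matching_weights(net2, tempfile()), "I/O error")
})

test_that("save-after-load reproduces the loaded tensors bitwise", {
  seed_everything(36)
  net <- build_unet(base_filters = 4L, depth = 2L)
  wf <- tempfile(fileext = ".weights")
  save_weights(net, wf)
  net2 <- load_matching_weights(build_unet(base_filters = 4L, depth = 2L),
                                wf)$net
  wf2 <- tempfile(fileext = ".weights")
  save_weights(net2, wf2)
  expect_identical(readRDS(wf)$tensors, readRDS(wf2)$tensors)
})

test_that("instance masks from semantic masks partition the foreground", {
  m <- matrix(0, 10, 10)
  m[2:4, 2:4] <- 1; m[7:9, 7:9] <- 1
  inst <- masks_from_semantic(m)
  expect_length(inst, 2L)
  expect_equal(vapply(inst, function(i) sum(i$mask), 0), c(9, 9))
  expect_length(masks_from_semantic(matrix(0, 5, 5)), 0L)
  expect_error(masks_from_semantic(matrix(0.5, 3, 3)), "binary")
  # bounding boxes contain their masks
  for (i in inst) {
    idx <- which(i$mask == 1, arr.ind = TRUE)
    expect_true(all(idx[, 1] >= i$bbox[1, 1] & idx[, 1] <= i$bbox[2, 1]))
    expect_true(all(idx[, 2] >= i$bbox[1, 2] & idx[, 2] <= i$bbox[2, 2]))
  }
})

test_that("component labeling matches a flood-fill oracle on random masks", {
  seed_everything(37)
  for (rep in 1:25) {
    m <- matrix(rbinom(256, 1, runif(1, 0.2, 0.6)), 16, 16)
    inst <- masks_from_semantic(m)
    expect_equal(length(inst), oracle_flood_count(m))
    if (length(inst)) {
      u <- Reduce(`+`, lapply(inst, function(i) i$mask))
      expect_true(all(u %in% c(0, 1)))   # pairwise disjoint
      expect_equal(u, m)                 # union covers the foreground
    }
  }
  # 3D: diagonal voxel chain is one 26-connected component
  m3 <- array(0, c(3, 3, 3)); m3[1, 1, 1] <- 1; m3[2, 2, 2] <- 1
  expect_length(masks_from_semantic(m3), 1L)
})
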