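test_that("unknown operators are rejected and empty specs are identity", {
  expect_error(augmentation_spec("wobble"), "unknown augmentation")
  spec <- augmentation_spec(character(0))
  tr <- sample_transform(spec)
  img <- matrix(runif(64), 8, 8)
  msk <- matrix(rbinom(64, 1, 0.5), 8, 8)
  sp <- apply_spatial(tr, img, msk)
  expect_identical(sp$image, img)   # bitwise identity with nothing enabled
  expect_identical(sp$label, msk)
  expect_identical(apply_color(tr, img), img)
})

test_that("transform sampling respects probabilities and is reproducible", {
  spec <- augmentation_spec("horizontal_flip",
                            params = list(horizontal_flip = list(p = 1)))
  tr <- sample_transform(spec)
  expect_length(tr, 1L)
  expect_equal(tr[[1L]]$op, "horizontal_flip")
  spec0 <- augmentation_spec("horizontal_flip",
                             params = list(horizontal_flip = list(p = 0)))
  expect_length(sample_transform(spec0), 0L)
  spec <- augmentation_spec(c("rotation", "gamma_shift"))
  seed_everything(3)
  a <- sample_transform(spec)
  seed_everything(3)
  expect_identical(sample_transform(spec), a)
})

test_that("flips are involutions and move image and mask identically", {
  seed_everything(8)
  img <- matrix(runif(64), 8, 8)
  msk <- random_binary(8)
  for (op in c("horizontal_flip", "vertical_flip")) {
    tr <- structure(list(list(op = op)), class = "augmentation_transform")
    once <- apply_spatial(tr, img, msk)
    twice <- apply_spatial(tr, once$image, once$label)
    expect_identical(twice$image, img)
    expect_identical(twice$label, msk)
    # per-pixel: flipped mask foreground equals foreground of flipped mask
    flip <- function(m) if (op == "horizontal_flip")
      m[, rev(seq_len(ncol(m)))] else m[rev(seq_len(nrow(m))), ]
    expect_equal(once$label, flip(msk))
    expect_equal(once$image, flip(img))
  }
})

test_that("identity-parameter spatial and color operators change nothing", {
  img <- matrix(runif(256), 16, 16)
  tr <- structure(list(list(op = "rotation", value = 0),
                       list(op = "zoom", value = 1)),
                  class = "augmentation_transform")
  sp <- apply_spatial(tr, img, img, binary_label = FALSE)
  expect_equal(sp$image, img, tolerance = 1e-12)
  tr <- structure(list(list(op = "gamma_shift", value = 1),
                       list(op = "brightness", value = 0),
                       list(op = "contrast", value = 1)),
                  class = "augmentation_transform")
  expect_equal(apply_color(tr, img), img, tolerance = 1e-12)
})

test_that("spatial ops keep shape, preserve mask binarity, track markers", {
  seed_everything(21)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- matrix(0, 32, 32); msk[10:14, 20:24] <- 1
  spec <- augmentation_spec(c("rotation", "zoom"),
                            params = list(rotation = list(p = 1),
                                          zoom = list(p = 1)))
  for (i in 1:5) {
    tr <- sample_transform(spec)
    sp <- apply_spatial(tr, img, msk)
    expect_equal(dim(sp$image), dim(img))
    expect_equal(dim(sp$label), dim(msk))
    expect_true(all(sp$label %in% c(0, 1)))
    # the marker block must move with the image: the mask foreground stays
    # where the image carries the (bright) marker pixels
    img2 <- img; img2[msk == 1] <- 5
    sp2 <- apply_spatial(tr, img2, msk)
    expect_gt(mean(sp2$image[sp2$label == 1]),
              mean(sp2$image[sp2$label == 0]))
  }
})

test_that("color operators obey their analytic contracts", {
  img <- matrix(runif(256, 0.2, 0.8), 16, 16)
  zs <- apply_color(structure(list(list(op = "mean_std_normalization")),
                              class = "augmentation_transform"), img)
  expect_lt(abs(mean(zs)), 1e-6)
  expect_lt(abs(sd(zs) - 1), 1e-6)
  g <- apply_color(structure(list(list(op = "gamma_shift", value = 2)),
                             class = "augmentation_transform"), img)
  expect_equal(g, img^2)
  expect_error(apply_color(structure(list(list(op = "gamma_shift",
                                               value = -1)),
                                     class = "augmentation_transform"), img),
               "gamma")
  seed_everything(5)
  pn <- apply_color(structure(list(list(op = "poisson_noise", scale = 255)),
                              class = "augmentation_transform"), img)
  expect_true(all(pn >= 0 & pn <= 1))
  expect_false(identical(pn, img))
})

test_that("augmenting a sample never lets color ops touch the label", {
  seed_everything(14)
  img <- matrix(runif(256), 16, 16)
  msk <- random_binary(16)
  spec <- augmentation_spec(c("brightness", "contrast", "gamma_shift",
                              "poisson_noise"),
                            params = lapply(
                              stats::setNames(nm = c("brightness", "contrast",
                                                     "gamma_shift",
                                                     "poisson_noise")),
                              function(x) list(p = 1)))
  a <- bioimagedl:::augment_sample(spec, img, msk)
  expect_identical(a$label, msk)
  expect_false(identical(a$image, img))
})
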