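test_that("Otsu separates bimodal maps and handles constant maps", {
  m <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  ot <- otsu_threshold(m)
  expect_gt(ot$threshold, 0.1)
  expect_lt(ot$threshold, 0.9)
  expect_equal(ot$mask, (m > 0.5) * 1)
  otc <- otsu_threshold(matrix(0.3, 5, 5))
  expect_equal(otc$threshold, 0.3)
  expect_true(all(otc$mask == 0))
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  seed_everything(51)
  for (rep in 1:30) {
    m <- random_prob_map(16)
    expect_equal(otsu_threshold(m)$threshold, oracle_otsu(m))
  }
})

test_that("MC dropout produces T stochastic but seed-reproducible passes", {
  seed_everything(52)
  net <- tiny_unet(dropout_rate = 0.3)
  x <- matrix(runif(16 * 16), 16, 16)
  passes <- mc_dropout_predict(net, x, T = 20L)
  expect_length(passes, 20L)
  expect_false(identical(passes[[1]], passes[[2]]))
  seed_everything(99)
  a <- mc_dropout_predict(net, x, T = 3L)
  seed_everything(99)
  b <- mc_dropout_predict(net, x, T = 3L)
  expect_identical(a, b)
  net0 <- tiny_unet(dropout_rate = 0)
  p0 <- mc_dropout_predict(net0, x, T = 5L)
  for (p in p0[-1]) expect_identical(p, p0[[1]])
  expect_error(mc_dropout_predict(net, x, T = 1L), "T must be")
})

test_that("pixel uncertainty is the per-pixel population sd and u its mean", {
  expect_equal(pixel_uncertainty(list(matrix(0.4, 1, 1),
                                      matrix(0.6, 1, 1)))$u, 0.1)
  id <- matrix(runif(16), 4, 4)
  pu <- pixel_uncertainty(list(id, id, id))
  expect_true(all(pu$map == 0))
  expect_equal(pu$u, 0)
  seed_everything(53)
  passes <- lapply(1:7, function(i) matrix(runif(16), 4, 4))
  pu <- pixel_uncertainty(passes)
  arr <- simplify2array(passes)
  expect_equal(pu$map, apply(arr, c(1, 2), function(v)
    sqrt(mean((v - mean(v))^2))), tolerance = 1e-12)
  expect_equal(pu$u, mean(pu$map))
  expect_error(pixel_uncertainty(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "shape")
})

test_that("classification uncertainty hits its entropy anchors", {
  onehot <- c(1, 0, 0)
  expect_equal(classification_uncertainty(list(onehot, onehot, onehot)), 0)
  expect_equal(classification_uncertainty(list(c(0.4, 0.6), c(0.6, 0.4))), 1)
  u <- classification_uncertainty(list(c(0.25, 0.25, 0.25, 0.25),
                                       c(0.25, 0.25, 0.25, 0.25)))
  expect_equal(u, 1)
  expect_error(classification_uncertainty(list(c(0.5, 0.5), c(1, 0, 0))),
               "unequal")
})

test_that("the rank test separates disjoint score sets and ties give p ~ 1", {
  r <- compare_uncertainty_distributions(c(0, 0, 0), c(1, 1, 1))
  expect_lt(r$p_value, 0.1)
  expect_equal(r$U, 9)  # all 9 pairs have correct < incorrect
  same <- compare_uncertainty_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  expect_error(compare_uncertainty_distributions(numeric(0), 1), "non-empty")
})

test_that("the U statistic equals exhaustive pair counting", {
  seed_everything(54)
  for (rep in 1:20) {
    a <- round(runif(5), 1)   # rounding forces occasional ties
    b <- round(runif(5), 1)
    expect_equal(compare_uncertainty_distributions(a, b)$U, oracle_U(a, b))
  }
})

test_that("test-set prediction writes one output set per sample", {
  seed_everything(55)
  net <- tiny_unet()
  test <- lapply(1:5, function(i)
    list(id = sprintf("t%d.tif", i), x = matrix(runif(256), 16, 16)))
  out <- tempfile("res")
  pred <- predict_test_set(net, test, "semantic_segmentation", out)
  expect_length(pred$predictions, 5L)
  expect_length(pred$files, 10L)  # continuous + binary per image
  expect_true(all(file.exists(pred$files)))
  # deterministic with dropout off
  pred2 <- predict_test_set(net, test, "semantic_segmentation", out)
  expect_identical(lapply(pred$predictions, `[[`, "prob"),
                   lapply(pred2$predictions, `[[`, "prob"))
})

test_that("classification prediction writes a per-class probability CSV", {
  seed_everything(56)
  net <- build_classifier(n_classes = 2L)
  net$spec$class_levels <- c("benign", "blast")
  test <- lapply(1:4, function(i)
    list(id = sprintf("c%d.tif", i), x = matrix(runif(32 * 32), 32, 32),
         y = i %% 2L))
  out <- tempfile("res")
  pred <- predict_test_set(net, test, "classification", out,
                           class_levels = c("benign", "blast"))
  df <- read.csv(pred$results_csv)
  expect_equal(nrow(df), 4L)
  expect_equal(names(df),
               c("filename", "predicted_label", "prob_benign", "prob_blast"))
  expect_equal(df$prob_benign + df$prob_blast, rep(1, 4), tolerance = 1e-6)
})
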