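test_that("Jaccard matches set counting and its edge conventions", {
  p <- matrix(c(1, 1, 0, 0), 2, 2)
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(jaccard_index(p, t), 1 / 3)
  expect_equal(jaccard_index(t, t), 1)
  expect_equal(jaccard_index(matrix(c(1, 0), 1, 2), matrix(c(0, 1), 1, 2)), 0)
  expect_equal(jaccard_index(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  expect_error(jaccard_index(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
  expect_error(jaccard_index(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("pixel metrics match hand calculations", {
  p <- array(c(0, 0, 1, 1), c(2, 2))
  t <- array(c(0, 1, 1, 0), c(2, 2))
  m <- pixel_metrics(p, t)
  expect_equal(m$mean_absolute_error, 0.5)
  expect_equal(m$accuracy, 0.5)
  mm <- pixel_metrics(t, t)
  expect_equal(mm$mean_absolute_error, 0)
  expect_equal(mm$accuracy, 1)
  expect_equal(mm$pearson_r, 1)
  inv <- pixel_metrics(1 - t, t)
  expect_equal(inv$accuracy, 0)
  expect_equal(inv$pearson_r, -1)
  expect_true(is.na(pixel_metrics(p, array(1, c(2, 2)))$pearson_r))
})

test_that("all pixel metrics agree with brute-force loops on random arrays", {
  seed_everything(61)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    p <- matrix(runif(n * n), n, n)
    t <- matrix(runif(n * n), n, n)
    m <- pixel_metrics(p, t)
    expect_equal(m$mean_absolute_error, oracle_mae(p, t), tolerance = 1e-10)
    expect_equal(m$mean_relative_error, oracle_mre(p, t), tolerance = 1e-10)
    expect_equal(m$pearson_r, oracle_pearson(p, t), tolerance = 1e-10)
    pb <- random_binary(n); tb <- random_binary(n)
    expect_equal(pixel_metrics(pb, tb)$accuracy, oracle_accuracy(pb, tb),
                 tolerance = 1e-10)
    expect_equal(jaccard_index(pb, tb), oracle_jaccard(pb, tb),
                 tolerance = 1e-10)
  }
})

test_that("classification report covers its analytic anchors", {
  probs <- rbind(c(0.1, 0.9), c(0.2, 0.8), c(0.7, 0.3), c(0.6, 0.4))
  truths <- c(1L, 1L, 0L, 0L)
  rep <- classification_report(probs, truths)
  expect_equal(rep$auc, 1.0)
  expect_equal(unname(rep$confusion_matrix), diag(2L) * 2L)
  expect_equal(rep$jaccard, 1.0)
  flat <- classification_report(matrix(0.5, 4, 2), truths)
  expect_equal(flat$auc, 0.5)
  scores <- c(0.9, 0.8, 0.3, 0.1)
  r2 <- classification_report(cbind(1 - scores, scores), c(1L, 1L, 0L, 0L))
  expect_equal(r2$auc, 1.0)
  expect_error(classification_report(matrix(0, 0, 2), integer(0)), "empty")
})

test_that("AUC equals exhaustive pair counting and survives monotone maps", {
  seed_everything(62)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    scores <- round(runif(n), 1)
    truths <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE)) # both classes
    auc <- classification_report(cbind(1 - scores, scores), truths)$auc
    expect_equal(auc, oracle_auc(scores, truths), tolerance = 1e-10)
    mono <- exp(3 * scores) / 10      # strictly monotone transform
    auc2 <- classification_report(cbind(1 - mono, mono), truths)$auc
    expect_equal(auc2, auc, tolerance = 1e-10)
  }
})

test_that("confusion matrices count truth rows against prediction columns", {
  seed_everything(63)
  K <- 3L
  probs <- matrix(runif(30), 10, K)
  probs <- probs / rowSums(probs)
  truths <- sample(0:(K - 1), 10, replace = TRUE)
  rep <- classification_report(probs, truths)
  pred_lab <- max.col(probs, ties.method = "first") - 1L
  expect_equal(unname(rep$confusion_matrix),
               oracle_confusion(pred_lab, truths, K))
  expect_equal(sum(rep$confusion_matrix), 10L)
})

test_that("bootstrap of a constant list is degenerate and seeded runs agree", {
  bs <- bootstrap_metric(rep(0.7, 12), n_rounds = 100L, fraction = 0.5,
                         seed = 3)
  expect_length(bs$medians, 100L)
  expect_true(all(bs$medians == 0.7))
  expect_equal(bs$median, 0.7)
  expect_equal(bs$q25, 0.7)
  v <- runif(20)
  a <- bootstrap_metric(v, seed = 11)
  b <- bootstrap_metric(v, seed = 11)
  expect_identical(a, b)
  expect_identical(bootstrap_metric(rev(v), seed = 11), a)  # order-invariant
  expect_error(bootstrap_metric(numeric(0)), "empty")
  expect_error(bootstrap_metric(1:3, fraction = 1.5), "fraction")
})

test_that("bootstrap medians concentrate around the plain median", {
  v <- rep(c(0, 1), 40)
  bs <- bootstrap_metric(v, n_rounds = 200L, fraction = 0.5, seed = 7)
  expect_lt(abs(bs$median - median(v)), 0.1)
})

test_that("error maps flag over- and under-prediction with the right sign", {
  p <- matrix(c(1, 0, 1, 0), 2, 2)
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  em <- error_map(p, t)
  expect_equal(em, matrix(c(0, -1, 1, 0), 2, 2))
  expect_true(all(error_map(t, t) == 0))
  expect_true(all(error_map(matrix(1, 2, 2), matrix(0, 2, 2)) == 1))
  expect_equal(sum(em != 0),
               sum((p + t) > 0) - sum(p * t))  # |P u T| - |P n T|
})

test_that("the evaluation report writes tables, summaries and figures", {
  seed_everything(64)
  preds <- lapply(1:6, function(i) random_binary(16))
  names(preds) <- sprintf("img%d.tif", 1:6)
  truths <- lapply(preds, function(p) {
    q <- p; q[1, 1] <- 1 - q[1, 1]; q
  })
  out <- tempfile("eval")
  rep <- evaluate_predictions(preds, truths, "semantic_segmentation", out)
  expect_true(file.exists(file.path(out, "metrics_per_image.csv")))
  expect_true(file.exists(file.path(out, "metrics_summary.json")))
  expect_true(file.exists(file.path(out, "bootstrap_jaccard.csv")))
  expect_true(any(grepl("panel", list.files(out))))
  tab <- read.csv(file.path(out, "metrics_per_image.csv"))
  expect_equal(nrow(tab), 6L)
  # aggregates recomputable from the per-image table
  expect_equal(rep$summary$jaccard$median, median(tab$jaccard))
  # bootstrap percentiles bracket the bootstrap median
  expect_lte(rep$bootstrap$jaccard$q25, rep$bootstrap$jaccard$median)
  expect_gte(rep$bootstrap$jaccard$q75, rep$bootstrap$jaccard$median)
})
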