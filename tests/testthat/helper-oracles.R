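# Independent brute-force oracles: scalar loops and exhaustive enumeration,
# deliberately written without reusing any package internals.

oracle_jaccard <- function(p, t) {
  inter <- 0; uni <- 0
  for (i in seq_along(p)) {
    if (p[i] == 1 && t[i] == 1) inter <- inter + 1
    if (p[i] == 1 || t[i] == 1) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

oracle_accuracy <- function(p, t) {
  agree <- 0
  for (i in seq_along(p)) if (p[i] == t[i]) agree <- agree + 1
  agree / length(p)
}

oracle_mae <- function(p, t) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(p[i] - t[i])
  s / length(p)
}

oracle_mre <- function(p, t, eps = 1e-8) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(p[i] - t[i]) / (abs(t[i]) + eps)
  s / length(p)
}

oracle_pearson <- function(p, t) {
  n <- length(p)
  mp <- sum(p) / n; mt <- sum(t) / n
  num <- 0; dp <- 0; dt <- 0
  for (i in seq_len(n)) {
    num <- num + (p[i] - mp) * (t[i] - mt)
    dp <- dp + (p[i] - mp)^2
    dt <- dt + (t[i] - mt)^2
  }
  num / sqrt(dp * dt)
}

# AUC by exhaustive pair counting: concordant pairs + half ties over all
# (positive, negative) pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Mann-Whitney U: count of pairs (a from first, b from second) with a < b
# plus half the ties.
oracle_U <- function(first, second) {
  s <- 0
  for (a in first) for (b in second)
    s <- s + if (a < b) 1 else if (a == b) 0.5 else 0
  s
}

oracle_confusion <- function(pred_lab, truths, K) {
  cm <- matrix(0L, K, K)
  for (i in seq_along(truths))
    cm[truths[i] + 1L, pred_lab[i] + 1L] <- cm[truths[i] + 1L,
                                               pred_lab[i] + 1L] + 1L
  cm
}

# Otsu by exhaustive search over the 255 interior edges of a 256-bin
# histogram: class statistics computed directly from the pixel values.
oracle_otsu <- function(map) {
  rng <- range(map)
  nb <- 256L
  width <- (rng[2] - rng[1]) / nb
  best <- -Inf; best_thr <- NA
  for (k in seq_len(nb - 1L)) {
    e <- rng[1] + k * width
    c0 <- map[map < e]; c1 <- map[map >= e]
    if (length(c0) == 0 || length(c1) == 0) next
    bcv <- length(c0) * length(c1) * (mean(c0) - mean(c1))^2
    if (bcv > best) { best <- bcv; best_thr <- e }
  }
  best_thr
}

# Connected components by iterative flood fill in plain R (8-connectivity).
oracle_flood_count <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  count <- 0
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || seen[i, j]) next
    count <- count + 1
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        if (mask[ii, jj] == 1 && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

# Scalar-loop losses on small arrays.
oracle_mse_loss <- function(p, t) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - t[i])^2
  s / length(p)
}
oracle_bce_loss <- function(p, t, eps = 1e-7) {
  s <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    s <- s - (t[i] * log(pi) + (1 - t[i]) * log(1 - pi))
  }
  s / length(p)
}
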