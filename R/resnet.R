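#' Build a residual network classifier with dropout
#'
#' Two layouts are available. `"resnet50"` is the canonical 50-weight-layer
#' bottleneck layout (stages of 3/4/6/3 blocks, 7x7 stem, channel widths
#' 256/512/1024/2048) with dropout added after each residual stage and
#' before the final dense layer, so that Monte-Carlo-dropout uncertainty is
#' available at inference. `"resnet_lite"` is a reduced-depth basic-block
#' layout (18 weight layers) sized for CPU-scale experiments. Softmax output
#' sums to one per sample.
#'
#' @param input_channels Number of input image channels.
#' @param n_classes Number of classes (>= 2).
#' @param variant `"resnet_lite"` (default) or `"resnet50"`.
#' @param dropout_rate Dropout rate before the final dense layer; each
#'   residual stage uses `dropout_rate_stage`.
#' @param dropout_rate_stage Dropout rate applied after each residual stage.
#' @return A `dl_network` object.
#' @export
build_classifier <- function(input_channels = 1L, n_classes = 2L,
                             variant = c("resnet_lite", "resnet50"),
                             dropout_rate = 0.5, dropout_rate_stage = 0.2) {
  variant <- match.arg(variant)
  if (n_classes < 2L)
    stop("configuration error: n_classes must be >= 2", call. = FALSE)
  if (variant == "resnet50") {
    layout <- list(block = "bottleneck",
                   stem = list(k = 7L, stride = 2L, pool = TRUE, ch = 64L),
                   channels = c(256L, 512L, 1024L, 2048L),
                   blocks = c(3L, 4L, 6L, 3L))
  } else {
    layout <- list(block = "basic",
                   stem = list(k = 3L, stride = 1L, pool = TRUE, ch = 8L),
                   channels = c(8L, 16L, 32L),
                   blocks = c(2L, 2L, 2L))
  }
  p <- list()
  st <- layout$stem
  p$stem_W <- init_conv(st$k, st$k, input_channels, st$ch)
  p$stem_b <- numeric(st$ch)
  blocks <- list()
  cin <- st$ch
  for (si in seq_along(layout$channels)) {
    cout <- layout$channels[si]
    mid <- if (layout$block == "bottleneck") cout %/% 4L else cout
    for (bi in seq_len(layout$blocks[si])) {
      stride <- if (bi == 1L && si > 1L) 2L else 1L
      proj <- (stride != 1L || cin != cout)
      id <- paste0("s", si, "b", bi)
      if (layout$block == "basic") {
        p[[paste0(id, "_c1_W")]] <- init_conv(3, 3, cin, cout)
        p[[paste0(id, "_c1_b")]] <- numeric(cout)
        p[[paste0(id, "_c2_W")]] <- init_conv(3, 3, cout, cout)
        p[[paste0(id, "_c2_b")]] <- numeric(cout)
      } else {
        p[[paste0(id, "_c1_W")]] <- init_conv(1, 1, cin, mid)
        p[[paste0(id, "_c1_b")]] <- numeric(mid)
        p[[paste0(id, "_c2_W")]] <- init_conv(3, 3, mid, mid)
        p[[paste0(id, "_c2_b")]] <- numeric(mid)
        p[[paste0(id, "_c3_W")]] <- init_conv(1, 1, mid, cout)
        p[[paste0(id, "_c3_b")]] <- numeric(cout)
      }
      if (proj) {
        p[[paste0(id, "_p_W")]] <- init_conv(1, 1, cin, cout)
        p[[paste0(id, "_p_b")]] <- numeric(cout)
      }
      blocks[[id]] <- list(id = id, stage = si, stride = stride, proj = proj,
                           cin = cin, cout = cout, mid = mid)
      cin <- cout
    }
  }
  p$fc_W <- init_dense(cin, n_classes)
  p$fc_b <- numeric(n_classes)
  structure(list(arch = "resnet",
                 spec = list(input_channels = input_channels,
                             n_classes = n_classes, variant = variant,
                             block = layout$block, stem = layout$stem,
                             stages = length(layout$channels),
                             blocks = blocks,
                             dropout_rate = dropout_rate,
                             dropout_rate_stage = dropout_rate_stage),
                 params = p),
            class = "dl_network")
}

resnet_forward <- function(net, x, training = FALSE, dropout_on = training) {
  s <- net$spec; p <- net$params
  rs <- if (dropout_on) s$dropout_rate_stage else 0
  rh <- if (dropout_on) s$dropout_rate else 0
  st <- s$stem
  zs <- conv_fwd(x, p$stem_W, p$stem_b, stride = st$stride,
                 pad = (st$k - 1L) %/% 2L)
  as_ <- relu_fwd(zs)
  stem_cache <- list(x = x, z = zs)
  if (st$pool) {
    mp <- maxpool_fwd(as_)
    stem_cache$idx <- mp$idx
    stem_cache$prepool_dim <- dim(as_)
    h <- mp$y
  } else h <- as_
  bc <- list(); sdrop <- list()
  cur_stage <- 1L
  for (id in names(s$blocks)) {
    b <- s$blocks[[id]]
    if (b$stage != cur_stage) {
      dp <- dropout_fwd(h, rs)
      sdrop[cur_stage] <- list(dp$mask)
      h <- dp$y
      cur_stage <- b$stage
    }
    cc <- list(x = h)
    if (s$block == "basic") {
      cc$z1 <- conv_fwd(h, p[[paste0(id, "_c1_W")]], p[[paste0(id, "_c1_b")]],
                        stride = b$stride, pad = 1L)
      cc$a1 <- relu_fwd(cc$z1)
      cc$z2 <- conv_fwd(cc$a1, p[[paste0(id, "_c2_W")]],
                        p[[paste0(id, "_c2_b")]])
      sc <- if (b$proj)
        conv_fwd(h, p[[paste0(id, "_p_W")]], p[[paste0(id, "_p_b")]],
                 stride = b$stride, pad = 0L) else h
      cc$zs <- cc$z2 + sc
    } else {
      cc$z1 <- conv_fwd(h, p[[paste0(id, "_c1_W")]], p[[paste0(id, "_c1_b")]],
                        stride = b$stride, pad = 0L)
      cc$a1 <- relu_fwd(cc$z1)
      cc$z2 <- conv_fwd(cc$a1, p[[paste0(id, "_c2_W")]],
                        p[[paste0(id, "_c2_b")]])
      cc$a2 <- relu_fwd(cc$z2)
      cc$z3 <- conv_fwd(cc$a2, p[[paste0(id, "_c3_W")]],
                        p[[paste0(id, "_c3_b")]], pad = 0L)
      sc <- if (b$proj)
        conv_fwd(h, p[[paste0(id, "_p_W")]], p[[paste0(id, "_p_b")]],
                 stride = b$stride, pad = 0L) else h
      cc$zs <- cc$z3 + sc
    }
    h <- relu_fwd(cc$zs)
    bc[[id]] <- cc
  }
  dp <- dropout_fwd(h, rs)
  sdrop[cur_stage] <- list(dp$mask)
  h <- dp$y
  feat_dim <- dim(h)
  gp <- gap_fwd(h)                      # (N, C)
  hd <- dropout_fwd(gp, rh)
  logits <- dense_fwd(hd$y, p$fc_W, p$fc_b)
  probs <- softmax_rows(logits)
  list(out = probs,
       cache = list(stem = stem_cache, blocks = bc, sdrop = sdrop,
                    feat = h, feat_dim = feat_dim, gp = gp,
                    head_mask = hd$mask, gp_drop = hd$y, logits = logits))
}

# dz: gradient w.r.t. the dense-layer logits (N x K).
resnet_backward <- function(net, cache, dz) {
  s <- net$spec; p <- net$params
  g <- list()
  bw <- dense_bwd(cache$gp_drop, p$fc_W, dz)
  g$fc_W <- bw$dw; g$fc_b <- bw$db
  dgp <- dropout_bwd(bw$dx, cache$head_mask)
  hg <- gap_bwd(dgp, cache$feat_dim)
  stage_mask <- function(k)
    if (length(cache$sdrop) >= k) cache$sdrop[[k]] else NULL
  ids <- rev(names(s$blocks))
  cur_stage <- s$blocks[[ids[1L]]]$stage
  hg <- dropout_bwd(hg, stage_mask(cur_stage))
  for (id in ids) {
    b <- s$blocks[[id]]
    if (b$stage != cur_stage) {
      cur_stage <- b$stage
      hg <- dropout_bwd(hg, stage_mask(cur_stage))
    }
    cc <- cache$blocks[[id]]
    dzs <- relu_bwd(hg, cc$zs)
    if (s$block == "basic") {
      bw <- conv_bwd(cc$a1, p[[paste0(id, "_c2_W")]], dzs)
      g[[paste0(id, "_c2_W")]] <- bw$dw; g[[paste0(id, "_c2_b")]] <- bw$db
      dz1 <- relu_bwd(bw$dx, cc$z1)
      bw <- conv_bwd(cc$x, p[[paste0(id, "_c1_W")]], dz1,
                     stride = b$stride, pad = 1L)
      g[[paste0(id, "_c1_W")]] <- bw$dw; g[[paste0(id, "_c1_b")]] <- bw$db
      dx <- bw$dx
    } else {
      bw <- conv_bwd(cc$a2, p[[paste0(id, "_c3_W")]], dzs, pad = 0L)
      g[[paste0(id, "_c3_W")]] <- bw$dw; g[[paste0(id, "_c3_b")]] <- bw$db
      dz2 <- relu_bwd(bw$dx, cc$z2)
      bw <- conv_bwd(cc$a1, p[[paste0(id, "_c2_W")]], dz2)
      g[[paste0(id, "_c2_W")]] <- bw$dw; g[[paste0(id, "_c2_b")]] <- bw$db
      dz1 <- relu_bwd(bw$dx, cc$z1)
      bw <- conv_bwd(cc$x, p[[paste0(id, "_c1_W")]], dz1,
                     stride = b$stride, pad = 0L)
      g[[paste0(id, "_c1_W")]] <- bw$dw; g[[paste0(id, "_c1_b")]] <- bw$db
      dx <- bw$dx
    }
    if (b$proj) {
      bw <- conv_bwd(cc$x, p[[paste0(id, "_p_W")]], dzs,
                     stride = b$stride, pad = 0L)
      g[[paste0(id, "_p_W")]] <- bw$dw; g[[paste0(id, "_p_b")]] <- bw$db
      hg <- dx + bw$dx
    } else {
      hg <- dx + dzs
    }
  }
  sc <- cache$stem
  if (!is.null(sc$idx)) hg <- maxpool_bwd(hg, sc$idx, sc$prepool_dim)
  dzst <- relu_bwd(hg, sc$z)
  st <- s$stem
  bw <- conv_bwd(sc$x, p$stem_W, dzst, stride = st$stride,
                 pad = (st$k - 1L) %/% 2L)
  g$stem_W <- bw$dw; g$stem_b <- bw$db
  g
}
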