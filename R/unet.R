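#' Build a U-Net with padded convolutions and encoder dropout
#'
#' Encoder-decoder with skip connections. All convolutions are zero-padded so
#' the output spatial shape equals the input shape; every encoder block (and
#' the bottleneck) carries a dropout unit that can be switched on at
#' inference time for Monte-Carlo-dropout uncertainty. The sigmoid head
#' yields per-pixel foreground probabilities in (0,1); the linear head is
#' used for pixel-wise regression.
#'
#' @param input_channels Number of input channels.
#' @param base_filters Filters in the first encoder block; doubled per level.
#' @param depth Number of 2x down-samplings.
#' @param dropout_rate Dropout rate of the encoder/bottleneck dropout units.
#' @param head `"sigmoid"` (segmentation) or `"linear"` (regression).
#' @param out_channels Number of output channels (1 for binary/regression).
#' @param auto_pad Zero-pad inputs whose sides are not divisible by
#'   `2^depth` (output is cropped back). If `FALSE`, such inputs error.
#' @return A `dl_network` object.
#' @export
build_unet <- function(input_channels = 1L, base_filters = 16L, depth = 3L,
                       dropout_rate = 0.25, head = c("sigmoid", "linear"),
                       out_channels = 1L, auto_pad = TRUE) {
  head <- match.arg(head)
  cs <- base_filters * 2^(seq_len(depth) - 1L)
  cb <- base_filters * 2^depth
  p <- list()
  for (i in seq_len(depth)) {
    cin <- if (i == 1L) input_channels else cs[i - 1L]
    p[[paste0("enc", i, "_conv1_W")]] <- init_conv(3, 3, cin, cs[i])
    p[[paste0("enc", i, "_conv1_b")]] <- numeric(cs[i])
    p[[paste0("enc", i, "_conv2_W")]] <- init_conv(3, 3, cs[i], cs[i])
    p[[paste0("enc", i, "_conv2_b")]] <- numeric(cs[i])
  }
  p[["bot_conv1_W"]] <- init_conv(3, 3, cs[depth], cb)
  p[["bot_conv1_b"]] <- numeric(cb)
  p[["bot_conv2_W"]] <- init_conv(3, 3, cb, cb)
  p[["bot_conv2_b"]] <- numeric(cb)
  for (i in seq_len(depth)) {
    cup <- if (i == depth) cb else cs[i + 1L]
    p[[paste0("up", i, "_W")]] <- init_conv(3, 3, cup, cs[i])
    p[[paste0("up", i, "_b")]] <- numeric(cs[i])
    p[[paste0("dec", i, "_conv1_W")]] <- init_conv(3, 3, 2L * cs[i], cs[i])
    p[[paste0("dec", i, "_conv1_b")]] <- numeric(cs[i])
    p[[paste0("dec", i, "_conv2_W")]] <- init_conv(3, 3, cs[i], cs[i])
    p[[paste0("dec", i, "_conv2_b")]] <- numeric(cs[i])
  }
  p[["head_W"]] <- init_conv(1, 1, cs[1L], out_channels)
  p[["head_b"]] <- numeric(out_channels)
  structure(list(arch = "unet",
                 spec = list(input_channels = input_channels,
                             base_filters = base_filters, depth = depth,
                             dropout_rate = dropout_rate, head = head,
                             out_channels = out_channels, auto_pad = auto_pad),
                 params = p),
            class = "dl_network")
}

unet_forward <- function(net, x, training = FALSE, dropout_on = training) {
  s <- net$spec; p <- net$params
  d <- s$depth; rate <- if (dropout_on) s$dropout_rate else 0
  H <- dim(x)[1]; W <- dim(x)[2]
  m <- 2^d
  Hp <- as.integer(ceiling(H / m) * m); Wp <- as.integer(ceiling(W / m) * m)
  if ((Hp != H || Wp != W)) {
    if (!s$auto_pad)
      stop("shape error: input sides must be divisible by 2^depth = ", m,
           call. = FALSE)
    xp <- array(0, c(Hp, Wp, dim(x)[3], dim(x)[4]))
    xp[seq_len(H), seq_len(W), , ] <- x
    x <- xp
  }
  enc <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    z1 <- conv_fwd(h, p[[paste0("enc", i, "_conv1_W")]],
                   p[[paste0("enc", i, "_conv1_b")]])
    a1 <- relu_fwd(z1)
    z2 <- conv_fwd(a1, p[[paste0("enc", i, "_conv2_W")]],
                   p[[paste0("enc", i, "_conv2_b")]])
    a2 <- relu_fwd(z2)
    dp <- dropout_fwd(a2, rate)
    mp <- maxpool_fwd(dp$y)
    enc[[i]] <- list(x = h, z1 = z1, a1 = a1, z2 = z2, mask = dp$mask,
                     skip = dp$y)
    enc[[i]]$idx <- mp$idx
    h <- mp$y
  }
  bz1 <- conv_fwd(h, p$bot_conv1_W, p$bot_conv1_b)
  ba1 <- relu_fwd(bz1)
  bz2 <- conv_fwd(ba1, p$bot_conv2_W, p$bot_conv2_b)
  ba2 <- relu_fwd(bz2)
  bdp <- dropout_fwd(ba2, rate)
  bot <- list(x = h, z1 = bz1, a1 = ba1, z2 = bz2, mask = bdp$mask)
  h <- bdp$y
  dec <- vector("list", d)
  for (i in rev(seq_len(d))) {
    u <- upsample2_fwd(h)
    zu <- conv_fwd(u, p[[paste0("up", i, "_W")]], p[[paste0("up", i, "_b")]])
    au <- relu_fwd(zu)
    ct <- concat_channels(enc[[i]]$skip, au)
    z1 <- conv_fwd(ct, p[[paste0("dec", i, "_conv1_W")]],
                   p[[paste0("dec", i, "_conv1_b")]])
    a1 <- relu_fwd(z1)
    z2 <- conv_fwd(a1, p[[paste0("dec", i, "_conv2_W")]],
                   p[[paste0("dec", i, "_conv2_b")]])
    a2 <- relu_fwd(z2)
    dec[[i]] <- list(u = u, zu = zu, ct = ct, z1 = z1, a1 = a1, z2 = z2)
    h <- a2
  }
  zh <- conv_fwd(h, p$head_W, p$head_b, pad = 0L)
  out <- if (s$head == "sigmoid") sigmoid(zh) else zh
  if (Hp != H || Wp != W) out <- out[seq_len(H), seq_len(W), , , drop = FALSE]
  list(out = out,
       cache = list(enc = enc, bot = bot, dec = dec, hfin = h,
                    orig = c(H, W), padded = c(Hp, Wp)))
}

# dz: gradient of the loss w.r.t. the head pre-activation, at the (cropped)
# output shape. Returns the named gradient list matching net$params.
unet_backward <- function(net, cache, dz) {
  s <- net$spec; p <- net$params; d <- s$depth
  g <- list()
  if (any(cache$padded != cache$orig)) {
    dzp <- array(0, c(cache$padded, dim(dz)[3], dim(dz)[4]))
    dzp[seq_len(cache$orig[1]), seq_len(cache$orig[2]), , ] <- dz
    dz <- dzp
  }
  bw <- conv_bwd(cache$hfin, p$head_W, dz, pad = 0L)
  g$head_W <- bw$dw; g$head_b <- bw$db
  hg <- bw$dx
  dskip <- vector("list", d)
  for (i in seq_len(d)) {
    cc <- cache$dec[[i]]
    gz2 <- relu_bwd(hg, cc$z2)
    bw <- conv_bwd(cc$a1, p[[paste0("dec", i, "_conv2_W")]], gz2)
    g[[paste0("dec", i, "_conv2_W")]] <- bw$dw
    g[[paste0("dec", i, "_conv2_b")]] <- bw$db
    gz1 <- relu_bwd(bw$dx, cc$z1)
    bw <- conv_bwd(cc$ct, p[[paste0("dec", i, "_conv1_W")]], gz1)
    g[[paste0("dec", i, "_conv1_W")]] <- bw$dw
    g[[paste0("dec", i, "_conv1_b")]] <- bw$db
    nsk <- dim(cache$enc[[i]]$skip)[3]
    dskip[[i]] <- bw$dx[, , seq_len(nsk), , drop = FALSE]
    dau <- bw$dx[, , nsk + seq_len(dim(bw$dx)[3] - nsk), , drop = FALSE]
    gzu <- relu_bwd(dau, cc$zu)
    bw <- conv_bwd(cc$u, p[[paste0("up", i, "_W")]], gzu)
    g[[paste0("up", i, "_W")]] <- bw$dw
    g[[paste0("up", i, "_b")]] <- bw$db
    hg <- upsample2_bwd(bw$dx)
  }
  bc <- cache$bot
  hg <- dropout_bwd(hg, bc$mask)
  gz2 <- relu_bwd(hg, bc$z2)
  bw <- conv_bwd(bc$a1, p$bot_conv2_W, gz2)
  g$bot_conv2_W <- bw$dw; g$bot_conv2_b <- bw$db
  gz1 <- relu_bwd(bw$dx, bc$z1)
  bw <- conv_bwd(bc$x, p$bot_conv1_W, gz1)
  g$bot_conv1_W <- bw$dw; g$bot_conv1_b <- bw$db
  hg <- bw$dx
  for (i in rev(seq_len(d))) {
    ec <- cache$enc[[i]]
    hg <- maxpool_bwd(hg, ec$idx, dim(ec$skip)) + dskip[[i]]
    hg <- dropout_bwd(hg, ec$mask)
    gz2 <- relu_bwd(hg, ec$z2)
    bw <- conv_bwd(ec$a1, p[[paste0("enc", i, "_conv2_W")]], gz2)
    g[[paste0("enc", i, "_conv2_W")]] <- bw$dw
    g[[paste0("enc", i, "_conv2_b")]] <- bw$db
    gz1 <- relu_bwd(bw$dx, ec$z1)
    bw <- conv_bwd(ec$x, p[[paste0("enc", i, "_conv1_W")]], gz1)
    g[[paste0("enc", i, "_conv1_W")]] <- bw$dw
    g[[paste0("enc", i, "_conv1_b")]] <- bw$db
    hg <- bw$dx
  }
  g
}
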