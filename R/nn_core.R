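# Minimal CPU deep-learning core: layer primitives, initializers and Adam.
# Feature maps are (H, W, C, N) arrays; convolution weights (kh, kw, Cin, Cout).
# Forward passes return caches consumed by the matching backward pass.

conv_fwd <- function(x, w, b, stride = 1L, pad = 1L)
  cpp_conv2d_forward(x, w, b, as.integer(stride), as.integer(pad))

conv_bwd <- function(x, w, dy, stride = 1L, pad = 1L)
  cpp_conv2d_backward(x, w, dy, as.integer(stride), as.integer(pad))

relu_fwd <- function(z) {
  z[z < 0] <- 0
  z
}
relu_bwd <- function(dz, z) dz * (z > 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

maxpool_fwd <- function(x) cpp_maxpool2_forward(x)
maxpool_bwd <- function(dy, idx, xdim) cpp_maxpool2_backward(dy, idx, xdim)

# Nearest-neighbour 2x upsampling and its adjoint (2x2 block sum).
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}
upsample2_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  dy[io, jo, , , drop = FALSE] + dy[io + 1L, jo, , , drop = FALSE] +
    dy[io, jo + 1L, , , drop = FALSE] + dy[io + 1L, jo + 1L, , , drop = FALSE]
}

# Inverted dropout; mask drawn from the global RNG so runs are seed-reproducible.
dropout_fwd <- function(x, rate) {
  if (rate <= 0) return(list(y = x, mask = NULL))
  keep <- 1 - rate
  mask <- array((runif(length(x)) < keep) / keep, dim(x))
  list(y = x * mask, mask = mask)
}
dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

# Global average pooling (H,W,C,N) -> (N,C) matrix.
gap_fwd <- function(x) {
  d <- dim(x)
  t(apply(x, c(3L, 4L), mean))
}
gap_bwd <- function(dy, xdim) {
  # dy: (N, C) -> spread uniformly over H*W
  scale <- 1 / (xdim[1] * xdim[2])
  out <- array(0, xdim)
  for (n in seq_len(xdim[4]))
    out[, , , n] <- rep(dy[n, ] * scale, each = xdim[1] * xdim[2])
  out
}

dense_fwd <- function(x, w, b) sweep(x %*% w, 2L, b, "+")
dense_bwd <- function(x, w, dy)
  list(dx = dy %*% t(w), dw = t(x) %*% dy, db = colSums(dy))

# He-normal initializers.
init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)), c(kh, kw, cin, cout))
}
init_dense <- function(nin, nout)
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
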