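`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seed every random stream used by the pipeline
#'
#' All randomness in the package (validation split, shuffling, augmentation
#' sampling, weight initialization, dropout masks) is drawn from R's global
#' RNG, so a single seed makes a full run reproducible.
#'
#' @param seed Integer seed (any value accepted by [set.seed()], including 0).
#' @return Invisibly, the seed.
#' @export
seed_everything <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(as.integer(seed))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Used where determinism must depend only on the
# function arguments (validation split, bootstrap), not on call history.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Clip values into [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

is_binary_array <- function(x) all(x %in% c(0, 1))

# Ensure a sample array has an explicit channel axis: (H,W) -> (H,W,1).
ensure_hwc <- function(x) {
  if (length(dim(x)) < 2L) stop("expected an array with at least 2 dimensions")
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# Stack a list of (H,W,C) samples into an (H,W,C,N) batch array.
stack_batch <- function(samples) {
  samples <- lapply(samples, ensure_hwc)
  d <- dim(samples[[1L]])
  out <- array(0, c(d, length(samples)))
  for (i in seq_along(samples)) out[, , , i] <- samples[[i]]
  out
}

# Concatenate two (H,W,C,N) arrays along the channel axis.
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
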