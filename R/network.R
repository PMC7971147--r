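# Architecture dispatch: one forward/backward surface for all networks.

net_forward <- function(net, x, training = FALSE, dropout_on = training) {
  switch(net$arch,
         unet = unet_forward(net, x, training, dropout_on),
         resnet = resnet_forward(net, x, training, dropout_on),
         stop("unknown architecture: ", net$arch, call. = FALSE))
}

net_backward <- function(net, cache, dz) {
  switch(net$arch,
         unet = unet_backward(net, cache, dz),
         resnet = resnet_backward(net, cache, dz),
         stop("unknown architecture: ", net$arch, call. = FALSE))
}

net_has_dropout <- function(net) {
  !is.null(net$spec$dropout_rate)
}

#' Predict from a trained network
#'
#' @param object A `dl_network`.
#' @param newdata A single sample (`(H,W)` or `(H,W,C)` array), a list of
#'   samples, or an `(H,W,C,N)` batch array.
#' @param dropout Keep dropout active (stochastic forward pass, used for
#'   Monte-Carlo-dropout sampling)? Default `FALSE`.
#' @param ... Unused.
#' @return For a single sample, the prediction with the batch axis dropped;
#'   otherwise a list of predictions (U-Net) or a probability matrix
#'   (classifier).
#' @export
predict.dl_network <- function(object, newdata, dropout = FALSE, ...) {
  single <- FALSE
  if (is.list(newdata) && !is.array(newdata)) {
    x <- stack_batch(newdata)
  } else {
    nd <- length(dim(newdata))
    if (nd == 4L) x <- newdata
    else { x <- stack_batch(list(newdata)); single <- TRUE }
  }
  out <- net_forward(object, x, training = FALSE, dropout_on = dropout)$out
  if (object$arch == "resnet") {
    colnames(out) <- object$spec$class_levels %||% NULL
    return(if (single) out[1L, ] else out)
  }
  if (single) {
    pred <- out[, , , 1L]
    if (length(dim(pred)) == 0L) dim(pred) <- dim(out)[1:2]
    return(pred)
  }
  lapply(seq_len(dim(out)[4]), function(n) {
    p <- out[, , , n]
    if (is.null(dim(p))) dim(p) <- dim(out)[1:2]
    p
  })
}

#' @export
print.dl_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("<dl_network> arch:", x$arch,
      if (x$arch == "resnet") paste0("(", x$spec$variant, ")") else
        paste0("(depth ", x$spec$depth, ", base ", x$spec$base_filters,
               ", ", x$spec$head, " head)"),
      "\n  parameters:", format(np, big.mark = ","),
      " dropout rate:", x$spec$dropout_rate, "\n")
  invisible(x)
}

#' @export
summary.dl_network <- function(object, ...) {
  shapes <- lapply(object$params, function(p) dim(p) %||% length(p))
  df <- data.frame(layer = names(shapes),
                   shape = vapply(shapes, function(s)
                     paste(s, collapse = "x"), ""),
                   n = vapply(object$params, length, 1L),
                   row.names = NULL)
  cat("<dl_network>", object$arch, "with",
      format(sum(df$n), big.mark = ","), "parameters in",
      nrow(df), "tensors\n")
  print(df, row.names = FALSE)
  invisible(df)
}
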