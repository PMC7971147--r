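#' Compute a training/validation loss
#'
#' Losses are means over all elements (MSE, binary cross-entropy) or over
#' samples (categorical cross-entropy). Probabilities are clipped at
#' `1e-7` before taking logarithms. `"instance_composite"` maps to binary
#' cross-entropy for the reference instance backend, whose mask head is a
#' semantic network.
#'
#' @param name One of `"mse"`, `"binary_crossentropy"`,
#'   `"categorical_crossentropy"`, `"instance_composite"`.
#' @param prediction,target Arrays of identical shape (for categorical
#'   cross-entropy: `N x K` probability and one-hot matrices).
#' @return Non-negative scalar loss.
#' @export
compute_loss <- function(name, prediction, target) {
  if (!identical(dim(prediction) %||% length(prediction),
                 dim(target) %||% length(target)))
    stop("contract error: prediction and target shapes differ", call. = FALSE)
  eps <- 1e-7
  switch(name,
         mse = mean((prediction - target)^2),
         binary_crossentropy = ,
         instance_composite = {
           p <- clip01(prediction, eps, 1 - eps)
           -mean(target * log(p) + (1 - target) * log(1 - p))
         },
         categorical_crossentropy = {
           p <- clip01(prediction, eps, 1 - eps)
           -mean(rowSums(target * log(p)))
         },
         stop("unknown loss: ", name, call. = FALSE))
}

# Gradient of the loss w.r.t. the network head pre-activation (logits),
# exploiting the standard sigmoid+bce / softmax+cce / linear+mse pairings.
loss_grad_logits <- function(name, prediction, target) {
  switch(name,
         mse = 2 * (prediction - target) / length(target),
         binary_crossentropy = ,
         instance_composite = (prediction - target) / length(target),
         categorical_crossentropy = (prediction - target) / nrow(target),
         stop("unknown loss: ", name, call. = FALSE))
}

#' Train a network with Adam and early stopping
#'
#' Runs up to `epochs` epochs over the training samples, evaluating the
#' validation loss after each epoch. Training stops early after `patience`
#' epochs without an improvement larger than `min_delta`, and the parameters
#' from the best validation epoch are restored and (optionally)
#' checkpointed. Per-epoch losses are appended to `training_log.csv` in
#' `log_dir`. A non-finite training loss aborts with a diagnostic naming the
#' epoch and batch.
#'
#' @param net A `dl_network`.
#' @param train,validation Lists of samples, each `list(id=, x=, y=)` where
#'   `x` is an `(H,W,C)` array and `y` an array (image tasks) or a one-hot
#'   vector (classification).
#' @param loss_name Loss enum (see [compute_loss()]).
#' @param epochs,batch_size Training schedule.
#' @param learning_rate,patience,min_delta Optimization settings; `patience`
#'   defaults to `max(5, epochs %/% 10)`.
#' @param augment Optional `augmentation_spec` applied online to training
#'   samples (never to validation).
#' @param spatial_labels Do labels transform spatially with the image?
#' @param binary_labels Re-binarize labels after spatial interpolation?
#' @param log_dir Directory for `training_log.csv` and the best checkpoint;
#'   `NULL` disables file output.
#' @return A `train_state` list: the trained `net` (best weights), per-epoch
#'   losses, best epoch, checkpoint path and the per-epoch batch order.
#' @export
train_model <- function(net, train, validation, loss_name,
                        epochs = 100L, batch_size = 1L,
                        learning_rate = 1e-4, patience = NULL,
                        min_delta = 1e-5, augment = NULL,
                        spatial_labels = TRUE, binary_labels = FALSE,
                        log_dir = NULL) {
  if (length(train) == 0L || length(validation) == 0L)
    stop("data error: empty training or validation set", call. = FALSE)
  patience <- patience %||% max(5L, epochs %/% 10L)
  opt <- adam_init(net$params)
  best_val <- Inf; best_epoch <- 0L; best_params <- net$params
  tl <- numeric(0); vl <- numeric(0)
  batch_order <- list()
  csv_path <- NULL
  if (!is.null(log_dir)) {
    dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
    csv_path <- file.path(log_dir, "training_log.csv")
    cat("epoch,train_loss,val_loss\n", file = csv_path)
  }
  classif <- net$arch == "resnet"
  eval_loss <- function(samples) {
    tot <- 0
    for (i in seq(1L, length(samples), by = batch_size)) {
      idx <- i:min(i + batch_size - 1L, length(samples))
      b <- make_batch(samples[idx], classif, net$spec$n_classes)
      out <- net_forward(net, b$x, training = FALSE)$out
      tot <- tot + compute_loss(loss_name, out, b$y) * length(idx)
    }
    tot / length(samples)
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(length(train))
    batch_order[[ep]] <- vapply(train[ord], function(s) s$id, "")
    ep_loss <- 0
    nb <- 0L
    for (i in seq(1L, length(train), by = batch_size)) {
      nb <- nb + 1L
      idx <- ord[i:min(i + batch_size - 1L, length(train))]
      samples <- train[idx]
      if (!is.null(augment))
        samples <- lapply(samples, function(s) {
          a <- augment_sample(augment, s$x,
                              if (spatial_labels) s$y else NULL,
                              binary_label = binary_labels)
          s$x <- a$image
          if (spatial_labels && !is.null(a$label)) s$y <- a$label
          s
        })
      b <- make_batch(samples, classif, net$spec$n_classes)
      fw <- net_forward(net, b$x, training = TRUE)
      ls <- compute_loss(loss_name, fw$out, b$y)
      if (!is.finite(ls))
        stop("training aborted: non-finite loss at epoch ", ep,
             ", batch ", nb, call. = FALSE)
      ep_loss <- ep_loss + ls * length(idx)
      dz <- loss_grad_logits(loss_name, fw$out, b$y)
      grads <- net_backward(net, fw$cache, dz)
      upd <- adam_step(net$params, grads, opt, lr = learning_rate)
      net$params <- upd$params
      opt <- upd$state
    }
    tl[ep] <- ep_loss / length(train)
    vl[ep] <- eval_loss(validation)
    if (!is.null(csv_path))
      cat(sprintf("%d,%.8f,%.8f\n", ep, tl[ep], vl[ep]),
          file = csv_path, append = TRUE)
    if (vl[ep] < best_val - min_delta) {
      best_val <- vl[ep]; best_epoch <- ep; best_params <- net$params
    } else if (ep - best_epoch >= patience) {
      break
    }
  }
  net$params <- best_params
  ckpt <- NULL
  if (!is.null(log_dir)) {
    ckpt <- file.path(log_dir, "best_model.weights")
    save_weights(net, ckpt)
  }
  structure(list(net = net, train_losses = tl, val_losses = vl,
                 best_epoch = best_epoch, best_val_loss = best_val,
                 epochs_run = length(tl), checkpoint = ckpt,
                 batch_order = batch_order, log_csv = csv_path),
            class = "train_state")
}

# Assemble a batch array and matching target from samples.
make_batch <- function(samples, classif, n_classes = NULL) {
  x <- stack_batch(lapply(samples, function(s) s$x))
  if (classif) {
    y <- matrix(0, length(samples), n_classes)
    for (j in seq_along(samples)) y[j, samples[[j]]$y + 1L] <- 1
  } else {
    y <- stack_batch(lapply(samples, function(s) s$y))
  }
  list(x = x, y = y)
}

#' @export
print.train_state <- function(x, ...) {
  cat("<train_state>", x$epochs_run, "epochs; best epoch", x$best_epoch,
      sprintf("(val loss %.5g)", x$best_val_loss), "\n")
  invisible(x)
}
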