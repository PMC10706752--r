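# Training loop and inference.

fit_normalization <- function(images) {
  x <- images / 255
  m <- numeric(3); v <- numeric(3)
  for (ch in 1:3) {
    plane <- x[, , ch, ]
    m[ch] <- mean(plane)
    v[ch] <- mean((plane - m[ch])^2)
  }
  list(norm_mean = m, norm_var = v, norm_count = dim(images)[4])
}

#' Train a model
#'
#' Minimizes sparse categorical cross-entropy with Adam and decoupled weight
#' decay. Input-standardization statistics are fitted from the training
#' images before the first epoch. When validation data are supplied and
#' `cfg$early_stop_on_val` is `TRUE`, the returned model carries the weights
#' of the best validation-loss epoch. The whole run -- data order, dropout
#' masks, augmentation draws -- is deterministic in `cfg$seed`.
#'
#' @param model An `abisa_model` from [build_abisa()] or
#'   [build_standard_vit()].
#' @param images Training images, `image_size` x `image_size` x 3 x N array
#'   on the 0..255 scale.
#' @param labels Integer class labels in `0 .. num_classes - 1`.
#' @param cfg A [train_config()].
#' @param val_images,val_labels Optional validation set, same conventions.
#' @param augment Optional [augment_config()]; when given, each training
#'   batch is augmented on the fly (validation data are never augmented).
#' @param verbose Print one line per epoch.
#' @return List with `model` (trained) and `history` (data frame with one row
#'   per epoch: `epoch`, `loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_model <- function(model, images, labels, cfg = train_config(),
                        val_images = NULL, val_labels = NULL, augment = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "abisa_model"),
            inherits(cfg, "abisa_train_config"))
  n <- dim(images)[4]
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("one label per image is required", call. = FALSE)
  if (any(labels < 0L | labels >= model$config$num_classes))
    stop("labels must lie in 0 .. num_classes - 1", call. = FALSE)
  has_val <- !is.null(val_images) && !is.null(val_labels)
  if (has_val) val_labels <- as.integer(val_labels)
  if (!is.null(augment)) augment$seed <- NULL   # draw from the training stream
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric(), val_loss = numeric(),
                        val_accuracy = numeric())
  local_seed(cfg$seed, {
    model$buffers <- fit_normalization(images)
    model$params <- deep_copy_params(model$params)  # optimizer works in place
    state <- adam_init(model$params)
    best_loss <- Inf
    best_params <- NULL
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      tot_loss <- 0; tot_correct <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        xb <- images[, , , idx, drop = FALSE]
        yb <- labels[idx]
        if (!is.null(augment)) xb <- augment_batch(xb, augment)
        fw <- nn_forward(model, xb, training = TRUE)
        tot_loss <- tot_loss + ce_loss(fw$probs, yb) * length(idx)
        tot_correct <- tot_correct +
          sum(max.col(fw$probs) - 1L == yb)
        grads <- nn_backward(model, fw, yb)
        upd <- adamw_update(model$params, grads, state,
                            cfg$learning_rate, cfg$weight_decay)
        model$params <- upd$params
        state <- upd$state
      }
      vl <- NA_real_; va <- NA_real_
      if (has_val) {
        pv <- predict_core(model, val_images)
        vl <- ce_loss(pv, val_labels)
        va <- mean(max.col(pv) - 1L == val_labels)
        if (cfg$early_stop_on_val && vl < best_loss) {
          best_loss <- vl
          best_params <- deep_copy_params(model$params)
        }
      }
      history[epoch, ] <- list(epoch, tot_loss / n, tot_correct / n, vl, va)
      if (verbose)
        message(sprintf(
          "epoch %2d  loss %.4f  acc %.3f  val_loss %s  val_acc %s",
          epoch, tot_loss / n, tot_correct / n,
          ifelse(is.na(vl), "-", sprintf("%.4f", vl)),
          ifelse(is.na(va), "-", sprintf("%.3f", va))))
    }
    if (has_val && cfg$early_stop_on_val && !is.null(best_params))
      model$params <- best_params
  })
  list(model = model, history = history)
}

# batched eval-mode forward returning the probability matrix
predict_core <- function(model, images, batch_size = 64L) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  out <- matrix(0, n, model$config$num_classes)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    out[idx, ] <- nn_forward(model, images[, , , idx, drop = FALSE],
                             training = FALSE)$probs
  }
  out
}

#' Predict class probabilities and labels for tiles
#'
#' Batched inference with dropout disabled, so predictions are deterministic.
#'
#' @param model A (trained) `abisa_model`.
#' @param tiles `image_size` x `image_size` x 3 x N array (a single tile is
#'   accepted), values on the 0..255 scale.
#' @param batch_size Inference batch size.
#' @return List with `probabilities` (N x num_classes matrix, rows sum to 1;
#'   for two classes the columns are named `non_recurring` and `recurring`)
#'   and `labels` (integer argmax labels, 0-based).
#' @export
predict_tiles <- function(model, tiles, batch_size = 64L) {
  stopifnot(inherits(model, "abisa_model"))
  probs <- predict_core(model, tiles, batch_size)
  if (model$config$num_classes == 2L)
    colnames(probs) <- c("non_recurring", "recurring")
  list(probabilities = probs, labels = max.col(probs) - 1L)
}
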