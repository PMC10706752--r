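# Model configuration and construction for the attention-based image sequence
# analyzer (ABISA) and the standard vision-transformer baseline it is compared
# against.
#
# Shared trunk: input standardization (per-channel mean/variance statistics,
# non-trainable) -> non-overlapping patch extraction -> linear patch encoder
# with learned positional embeddings -> a stack of transformer blocks
# (multi-head self-attention, skip connection, layer normalization; an
# optional position-wise feed-forward sub-block can be switched on). ABISA
# then runs an LSTM over the patch sequence and layer-normalizes its 32-wide
# output sequence before the flatten/dropout/GELU-MLP head; the baseline
# layer-normalizes and flattens the 64-wide encoded sequence directly. The
# narrower LSTM output is what makes the ABISA head (and hence the whole
# model) smaller than the baseline.

#' Model architecture configuration
#'
#' Defaults are the reference hyperparameters of the tile classifier: 64 px
#' inputs cut into 6 px patches (100 patches), 64-dimensional patch
#' embeddings, 4 transformer layers with 4 attention heads of per-head width
#' 64, a 32-unit LSTM, and a `[2048, 1024]` GELU MLP head over 2 classes.
#'
#' @param image_size Model input side length in pixels.
#' @param patch_size Patch side length in pixels; must not exceed
#'   `image_size`. Pixels beyond the covered grid are ignored.
#' @param projection_dim Patch embedding width.
#' @param num_heads Number of self-attention heads.
#' @param key_dim Per-head query/key/value width.
#' @param transformer_layers Number of transformer blocks.
#' @param attention_dropout Dropout rate on attention scores (and inside the
#'   optional block FFN).
#' @param lstm_units LSTM hidden/cell width (ABISA only).
#' @param head_dropout Dropout rate after the flatten, before the MLP head.
#' @param mlp_head_units Widths of the two GELU dense layers in the head.
#' @param num_classes Number of output classes.
#' @param use_block_ffn Include a position-wise feed-forward sub-block (GELU,
#'   own skip + layer norm) in every transformer block. Off by default: the
#'   attention-only block is the layout whose parameter totals match the
#'   reference architecture exactly; the flag exists so both layouts can be
#'   built and compared.
#' @param block_ffn_units Widths of the FFN sub-block when enabled.
#' @return An object of class `abisa_model_config`. `num_patches` is always
#'   recomputed as `(image_size %/% patch_size)^2`.
#' @export
model_config <- function(image_size = 64L, patch_size = 6L,
                         projection_dim = 64L, num_heads = 4L, key_dim = 64L,
                         transformer_layers = 4L, attention_dropout = 0.1,
                         lstm_units = 32L, head_dropout = 0.5,
                         mlp_head_units = c(2048L, 1024L), num_classes = 2L,
                         use_block_ffn = FALSE, block_ffn_units = NULL) {
  dims <- c(image_size, patch_size, projection_dim, num_heads, key_dim,
            transformer_layers, lstm_units, mlp_head_units, num_classes)
  if (any(dims < 1)) stop("all dimensions must be >= 1", call. = FALSE)
  if (patch_size > image_size)
    stop("`patch_size` must not exceed `image_size`", call. = FALSE)
  if (attention_dropout < 0 || attention_dropout >= 1 ||
      head_dropout < 0 || head_dropout >= 1)
    stop("dropout rates must lie in [0, 1)", call. = FALSE)
  if (length(mlp_head_units) != 2L)
    stop("`mlp_head_units` must have exactly two entries", call. = FALSE)
  if (is.null(block_ffn_units))
    block_ffn_units <- c(2L * projection_dim, projection_dim)
  structure(list(
    image_size = as.integer(image_size), patch_size = as.integer(patch_size),
    num_patches = as.integer((image_size %/% patch_size)^2),
    projection_dim = as.integer(projection_dim),
    num_heads = as.integer(num_heads), key_dim = as.integer(key_dim),
    transformer_layers = as.integer(transformer_layers),
    attention_dropout = attention_dropout,
    lstm_units = as.integer(lstm_units), head_dropout = head_dropout,
    mlp_head_units = as.integer(mlp_head_units),
    num_classes = as.integer(num_classes),
    use_block_ffn = isTRUE(use_block_ffn),
    block_ffn_units = as.integer(block_ffn_units)),
    class = "abisa_model_config")
}

#' Training configuration
#'
#' Defaults mirror the reference training recipe: Adam with decoupled weight
#' decay, learning rate 1e-4, weight decay 1e-3, batch size 20, 25 epochs,
#' sparse categorical cross-entropy over integer labels, early stopping on
#' validation loss with best-epoch weight restoration.
#'
#' @param learning_rate,weight_decay Positive optimizer constants.
#' @param batch_size,epochs Positive integers.
#' @param early_stop_on_val Restore the weights of the best validation-loss
#'   epoch when validation data are supplied.
#' @param seed Integer seed covering data order, dropout and augmentation.
#' @return An object of class `abisa_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-3,
                         batch_size = 20L, epochs = 25L,
                         early_stop_on_val = TRUE, seed = 1L) {
  if (learning_rate <= 0 || weight_decay <= 0)
    stop("learning_rate and weight_decay must be > 0", call. = FALSE)
  if (epochs < 1 || batch_size < 1)
    stop("epochs and batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stop_on_val = isTRUE(early_stop_on_val),
                 seed = as.integer(seed)),
            class = "abisa_train_config")
}

new_model <- function(arch, cfg, seed) {
  params <- local_seed(seed, init_params(cfg, arch))
  structure(list(arch = arch, config = cfg, params = params,
                 buffers = list(norm_mean = numeric(3),
                                norm_var = rep(1, 3),
                                norm_count = 0)),
            class = "abisa_model")
}

#' Build the attention-based image sequence analyzer
#'
#' Composes: input standardization, patch extraction, patch encoder,
#' `transformer_layers` transformer blocks, an LSTM over the patch sequence
#' (returning the full output sequence), layer normalization, flatten,
#' dropout, and the GELU MLP head with softmax output.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `abisa_model` with `arch = "abisa"`.
#' @export
build_abisa <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "abisa_model_config"))
  new_model("abisa", cfg, seed)
}

#' Build the standard vision-transformer baseline
#'
#' Identical to [build_abisa()] but without the LSTM: after the transformer
#' stack the encoded patch sequence is layer-normalized and flattened straight
#' into the MLP head. With shared hyperparameters this baseline always has
#' more trainable parameters than the ABISA model whenever `lstm_units <
#' projection_dim`.
#'
#' @inheritParams build_abisa
#' @return An object of class `abisa_model` with `arch = "vit"`.
#' @export
build_standard_vit <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "abisa_model_config"))
  new_model("vit", cfg, seed)
}

#' Count model parameters
#'
#' Sums the sizes of all trainable weight tensors; with
#' `trainable_only = FALSE` the non-trainable input-standardization
#' statistics (per-channel mean and variance plus the accumulation count,
#' 7 values for RGB input) are included, which is the convention framework
#' model summaries use for their printed totals.
#'
#' @param model An `abisa_model`.
#' @param trainable_only Count only trainable tensors (default `TRUE`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model, trainable_only = TRUE) {
  stopifnot(inherits(model, "abisa_model"))
  n <- sum(vapply(model$params, length, numeric(1)))
  if (!trainable_only)
    n <- n + sum(vapply(model$buffers, length, numeric(1)))
  as.integer(n)
}

#' Layer-by-layer model summary
#'
#' @param model An `abisa_model`.
#' @return Data frame with one row per layer: name, output shape and
#'   parameter count (negative counts never occur; the input-standardization
#'   row reports its 7 non-trainable statistics).
#' @export
model_summary <- function(model) {
  cfg <- model$config
  T <- cfg$num_patches; D <- cfg$projection_dim
  Hd <- cfg$num_heads * cfg$key_dim
  Fdim <- 3L * cfg$patch_size^2
  rows <- list(
    c("input_standardization", sprintf("%d x %d x 3", cfg$image_size,
                                       cfg$image_size), 7),
    c("patches", sprintf("%d x %d", T, Fdim), 0),
    c("patch_encoder", sprintf("%d x %d", T, D),
      Fdim * D + D + T * D))
  for (l in seq_len(cfg$transformer_layers)) {
    np <- 3L * (D * Hd + Hd) + Hd * D + D + 2L * D
    if (cfg$use_block_ffn) {
      u1 <- cfg$block_ffn_units[1]; u2 <- cfg$block_ffn_units[2]
      np <- np + D * u1 + u1 + u1 * u2 + u2 + 2L * D
    }
    rows[[length(rows) + 1L]] <-
      c(sprintf("transformer_block_%d", l), sprintf("%d x %d", T, D), np)
  }
  if (model$arch == "abisa") {
    u <- cfg$lstm_units
    rows[[length(rows) + 1L]] <- c("lstm", sprintf("%d x %d", T, u),
                                   4 * ((D + u) * u + u))
    rows[[length(rows) + 1L]] <- c("layer_norm", sprintf("%d x %d", T, u),
                                   2 * u)
    flat <- T * u
  } else {
    rows[[length(rows) + 1L]] <- c("layer_norm", sprintf("%d x %d", T, D),
                                   2 * D)
    flat <- T * D
  }
  rows[[length(rows) + 1L]] <- c("flatten_dropout", as.character(flat), 0)
  h1 <- cfg$mlp_head_units[1]; h2 <- cfg$mlp_head_units[2]
  rows[[length(rows) + 1L]] <- c("dense_gelu_1", as.character(h1),
                                 flat * h1 + h1)
  rows[[length(rows) + 1L]] <- c("dense_gelu_2", as.character(h2),
                                 h1 * h2 + h2)
  rows[[length(rows) + 1L]] <- c("dense_softmax",
                                 as.character(cfg$num_classes),
                                 h2 * cfg$num_classes + cfg$num_classes)
  data.frame(layer = vapply(rows, `[`, "", 1),
             output_shape = vapply(rows, `[`, "", 2),
             parameters = as.numeric(vapply(rows, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Extract non-overlapping patches from one image
#'
#' Traverses the `floor(image_size / patch_size)^2` patch grid row-major and
#' raster-flattens each patch (pixels row by row, RGB interleaved). Pixels
#' beyond the covered region -- for example the outer 4-pixel margin of a
#' 64 px image at patch size 6 -- are ignored.
#'
#' @param image H x W x 3 array.
#' @param patch_size Patch side length; must not exceed the image size.
#' @return `num_patches` x `(3 * patch_size^2)` matrix, one patch per row.
#' @examples
#' img <- make_tile("non_recurring", 64, seed = 3)
#' dim(extract_patches(img, 6)) # 100 x 108
#' @export
extract_patches <- function(image, patch_size) {
  check_image(image, "image")
  if (patch_size > min(dim(image)[1:2]))
    stop("`patch_size` must not exceed the image size", call. = FALSE)
  x <- array(image, dim = c(dim(image), 1L))
  batch_patch_matrix(x, as.integer(patch_size))
}

#' Encode patch vectors with a model's patch encoder
#'
#' Applies the learned linear projection and adds the positional embedding of
#' each patch index: `output_i = W p_i + b + E[i]`.
#'
#' @param model An `abisa_model`.
#' @param patches Matrix of flattened patch vectors (at most `num_patches`
#'   rows).
#' @return Matrix of `projection_dim`-wide embeddings.
#' @export
encode_patches <- function(model, patches) {
  stopifnot(inherits(model, "abisa_model"))
  if (ncol(patches) != nrow(model$params$enc_W))
    stop("patch vector length does not match the encoder", call. = FALSE)
  if (nrow(patches) > model$config$num_patches)
    stop("more patches than positional embeddings", call. = FALSE)
  add_row_vec(patches %*% model$params$enc_W, model$params$enc_b) +
    model$params$pos_E[seq_len(nrow(patches)), , drop = FALSE]
}

#' Apply one transformer block to an encoded patch sequence
#'
#' Runs a single sequence (inference mode, no dropout) through the block:
#' multi-head self-attention, skip connection, layer normalization, and the
#' FFN sub-block when the model was configured with one. Attention weights
#' are attached as the `"attention"` attribute (a `T x T x num_heads` array;
#' every row of every head sums to 1).
#'
#' @param model An `abisa_model`.
#' @param encoded `T x projection_dim` matrix.
#' @param layer Block index, 1-based.
#' @return Matrix of the same shape as `encoded`.
#' @export
transformer_block <- function(model, encoded, layer = 1L) {
  stopifnot(inherits(model, "abisa_model"))
  if (ncol(encoded) != model$config$projection_dim)
    stop("embedding width must equal projection_dim", call. = FALSE)
  res <- block_forward(encoded, model, layer, training = FALSE,
                       B = 1L, T = nrow(encoded))
  out <- res$Z
  attr(out, "attention") <- res$cache$A   # T x T x num_heads for one sequence
  out
}

#' Run a model's LSTM head over an encoded sequence
#'
#' Standard LSTM recurrence over the patch order with zero-initialized hidden
#' and cell states, returning the full output sequence (one `lstm_units`-wide
#' vector per patch).
#'
#' @param model An ABISA `abisa_model`.
#' @param encoded `T x projection_dim` matrix.
#' @return `T x lstm_units` matrix.
#' @export
lstm_head <- function(model, encoded) {
  stopifnot(inherits(model, "abisa_model"))
  if (model$arch != "abisa") stop("model has no LSTM head", call. = FALSE)
  lstm_forward(encoded, model$params$lstm_Wx, model$params$lstm_Wh,
               model$params$lstm_b, B = 1L, T = nrow(encoded))$H
}
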