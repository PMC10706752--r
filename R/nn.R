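# Neural-network engine: forward passes, hand-derived backpropagation and the
# AdamW optimizer for the two architectures built in model.R. Activations for
# a batch of B images are kept as (B * num_patches) x width matrices with the
# token index varying fastest (row = t + T * (b - 1)), so every linear layer
# is a single BLAS matmul; attention mixes tokens per sample and per head.
#
# Correctness of every backward formula is guarded by a finite-difference
# gradient check in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

row_softmax <- function(S) {
  E <- exp(S - S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))])
  E / rowSums(E)
}

# inverted dropout mask, already scaled by 1/(1-p)
drop_mask <- function(dims, p) {
  array(as.numeric(stats::runif(prod(dims)) >= p) / (1 - p), dims)
}

# mean negative log-probability of the true class (sparse categorical
# cross-entropy), probabilities clipped at 1e-15
ce_loss <- function(probs, y) {
  pt <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(pt, 1e-15)))
}

## ---- layer normalization (over the feature axis, per row) ----

ln_forward <- function(X, g, b, eps = 1e-3) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = add_row_vec(xhat * rep(g, each = nrow(X)), b),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- patch extraction ----

# (H, W, 3, B) array -> (B*T) x (3*p*p) matrix; tokens traverse the patch grid
# row-major, features raster-flatten each patch with RGB interleaved per pixel
batch_patch_matrix <- function(xs, p) {
  g <- dim(xs)[1] %/% p
  B <- dim(xs)[4]
  A <- xs[seq_len(g * p), seq_len(g * p), , , drop = FALSE]
  dim(A) <- c(p, g, p, g, 3L, B)            # (ri, pr, ci, pc, ch, b)
  A <- aperm(A, c(5L, 3L, 1L, 4L, 2L, 6L))  # (ch, ci, ri, pc, pr, b)
  dim(A) <- c(3L * p * p, g * g * B)
  t(A)
}

## ---- transformer block: MHSA + skip + LayerNorm (optional FFN sub-block) ----

block_param_names <- function(use_ffn) {
  nms <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo", "ln1_g", "ln1_b")
  if (use_ffn)
    nms <- c(nms, "f1_W", "f1_b", "f2_W", "f2_b", "ln2_g", "ln2_b")
  nms
}

bp <- function(l, nm) sprintf("blk%d_%s", l, nm)

block_forward <- function(Z, model, l, training, B, T) {
  p <- model$params; cfg <- model$config
  Hh <- cfg$num_heads; dk <- cfg$key_dim
  scal <- 1 / sqrt(dk)
  pd <- cfg$attention_dropout
  Q <- add_row_vec(Z %*% p[[bp(l, "Wq")]], p[[bp(l, "bq")]])
  K <- add_row_vec(Z %*% p[[bp(l, "Wk")]], p[[bp(l, "bk")]])
  V <- add_row_vec(Z %*% p[[bp(l, "Wv")]], p[[bp(l, "bv")]])
  att <- attn_forward_cpp(Q, K, V, B, T, Hh, dk,
                          if (training) pd else 0)
  O <- att$O          # A is a (T, T, Hh*B) array, slice index h + Hh*(b-1)
  attn <- add_row_vec(O %*% p[[bp(l, "Wo")]], p[[bp(l, "bo")]])
  ln1 <- ln_forward(Z + attn, p[[bp(l, "ln1_g")]], p[[bp(l, "ln1_b")]])
  out <- ln1$y
  cache <- list(Z_in = Z, Q = Q, K = K, V = V, A = att$A, M = att$M, O = O,
                ln1 = ln1)
  if (cfg$use_block_ffn) {
    U1 <- add_row_vec(out %*% p[[bp(l, "f1_W")]], p[[bp(l, "f1_b")]])
    Gf <- gelu(U1)
    m1 <- if (training && pd > 0) drop_mask(dim(Gf), pd) else NULL
    Gfd <- if (is.null(m1)) Gf else Gf * m1
    U2 <- add_row_vec(Gfd %*% p[[bp(l, "f2_W")]], p[[bp(l, "f2_b")]])
    m2 <- if (training && pd > 0) drop_mask(dim(U2), pd) else NULL
    U2d <- if (is.null(m2)) U2 else U2 * m2
    ln2 <- ln_forward(out + U2d, p[[bp(l, "ln2_g")]], p[[bp(l, "ln2_b")]])
    cache <- c(cache, list(ffn_in = out, U1 = U1, Gfd = Gfd, m1 = m1,
                           m2 = m2, ln2 = ln2))
    out <- ln2$y
  }
  list(Z = out, cache = cache)
}

block_backward <- function(dout, cache, model, l) {
  p <- model$params; cfg <- model$config
  Hh <- cfg$num_heads; dk <- cfg$key_dim
  scal <- 1 / sqrt(dk)
  g <- list()
  if (cfg$use_block_ffn) {
    lb <- ln_backward(dout, cache$ln2, p[[bp(l, "ln2_g")]])
    g[[bp(l, "ln2_g")]] <- lb$dgamma; g[[bp(l, "ln2_b")]] <- lb$dbeta
    dres <- lb$dx                       # grad of (ffn_in + U2d)
    dU2 <- if (is.null(cache$m2)) dres else dres * cache$m2
    g[[bp(l, "f2_W")]] <- crossprod(cache$Gfd, dU2)
    g[[bp(l, "f2_b")]] <- colSums(dU2)
    dGfd <- tcrossprod(dU2, p[[bp(l, "f2_W")]])
    dGf <- if (is.null(cache$m1)) dGfd else dGfd * cache$m1
    dU1 <- dGf * gelu_grad(cache$U1)
    g[[bp(l, "f1_W")]] <- crossprod(cache$ffn_in, dU1)
    g[[bp(l, "f1_b")]] <- colSums(dU1)
    dout <- dres + tcrossprod(dU1, p[[bp(l, "f1_W")]])
  }
  lb <- ln_backward(dout, cache$ln1, p[[bp(l, "ln1_g")]])
  g[[bp(l, "ln1_g")]] <- lb$dgamma; g[[bp(l, "ln1_b")]] <- lb$dbeta
  dres <- lb$dx                         # grad of (Z_in + attn)
  g[[bp(l, "Wo")]] <- crossprod(cache$O, dres)
  g[[bp(l, "bo")]] <- colSums(dres)
  dO <- tcrossprod(dres, p[[bp(l, "Wo")]])
  T <- dim(cache$A)[1]; B <- nrow(dres) %/% T
  ab <- attn_backward_cpp(dO, cache$Q, cache$K, cache$V, cache$A,
                          B, T, Hh, dk, cache$M)
  dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
  Zi <- cache$Z_in
  g[[bp(l, "Wq")]] <- crossprod(Zi, dQ); g[[bp(l, "bq")]] <- colSums(dQ)
  g[[bp(l, "Wk")]] <- crossprod(Zi, dK); g[[bp(l, "bk")]] <- colSums(dK)
  g[[bp(l, "Wv")]] <- crossprod(Zi, dV); g[[bp(l, "bv")]] <- colSums(dV)
  dZ <- dres + tcrossprod(dQ, p[[bp(l, "Wq")]]) +
    tcrossprod(dK, p[[bp(l, "Wk")]]) + tcrossprod(dV, p[[bp(l, "Wv")]])
  list(dZ = dZ, grads = g)
}

## ---- LSTM over the patch sequence (full output sequence returned) ----

lstm_forward <- function(Z, Wx, Wh, b, B, T) {
  u <- nrow(Wh)
  XP <- add_row_vec(Z %*% Wx, b)
  H <- matrix(0, B * T, u)
  I <- array(0, c(B, u, T)); Fg <- I; G <- I; O <- I; HC <- I; Cprev <- I
  h <- matrix(0, B, u); cs <- matrix(0, B, u)
  iu <- seq_len(u)
  for (t in seq_len(T)) {
    rows <- (seq_len(B) - 1L) * T + t
    zg <- XP[rows, , drop = FALSE] + h %*% Wh
    i <- sigmoid(zg[, iu, drop = FALSE])
    f <- sigmoid(zg[, u + iu, drop = FALSE])
    gg <- tanh(zg[, 2L * u + iu, drop = FALSE])
    o <- sigmoid(zg[, 3L * u + iu, drop = FALSE])
    Cprev[, , t] <- cs
    cs <- f * cs + i * gg
    hc <- tanh(cs)
    h <- o * hc
    I[, , t] <- i; Fg[, , t] <- f; G[, , t] <- gg; O[, , t] <- o
    HC[, , t] <- hc
    H[rows, ] <- h
  }
  list(H = H, I = I, Fg = Fg, G = G, O = O, HC = HC, Cprev = Cprev)
}

lstm_backward <- function(dH, cache, Z, Wx, Wh, B, T) {
  u <- nrow(Wh)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, u, ncol(Wh))
  db <- numeric(ncol(Wx))
  dZ <- matrix(0, nrow(Z), ncol(Z))
  dh_next <- matrix(0, B, u); dc_next <- matrix(0, B, u)
  for (t in rev(seq_len(T))) {
    rows <- (seq_len(B) - 1L) * T + t
    i <- cache$I[, , t]; f <- cache$Fg[, , t]; gg <- cache$G[, , t]
    o <- cache$O[, , t]; hc <- cache$HC[, , t]; cprev <- cache$Cprev[, , t]
    if (B == 1L) {       # drop=FALSE semantics for the degenerate batch
      i <- matrix(i, 1); f <- matrix(f, 1); gg <- matrix(gg, 1)
      o <- matrix(o, 1); hc <- matrix(hc, 1); cprev <- matrix(cprev, 1)
    }
    dh <- dH[rows, , drop = FALSE] + dh_next
    do <- dh * hc
    dc <- dc_next + dh * o * (1 - hc * hc)
    di <- dc * gg; dg <- dc * i; df <- dc * cprev
    dc_next <- dc * f
    DZ <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - gg * gg), do * o * (1 - o))
    xt <- Z[rows, , drop = FALSE]
    hprev <- if (t > 1L) cache$H[rows - 1L, , drop = FALSE]
             else matrix(0, B, u)
    dWx <- dWx + crossprod(xt, DZ)
    dWh <- dWh + crossprod(hprev, DZ)
    db <- db + colSums(DZ)
    dh_next <- tcrossprod(DZ, Wh)
    dZ[rows, ] <- tcrossprod(DZ, Wx)
  }
  list(dZ = dZ, dWx = dWx, dWh = dWh, db = db)
}

## ---- token flatten: (B*T) x u  <->  B x (T*u), feature index fastest ----

flatten_tokens <- function(H, B, T) {
  u <- ncol(H)
  A <- array(H, dim = c(T, B, u))
  A <- aperm(A, c(3L, 1L, 2L))
  dim(A) <- c(u * T, B)
  t(A)
}

unflatten_tokens <- function(dF, B, T, u) {
  A <- t(dF)
  dim(A) <- c(u, T, B)
  A <- aperm(A, c(2L, 3L, 1L))
  dim(A) <- c(T * B, u)
  A
}

## ---- full forward / backward ----

nn_forward <- function(model, X, training = FALSE) {
  p <- model$params; cfg <- model$config
  if (length(dim(X)) != 4L ||
      dim(X)[1] != cfg$image_size || dim(X)[2] != cfg$image_size ||
      dim(X)[3] != 3L)
    stop("input must be an image_size x image_size x 3 x N array",
         call. = FALSE)
  B <- dim(X)[4]
  ps <- cfg$patch_size
  T <- (cfg$image_size %/% ps)^2
  xs <- X / 255
  for (ch in 1:3)
    xs[, , ch, ] <- (xs[, , ch, ] - model$buffers$norm_mean[ch]) /
      sqrt(model$buffers$norm_var[ch] + 1e-6)
  P <- batch_patch_matrix(xs, ps)
  Z <- add_row_vec(P %*% p$enc_W, p$enc_b) + p$pos_E[rep(seq_len(T), B), ]
  cache <- list(P = P, B = B, T = T, blocks = vector("list",
                                                     cfg$transformer_layers))
  for (l in seq_len(cfg$transformer_layers)) {
    res <- block_forward(Z, model, l, training, B, T)
    Z <- res$Z
    cache$blocks[[l]] <- res$cache
  }
  cache$Z_final <- Z
  if (model$arch == "abisa") {
    lst <- lstm_forward(Z, p$lstm_Wx, p$lstm_Wh, p$lstm_b, B, T)
    ln <- ln_forward(lst$H, p$post_g, p$post_b)
    cache$lstm <- lst
  } else {
    ln <- ln_forward(Z, p$post_g, p$post_b)
  }
  cache$post_ln <- ln
  Fb <- flatten_tokens(ln$y, B, T)
  if (training && cfg$head_dropout > 0) {
    cache$head_mask <- drop_mask(dim(Fb), cfg$head_dropout)
    Fb <- Fb * cache$head_mask
  }
  cache$Fb <- Fb
  A1 <- add_row_vec(Fb %*% p$h1_W, p$h1_b); G1 <- gelu(A1)
  A2 <- add_row_vec(G1 %*% p$h2_W, p$h2_b); G2 <- gelu(A2)
  logits <- add_row_vec(G2 %*% p$out_W, p$out_b)
  cache$A1 <- A1; cache$G1 <- G1; cache$A2 <- A2; cache$G2 <- G2
  list(probs = row_softmax(logits), logits = logits, cache = cache)
}

nn_backward <- function(model, fw, y) {
  p <- model$params; cfg <- model$config
  cache <- fw$cache
  B <- cache$B; T <- cache$T
  Y <- matrix(0, B, cfg$num_classes)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (fw$probs - Y) / B
  g <- list()
  g$out_W <- crossprod(cache$G2, dlogits); g$out_b <- colSums(dlogits)
  dG2 <- tcrossprod(dlogits, p$out_W)
  dA2 <- dG2 * gelu_grad(cache$A2)
  g$h2_W <- crossprod(cache$G1, dA2); g$h2_b <- colSums(dA2)
  dG1 <- tcrossprod(dA2, p$h2_W)
  dA1 <- dG1 * gelu_grad(cache$A1)
  g$h1_W <- crossprod(cache$Fb, dA1); g$h1_b <- colSums(dA1)
  dFb <- tcrossprod(dA1, p$h1_W)
  if (!is.null(cache$head_mask)) dFb <- dFb * cache$head_mask
  u <- if (model$arch == "abisa") cfg$lstm_units else cfg$projection_dim
  dHn <- unflatten_tokens(dFb, B, T, u)
  lb <- ln_backward(dHn, cache$post_ln, p$post_g)
  g$post_g <- lb$dgamma; g$post_b <- lb$dbeta
  if (model$arch == "abisa") {
    lg <- lstm_backward(lb$dx, cache$lstm, cache$Z_final,
                        p$lstm_Wx, p$lstm_Wh, B, T)
    g$lstm_Wx <- lg$dWx; g$lstm_Wh <- lg$dWh; g$lstm_b <- lg$db
    dZ <- lg$dZ
  } else {
    dZ <- lb$dx
  }
  for (l in rev(seq_len(cfg$transformer_layers))) {
    bb <- block_backward(dZ, cache$blocks[[l]], model, l)
    g <- c(g, bb$grads)
    dZ <- bb$dZ
  }
  g$enc_W <- crossprod(cache$P, dZ)
  g$enc_b <- colSums(dZ)
  g$pos_E <- rowsum(dZ, group = rep(seq_len(T), B))
  g
}

## ---- initialization ----

glorot_uniform <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

orthogonal_mat <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

init_params <- function(cfg, arch) {
  D <- cfg$projection_dim
  T <- cfg$num_patches
  Fdim <- 3L * cfg$patch_size^2
  Hd <- cfg$num_heads * cfg$key_dim
  p <- list(
    enc_W = glorot_uniform(Fdim, D),
    enc_b = numeric(D),
    pos_E = matrix(stats::runif(T * D, -0.05, 0.05), T, D)
  )
  for (l in seq_len(cfg$transformer_layers)) {
    p[[bp(l, "Wq")]] <- glorot_uniform(D, Hd); p[[bp(l, "bq")]] <- numeric(Hd)
    p[[bp(l, "Wk")]] <- glorot_uniform(D, Hd); p[[bp(l, "bk")]] <- numeric(Hd)
    p[[bp(l, "Wv")]] <- glorot_uniform(D, Hd); p[[bp(l, "bv")]] <- numeric(Hd)
    p[[bp(l, "Wo")]] <- glorot_uniform(Hd, D); p[[bp(l, "bo")]] <- numeric(D)
    p[[bp(l, "ln1_g")]] <- rep(1, D); p[[bp(l, "ln1_b")]] <- numeric(D)
    if (cfg$use_block_ffn) {
      u1 <- cfg$block_ffn_units[1]; u2 <- cfg$block_ffn_units[2]
      p[[bp(l, "f1_W")]] <- glorot_uniform(D, u1)
      p[[bp(l, "f1_b")]] <- numeric(u1)
      p[[bp(l, "f2_W")]] <- glorot_uniform(u1, u2)
      p[[bp(l, "f2_b")]] <- numeric(u2)
      p[[bp(l, "ln2_g")]] <- rep(1, D); p[[bp(l, "ln2_b")]] <- numeric(D)
    }
  }
  if (arch == "abisa") {
    u <- cfg$lstm_units
    p$lstm_Wx <- glorot_uniform(D, 4L * u)
    p$lstm_Wh <- do.call(cbind, lapply(1:4, function(i) orthogonal_mat(u)))
    b <- numeric(4L * u)
    b[u + seq_len(u)] <- 1          # unit forget-gate bias
    p$lstm_b <- b
    p$post_g <- rep(1, u); p$post_b <- numeric(u)
    flat_in <- T * u
  } else {
    p$post_g <- rep(1, D); p$post_b <- numeric(D)
    flat_in <- T * D
  }
  h1 <- cfg$mlp_head_units[1]; h2 <- cfg$mlp_head_units[2]
  p$h1_W <- glorot_uniform(flat_in, h1); p$h1_b <- numeric(h1)
  p$h2_W <- glorot_uniform(h1, h2); p$h2_b <- numeric(h2)
  p$out_W <- glorot_uniform(h2, cfg$num_classes)
  p$out_b <- numeric(cfg$num_classes)
  p
}

## ---- AdamW (decoupled weight decay on weight matrices) ----

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

# One optimizer step, updating every tensor in place (the training loop owns
# deep copies of the parameters and the moment estimates). Decoupled weight
# decay is applied to kernels and embeddings, not to biases or layer-norm
# parameters.
adamw_update <- function(params, grads, state, lr, weight_decay,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params))
    adamw_step_cpp(params[[nm]], state$m[[nm]], state$v[[nm]], grads[[nm]],
                   lr, weight_decay, beta1, beta2, eps, bc1, bc2,
                   is.matrix(params[[nm]]))
  list(params = params, state = state)
}

# duplicate every tensor so in-place optimizer steps cannot alias user data
deep_copy_params <- function(params) lapply(params, function(x) x + 0)
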