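# Bilinear resampling primitives. A single inverse-mapping sampler with
# edge-clamped coordinates backs both tile resizing and the random affine
# augmentation, so the two share one interpolation convention.

# Sample an H x W x 3 image at fractional (row, col) coordinates (1-based).
# Coordinates outside the raster are clamped to the nearest edge pixel, which
# extends border values instead of introducing a constant fill colour.
bilinear_sample <- function(pixels, rows, cols) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  r <- clamp(rows, 1, h)
  c <- clamp(cols, 1, w)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- r - r0; fc <- c - c0
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc); w11 <- fr * fc
  out <- array(0, dim = c(length(rows) / 1L, 3L))
  i00 <- r0 + (c0 - 1) * h; i01 <- r0 + (c1 - 1) * h
  i10 <- r1 + (c0 - 1) * h; i11 <- r1 + (c1 - 1) * h
  for (ch in 1:3) {
    plane <- pixels[, , ch]
    out[, ch] <- w00 * plane[i00] + w01 * plane[i01] +
      w10 * plane[i10] + w11 * plane[i11]
  }
  out
}

#' Resize a tile with bilinear interpolation
#'
#' Resamples an RGB tile to `target` x `target` pixels using bilinear
#' interpolation with half-pixel centre alignment, the convention used when
#' shrinking native-resolution tiles (for example 2048 x 2048) down to the
#' classifier's input size. Output values are clipped to the 8-bit range.
#'
#' @param pixels H x W x 3 numeric array on the 0..255 scale.
#' @param target Side length of the square output, a positive integer.
#' @return A `target` x `target` x 3 numeric array.
#' @examples
#' tile <- make_tile("non_recurring", size_px = 128, seed = 1)
#' small <- resize_tile(tile, 64)
#' dim(small)
#' @export
resize_tile <- function(pixels, target) {
  check_image(pixels)
  if (!is.numeric(target) || length(target) != 1L || target < 1)
    stop("`target` must be a positive integer", call. = FALSE)
  target <- as.integer(target)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h == target && w == target) return(pixels)
  # half-pixel centres: dst pixel i samples src at (i - 0.5) * scale + 0.5
  ry <- (seq_len(target) - 0.5) * (h / target) + 0.5
  rx <- (seq_len(target) - 0.5) * (w / target) + 0.5
  rows <- rep(ry, times = target)
  cols <- rep(rx, each = target)
  flat <- bilinear_sample(pixels, rows, cols)
  out <- array(0, dim = c(target, target, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(flat[, ch], target, target)
  clamp(out, 0, 255)
}

# Apply a 2x2 linear map `A` plus translation (pixels) about the image centre,
# by inverse mapping: each output pixel is pulled from A^{-1} (p - t).
apply_affine <- function(pixels, A, tx = 0, ty = 0) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  Ainv <- solve(A)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- rep(seq_len(h), times = w) - cy - ty
  xx <- rep(seq_len(w), each = h) - cx - tx
  src_x <- Ainv[1, 1] * xx + Ainv[1, 2] * yy + cx
  src_y <- Ainv[2, 1] * xx + Ainv[2, 2] * yy + cy
  flat <- bilinear_sample(pixels, src_y, src_x)
  out <- array(0, dim = dim(pixels))
  for (ch in 1:3) out[, , ch] <- matrix(flat[, ch], h, w)
  clamp(out, 0, 255)
}
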