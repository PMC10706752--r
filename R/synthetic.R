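# Deterministic synthetic histology-like tiles, white tiles, and composite
# slides with ground truth. The generator exists so the whole pipeline --
# tiling, filtering, training, evaluation, slide aggregation -- is testable
# without any private whole-slide data.
#
# The two tissue classes differ by exactly one discriminative motif: recurring
# tiles carry a smooth horizontal band of high-saturation eosinophilic colour
# (emulating a band of subepithelial hyalinization), overlaid on the same
# H&E-like pink/purple speckle texture that non-recurring tiles consist of.
# White tiles are near-uniform bright pixels that the entropy/variance filter
# must reject.

# Palette constants (8-bit RGB). Chosen once: eosin pink and hematoxylin
# purple bracket typical H&E tile colour with enough luma contrast that
# tissue tiles sit well above the default entropy/variance thresholds even
# when a band covers 40% of the tile; the band colour is a brighter, more
# saturated pink so per-row saturation separates the classes.
.PALETTE <- list(pink = c(240, 168, 200), purple = c(112, 70, 148),
                 band = c(244, 100, 136))

.TILE_CLASSES <- c("non_recurring", "recurring", "white")

# smoothed uniform noise field in [0, 1] (separable circular box filter)
smooth_noise_field <- function(n, k = max(3L, as.integer(n / 16))) {
  if (k %% 2L == 0L) k <- k + 1L
  u <- matrix(stats::runif(n * n), n, n)
  f <- rep(1 / k, k)
  u <- apply(u, 2, function(col) stats::filter(col, f, circular = TRUE))
  u <- t(apply(u, 1, function(row) stats::filter(row, f, circular = TRUE)))
  rng <- range(u)
  if (rng[2] > rng[1]) (u - rng[1]) / (rng[2] - rng[1]) else u * 0 + 0.5
}

#' Generate one synthetic tile
#'
#' Produces a deterministic RGB tile of one of three classes:
#' * `"white"` -- near-uniform bright pixels (grayscale entropy under 1 bit,
#'   variance under 10), emulating background/glass;
#' * `"non_recurring"` -- a pink/purple speckle texture (smoothed seeded noise
#'   blended across an H&E-like palette plus fine per-channel speckle);
#' * `"recurring"` -- the same texture plus a smooth horizontal band of
#'   high-saturation colour spanning 22--40% of the tile height, centred in
#'   the middle portion of the tile.
#'
#' The same `(tile_class, size_px, seed)` triple always yields byte-identical
#' pixels, and the caller's RNG stream is left untouched.
#'
#' @param tile_class One of `"non_recurring"`, `"recurring"`, `"white"`.
#' @param size_px Tile side length in pixels (256 suits tiling tests, 64 the
#'   classifier input).
#' @param seed Integer seed.
#' @return A `size_px` x `size_px` x 3 numeric array on the 0..255 scale.
#' @examples
#' t1 <- make_tile("recurring", size_px = 64, seed = 7)
#' shannon_entropy(t1) > 4
#' @export
make_tile <- function(tile_class, size_px = 256L, seed = 1L) {
  if (!is.character(tile_class) || !(tile_class %in% .TILE_CLASSES))
    stop("`tile_class` must be one of: ",
         paste(.TILE_CLASSES, collapse = ", "), call. = FALSE)
  if (size_px < 8) stop("`size_px` must be >= 8", call. = FALSE)
  n <- as.integer(size_px)
  local_seed(seed, {
    if (tile_class == "white") {
      g <- 250 + sample(c(-1L, 0L, 1L), n * n, replace = TRUE,
                        prob = c(0.02, 0.96, 0.02))
      px <- array(rep(as.numeric(g), 3L), dim = c(n, n, 3L))
    } else {
      t_field <- smooth_noise_field(n)
      px <- array(0, dim = c(n, n, 3L))
      for (ch in 1:3)
        px[, , ch] <- .PALETTE$purple[ch] * t_field +
          .PALETTE$pink[ch] * (1 - t_field) +
          matrix(stats::runif(n * n, -24, 24), n, n)
      if (tile_class == "recurring") {
        centre <- stats::runif(1, 0.42, 0.58) * n
        half <- stats::runif(1, 0.22, 0.40) / 2 * n
        edge <- max(2, 0.05 * n)
        d <- (abs(seq_len(n) - centre) - half) / edge
        w <- clamp(1 - d, 0, 1)          # 1 inside band, linear taper at edges
        for (ch in 1:3)
          px[, , ch] <- (1 - w) * px[, , ch] + w *
            (.PALETTE$band[ch] + matrix(stats::runif(n * n, -16, 16), n, n))
      }
      px <- clamp(px, 0, 255)
    }
    px
  })
}

#' Assemble a synthetic slide with known per-tile classes
#'
#' Places exactly `round(recurring_fraction * n_cells)` recurring tiles and
#' `round(white_fraction * n_cells)` white tiles at seeded random grid
#' positions; all remaining cells are non-recurring texture. The ground-truth
#' manifest records every cell's class.
#'
#' @param n_rows,n_cols Tile grid size.
#' @param recurring_fraction,white_fraction Fractions of grid cells, summing
#'   to at most 1.
#' @param tile_size Tile side length in pixels.
#' @param seed Integer seed.
#' @return List with `image` (the composite `n_rows*tile_size` x
#'   `n_cols*tile_size` x 3 array) and `truth` (data frame with 0-based `row`,
#'   `col` and `class`).
#' @export
make_slide <- function(n_rows, n_cols, recurring_fraction = 0,
                       white_fraction = 0, tile_size = 256L, seed = 1L) {
  if (n_rows < 1 || n_cols < 1) stop("grid must be non-empty", call. = FALSE)
  if (recurring_fraction < 0 || white_fraction < 0 ||
      recurring_fraction + white_fraction > 1)
    stop("class fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  n <- n_rows * n_cols
  n_rec <- round(recurring_fraction * n)
  n_white <- min(round(white_fraction * n), n - n_rec)
  classes <- local_seed(seed, {
    cl <- rep("non_recurring", n)
    pos <- sample.int(n)
    if (n_rec > 0) cl[pos[seq_len(n_rec)]] <- "recurring"
    if (n_white > 0) cl[pos[n_rec + seq_len(n_white)]] <- "white"
    cl
  })
  ts <- as.integer(tile_size)
  img <- array(0, dim = c(n_rows * ts, n_cols * ts, 3L))
  truth <- data.frame(row = rep(0:(n_rows - 1L), each = n_cols),
                      col = rep(0:(n_cols - 1L), times = n_rows),
                      class = classes, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    r <- truth$row[k]; cc <- truth$col[k]
    img[(r * ts + 1L):((r + 1L) * ts), (cc * ts + 1L):((cc + 1L) * ts), ] <-
      make_tile(classes[k], ts, derive_seed(seed, k))
  }
  list(image = img, truth = truth)
}

#' Generate a balanced labelled tile dataset at model input scale
#'
#' Equal numbers of recurring (label 1) and non-recurring (label 0) synthetic
#' tiles, in seeded shuffled order. Deterministic in `seed`.
#'
#' @param n_per_class Tiles per class, at least 1.
#' @param size_px Tile side length (default 64, the classifier input size).
#' @param seed Integer seed.
#' @return List with `images` (`size_px` x `size_px` x 3 x `2*n_per_class`
#'   array, 0..255) and `labels` (integer vector of 0/1).
#' @export
make_labeled_dataset <- function(n_per_class, size_px = 64L, seed = 1L) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c(0L, 1L), each = n_per_class)
  ord <- local_seed(derive_seed(seed, 0L), sample.int(n))
  images <- array(0, dim = c(size_px, size_px, 3L, n))
  for (i in seq_len(n)) {
    j <- ord[i]
    cl <- if (labels[j] == 1L) "recurring" else "non_recurring"
    images[, , , i] <- make_tile(cl, size_px, derive_seed(seed, j))
  }
  list(images = images, labels = labels[ord])
}
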