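# Dataset splitting and training-time augmentation.
#
# Labelled tiles are partitioned 70-10-20 into train/validation/test. Test and
# validation sizes are rounded to the nearest integer and train takes the
# remainder, so 508 tiles yield a 102-tile test partition. Augmentation is
# sampled on the fly per batch: an independent random affine transform per
# image within the configured ranges plus a fair-coin horizontal flip.

#' Split configuration
#'
#' @param train_frac,val_frac,test_frac Partition fractions, summing to 1
#'   (defaults 0.70 / 0.10 / 0.20).
#' @param stratified Preserve class proportions within each partition
#'   (default `TRUE`).
#' @param seed Integer seed; the split is deterministic in it.
#' @return An object of class `split_config`.
#' @export
split_config <- function(train_frac = 0.70, val_frac = 0.10,
                         test_frac = 0.20, stratified = TRUE, seed = 1L) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  if (min(train_frac, val_frac, test_frac) < 0)
    stop("split fractions must be non-negative", call. = FALSE)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_config")
}

# Largest-remainder apportionment of `total` items over strata of sizes `ns`.
apportion <- function(total, ns) {
  if (total == 0L) return(rep(0L, length(ns)))
  q <- total * ns / sum(ns)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split labelled items into train/validation/test index sets
#'
#' `|test| = round(test_frac * N)` and `|val| = round(val_frac * N)`; train
#' takes the remainder. Under stratification the per-class counts inside each
#' partition follow largest-remainder apportionment, keeping class proportions
#' within one item of exact.
#'
#' @param labels Vector of class labels, one per item (any atomic type). For
#'   an unstratified split only its length is used.
#' @param cfg A [split_config()].
#' @return List of integer index vectors `train`, `val`, `test`: disjoint,
#'   exhaustive, deterministic in `cfg$seed`.
#' @examples
#' s <- split_dataset(rep(0:1, each = 254), split_config(seed = 42))
#' lengths(s) # 355 / 51 / 102
#' @export
split_dataset <- function(labels, cfg = split_config()) {
  n <- length(labels)
  if (n < 3) stop("need at least 3 items to split", call. = FALSE)
  n_test <- as.integer(round(cfg$test_frac * n))
  n_val <- as.integer(round(cfg$val_frac * n))
  if (n_test + n_val > n)
    stop("val + test rounding exceeds dataset size", call. = FALSE)
  local_seed(cfg$seed, {
    if (cfg$stratified) {
      classes <- sort(unique(labels))
      if (any(table(labels) < 1L))
        stop("every class needs at least one item under stratification",
             call. = FALSE)
      by_class <- lapply(classes, function(cl) sample(which(labels == cl)))
      ns <- lengths(by_class)
      t_c <- apportion(n_test, ns)
      v_c <- apportion(n_val, ns)
      # a tiny class can be exhausted by test+val apportionment; shift the
      # overflow to the largest class so partitions stay disjoint
      over <- pmax(t_c + v_c - ns, 0L)
      if (any(over > 0L)) {
        v_c <- v_c - over
        v_c[which.max(ns - t_c - v_c)] <- v_c[which.max(ns - t_c - v_c)] +
          sum(over)
      }
      test <- integer(0); val <- integer(0); train <- integer(0)
      for (i in seq_along(classes)) {
        idx <- by_class[[i]]
        test <- c(test, idx[seq_len(t_c[i])])
        val <- c(val, idx[t_c[i] + seq_len(v_c[i])])
        train <- c(train, idx[-seq_len(t_c[i] + v_c[i])])
      }
    } else {
      perm <- sample.int(n)
      test <- perm[seq_len(n_test)]
      val <- perm[n_test + seq_len(n_val)]
      train <- perm[-seq_len(n_test + n_val)]
    }
    list(train = sort(train), val = sort(val), test = sort(test))
  })
}

#' Augmentation configuration
#'
#' Ranges follow the common image-augmentation convention: rotation in
#' degrees sampled uniformly in `[-rotation, +rotation]`; shifts as fractions
#' of image size; shear as a shear factor; zoom sampled per axis in
#' `[1 - zoom, 1 + zoom]`; horizontal flip with probability one half.
#' Out-of-bounds samples take the nearest edge pixel.
#'
#' @param rotation_range_deg Maximum absolute rotation, degrees (default 20).
#' @param width_shift_frac,height_shift_frac Maximum absolute shift as a
#'   fraction of width/height (default 0.1).
#' @param shear_range Maximum absolute shear factor (default 0.2).
#' @param zoom_range Zoom half-range (default 0.2).
#' @param horizontal_flip Enable fair-coin horizontal flips (default `TRUE`).
#' @param seed Integer seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_range_deg = 20, width_shift_frac = 0.1,
                           height_shift_frac = 0.1, shear_range = 0.2,
                           zoom_range = 0.2, horizontal_flip = TRUE,
                           seed = 1L) {
  vals <- c(rotation_range_deg, width_shift_frac, height_shift_frac,
            shear_range, zoom_range)
  if (any(vals < 0)) stop("augmentation ranges must be >= 0", call. = FALSE)
  structure(list(rotation_range_deg = rotation_range_deg,
                 width_shift_frac = width_shift_frac,
                 height_shift_frac = height_shift_frac,
                 shear_range = shear_range, zoom_range = zoom_range,
                 horizontal_flip = isTRUE(horizontal_flip),
                 seed = as.integer(seed)),
            class = "augment_config")
}

# One random affine for a single image, drawn from the configured ranges.
random_affine_once <- function(img, cfg) {
  h <- dim(img)[1]; w <- dim(img)[2]
  theta <- stats::runif(1, -cfg$rotation_range_deg, cfg$rotation_range_deg) *
    pi / 180
  sh <- stats::runif(1, -cfg$shear_range, cfg$shear_range)
  zx <- stats::runif(1, 1 - cfg$zoom_range, 1 + cfg$zoom_range)
  zy <- stats::runif(1, 1 - cfg$zoom_range, 1 + cfg$zoom_range)
  tx <- stats::runif(1, -cfg$width_shift_frac, cfg$width_shift_frac) * w
  ty <- stats::runif(1, -cfg$height_shift_frac, cfg$height_shift_frac) * h
  flip <- cfg$horizontal_flip && stats::runif(1) < 0.5
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)          # shear along x
  Z <- diag(c(zx, zy))
  Fm <- diag(c(if (flip) -1 else 1, 1))
  A <- Fm %*% R %*% S %*% Z                   # maps (x, y) input -> output
  if (all(A == diag(2)) && tx == 0 && ty == 0) return(img)
  apply_affine(img, A, tx = tx, ty = ty)
}

#' Apply random affine augmentation to a batch of images
#'
#' Each image receives an independent transform; output shapes equal input
#' shapes, and results are deterministic in `cfg$seed`. Augmentation is meant
#' for training batches only -- validation and test data pass through the
#' pipeline untouched.
#'
#' @param images H x W x 3 x N array (a single H x W x 3 image is accepted).
#' @param cfg An [augment_config()].
#' @return Array of the same shape.
#' @export
augment_batch <- function(images, cfg = augment_config()) {
  single <- length(dim(images)) == 3L
  if (single) dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 4L || dim(images)[3] != 3L)
    stop("`images` must be an H x W x 3 x N array", call. = FALSE)
  out <- local_seed(cfg$seed, {
    res <- images
    for (i in seq_len(dim(images)[4]))
      res[, , , i] <- random_affine_once(images[, , , i], cfg)
    res
  })
  if (single) dim(out) <- dim(out)[1:3]
  out
}
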