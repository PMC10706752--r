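# Slide reading, tiling, and low-information (white) tile rejection.
#
# Whole slides are cut into a floor grid of non-overlapping square tiles at the
# highest available resolution. Each tile gets two information statistics on
# its 8-bit grayscale rendering -- Shannon entropy of the 256-bin histogram and
# the population pixel variance -- and is discarded when either falls below its
# threshold, which removes background/glass ("white") tiles before
# classification.

#' Tile filter configuration
#'
#' Holds the tile size and the entropy/variance thresholds used to reject
#' low-information tiles. A tile is kept only when its grayscale Shannon
#' entropy is at least `entropy_min` bits *and* its grayscale pixel variance is
#' at least `variance_min`; failing either test marks it as background.
#'
#' @param tile_size Tile side length in pixels (default 2048, the native tile
#'   size cut from the highest zoom level).
#' @param entropy_min Minimum grayscale entropy in bits, in \[0, 8\].
#' @param variance_min Minimum grayscale intensity variance, non-negative.
#' @return An object of class `tile_filter_config`.
#' @export
tile_filter_config <- function(tile_size = 2048L, entropy_min = 4.0,
                               variance_min = 100.0) {
  if (tile_size < 1) stop("`tile_size` must be >= 1", call. = FALSE)
  if (entropy_min < 0 || entropy_min > 8)
    stop("`entropy_min` must lie in [0, 8] bits", call. = FALSE)
  if (variance_min < 0) stop("`variance_min` must be >= 0", call. = FALSE)
  structure(list(tile_size = as.integer(tile_size),
                 entropy_min = entropy_min, variance_min = variance_min),
            class = "tile_filter_config")
}

#' Tile grid dimensions for a slide
#'
#' Number of whole tiles that fit along each axis. Partial edge tiles are
#' discarded (floor policy): the classifier needs fixed-size inputs, and a
#' 126,976-pixel-square slide at tile size 2048 yields exactly 62 x 62 = 3844
#' tiles.
#'
#' @param width_px,height_px Slide pixel dimensions at the tiled level.
#' @param tile_size Tile side length in pixels.
#' @return Integer vector `c(n_rows, n_cols)`.
#' @examples
#' grid_dimensions(126976, 126976, 2048) # 62 x 62
#' @export
grid_dimensions <- function(width_px, height_px, tile_size) {
  if (any(c(width_px, height_px, tile_size) < 1))
    stop("all arguments must be >= 1", call. = FALSE)
  c(n_rows = as.integer(height_px %/% tile_size),
    n_cols = as.integer(width_px %/% tile_size))
}

#' Shannon entropy of a tile's grayscale histogram
#'
#' Converts the tile to 8-bit grayscale (BT.601 luma, rounded to integer bins)
#' and returns the Shannon entropy, in bits, of the 256-bin histogram. Empty
#' bins contribute zero, so the value lies in \[0, 8\] and is bounded by
#' log2 of the number of distinct grayscale values present.
#'
#' @param pixels H x W x 3 RGB array (0..255); a 2-D grayscale matrix is also
#'   accepted.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(pixels) {
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric array", call. = FALSE)
  g <- grayscale_u8(pixels)
  counts <- tabulate(as.integer(g) + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(g)
  -sum(p * log2(p))
}

#' Grayscale pixel variance of a tile
#'
#' Population variance (divisor n) of the 8-bit grayscale pixel values.
#'
#' @inheritParams shannon_entropy
#' @return Non-negative variance.
#' @export
pixel_variance <- function(pixels) {
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty numeric array", call. = FALSE)
  g <- as.numeric(grayscale_u8(pixels))
  mean((g - mean(g))^2)
}

#' Is a tile informative (tissue) rather than background?
#'
#' @param tile A tile object from [tile_slide()], or a raw H x W x 3 pixel
#'   array whose statistics are computed on the fly.
#' @param cfg A [tile_filter_config()].
#' @return `TRUE` when entropy and variance both meet their thresholds.
#' @export
is_informative <- function(tile, cfg = tile_filter_config()) {
  if (is.numeric(tile)) {
    e <- shannon_entropy(tile); v <- pixel_variance(tile)
  } else {
    e <- tile$entropy_bits; v <- tile$variance
  }
  isTRUE(e >= cfg$entropy_min && v >= cfg$variance_min)
}

#' Reference to a slide image
#'
#' Wraps either a path to a raster image (PNG or TIFF; a multi-page pyramidal
#' TIFF resolves to its highest-resolution page) or an in-memory H x W x 3
#' array. Plain rasters are treated as single-level slides so no pyramidal
#' fixture is ever required.
#'
#' @param x File path or numeric H x W x 3 array on the 0..255 scale.
#' @param slide_id Identifier used in manifests; defaults to the file base
#'   name, or `"slide"` for in-memory arrays.
#' @return An object of class `slide_ref` with fields `slide_id`, `path`,
#'   `width_px`, `height_px`, `level` and the pixel data.
#' @export
slide_ref <- function(x, slide_id = NULL) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("cannot read slide: ", x, call. = FALSE)
    img <- read_slide_image(x)
    path <- x
    slide_id <- slide_id %||% sub("\\.[^.]+$", "", basename(x))
    level <- attr(img, "level") %||% 0L
  } else {
    check_image(x, "x")
    img <- x
    path <- NA_character_
    slide_id <- slide_id %||% "slide"
    level <- 0L
  }
  structure(list(slide_id = slide_id, path = path,
                 width_px = dim(img)[2], height_px = dim(img)[1],
                 level = level, pixels = img),
            class = "slide_ref")
}

# Read PNG/TIFF into a 0..255 H x W x 3 array; multi-page TIFFs resolve to the
# largest (highest-resolution) page, recorded as the `level` attribute.
read_slide_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    img <- png::readPNG(path)
    level <- 0L
  } else if (ext %in% c("tif", "tiff", "svs")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    areas <- vapply(pages, function(p) prod(dim(p)[1:2]), numeric(1))
    level <- which.max(areas)
    img <- pages[[level]]
    level <- level - 1L
  } else stop("unsupported slide format: .", ext, call. = FALSE)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  out <- img * 255
  attr(out, "level") <- level
  out
}

#' Cut a slide into tiles and reject white tiles
#'
#' Iterates the full floor grid from [grid_dimensions()] in row-major order,
#' computes entropy and variance for every tile, and keeps the informative
#' ones. Every grid position appears in the manifest exactly once with its
#' statistics and kept flag.
#'
#' @param slide A [slide_ref()], a file path, or an H x W x 3 array.
#' @param cfg A [tile_filter_config()].
#' @param keep_pixels Attach pixel arrays to the returned kept tiles (default
#'   `TRUE`; set to `FALSE` to save memory when only the manifest is needed).
#' @return A list with `tiles` (kept tiles, row-major; each has `row`, `col`,
#'   `origin_x`, `origin_y`, `entropy_bits`, `variance`, `kept` and optionally
#'   `pixels`) and `manifest` (a data frame over all grid positions with the
#'   filter thresholds recorded as attributes).
#' @examples
#' syn <- make_slide(2, 2, recurring_fraction = 0.25, white_fraction = 0.25,
#'                   tile_size = 64, seed = 1)
#' res <- tile_slide(syn$image, tile_filter_config(tile_size = 64))
#' table(res$manifest$kept)
#' @export
tile_slide <- function(slide, cfg = tile_filter_config(), keep_pixels = TRUE) {
  if (!inherits(slide, "slide_ref")) slide <- slide_ref(slide)
  ts <- cfg$tile_size
  g <- grid_dimensions(slide$width_px, slide$height_px, ts)
  n_rows <- g[["n_rows"]]; n_cols <- g[["n_cols"]]
  if (n_rows == 0L || n_cols == 0L) {
    warning("slide smaller than tile size: zero-tile grid", call. = FALSE)
    man <- empty_manifest()
    attr(man, "filter") <- unclass(cfg)
    return(list(tiles = list(), manifest = man))
  }
  n <- n_rows * n_cols
  man <- data.frame(slide_id = rep(slide$slide_id, n),
                    row = integer(n), col = integer(n),
                    origin_x = integer(n), origin_y = integer(n),
                    entropy_bits = numeric(n), variance = numeric(n),
                    kept = logical(n), stringsAsFactors = FALSE)
  tiles <- vector("list", n)
  k <- 0L
  for (r in 0:(n_rows - 1L)) {
    for (cc in 0:(n_cols - 1L)) {
      k <- k + 1L
      px <- slide$pixels[(r * ts + 1L):((r + 1L) * ts),
                         (cc * ts + 1L):((cc + 1L) * ts), , drop = FALSE]
      e <- shannon_entropy(px)
      v <- pixel_variance(px)
      kept <- e >= cfg$entropy_min && v >= cfg$variance_min
      man$row[k] <- r; man$col[k] <- cc
      man$origin_x[k] <- cc * ts; man$origin_y[k] <- r * ts
      man$entropy_bits[k] <- e; man$variance[k] <- v; man$kept[k] <- kept
      if (kept)
        tiles[[k]] <- structure(
          list(row = r, col = cc, origin_x = cc * ts, origin_y = r * ts,
               pixels = if (keep_pixels) px else NULL,
               entropy_bits = e, variance = v, kept = TRUE),
          class = "abisa_tile")
    }
  }
  attr(man, "filter") <- unclass(cfg)
  list(tiles = Filter(Negate(is.null), tiles), manifest = man)
}

empty_manifest <- function() {
  data.frame(slide_id = character(), row = integer(), col = integer(),
             origin_x = integer(), origin_y = integer(),
             entropy_bits = numeric(), variance = numeric(),
             kept = logical(), stringsAsFactors = FALSE)
}

#' Write a tile manifest to CSV or JSON
#'
#' @param manifest Manifest data frame from [tile_slide()].
#' @param path Output file; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path,
                           format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv")
    utils::write.csv(manifest, path, row.names = FALSE)
  else
    jsonlite::write_json(manifest, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Write kept tiles as PNG files
#'
#' Files are named `{slide_id}_r{row}_c{col}.png`.
#'
#' @param tiles Kept tiles from [tile_slide()] (with pixels attached).
#' @param dir Output directory, created if needed.
#' @param slide_id Identifier used in file names.
#' @return Character vector of written paths, invisibly.
#' @export
write_tiles <- function(tiles, dir, slide_id = "slide") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(tiles, function(t) {
    p <- file.path(dir, sprintf("%s_r%d_c%d.png", slide_id, t$row, t$col))
    png::writePNG(clamp(t$pixels, 0, 255) / 255, p)
    p
  }, character(1))
  invisible(paths)
}
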