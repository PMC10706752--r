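# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards so seeded helpers never perturb user code.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(abs(seed) %% 2147483647L))
  }
  force(code)
}

# Deterministic stream of sub-seeds; plain double arithmetic keeps every
# intermediate below 2^53 so the result is exact, and the output fits in a
# 32-bit integer.
derive_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  as.integer(((s * 48271 + as.numeric(k) * 9349) %% 2147483587) + 1)
}

# Validate an H x W x 3 numeric image array on the 0..255 scale.
check_image <- function(pixels, arg = "pixels") {
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop(sprintf("`%s` must be a non-empty numeric array", arg), call. = FALSE)
  d <- dim(pixels)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 RGB array", arg), call. = FALSE)
  invisible(pixels)
}

# ITU-R BT.601 luma, rounded to the nearest 8-bit bin.
grayscale_u8 <- function(pixels) {
  g <- if (length(dim(pixels)) == 3L)
    0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  else pixels
  pmin(pmax(round(g), 0), 255)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Add a row vector to every row of a matrix. In-place C++ kernel: only ever
# applied to freshly allocated matmul/elementwise results.
add_row_vec <- function(M, v) addrow_cpp(M, v)
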