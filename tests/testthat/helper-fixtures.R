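# Shared fixtures: a tiny architecture for fast exact tests, and small image
# constructors.

tiny_config <- function(...) {
  args <- list(image_size = 8, patch_size = 4, projection_dim = 6,
               num_heads = 2, key_dim = 5, transformer_layers = 2,
               lstm_units = 4, mlp_head_units = c(10, 7),
               attention_dropout = 0, head_dropout = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_config, args)
}

random_images <- function(n, size = 8, seed = 1) {
  set.seed(seed)
  array(runif(size * size * 3 * n) * 255, c(size, size, 3, n))
}

# solid-gray RGB tile
constant_tile <- function(value, size = 16) {
  array(value, c(size, size, 3))
}

# tile whose grayscale is exactly half `lo`, half `hi` (all channels equal)
two_level_tile <- function(lo = 0, hi = 255, size = 16) {
  g <- matrix(c(rep(lo, size * size / 2), rep(hi, size * size / 2)),
              size, size)
  array(rep(g, 3), c(size, size, 3))
}
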