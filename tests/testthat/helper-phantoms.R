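# Cheap fixtures: a coarse-spacing phantom (same physical geometry, ~16x
# fewer voxels) and a small network configuration for contract tests.

coarse_spec <- function(seed = 1L, ...) {
  phantom_spec(seed = seed, grid_shape = c(24L, 28L, 20L),
               spacing = c(3.6, 2.8, 5.0), ...)
}

tiny_net <- function(seed = 1L, epochs = 2L, ...) {
  net_config(depth = 2L, base_channels = 4L, epochs = epochs,
             slices_per_volume = 8L, iso_mm = 3, seed = seed, ...)
}

coarse_dataset <- function(n, seed = 1L, ...) {
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(coarse_spec(seed = seed + i, ...))
    list(volume = ph$volume, labels = ph$labels)
  })
}

# Random probability array with prescribed per-voxel argmax.
probs_with_argmax <- function(argmax_vec, dims, K = 5L, seed = 1L) {
  set.seed(seed)
  n <- prod(dims)
  p <- matrix(runif(n * K, 0.01, 0.5), n, K)
  p[cbind(seq_len(n), argmax_vec)] <- 1
  p <- p / rowSums(p)
  array(p, dim = c(dims, K))
}
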