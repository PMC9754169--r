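# Shared fixtures, all generated in code.

# A dense volume whose intensity is affine in slice index: background plus
# a per-slice constant increment. Linear interpolation is exact on it.
ramp_volume <- function(h = 8, w = 8, n_slices = 7, base = 0.2,
                        slope = NULL) {
  if (is.null(slope)) slope <- 0.6 / (n_slices - 1)
  vox <- array(0, dim = c(h, w, n_slices))
  plane <- matrix(seq(0, 0.1, length.out = h * w), h, w)
  for (z in seq_len(n_slices))
    vox[, , z] <- base + plane + slope * (z - 1)
  normalized_volume(vox, window = c(-1000, 1000), spacing = c(1, 1, 2.5),
                    slice_axis = 3L)
}

# Tiny phantom configuration for fast tests.
tiny_phantom_cfg <- function(seed = 5, n_slices = 13, shape = c(32, 32),
                             ...) {
  phantom_config(shape = shape, n_slices = n_slices, seed = seed, ...)
}

# Tiny network spec for fast model tests.
tiny_spec <- function(shape = c(16, 16), base_channels = 4,
                      dropout_rate = 0, ...) {
  unet_spec(shape, base_channels = base_channels, encoder_blocks = 2,
            dropout_rate = dropout_rate, ...)
}

# Analytic training examples: targets are smooth nonlinear blends of the
# two inputs, so a small network can learn them quickly.
blend_examples <- function(n = 10, shape = c(16, 16), t = 1, seed = 99) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    l <- matrix(runif(prod(shape), 0.2, 0.5), shape[1], shape[2])
    r <- matrix(runif(prod(shape), 0.5, 0.8), shape[1], shape[2])
    tg <- array(0, dim = c(shape, t))
    for (k in seq_len(t)) {
      f <- k / (t + 1)
      lin <- (1 - f) * l + f * r
      # markedly nonlinear in the inputs, so the residual is substantial
      tg[, , k] <- pmin(pmax(lin^2 + 0.08 * sin(6 * lin), 0), 1)
    }
    list(input = array(c(l, r), dim = c(shape, 2)), target = tg)
  })
}
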