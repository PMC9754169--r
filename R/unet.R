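# U-net: an encoder path of conv-BN-ReLU blocks with 2x2 max pooling, a
# bottleneck, and a decoder path of nearest-neighbour upsampling + skip
# concatenation + conv-BN-ReLU blocks, closed by a 1x1 linear projection
# to the output channels. Input and output share the spatial shape. A
# dropout layer sits in the last decoder block, the placement used for
# regularising image-to-image regression here.

#' U-net architecture specification
#'
#' `encoder_blocks` counts the resolution levels of the encoder including
#' the bottleneck; the decoder has one fewer (`decoder_blocks`), one per
#' upsampling stage. The full-scale default is 8 encoder / 7 decoder
#' blocks. When the image is too small for the requested depth (each level
#' must keep both spatial extents even and at least 2 before pooling), the
#' depth is reduced automatically and the effective value is stored in
#' `levels`.
#'
#' @param image_shape integer (height, width) of input/output slices.
#' @param base_channels channels of the first level; doubled per level,
#'   capped at `channel_cap`.
#' @param encoder_blocks,decoder_blocks requested depth; by default
#'   `decoder_blocks = encoder_blocks - 1`.
#' @param input_channels number of input slices stacked as channels (2:
#'   the two neighbours).
#' @param output_channels predicted slices per forward pass (1 for a
#'   parallel branch; `2m - 1` for the single multi-output variant).
#' @param dropout_rate dropout probability in the last decoder block.
#' @param use_batchnorm add batch normalization after every convolution.
#' @param residual if TRUE (default) a branch predicts the correction to
#'   the linear-interpolation estimate of its target position, so an
#'   untrained model coincides with the linear baseline and training is
#'   spent on what linear interpolation gets wrong; FALSE predicts the
#'   slice directly.
#' @param channel_cap maximum channel width.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(image_shape, base_channels = 64, encoder_blocks = 8,
                      decoder_blocks = encoder_blocks - 1,
                      input_channels = 2, output_channels = 1,
                      dropout_rate = 0.5, use_batchnorm = TRUE,
                      residual = TRUE, channel_cap = 512) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 4L))
    stop("image_shape must be (height, width), both >= 4")
  if (decoder_blocks != encoder_blocks - 1)
    stop("decoder_blocks must equal encoder_blocks - 1")
  if (encoder_blocks < 2L) stop("encoder_blocks must be >= 2")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  # deepest usable level: every pre-pool extent even and >= 2 after pooling
  max_pools <- 0L
  h <- image_shape[1]; w <- image_shape[2]
  while (h %% 2L == 0L && w %% 2L == 0L && h >= 4L && w >= 4L &&
         max_pools < encoder_blocks - 1L) {
    h <- h %/% 2L; w <- w %/% 2L
    max_pools <- max_pools + 1L
  }
  levels <- max_pools + 1L
  if (levels < 2L)
    stop("image_shape not reconcilable with any downsampling depth")
  structure(list(image_shape = image_shape,
                 base_channels = as.integer(base_channels),
                 encoder_blocks = as.integer(encoder_blocks),
                 decoder_blocks = as.integer(decoder_blocks),
                 levels = levels,
                 input_channels = as.integer(input_channels),
                 output_channels = as.integer(output_channels),
                 dropout_rate = dropout_rate,
                 use_batchnorm = isTRUE(use_batchnorm),
                 residual = isTRUE(residual),
                 channel_cap = as.integer(channel_cap)),
            class = "unet_spec")
}

unet_channels <- function(spec) {
  pmin(spec$base_channels * 2^(seq_len(spec$levels) - 1L), spec$channel_cap)
}

#' Build a U-net with seeded initial parameters
#'
#' @param spec a [unet_spec()].
#' @param seed integer seed fixing the parameter initialisation.
#' @return An object of class `unet` holding the layer parameters.
#' @export
build_unet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  set.seed(seed)
  ch <- unet_channels(spec)
  L <- spec$levels
  bn <- spec$use_batchnorm
  layers <- list()
  cin <- spec$input_channels
  for (i in seq_len(L - 1L)) {
    layers[[sprintf("enc%d_a", i)]] <- nn_conv_layer(cin, ch[i], bn)
    layers[[sprintf("enc%d_b", i)]] <- nn_conv_layer(ch[i], ch[i], bn)
    cin <- ch[i]
  }
  layers$bot_a <- nn_conv_layer(cin, ch[L], bn)
  layers$bot_b <- nn_conv_layer(ch[L], ch[L], bn)
  for (i in rev(seq_len(L - 1L))) {
    layers[[sprintf("dec%d_a", i)]] <- nn_conv_layer(ch[i] + ch[i + 1L],
                                                     ch[i], bn)
    layers[[sprintf("dec%d_b", i)]] <- nn_conv_layer(ch[i], ch[i], bn)
  }
  layers$final <- nn_dense_layer(ch[1], spec$output_channels)
  structure(list(spec = spec, layers = layers, seed = as.integer(seed)),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<unet> %dx%d, %d levels (requested %d enc/%d dec), base %d ch, %d -> %d ch\n",
    s$image_shape[1], s$image_shape[2], s$levels, s$encoder_blocks,
    s$decoder_blocks, s$base_channels, s$input_channels, s$output_channels))
  invisible(x)
}

# Forward pass. X: (N*H*W) x input_channels matrix. Returns list(out=,
# net=, caches=) where net carries updated BN running stats; caches is
# NULL unless train = TRUE.
unet_forward <- function(net, X, N, train = FALSE) {
  spec <- net$spec
  bn <- spec$use_batchnorm
  L <- spec$levels
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  layers <- net$layers
  caches <- list()
  skips <- list()
  dims <- list()
  for (i in seq_len(L - 1L)) {
    for (s in c("a", "b")) {
      nm <- sprintf("enc%d_%s", i, s)
      r <- conv_bn_relu_forward(X, layers[[nm]], N, H, W, train, bn)
      X <- r$out; layers[[nm]] <- r$layer; caches[[nm]] <- r$cache
    }
    skips[[i]] <- X
    dims[[i]] <- c(H, W)
    mp <- maxpool2x2_forward(X, N, H, W)
    X <- mp$Y
    caches[[sprintf("pool%d", i)]] <- list(argmax = mp$argmax,
                                           n_rows = N * H * W)
    H <- H %/% 2L; W <- W %/% 2L
  }
  for (nm in c("bot_a", "bot_b")) {
    r <- conv_bn_relu_forward(X, layers[[nm]], N, H, W, train, bn)
    X <- r$out; layers[[nm]] <- r$layer; caches[[nm]] <- r$cache
  }
  for (i in rev(seq_len(L - 1L))) {
    idx <- upsample_index(N, H, W)
    X <- X[idx, , drop = FALSE]
    H <- 2L * H; W <- 2L * W
    caches[[sprintf("up%d", i)]] <- list(idx = idx)
    n_up <- ncol(X)
    X <- cbind(X, skips[[i]])
    caches[[sprintf("cat%d", i)]] <- list(n_up = n_up)
    for (s in c("a", "b")) {
      nm <- sprintf("dec%d_%s", i, s)
      r <- conv_bn_relu_forward(X, layers[[nm]], N, H, W, train, bn)
      X <- r$out; layers[[nm]] <- r$layer; caches[[nm]] <- r$cache
    }
    if (i == 1L && train && spec$dropout_rate > 0) {
      keep <- (runif(length(X)) >= spec$dropout_rate) /
        (1 - spec$dropout_rate)
      dim(keep) <- dim(X)
      X <- X * keep
      caches$dropout <- list(mask = keep)
    }
  }
  caches$final_in <- X
  out <- X %*% layers$final$W
  out <- sweep(out, 2, layers$final$b, "+")
  net$layers <- layers
  list(out = out, net = net, caches = if (train) caches else NULL)
}

# Backward pass; returns per-layer gradients (named like net$layers).
# Traverses the decoder shallow-to-deep, then the bottleneck, then the
# encoder deep-to-shallow, mirroring unet_forward exactly.
unet_backward <- function(net, caches, dOut) {
  spec <- net$spec
  bn <- spec$use_batchnorm
  L <- spec$levels
  layers <- net$layers
  grads <- list()
  Xf <- caches$final_in
  grads$final <- list(dW = crossprod(Xf, dOut), db = colSums(dOut))
  dX <- dOut %*% t(layers$final$W)
  if (!is.null(caches$dropout)) dX <- dX * caches$dropout$mask
  d_skips <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {           # decoder: shallow to deep
    for (s in c("b", "a")) {
      nm <- sprintf("dec%d_%s", i, s)
      g <- conv_bn_relu_backward(dX, layers[[nm]], caches[[nm]], bn)
      dX <- g$dX; g$dX <- NULL; grads[[nm]] <- g
    }
    n_up <- caches[[sprintf("cat%d", i)]]$n_up
    d_skips[[i]] <- dX[, -seq_len(n_up), drop = FALSE]
    idx <- caches[[sprintf("up%d", i)]]$idx
    dX <- rowsum(dX[, seq_len(n_up), drop = FALSE], group = idx,
                 reorder = TRUE)
  }
  for (nm in c("bot_b", "bot_a")) {
    g <- conv_bn_relu_backward(dX, layers[[nm]], caches[[nm]], bn)
    dX <- g$dX; g$dX <- NULL; grads[[nm]] <- g
  }
  for (i in rev(seq_len(L - 1L))) {      # encoder: deep to shallow
    pl <- caches[[sprintf("pool%d", i)]]
    dX <- maxpool2x2_backward(dX, pl$argmax, pl$n_rows) + d_skips[[i]]
    for (s in c("b", "a")) {
      nm <- sprintf("enc%d_%s", i, s)
      g <- conv_bn_relu_backward(dX, layers[[nm]], caches[[nm]], bn)
      dX <- g$dX; g$dX <- NULL; grads[[nm]] <- g
    }
  }
  grads
}
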