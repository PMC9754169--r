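# Minimal CNN engine for 2-D image-to-image regression. Activations are
# (N*H*W) x C matrices; each image slab is the column-major vectorisation
# of an H x W slice (matching R's array layout), so reshaping between
# slice matrices and activation rows is a plain dim<- change. The 3x3
# convolution and 2x2 max-pool kernels live in src/conv_ops.cpp; batch
# norm, ReLU, dropout, nearest-neighbour upsampling and Adam are R-level
# matrix operations. All randomness (init, shuffling, dropout) draws from
# R's RNG so seeded runs are bit-reproducible.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

nn_conv_layer <- function(c_in, c_out, use_batchnorm) {
  # He-normal fan-in init for 3x3 kernels
  w <- matrix(rnorm(9 * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
              nrow = 9 * c_in, ncol = c_out)
  l <- list(W = w, b = rep(0, c_out))
  if (use_batchnorm) {
    l$gamma <- rep(1, c_out)
    l$beta <- rep(0, c_out)
    l$run_mean <- rep(0, c_out)
    l$run_var <- rep(1, c_out)
  }
  l
}

# Final 1x1 projection starts at zero so the network's initial output is
# the residual anchor itself (exactly the linear estimate when the spec's
# residual parameterization is on); gradients flow from step one.
nn_dense_layer <- function(c_in, c_out) {
  list(W = matrix(0, nrow = c_in, ncol = c_out),
       b = rep(0, c_out))
}

# Conv -> (BN) -> ReLU. Returns new activations, an updated layer (running
# BN stats) and, when training, the cache needed for backward.
conv_bn_relu_forward <- function(X, layer, N, H, W, train, use_bn) {
  Y <- conv3x3_forward(X, layer$W, layer$b, N, H, W)
  cache <- list(X = X, N = N, H = H, W = W)
  if (use_bn) {
    if (train) {
      mu <- colMeans(Y)
      v <- colMeans(Y * Y) - mu^2
      v[v < 0] <- 0
      layer$run_mean <- (1 - .bn_momentum) * layer$run_mean + .bn_momentum * mu
      layer$run_var <- (1 - .bn_momentum) * layer$run_var + .bn_momentum * v
    } else {
      mu <- layer$run_mean
      v <- layer$run_var
    }
    inv_sd <- 1 / sqrt(v + .bn_eps)
    xhat <- colscale_add(Y, inv_sd, -mu * inv_sd)
    Y <- colscale_add(xhat, layer$gamma, layer$beta)
    if (train) {
      cache$xhat <- xhat
      cache$inv_sd <- inv_sd
    }
  }
  mask <- Y > 0
  Z <- Y * mask
  if (train) cache$relu_mask <- mask
  list(out = Z, layer = layer, cache = if (train) cache else NULL)
}

conv_bn_relu_backward <- function(dZ, layer, cache, use_bn) {
  dY <- dZ * cache$relu_mask
  grads <- list()
  if (use_bn) {
    xhat <- cache$xhat
    grads$dgamma <- colSums(dY * xhat)
    grads$dbeta <- colSums(dY)
    # population-variance batch norm backward
    dxhat <- colscale_add(dY, layer$gamma, numeric(ncol(dY)))
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dY <- bn_backward_input(dxhat, xhat, m1, m2, cache$inv_sd)
  }
  cb <- conv3x3_backward(cache$X, layer$W, dY, cache$N, cache$H, cache$W)
  grads$dW <- cb$dW
  grads$db <- as.numeric(cb$db)
  grads$dX <- cb$dX
  grads
}

# Row-gather index that doubles spatial resolution by nearest neighbour.
upsample_index <- function(N, H, W) {
  Hb <- 2L * H; Wb <- 2L * W
  ys <- rep.int((0:(Hb - 1L)) %/% 2L, Wb)
  xs <- rep((0:(Wb - 1L)) %/% 2L, each = Hb)
  per_img <- xs * H + ys + 1L
  if (N == 1L) return(per_img)
  offs <- rep((0:(N - 1L)) * H * W, each = length(per_img))
  rep.int(per_img, N) + offs
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    s <- list()
    for (nm in intersect(names(l), c("W", "b", "gamma", "beta")))
      s[[nm]] <- list(m = l[[nm]] * 0, v = l[[nm]] * 0)
    s
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (ln in names(grads)) {
    g <- grads[[ln]]
    map <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
    for (pn in names(map)) {
      gn <- map[[pn]]
      if (is.null(g[[gn]])) next
      st <- state[[ln]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[gn]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[gn]]^2
      layers[[ln]][[pn]] <- layers[[ln]][[pn]] -
        lr * (st$m / c1) / (sqrt(st$v / c2) + eps)
      state[[ln]][[pn]] <- st
    }
  }
  list(layers = layers, state = state)
}
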