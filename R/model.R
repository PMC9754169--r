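# The parallel architecture: 2m-1 independently parameterized U-nets that
# share the same two-neighbour input, branch k predicting the k-th target
# position of the gap. Branch independence is structural — branches never
# exchange activations, gradients or parameters — so one reconstructed
# slice cannot influence another. A single-network multi-output variant
# (one U-net emitting all 2m-1 slices) is provided as a comparator.

#' Training configuration
#'
#' @param loss `"mae"` (default; matches the intensity criterion used for
#'   evaluation) or `"mse"`.
#' @param optimizer only `"adam"` is implemented.
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed integer; fixes initialisation order, shuffling and dropout.
#' @param val_fraction fraction of training gaps held out for the
#'   per-epoch validation MAE in the history.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = c("mae", "mse"), optimizer = "adam",
                         lr = 1e-4, epochs = 20, batch_size = 8,
                         seed = 1L, val_fraction = 0.1) {
  loss <- match.arg(loss)
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  structure(list(loss = loss, optimizer = optimizer, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), val_fraction = val_fraction),
            class = "train_config")
}

#' Build the parallel multi-branch model
#'
#' @param spec a [unet_spec()] with `output_channels = 1`.
#' @param targets_per_gap number of branches, `2m - 1` (>= 1).
#' @param seed integer; branch k is initialised with `seed + k` so branch
#'   parameters are independent yet reproducible.
#' @return An object of class `parallel_unet`.
#' @export
build_parallel <- function(spec, targets_per_gap, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  targets_per_gap <- as.integer(targets_per_gap)
  if (targets_per_gap < 1L) stop("targets_per_gap must be >= 1")
  if (spec$output_channels != 1L)
    spec$output_channels <- 1L
  branches <- lapply(seq_len(targets_per_gap), function(k)
    build_unet(spec, seed = seed + k))
  structure(list(spec = spec, branches = branches,
                 targets_per_gap = targets_per_gap, seed = as.integer(seed)),
            class = "parallel_unet")
}

#' Build the single-network multi-output comparator
#'
#' One U-net emitting all `2m - 1` target slices as output channels.
#'
#' @inheritParams build_parallel
#' @return An object of class `single_unet`.
#' @export
build_multiout <- function(spec, targets_per_gap, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  targets_per_gap <- as.integer(targets_per_gap)
  if (targets_per_gap < 1L) stop("targets_per_gap must be >= 1")
  spec$output_channels <- targets_per_gap
  structure(list(spec = spec, net = build_unet(spec, seed = seed + 1L),
                 targets_per_gap = targets_per_gap, seed = as.integer(seed)),
            class = "single_unet")
}

# Training examples: list of list(input = H x W x 2, target = H x W x t).
# B holds the linear-interpolation anchor for every target position (used
# when the spec's residual parameterization is on).
as_example_matrices <- function(ex, hw, t) {
  inp <- ex$input
  tg <- ex$target
  if (length(dim(tg)) == 2L) tg <- array(tg, dim = c(dim(tg), 1L))
  X <- matrix(inp, nrow = hw)
  fr <- fraction_schedule(t)
  B <- vapply(fr, function(f) (1 - f) * X[, 1] + f * X[, 2],
              numeric(hw))
  list(X = X, Y = matrix(tg, nrow = hw), B = B)
}

loss_grad <- function(pred, target, loss) {
  d <- pred - target
  if (loss == "mae") {
    list(value = mean(abs(d)), grad = sign(d) / length(d))
  } else {
    list(value = mean(d * d), grad = 2 * d / length(d))
  }
}

# Train one U-net on (X, Y-channel-subset) examples. Returns net + history.
train_one_net <- function(net, examples, target_cols, cfg, val_idx,
                          branch_tag, targets_per_gap = max(target_cols)) {
  hw <- prod(net$spec$image_shape)
  residual <- isTRUE(net$spec$residual)
  mats <- lapply(examples, as_example_matrices, hw = hw,
                 t = targets_per_gap)
  train_idx <- setdiff(seq_along(mats), val_idx)
  if (length(train_idx) == 0L) stop("no training examples left after split")
  state <- adam_init(net$layers)
  tstep <- 0L
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- train_idx[sample.int(length(train_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      N <- length(bt)
      X <- do.call(rbind, lapply(mats[bt], `[[`, "X"))
      Y <- do.call(rbind, lapply(mats[bt], function(m)
        m$Y[, target_cols, drop = FALSE]))
      if (residual)
        Y <- Y - do.call(rbind, lapply(mats[bt], function(m)
          m$B[, target_cols, drop = FALSE]))
      fw <- unet_forward(net, X, N, train = TRUE)
      net <- fw$net
      lg <- loss_grad(fw$out, Y, cfg$loss)
      ep_loss <- ep_loss + lg$value * N
      grads <- unet_backward(net, fw$caches, lg$grad)
      tstep <- tstep + 1L
      upd <- adam_step(net$layers, grads, state, cfg$lr, tstep)
      net$layers <- upd$layers
      state <- upd$state
    }
    val_mae <- NA_real_
    if (length(val_idx) > 0L) {
      err <- 0; nv <- 0
      for (vi in val_idx) {
        fw <- unet_forward(net, mats[[vi]]$X, 1L, train = FALSE)
        pred <- fw$out
        if (residual)
          pred <- pred + mats[[vi]]$B[, target_cols, drop = FALSE]
        pred <- pmin(pmax(pred, 0), 1)
        err <- err + mean(abs(pred - mats[[vi]]$Y[, target_cols, drop = FALSE]))
        nv <- nv + 1
      }
      val_mae <- err / nv
    }
    hist[[ep]] <- data.frame(branch = branch_tag, epoch = ep,
                             train_loss = ep_loss / length(train_idx),
                             val_mae = val_mae)
  }
  list(net = net, history = do.call(rbind, hist))
}

#' Train a slice-reconstruction model
#'
#' For the parallel model each branch is trained only on its own target
#' position, with a branch-specific RNG stream derived from `cfg$seed`, so
#' training a branch alone is identical to training it inside the parallel
#' run. For the single multi-output variant the one network is trained on
#' all target positions jointly.
#'
#' @param model a `parallel_unet` or `single_unet`.
#' @param examples list of training gaps, each
#'   `list(input = H x W x 2 array, target = H x W x t array)` where the
#'   two input channels are the left and right neighbour slices and the
#'   target array holds all `t = 2m - 1` intermediate slices in order.
#' @param cfg a [train_config()].
#' @return `list(model =, history =)`; `history` has one row per branch
#'   and epoch with the training loss and held-out validation MAE
#'   (normalized units).
#' @export
train_parallel <- function(model, examples, cfg = train_config()) {
  t <- model$targets_per_gap
  bad <- vapply(examples, function(e) {
    tg <- e$target
    nt <- if (length(dim(tg)) == 2L) 1L else dim(tg)[3]
    nt != t
  }, logical(1))
  if (any(bad))
    stop("every example must supply all ", t, " target positions")
  set.seed(cfg$seed)
  n_val <- floor(cfg$val_fraction * length(examples))
  val_idx <- if (n_val > 0) sort(sample.int(length(examples), n_val))
             else integer(0)
  if (inherits(model, "parallel_unet")) {
    hists <- vector("list", t)
    for (k in seq_len(t)) {
      set.seed(cfg$seed + 7919L * k)
      r <- train_one_net(model$branches[[k]], examples, k, cfg, val_idx,
                         branch_tag = k, targets_per_gap = t)
      model$branches[[k]] <- r$net
      hists[[k]] <- r$history
    }
    list(model = model, history = do.call(rbind, hists))
  } else if (inherits(model, "single_unet")) {
    set.seed(cfg$seed + 7919L)
    r <- train_one_net(model$net, examples, seq_len(t), cfg, val_idx,
                       branch_tag = 0L, targets_per_gap = t)
    model$net <- r$net
    list(model = model, history = r$history)
  } else stop("model must be a parallel_unet or single_unet")
}

#' Predict the intermediate slices for one neighbour pair
#'
#' @param model a trained `parallel_unet` or `single_unet`.
#' @param left,right neighbour slice matrices matching the spec's
#'   `image_shape`, values in [0, 1].
#' @return H x W x (2m-1) array; position k is branch k's prediction,
#'   clamped to [0, 1].
#' @export
predict_slices <- function(model, left, right) {
  hw_shape <- model$spec$image_shape
  if (!all(dim(left) == hw_shape) || !all(dim(right) == hw_shape))
    stop("slice shape does not match the model's image_shape")
  X <- cbind(as.vector(left), as.vector(right))
  t <- model$targets_per_gap
  residual <- isTRUE(model$spec$residual)
  fr <- fraction_schedule(t)
  anchor <- function(k) (1 - fr[k]) * X[, 1] + fr[k] * X[, 2]
  out <- array(0, dim = c(hw_shape, t))
  if (inherits(model, "parallel_unet")) {
    for (k in seq_len(t)) {
      fw <- unet_forward(model$branches[[k]], X, 1L, train = FALSE)
      y <- fw$out[, 1]
      if (residual) y <- y + anchor(k)
      out[, , k] <- matrix(pmin(pmax(y, 0), 1), nrow = hw_shape[1])
    }
  } else {
    fw <- unet_forward(model$net, X, 1L, train = FALSE)
    for (k in seq_len(t)) {
      y <- fw$out[, k]
      if (residual) y <- y + anchor(k)
      out[, , k] <- matrix(pmin(pmax(y, 0), 1), nrow = hw_shape[1])
    }
  }
  out
}

#' Reconstruct all gaps of a sparse stack with a trained model
#'
#' @param model a trained model accepted by [predict_slices()].
#' @param sparse H x W x K array of sparse slices.
#' @return list of K-1 arrays (one per gap), as [reconstruct_linear()].
#' @export
reconstruct_model <- function(model, sparse) {
  lapply(neighbor_pairs(sparse), function(p)
    predict_slices(model, p$left, p$right))
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the spec, seed and all parameters; the range-clip
#' parameters of an organ model travel alongside in the bundle manifest.
#'
#' @param model a model object.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
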