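# Structural similarity (SSIM), Wang et al. formulation: local means,
# variances and covariance under a Gaussian window (sigma 1.5, 11 taps),
# population covariance, stabilisation constants C1 = (K1 R)^2,
# C2 = (K2 R)^2, and a border crop of the filter radius. The arithmetic
# matches scikit-image's structural_similarity with gaussian_weights=TRUE
# to well below 1e-6, which the test suite uses as an independent
# cross-check.

# Separable Gaussian blur with symmetric ("reflect including edge")
# padding, kernel sampled at integers -r..r and normalized.
gaussian_blur <- function(img, sigma, r) {
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad_idx <- function(n) c(r:1, 1:n, n:(n - r + 1))
  p <- img[pad_idx(h), pad_idx(w)]
  # rows
  out <- matrix(0, h, w + 2 * r)
  for (i in -r:r)
    out <- out + k[i + r + 1] * p[(1 + r + i):(h + r + i), ]
  # cols
  res <- matrix(0, h, w)
  for (j in -r:r)
    res <- res + k[j + r + 1] * out[, (1 + r + j):(w + r + j)]
  res
}

#' Per-slice SSIM with independent intensity normalization
#'
#' Each slice is first normalized on its own (min-max by default, z-score
#' or none as alternatives), then the standard SSIM with a Gaussian window
#' is computed; the reported value is the mean of the SSIM map with the
#' filter-radius border cropped. With a mask, the mean is taken over the
#' masked voxels inside the cropped region instead.
#'
#' A slice with zero dynamic range cannot be min-max normalized; in that
#' case the SSIM of the unnormalized pair is returned (with a message).
#'
#' @param pred,true matrices of identical shape.
#' @param mask optional logical matrix; average the SSIM map over it.
#' @param normalize `"minmax"` (default), `"zscore"` or `"none"`.
#' @param sigma Gaussian window standard deviation (1.5).
#' @param win_size odd window size; default `2 * round(3.5 * sigma) + 1`
#'   (11 at the default sigma).
#' @param data_range dynamic range R of the (normalized) inputs; 1 for
#'   min-max, estimated from the data otherwise.
#' @param K1,K2 stabilisation constants (0.01, 0.03).
#' @return SSIM value in [-1, 1].
#' @export
ssim_slice <- function(pred, true, mask = NULL,
                       normalize = c("minmax", "zscore", "none"),
                       sigma = 1.5, win_size = NULL, data_range = NULL,
                       K1 = 0.01, K2 = 0.03) {
  normalize <- match.arg(normalize)
  if (!all(dim(pred) == dim(true))) stop("slice shapes differ")
  if (normalize == "minmax") {
    rp <- range(pred); rt <- range(true)
    if (diff(rp) == 0 || diff(rt) == 0) {
      message("zero dynamic range; SSIM computed on the unnormalized pair")
      dr <- diff(range(c(pred, true)))
      if (dr == 0) return(1)
      normalize <- "none"
      if (is.null(data_range)) data_range <- dr
    } else {
      pred <- (pred - rp[1]) / diff(rp)
      true <- (true - rt[1]) / diff(rt)
      if (is.null(data_range)) data_range <- 1
    }
  } else if (normalize == "zscore") {
    if (sd(pred) == 0 || sd(true) == 0)
      stop("zero dynamic range; z-score normalization undefined")
    pred <- (pred - mean(pred)) / sd(pred)
    true <- (true - mean(true)) / sd(true)
    if (is.null(data_range)) data_range <- diff(range(c(pred, true)))
  } else if (is.null(data_range)) {
    data_range <- 1
  }
  if (is.null(win_size)) {
    r <- as.integer(3.5 * sigma + 0.5)
  } else {
    if (win_size %% 2 != 1) stop("win_size must be odd")
    r <- (as.integer(win_size) - 1L) %/% 2L
  }
  if (min(dim(pred)) < 2 * r + 1)
    stop("window exceeds image extent; reduce win_size")
  ux <- gaussian_blur(pred, sigma, r)
  uy <- gaussian_blur(true, sigma, r)
  uxx <- gaussian_blur(pred * pred, sigma, r)
  uyy <- gaussian_blur(true * true, sigma, r)
  uxy <- gaussian_blur(pred * true, sigma, r)
  vx <- uxx - ux * ux
  vy <- uyy - uy * uy
  vxy <- uxy - ux * uy
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  h <- nrow(S); w <- ncol(S)
  keep_r <- (r + 1):(h - r)
  keep_c <- (r + 1):(w - r)
  S <- S[keep_r, keep_c]
  if (is.null(mask)) return(mean(S))
  mk <- mask[keep_r, keep_c]
  if (!any(mk)) stop("mask empty inside the cropped SSIM region")
  mean(S[mk])
}
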