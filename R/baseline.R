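# Linear interpolation reference reconstructor. For equally spaced dense
# slices the k-th of the 2m-1 targets between a neighbor pair sits at
# fraction k / (2m) of the gap, so its linear estimate is the convex
# combination of the two originals at that weight.

#' Interpolation weights for one gap
#'
#' @param targets_per_gap number of targets, `2m - 1`.
#' @return fractions `k / (2m)` for `k = 1 .. 2m - 1`.
#' @export
fraction_schedule <- function(targets_per_gap) {
  targets_per_gap <- as.integer(targets_per_gap)
  if (targets_per_gap < 1L) stop("targets_per_gap must be >= 1")
  seq_len(targets_per_gap) / (targets_per_gap + 1L)
}

#' Linearly interpolate between two slices
#'
#' Voxelwise `(1 - fraction) * left + fraction * right`.
#'
#' @param left,right matrices of identical shape.
#' @param fraction weight in [0, 1] (0 gives `left`, 1 gives `right`).
#' @return interpolated matrix.
#' @export
linear_interpolate <- function(left, right, fraction) {
  if (!all(dim(left) == dim(right))) stop("slice shapes differ")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  (1 - fraction) * left + fraction * right
}

#' Linear-interpolation reconstruction of all gaps
#'
#' @param sparse H x W x K array of sparse slices.
#' @param targets_per_gap number of slices to synthesize per gap.
#' @return list of K-1 arrays, each H x W x targets_per_gap, ready for
#'   [merge_reconstruction()].
#' @export
reconstruct_linear <- function(sparse, targets_per_gap) {
  fr <- fraction_schedule(targets_per_gap)
  pairs <- neighbor_pairs(sparse)
  lapply(pairs, function(p) {
    out <- array(0, dim = c(dim(p$left), length(fr)))
    for (k in seq_along(fr))
      out[, , k] <- linear_interpolate(p$left, p$right, fr[k])
    out
  })
}
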