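# Sparse/target slice bookkeeping. For an interpolation factor m (a
# multiple of 0.5 with 2m an integer step), the dense slices S_1..S_n are
# separated into a sparse subset at positions 1, 1+2m, 1+4m, ... and the
# target subset of all slices strictly between consecutive sparse slices;
# each gap holds exactly 2m-1 targets. Trailing slices that do not complete
# a final gap belong to neither group and are reported as excluded.

#' Build the sparse/target slice grouping
#'
#' @param n_dense total number of dense slices (>= 2m + 1).
#' @param targets_per_gap number of slices to synthesize per gap, `2m - 1`.
#'   Supply either this or `m`.
#' @param m interpolation half-gap factor; multiples of 0.5 so that
#'   `2m - 1` is a positive integer. Values with `2m - 1` in 1..5 are the
#'   validated range; larger values are accepted with a warning.
#' @return A `slice_grouping`: `m`, `step` (= 2m), `targets_per_gap`,
#'   `n_dense`, `sparse_indices` (1-based), `gaps` (list of
#'   `left`/`right`/`targets`), and `excluded` trailing indices.
#' @export
slice_grouping <- function(n_dense, targets_per_gap = NULL, m = NULL) {
  if (is.null(targets_per_gap)) {
    if (is.null(m)) stop("supply targets_per_gap or m")
    if (abs(2 * m - round(2 * m)) > 1e-9 || m <= 0.5)
      stop("m must be a multiple of 0.5 greater than 0.5")
    targets_per_gap <- as.integer(round(2 * m)) - 1L
  }
  targets_per_gap <- as.integer(targets_per_gap)
  if (targets_per_gap < 1L) stop("targets_per_gap must be >= 1")
  if (targets_per_gap > 5L)
    warning("targets_per_gap > 5 is outside the validated range")
  step <- targets_per_gap + 1L            # = 2m
  m_val <- step / 2
  n_dense <- as.integer(n_dense)
  if (n_dense < step + 1L)
    stop(sprintf("n_dense must be >= %d for targets_per_gap = %d",
                 step + 1L, targets_per_gap))
  sparse <- seq(1L, n_dense, by = step)
  k <- length(sparse)
  last <- sparse[k]
  excluded <- if (last < n_dense) seq(last + 1L, n_dense) else integer(0)
  gaps <- lapply(seq_len(k - 1L), function(j) {
    left <- sparse[j]; right <- sparse[j + 1L]
    list(left = left, right = right,
         targets = seq(left + 1L, right - 1L))
  })
  structure(list(m = m_val, step = step, targets_per_gap = targets_per_gap,
                 n_dense = n_dense, sparse_indices = sparse, gaps = gaps,
                 excluded = excluded),
            class = "slice_grouping")
}

#' @export
print.slice_grouping <- function(x, ...) {
  cat(sprintf("<slice_grouping> m = %g (%d targets/gap), %d dense slices\n",
              x$m, x$targets_per_gap, x$n_dense))
  cat("  sparse:", paste(x$sparse_indices, collapse = " "), "\n")
  if (length(x$excluded))
    cat("  excluded trailing:", paste(x$excluded, collapse = " "), "\n")
  invisible(x)
}

#' Export a grouping summary as JSON
#'
#' @param g a [slice_grouping()].
#' @param path optional file; if `NULL` the JSON string is returned.
#' @export
grouping_json <- function(g, path = NULL) {
  stopifnot(inherits(g, "slice_grouping"))
  j <- jsonlite::toJSON(list(m = g$m, targets_per_gap = g$targets_per_gap,
                             n_dense = g$n_dense,
                             sparse_indices = g$sparse_indices,
                             excluded = g$excluded),
                        auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}

# Extract the slice stack of a volume as an array with slices on axis 3,
# regardless of the volume's stored slice axis.
slice_stack <- function(vol) {
  a <- if (is.list(vol)) vol$voxels else vol
  ax <- if (is.list(vol)) vol$slice_axis else 3L
  if (ax != 3L) a <- aperm(a, c(setdiff(1:3, ax), ax))
  a
}

#' Split a dense volume into sparse and target stacks
#'
#' @param vol a [normalized_volume()] (or plain 3-D array with slices on
#'   axis 3).
#' @param g a [slice_grouping()].
#' @return list with `sparse` (H x W x K array) and `target`
#'   (H x W x total-targets array), slices in index order.
#' @export
split_volume <- function(vol, g) {
  stopifnot(inherits(g, "slice_grouping"))
  a <- slice_stack(vol)
  if (dim(a)[3] < max(g$sparse_indices))
    stop("grouping exceeds volume extent")
  tidx <- unlist(lapply(g$gaps, `[[`, "targets"))
  list(sparse = a[, , g$sparse_indices, drop = FALSE],
       target = a[, , tidx, drop = FALSE])
}

#' Consecutive neighbor pairs of a sparse stack
#'
#' @param sparse H x W x K array of sparse slices (K >= 2).
#' @return list of `K - 1` elements, each `list(left =, right =)` matrices.
#' @export
neighbor_pairs <- function(sparse) {
  k <- dim(sparse)[3]
  if (is.na(k) || k < 2) stop("need at least 2 sparse slices")
  lapply(seq_len(k - 1), function(j)
    list(left = sparse[, , j], right = sparse[, , j + 1]))
}

#' Merge reconstructed gap stacks with the original sparse slices
#'
#' The originals are copied unchanged into their sparse positions; each
#' gap's reconstructed slices fill the target positions between them. With
#' K sparse slices and t targets per gap the output has `K + (K-1) t`
#' slices.
#'
#' @param sparse H x W x K array of original sparse slices.
#' @param recon list of K-1 arrays, each H x W x targets_per_gap.
#' @param g the [slice_grouping()] used to split.
#' @return H x W x (K + (K-1) t) array.
#' @export
merge_reconstruction <- function(sparse, recon, g) {
  stopifnot(inherits(g, "slice_grouping"))
  k <- dim(sparse)[3]
  if (length(recon) != k - 1)
    stop("need one reconstructed stack per gap (", k - 1, "), got ",
         length(recon))
  t <- g$targets_per_gap
  out <- array(0, dim = c(dim(sparse)[1:2], k + (k - 1L) * t))
  out[, , g$sparse_indices] <- sparse
  for (j in seq_len(k - 1)) {
    r <- recon[[j]]
    if (length(dim(r)) == 2L) r <- array(r, dim = c(dim(r), 1L))
    if (!all(dim(r) == c(dim(sparse)[1:2], t)))
      stop("gap ", j, ": reconstructed stack has wrong shape")
    out[, , g$gaps[[j]]$targets] <- r
  }
  out
}
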