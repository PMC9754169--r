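# Organ intensity range-clip. Soft organs occupy a narrow sub-range
# [R_ll, R_lh] of the normalized [0, 1] intensity scale. The transform
#   f(x) = 0            if x < R_ll
#          1            if x > R_lh
#          B (x - C)    if R_ll <= x <= R_lh
# with C = R_ll and B = 1 / (R_lh - R_ll) stretches the organ's range onto
# the full [0, 1] interval, concentrating the learning signal on in-organ
# contrast. f is lossy outside the organ range (everything clamps to 0 or
# 1), which is why organ-oriented reconstruction merges the inverse-
# transformed organ prediction into a base prediction rather than using it
# everywhere.

#' Estimate an organ's normalized intensity range from labeled data
#'
#' Pools all voxels carrying `code` across the training volumes and
#' returns trimmed empirical bounds. Percentile trimming stands in for
#' manual removal of foreign-object noise (tubes, staples) from the organ
#' histogram. For gas-containing organs (stomach), voxels darker than
#' `air_threshold` can be excluded first.
#'
#' @param volumes list of [normalized_volume()] (or arrays in [0, 1]).
#' @param labels list of matching [label_volume()] (or integer arrays).
#' @param code integer organ code to pool.
#' @param trim percentile pair, default `c(0.5, 99.5)`.
#' @param exclude_air if TRUE, drop voxels below `air_threshold` before
#'   computing the range.
#' @param air_threshold normalized air cutoff, default 0.25 (-500 HU under
#'   the [-1000, 1000] window).
#' @return numeric `c(R_ll, R_lh)`.
#' @export
estimate_range <- function(volumes, labels, code, trim = c(0.5, 99.5),
                           exclude_air = FALSE, air_threshold = 0.25) {
  if (!is.list(volumes) || inherits(volumes, "normalized_volume"))
    volumes <- list(volumes)
  if (!is.list(labels) || inherits(labels, "label_volume"))
    labels <- list(labels)
  stopifnot(length(volumes) == length(labels))
  if (trim[1] < 0 || trim[2] > 100 || trim[1] >= trim[2])
    stop("trim must be increasing percentiles within [0, 100]")
  vals <- unlist(lapply(seq_along(volumes), function(i) {
    v <- if (is.list(volumes[[i]])) volumes[[i]]$voxels else volumes[[i]]
    l <- if (is.list(labels[[i]])) labels[[i]]$codes else labels[[i]]
    if (!all(dim(v) == dim(l))) stop("volume/label shape mismatch")
    v[l == code]
  }))
  if (exclude_air) vals <- vals[vals >= air_threshold]
  if (length(vals) == 0L) stop("no voxels labeled with code ", code)
  as.numeric(quantile(vals, probs = trim / 100, names = FALSE, type = 7))
}

#' Fit range-clip parameters from an organ range
#'
#' Returns the unique affine map spanning [0, 1] over `[R_ll, R_lh]`:
#' `C = R_ll`, `B = 1 / (R_lh - R_ll)`.
#'
#' @param R_ll,R_lh normalized range bounds, `0 <= R_ll < R_lh <= 1`.
#' @param organ organ name carried for reporting.
#' @return An object of class `rangeclip_params` with fields `organ`,
#'   `R_ll`, `R_lh`, `C`, `B`.
#' @export
fit_rangeclip <- function(R_ll, R_lh, organ = "organ") {
  if (R_ll < 0 || R_lh > 1 || R_ll > R_lh)
    stop("need 0 <= R_ll <= R_lh <= 1")
  if (R_lh - R_ll <= 0)
    stop("zero-width organ range; cannot fit range-clip parameters")
  structure(list(organ = organ, R_ll = R_ll, R_lh = R_lh,
                 C = R_ll, B = 1 / (R_lh - R_ll)),
            class = "rangeclip_params")
}

#' Assemble range-clip parameters from published-style (C, B) constants
#'
#' The inverse of [fit_rangeclip()]: the implied range is
#' `[C, C + 1/B]`.
#'
#' @param C offset constant (= R_ll).
#' @param B gain constant (= 1 / range width), must be positive.
#' @param organ organ name.
#' @export
rangeclip_from_cb <- function(C, B, organ = "organ") {
  if (B <= 0) stop("B must be positive")
  fit_rangeclip(C, C + 1 / B, organ = organ)
}

#' @export
print.rangeclip_params <- function(x, ...) {
  cat(sprintf("<rangeclip_params> %s: [%0.4f, %0.4f] -> C = %0.4f, B = %0.4f\n",
              x$organ, x$R_ll, x$R_lh, x$C, x$B))
  invisible(x)
}

#' Apply the range-clip transform f
#'
#' @param x numeric array/matrix/vector of normalized intensities in
#'   [0, 1], or a [normalized_volume()].
#' @param p a `rangeclip_params`.
#' @return object of the same shape with f applied voxelwise.
#' @export
apply_rangeclip <- function(x, p) {
  stopifnot(inherits(p, "rangeclip_params"))
  if (inherits(x, "normalized_volume")) {
    x$voxels <- apply_rangeclip(x$voxels, p)
    return(x)
  }
  y <- p$B * (x - p$C)
  y[x < p$R_ll] <- 0
  y[x > p$R_lh] <- 1
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}

#' Apply the inverse transform f^-1
#'
#' `y -> y / B + C`; composed with [apply_rangeclip()] it is the identity
#' on `[R_ll, R_lh]` (values outside the organ range cannot be recovered —
#' the transform clamps them).
#'
#' @inheritParams apply_rangeclip
#' @export
apply_rangeclip_inverse <- function(x, p) {
  stopifnot(inherits(p, "rangeclip_params"))
  if (inherits(x, "normalized_volume")) {
    x$voxels <- apply_rangeclip_inverse(x$voxels, p)
    return(x)
  }
  x / p$B + p$C
}

#' Mark air voxels
#'
#' @param x normalized intensities (array or [normalized_volume()]).
#' @param threshold normalized cutoff in [0, 1]; default 0.25, i.e. -500
#'   HU under the fixed [-1000, 1000] window.
#' @return logical mask, TRUE where the voxel is air.
#' @export
air_mask <- function(x, threshold = 0.25) {
  if (inherits(x, "normalized_volume")) x <- x$voxels
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  x < threshold
}

#' Serialize range-clip parameters to / from JSON
#'
#' @param p a `rangeclip_params` (or named list of them).
#' @param path output file.
#' @export
rangeclip_to_json <- function(p, path) {
  if (inherits(p, "rangeclip_params")) p <- list(p)
  jsonlite::write_json(lapply(p, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname rangeclip_to_json
#' @export
rangeclip_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(raw)), function(i)
    structure(as.list(raw[i, ]), class = "rangeclip_params"))
  names(out) <- vapply(out, `[[`, "", "organ")
  out
}
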