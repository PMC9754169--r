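#' CT volume container
#'
#' A 3-D scalar grid of CT intensities in Hounsfield units (HU) together
#' with its voxel spacing and the index of the longitudinal (through-plane)
#' axis, the axis along which slices are reconstructed. By default the
#' longitudinal axis is the axis with the largest voxel spacing, the usual
#' situation for anisotropic abdominal CT.
#'
#' @param voxels 3-D numeric array of intensities in HU.
#' @param spacing numeric length-3, voxel spacing in mm along each array
#'   dimension; all components must be strictly positive.
#' @param slice_axis integer in 1..3; defaults to `which.max(spacing)`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), slice_axis = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  if (is.null(slice_axis)) slice_axis <- which.max(spacing)
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  if (dim(voxels)[slice_axis] < 2L)
    stop("volume must have at least 2 slices along the longitudinal axis")
  structure(list(voxels = voxels, spacing = spacing, slice_axis = slice_axis),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, slice axis %d\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 5), collapse = " x "),
              x$slice_axis))
  invisible(x)
}

#' Normalized intensity volume
#'
#' A volume whose voxels lie in the dimensionless range [0, 1], obtained by
#' an affine map from an HU window recorded in `window` so the map can be
#' inverted exactly.
#'
#' @param voxels 3-D numeric array with all values in [0, 1].
#' @param window numeric length-2, the (lo, hi) HU window of provenance.
#' @param spacing,slice_axis as in [ct_volume()].
#' @return An object of class `normalized_volume`.
#' @export
normalized_volume <- function(voxels, window, spacing = c(1, 1, 1),
                              slice_axis = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (min(voxels) < 0 || max(voxels) > 1)
    stop("normalized voxel values must lie in [0, 1]")
  window <- as.numeric(window)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be an increasing (lo, hi) pair")
  if (is.null(slice_axis)) slice_axis <- which.max(spacing)
  structure(list(voxels = voxels, window = window,
                 spacing = as.numeric(spacing),
                 slice_axis = as.integer(slice_axis)),
            class = "normalized_volume")
}

#' @export
print.normalized_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<normalized_volume> %d x %d x %d, window [%g, %g] HU, slice axis %d\n",
              d[1], d[2], d[3], x$window[1], x$window[2], x$slice_axis))
  invisible(x)
}

#' Organ label volume
#'
#' Integer organ codes aligned voxel-for-voxel with a CT volume. Code 0 is
#' background; every nonzero code present in the grid must be named in
#' `organ_map`.
#'
#' @param codes 3-D integer array of organ codes.
#' @param organ_map named character vector mapping code (as name) to organ
#'   name, e.g. `c("1" = "liver")`.
#' @param spacing,slice_axis as in [ct_volume()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(codes, organ_map, spacing = c(1, 1, 1),
                         slice_axis = NULL) {
  codes <- as.array(codes)
  storage.mode(codes) <- "integer"
  if (length(dim(codes)) != 3L) stop("codes must be a 3-D array")
  present <- setdiff(sort(unique(as.vector(codes))), 0L)
  missing <- setdiff(as.character(present), names(organ_map))
  if (length(missing) > 0)
    stop("codes present but absent from organ_map: ",
         paste(missing, collapse = ", "))
  if (is.null(slice_axis)) slice_axis <- which.max(spacing)
  structure(list(codes = codes, organ_map = organ_map,
                 spacing = as.numeric(spacing),
                 slice_axis = as.integer(slice_axis)),
            class = "label_volume")
}

#' Read a CT volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file; voxel spacing is taken from the header and
#' the longitudinal axis defaults to the axis with the largest spacing
#' (overridable).
#'
#' @param path path to a NIfTI file.
#' @param slice_axis optional explicit longitudinal axis.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, slice_axis = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  vox <- array(as.vector(img), dim = dim(img))
  ct_volume(vox, spacing = spacing[1:3], slice_axis = slice_axis)
}

#' Write a CT volume to NIfTI
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write organ label masks as NIfTI
#'
#' @param path NIfTI file of integer organ codes.
#' @param organ_map named character vector, code -> organ name.
#' @param slice_axis optional explicit longitudinal axis.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, organ_map, slice_axis = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  codes <- array(as.integer(round(as.vector(img))), dim = dim(img))
  label_volume(codes, organ_map,
               spacing = RNifti::pixdim(img)[1:3], slice_axis = slice_axis)
}

#' @rdname read_labels
#' @param lab a [label_volume()].
#' @export
write_labels <- function(lab, path) {
  stopifnot(inherits(lab, "label_volume"))
  img <- RNifti::asNifti(lab$codes)
  RNifti::pixdim(img) <- lab$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Clip HU values to a window
#'
#' Limits every voxel to the `[lo, hi]` window; the default window of
#' [-1000, 1000] HU spans air to dense soft tissue and excludes bone.
#'
#' @param vol a [ct_volume()].
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return A clipped [ct_volume()].
#' @export
clip_hu <- function(vol, lo = -1000, hi = 1000) {
  stopifnot(inherits(vol, "ct_volume"))
  if (lo >= hi) stop("lo must be < hi")
  v <- vol$voxels
  v[v < lo] <- lo
  v[v > hi] <- hi
  ct_volume(v, spacing = vol$spacing, slice_axis = vol$slice_axis)
}

#' Normalize a clipped volume to [0, 1]
#'
#' Affine map `v -> (v - lo) / (hi - lo)`. The volume must already be
#' clipped to the window; the window is recorded in the result so the map
#' is exactly invertible with [denormalize_volume()].
#'
#' @param vol a [ct_volume()] with all voxels inside `[lo, hi]`.
#' @param lo,hi HU window, defaults [-1000, 1000].
#' @return A [normalized_volume()].
#' @export
normalize_volume <- function(vol, lo = -1000, hi = 1000) {
  stopifnot(inherits(vol, "ct_volume"))
  if (lo >= hi) stop("lo must be < hi")
  rng <- range(vol$voxels)
  if (rng[1] < lo || rng[2] > hi)
    stop("voxels outside the window; clip with clip_hu() first")
  normalized_volume((vol$voxels - lo) / (hi - lo), window = c(lo, hi),
                    spacing = vol$spacing, slice_axis = vol$slice_axis)
}

#' Invert the [0, 1] normalization back to HU
#'
#' @param nvol a [normalized_volume()].
#' @return A [ct_volume()] in HU.
#' @export
denormalize_volume <- function(nvol) {
  stopifnot(inherits(nvol, "normalized_volume"))
  w <- nvol$window
  ct_volume(nvol$voxels * (w[2] - w[1]) + w[1], spacing = nvol$spacing,
            slice_axis = nvol$slice_axis)
}

# Convert normalized values to HU on the given window (used for reporting
# errors in HU: a difference of d in normalized units is d * (hi - lo) HU).
hu_scale <- function(window) diff(window)
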