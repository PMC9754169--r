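# Organ-oriented reconstruction: a base parallel model trained on original
# intensities provides the prediction everywhere; for each organ, a second
# parallel model trained on range-clipped data predicts from f-transformed
# inputs, and its inverse-transformed output replaces the base prediction
# inside that organ's mask only. Masks of different organs must not
# overlap — replacement is per-voxel and unambiguous.

#' Bundle a base model with per-organ range-clip models
#'
#' @param base_model `parallel_unet` trained on original data.
#' @param organ_models named list; each element
#'   `list(model = <parallel_unet trained on f-transformed data>,
#'   params = <rangeclip_params>)`.
#' @return An object of class `organ_bundle`.
#' @export
organ_bundle <- function(base_model, organ_models = list()) {
  t <- base_model$targets_per_gap
  for (nm in names(organ_models)) {
    om <- organ_models[[nm]]
    if (is.null(om$model) || is.null(om$params))
      stop("organ model '", nm, "' needs fields model and params")
    if (om$model$targets_per_gap != t)
      stop("organ model '", nm, "' has a different targets_per_gap")
    if (!all(om$model$spec$image_shape == base_model$spec$image_shape))
      stop("organ model '", nm, "' has a different image shape")
    if (!inherits(om$params, "rangeclip_params"))
      stop("organ model '", nm, "' params must be rangeclip_params")
  }
  structure(list(base_model = base_model, organ_models = organ_models,
                 targets_per_gap = t),
            class = "organ_bundle")
}

#' Transform a neighbour pair through the range-clip f
#'
#' @param left,right slice matrices in [0, 1].
#' @param p a `rangeclip_params`.
#' @return `list(left =, right =)` transformed slices.
#' @export
transform_inputs <- function(left, right, p) {
  list(left = apply_rangeclip(left, p), right = apply_rangeclip(right, p))
}

#' Interpolate an organ mask to a target position
#'
#' For inference without dense labels: the mask at fraction `fraction`
#' between the two sparse-slice masks is the set of voxels whose linearly
#' interpolated membership is at least 0.5.
#'
#' @param left_mask,right_mask logical matrices.
#' @param fraction position fraction in (0, 1).
#' @return logical matrix.
#' @export
interpolate_mask <- function(left_mask, right_mask, fraction) {
  if (!all(dim(left_mask) == dim(right_mask))) stop("mask shapes differ")
  (1 - fraction) * left_mask + fraction * right_mask >= 0.5
}

#' Organ-oriented reconstruction of one gap
#'
#' Runs the base model on the original pair, then for each organ runs that
#' organ's model on the f-transformed pair and writes the inverse-
#' transformed prediction into the organ's mask. Voxels outside all masks
#' are exactly the base prediction.
#'
#' @param bundle an [organ_bundle()].
#' @param left,right neighbour slice matrices in [0, 1].
#' @param masks named list (same names as the bundle's organ models); each
#'   element an H x W x (2m-1) logical array of per-target-position organ
#'   masks. For the stomach, air voxels must already be excluded from the
#'   mask. Organs whose name has no mask are skipped; masks of different
#'   organs must not overlap.
#' @return H x W x (2m-1) array.
#' @export
reconstruct_organ_oriented <- function(bundle, left, right, masks = list()) {
  stopifnot(inherits(bundle, "organ_bundle"))
  t <- bundle$targets_per_gap
  shape <- bundle$base_model$spec$image_shape
  use <- intersect(names(masks), names(bundle$organ_models))
  missing <- setdiff(names(masks), names(bundle$organ_models))
  if (length(missing) > 0)
    stop("mask supplied for organ(s) without a model: ",
         paste(missing, collapse = ", "))
  for (nm in use) {
    mk <- masks[[nm]]
    if (length(dim(mk)) == 2L) mk <- array(mk, dim = c(dim(mk), 1L))
    if (!all(dim(mk) == c(shape, t)))
      stop("mask for '", nm, "' must be H x W x targets_per_gap")
    masks[[nm]] <- mk
  }
  if (length(use) > 1L) {
    overlap <- Reduce(`+`, lapply(masks[use], function(m) m * 1))
    if (any(overlap > 1)) stop("organ masks overlap; replacement ambiguous")
  }
  out <- predict_slices(bundle$base_model, left, right)
  for (nm in use) {
    om <- bundle$organ_models[[nm]]
    tr <- transform_inputs(left, right, om$params)
    pred <- predict_slices(om$model, tr$left, tr$right)
    pred <- apply_rangeclip_inverse(pred, om$params)
    mk <- masks[[nm]]
    out[mk] <- pred[mk]
  }
  out
}

#' Organ-oriented reconstruction of all gaps of a sparse stack
#'
#' @param bundle an [organ_bundle()].
#' @param sparse H x W x K array of sparse slices.
#' @param gap_masks list of K-1 elements, each the `masks` argument of
#'   [reconstruct_organ_oriented()] for that gap.
#' @return list of K-1 arrays, as [reconstruct_linear()].
#' @export
reconstruct_organ_oriented_stack <- function(bundle, sparse, gap_masks) {
  pairs <- neighbor_pairs(sparse)
  if (length(gap_masks) != length(pairs))
    stop("need one mask set per gap")
  lapply(seq_along(pairs), function(j)
    reconstruct_organ_oriented(bundle, pairs[[j]]$left, pairs[[j]]$right,
                               gap_masks[[j]]))
}

#' Write / read a bundle manifest binding checkpoints and parameters
#'
#' The manifest is JSON naming the base checkpoint, each organ checkpoint
#' and its range-clip parameters, so train-time and test-time transforms
#' match exactly.
#'
#' @param bundle an [organ_bundle()].
#' @param dir output directory.
#' @return path of the manifest file.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base_path <- file.path(dir, "base_model.rds")
  save_checkpoint(bundle$base_model, base_path)
  organs <- list()
  for (nm in names(bundle$organ_models)) {
    om <- bundle$organ_models[[nm]]
    op <- file.path(dir, paste0("organ_", nm, ".rds"))
    save_checkpoint(om$model, op)
    organs[[nm]] <- list(checkpoint = basename(op),
                         params = unclass(om$params))
  }
  manifest <- list(base_checkpoint = basename(base_path),
                   targets_per_gap = bundle$targets_per_gap,
                   organs = organs)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  mpath
}

#' @rdname save_bundle
#' @param manifest_path path to a manifest written by [save_bundle()].
#' @export
load_bundle <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  dir <- dirname(manifest_path)
  base <- load_checkpoint(file.path(dir, man$base_checkpoint))
  organs <- lapply(man$organs, function(o)
    list(model = load_checkpoint(file.path(dir, o$checkpoint)),
         params = structure(o$params, class = "rangeclip_params")))
  organ_bundle(base, organs)
}
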