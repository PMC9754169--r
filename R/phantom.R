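# Synthetic labeled abdominal-CT-like phantom. Emulates the statistical
# structure the method relies on: a smooth wide-range background, several
# compact "organ" regions each occupying a narrow normalized intensity
# sub-range, organ cross-sections whose position and size drift
# nonlinearly along the longitudinal axis (so linear interpolation blurs
# and ghosts organ boundaries), and an optional air pocket inside the
# "stomach" region (labeled as stomach, so the air filter has work to
# do). No CT physics is simulated.

#' Default phantom organ descriptors
#'
#' A liver, two kidneys and a stomach, each a drifting/pulsating
#' ellipsoid with a narrow normalized intensity range; see
#' [phantom_config()] for the field meanings.
#'
#' @return named list of organ descriptors.
#' @export
default_phantom_organs <- function() {
  list(
    liver = list(code = 1L, name = "liver", range = c(0.56, 0.64),
                 center = c(0.38, 0.35), radii = c(0.24, 0.28),
                 drift_amp = c(0.10, 0.08), drift_phase = c(0.3, 1.2),
                 pulse = 0.22, pulse_phase = 0.8),
    left_kidney = list(code = 2L, name = "left_kidney", range = c(0.50, 0.56),
                       center = c(0.70, 0.28), radii = c(0.11, 0.10),
                       drift_amp = c(0.07, 0.09), drift_phase = c(1.9, 0.4),
                       pulse = 0.25, pulse_phase = 2.1),
    right_kidney = list(code = 3L, name = "right_kidney", range = c(0.52, 0.58),
                        center = c(0.70, 0.74), radii = c(0.11, 0.10),
                        drift_amp = c(0.08, 0.07), drift_phase = c(0.9, 2.6),
                        pulse = 0.25, pulse_phase = 1.4),
    stomach = list(code = 4L, name = "stomach", range = c(0.40, 0.48),
                   center = c(0.30, 0.72), radii = c(0.15, 0.13),
                   drift_amp = c(0.09, 0.10), drift_phase = c(2.4, 1.0),
                   pulse = 0.28, pulse_phase = 0.2)
  )
}

#' Phantom configuration
#'
#' @param shape in-plane (height, width) of each slice.
#' @param n_slices number of dense slices.
#' @param organs list of organ descriptors (code, name, normalized
#'   intensity `range`, fractional `center` (y, x), fractional `radii`,
#'   sinusoidal `drift_amp`/`drift_phase` per axis, radius `pulse`
#'   amplitude and phase); defaults emulate a liver, two kidneys and a
#'   stomach.
#' @param background list with `range`: the wide normalized intensity
#'   range of the smooth background field (organs are much narrower).
#' @param air_pocket `NULL`, or list(`code`, `radius_frac`, `value`): an
#'   air cavity inside the named organ, labeled as that organ.
#' @param noise_sd per-voxel Gaussian noise, normalized units (0.005 =
#'   10 HU under the [-1000, 1000] window).
#' @param nonlinearity scales all through-plane drift/pulsation; 0 gives
#'   a volume whose every voxel is affine in slice index (static organ
#'   cross-sections, linear background ramp) on which linear interpolation
#'   is exact.
#' @param spacing voxel spacing (dy, dx, dz) in mm.
#' @param seed integer seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64, 64), n_slices = 25,
                           organs = default_phantom_organs(),
                           background = list(range = c(0.25, 0.75)),
                           air_pocket = list(code = 4L, radius_frac = 0.45,
                                             value = 0.02),
                           noise_sd = 0.005, nonlinearity = 1,
                           spacing = c(1.0742, 1.0742, 2.5), seed = 1L) {
  for (o in organs) {
    if (o$range[1] < 0 || o$range[2] > 1 || o$range[1] >= o$range[2])
      stop("organ intensity ranges must be increasing and within [0, 1]")
    if (diff(o$range) >= diff(background$range))
      stop("organ ranges must be narrower than the background range")
    if (any(o$center - o$radii - 0.02 < 0) || any(o$center + o$radii + 0.02 > 1))
      stop("organ '", o$name, "' ellipsoid extends outside the grid")
  }
  structure(list(shape = as.integer(shape), n_slices = as.integer(n_slices),
                 organs = organs, background = background,
                 air_pocket = air_pocket, noise_sd = noise_sd,
                 nonlinearity = nonlinearity, spacing = spacing,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

organ_geometry <- function(o, u, nl) {
  # u in [0, 1]: normalized slice coordinate
  cy <- o$center[1] + nl * o$drift_amp[1] * sin(2 * pi * u + o$drift_phase[1])
  cx <- o$center[2] + nl * o$drift_amp[2] * sin(2 * pi * u + o$drift_phase[2])
  pulse <- 1 + nl * o$pulse * sin(2 * pi * u + o$pulse_phase)
  # longitudinal taper keeps organs compact ellipsoids, not cylinders
  taper <- if (nl > 0) sqrt(pmax(0, 1 - ((u - 0.5) / 0.62)^2)) else 1
  list(cy = cy, cx = cx, ry = o$radii[1] * pulse * taper,
       rx = o$radii[2] * pulse * taper)
}

#' Generate one labeled phantom volume
#'
#' Deterministic given `cfg$seed`. Organ voxels lie inside the organ's
#' configured intensity range (a smooth radial profile spanning it), the
#' air pocket sits near 0 while keeping its enclosing organ's label, and
#' Gaussian noise of sd `noise_sd` is added everywhere except that organ
#' voxels are clamped back into their range.
#'
#' @param cfg a [phantom_config()].
#' @return `list(volume = normalized_volume, labels = label_volume)`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  h <- cfg$shape[1]; w <- cfg$shape[2]; s <- cfg$n_slices
  nl <- cfg$nonlinearity
  yf <- (seq_len(h) - 0.5) / h
  xf <- (seq_len(w) - 0.5) / w
  # smooth low-frequency background field in [-1, 1]
  gfield <- matrix(0, h, w)
  for (i in 1:3) for (j in 1:3) {
    a <- rnorm(1)
    gfield <- gfield + a * outer(cos(pi * i * yf + runif(1, 0, 2 * pi)),
                                 cos(pi * j * xf + runif(1, 0, 2 * pi)))
  }
  gfield <- gfield / max(abs(gfield))
  bgr <- cfg$background$range
  bg_mid <- mean(bgr); bg_half <- diff(bgr) / 2
  zphase <- runif(1, 0, 2 * pi)
  vox <- array(0, dim = c(h, w, s))
  codes <- array(0L, dim = c(h, w, s))
  for (z in seq_len(s)) {
    u <- if (s > 1) (z - 1) / (s - 1) else 0.5
    zmod <- if (nl > 0) 0.75 + 0.25 * sin(2 * pi * u * nl + zphase)
            else 0.75
    sl <- bg_mid + bg_half * gfield * zmod +
      (if (nl == 0) bg_half * 0.4 * (u - 0.5) else 0)
    lab <- matrix(0L, h, w)
    for (o in cfg$organs) {
      geo <- organ_geometry(o, u, nl)
      if (geo$ry <= 0 || geo$rx <= 0) next
      d2 <- outer(((yf - geo$cy) / geo$ry)^2, ((xf - geo$cx) / geo$rx)^2, "+")
      inside <- d2 <= 1
      if (!any(inside)) next
      prof <- o$range[1] + diff(o$range) * (1 - d2[inside])
      sl[inside] <- prof
      lab[inside] <- o$code
    }
    if (!is.null(cfg$air_pocket)) {
      host <- Filter(function(o) o$code == cfg$air_pocket$code, cfg$organs)
      if (length(host) == 1L) {
        o <- host[[1]]
        geo <- organ_geometry(o, u, nl)
        if (geo$ry > 0) {
          fr <- cfg$air_pocket$radius_frac
          d2 <- outer(((yf - geo$cy) / (geo$ry * fr))^2,
                      ((xf - geo$cx) / (geo$rx * fr))^2, "+")
          pocket <- d2 <= 1
          sl[pocket] <- cfg$air_pocket$value
        }
      }
    }
    vox[, , z] <- sl
    codes[, , z] <- lab
  }
  if (cfg$noise_sd > 0) {
    vox <- vox + rnorm(length(vox), sd = cfg$noise_sd)
    # keep organ voxels inside their configured range (air pocket excepted)
    for (o in cfg$organs) {
      sel <- codes == o$code & vox > 0.2    # exclude air-pocket voxels
      vox[sel] <- pmin(pmax(vox[sel], o$range[1]), o$range[2])
    }
  }
  vox[vox < 0] <- 0
  vox[vox > 1] <- 1
  organ_map <- vapply(cfg$organs, `[[`, "", "name")
  names(organ_map) <- vapply(cfg$organs, function(o) as.character(o$code), "")
  list(volume = normalized_volume(vox, window = c(-1000, 1000),
                                  spacing = cfg$spacing, slice_axis = 3L),
       labels = label_volume(codes, organ_map, spacing = cfg$spacing,
                             slice_axis = 3L))
}

#' Generate a seeded train/test phantom dataset
#'
#' Each volume gets its own jittered organ paths, ranges and background
#' (seeded from `seed`), and the split is disjoint at the volume level.
#'
#' @param cfg a [phantom_config()] template.
#' @param n_volumes number of volumes (>= 2).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed master seed controlling jitter and split membership.
#' @return `list(train =, test =)`, each a list of
#'   `list(volume =, labels =)`.
#' @export
generate_dataset <- function(cfg, n_volumes = 30, train_fraction = 0.8,
                             seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"))
  n_volumes <- as.integer(n_volumes)
  if (n_volumes < 2L) stop("n_volumes must be >= 2")
  n_test <- max(1L, round((1 - train_fraction) * n_volumes))
  if (n_test >= n_volumes) stop("degenerate split: no training volumes")
  set.seed(seed)
  jitters <- lapply(seq_len(n_volumes), function(v) {
    list(center = runif(2 * length(cfg$organs), -0.02, 0.02),
         amp = runif(length(cfg$organs), 0.85, 1.15),
         phase = runif(2 * length(cfg$organs), -0.4, 0.4),
         range_shift = runif(length(cfg$organs), -0.008, 0.008),
         seed = sample.int(1e6, 1))
  })
  test_idx <- sort(sample.int(n_volumes, n_test))
  vols <- lapply(seq_len(n_volumes), function(v) {
    jt <- jitters[[v]]
    cfg_v <- cfg
    for (i in seq_along(cfg_v$organs)) {
      o <- cfg_v$organs[[i]]
      o$center <- o$center + jt$center[(2 * i - 1):(2 * i)]
      o$drift_amp <- o$drift_amp * jt$amp[i]
      o$drift_phase <- o$drift_phase + jt$phase[(2 * i - 1):(2 * i)]
      o$range <- pmin(pmax(o$range + jt$range_shift[i], 0), 1)
      cfg_v$organs[[i]] <- o
    }
    cfg_v$seed <- jt$seed
    generate_phantom(cfg_v)
  })
  list(train = vols[setdiff(seq_len(n_volumes), test_idx)],
       test = vols[test_idx])
}

#' Build training examples (gap input pairs + targets) from dense volumes
#'
#' @param volumes list of `list(volume =, labels =)` (or of
#'   [normalized_volume()]).
#' @param grouping a [slice_grouping()].
#' @return list of `list(input = H x W x 2, target = H x W x t)` examples
#'   pooled over all volumes, in volume-then-gap order.
#' @export
make_training_examples <- function(volumes, grouping) {
  out <- list()
  for (v in volumes) {
    nv <- if (!is.null(v$volume)) v$volume else v
    sp <- split_volume(nv, grouping)
    t <- grouping$targets_per_gap
    pairs <- neighbor_pairs(sp$sparse)
    for (j in seq_along(pairs)) {
      tg <- sp$target[, , ((j - 1) * t + 1):(j * t), drop = FALSE]
      out[[length(out) + 1L]] <-
        list(input = array(c(pairs[[j]]$left, pairs[[j]]$right),
                           dim = c(dim(pairs[[j]]$left), 2L)),
             target = tg)
    }
  }
  out
}
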