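# Evaluation protocol: per-target-position MAE in HU (errors on the
# normalized scale multiplied by the HU window width), per-slice
# normalized SSIM, improvement percentages between methods, paired
# significance tests on per-slice errors, and the threshold rule for
# choosing the interpolation factor m.

#' Mean absolute error
#'
#' @param pred,true numeric arrays of identical shape.
#' @param mask optional logical array; average over masked voxels only.
#' @param scale multiplier applied to the mean absolute difference; use
#'   the HU window width (2000 for [-1000, 1000]) to report normalized
#'   errors in HU.
#' @return nonnegative scalar.
#' @export
mae <- function(pred, true, mask = NULL, scale = 1) {
  if (!all(dim(pred) == dim(true) | is.null(dim(pred)))) stop("shape mismatch")
  d <- abs(pred - true)
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty mask")
    d <- d[mask]
  }
  mean(d) * scale
}

#' Maximum pixel-wise MAE of a reconstruction
#'
#' The MAE is computed per pixel across all evaluated slices, and the
#' maximum over pixels is returned — the quantity thresholded by the
#' m-selection rule.
#'
#' @param pred,true H x W x S arrays.
#' @param scale as in [mae()].
#' @export
max_pixelwise_mae <- function(pred, true, scale = 1) {
  if (!all(dim(pred) == dim(true))) stop("shape mismatch")
  per_pixel <- apply(abs(pred - true), c(1, 2), mean)
  max(per_pixel) * scale
}

#' Improvement percentage of one method over a reference
#'
#' For error metrics (MAE) a positive value means `new` is lower than
#' `reference`: `100 (reference - new) / reference`. For similarity
#' metrics (SSIM) a positive value means `new` is higher:
#' `100 (new - reference) / reference`.
#'
#' @param reference,new metric values; `reference` must be positive.
#' @param type `"error"` or `"similarity"`.
#' @return percentage (unrounded; reports round to 2 decimals).
#' @export
improvement_pct <- function(reference, new, type = c("error", "similarity")) {
  type <- match.arg(type)
  if (any(reference <= 0)) stop("reference must be positive")
  if (type == "error") 100 * (reference - new) / reference
  else 100 * (new - reference) / reference
}

#' Paired significance test between two error samples
#'
#' Two-sided paired Wilcoxon signed-rank test by default (paired t-test
#' behind a flag), plus the sign of the median difference so the direction
#' of the effect is explicit.
#'
#' @param errors_a,errors_b paired samples (e.g. per-slice absolute
#'   errors) of equal length.
#' @param method `"wilcoxon"` or `"ttest"`.
#' @return list with `p_value`, `direction` (-1: A smaller, +1: B
#'   smaller, 0: tie), `method`, and `degenerate` (TRUE when all pairs
#'   tie, leaving no test statistic).
#' @export
significance_test <- function(errors_a, errors_b,
                              method = c("wilcoxon", "ttest")) {
  method <- match.arg(method)
  if (length(errors_a) != length(errors_b)) stop("paired samples differ in length")
  d <- errors_a - errors_b
  if (all(d == 0))
    return(list(p_value = 1, direction = 0, method = method,
                degenerate = TRUE))
  p <- if (method == "wilcoxon") {
    suppressWarnings(wilcox.test(errors_a, errors_b, paired = TRUE,
                                 exact = FALSE)$p.value)
  } else {
    t.test(errors_a, errors_b, paired = TRUE)$p.value
  }
  list(p_value = p, direction = sign(median(d)), method = method,
       degenerate = FALSE)
}

#' Choose the interpolation factor m under a noise threshold
#'
#' Scans the table in order of increasing m and stops as soon as the
#' maximum pixel-wise MAE exceeds `mu`; the last m before the stop is
#' returned. If the smallest m already exceeds `mu`, it is returned with a
#' warning.
#'
#' @param tbl data frame with columns `m` and `max_mae`, ordered by
#'   increasing m.
#' @param mu positive threshold on the maximum pixel-wise MAE (HU).
#' @return the chosen m.
#' @export
select_m <- function(tbl, mu) {
  if (!is.data.frame(tbl) || nrow(tbl) == 0) stop("empty m table")
  if (!all(c("m", "max_mae") %in% names(tbl))) stop("need columns m and max_mae")
  if (is.unsorted(tbl$m, strictly = TRUE)) stop("table must be ordered by increasing m")
  if (mu <= 0) stop("mu must be positive")
  ok <- tbl$max_mae <= mu
  if (!ok[1]) {
    warning("smallest m already exceeds mu; returning it")
    return(tbl$m[1])
  }
  first_bad <- which(!ok)[1]
  if (is.na(first_bad)) tbl$m[nrow(tbl)] else tbl$m[first_bad - 1L]
}

# Concatenate per-gap reconstruction lists into one target stack whose
# slices are ordered gap by gap, position 1..t within each gap (the same
# order split_volume() emits targets).
gap_list_to_stack <- function(recon) {
  d <- dim(recon[[1]])
  array(unlist(recon, use.names = FALSE),
        dim = c(d[1], d[2], d[3] * length(recon)))
}

# Position within the gap (1..t) of each slice of a target stack.
target_positions <- function(n_slices, targets_per_gap) {
  rep(seq_len(targets_per_gap), length.out = n_slices)
}

#' Build the evaluation report
#'
#' Compares reconstruction methods against dense ground truth on the
#' held-out target slices: per-position MAE (HU) pooled over all gaps,
#' per-position mean per-slice SSIM (after per-slice normalization),
#' optional per-organ tables over labeled regions, improvement rows of
#' every method against the reference (first method), and pairwise paired
#' significance tests on per-slice MAEs.
#'
#' @param preds named list of predictions, one per method; each either a
#'   per-gap list (as returned by [reconstruct_linear()] /
#'   [reconstruct_model()]) or an H x W x T target stack.
#' @param truth H x W x T array of true target slices (the `target`
#'   element of [split_volume()]), or a per-gap list.
#' @param grouping the [slice_grouping()] used.
#' @param labels optional H x W x T integer array of organ codes at the
#'   target slices.
#' @param organ_map named character vector code -> organ name (required
#'   with `labels`).
#' @param window HU window used to scale MAE, default [-1000, 1000].
#' @param reference name of the reference method for improvement rows;
#'   default the first.
#' @param ssim_normalize per-slice normalization mode for SSIM.
#' @return An object of class `eval_report`: data frames `per_position`,
#'   `averages`, `per_organ`, `improvements`, `p_values`.
#' @export
build_report <- function(preds, truth, grouping, labels = NULL,
                         organ_map = NULL, window = c(-1000, 1000),
                         reference = NULL,
                         ssim_normalize = "minmax") {
  t <- grouping$targets_per_gap
  if (is.list(truth) && !is.array(truth)) truth <- gap_list_to_stack(truth)
  preds <- lapply(preds, function(p)
    if (is.list(p) && !is.array(p)) gap_list_to_stack(p) else p)
  if (is.null(names(preds)) || any(names(preds) == ""))
    stop("preds must be a named list")
  for (nm in names(preds))
    if (!all(dim(preds[[nm]]) == dim(truth)))
      stop("method '", nm, "': prediction shape differs from truth")
  if (!is.null(labels) && !all(dim(labels) == dim(truth)))
    stop("labels shape differs from truth")
  n_slices <- dim(truth)[3]
  pos <- target_positions(n_slices, t)
  scale <- hu_scale(window)
  methods <- names(preds)
  if (is.null(reference)) reference <- methods[1]

  per_position <- do.call(rbind, lapply(methods, function(nm) {
    p <- preds[[nm]]
    do.call(rbind, lapply(seq_len(t), function(k) {
      idx <- which(pos == k)
      m_hu <- mae(p[, , idx, drop = FALSE], truth[, , idx, drop = FALSE],
                  scale = scale)
      ss <- mean(vapply(idx, function(j)
        ssim_slice(p[, , j], truth[, , j], normalize = ssim_normalize),
        numeric(1)))
      data.frame(method = nm, position = k, mae_hu = m_hu, ssim = ss)
    }))
  }))
  averages <- do.call(rbind, lapply(methods, function(nm) {
    sub <- per_position[per_position$method == nm, ]
    data.frame(method = nm, mae_hu = mean(sub$mae_hu), ssim = mean(sub$ssim))
  }))

  per_organ <- NULL
  if (!is.null(labels)) {
    if (is.null(organ_map)) stop("organ_map required with labels")
    per_organ <- do.call(rbind, lapply(names(organ_map), function(code_chr) {
      code <- as.integer(code_chr)
      organ <- organ_map[[code_chr]]
      do.call(rbind, lapply(methods, function(nm) {
        p <- preds[[nm]]
        do.call(rbind, lapply(seq_len(t), function(k) {
          idx <- which(pos == k)
          mk <- labels[, , idx, drop = FALSE] == code
          if (!any(mk)) return(NULL)
          m_hu <- mae(p[, , idx, drop = FALSE],
                      truth[, , idx, drop = FALSE], mask = mk, scale = scale)
          slice_ssim <- vapply(idx, function(j) {
            mj <- labels[, , j] == code
            if (!any(mj)) return(NA_real_)
            tryCatch(ssim_slice(p[, , j], truth[, , j], mask = mj,
                                normalize = ssim_normalize),
                     error = function(e) NA_real_)
          }, numeric(1))
          data.frame(organ = organ, method = nm, position = k,
                     mae_hu = m_hu, ssim = mean(slice_ssim, na.rm = TRUE))
        }))
      }))
    }))
  }

  improvements <- NULL
  if (length(methods) > 1) {
    others <- setdiff(methods, reference)
    ref_pp <- per_position[per_position$method == reference, ]
    improvements <- do.call(rbind, lapply(others, function(nm) {
      new_pp <- per_position[per_position$method == nm, ]
      rows <- data.frame(
        comparison = paste(nm, "vs", reference),
        position = c(ref_pp$position, NA),
        mae_improvement_pct = round(c(
          improvement_pct(ref_pp$mae_hu, new_pp$mae_hu, "error"),
          improvement_pct(mean(ref_pp$mae_hu), mean(new_pp$mae_hu), "error")), 2),
        ssim_improvement_pct = round(c(
          improvement_pct(ref_pp$ssim, new_pp$ssim, "similarity"),
          improvement_pct(mean(ref_pp$ssim), mean(new_pp$ssim), "similarity")), 2))
      rows
    }))
  }

  p_values <- NULL
  if (length(methods) > 1) {
    slice_mae <- lapply(preds, function(p) vapply(seq_len(n_slices),
      function(j) mae(p[, , j], truth[, , j], scale = scale), numeric(1)))
    combos <- utils::combn(methods, 2, simplify = FALSE)
    p_values <- do.call(rbind, lapply(combos, function(cb) {
      st <- significance_test(slice_mae[[cb[1]]], slice_mae[[cb[2]]])
      data.frame(method_a = cb[1], method_b = cb[2],
                 p_value = st$p_value, direction = st$direction,
                 test = st$method)
    }))
  }

  structure(list(per_position = per_position, averages = averages,
                 per_organ = per_organ, improvements = improvements,
                 p_values = p_values, reference = reference,
                 window = window, targets_per_gap = t),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> per-position MAE (HU) and SSIM\n")
  print(x$averages, row.names = FALSE)
  if (!is.null(x$improvements)) {
    cat("improvements vs", x$reference, "(average rows):\n")
    print(x$improvements[is.na(x$improvements$position), ],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write an evaluation report to CSV files and combined JSON
#'
#' @param report an [build_report()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$per_position, file.path(dir, "per_position.csv"),
            row.names = FALSE)
  write.csv(report$averages, file.path(dir, "averages.csv"),
            row.names = FALSE)
  if (!is.null(report$per_organ))
    write.csv(report$per_organ, file.path(dir, "per_organ.csv"),
              row.names = FALSE)
  if (!is.null(report$improvements))
    write.csv(report$improvements, file.path(dir, "improvements.csv"),
              row.names = FALSE)
  if (!is.null(report$p_values))
    write.csv(report$p_values, file.path(dir, "p_values.csv"),
              row.names = FALSE)
  jsonlite::write_json(lapply(unclass(report), function(x) x),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(dir)
}
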