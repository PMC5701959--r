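# --- curve-level cores -----------------------------------------------------
# The selection criteria and shifts only ever use per-pixel time curves and
# region-mean curves; these cores operate on those directly so that sweep
# code can reuse reduced summaries of a reconstruction without holding the
# full 4D arrays.

# criterion 2: keep the thresh_range% of ROI pixels with smallest
# magnitude range (>= 1 pixel; ties broken by voxel index)
criterion2_core <- function(signal_range, roi, thresh_range) {
  keep_n <- max(1L, round_half_up(thresh_range / 100 * length(roi)))
  keep_n <- min(keep_n, length(roi))
  ord <- order(signal_range, roi)
  sort(roi[ord[seq_len(keep_n)]])
}

# tail-to-peak ratio of the brain-mean curve shifted by one candidate curve,
# baseline-referenced (raw QSM values carry an arbitrary offset)
tailpeak_ratio_core <- function(brain_mean, pixel_curve, pre_idx, tail_idx,
                                peak_idx) {
  shifted <- brain_mean - pixel_curve
  base <- mean(shifted[pre_idx])
  (mean(shifted[tail_idx]) - base) / (mean(shifted[peak_idx]) - base)
}

# criterion 3 on curves; chi_cand is a matrix candidates x time
criterion3_core <- function(brain_mean_chi, chi_cand, candidates,
                            mag_brain_mean, cfg, pre_idx) {
  nt <- length(brain_mean_chi)
  i_min <- which.min(mag_brain_mean)
  half <- (cfg$n_peak - 1L) %/% 2L
  peak_idx <- seq.int(i_min - half, i_min + half)
  peak_idx <- peak_idx[peak_idx >= 1L & peak_idx <= nt]
  tail_idx <- seq.int(nt - cfg$n_tail + 1L, nt)
  ratios <- vapply(seq_along(candidates), function(i)
    tailpeak_ratio_core(brain_mean_chi, chi_cand[i, ], pre_idx, tail_idx,
                        peak_idx), numeric(1))
  n_side <- round_half_up(cfg$thresh_tailpeak / 100 * length(candidates) / 2)
  keep <- rep(TRUE, length(candidates))
  if (n_side > 0) {
    ord <- order(ratios, candidates)
    keep[ord[seq_len(min(n_side, length(ord)))]] <- FALSE
    keep[rev(ord)[seq_len(min(n_side, length(ord)))]] <- FALSE
  }
  if (!any(keep))
    stop("all candidate pixels discarded by the tail-to-peak criterion; ",
         "lower thresh_tailpeak")
  structure(
    list(pixels = sort(candidates[keep]),
         tailpeak_ratio = stats::setNames(ratios, candidates),
         peak_window = peak_idx, tail_window = tail_idx, config = cfg),
    class = "reference_selection"
  )
}

# per-frame scalar that flattens the reference mean curve at its baseline
shift_curve_core <- function(ref_mean_curve, pre_idx) {
  ref_mean_curve - mean(ref_mean_curve[pre_idx])
}

# rows of a 4D array as a pixels x time matrix
pixel_curves <- function(values4, pixels) {
  dm <- dim(values4)
  matrix(values4, nrow = prod(dm[1:3]))[pixels, , drop = FALSE]
}

region_mean_curve <- function(values4, mask) {
  colMeans(pixel_curves(values4, which(mask)))
}

# --- public module surface -------------------------------------------------

#' Candidate CSF reference ROI
#'
#' Returns the ventricular CSF voxel set from which reference pixels are
#' selected.  In the phantom setting the ground-truth ventricle mask stands
#' in for the manually drawn ROI covering most of the lateral ventricles.
#'
#' @param masks a named list of 3D logical masks containing at least `csf`,
#'   e.g. `phantom$masks`.
#' @return integer vector of linear voxel indices.
#' @export
candidate_roi <- function(masks) {
  if (is.null(masks$csf) || !any(masks$csf))
    stop("CSF mask is empty: no candidate reference region")
  which(masks$csf)
}

#' Filter CSF candidates by magnitude signal range (criterion 2)
#'
#' For each candidate pixel the range (max - min) of its magnitude time
#' curve is computed; the `thresh_range` percent of pixels with the
#' smallest range are kept (at least one; ties broken by voxel index).
#' Pixels showing little magnitude change during the bolus passage are the
#' ones least affected by the contrast agent.
#'
#' @param series a [dynamic_series()] object.
#' @param roi candidate voxel indices, from [candidate_roi()].
#' @param cfg a [reference_config()].
#' @return list with `pixels` (selected indices) and `signal_range`
#'   (named per-candidate ranges).
#' @export
filter_by_signal_range <- function(series, roi, cfg = reference_config()) {
  if (length(roi) == 0L) stop("candidate ROI is empty")
  m <- pixel_curves(series$magnitude, roi)
  rng <- apply(m, 1L, function(v) max(v) - min(v))
  list(pixels = criterion2_core(rng, roi, cfg$thresh_range),
       signal_range = stats::setNames(rng, roi))
}

#' Filter CSF candidates by tail-to-peak ratio (criterion 3)
#'
#' Each candidate pixel is applied alone as the CSF reference; the
#' resulting shifted whole-brain mean susceptibility curve must show a
#' tail-to-peak ratio similar to that of the other candidates.  The peak
#' window is the `n_peak` frames including and surrounding the frame at
#' which the whole-brain mean magnitude is minimal; the tail window is the
#' last `n_tail` frames.  Ratios are computed on baseline-subtracted
#' curves (raw susceptibility values carry an arbitrary offset).  The
#' `thresh_tailpeak` percent of candidates with the most extreme ratios
#' are discarded, half from each end of the ratio distribution (counts
#' rounded half-up); the rest are retained.
#'
#' @param chi_series a [susceptibility_series()] (unshifted is fine: the
#'   ratio is offset-free).
#' @param series the [dynamic_series()] providing magnitude data.
#' @param candidates candidate voxel indices (after criterion 2).
#' @param brain_mask 3D brain mask over which the mean curve is formed.
#' @param cfg a [reference_config()].
#' @param windows a [steady_state_windows()] (baseline definition).
#' @return an object of class `reference_selection`.
#' @export
filter_by_tailpeak <- function(chi_series, series, candidates, brain_mask,
                               cfg = reference_config(),
                               windows = steady_state_windows()) {
  if (length(candidates) == 0L) stop("no candidate reference pixels")
  brain_mask <- stopifnot_mask(brain_mask, dim(chi_series$chi)[1:3])
  criterion3_core(
    brain_mean_chi = region_mean_curve(chi_series$chi, brain_mask),
    chi_cand = pixel_curves(chi_series$chi, candidates),
    candidates = candidates,
    mag_brain_mean = region_mean_curve(series$magnitude, brain_mask),
    cfg = cfg, pre_idx = windows$pre)
}

#' @export
print.reference_selection <- function(x, ...) {
  cat("<reference_selection>", length(x$pixels), "reference pixels",
      "| thresh_tailpeak", x$config$thresh_tailpeak, "%\n")
  invisible(x)
}

#' Select CSF reference pixels by the three criteria
#'
#' Convenience wrapper chaining [candidate_roi()],
#' [filter_by_signal_range()] and [filter_by_tailpeak()].
#'
#' @inheritParams filter_by_tailpeak
#' @param masks phantom-style mask list (criterion 1 candidate region).
#' @return a `reference_selection` object with per-pixel signal-range
#'   diagnostics attached.
#' @export
select_csf_reference <- function(chi_series, series, masks,
                                 cfg = reference_config(),
                                 windows = steady_state_windows()) {
  roi <- candidate_roi(masks)
  cr2 <- filter_by_signal_range(series, roi, cfg)
  sel <- filter_by_tailpeak(chi_series, series, cr2$pixels, masks$brain,
                            cfg, windows)
  sel$signal_range <- cr2$signal_range
  sel
}

#' Anchor a susceptibility series to the CSF reference
#'
#' At each time point the mean susceptibility over the reference pixels is
#' subtracted and the baseline value of that reference curve (mean over
#' the baseline window) is added back, so the reference CSF curve is flat
#' at its baseline level; every other voxel is shifted by the same scalar
#' per time point, preserving all spatial differences.  Idempotent.
#'
#' @param chi_series a [susceptibility_series()].
#' @param selection a `reference_selection`.
#' @param windows a [steady_state_windows()].
#' @return a [susceptibility_series()] with
#'   `reference_state = "csf_shifted"`; the applied per-frame shift is
#'   stored in `diagnostics$reference_shift`.
#' @export
shift_susceptibility <- function(chi_series, selection,
                                 windows = steady_state_windows()) {
  if (length(selection$pixels) == 0L) stop("empty reference selection")
  ref_curve <- colMeans(pixel_curves(chi_series$chi, selection$pixels))
  sh <- shift_curve_core(ref_curve, windows$pre)
  out <- chi_series$chi
  for (t in seq_along(sh)) out[, , , t] <- out[, , , t] - sh[t]
  susceptibility_series(out, chi_series$mask,
                        reference_state = "csf_shifted",
                        diagnostics = c(chi_series$diagnostics,
                                        list(reference_shift = sh)))
}

#' Drift-correct an unwrapped phase series using the CSF reference
#'
#' Applies the same scalar-per-time-point subtraction to the unfiltered,
#' unwrapped phase, so that no phase change is seen in the CSF reference
#' pixels during the contrast passage; used for vessel measurements, where
#' filtered maps are unreliable near the brain edge.
#'
#' @param field a [field_series()] at stage `"unwrapped"` (rad).
#' @param selection a `reference_selection`.
#' @param windows a [steady_state_windows()].
#' @return a [field_series()] (same stage/unit) with the correction
#'   applied and stored in `diagnostics$reference_shift`.
#' @export
shift_phase <- function(field, selection,
                        windows = steady_state_windows()) {
  if (!inherits(field, "field_series") || field$stage != "unwrapped")
    stop("shift_phase expects an unwrapped, unfiltered field_series")
  if (length(selection$pixels) == 0L) stop("empty reference selection")
  ref_curve <- colMeans(pixel_curves(field$values, selection$pixels))
  sh <- shift_curve_core(ref_curve, windows$pre)
  out <- field$values
  for (t in seq_along(sh)) out[, , , t] <- out[, , , t] - sh[t]
  field_series(out, field$mask, stage = "unwrapped", unit = field$unit,
               params = field$params,
               diagnostics = c(field$diagnostics,
                               list(reference_shift = sh)))
}
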