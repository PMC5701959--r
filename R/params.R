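#' Acquisition parameters for a dynamic gradient-echo series
#'
#' Container for the acquisition settings of a dynamic susceptibility
#' contrast (DSC) protocol.  Defaults mirror a single-shot GRE-EPI perfusion
#' protocol at 3 T: TE = 29 ms, 70 dynamics at 1.24 s temporal resolution.
#'
#' @param te echo time (s).
#' @param b0 main magnetic field (T).
#' @param gamma proton gyromagnetic ratio (rad s^-1 T^-1).
#' @param n_timepoints number of dynamic frames (>= 20; the steady-state
#'   windows need at least 19 points).
#' @param dt temporal resolution (s per frame).
#' @param voxel_size 3-vector of voxel dimensions (mm).
#' @param b0_drift_rate scanner frequency drift expressed as field drift in
#'   ppb per time point.  The default of 0.2 ppb/frame corresponds to a slow
#'   thermal drift of roughly 0.015 ppm over the 87 s scan.
#' @return an object of class `acquisition_params`.
#' @export
acquisition_params <- function(te = 0.029, b0 = 3, gamma = 2.675e8,
                               n_timepoints = 70L, dt = 1.24,
                               voxel_size = c(2, 2, 2),
                               b0_drift_rate = 0.2) {
  stopifnot(te > 0, b0 > 0, gamma > 0, dt > 0)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 20L)
    stop("n_timepoints must be >= 20: the baseline window (5-14) and the ",
         "steady-state tail need at least 19 usable frames")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive components (mm)")
  structure(
    list(te = te, b0 = b0, gamma = gamma, n_timepoints = n_timepoints,
         dt = dt, voxel_size = voxel_size, b0_drift_rate = b0_drift_rate),
    class = "acquisition_params"
  )
}

#' Physiological constants for CBV estimation
#'
#' @param rho brain density (g/mL); 1.04 by convention.
#' @param hct_lv large-vessel hematocrit (fraction).
#' @param hct_sv small-vessel hematocrit (fraction).
#' @param chi_mol molar susceptibility of the Gd contrast agent (ppm/M).
#' @return an object of class `physio_constants`.
#' @export
physio_constants <- function(rho = 1.04, hct_lv = 0.45, hct_sv = 0.25,
                             chi_mol = 308) {
  stopifnot(rho > 0, chi_mol > 0)
  if (!(hct_sv > 0 && hct_sv < hct_lv && hct_lv < 1))
    stop("hematocrits must satisfy 0 < hct_sv < hct_lv < 1")
  structure(
    list(rho = rho, hct_lv = hct_lv, hct_sv = hct_sv, chi_mol = chi_mol),
    class = "physio_constants"
  )
}

#' Steady-state analysis windows
#'
#' The pre-contrast baseline is fixed to dynamic frames 5-14 (1-based,
#' inclusive); frames 1-4 are discarded for saturation effects.  The
#' post-contrast steady-state window covers the final `post_n` frames
#' (between 4 and 10; default 7, the midpoint of that range).
#'
#' @param pre integer vector of baseline frame indices (1-based).
#' @param post_n number of trailing frames forming the steady-state window.
#' @return an object of class `steady_state_windows`.
#' @export
steady_state_windows <- function(pre = 5:14, post_n = 7L) {
  post_n <- as.integer(post_n)
  if (post_n < 1L) stop("post_n must be >= 1")
  stopifnot(all(pre >= 1L))
  structure(list(pre = as.integer(pre), post_n = post_n),
            class = "steady_state_windows")
}

# resolve the pre/post frame indices for a series with nt frames
window_indices <- function(windows, nt) {
  post <- seq.int(nt - windows$post_n + 1L, nt)
  if (max(windows$pre) >= min(post))
    stop("baseline and steady-state windows overlap; series too short")
  list(pre = windows$pre, post = post)
}

#' Configuration of the dipole inversion
#'
#' @param lam regularization parameter lambda of the regularized
#'   (morphology-enabled) inversion; multiplies the data-fidelity term, so
#'   larger lambda means stronger fidelity and higher tissue contrast.
#' @param method `"tkd"` (thresholded k-space division, fast, linear) or
#'   `"medi_like"` (edge-weighted total-variation regularized inversion).
#' @param tkd_threshold kernel truncation level in (0, 1/3].
#' @param tkd_correct apply the standard truncation-bias (point-spread)
#'   amplitude correction `mean(D/D_trunc)` to TKD output.
#' @param max_iter iteration caps: for `medi_like`, inner conjugate-gradient
#'   iterations per reweighting step.
#' @param n_outer outer reweighting steps of the iteratively reweighted
#'   least-squares scheme (`medi_like` only).
#' @param tol relative residual tolerance of the inner solver.
#' @param edge_percentile magnitude-gradient percentile above which voxels
#'   are treated as edges and excluded from the smoothing penalty.
#' @param eps smoothing parameter of the reweighted L1 gradient penalty.
#' @param w_floor lower bound added to the reweighted gradient penalty,
#'   keeping weakly-determined (near-cone) modes regularized at large
#'   `lam`.
#' @param ridge small lambda-independent L2 anchor for the smooth
#'   magic-angle-cone modes that neither the fidelity nor the gradient
#'   penalty constrains.
#' @return an object of class `inversion_config`.
#' @export
inversion_config <- function(lam = 300, method = c("tkd", "medi_like"),
                             tkd_threshold = 0.15, tkd_correct = TRUE,
                             max_iter = 50L, n_outer = 3L, tol = 1e-4,
                             edge_percentile = 0.70, eps = 1e-6,
                             w_floor = 10, ridge = 0.5) {
  method <- match.arg(method)
  stopifnot(lam > 0, tol > 0, max_iter >= 1, n_outer >= 1)
  if (!(tkd_threshold > 0 && tkd_threshold <= 1 / 3))
    stop("tkd_threshold must lie in (0, 1/3]")
  structure(
    list(lam = lam, method = method, tkd_threshold = tkd_threshold,
         tkd_correct = tkd_correct, max_iter = as.integer(max_iter),
         n_outer = as.integer(n_outer), tol = tol,
         edge_percentile = edge_percentile, eps = eps, w_floor = w_floor,
         ridge = ridge),
    class = "inversion_config"
  )
}

#' Configuration of CSF reference pixel selection
#'
#' @param thresh_range percentage of the candidate CSF ROI retained by the
#'   magnitude signal-range criterion (criterion 2).
#' @param thresh_tailpeak percentage of candidates discarded by the
#'   tail-to-peak ratio criterion (criterion 3), split evenly between the
#'   high and low tails of the ratio distribution.
#' @param n_tail number of trailing frames defining the tail window.
#' @param n_peak number of frames in the peak window (centred on the frame
#'   of minimal whole-brain mean magnitude).
#' @return an object of class `reference_config`.
#' @export
reference_config <- function(thresh_range = 10, thresh_tailpeak = 30,
                             n_tail = 5L, n_peak = 5L) {
  if (!(thresh_range > 0 && thresh_range <= 100))
    stop("thresh_range must be in (0, 100]")
  if (!(thresh_tailpeak >= 0 && thresh_tailpeak < 100))
    stop("thresh_tailpeak must be in [0, 100)")
  structure(
    list(thresh_range = thresh_range, thresh_tailpeak = thresh_tailpeak,
         n_tail = as.integer(n_tail), n_peak = as.integer(n_peak)),
    class = "reference_config"
  )
}
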