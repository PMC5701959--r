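#' Contrast-agent concentration from shifted susceptibility
#'
#' `[CA](v,t) = (chi(v,t) - chi0(v)) / chi_mol`, with `chi0` the mean over
#' the baseline window.  With `chi` in ppm and `chi_mol` in ppm/M the
#' factor 1000 yields mM.
#'
#' @param chi_shifted a [susceptibility_series()] with
#'   `reference_state = "csf_shifted"`.
#' @param windows a [steady_state_windows()].
#' @param physio a [physio_constants()].
#' @return 4D concentration array (mM).
#' @export
concentration_from_susceptibility <- function(chi_shifted,
                                              windows = steady_state_windows(),
                                              physio = physio_constants()) {
  if (!inherits(chi_shifted, "susceptibility_series") ||
      chi_shifted$reference_state != "csf_shifted")
    stop("concentration requires a csf_shifted susceptibility series; ",
         "apply shift_susceptibility() first")
  chi <- chi_shifted$chi
  nt <- n_frames(chi)
  chi0 <- apply(chi[, , , windows$pre, drop = FALSE], 1:3, mean)
  out <- array(0, dim(chi))
  for (t in seq_len(nt))
    out[, , , t] <- ppm_to_conc(frame4(chi, t) - chi0, physio$chi_mol)
  out
}

#' CA-induced change in transverse relaxation rate from magnitude
#'
#' `DeltaR2*(v,t) = -(1/TE) * ln(S(v,t)/S0(v))` with `S0` the baseline
#' (pre-contrast) mean magnitude.  Valid for single-echo, purely
#' T2*-weighted magnitude data.  Voxels with non-positive signal at any
#' frame are flagged invalid (NA) rather than propagated.
#'
#' @param series a [dynamic_series()].
#' @param windows a [steady_state_windows()].
#' @return 4D Delta-R2* array (s^-1); attribute `invalid` holds the 3D mask
#'   of excluded voxels.
#' @export
delta_r2star <- function(series, windows = steady_state_windows()) {
  mag <- series$magnitude
  nt <- n_frames(mag)
  s0 <- apply(mag[, , , windows$pre, drop = FALSE], 1:3, mean)
  bad3 <- s0 <= 0 | apply(mag <= 0, 1:3, any)
  out <- array(0, dim(mag))
  te <- series$params$te
  for (t in seq_len(nt)) {
    fr <- -log(frame4(mag, t) / s0) / te
    fr[bad3] <- NA_real_
    out[, , , t] <- fr
  }
  attr(out, "invalid") <- bad3
  out
}

#' Blood susceptibility change from vessel phase
#'
#' Mean vessel-ROI phase in the baseline and steady-state windows is
#' converted with the infinite-cylinder relation
#' ([cylinder_susceptibility()]); the blood susceptibility change is the
#' post-minus-pre difference.  Phase differences are formed wrap-robustly:
#' each pixel's curve minus its baseline mean is re-wrapped into
#' (-pi, pi], so residual 2*pi unwrapping errors in vessel voxels cancel,
#' as long as the CA-induced vessel phase shift itself stays below pi.
#'
#' @param phase_corrected a drift-corrected unwrapped [field_series()]
#'   (rad), from [shift_phase()].
#' @param vessel a [vessel_roi()] (pixel indices and angle `theta`).
#' @param windows a [steady_state_windows()].
#' @param params an [acquisition_params()].
#' @return list with `delta_chi` (ppm), `chi_pre`, `chi_post`, and the
#'   window phase means.
#' @export
blood_delta_chi <- function(phase_corrected, vessel,
                            windows = steady_state_windows(),
                            params = acquisition_params()) {
  if (phase_corrected$unit != "rad")
    stop("vessel measurement expects phase in rad (unfiltered)")
  nt <- dim(phase_corrected$values)[4]
  curves <- pixel_curves(phase_corrected$values, vessel$pixels)
  blood_dchi_core(curves, vessel$theta, windows, params)
}

# curve-level core: vessel pixel curves (pixels x time), already
# drift-corrected; wrap-robust differencing against the baseline mean
blood_dchi_core <- function(curves, theta,
                            windows = steady_state_windows(),
                            params = acquisition_params()) {
  nt <- ncol(curves)
  idx <- window_indices(windows, nt)
  base <- rowMeans(curves[, idx$pre, drop = FALSE])
  rel <- wrap_to_pi(sweep(curves, 1L, base, "-"))
  phi_pre <- mean(rel[, idx$pre])
  phi_post <- mean(rel[, idx$post])
  chi_pre <- cylinder_susceptibility(phi_pre, theta, params)
  chi_post <- cylinder_susceptibility(phi_post, theta, params)
  list(delta_chi = chi_post - chi_pre, chi_pre = chi_pre,
       chi_post = chi_post, phi_pre = phi_pre, phi_post = phi_post)
}

new_cbv_result <- function(region, dct, dcb, cbv, method) {
  structure(list(region = region, delta_tissue = dct, delta_blood = dcb,
                 cbv = cbv, method = method),
            class = "cbv_result")
}

#' @export
print.cbv_result <- function(x, ...) {
  cat(sprintf("<cbv_result> %s [%s]: CBV %.3f mL/100g (d_tissue %.4g, d_blood %.4g)\n",
              x$region, x$method, x$cbv, x$delta_tissue, x$delta_blood))
  invisible(x)
}

#' Steady-state CBV from susceptibility differences
#'
#' `CBV = 100 * (1/rho) * (1-Hct_LV)/(1-Hct_SV) * dchi_tissue/dchi_blood`
#' in mL/100 g.
#'
#' @param delta_chi_tissue tissue susceptibility change (ppm).
#' @param delta_chi_blood blood susceptibility change (ppm); must be
#'   nonzero.
#' @param physio a [physio_constants()].
#' @param region label carried into the result.
#' @return a `cbv_result` (method `"qsm"`).
#' @export
cbv_qsm <- function(delta_chi_tissue, delta_chi_blood,
                    physio = physio_constants(), region = "tissue") {
  if (!is.finite(delta_chi_blood) || delta_chi_blood == 0)
    stop("blood susceptibility difference is zero: CBV undefined")
  cbv <- 100 / physio$rho * (1 - physio$hct_lv) / (1 - physio$hct_sv) *
    delta_chi_tissue / delta_chi_blood
  new_cbv_result(region, delta_chi_tissue, delta_chi_blood, cbv, "qsm")
}

#' Steady-state CBV from Delta-R2* (relaxivity-based analogue)
#'
#' `CBV = 100 (1-Hct_LV) dR2*_tissue / (rho (1-Hct_SV) dR2*_blood)`.
#' Assumes equal relaxivity in tissue and blood; since tissue r2* exceeds
#' blood r2* in vivo, this estimator overestimates CBV by that relaxivity
#' ratio -- the comparison with [cbv_qsm()] illustrates the relaxivity
#' problem that motivates susceptibility-based estimation.
#'
#' @param dr2s_tissue tissue Delta-R2* (s^-1).
#' @param dr2s_blood blood Delta-R2* (s^-1); nonzero.
#' @param physio a [physio_constants()].
#' @param region label.
#' @return a `cbv_result` (method `"dr2s"`).
#' @export
cbv_dr2s <- function(dr2s_tissue, dr2s_blood, physio = physio_constants(),
                     region = "tissue") {
  if (!is.finite(dr2s_blood) || dr2s_blood == 0)
    stop("blood Delta-R2* is zero: CBV undefined")
  cbv <- 100 * (1 - physio$hct_lv) * dr2s_tissue /
    (physio$rho * (1 - physio$hct_sv) * dr2s_blood)
  new_cbv_result(region, dr2s_tissue, dr2s_blood, cbv, "dr2s")
}

# post-minus-pre window difference of region-mean values of a 4D array
window_difference <- function(values4, mask, windows) {
  nt <- n_frames(values4)
  idx <- window_indices(windows, nt)
  m <- matrix(values4, nrow = prod(dim(values4)[1:3]))[which(mask), ,
                                                       drop = FALSE]
  curve <- colMeans(m, na.rm = TRUE)
  mean(curve[idx$post]) - mean(curve[idx$pre])
}

#' Regional steady-state CBV from a reconstructed study
#'
#' Tissue susceptibility changes are window means of the shifted
#' susceptibility series over the region masks; the blood change comes
#' from the drift-corrected unfiltered vessel phase (never from filtered
#' maps, which are unreliable near the brain edge).
#'
#' @param chi_shifted csf-shifted [susceptibility_series()].
#' @param phase_corrected drift-corrected unwrapped [field_series()].
#' @param masks named list of 3D region masks (e.g. wm, gm, brain).
#' @param vessel a [vessel_roi()].
#' @param windows a [steady_state_windows()].
#' @param params an [acquisition_params()].
#' @param physio a [physio_constants()].
#' @param regions which mask names to report.
#' @return data.frame with region, delta_chi_tissue, delta_chi_blood, cbv,
#'   method.
#' @export
cbv_regional <- function(chi_shifted, phase_corrected, masks, vessel,
                         windows = steady_state_windows(),
                         params = acquisition_params(),
                         physio = physio_constants(),
                         regions = c("wm", "gm", "brain")) {
  if (chi_shifted$reference_state != "csf_shifted")
    stop("cbv_regional requires a csf_shifted susceptibility series")
  blood <- blood_delta_chi(phase_corrected, vessel, windows, params)
  rows <- lapply(regions, function(rg) {
    dct <- window_difference(chi_shifted$chi, masks[[rg]], windows)
    res <- cbv_qsm(dct, blood$delta_chi, physio, region = rg)
    data.frame(region = rg, delta_chi_tissue = dct,
               delta_chi_blood = blood$delta_chi, cbv = res$cbv,
               method = "qsm", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the in vivo tissue relaxivity r2*
#'
#' Pools per-frame whole-mask means of Delta-R2* and concentration from
#' frame 15 to the end of the series (frames 1-4 are excluded for
#' saturation effects and 5-14 define zero concentration) and fits
#' ordinary least squares `DeltaR2* ~ [CA]`; the slope is r2*.
#'
#' @param dr2s_series 4D Delta-R2* array from [delta_r2star()].
#' @param conc_series 4D concentration array (mM).
#' @param mask 3D region mask to average over.
#' @param windows a [steady_state_windows()].
#' @return an object of class `relaxivity_fit`: slope r2* (mM^-1 s^-1),
#'   intercept (s^-1), correlation r, n_points.
#' @export
fit_relaxivity <- function(dr2s_series, conc_series, mask,
                           windows = steady_state_windows()) {
  nt <- n_frames(dr2s_series)
  pool_idx <- seq.int(max(windows$pre) + 1L, nt)
  if (length(pool_idx) < 3L) stop("need at least 3 pooled time points")
  nvox <- prod(dim(dr2s_series)[1:3])
  mdr <- matrix(dr2s_series, nrow = nvox)[which(mask), , drop = FALSE]
  mco <- matrix(conc_series, nrow = nvox)[which(mask), , drop = FALSE]
  y <- colMeans(mdr, na.rm = TRUE)[pool_idx]
  x <- colMeans(mco, na.rm = TRUE)[pool_idx]
  if (sd(x) < .Machine$double.eps^0.5)
    stop("degenerate fit: concentration is constant over the pooled frames")
  fit <- lm(y ~ x)
  r <- suppressWarnings(stats::cor(x, y))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, n_points = length(x),
                 conc = x, dr2s = y),
            class = "relaxivity_fit")
}

#' @export
print.relaxivity_fit <- function(x, ...) {
  cat(sprintf("<relaxivity_fit> r2* = %.2f mM^-1 s^-1 (intercept %.3f s^-1, r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n_points))
  invisible(x)
}

#' Theory-expected steady-state concentrations and susceptibility changes
#'
#' Expected-value arithmetic for the steady state: the blood tail
#' concentration is `peak / ratio`; blood `dchi = conc * chi_mol`; tissue
#' `dchi = (cbv/100) * rho * (1-Hct_SV)/(1-Hct_LV) * dchi_blood` (the CBV
#' relation inverted, using literature CBV values); tissue concentration
#' follows by dividing by `chi_mol` again.  Reported rounding: blood dchi
#' to 2 decimals, tissue dchi to 3 decimals (ppm).
#'
#' @param peak_conc_range range of assumed peak blood concentration (mM).
#' @param peak_to_tail_ratio peak-to-tail concentration ratio.
#' @param literature_cbv named vector of literature CBV values (mL/100 g),
#'   default `c(wm = 1.91, gm = 3.85)`.
#' @param physio a [physio_constants()].
#' @return data.frame with compartment, bound (lower/upper), concentration
#'   (mM), delta_chi (ppm) and the rounded report values.
#' @export
theory_expected_values <- function(peak_conc_range = c(5, 10),
                                   peak_to_tail_ratio = 9,
                                   literature_cbv = c(wm = 1.91, gm = 3.85),
                                   physio = physio_constants()) {
  if (peak_to_tail_ratio <= 1) stop("peak_to_tail_ratio must exceed 1")
  tail_conc <- sort(peak_conc_range) / peak_to_tail_ratio
  bounds <- c("lower", "upper")[seq_along(tail_conc)]
  rows <- list()
  dchi_blood <- conc_to_ppm(tail_conc, physio$chi_mol)
  rows[["blood"]] <- data.frame(
    compartment = "blood", bound = bounds, concentration = tail_conc,
    delta_chi = dchi_blood,
    delta_chi_report = round_half_up(dchi_blood * 100) / 100,
    stringsAsFactors = FALSE)
  for (rg in names(literature_cbv)) {
    dchi_t <- literature_cbv[[rg]] / 100 * physio$rho *
      (1 - physio$hct_sv) / (1 - physio$hct_lv) * dchi_blood
    rows[[rg]] <- data.frame(
      compartment = rg, bound = bounds,
      concentration = ppm_to_conc(dchi_t, physio$chi_mol),
      delta_chi = dchi_t,
      delta_chi_report = round_half_up(dchi_t * 1000) / 1000,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
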