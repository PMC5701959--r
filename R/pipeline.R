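#' Reconstruct susceptibility maps from a dynamic series
#'
#' Runs the reconstruction chain: quality-guided unwrapping over the
#' signal region, background-field removal (exterior dipole fit), and
#' per-frame dipole inversion.  The returned bundle carries every stage
#' plus curve summaries used by the reference-selection and quantification
#' steps.
#'
#' @param series a [dynamic_series()].
#' @param masks phantom-style mask list (needs `brain`, `csf`, and region
#'   masks for summaries).
#' @param vessel optional [vessel_roi()] for blood-phase summaries.
#' @param inv_cfg an [inversion_config()].
#' @param windows a [steady_state_windows()] (baseline magnitude map).
#' @param pdf_gap,pdf_tol,pdf_max_iter background-removal controls (see
#'   [remove_background_pdf()]).
#' @param signal_frac unwrapping region: voxels with baseline magnitude
#'   above this fraction of the brain mean.
#' @return an object of class `qsm_recon`.
#' @export
reconstruct_series <- function(series, masks, vessel = NULL,
                               inv_cfg = inversion_config(),
                               windows = steady_state_windows(),
                               pdf_gap = NULL, pdf_tol = 1e-3,
                               pdf_max_iter = 0L, pdf_max_iter_ref = 60L,
                               signal_frac = 0.25) {
  params <- series$params
  pre_idx <- windows$pre
  mag_ref <- apply(series$magnitude[, , , pre_idx, drop = FALSE], 1:3, mean)
  sig_mask <- mag_ref > signal_frac * mean(mag_ref[masks$brain])
  sig_mask <- sig_mask | masks$brain
  unwrapped <- unwrap_phase(series, sig_mask)
  w <- mag_ref
  w[!sig_mask] <- 0
  # exclude voxels whose unwrapped phase is temporally unstable over the
  # pre-contrast baseline: nothing changes there physically except uniform
  # drift and noise, so high variance marks unreliable (aliased) unwrapping,
  # e.g. at steep field gradients near the skull.  Their field values are
  # replaced by the model-consistent completion downstream.
  nb <- length(pre_idx)
  mb <- matrix(unwrapped$values[, , , pre_idx], ncol = nb)
  sdv <- sqrt(pmax(0, (rowMeans(mb^2) - rowMeans(mb)^2) * nb / (nb - 1)))
  sd_map <- array(sdv, dim(mag_ref))
  unstable <- sd_map > pmax(0.25, 6 * median(sd_map[masks$brain]))
  w[unstable] <- 0
  local <- remove_background_pdf(unwrapped, masks$brain, weight = w,
                                 gap = pdf_gap, tol = pdf_tol,
                                 max_iter = pdf_max_iter,
                                 max_iter_ref = pdf_max_iter_ref,
                                 ref_frames = windows$pre)
  chi <- invert_dipole(local, mag_ref, masks$brain, inv_cfg)
  xtalk <- if (inv_cfg$method == "tkd" &&
               all(c("wm", "gm", "vessel", "csf") %in% names(masks)))
    region_crosstalk_matrix(masks, w > 0, params, inv_cfg)
  # finite-vessel geometry calibration for the phase-based blood
  # measurement: the infinite-cylinder relation overstates the interior
  # field of the actual (finite, clipped) vessel; the ratio of the true
  # geometric response at the ROI pixels to the infinite-cylinder factor
  # corrects the deterministic bias.  Uses only the masks.
  vessel_cal <- NULL
  if (!is.null(vessel) && !is.null(masks$vessel)) {
    fv <- forward_field(array(as.numeric(masks$vessel), dim(mag_ref)),
                        params$voxel_size)
    geom <- (3 * cos(vessel$theta)^2 - 1) / 6
    vessel_cal <- (mean(fv[vessel$pixels]) - mean(fv[masks$csf])) / geom
  }
  rec <- structure(
    list(field_unwrapped = unwrapped, local_field = local, chi = chi,
         masks = masks, vessel = vessel, params = params,
         magnitude_ref = mag_ref, crosstalk = xtalk,
         vessel_cal = vessel_cal,
         magnitude = series$magnitude),
    class = "qsm_recon")
  rec$summary <- summarize_recon(rec, series)
  rec
}

#' @export
print.qsm_recon <- function(x, ...) {
  cat("<qsm_recon>", paste(dim(x$chi$chi)[1:3], collapse = "x"), "x",
      dim(x$chi$chi)[4], "| inversion:", x$chi$diagnostics$method, "\n")
  invisible(x)
}

#' Reduce a reconstruction to the curves needed for quantification
#'
#' Extracts the per-pixel and region-mean time curves that the CSF
#' reference selection, shifting, and CBV quantification consume, so that
#' sweep analyses over many subjects do not need the full 4D arrays.
#'
#' @param recon a `qsm_recon` bundle.
#' @param series the originating [dynamic_series()].
#' @param regions region masks to summarize.
#' @return an object of class `recon_summary`.
#' @export
summarize_recon <- function(recon, series,
                            regions = c("wm", "gm", "brain")) {
  masks <- recon$masks
  roi <- candidate_roi(masks)
  chi4 <- recon$chi$chi
  structure(
    list(
      csf_roi = roi,
      mag_roi = pixel_curves(series$magnitude, roi),
      chi_roi = pixel_curves(chi4, roi),
      phase_roi = pixel_curves(recon$field_unwrapped$values, roi),
      chi_brain_mean = region_mean_curve(chi4, masks$brain),
      mag_brain_mean = region_mean_curve(series$magnitude, masks$brain),
      chi_region = stats::setNames(
        lapply(regions, function(rg) region_mean_curve(chi4, masks[[rg]])),
        regions),
      phase_vessel = if (!is.null(recon$vessel))
        pixel_curves(recon$field_unwrapped$values, recon$vessel$pixels),
      vessel_theta = if (!is.null(recon$vessel)) recon$vessel$theta,
      crosstalk = recon$crosstalk,
      vessel_cal = recon$vessel_cal,
      params = recon$params
    ),
    class = "recon_summary")
}

#' Select the CSF reference and quantify regional CBV
#'
#' Applies the three reference-selection criteria, anchors the
#' susceptibility curves, drift-corrects the vessel phase with the same
#' reference, and evaluates the steady-state CBV relation per region.
#' Operates on a `recon_summary` (or a full `qsm_recon`, whose summary is
#' used).
#'
#' @param rec a `recon_summary` or `qsm_recon`.
#' @param cfg a [reference_config()].
#' @param windows a [steady_state_windows()].
#' @param physio a [physio_constants()].
#' @param regions regions to report.
#' @param crosstalk apply the regional cross-talk correction
#'   ([region_crosstalk_matrix()]) when the reconstruction bundle carries
#'   it: the raw region-mean susceptibility differences are deconvolved
#'   through the inversion's regional response matrix, with the vessel
#'   contribution fixed by the phase-based blood measurement.
#' @return list with `selection`, `blood` (vessel measurement), `shift`
#'   (per-frame susceptibility shift) and `cbv` (regional data.frame with
#'   both raw and reported tissue differences).
#' @export
quantify_cbv <- function(rec, cfg = reference_config(),
                         windows = steady_state_windows(),
                         physio = physio_constants(),
                         regions = c("wm", "gm", "brain"),
                         crosstalk = TRUE) {
  if (inherits(rec, "qsm_recon")) rec <- rec$summary
  if (!inherits(rec, "recon_summary"))
    stop("quantify_cbv expects a qsm_recon or recon_summary")
  regions <- intersect(regions, names(rec$chi_region))
  roi <- rec$csf_roi
  rng <- apply(rec$mag_roi, 1L, function(v) max(v) - min(v))
  kept2 <- criterion2_core(rng, roi, cfg$thresh_range)
  rows2 <- match(kept2, roi)
  sel <- criterion3_core(rec$chi_brain_mean,
                         rec$chi_roi[rows2, , drop = FALSE], kept2,
                         rec$mag_brain_mean, cfg, windows$pre)
  sel$signal_range <- stats::setNames(rng, roi)
  rows_sel <- match(sel$pixels, roi)
  sh <- shift_curve_core(colMeans(rec$chi_roi[rows_sel, , drop = FALSE]),
                         windows$pre)
  nt <- length(sh)
  idx <- window_indices(windows, nt)
  blood <- NULL
  cbv_rows <- list()
  if (!is.null(rec$phase_vessel)) {
    ph_sh <- shift_curve_core(
      colMeans(rec$phase_roi[rows_sel, , drop = FALSE]), windows$pre)
    vessel_corr <- sweep(rec$phase_vessel, 2L, ph_sh, "-")
    blood <- blood_dchi_core(vessel_corr, rec$vessel_theta, windows,
                             rec$params)
    if (isTRUE(crosstalk) && !is.null(rec$vessel_cal) &&
        is.finite(rec$vessel_cal) && rec$vessel_cal > 0.2) {
      blood$delta_chi_raw <- blood$delta_chi
      blood$delta_chi <- blood$delta_chi / rec$vessel_cal
      blood$geometry_factor <- rec$vessel_cal
    }
    raw <- vapply(regions, function(rg) {
      curve <- rec$chi_region[[rg]] - sh
      mean(curve[idx$post]) - mean(curve[idx$pre])
    }, numeric(1))
    rep_val <- raw
    if (isTRUE(crosstalk) && !is.null(rec$crosstalk) &&
        all(c("wm", "gm") %in% regions)) {
      M <- rec$crosstalk$M
      fr <- rec$crosstalk$frac
      y <- raw[c("wm", "gm")] -
        blood$delta_chi * M[c("wm", "gm"), "vessel"]
      a <- solve(M[c("wm", "gm"), c("wm", "gm")], y)
      rep_val["wm"] <- a["wm"]
      rep_val["gm"] <- a["gm"]
      if ("brain" %in% regions)
        rep_val["brain"] <- a["wm"] * fr[["wm"]] + a["gm"] * fr[["gm"]] +
          blood$delta_chi * fr[["vessel"]]
    }
    for (rg in regions) {
      res <- cbv_qsm(rep_val[[rg]], blood$delta_chi, physio, region = rg)
      cbv_rows[[rg]] <- data.frame(region = rg,
                                   delta_chi_tissue = rep_val[[rg]],
                                   delta_chi_tissue_raw = raw[[rg]],
                                   delta_chi_blood = blood$delta_chi,
                                   cbv = res$cbv, method = "qsm",
                                   stringsAsFactors = FALSE)
    }
  }
  list(selection = sel, blood = blood, shift = sh,
       cbv = if (length(cbv_rows)) do.call(rbind, cbv_rows))
}

#' Simulate and reconstruct a test-retest cohort
#'
#' Each subject gets a seed-jittered phantom with a subject-specific
#' global CBV scale; each of the two visits is simulated with independent
#' noise, drift and bolus-shape jitter (and, optionally, independent CSF
#' phase-spike artifacts), reconstructed, and reduced to a
#' [summarize_recon()] bundle.
#'
#' @param n_subjects number of subjects.
#' @param grid_shape phantom grid.
#' @param params an [acquisition_params()].
#' @param physio a [physio_constants()].
#' @param noise_sd complex noise fraction (1/SNR).
#' @param csf_spike_frac,csf_spike_amp CSF artifact controls
#'   (see [simulate_series()]).
#' @param cbv_scale_sd between-subject SD of the global CBV scale.
#' @param peak_conc bolus peak concentration (mM).
#' @param bolus_jitter relative between-visit bolus shape jitter.
#' @param inv_cfg an [inversion_config()].
#' @param windows a [steady_state_windows()].
#' @param seed master seed.
#' @return list with `subjects` (each `visit1`/`visit2` summaries plus the
#'   true CBV scale) and `truth` (data.frame).
#' @export
simulate_retest_cohort <- function(n_subjects = 5L,
                                   grid_shape = c(40L, 40L, 40L),
                                   params = acquisition_params(),
                                   physio = physio_constants(),
                                   noise_sd = 0.02,
                                   csf_spike_frac = 0,
                                   csf_spike_amp = 1.5,
                                   cbv_scale_sd = 0.15,
                                   peak_conc = 5,
                                   bolus_jitter = 0.05,
                                   inv_cfg = inversion_config(),
                                   windows = steady_state_windows(),
                                   seed = 1L) {
  scales <- with_seed(seed, pmax(0.5, 1 + rnorm(n_subjects, 0, cbv_scale_sd)))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ph <- build_phantom(grid_shape, seed = seed + 1000L * s,
                        cbv_scale = scales[s])
    vr <- vessel_roi(ph)
    visits <- lapply(1:2, function(v) {
      vseed <- seed + 1000L * s + v
      blood <- simulate_blood_curve(params, peak_conc = peak_conc,
                                    seed = vseed, jitter = bolus_jitter)
      ser <- simulate_series(ph, blood, params, physio,
                             noise_sd = noise_sd, seed = vseed,
                             csf_spike_frac = csf_spike_frac,
                             csf_spike_amp = csf_spike_amp)
      rec <- reconstruct_series(ser, ph$masks, vr, inv_cfg, windows)
      rec$summary
    })
    subjects[[s]] <- list(visit1 = visits[[1]], visit2 = visits[[2]],
                          cbv_scale = scales[s])
  }
  list(subjects = subjects,
       truth = data.frame(subject = seq_len(n_subjects),
                          cbv_scale = scales))
}

#' Assemble a full run configuration
#'
#' Collects every stage parameter into one nested list that serializes
#' losslessly to JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param grid_shape phantom grid dimensions.
#' @param seed master seed.
#' @param noise_sd complex noise fraction.
#' @param peak_conc,peak_to_tail_ratio bolus parameters (mM, ratio).
#' @param cbv_scale phantom CBV scale.
#' @param csf_spike_frac,csf_spike_amp CSF artifact controls.
#' @param acquisition an [acquisition_params()].
#' @param physio a [physio_constants()].
#' @param inversion an [inversion_config()].
#' @param reference a [reference_config()].
#' @param windows a [steady_state_windows()].
#' @param out_dir optional output directory for artifacts.
#' @return an object of class `run_config`.
#' @export
run_config <- function(grid_shape = c(64L, 64L, 64L), seed = 1L,
                       noise_sd = 0, peak_conc = 5, peak_to_tail_ratio = 9,
                       cbv_scale = 1, csf_spike_frac = 0,
                       csf_spike_amp = 1.5,
                       acquisition = acquisition_params(),
                       physio = physio_constants(),
                       inversion = inversion_config(),
                       reference = reference_config(),
                       windows = steady_state_windows(),
                       out_dir = NULL) {
  structure(
    list(grid_shape = as.integer(grid_shape), seed = as.integer(seed),
         noise_sd = noise_sd, peak_conc = peak_conc,
         peak_to_tail_ratio = peak_to_tail_ratio, cbv_scale = cbv_scale,
         csf_spike_frac = csf_spike_frac, csf_spike_amp = csf_spike_amp,
         acquisition = acquisition, physio = physio, inversion = inversion,
         reference = reference, windows = windows, out_dir = out_dir),
    class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' simulate -> unwrap -> background removal -> inversion -> CSF reference
#' selection -> shift -> concentration / Delta-R2* / CBV.  Deterministic
#' given the configuration seed.  If `config$out_dir` is set, artifacts
#' (NIfTI volumes, regional CBV CSV, selection diagnostics CSV, resolved
#' config and log JSON) are written there.
#'
#' @param config a [run_config()].
#' @param keep_volumes keep the derived 4D volumes (shifted
#'   susceptibility, concentration, Delta-R2*) in the returned bundle;
#'   defaults to on only when artifacts are written, since these arrays
#'   are large.
#' @return list with the phantom, series, reconstruction bundle,
#'   quantification result, relaxivity fit and regional CBV table.
#' @export
run_pipeline <- function(config = run_config(),
                         keep_volumes = !is.null(config$out_dir)) {
  stopifnot(inherits(config, "run_config"))
  params <- config$acquisition
  physio <- config$physio
  windows <- config$windows
  phantom <- build_phantom(config$grid_shape, seed = config$seed,
                           cbv_scale = config$cbv_scale)
  if (is.null(phantom$masks$csf) || !any(phantom$masks$csf))
    stop("csf_reference: no CSF mask available for reference selection")
  blood <- simulate_blood_curve(params, peak_conc = config$peak_conc,
                                peak_to_tail_ratio = config$peak_to_tail_ratio,
                                seed = config$seed)
  series <- simulate_series(phantom, blood, params, physio,
                            noise_sd = config$noise_sd, seed = config$seed,
                            csf_spike_frac = config$csf_spike_frac,
                            csf_spike_amp = config$csf_spike_amp)
  vr <- vessel_roi(phantom)
  recon <- reconstruct_series(series, phantom$masks, vr, config$inversion,
                              windows)
  quant <- quantify_cbv(recon, config$reference, windows, physio)
  chi_shifted <- shift_susceptibility(recon$chi, quant$selection, windows)
  conc <- concentration_from_susceptibility(chi_shifted, windows, physio)
  dr2s <- delta_r2star(series, windows)
  tissue_mask <- phantom$masks$wm | phantom$masks$gm
  relax <- fit_relaxivity(dr2s, conc, tissue_mask, windows)
  out <- list(config = config, phantom = phantom, blood = blood,
              series = series, recon = recon, quant = quant,
              chi_shifted = chi_shifted, concentration = conc,
              delta_r2star = dr2s, relaxivity = relax, cbv = quant$cbv)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  if (!keep_volumes) {
    out$chi_shifted <- NULL
    out$concentration <- NULL
    out$delta_r2star <- NULL
    out$recon$field_unwrapped$values <- NULL
    out$recon$local_field$values <- NULL
  }
  invisible(out)
}
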