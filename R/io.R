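#' Write a dynamic series as paired 4D NIfTI files
#'
#' @param series a [dynamic_series()].
#' @param magnitude_path,phase_path output NIfTI paths.
#' @return the paths, invisibly.
#' @export
write_series <- function(series, magnitude_path, phase_path) {
  vs <- series$params$voxel_size
  pd <- c(vs, series$params$dt)
  RNifti::writeNifti(RNifti::asNifti(series$magnitude, pixdim = pd),
                     magnitude_path)
  RNifti::writeNifti(RNifti::asNifti(series$phase, pixdim = pd), phase_path)
  invisible(c(magnitude_path, phase_path))
}

#' Read a dynamic series from paired NIfTI files
#'
#' Validates that magnitude and phase share a grid, and re-wraps the phase
#' to (-pi, pi] if it is stored in another convention.  The phase dialect
#' is detected by a range heuristic: values beyond pi but within ~360 are
#' taken as degrees; within ~2*pi as unwrapped radians (re-wrapped); an
#' explicit `phase_units` overrides the heuristic.
#'
#' @param magnitude_path,phase_path NIfTI paths.
#' @param params optional [acquisition_params()]; if `NULL`, a default
#'   parameter set is built with the frame count and pixdim from the file.
#' @param phase_units `"auto"`, `"rad"` or `"deg"`.
#' @return a [dynamic_series()].
#' @export
read_series <- function(magnitude_path, phase_path, params = NULL,
                        phase_units = c("auto", "rad", "deg")) {
  phase_units <- match.arg(phase_units)
  if (!file.exists(magnitude_path)) stop("magnitude file not found: ",
                                         magnitude_path)
  if (!file.exists(phase_path)) stop("phase file not found: ", phase_path)
  mag <- RNifti::readNifti(magnitude_path)
  ph <- RNifti::readNifti(phase_path)
  if (!identical(dim(mag), dim(ph)))
    stop("magnitude and phase grids differ: ",
         paste(dim(mag), collapse = "x"), " vs ",
         paste(dim(ph), collapse = "x"))
  if (length(dim(mag)) != 4L)
    stop("expected 4D dynamic volumes, got ", length(dim(mag)), "D")
  hdr <- RNifti::niftiHeader(mag)
  if (is.null(params)) {
    params <- acquisition_params(
      n_timepoints = dim(mag)[4],
      dt = if (hdr$pixdim[5] > 0) hdr$pixdim[5] else 1.24,
      voxel_size = hdr$pixdim[2:4])
  } else if (params$n_timepoints != dim(mag)[4]) {
    stop("time dimension mismatch: params expect ", params$n_timepoints,
         " frames, file has ", dim(mag)[4])
  }
  ph <- array(as.numeric(ph), dim(ph))
  mag <- array(as.numeric(mag), dim(mag))
  mx <- max(abs(ph))
  if (phase_units == "deg" || (phase_units == "auto" && mx > 2 * pi + 0.1
                               && mx <= 361)) {
    ph <- ph * pi / 180
  }
  ph <- wrap_to_pi(ph)
  dynamic_series(mag, ph, params)
}

# phantom compartment labels used in the exported label volume
phantom_labels <- c(air = 0L, soft = 1L, skull = 2L, wm = 3L, gm = 4L,
                    csf = 5L, vessel = 6L)

#' Write phantom ground truth to disk
#'
#' Integer compartment labels, true CBV, baseline susceptibility/relaxation
#' and signal maps as 3D NIfTI, plus a JSON sidecar with all scalar
#' parameters and the seed.
#'
#' @param phantom a [build_phantom()] object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- phantom$masks
  lab <- array(0L, phantom$grid_shape)
  lab[m$head] <- phantom_labels[["soft"]]
  lab[m$skull] <- phantom_labels[["skull"]]
  lab[m$wm] <- phantom_labels[["wm"]]
  lab[m$gm] <- phantom_labels[["gm"]]
  lab[m$csf] <- phantom_labels[["csf"]]
  lab[m$vessel] <- phantom_labels[["vessel"]]
  RNifti::writeNifti(RNifti::asNifti(lab), file.path(dir, "labels.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$cbv_map),
                     file.path(dir, "cbv_true.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$chi0_map),
                     file.path(dir, "chi0.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$s0_map),
                     file.path(dir, "s0.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$r2s0_map),
                     file.path(dir, "r2s0.nii.gz"))
  side <- list(grid_shape = phantom$grid_shape, seed = phantom$seed,
               cbv_scale = phantom$cbv_scale,
               vessel_angle = phantom$vessel_angle,
               r2s_tissue_relaxivity = phantom$r2s_tissue_relaxivity,
               r2s_blood_relaxivity = phantom$r2s_blood_relaxivity,
               labels = as.list(phantom_labels))
  jsonlite::write_json(side, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# minimal polynomial rolling hash of a string, for provenance stamps
poly_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_to_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), config_to_list) else x
}

#' Serialize / restore a run configuration
#'
#' The configuration round-trips losslessly through JSON; every pipeline
#' run writes the fully resolved configuration it used, together with a
#' content hash for provenance.
#'
#' @param config a [run_config()].
#' @param path JSON path.
#' @return `write_run_config` returns the path; `read_run_config` returns
#'   the restored `run_config`; `config_hash` the provenance hash string.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    grid_shape = x$grid_shape, seed = x$seed, noise_sd = x$noise_sd,
    peak_conc = x$peak_conc, peak_to_tail_ratio = x$peak_to_tail_ratio,
    cbv_scale = x$cbv_scale, csf_spike_frac = x$csf_spike_frac,
    csf_spike_amp = x$csf_spike_amp,
    acquisition = do.call(acquisition_params, x$acquisition),
    physio = do.call(physio_constants, x$physio),
    inversion = do.call(inversion_config, x$inversion),
    reference = do.call(reference_config, x$reference),
    windows = do.call(steady_state_windows, x$windows),
    out_dir = if (!is.null(x$out_dir) && length(x$out_dir)) x$out_dir)
}

#' @rdname write_run_config
#' @export
config_hash <- function(config) {
  poly_hash(jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                             digits = NA))
}

# write the artifact bundle of a pipeline run
write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- out$config
  write_series(out$series, file.path(dir, "magnitude.nii.gz"),
               file.path(dir, "phase.nii.gz"))
  write_phantom(out$phantom, file.path(dir, "phantom"))
  vs <- cfg$acquisition$voxel_size
  RNifti::writeNifti(RNifti::asNifti(out$chi_shifted$chi,
                                     pixdim = c(vs, cfg$acquisition$dt)),
                     file.path(dir, "chi_shifted.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(out$concentration,
                                     pixdim = c(vs, cfg$acquisition$dt)),
                     file.path(dir, "concentration.nii.gz"))
  sel_mask <- array(0L, cfg$grid_shape)
  sel_mask[out$quant$selection$pixels] <- 1L
  RNifti::writeNifti(RNifti::asNifti(sel_mask),
                     file.path(dir, "csf_reference.nii.gz"))
  utils::write.csv(out$cbv, file.path(dir, "cbv_regional.csv"),
                   row.names = FALSE)
  sel <- out$quant$selection
  diag_df <- data.frame(pixel = as.integer(names(sel$tailpeak_ratio)),
                        tailpeak_ratio = as.numeric(sel$tailpeak_ratio))
  diag_df$selected <- diag_df$pixel %in% sel$pixels
  diag_df$signal_range <-
    sel$signal_range[as.character(diag_df$pixel)]
  utils::write.csv(diag_df, file.path(dir, "csf_selection_diagnostics.csv"),
                   row.names = FALSE)
  write_run_config(cfg, file.path(dir, "config.json"))
  log <- list(config_hash = config_hash(cfg),
              seed = cfg$seed,
              n_reference_pixels = length(sel$pixels),
              pdf_iters = out$recon$local_field$diagnostics$pdf_iters,
              pdf_rel = out$recon$local_field$diagnostics$pdf_rel,
              unwrap_suspect = out$recon$field_unwrapped$diagnostics$n_suspect,
              unwrap_residues = out$recon$field_unwrapped$diagnostics$n_residue,
              relaxivity_slope = out$relaxivity$slope,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
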