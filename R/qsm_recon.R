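#' Field series container
#'
#' 4D field data at a known processing stage.  `unit` is `"rad"` directly
#' after unwrapping and `"ppm"` once converted; `stage` moves forward only
#' (`unwrapped` -> `background-removed`).
#'
#' @param values 4D array.
#' @param mask 3D brain mask.
#' @param stage processing stage.
#' @param unit `"rad"` or `"ppm"`.
#' @param params acquisition parameters carried along.
#' @param diagnostics per-frame diagnostics list.
#' @return an object of class `field_series`.
#' @export
field_series <- function(values, mask, stage = c("unwrapped",
                                                 "background-removed"),
                         unit = c("rad", "ppm"), params = NULL,
                         diagnostics = list()) {
  stage <- match.arg(stage)
  unit <- match.arg(unit)
  structure(list(values = values, mask = mask, stage = stage, unit = unit,
                 params = params, diagnostics = diagnostics),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<field_series>", paste(d[1:3], collapse = "x"), "x", d[4],
      "| stage:", x$stage, "| unit:", x$unit, "\n")
  invisible(x)
}

#' Susceptibility series container
#'
#' @param chi 4D susceptibility array (ppm).
#' @param mask 3D brain mask.
#' @param reference_state `"unshifted"` (absolute level arbitrary per frame)
#'   or `"csf_shifted"` (anchored to the CSF reference).
#' @param diagnostics reconstruction diagnostics.
#' @return an object of class `susceptibility_series`.
#' @export
susceptibility_series <- function(chi, mask,
                                  reference_state = c("unshifted",
                                                      "csf_shifted"),
                                  diagnostics = list()) {
  reference_state <- match.arg(reference_state)
  structure(list(chi = chi, mask = mask, reference_state = reference_state,
                 diagnostics = diagnostics),
            class = "susceptibility_series")
}

#' @export
print.susceptibility_series <- function(x, ...) {
  d <- dim(x$chi)
  cat("<susceptibility_series>", paste(d[1:3], collapse = "x"), "x", d[4],
      "| reference:", x$reference_state, "\n")
  invisible(x)
}

# local phase-gradient coherence weighted by magnitude: high where the
# wrapped gradients are spatially consistent and signal is strong
unwrap_quality <- function(phase, magnitude) {
  v <- array(0, dim(phase))
  for (ax in 1:3) {
    gp <- wrap_to_pi(shift3(phase, ax, 1L) - phase)
    gm <- wrap_to_pi(phase - shift3(phase, ax, -1L))
    v <- v + (gp - gm)^2
  }
  magnitude / (1 + v)
}

#' Quality-guided phase unwrapping of a dynamic series
#'
#' Region-growing unwrapping per time point, admitting voxels in order of
#' decreasing quality (local wrapped-phase-gradient coherence weighted by
#' magnitude), so the less noisy regions are unwrapped first.  On clean data
#' the output differs from the true phase by a single 2*pi multiple per
#' connected region.  Voxels reached through a neighbour step whose
#' unwrapped difference is large are flagged as suspect rather than
#' silently accepted (spatial jumps above pi are indistinguishable from
#' wraps); per-frame suspect and residue counts are reported in
#' `diagnostics`.
#'
#' @param series a [dynamic_series()] object.
#' After the per-frame spatial unwrap, a temporal-consistency correction
#' replaces each voxel's value at frame t by the 2*pi-congruent value
#' nearest its baseline phase (the automated counterpart of correcting
#' obvious residual wraps by hand).  This removes the arbitrary global
#' branch of each frame and repairs frame-to-frame branch flips in steep
#' regions (e.g. vessel edges once the contrast agent arrives), and is
#' exact wherever the true temporal phase change stays below pi -- which
#' holds in tissue and, at steady state, in the vessel.
#'
#' @param mask region to unwrap (default: voxels with non-negligible
#'   signal).  Must be non-empty and within the volume.
#' @param suspect_thresh neighbour-difference threshold (rad) above which a
#'   voxel is flagged (default 0.8*pi).
#' @param temporal_anchor apply the temporal-consistency correction.
#' @param anchor_frames frames whose mean defines the baseline phase
#'   (default 5-14, clipped to the series length).
#' @param count_residues also count 2x2-loop phase residues per frame
#'   (extra diagnostic, off by default).
#' @return a [field_series()] with `stage = "unwrapped"`, `unit = "rad"`.
#' @export
unwrap_phase <- function(series, mask = NULL, suspect_thresh = 0.8 * pi,
                         temporal_anchor = TRUE, anchor_frames = 5:14,
                         count_residues = FALSE) {
  dm <- dim(series$phase)[1:3]
  if (is.null(mask)) {
    m1 <- frame4(series$magnitude, 1L)
    mask <- m1 > 0.1 * mean(m1)
  }
  mask <- stopifnot_mask(mask, dm)
  if (!any(mask)) stop("empty mask: nothing to unwrap")
  nt <- n_frames(series$phase)
  out <- array(0, dim(series$phase))
  n_suspect <- integer(nt)
  n_residue <- integer(nt)
  for (t in seq_len(nt)) {
    ph <- frame4(series$phase, t)
    mg <- frame4(series$magnitude, t)
    q <- unwrap_quality(ph, mg)
    res <- .unwrap3d_cpp(as.numeric(ph), as.numeric(q), as.logical(mask),
                         as.integer(dm), suspect_thresh)
    out[, , , t] <- array(res$unwrapped, dm)
    n_suspect[t] <- res$n_suspect
    if (count_residues)
      n_residue[t] <- .count_residues_cpp(as.numeric(ph), as.integer(dm))
  }
  if (isTRUE(temporal_anchor) && nt > 1L) {
    af <- anchor_frames[anchor_frames <= nt]
    if (!length(af)) af <- 1L
    # align the anchor frames' global branches to the first of them, then
    # anchor every frame to the mean baseline phase
    base <- frame4(out, af[1])
    if (length(af) > 1L) {
      acc <- base
      for (t in af[-1]) {
        fr <- frame4(out, t)
        k <- round(mean((fr - base)[mask]) / (2 * pi))
        acc <- acc + fr - 2 * pi * k
      }
      base <- acc / length(af)
    }
    for (t in seq_len(nt))
      out[, , , t] <- base + wrap_to_pi(frame4(out, t) - base)
  }
  field_series(out, mask, stage = "unwrapped", unit = "rad",
               params = series$params,
               diagnostics = list(n_suspect = n_suspect,
                                  n_residue = n_residue,
                                  suspect_thresh = suspect_thresh))
}

# conjugate gradient on the normal equations of the exterior-source fit
pdf_fit_cg <- function(f, W2, sup, D, tol, max_iter, x0 = NULL) {
  Aop <- function(x) {
    y <- ifft_re(D * fft(W2 * ifft_re(D * fft(x))))
    y[!sup] <- 0
    y
  }
  b <- ifft_re(D * fft(W2 * f))
  b[!sup] <- 0
  x <- if (is.null(x0)) array(0, dim(f)) else x0
  r <- b - Aop(x)
  p <- r
  rs <- sum(r * r)
  rs0 <- sum(b * b)
  it <- 0L
  while (it < max_iter && rs > tol^2 * rs0) {
    Ap <- Aop(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- sum(r * r)
    p <- r + (rs2 / rs) * p
    rs <- rs2
    it <- it + 1L
  }
  list(x = x, iters = it, rel = sqrt(rs / max(rs0, .Machine$double.eps)))
}

#' Background-field removal by projection onto exterior dipole fields
#'
#' Fits a susceptibility distribution supported outside the brain mask
#' (excluding a guard gap of `gap` dilation steps around the mask) to the
#' measured field by magnitude-weighted least squares over the full volume,
#' and subtracts the fitted sources' field.  Weighting by the magnitude
#' uses the phase information wherever there is signal: voxels outside the
#' object contribute negligible weight, while the scalp/skull region
#' constrains the exterior sources.  The guard gap keeps boundary-hugging
#' source layers -- which could mimic interior-generated harmonic fields
#' while producing almost no exterior field -- out of the admissible set,
#' so the interior local field is retained.  The field is first demeaned
#' over the mask (weighted), making the output invariant to spatially
#' uniform offsets.
#'
#' @param field a [field_series()] at stage `"unwrapped"` (rad or ppm).
#' @param mask brain mask (defaults to the mask stored in `field`).
#' @param weight 3D weight map, typically the time-averaged magnitude.  If
#'   `NULL`, uniform weight inside the mask (plus a small exterior floor).
#' @param gap guard gap in dilation steps; default scales with grid size.
#' @param tol,max_iter conjugate-gradient stopping controls for the
#'   per-frame refinement.
#' @param max_iter_ref iterations for the shared reference fit on the
#'   time-mean field.  Every frame is then refined from that common
#'   starting point with identical solver settings, so the static
#'   background's fit is frame-independent and cancels exactly in temporal
#'   differences of the local field.
#' @return a [field_series()] with `stage = "background-removed"`,
#'   `unit = "ppm"`; per-frame solver iterations, relative residuals and a
#'   convergence flag are in `diagnostics`.
#' @export
remove_background_pdf <- function(field, mask = NULL, weight = NULL,
                                  gap = NULL, tol = 1e-3, max_iter = 0L,
                                  max_iter_ref = 60L, ref_frames = NULL,
                                  n_complete = 3L, mask_output = FALSE) {
  if (!inherits(field, "field_series") || field$stage != "unwrapped")
    stop("remove_background_pdf expects a field_series at stage 'unwrapped'")
  if (is.null(mask)) mask <- field$mask
  dm <- dim(field$values)[1:3]
  mask <- stopifnot_mask(mask, dm)
  vals <- field$values
  if (field$unit == "rad") {
    if (is.null(field$params))
      stop("cannot convert rad to ppm: no acquisition params attached")
    vals <- phase_to_field(vals, field$params)
  }
  if (is.null(gap)) gap <- max(3L, round(0.09 * min(dm)))
  sup <- !dilate_mask(mask, gap)
  if (!any(sup))
    stop("guard gap leaves no exterior support; reduce gap or enlarge grid")
  if (is.null(weight)) {
    weight <- array(0.05, dm)
    weight[mask] <- 1
  }
  W2 <- weight^2
  wm_in <- sum(W2[mask])
  voxel_size <- if (!is.null(field$params)) field$params$voxel_size
                else c(1, 1, 1)
  D <- dipole_kernel(dm, voxel_size)
  nt <- n_frames(vals)
  out <- array(0, dim(vals))
  iters <- integer(nt)
  rels <- numeric(nt)
  # shared reference fit on the demeaned time-mean field (optionally only
  # the baseline frames, where no contrast agent is present)
  if (is.null(ref_frames)) ref_frames <- seq_len(n_frames(vals))
  fbar <- apply(vals[, , , ref_frames, drop = FALSE], 1:3, mean)
  fbar <- fbar - sum((W2 * fbar)[mask]) / wm_in
  fbar <- fbar - sum((W2 * fbar)[mask]) / wm_in
  ref <- pdf_fit_cg(fbar, W2, sup, D, tol, max_iter_ref)
  bg_field <- ifft_re(D * fft(ref$x))
  invalid <- W2 == 0
  kc <- tkd_kernel(D, 0.15)
  # Gaussian k-space filter used to smooth the completion's source
  # attribution: the predicted far-field tails are spatially smooth, while
  # the high-k content of the attribution is noise that would otherwise be
  # re-amplified through the completion iterations
  kg <- local({
    kidx <- function(n) { i <- 0:(n - 1); i[i > n / 2] <- i[i > n / 2] - n
      i / n }
    K2 <- outer(outer(kidx(dm[1])^2, kidx(dm[2])^2, "+"), kidx(dm[3])^2,
                "+")
    exp(-2 * pi^2 * 1.5^2 * K2)
  })
  # scalar (drift + arbitrary offset) estimated outside the brain, where
  # the contrast agent does not reach; falls back to the mask if the
  # weighting leaves no extracerebral signal
  ring <- !mask & !invalid
  if (!any(ring)) ring <- mask
  w_ring <- sum(W2[ring])
  for (t in seq_len(nt)) {
    f <- frame4(vals, t)
    if (max_iter > 0L) {
      fit <- pdf_fit_cg(f, W2, sup, D, tol, max_iter, ref$x)
      loc <- f - ifft_re(D * fft(fit$x))
    } else {
      fit <- list(iters = 0L, rel = NA_real_)
      loc <- f - bg_field
    }
    # absorb the frame's uniform level so it cannot turn into a structured
    # valid-region term; the output is then invariant to spatially uniform
    # offsets of the input field
    c_t <- sum((W2 * loc)[ring]) / w_ring
    loc <- loc - c_t
    loc[invalid] <- 0
    # model-consistent completion of the no-data region: the field there
    # is predicted from sources attributed to the brain (boosted by the
    # same truncation-bias factor as the final inversion), so the
    # inversion sees dipole-consistent tails instead of a zero plateau
    for (k in seq_len(n_complete)) {
      chi_hat <- tkd_invert_frame(loc, kc$Dt, kc$cfac)
      chi_hat[!mask] <- 0
      pred <- ifft_re(D * kg * fft(chi_hat))
      loc[invalid] <- pred[invalid]
    }
    if (mask_output) loc[!mask] <- 0
    out[, , , t] <- loc
    iters[t] <- fit$iters
    # post-removal weighted residual field norm (relative to the input)
    rels[t] <- if (is.na(fit$rel))
      sqrt(sum((W2 * loc^2)[mask]) / max(sum((W2 * f^2)[mask]),
                                         .Machine$double.eps))
    else fit$rel
  }
  field_series(out, mask, stage = "background-removed", unit = "ppm",
               params = field$params,
               diagnostics = c(field$diagnostics,
                               list(pdf_iters = iters, pdf_rel = rels,
                                    pdf_ref_rel = ref$rel,
                                    pdf_converged = ref$rel <= tol,
                                    gap = gap)))
}

# truncated kernel and its point-spread amplitude correction factor
tkd_kernel <- function(D, thr) {
  Dt <- D
  s <- ifelse(D >= 0, 1, -1)
  low <- abs(D) < thr
  Dt[low] <- (s * thr)[low]
  list(Dt = Dt, cfac = mean(D / Dt))
}

tkd_invert_frame <- function(f, Dt, cfac) {
  Fk <- fft(f) / Dt
  Fk[1, 1, 1] <- 0
  ifft_re(Fk) / cfac
}

# forward gradient (periodic) and its negative adjoint (divergence)
grad3p <- function(x) {
  d <- dim(x)
  list(x[c(2:d[1], 1), , ] - x,
       x[, c(2:d[2], 1), ] - x,
       x[, , c(2:d[3], 1)] - x)
}

divergence3p <- function(gl) {
  gx <- gl[[1]]; gy <- gl[[2]]; gz <- gl[[3]]
  d <- dim(gx)
  (gx[c(d[1], 1:(d[1] - 1)), , ] - gx) +
    (gy[, c(d[2], 1:(d[2] - 1)), ] - gy) +
    (gz[, , c(d[3], 1:(d[3] - 1))] - gz)
}

# one preconditioned conjugate-gradient solve of the fixed-weight system
# (lam D' W^2 D + G' diag(wir) G + mu_ext) chi = lam D' W^2 f.
# The preconditioner is the Fourier symbol of the spatially-averaged
# operator, so convergence speed is comparable across the whole lambda
# range.
medi_cg_solve <- function(f, W2, wir, mu_ext, D, lam, tol, max_iter,
                          chi0 = NULL) {
  dm <- dim(f)
  lap <- local({
    s2 <- function(n) 4 * sin(pi * (0:(n - 1)) / n)^2
    outer(outer(s2(dm[1]), s2(dm[2]), "+"), s2(dm[3]), "+")
  })
  Mk <- lam * D^2 * mean(W2) + mean(wir) * lap + mean(mu_ext)
  Mk[Mk < max(Mk) * 1e-8] <- max(Mk) * 1e-8
  prec <- function(x) ifft_re(fft(x) / Mk)
  Aop <- function(x) {
    gx <- grad3p(x)
    lam * ifft_re(D * fft(W2 * ifft_re(D * fft(x)))) +
      divergence3p(lapply(gx, function(gg) wir * gg)) + mu_ext * x
  }
  b <- lam * ifft_re(D * fft(W2 * f))
  chi <- if (is.null(chi0)) array(0, dim(f)) else chi0
  r <- b - Aop(chi)
  z <- prec(r)
  p <- z
  rz <- sum(r * z)
  rs0 <- sum(b * b)
  it <- 0L
  while (it < max_iter && sum(r * r) > tol^2 * rs0) {
    Ap <- Aop(p)
    alpha <- rz / sum(p * Ap)
    chi <- chi + alpha * p
    r <- r - alpha * Ap
    z <- prec(r)
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
    it <- it + 1L
  }
  chi
}

# IRLS on a reference field fixes the morphology weights; each frame is
# then a linear solve with those shared weights, so temporal differences
# of the reconstructed maps respond linearly to field differences and the
# static structure is smoothed identically in every frame
medi_weights <- function(f_ref, W2, Medge, D, cfg, mask) {
  lam <- cfg$lam
  # exterior confinement plus a small lambda-independent ridge: smooth
  # modes along the magic-angle cone see neither fidelity (D ~ 0) nor
  # gradient penalty (k ~ 0) and need an absolute anchor
  mu_ext <- lam * 0.1 * (!mask) + cfg$ridge
  wir <- Medge / sqrt(cfg$eps) + cfg$w_floor
  chi <- NULL
  for (o in seq_len(cfg$n_outer)) {
    chi <- medi_cg_solve(f_ref, W2, wir, mu_ext, D, lam, cfg$tol,
                         cfg$max_iter, chi)
    gl <- grad3p(chi)
    wir <- Medge / sqrt(gl[[1]]^2 + gl[[2]]^2 + gl[[3]]^2 + cfg$eps) +
      cfg$w_floor
  }
  list(wir = wir, mu_ext = mu_ext)
}

#' Dipole inversion of a local field series
#'
#' Reconstructs a susceptibility map per time point from the
#' background-removed field.  Two methods are provided:
#'
#' * `"tkd"`: thresholded k-space division.  Kernel values with
#'   `|D| < tkd_threshold` are replaced by `sign(D)*tkd_threshold`; the
#'   systematic amplitude underestimation this causes is corrected by the
#'   point-spread factor `mean(D/D_trunc)` (disable with
#'   `tkd_correct = FALSE`).  Fast and linear in the data, so temporal
#'   differences of frames are reconstructed without nonlinear coupling.
#' * `"medi_like"`: morphology-enabled regularized inversion, minimizing
#'   `lam * ||W (D chi - f)||^2 + || M grad chi ||_1` by iteratively
#'   reweighted least squares with conjugate-gradient inner loops.  `M`
#'   excludes magnitude edges (gradient magnitude above
#'   `edge_percentile`) from the smoothing penalty.  `lam` multiplies the
#'   data fidelity, so larger `lam` yields higher tissue contrast.
#'
#' The absolute susceptibility level per frame is not recoverable
#' (`D(0) = 0`); the output is `"unshifted"` until anchored by
#' [shift_susceptibility()].
#'
#' @param local_field a [field_series()] at stage `"background-removed"`.
#' @param magnitude 3D magnitude map (noise weighting and edge mask);
#'   typically the baseline mean magnitude.
#' @param mask brain mask.
#' @param cfg an [inversion_config()].
#' @return a [susceptibility_series()], `reference_state = "unshifted"`.
#' @export
invert_dipole <- function(local_field, magnitude, mask = NULL,
                          cfg = inversion_config()) {
  if (!inherits(local_field, "field_series") ||
      local_field$stage != "background-removed")
    stop("invert_dipole expects a field_series at stage 'background-removed'")
  if (is.null(mask)) mask <- local_field$mask
  dm <- dim(local_field$values)[1:3]
  mask <- stopifnot_mask(mask, dm)
  vals <- local_field$values
  if (any(!is.finite(vals[rep(mask, n_frames(vals))])))
    stop("non-finite field values inside mask")
  voxel_size <- if (!is.null(local_field$params))
    local_field$params$voxel_size else c(1, 1, 1)
  D <- dipole_kernel(dm, voxel_size)
  nt <- n_frames(vals)
  out <- array(0, dim(vals))
  if (cfg$method == "tkd") {
    kk <- tkd_kernel(D, cfg$tkd_threshold)
    cfac <- if (isTRUE(cfg$tkd_correct)) kk$cfac else 1
    for (t in seq_len(nt))
      out[, , , t] <- tkd_invert_frame(frame4(vals, t), kk$Dt, cfac)
    diag <- list(method = "tkd", tkd_threshold = cfg$tkd_threshold,
                 psf_correction = kk$cfac)
  } else {
    W <- magnitude
    W[!mask] <- 0
    W <- W / mean(W[mask])
    W2 <- W^2
    gmag <- magnitude
    gl <- grad3p(gmag)
    gnorm <- sqrt(gl[[1]]^2 + gl[[2]]^2 + gl[[3]]^2)
    Medge <- array(1, dm)
    Medge[gnorm > quantile(gnorm[mask], cfg$edge_percentile)] <- 0
    f_ref <- if (nt > 1L) apply(vals, 1:3, mean) else frame4(vals, 1L)
    wts <- medi_weights(f_ref, W2, Medge, D, cfg, mask)
    for (t in seq_len(nt))
      out[, , , t] <- medi_cg_solve(frame4(vals, t), W2, wts$wir,
                                    wts$mu_ext, D, cfg$lam, cfg$tol,
                                    cfg$max_iter)
    diag <- list(method = "medi_like", lam = cfg$lam)
  }
  susceptibility_series(out, mask, reference_state = "unshifted",
                        diagnostics = c(local_field$diagnostics, diag))
}

#' Regional response (cross-talk) matrix of the dynamic reconstruction
#'
#' The dynamic path of the reconstruction -- forward dipole field,
#' uniform-level removal over the extracerebral ring, zero-filling plus
#' model-consistent completion of no-data regions, thresholded kernel
#' division -- is linear.  Pushing each compartment's unit indicator
#' through that operator yields the matrix of region-mean responses:
#' entry (r, s) is the CSF-referenced mean over region r of the
#' reconstruction of a unit susceptibility in compartment s.  Solving
#' this small system against measured region means removes the
#' structure-dependent attenuation and cross-talk of the inversion
#' (the same idea as partial-volume cross-talk correction in regional
#' PET/MRI quantification).  Only the region masks enter; no true
#' susceptibility values are used.
#'
#' @param masks mask list with `wm`, `gm`, `vessel`, `csf`, `brain`.
#' @param valid 3D logical: voxels with usable phase data.
#' @param params [acquisition_params()] (voxel size for the kernel).
#' @param cfg [inversion_config()] (tkd settings must match the
#'   reconstruction).
#' @param gap guard gap used by the background stage (for the ring
#'   definition; unused otherwise).
#' @param n_complete completion iterations, as in
#'   [remove_background_pdf()].
#' @return list with `M` (rows wm/gm/brain, columns wm/gm/vessel,
#'   CSF-referenced) and `frac` (volume fractions of the source
#'   compartments within the brain mask).
#' @export
region_crosstalk_matrix <- function(masks, valid, params = acquisition_params(),
                                    cfg = inversion_config(), gap = NULL,
                                    n_complete = 3L) {
  dm <- dim(masks$brain)
  D <- dipole_kernel(dm, params$voxel_size)
  kc <- tkd_kernel(D, 0.15)
  kf <- tkd_kernel(D, cfg$tkd_threshold)
  cfac <- if (isTRUE(cfg$tkd_correct)) kf$cfac else 1
  kg <- local({
    kidx <- function(n) { i <- 0:(n - 1); i[i > n / 2] <- i[i > n / 2] - n
      i / n }
    K2 <- outer(outer(kidx(dm[1])^2, kidx(dm[2])^2, "+"), kidx(dm[3])^2,
                "+")
    exp(-2 * pi^2 * 1.5^2 * K2)
  })
  invalid <- !valid
  ring <- valid & !masks$brain
  if (!any(ring)) ring <- masks$brain
  respond <- function(src) {
    loc <- ifft_re(D * fft(src))
    loc <- loc - mean(loc[ring])
    loc[invalid] <- 0
    for (k in seq_len(n_complete)) {
      chi_hat <- tkd_invert_frame(loc, kc$Dt, kc$cfac)
      chi_hat[!masks$brain] <- 0
      pred <- ifft_re(D * kg * fft(chi_hat))
      loc[invalid] <- pred[invalid]
    }
    tkd_invert_frame(loc, kf$Dt, cfac)
  }
  srcs <- c("wm", "gm", "vessel")
  rows <- c("wm", "gm", "brain")
  M <- matrix(0, length(rows), length(srcs),
              dimnames = list(rows, srcs))
  for (s in srcs) {
    src <- array(0, dm)
    src[masks[[s]]] <- 1
    r <- respond(src)
    csf_mean <- mean(r[masks$csf])
    for (rr in rows) M[rr, s] <- mean(r[masks[[rr]]]) - csf_mean
  }
  nb <- sum(masks$brain)
  frac <- vapply(srcs, function(s) sum(masks[[s]] & masks$brain) / nb,
                 numeric(1))
  list(M = M, frac = frac)
}

#' Susceptibility of an infinite cylinder from its interior phase shift
#'
#' For a long cylindrical vessel at angle `theta` to the main field, the
#' interior phase shift and susceptibility are related by
#' `chi = 6 phi / (gamma * TE * (3 cos^2 theta - 1) * B0)`; the result is
#' returned in ppm.  The relation degenerates at the magic angle
#' (`3 cos^2 theta = 1`), where an explicit error is raised.
#'
#' @param phase_shift interior phase shift (rad), scalar or vector.
#' @param theta angle between the cylinder axis and B0 (rad).
#' @param params an [acquisition_params()] object.
#' @param epsilon guard on `|3 cos^2 theta - 1|` (default 0.05).
#' @return susceptibility in ppm.
#' @export
cylinder_susceptibility <- function(phase_shift, theta,
                                    params = acquisition_params(),
                                    epsilon = 0.05) {
  geom <- 3 * cos(theta)^2 - 1
  if (abs(geom) <= epsilon)
    stop("theta is within ", epsilon, " of the magic angle: the ",
         "cylinder phase-susceptibility relation degenerates ",
         "(3cos^2(theta)-1 ~ 0)")
  6 * phase_shift / (params$gamma * params$te * geom * params$b0) * 1e6
}
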