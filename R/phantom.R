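# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a digital head phantom for dynamic susceptibility imaging
#'
#' Constructs a 3D isotropic head phantom: an ellipsoidal brain with a grey
#' matter shell, white matter core and two ventricular CSF compartments; a
#' finite superior-sagittal-sinus-like vessel cylinder at the posterior edge
#' of the brain, tilted away from the B0 (z) axis; and, outside the brain,
#' interstitial soft tissue, a diamagnetic skull shell and strongly
#' paramagnetic air.  The skull/air compartments generate the background
#' fields that the background-removal stage must handle, as in a real
#' acquisition.
#'
#' True cerebral blood volume is piecewise constant (distinct white and grey
#' matter levels taken from literature reference values); vessel voxels
#' represent 100% blood.  Small seed-dependent jitters of the geometry and
#' baseline maps emulate between-subject variability.
#'
#' @param grid_shape integer 3-vector of grid dimensions (each >= 32).
#' @param seed integer seed controlling geometric jitter (deterministic).
#' @param cbv_scale multiplicative factor applied to the tissue CBV levels
#'   (per-subject global blood-volume variation).
#' @param vessel_angle angle (rad) between the vessel axis and B0; default
#'   25 degrees.
#' @param cbv_wm,cbv_gm true CBV in white/grey matter (mL/100 g).
#' @param r2s_tissue_relaxivity,r2s_blood_relaxivity transverse relaxivities
#'   r2* (mM^-1 s^-1) of tissue and whole blood.
#' @return an object of class `phantom` with elements `masks` (logical 3D
#'   arrays: brain, wm, gm, csf, vessel, head, skull, air), `chi0_map` (ppm),
#'   `cbv_map` (mL/100 g), `r2s0_map` (s^-1), `s0_map` (a.u.),
#'   `vessel_angle`, `vessel_axis`, `vessel_center`, relaxivities and the
#'   grid shape.
#' @export
build_phantom <- function(grid_shape = c(64L, 64L, 64L), seed = 1L,
                          cbv_scale = 1, vessel_angle = 25 * pi / 180,
                          cbv_wm = 1.91, cbv_gm = 3.85,
                          r2s_tissue_relaxivity = 85,
                          r2s_blood_relaxivity = 30) {
  dm <- as.integer(grid_shape)
  if (length(dm) != 3L) stop("grid_shape must have 3 components")
  if (any(dm < 32L))
    stop("grid too small: each dimension must be >= 32 to contain the ",
         "brain, ventricle, vessel and skull compartments")
  jit <- with_seed(seed, rnorm(8, 0, 1))
  g <- index_grids(dm)
  cx <- (dm + 1) / 2 + 0.01 * dm * jit[1:3] / 3
  n <- min(dm)
  ell <- function(a, b, c, ox = 0, oy = 0, oz = 0) {
    ((g$x - cx[1] - ox) / a)^2 + ((g$y - cx[2] - oy) / b)^2 +
      ((g$z - cx[3] - oz) / c)^2 <= 1
  }
  ax_sc <- 1 + 0.02 * jit[4]
  ba <- c(0.40, 0.43, 0.36) * n * ax_sc
  brain <- ell(ba[1], ba[2], ba[3])
  inner <- ell(0.78 * ba[1], 0.78 * ba[2], 0.78 * ba[3])
  vsc <- 1 + 0.05 * jit[5]
  vent <- ell(0.065 * n * vsc, 0.18 * n * vsc, 0.09 * n * vsc,
              ox = -0.10 * n) |
    ell(0.065 * n * vsc, 0.18 * n * vsc, 0.09 * n * vsc, ox = 0.10 * n)
  vent <- vent & inner
  gm <- brain & !inner
  wm <- inner & !vent

  # finite tilted vessel: axis in the y-z plane at angle theta to z (=B0)
  theta <- vessel_angle
  axis_dir <- c(0, sin(theta), cos(theta))
  y0 <- cx[2] + (0.34 + 0.005 * jit[6]) * n
  ctr <- c(cx[1], y0, cx[3])
  px <- g$x - ctr[1]; py <- g$y - ctr[2]; pz <- g$z - ctr[3]
  dot <- py * axis_dir[2] + pz * axis_dir[3]
  rad2 <- px^2 + (py - dot * axis_dir[2])^2 + (pz - dot * axis_dir[3])^2
  vr <- max(2.6, 0.036 * n)
  cyl <- rad2 <= vr^2 & abs(dot) < 0.28 * n
  vessel <- cyl & brain
  gm <- gm & !vessel
  wm <- wm & !vessel
  if (!any(vessel)) stop("grid too small: vessel not contained in brain")
  if (!any(vent)) stop("grid too small: ventricles not contained in brain")

  skull_out <- ell(0.55 * n, 0.58 * n, 0.51 * n)
  skull_in <- ell(0.50 * n, 0.53 * n, 0.46 * n)
  skull <- skull_out & !skull_in
  head <- skull_out
  soft <- skull_in & !brain
  air <- !head

  chi0 <- array(9.4, dm)               # air, relative to water (ppm)
  chi0[skull] <- -2.0                  # cortical bone
  chi0[soft] <- 0
  chi0[brain] <- 0
  chi0[wm] <- -0.03 * (1 + 0.05 * jit[7])
  chi0[gm] <- 0.02 * (1 + 0.05 * jit[8])
  chi0[vent] <- 0
  chi0[vessel] <- 0.27                 # partially deoxygenated venous blood

  cbv <- array(0, dm)
  cbv[wm] <- cbv_wm * cbv_scale
  cbv[gm] <- cbv_gm * cbv_scale
  # pure-blood equivalent of a 100% blood voxel under the default constants
  cbv[vessel] <- 100 / 1.04 * (1 - 0.45) / (1 - 0.25)

  r2s0 <- array(0, dm)
  r2s0[soft] <- 25; r2s0[skull] <- 60
  r2s0[wm] <- 18; r2s0[gm] <- 22; r2s0[vent] <- 1.5; r2s0[vessel] <- 35

  s0 <- array(0.03, dm)                # air: noise-floor signal
  s0[soft] <- 0.5; s0[skull] <- 0.15
  s0[wm] <- 0.75; s0[gm] <- 0.85; s0[vent] <- 1.0; s0[vessel] <- 0.9

  structure(
    list(
      masks = list(brain = brain, wm = wm, gm = gm, csf = vent,
                   vessel = vessel, head = head, skull = skull, air = air),
      chi0_map = chi0, cbv_map = cbv, r2s0_map = r2s0, s0_map = s0,
      r2s_tissue_relaxivity = r2s_tissue_relaxivity,
      r2s_blood_relaxivity = r2s_blood_relaxivity,
      vessel_angle = theta, vessel_axis = axis_dir, vessel_center = ctr,
      grid_shape = dm, seed = seed, cbv_scale = cbv_scale
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>", paste(x$grid_shape, collapse = "x"),
      "| brain voxels:", sum(x$masks$brain),
      "| CSF:", sum(x$masks$csf),
      "| vessel:", sum(x$masks$vessel),
      "| vessel angle:", round(x$vessel_angle * 180 / pi, 1), "deg\n")
  invisible(x)
}

# per-voxel multiplier g(v) such that [CA](v,t) = g(v) * [CA]_blood(t):
# hematocrit-corrected cbv fraction in tissue, 1 in the vessel, 0 in CSF
conc_pattern <- function(phantom, physio) {
  pat <- phantom$cbv_map / 100 * physio$rho *
    (1 - physio$hct_sv) / (1 - physio$hct_lv)
  pat[phantom$masks$csf] <- 0
  pat[!phantom$masks$brain] <- 0
  pat[phantom$masks$vessel] <- 1
  pat
}

#' Tissue contrast-agent concentration series implied by a phantom
#'
#' Maps a whole-blood concentration curve onto the phantom: tissue voxels
#' carry `(cbv/100) * rho * (1-Hct_sv)/(1-Hct_lv) * [CA]_blood(t)` (the
#' steady-state CBV relation read in the forward direction), vessel voxels
#' carry the blood curve itself, CSF carries zero.
#'
#' @param phantom a [build_phantom()] object.
#' @param blood a [simulate_blood_curve()] object.
#' @param physio a [physio_constants()] object.
#' @return 4D array of concentration (mM), dimensions `c(grid, n_timepoints)`.
#' @export
tissue_concentration_series <- function(phantom, blood,
                                        physio = physio_constants()) {
  pat <- conc_pattern(phantom, physio)
  nt <- length(blood$concentration)
  out <- array(outer(as.vector(pat), blood$concentration),
               c(phantom$grid_shape, nt))
  out
}

#' Pick a vessel measurement ROI
#'
#' Selects `n` voxels closest to the vessel axis near the vessel
#' mid-length, emulating a small manual ROI in the superior sagittal sinus.
#'
#' @param phantom a [build_phantom()] object.
#' @param n number of pixels (default 3).
#' @return an object of class `vessel_roi` with voxel indices (linear) and
#'   the vessel angle `theta`.
#' @export
vessel_roi <- function(phantom, n = 3L) {
  dm <- phantom$grid_shape
  g <- index_grids(dm)
  a <- phantom$vessel_axis; ctr <- phantom$vessel_center
  px <- g$x - ctr[1]; py <- g$y - ctr[2]; pz <- g$z - ctr[3]
  dot <- py * a[2] + pz * a[3]
  rad2 <- px^2 + (py - dot * a[2])^2 + (pz - dot * a[3])^2
  cand <- which(phantom$masks$vessel & abs(dot) < 0.1 * min(dm))
  if (length(cand) < n) cand <- which(phantom$masks$vessel)
  ord <- order(rad2[cand])
  structure(list(pixels = cand[ord[seq_len(min(n, length(cand)))]],
                 theta = phantom$vessel_angle),
            class = "vessel_roi")
}
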