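#' Unit dipole kernel in k-space
#'
#' `D(k) = 1/3 - kz^2/|k|^2` on the continuous k-space coordinates of the
#' FFT grid, with z the B0 axis and `D(0) := 0` (demodulated-field
#' convention).  The identical kernel is used by the forward model, the
#' background-field removal and the dipole inversion.
#'
#' @param dm integer 3-vector of grid dimensions.
#' @param voxel_size voxel dimensions (mm).
#' @return 3D array of kernel values.
#' @export
dipole_kernel <- function(dm, voxel_size = c(1, 1, 1)) {
  kidx <- function(n, d) {
    i <- 0:(n - 1)
    i[i > n / 2] <- i[i > n / 2] - n
    i / (n * d)
  }
  kx <- kidx(dm[1], voxel_size[1])
  ky <- kidx(dm[2], voxel_size[2])
  kz <- kidx(dm[3], voxel_size[3])
  K2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  KZ2 <- outer(outer(kx * 0, ky * 0, "+"), kz^2, "+")
  D <- 1 / 3 - KZ2 / K2
  D[1, 1, 1] <- 0
  D
}

# real-valued inverse FFT of a Hermitian spectrum
ifft_re <- function(X) Re(fft(X, inverse = TRUE)) / length(X)

#' Dipole-convolution forward field
#'
#' Field perturbation (ppm) induced by a susceptibility distribution:
#' `field = IFFT( D(k) * FFT(chi) )`.  Linear and shift-covariant; with
#' `D(0) = 0` the spatial mean of the returned field is zero.
#'
#' @param chi_map 3D susceptibility map (ppm).
#' @param voxel_size voxel dimensions (mm).
#' @param D optional precomputed [dipole_kernel()] for the same grid.
#' @return 3D field map (ppm).
#' @export
forward_field <- function(chi_map, voxel_size = c(1, 1, 1), D = NULL) {
  if (any(!is.finite(chi_map))) stop("chi_map must be finite")
  if (is.null(D)) D <- dipole_kernel(dim(chi_map), voxel_size)
  ifft_re(D * fft(chi_map))
}

# first/second order real solid-harmonic basis over the grid (shim fields)
shim_basis <- function(dm) {
  g <- index_grids(dm)
  cx <- (dm + 1) / 2
  x <- (g$x - cx[1]) / dm[1]; y <- (g$y - cx[2]) / dm[2]
  z <- (g$z - cx[3]) / dm[3]
  list(x = x, y = y, z = z, xy = x * y, xz = x * z, yz = y * z,
       x2y2 = x^2 - y^2, z2 = 2 * z^2 - x^2 - y^2)
}

# emulate scanner shimming: remove the best-fitting constant + 1st/2nd order
# harmonic field over the brain mask (fit once, applied globally)
shim_correction <- function(field, mask) {
  B <- shim_basis(dim(field))
  X <- cbind(1, vapply(B, function(b) b[mask], numeric(sum(mask))))
  beta <- qr.solve(qr(X), field[mask])
  corr <- array(beta[1], dim(field))
  for (i in seq_along(B)) corr <- corr + beta[i + 1] * B[[i]]
  corr
}

#' Construct a dynamic magnitude/phase series object
#'
#' @param magnitude 4D non-negative magnitude array (a.u.).
#' @param phase 4D wrapped phase array (rad), values in (-pi, pi].
#' @param params an [acquisition_params()] object.
#' @return an object of class `dynamic_series`.
#' @export
dynamic_series <- function(magnitude, phase, params) {
  if (!identical(dim(magnitude), dim(phase)))
    stop("magnitude and phase must have identical dimensions")
  if (length(dim(magnitude)) != 4L)
    stop("magnitude and phase must be 4D (x, y, z, t)")
  structure(list(magnitude = magnitude, phase = phase, params = params),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat("<dynamic_series>", paste(d[1:3], collapse = "x"), "voxels,",
      d[4], "frames | TE", x$params$te * 1000, "ms | B0", x$params$b0, "T\n")
  invisible(x)
}

#' Simulate a dynamic gradient-echo magnitude/phase series
#'
#' Full forward model of the dynamic acquisition.  Per time point the
#' susceptibility distribution is `chi0 + chi_mol * [CA](t)`, the field
#' follows by dipole convolution (plus a global scanner drift), the phase is
#' `gamma*B0*TE*field*1e-6` wrapped to (-pi, pi], and the magnitude decays
#' as `s0 * exp(-TE * (R2*0 + r2* * [CA]))` with compartment-specific
#' relaxivity.  An emulated 1st/2nd-order shim (fitted on the baseline field
#' over the brain) is subtracted from all frames, as a scanner would.
#' Complex Gaussian noise (i.i.d. real/imaginary) is added before
#' magnitude/phase extraction, so magnitude noise is Rician and phase noise
#' scales inversely with local SNR.
#'
#' Optionally a subset of CSF voxels receives phase-only spike artifacts
#' (emulating pulsation artifacts in the ventricles): magnitude is
#' untouched, so the signal-range selection criterion cannot detect them.
#'
#' @param phantom a [build_phantom()] object.
#' @param blood a [simulate_blood_curve()] object.
#' @param params an [acquisition_params()] object.
#' @param physio a [physio_constants()] object.
#' @param noise_sd complex noise SD as a fraction of the mean baseline brain
#'   signal (0 = noiseless; `1/SNR`).
#' @param seed integer seed (noise and artifact placement).
#' @param csf_spike_frac fraction of CSF voxels given phase spike artifacts.
#' @param csf_spike_amp spike amplitude (rad).
#' @param csf_spike_sign `"positive"` for one-signed spikes (flow-phase
#'   bias, the default) or `"random"` for sign-symmetric ones.
#' @return a [dynamic_series()] object.
#' @export
simulate_series <- function(phantom, blood, params = acquisition_params(),
                            physio = physio_constants(), noise_sd = 0,
                            seed = 1L, csf_spike_frac = 0,
                            csf_spike_amp = 1.5,
                            csf_spike_sign = c("positive", "random")) {
  csf_spike_sign <- match.arg(csf_spike_sign)
  stopifnot(noise_sd >= 0)
  dm <- phantom$grid_shape
  nt <- params$n_timepoints
  if (length(blood$concentration) != nt)
    stop("blood curve length does not match n_timepoints")
  D <- dipole_kernel(dm, params$voxel_size)
  f_static <- forward_field(phantom$chi0_map, D = D)
  pat <- conc_pattern(phantom, physio)
  f_dyn_unit <- forward_field(conc_to_ppm(pat, physio$chi_mol), D = D)
  shim <- shim_correction(f_static, phantom$masks$brain)

  r2s_slope <- array(0, dm)
  r2s_slope[phantom$masks$brain] <- phantom$r2s_tissue_relaxivity
  r2s_slope[phantom$masks$vessel] <- phantom$r2s_blood_relaxivity

  mag <- array(0, c(dm, nt))
  ph <- array(0, c(dm, nt))
  s0 <- phantom$s0_map
  sig_ref <- mean(s0[phantom$masks$brain])
  phase_scale <- params$gamma * params$b0 * params$te * 1e-6

  spike <- NULL
  if (csf_spike_frac > 0) {
    spike <- with_seed(seed + 104729L, {
      csf_idx <- which(phantom$masks$csf)
      n_bad <- max(1L, round_half_up(csf_spike_frac * length(csf_idx)))
      bad <- sample(csf_idx, n_bad)
      # spikes concentrated in the post-bolus half of the series, always
      # hitting at least one tail frame
      frames <- lapply(seq_len(n_bad), function(i) {
        k <- sample(2:4, 1)
        unique(c(sample(seq.int(ceiling(nt / 2), nt), k), nt - sample(0:4, 1)))
      })
      amps <- lapply(frames, function(fr) {
        a <- csf_spike_amp * abs(1 + 0.3 * rnorm(length(fr)))
        if (csf_spike_sign == "random")
          a <- a * sign(runif(length(fr)) - 0.5)
        a
      })
      list(voxels = bad, frames = frames, amps = amps)
    })
  }

  noise <- NULL
  if (noise_sd > 0) noise_seed <- seed

  for (t in seq_len(nt)) {
    cb <- blood$concentration[t]
    field <- f_static - shim + cb * f_dyn_unit +
      params$b0_drift_rate * 1e-3 * (t - 1)
    phi <- phase_scale * field
    r2s <- phantom$r2s0_map + r2s_slope * (pat * cb)
    s <- s0 * exp(-params$te * r2s)
    if (!is.null(spike)) {
      for (i in seq_along(spike$voxels)) {
        hit <- which(spike$frames[[i]] == t)
        if (length(hit))
          phi[spike$voxels[i]] <- phi[spike$voxels[i]] +
            sum(spike$amps[[i]][hit])
      }
    }
    if (noise_sd > 0) {
      eps <- with_seed(noise_seed + t, {
        n <- prod(dm)
        complex(real = rnorm(n), imaginary = rnorm(n))
      })
      z <- s * exp(1i * phi) + noise_sd * sig_ref * eps
      mag[, , , t] <- array(Mod(z), dm)
      ph[, , , t] <- array(Arg(z), dm)
    } else {
      mag[, , , t] <- s
      ph[, , , t] <- wrap_to_pi(phi)
    }
  }
  dynamic_series(mag, ph, params)
}
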