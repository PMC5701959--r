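#' @useDynLib dynqsm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif quantile sd coef lm median
NULL

#' Wrap phase angles into (-pi, pi]
#'
#' @param phi numeric vector or array of phase values (rad).
#' @return values congruent to `phi` modulo 2*pi, in (-pi, pi].
#' @export
wrap_to_pi <- function(phi) {
  w <- phi - 2 * pi * floor((phi + pi) / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# round half away from zero, the convention used for all pixel-count
# thresholds (R's round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Phase/field conversion for gradient-echo acquisitions
#'
#' Centralizes the factor gamma * B0 * TE * 1e-6 linking an off-resonance
#' field expressed in ppm to the accrued phase in radians at echo time.
#'
#' @param phase phase (rad) for `phase_to_field`.
#' @param field field (ppm) for `field_to_phase`.
#' @param params an [acquisition_params()] object.
#' @return field map in ppm, or phase in rad.
#' @export
phase_to_field <- function(phase, params) {
  phase / (params$gamma * params$b0 * params$te * 1e-6)
}

#' @rdname phase_to_field
#' @export
field_to_phase <- function(field, params) {
  field * (params$gamma * params$b0 * params$te * 1e-6)
}

# mM -> ppm and back, always through chi_mol (ppm/M) with the 1e3 factor
# explicit in this one place
conc_to_ppm <- function(conc_mM, chi_mol) conc_mM * chi_mol / 1000
ppm_to_conc <- function(dchi_ppm, chi_mol) dchi_ppm * 1000 / chi_mol

# shift a 3D logical/numeric array by s along axis ax, replicating edges
shift3 <- function(m, ax, s) {
  d <- dim(m)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[ax]] <- pmin(pmax(idx[[ax]] + s, 1L), d[ax])
  m[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# binary erosion / dilation with a 6-neighbour cross, n passes
erode_mask <- function(m, n = 1L) {
  for (k in seq_len(n)) {
    e <- m
    for (ax in 1:3) for (s in c(-1L, 1L)) e <- e & shift3(m, ax, s)
    m <- e
  }
  m
}

dilate_mask <- function(m, n = 1L) {
  for (k in seq_len(n)) {
    e <- m
    for (ax in 1:3) for (s in c(-1L, 1L)) e <- e | shift3(m, ax, s)
    m <- e
  }
  m
}

# index grids for a 3D volume (1-based voxel centres)
index_grids <- function(dm) {
  list(
    x = array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm),
    y = array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm),
    z = array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  )
}

# slice one time point out of a 4D array, always returning a 3D array
frame4 <- function(a, t) {
  d <- dim(a)
  out <- a[, , , t, drop = FALSE]
  dim(out) <- d[1:3]
  out
}

`frame4<-` <- function(a, t, value) {
  a[, , , t] <- value
  a
}

n_frames <- function(a) dim(a)[4]

stopifnot_mask <- function(mask, dm) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (!identical(dim(mask)[1:3], dm[1:3]))
    stop("mask dimensions do not match volume dimensions")
  mask
}
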