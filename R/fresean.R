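#' Mass-weighted velocity cross-correlation matrices
#'
#' Computes the matrix of mass-weighted velocity time cross-correlation
#' functions for all degrees of freedom of an (aligned) trajectory:
#' `C_ij(t) = < sqrt(m_i m_j) v_i(t0) v_j(t0 + t) >`, averaged over all
#' valid time origins (optionally strided), for lags 0..`t_max`.  Each lag
#' matrix is then time-symmetrized, `C(t) <- (C(t) + C(t)^T) / 2`, which
#' makes the subsequent frequency-domain matrices real and symmetric.
#'
#' Entries are in amu nm^2/ps^2 = kJ/mol; at equipartition the diagonal of
#' `C(0)` is `kB T` per degree of freedom.
#'
#' @param traj an aligned [trajectory()] with velocities
#' @param masses per-site masses (amu)
#' @param t_max maximum correlation time (ps); must be a multiple of the
#'   sampling interval and at most a tenth of the trajectory length
#' @param origin_stride use every k-th frame as a time origin (1 = dense)
#' @param symmetrize apply time symmetrization (default TRUE)
#' @return object of class `corr_series`: lag times `lags` (ps), array `C`
#'   `[3n, 3n, n_lags]`, `dt`, `masses`, `reference` (mean structure),
#'   `symmetrized`
#' @export
velocity_cross_correlation <- function(traj, masses, t_max = 2,
                                       origin_stride = 1L,
                                       symmetrize = TRUE) {
  if (!has_velocities(traj))
    stop("trajectory has no velocities; spectral analysis needs them")
  if (length(masses) != n_sites(traj))
    stop("length(masses) must match the trajectory site count")
  dt <- traj$dt
  L <- t_max / dt
  if (abs(L - round(L)) > 1e-6)
    stop(sprintf("t_max = %g ps is not a multiple of dt = %g ps",
                 t_max, dt))
  L <- as.integer(round(L))
  duration <- (n_frames(traj) - 1L) * dt
  if (t_max > duration / 10)
    stop(sprintf(
      "trajectory too short: t_max = %g ps exceeds a tenth of %g ps",
      t_max, duration))
  U <- sweep(flatten_frames(traj$vel), 2, rep(sqrt(masses), each = 3),
             "*")
  C <- corr_lags(U, L, origin_stride, symmetrize)
  ref <- apply(traj$pos, c(2, 3), mean)
  structure(list(lags = (0:L) * dt, C = C, dt = dt,
                 masses = as.numeric(masses), reference = ref,
                 symmetrized = symmetrize),
            class = "corr_series")
}

# lag-resolved cross-correlation of the columns of U [frames x d]
corr_lags <- function(U, L, origin_stride = 1L, symmetrize = TRUE) {
  nf <- nrow(U); d <- ncol(U)
  C <- array(0, c(d, d, L + 1L))
  for (l in 0:L) {
    o <- seq.int(1L, nf - l, by = origin_stride)
    Cl <- crossprod(U[o, , drop = FALSE],
                    U[o + l, , drop = FALSE]) / length(o)
    if (symmetrize) Cl <- (Cl + t(Cl)) / 2
    C[, , l + 1L] <- Cl
  }
  C
}

#' @export
print.corr_series <- function(x, ...) {
  cat(sprintf("<corr_series> %d dof, %d lags (0..%g ps), %ssymmetrized\n",
              dim(x$C)[1], length(x$lags), max(x$lags),
              if (x$symmetrized) "" else "not "))
  invisible(x)
}

# Gaussian window: time-domain taper whose implied frequency-domain
# Gaussian has the requested FWHM (cm^-1).
gaussian_taper <- function(lags, window_fwhm) {
  sigma_nu <- window_fwhm / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * SPEED_OF_LIGHT_CM_PS * sigma_nu)
  exp(-lags^2 / (2 * sigma_t^2))
}

#' Frequency-domain spectral matrices
#'
#' Transforms a time-symmetrized correlation series into real symmetric
#' spectral matrices on a discrete wavenumber grid: each element is tapered
#' by a Gaussian window in time (chosen so the spectral resolution equals
#' `window_fwhm` in cm^-1) and cosine-transformed over the symmetric lag
#' range.  The normalization is one-sided per cm^-1:
#' `S(nu) = 2 c dt (C(0) + 2 sum_j w_j C(j dt) cos(2 pi c nu j dt))`,
#' so that the integral of each diagonal element over the frequency grid
#' recovers `C_ii(0)` (Parseval / equipartition check).
#'
#' @param corr a [velocity_cross_correlation()] result (symmetrized)
#' @param window_fwhm Gaussian window FWHM in cm^-1 (default 10)
#' @param pad_factor frequency-grid refinement: number of grid points is
#'   `pad_factor * n_lags` across 0..Nyquist, with 0 on the grid exactly
#' @return object of class `spectral_set`: `freq` (cm^-1), array `S`
#'   `[d, d, n_freq]` (kJ/mol per cm^-1), `window`, `masses`, `reference`
#' @export
spectral_matrix <- function(corr, window_fwhm = 10, pad_factor = 4L) {
  stopifnot(inherits(corr, "corr_series"))
  if (window_fwhm <= 0) stop("window_fwhm must be positive")
  if (!corr$symmetrized)
    stop("spectral_matrix needs a time-symmetrized correlation series")
  lags <- corr$lags
  L <- length(lags) - 1L
  w <- gaussian_taper(lags, window_fwhm)
  nyq <- 1 / (2 * SPEED_OF_LIGHT_CM_PS * corr$dt)
  n_freq <- pad_factor * (L + 1L)
  freq <- seq(0, nyq, length.out = n_freq)
  # basis: row j of B is the weighted cosine at lag j over the freq grid
  B <- matrix(0, L + 1L, n_freq)
  B[1, ] <- 1
  for (j in seq_len(L))
    B[j + 1L, ] <- 2 * w[j + 1L] *
      cos(2 * pi * SPEED_OF_LIGHT_CM_PS * freq * lags[j + 1L])
  d <- dim(corr$C)[1]
  Cflat <- matrix(corr$C, d * d, L + 1L)
  Sflat <- (2 * SPEED_OF_LIGHT_CM_PS * corr$dt) * (Cflat %*% B)
  S <- array(Sflat, c(d, d, n_freq))
  structure(list(freq = freq, S = S, window = window_fwhm,
                 masses = corr$masses, reference = corr$reference),
            class = "spectral_set")
}

#' @export
print.spectral_set <- function(x, ...) {
  cat(sprintf(
    "<spectral_set> %d dof, %d frequencies (0..%.0f cm^-1), window %g cm^-1\n",
    dim(x$S)[1], length(x$freq), max(x$freq), x$window))
  invisible(x)
}

#' Frequency-resolved (FRESEAN) modes at a chosen frequency
#'
#' Eigendecomposition of the spectral matrix at the requested frequency
#' (0 for the standard protocol).  Eigenvectors are collective displacement
#' directions in mass-weighted space; eigenvalues are each mode's
#' contribution to the vibrational density of states at that frequency and
#' are sorted descending.  For an aligned trajectory the leading six
#' zero-frequency modes describe rigid-body translation and rotation;
#' modes 7+ are the anharmonic low-frequency vibrations.
#'
#' @param spec a [spectral_matrix()] result
#' @param frequency requested frequency in cm^-1; snapped to the nearest
#'   grid point (the `freq_tag` of the result records the grid value
#'   used).  Frequencies outside the 0..Nyquist range of the grid are an
#'   error.  Default 0, which lies on the grid exactly.
#' @return a [mode_set()] tagged with the analysis frequency
#' @export
fresean_modes <- function(spec, frequency = 0) {
  stopifnot(inherits(spec, "spectral_set"))
  if (frequency < -1e-9 || frequency > max(spec$freq) + 1e-9)
    stop(sprintf("frequency %g cm^-1 not on the spectral grid (0..%g)",
                 frequency, max(spec$freq)))
  k <- which.min(abs(spec$freq - frequency))
  Sk <- spec$S[, , k]
  asym <- max(abs(Sk - t(Sk)))
  if (asym > 1e-6 * max(abs(Sk)))
    stop(sprintf("spectral matrix not symmetric (max asymmetry %.3g)",
                 asym))
  eig <- eigen((Sk + t(Sk)) / 2, symmetric = TRUE)  # descending values
  mode_set(eig$vectors, eig$values, spec$masses,
           freq_tag = spec$freq[k], reference = spec$reference,
           window = spec$window, kind = "fresean")
}

#' Vibrational density of states
#'
#' `total_vdos` returns the total VDoS, i.e. the trace of the spectral
#' matrix at every frequency (equivalently the sum of all per-dof power
#' spectra).  `mode_projected_vdos` projects the mass-weighted velocities
#' onto a single mode vector and returns that mode's contribution to the
#' spectrum at all frequencies; summed over a complete mode set this
#' reproduces the total VDoS exactly.
#'
#' @param x a [spectral_matrix()] result (or, for `total_vdos`, a
#'   [velocity_cross_correlation()] result, transformed with
#'   `window_fwhm`)
#' @param window_fwhm Gaussian window FWHM (cm^-1) when transforming
#' @return a tibble of class `vdos_spectrum` with columns `freq` (cm^-1)
#'   and `intensity` (kJ/mol per cm^-1)
#' @export
total_vdos <- function(x, window_fwhm = 10) {
  if (inherits(x, "corr_series")) x <- spectral_matrix(x, window_fwhm)
  stopifnot(inherits(x, "spectral_set"))
  d <- dim(x$S)[1]
  intensity <- vapply(seq_along(x$freq),
                      function(k) sum(diag(x$S[, , k])), numeric(1))
  new_spectrum(x$freq, intensity)
}

#' Integrate a spectrum over its frequency grid
#'
#' Trapezoidal quadrature over the wavenumber grid — the quadrature under
#' which the transform convention is exactly Parseval-consistent:
#' integrating a per-dof spectrum recovers that dof's `C(0)` (i.e. `kB T`
#' at equipartition) to machine precision.
#'
#' @param spectrum a `vdos_spectrum` tibble
#' @return the integral in kJ/mol
#' @export
spectrum_integral <- function(spectrum) {
  f <- spectrum$freq; y <- spectrum$intensity
  sum((y[-1] + y[-length(y)]) / 2 * diff(f))
}

new_spectrum <- function(freq, intensity) {
  out <- tibble::tibble(freq = freq, intensity = intensity)
  class(out) <- c("vdos_spectrum", class(out))
  out
}

#' @rdname total_vdos
#' @param traj an aligned [trajectory()] with velocities
#' @param mode a 3n mode vector or a [mode_set()] column index pair
#'   `list(modes, k)`
#' @param masses per-site masses (amu)
#' @param t_max maximum correlation time (ps)
#' @param origin_stride time-origin stride
#' @param pad_factor frequency-grid refinement
#' @export
mode_projected_vdos <- function(traj, mode, masses, t_max = 2,
                                window_fwhm = 10, origin_stride = 1L,
                                pad_factor = 4L) {
  if (inherits(mode, "mode_set")) stop("pass a single mode vector column")
  mode <- as.numeric(mode)
  if (length(mode) != 3L * n_sites(traj))
    stop(sprintf("mode length %d does not match 3 x %d sites",
                 length(mode), n_sites(traj)))
  U <- sweep(flatten_frames(traj$vel), 2, rep(sqrt(masses), each = 3),
             "*")
  u <- U %*% mode                      # scalar mode velocity
  L <- as.integer(round(t_max / traj$dt))
  C <- corr_lags(u, L, origin_stride, symmetrize = TRUE)
  corr <- structure(list(lags = (0:L) * traj$dt, C = C, dt = traj$dt,
                         masses = 1, reference = NULL,
                         symmetrized = TRUE),
                    class = "corr_series")
  sp <- spectral_matrix(corr, window_fwhm, pad_factor)
  new_spectrum(sp$freq, sp$S[1, 1, ])
}
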