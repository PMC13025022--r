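#' Langevin dynamics integrator (BAOAB splitting)
#'
#' Integrates underdamped Langevin dynamics for an arbitrary force field
#' with the BAOAB splitting: half kick, half drift, exact
#' Ornstein-Uhlenbeck velocity update, half drift, half kick.  BAOAB gives
#' accurate configurational sampling at moderate time steps and an exact
#' stationary velocity distribution in the free-particle limit.
#'
#' Units: nm, ps, amu, kJ/mol, K (so `kB = 0.0083144621` kJ/mol/K).
#'
#' @param force_fn function taking an `[n, 3]` position matrix and
#'   returning the `[n, 3]` force matrix (kJ/mol/nm)
#' @param masses per-site masses (amu)
#' @param x0 `[n, 3]` initial positions (nm)
#' @param dt integration step (ps)
#' @param n_steps number of integration steps
#' @param friction Langevin friction (1/ps)
#' @param temperature K
#' @param seed integer seed; same seed gives a bit-identical trajectory
#' @param output_stride store every `output_stride`-th step
#' @param burn_in fraction of steps discarded before output starts
#' @param v0 optional initial velocities; default Maxwell-Boltzmann draw
#' @return a [trajectory()] with `dt = output_stride * dt`
#' @export
langevin_dynamics <- function(force_fn, masses, x0, dt, n_steps,
                              friction = 1, temperature = 300, seed = 1,
                              output_stride = 1L, burn_in = 0.1,
                              v0 = NULL) {
  stopifnot(dt > 0, n_steps >= 1, friction >= 0, temperature >= 0)
  set.seed(seed)
  n <- nrow(x0)
  m <- matrix(rep(masses, 3), n, 3)
  kT <- kB * temperature
  sd_v <- sqrt(kT / m)
  x <- as.matrix(x0)
  v <- if (is.null(v0)) matrix(stats::rnorm(3 * n), n, 3) * sd_v
       else as.matrix(v0)
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2)
  n_burn <- floor(burn_in * n_steps)
  keep <- seq.int(n_burn + output_stride, n_steps, by = output_stride)
  nf <- length(keep)
  if (nf < 1L) stop("no frames left after burn-in; increase n_steps")
  pos <- array(0, c(nf, n, 3L))
  vel <- array(0, c(nf, n, 3L))
  f <- force_fn(x)
  out_i <- 1L
  e_scale <- max(3 * n * kT, 1)   # divergence guard scale
  for (s in seq_len(n_steps)) {
    v <- v + (0.5 * dt) * f / m
    x <- x + (0.5 * dt) * v
    v <- c1 * v + c2 * sd_v * matrix(stats::rnorm(3 * n), n, 3)
    x <- x + (0.5 * dt) * v
    f <- force_fn(x)
    v <- v + (0.5 * dt) * f / m
    if (s %% 1000L == 0L || s == n_steps) {
      ke <- 0.5 * sum(m * v * v)
      if (!is.finite(ke) || ke > 1e4 * e_scale)
        stop(sprintf(paste0("unstable integration at step %d: kinetic ",
                            "energy %.3g kJ/mol (reduce dt)"), s, ke))
    }
    if (out_i <= nf && s == keep[out_i]) {
      pos[out_i, , ] <- x
      vel[out_i, , ] <- v
      out_i <- out_i + 1L
    }
  }
  trajectory(pos, vel, dt = output_stride * dt)
}
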