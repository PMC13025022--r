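#' Harmonic bead-spring networks
#'
#' A `harmonic_network` is the package's analytically tractable stand-in
#' for a coarse-grained protein: point masses connected by Hookean springs
#' (optionally with finite rest lengths), evolved with Langevin dynamics at
#' a set temperature.  Its normal modes are known exactly, which makes it
#' the oracle for every spectral operation.
#'
#' @param masses bead masses (amu), length n >= 2
#' @param springs data frame with columns `i`, `j` (bead indices), `k`
#'   (stiffness, kJ/mol/nm^2) and optionally `r0` (rest length, nm).
#'   When `r0` is absent it defaults to the bead separation in `coords0`
#'   (elastic-network convention), so the supplied geometry is an
#'   equilibrium.  An explicit `r0 = 0` makes the spring act on the
#'   displacement difference vector itself (resisting transverse motion
#'   too).
#' @param coords0 `[n, 3]` equilibrium coordinates (nm)
#' @param temperature K
#' @param friction Langevin friction (1/ps)
#' @return an object of class `harmonic_network`
#' @export
harmonic_network <- function(masses, springs, coords0, temperature = 300,
                             friction = 1) {
  coords0 <- as.matrix(coords0)
  springs <- as.data.frame(springs)
  if (is.null(springs$r0))
    springs$r0 <- sqrt(rowSums((coords0[springs$i, , drop = FALSE] -
                                coords0[springs$j, , drop = FALSE])^2))
  stopifnot(length(masses) >= 2, all(masses > 0), all(springs$k > 0),
            nrow(coords0) == length(masses), ncol(coords0) == 3,
            all(springs$i >= 1), all(springs$j >= 1),
            all(springs$i <= length(masses)),
            all(springs$j <= length(masses)), all(springs$i != springs$j))
  net <- structure(list(masses = as.numeric(masses),
                        springs = tibble::as_tibble(springs),
                        coords0 = coords0,
                        temperature = temperature, friction = friction),
                   class = "harmonic_network")
  net$n_components <- network_components(net)
  # incidence matrix (n_springs x n): +1 at i, -1 at j; lets forces be
  # computed with two BLAS products per step
  B <- matrix(0, nrow(springs), length(masses))
  B[cbind(seq_len(nrow(springs)), springs$i)] <- 1
  B[cbind(seq_len(nrow(springs)), springs$j)] <- -1
  net$incidence <- B
  net
}

# connected components of the spring graph; >1 means extra zero modes
network_components <- function(net) {
  n <- length(net$masses)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (s in seq_len(nrow(net$springs))) {
      i <- net$springs$i[s]; j <- net$springs$j[s]
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) {
        comp[comp == comp[i] | comp == comp[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

#' @export
print.harmonic_network <- function(x, ...) {
  cat(sprintf(
    "<harmonic_network> %d beads, %d springs, T = %g K, gamma = %g/ps\n",
    length(x$masses), nrow(x$springs), x$temperature, x$friction))
  invisible(x)
}

#' Forces of a harmonic network at given positions
#' @param net a [harmonic_network()]
#' @param x `[n, 3]` positions (nm)
#' @return `[n, 3]` forces (kJ/mol/nm)
#' @export
network_forces <- function(net, x) {
  d <- net$incidence %*% x          # per-spring separation vectors
  if (all(net$springs$r0 == 0)) {
    fij <- -net$springs$k * d
  } else {
    r <- sqrt(rowSums(d * d))
    fij <- -(net$springs$k * (r - net$springs$r0) / r) * d
  }
  crossprod(net$incidence, fij)     # force on i gets +fij, on j gets -fij
}

#' Analytic Hessian of a harmonic network
#'
#' Per spring pair at separation vector `d` (unit `u`, length `r`), the 3x3
#' pair block is `k u u^T + k (r - r0)/r (I - u u^T)`; at `r0 = 0` this is
#' `k I`.  Evaluated at the supplied coordinates (default: equilibrium).
#'
#' @param net a [harmonic_network()]
#' @param x coordinates to expand about; default `net$coords0`
#' @return the `3n x 3n` Cartesian Hessian (kJ/mol/nm^2)
#' @export
network_hessian <- function(net, x = net$coords0) {
  n <- length(net$masses)
  H <- matrix(0, 3 * n, 3 * n)
  for (s in seq_len(nrow(net$springs))) {
    i <- net$springs$i[s]; j <- net$springs$j[s]
    k <- net$springs$k[s]; r0 <- net$springs$r0[s]
    d <- x[i, ] - x[j, ]
    if (r0 == 0) {
      Kp <- k * diag(3)
    } else {
      r <- sqrt(sum(d * d))
      u <- d / r
      Kp <- k * tcrossprod(u) + k * (r - r0) / r * (diag(3) - tcrossprod(u))
    }
    ii <- (3 * (i - 1) + 1):(3 * i)
    jj <- (3 * (j - 1) + 1):(3 * j)
    H[ii, ii] <- H[ii, ii] + Kp
    H[jj, jj] <- H[jj, jj] + Kp
    H[ii, jj] <- H[ii, jj] - Kp
    H[jj, ii] <- H[jj, ii] - Kp
  }
  H
}

#' Analytic normal modes of a harmonic network
#'
#' Eigendecomposition of the mass-weighted Hessian
#' `K = M^{-1/2} H M^{-1/2}`.  Eigenvalues are in 1/ps^2; harmonic
#' frequencies are reported in cm^-1 via `nu = sqrt(lambda) / (2 pi c)`.
#' Modes are sorted by frequency ascending.  A free (untethered) 3D network
#' has 6 zero-frequency modes (3 translations + 3 rotations); disconnected
#' networks have more, which is flagged but not an error.
#'
#' @param net a [harmonic_network()]
#' @param zero_tol eigenvalues below `zero_tol * max(lambda)` count as zero
#' @return a [mode_set()] with `frequencies` (cm^-1) and attribute
#'   `n_zero_modes`
#' @export
analytic_normal_modes <- function(net, zero_tol = 1e-9) {
  n <- length(net$masses)
  H <- network_hessian(net)
  sm <- rep(1 / sqrt(net$masses), each = 3)
  K <- H * tcrossprod(sm)           # M^-1/2 H M^-1/2
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  ord <- order(eig$values)          # ascending frequency
  lambda <- eig$values[ord]
  vec <- eig$vectors[, ord, drop = FALSE]
  lam_pos <- pmax(lambda, 0)
  freqs <- angular_ps_to_wavenumber(sqrt(lam_pos))
  out <- mode_set(vec, lambda, net$masses, freq_tag = NA_real_,
                  reference = net$coords0, frequencies = freqs,
                  kind = "hessian")
  attr(out, "n_zero_modes") <-
    sum(abs(lambda) < zero_tol * max(abs(lambda), 1e-300))
  if (net$n_components > 1L)
    attr(out, "disconnected") <- net$n_components
  out
}

#' Langevin trajectory of a harmonic network
#'
#' Integrates the network with [langevin_dynamics()] starting from its
#' equilibrium coordinates.  The step must resolve the fastest normal mode
#' (`dt * nu_max * c < 0.05`, i.e. at least 20 steps per fastest period).
#'
#' @param net a [harmonic_network()]
#' @param dt integration step (ps)
#' @param n_steps number of steps
#' @param seed RNG seed
#' @param output_stride store every k-th step
#' @param burn_in fraction of steps discarded (default 10%)
#' @return a [trajectory()]
#' @export
langevin_trajectory <- function(net, dt, n_steps, seed = 1,
                                output_stride = 1L, burn_in = 0.1) {
  nm <- analytic_normal_modes(net)
  nu_max <- max(nm$frequencies)
  if (dt * nu_max * SPEED_OF_LIGHT_CM_PS >= 0.05)
    stop(sprintf(
      "dt = %g ps too large for fastest mode (%.1f cm^-1): need dt < %.4g ps",
      dt, nu_max, 0.05 / (nu_max * SPEED_OF_LIGHT_CM_PS)))
  langevin_dynamics(function(x) network_forces(net, x),
                    net$masses, net$coords0, dt, n_steps,
                    friction = net$friction,
                    temperature = net$temperature, seed = seed,
                    output_stride = output_stride, burn_in = burn_in)
}

#' Rigid-body diffusion trajectory
#'
#' Generates a trajectory of a perfectly rigid body undergoing thermal
#' translational and rotational diffusion: the centre-of-mass velocity and
#' the body-frame angular velocity follow Ornstein-Uhlenbeck processes with
#' equipartition variances (`kT/M` per translational component, `kT/I_a`
#' per principal axis), and the orientation is propagated by exact
#' rotation-map updates, so intra-body distances are conserved to round-off.
#'
#' @param coords `[n, 3]` body geometry (nm), n >= 3, non-collinear
#' @param masses bead masses (amu)
#' @param temperature K (0 gives a static trajectory)
#' @param friction OU relaxation rate (1/ps)
#' @param dt time step between frames (ps)
#' @param n_steps number of frames
#' @param seed RNG seed
#' @return a [trajectory()] with exact rigid-body velocities
#' @export
rigid_body_trajectory <- function(coords, masses, temperature = 300,
                                  friction = 1, dt = 0.02, n_steps = 1000,
                                  seed = 1) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 3, length(masses) == nrow(coords))
  check_noncollinear(coords)
  set.seed(seed)
  n <- nrow(coords)
  M <- sum(masses)
  com <- colSums(coords * masses) / M
  q <- sweep(coords, 2, com)        # body-frame coordinates about COM
  # principal inertia tensor
  I3 <- diag(3)
  Iten <- matrix(0, 3, 3)
  for (i in seq_len(n))
    Iten <- Iten + masses[i] * (sum(q[i, ]^2) * I3 - tcrossprod(q[i, ]))
  ev <- eigen(Iten, symmetric = TRUE)
  axes <- ev$vectors                # columns: principal axes
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]  # keep a proper rotation
  Iprin <- ev$values
  q <- q %*% axes                   # express geometry in principal frame
  kT <- kB * temperature
  a <- exp(-friction * dt)
  sig_v <- sqrt(kT / M)
  sig_w <- sqrt(kT / Iprin)
  V <- stats::rnorm(3) * sig_v
  W <- stats::rnorm(3) * sig_w      # body-frame angular velocity
  R <- diag(3)
  X <- com
  pos <- array(0, c(n_steps, n, 3))
  vel <- array(0, c(n_steps, n, 3))
  b <- sqrt(1 - a^2)
  for (s in seq_len(n_steps)) {
    pos[s, , ] <- sweep(q %*% t(R), 2, X, "+")
    # v_i = V + R (W x q_i)
    wq <- cbind(W[2] * q[, 3] - W[3] * q[, 2],
                W[3] * q[, 1] - W[1] * q[, 3],
                W[1] * q[, 2] - W[2] * q[, 1])
    vel[s, , ] <- sweep(wq %*% t(R), 2, V, "+")
    X <- X + V * dt
    R <- R %*% rotation_exp(W * dt)
    V <- a * V + b * sig_v * stats::rnorm(3)
    W <- a * W + b * sig_w * stats::rnorm(3)
    if (s %% 1000L == 0L) {         # guard against orthogonality drift
      sv <- svd(R); R <- sv$u %*% t(sv$v)
    }
  }
  trajectory(pos, vel, dt = dt)
}

# Rodrigues rotation about axis w*|w| by angle |w| (exact exponential map)
rotation_exp <- function(w) {
  th <- sqrt(sum(w * w))
  if (th < 1e-300) return(diag(3))
  u <- w / th
  Kx <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
}

#' Two-state coarse-grained toy system with a known transition mode
#'
#' A bead network held near a reference geometry by a (tethered) harmonic
#' energy in all directions orthogonal to one declared collective
#' displacement vector, along which the potential is a symmetric double
#' well `B ((Q/Q0)^2 - 1)^2` with barrier height `B` (given in kBT) and
#' minima at `Q = +/- Q0`.  The declared transition mode is exactly the
#' displacement direction between the two minima.
#'
#' @param n_beads number of beads
#' @param barrier_kT barrier height between the two wells, in units of kBT
#' @param q0 half-distance between minima along the collective coordinate
#'   (nm, in the unnormalized Cartesian direction)
#' @param stiffness orthogonal restraint stiffness (kJ/mol/nm^2)
#' @param temperature K
#' @param friction 1/ps
#' @param seed seed used to draw the (fixed) geometry and mode direction
#' @return an object of class `two_state_system`: fields `force_fn`, `x0`
#'   (reference geometry), `masses`, `transition_mode` (3n unit vector),
#'   `minima` (two `[n,3]` geometries), `q0`, `barrier` (kJ/mol),
#'   `potential_1d` (function of Q)
#' @export
two_state_system <- function(n_beads = 6, barrier_kT = 8, q0 = 0.15,
                             stiffness = 2000, temperature = 300,
                             friction = 2, seed = 1) {
  set.seed(seed)
  masses <- rep(100, n_beads)
  # fixed, well-spread geometry
  x0 <- matrix(stats::rnorm(3 * n_beads, sd = 0.4), n_beads, 3)
  x0 <- sweep(x0, 2, colMeans(x0))
  d <- stats::rnorm(3 * n_beads)
  d <- d / sqrt(sum(d * d))         # Cartesian transition direction
  B <- barrier_kT * kB * temperature
  flat <- function(x) as.numeric(t(x))      # [n,3] -> (x1,y1,z1,...)
  unflat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  x0f <- flat(x0)
  if (barrier_kT > 0) {
    v_dw <- function(Q) B * ((Q / q0)^2 - 1)^2
    dv_dw <- function(Q) 4 * B * Q * ((Q / q0)^2 - 1) / q0^2
  } else {
    # zero barrier: unimodal quartic of comparable stiffness
    a <- kB * temperature / q0^4
    v_dw <- function(Q) a * Q^4
    dv_dw <- function(Q) 4 * a * Q^3
  }
  force_fn <- function(x) {
    delta <- flat(x) - x0f
    Q <- sum(d * delta)
    perp <- delta - Q * d
    g <- stiffness * perp + dv_dw(Q) * d    # gradient
    unflat(-g)
  }
  structure(list(force_fn = force_fn, x0 = x0, masses = masses,
                 transition_mode = d,
                 minima = list(unflat(x0f + q0 * d), unflat(x0f - q0 * d)),
                 q0 = q0, barrier = B, potential_1d = v_dw,
                 temperature = temperature, friction = friction,
                 stiffness = stiffness),
            class = "two_state_system")
}

#' Langevin trajectory of a two-state system
#'
#' @param sys a [two_state_system()]
#' @param dt time step (ps)
#' @param n_steps number of steps
#' @param seed RNG seed
#' @param output_stride store every k-th step
#' @param start `"minimum"` (default: start in the `+Q0` well) or
#'   `"reference"`
#' @return a [trajectory()]
#' @export
two_state_trajectory <- function(sys, dt = 0.005, n_steps = 1e4, seed = 1,
                                 output_stride = 1L, start = "minimum") {
  x0 <- if (start == "minimum") sys$minima[[1]] else sys$x0
  langevin_dynamics(sys$force_fn, sys$masses, x0, dt, n_steps,
                    friction = sys$friction,
                    temperature = sys$temperature, seed = seed,
                    output_stride = output_stride, burn_in = 0)
}

#' Project a trajectory on the declared transition coordinate
#' @param sys a [two_state_system()]
#' @param traj a matching [trajectory()]
#' @return numeric vector Q(t)
#' @export
two_state_q <- function(sys, traj) {
  n <- length(sys$masses)
  delta <- flatten_frames(traj$pos) -
    matrix(as.numeric(t(sys$x0)), n_frames(traj), 3 * n, byrow = TRUE)
  as.numeric(delta %*% sys$transition_mode)
}
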