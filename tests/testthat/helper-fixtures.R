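# Shared fixtures: small analytic systems and synthetic files, all built in
# code at test time.

kT300 <- freseanr::kB * 300

# two equal masses, one spring: the textbook dimer with stretch frequency
# sqrt(2k/m)
dimer_net <- function(m = 10, k = 500, sep = 0.5, friction = 1) {
  harmonic_network(c(m, m), data.frame(i = 1, j = 2, k = k),
                   rbind(c(0, 0, 0), c(sep, 0, 0)), friction = friction)
}

# 3-bead triangle with well-separated internal frequencies (~20/44/60 cm^-1)
triangle_net <- function(friction = 0.5) {
  x3 <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.2, 0.45, 0))
  pr <- t(utils::combn(3, 2))
  harmonic_network(c(12, 30, 60),
                   data.frame(i = pr[, 1], j = pr[, 2],
                              k = c(150, 700, 2500)),
                   x3, friction = friction)
}

# fully braced n-bead cluster (all-pairs springs): exactly 6 zero modes
braced_cluster <- function(n = 5, k = 300, masses = rep(12, n),
                           seed = 2, friction = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(3 * n, sd = 0.5), n, 3)
  pr <- t(utils::combn(n, 2))
  harmonic_network(masses, data.frame(i = pr[, 1], j = pr[, 2], k = k),
                   x, friction = friction)
}

# soft 10-bead network used for the replica-reproducibility analogue
soft_network <- function() {
  set.seed(42)
  n <- 10
  x <- matrix(stats::rnorm(3 * n, sd = 0.4), n, 3)
  pr <- t(utils::combn(n, 2))
  harmonic_network(rep(50, n),
                   data.frame(i = pr[, 1], j = pr[, 2], k = 1000),
                   x, friction = 1)
}

fresean_zero_modes <- function(traj, masses, t_max = 2, window = 10) {
  cc <- velocity_cross_correlation(traj, masses, t_max = t_max)
  fresean_modes(spectral_matrix(cc, window), 0)
}

# synthetic GRO file for a given residue sequence with standard atom names
write_test_gro <- function(resnames, path = tempfile(fileext = ".gro"),
                           seed = 1) {
  set.seed(seed)
  atoms_of <- function(rn) {
    if (rn == "GLY") c("N", "H", "CA", "HA1", "HA2", "C", "O")
    else c("N", "H", "CA", "HA", "CB", "HB1", "HB2", "HB3", "C", "O")
  }
  lines <- c("synthetic peptide", "")
  atnum <- 0L
  for (r in seq_along(resnames)) {
    ats <- atoms_of(resnames[r])
    for (a in ats) {
      atnum <- atnum + 1L
      lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                                r, resnames[r], a, atnum,
                                stats::runif(1), stats::runif(1),
                                stats::runif(1)))
    }
  }
  lines[2] <- sprintf("%d", atnum)
  lines <- c(lines, "   3.0   3.0   3.0")
  writeLines(lines, path)
  path
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]),
           2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
         3, 3, byrow = TRUE)
}

# unit mode orthogonal to the rigid-body subspace of (reference, masses)
nonrigid_unit_mode <- function(reference, masses, seed = 1,
                               orthogonal_to = NULL) {
  set.seed(seed)
  V <- rigid_body_basis(reference, masses)
  raw <- stats::rnorm(3 * nrow(reference))
  raw <- raw - V %*% crossprod(V, raw)
  if (!is.null(orthogonal_to))
    raw <- raw - orthogonal_to %*% crossprod(
      as.matrix(orthogonal_to), raw)
  as.numeric(raw / sqrt(sum(raw^2)))
}
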