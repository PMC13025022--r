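# Synthetic generators: analytic normal modes, Langevin sampling,
# rigid-body diffusion, two-state systems, toy well-tempered metadynamics.

test_that("analytic normal modes reproduce the textbook dimer", {
  m <- 10; k <- 500
  nm <- analytic_normal_modes(dimer_net(m, k))
  expect_equal(max(nm$frequencies),
               angular_ps_to_wavenumber(sqrt(2 * k / m)),
               tolerance = 1e-10)
  # free dimer: 3 translations + 2 rotations at zero
  expect_identical(attr(nm, "n_zero_modes"), 5L)
  G <- crossprod(nm$vectors)
  expect_lt(max(abs(G - diag(6))), 1e-10)
})

test_that("a braced 5-bead 3D cluster has exactly 6 zero modes", {
  nm <- analytic_normal_modes(braced_cluster(5))
  expect_identical(attr(nm, "n_zero_modes"), 6L)
})

test_that("analytic Hessian matches a finite-difference Hessian", {
  net <- braced_cluster(10, k = 400, seed = 7)
  H <- network_hessian(net)
  n <- length(net$masses)
  h <- 1e-5
  Hfd <- matrix(0, 3 * n, 3 * n)
  for (dof in seq_len(3 * n)) {
    bead <- (dof - 1) %/% 3 + 1; axis <- (dof - 1) %% 3 + 1
    xp <- net$coords0; xp[bead, axis] <- xp[bead, axis] + h
    xm <- net$coords0; xm[bead, axis] <- xm[bead, axis] - h
    Hfd[, dof] <- as.numeric(t(network_forces(net, xm) -
                               network_forces(net, xp))) / (2 * h)
  }
  expect_lt(max(abs(H - Hfd)), 1e-3 * max(abs(H)))
  # eigenvectors of the mass-weighted FD Hessian agree mode by mode
  sm <- rep(1 / sqrt(net$masses), each = 3)
  eig_fd <- eigen((Hfd + t(Hfd)) / 2 * tcrossprod(sm), symmetric = TRUE)
  nm <- analytic_normal_modes(net)
  vec_fd <- eig_fd$vectors[, order(eig_fd$values)]
  for (k in 7:(3 * n)) # above the zero-mode block (degenerate there)
    expect_gt(mode_correlation(nm$vectors[, k], vec_fd[, k]), 0.999)
})

test_that("disconnected networks are flagged with extra zero modes", {
  # two separate dimers: 2 components, 10 zero modes
  net <- harmonic_network(rep(5, 4),
                          data.frame(i = c(1, 3), j = c(2, 4), k = 100),
                          matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0, 1, 2, 0),
                                 4, 3, byrow = TRUE))
  expect_identical(net$n_components, 2L)
  nm <- analytic_normal_modes(net)
  expect_identical(attr(nm, "disconnected"), 2L)
  expect_identical(attr(nm, "n_zero_modes"), 10L)
})

test_that("Langevin sampling satisfies equipartition and is deterministic", {
  net <- triangle_net(friction = 5)
  tr <- langevin_trajectory(net, dt = 0.008, n_steps = 4e5, seed = 7)
  ke_per_dof <- sapply(1:3, function(a)
    0.5 * net$masses * colMeans(tr$vel[, , a]^2))
  expect_lt(max(abs(ke_per_dof / (kT300 / 2) - 1)), 0.03)
  tr2 <- langevin_trajectory(net, dt = 0.01, n_steps = 2000, seed = 3)
  tr3 <- langevin_trajectory(net, dt = 0.01, n_steps = 2000, seed = 3)
  expect_identical(tr2$pos, tr3$pos)
  expect_identical(tr2$vel, tr3$vel)
})

test_that("time step must resolve the fastest mode", {
  expect_error(langevin_trajectory(dimer_net(), dt = 0.05, n_steps = 10),
               "too large")
})

test_that("strongly damped velocities decorrelate monotonically", {
  # free particle at high friction: VACF = kT/m exp(-gamma t)
  tr <- langevin_dynamics(function(x) 0 * x, masses = 10,
                          x0 = matrix(0, 1, 3), dt = 0.01,
                          n_steps = 2e5, friction = 20, seed = 5)
  v <- tr$vel[, 1, 1]
  acf <- sapply(0:8, function(l)
    mean(v[1:(length(v) - l)] * v[(1 + l):length(v)]))
  expect_true(all(diff(acf) < 0))
})

test_that("unstable integration aborts with a diagnostic", {
  net <- dimer_net(m = 1, k = 5000)
  expect_error(
    langevin_dynamics(function(x) network_forces(net, x), net$masses,
                      net$coords0 + 0.5, dt = 0.5, n_steps = 5000,
                      friction = 0, temperature = 300, seed = 1),
    "unstable")
})

test_that("rigid-body trajectories are rigid, diffusive, and thermal", {
  set.seed(5)
  x <- matrix(rnorm(30, sd = 0.5), 10, 3)
  ms <- runif(10, 50, 150)
  tr <- rigid_body_trajectory(x, ms, temperature = 300, friction = 2,
                              dt = 0.02, n_steps = 2e4, seed = 5)
  d0 <- as.numeric(dist(tr$pos[1, , ]))
  dN <- as.numeric(dist(tr$pos[n_frames(tr), , ]))
  expect_lt(max(abs(d0 - dN)), 1e-9)
  # centre-of-mass MSD grows roughly linearly in t
  w <- ms / sum(ms)
  com <- sapply(1:3, function(a) tr$pos[, , a] %*% w)
  lags <- c(500, 1000, 2000, 4000)
  msd <- sapply(lags, function(l)
    mean(rowSums((com[-(1:l), , drop = FALSE] -
                  com[1:(nrow(com) - l), , drop = FALSE])^2)))
  slope <- coef(lm(log(msd) ~ log(lags)))[2]
  expect_gt(slope, 0.7)
  expect_lt(slope, 1.4)
  # zero temperature: static
  tr0 <- rigid_body_trajectory(x, ms, temperature = 0, dt = 0.02,
                               n_steps = 50, seed = 5)
  expect_equal(max(abs(sweep(tr0$pos, c(2, 3), tr0$pos[1, , ]))), 0)
  expect_equal(max(abs(tr0$vel)), 0)
  # collinear bodies are rejected
  xc <- cbind(1:4, 0, 0)
  expect_error(rigid_body_trajectory(xc, rep(1, 4), seed = 1),
               "collinear")
})

test_that("two-state systems have the declared transition mode", {
  sys <- two_state_system(n_beads = 6, barrier_kT = 8, q0 = 0.15,
                          seed = 5)
  dm <- as.numeric(t(sys$minima[[1]] - sys$minima[[2]]))
  dm <- dm / sqrt(sum(dm^2))
  expect_gt(abs(sum(dm * sys$transition_mode)), 0.95)
  expect_equal(sys$barrier, 8 * kT300)
})

test_that("an 8 kT barrier suppresses transitions in an unbiased run", {
  sys <- two_state_system(n_beads = 6, barrier_kT = 8, q0 = 0.15,
                          seed = 5)
  tr <- two_state_trajectory(sys, dt = 0.005, n_steps = 1e5, seed = 7,
                             output_stride = 10)
  q <- two_state_q(sys, tr)
  expect_lte(sum(diff(sign(q)) != 0), 2)   # 0 or few crossings
})

test_that("zero barrier gives unimodal sampling around the reference", {
  sys <- two_state_system(n_beads = 6, barrier_kT = 0, q0 = 0.15,
                          seed = 5)
  tr <- two_state_trajectory(sys, dt = 0.005, n_steps = 5e4, seed = 7,
                             output_stride = 10, start = "reference")
  q <- two_state_q(sys, tr)
  expect_gt(sum(diff(sign(q)) != 0), 50)   # crosses 0 constantly
  expect_lt(abs(median(q)), sys$q0 / 2)    # centred, single basin
})

test_that("unbiased toy dynamics samples the Boltzmann distribution", {
  pot <- toy_potential("double_well", list(barrier = 2 * kT300,
                                           x0 = 0.5))
  run <- toy_wt_metadynamics(pot, height = 0, sigma = 0.1,
                             n_steps = 1e6, dt = 0.002, friction = 2,
                             seed = 3)
  expect_identical(nrow(run$colvar), 100000L)
  gr <- seq(-2.5, 2.5, length.out = 4001)
  p <- exp(-pot$value(cbind(gr)) / kT300); p <- p / sum(p)
  ks <- max(abs(ecdf(run$colvar$cv1)(gr) - cumsum(p)))
  expect_lt(ks, 0.05)
})

test_that("deposited well-tempered bias converges to -(1-1/gamma) F", {
  pot <- toy_potential("double_well", list(barrier = 2 * kT300,
                                           x0 = 0.5))
  g <- 8
  run <- toy_wt_metadynamics(pot, height = 1.2, sigma = 0.08,
                             pace = 250, bias_factor = g,
                             n_steps = 4e5, dt = 0.002, friction = 5,
                             seed = 4)
  wells <- abs(run$grid[[1]]) < 0.75
  resid <- run$bias[wells] +
    (1 - 1 / g) * pot$value(cbind(run$grid[[1]][wells]))
  resid <- resid - mean(resid)
  expect_lt(max(abs(resid)), kT300)
})

test_that("large bias factors fill a symmetric double well evenly", {
  pot <- toy_potential("double_well", list(barrier = 2 * kT300,
                                           x0 = 0.5))
  run <- toy_wt_metadynamics(pot, height = 1.5, sigma = 0.08,
                             pace = 200, bias_factor = 50,
                             n_steps = 1e6, dt = 0.002, friction = 5,
                             seed = 6)
  x <- run$colvar$cv1[run$colvar$time > 0.2 * max(run$colvar$time)]
  ratio <- sum(x > 0) / sum(x < 0)
  expect_gt(ratio, 1 / 1.1)
  expect_lt(ratio, 1.1)
})

test_that("toy metadynamics is reproducible and validates inputs", {
  pot <- toy_potential("double_well")
  r1 <- toy_wt_metadynamics(pot, height = 1, sigma = 0.1, pace = 100,
                            bias_factor = 10, n_steps = 5000, seed = 9)
  r2 <- toy_wt_metadynamics(pot, height = 1, sigma = 0.1, pace = 100,
                            bias_factor = 10, n_steps = 5000, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_plumed_table(r1$hills, f1)
  write_plumed_table(r2$hills, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(toy_wt_metadynamics(pot, height = 1, sigma = 0.1,
                                   bias_factor = 1), "gamma")
  expect_error(toy_wt_metadynamics(pot, height = 1, sigma = -1,
                                   bias_factor = 5), "sigma")
})

test_that("toy potentials are bounded below with known minima", {
  for (form in c("double_well", "harmonic_valley", "double_well_2d",
                 "mueller_brown")) {
    pot <- toy_potential(form)
    x <- matrix(runif(200 * pot$dim, -2, 2), ncol = pot$dim)
    expect_true(all(is.finite(pot$value(x))))
    vmin <- pot$value(pot$minima)
    expect_lte(min(vmin), min(pot$value(x)) + 1e-9)
    # gradient vanishes near the declared minima (mueller_brown's are
    # literature values quoted to 3 decimals)
    g <- pot$gradient(pot$minima)
    expect_lt(max(abs(g)), if (form == "mueller_brown") 0.5 else 1e-8)
  }
})
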