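# COLVAR/HILLS parsing, bias reconstruction, reweighting, free-energy
# surfaces, information metrics, states, microstates and paths.

toy_biased_run <- function(barrier_kT = 3, tilt = 0, n_steps = 3e5,
                           seed = 41) {
  pot <- toy_potential("double_well",
                       list(barrier = barrier_kT * kT300, x0 = 0.5,
                            tilt = tilt))
  run <- toy_wt_metadynamics(pot, height = 1.2, sigma = 0.08,
                             pace = 250, bias_factor = 8,
                             n_steps = n_steps, dt = 0.002,
                             friction = 5, seed = seed)
  list(pot = pot, run = run)
}

test_that("PLUMED tables parse by field name and report bad input", {
  f <- tempfile()
  writeLines(c("#! FIELDS time d1 bias",
               "0.0 1.5 0.1", "1.0 1.6 0.2", "2.0 1.4 0.3"), f)
  cv <- read_colvar(f)
  expect_identical(nrow(cv), 3L)
  expect_equal(cv$d1, c(1.5, 1.6, 1.4))
  expect_error(read_colvar(f, require_fields = "missing_cv"),
               "missing_cv")
  writeLines(c("#! FIELDS time d1", "0.0 1.0", "0.5 2.0 99"), f)
  expect_error(read_colvar(f), "malformed line 3")
  writeLines(c("1 2 3"), f)
  expect_error(read_colvar(f), "FIELDS")
  # decreasing HILLS times are rejected
  writeLines(c("#! FIELDS time cv1 sigma_cv1 height biasf",
               "1 0 0.1 1 10", "0.5 0 0.1 1 10"), f)
  expect_error(read_hills(f), "increasing")
})

test_that("toy-engine COLVAR/HILLS files round-trip", {
  tb <- toy_biased_run(n_steps = 2e4)
  cf <- tempfile(); hf <- tempfile()
  write_plumed_table(tb$run$colvar, cf)
  write_plumed_table(tb$run$hills, hf)
  cv <- read_colvar(cf, require_fields = c("time", "cv1", "metad.bias"))
  hl <- read_hills(hf, require_fields = c("time", "cv1", "sigma_cv1",
                                          "height", "biasf"))
  expect_equal(as.matrix(cv), as.matrix(tb$run$colvar),
               tolerance = 1e-7)
  expect_equal(as.matrix(hl), as.matrix(tb$run$hills),
               tolerance = 1e-7)
})

test_that("bias reconstruction sums Gaussians exactly", {
  h <- tibble::tibble(time = c(1, 2), cv1 = c(0, 0),
                      sigma_cv1 = c(0.1, 0.1), height = c(1.2, 1.2),
                      biasf = 10)
  expect_equal(bias_at(h[0, ], 0), 0)
  expect_equal(bias_at(h[1, ], 0), 1.2)
  expect_equal(bias_at(h, 0), 2.4)
  expect_equal(bias_at(h, 0.1), 2.4 * exp(-0.5))
  expect_equal(bias_at(h, 0, up_to_time = 1), 1.2)
  # vectorized over points
  expect_equal(bias_at(h, cbind(c(0, 0.1))),
               c(2.4, 2.4 * exp(-0.5)))
})

test_that("reweighting handles trivial cases", {
  cv <- tibble::tibble(time = 1:100, cv1 = rnorm(100))
  h0 <- tibble::tibble(time = numeric(), cv1 = numeric(),
                       sigma_cv1 = numeric(), height = numeric(),
                       biasf = numeric())
  en <- reweight(cv, h0, 300)
  expect_equal(en$weights, rep(1 / 100, 100))
  expect_equal(sum(en$weights), 1)
  h1 <- tibble::tibble(time = 1, other = 0, sigma_other = 0.1,
                       height = 1, biasf = 10)
  expect_error(reweight(cv, h1, 300), "other")
  expect_error(reweight(cv, h0, 300, scheme = "nope"))
})

test_that("adding a constant to the bias leaves weights unchanged", {
  tb <- toy_biased_run(n_steps = 5e4)
  en <- reweight(tb$run$colvar, tb$run$hills, 300)
  # a near-infinite-width hill shifts the bias by a constant everywhere
  # (deposited at the existing end time so the transient-discard window
  # is unchanged)
  hshift <- tb$run$hills
  hshift[nrow(hshift) + 1L, ] <-
    list(max(hshift$time), 0, 1e6, 7.3, 8)
  en2 <- reweight(tb$run$colvar, hshift, 300)
  expect_equal(en2$weights, en$weights, tolerance = 1e-9)
})

test_that("final-bias reweighting recovers the analytic double well", {
  tb <- toy_biased_run(barrier_kT = 3, n_steps = 3e5, seed = 41)
  en <- reweight(tb$run$colvar, tb$run$hills, 300)
  f <- weighted_fes(en, vars = "cv1", bins = 50,
                    limits = list(c(-0.9, 0.9)))
  Fan <- tb$pot$value(cbind(f$centers[[1]])); Fan <- Fan - min(Fan)
  ok <- !is.na(f$F)
  expect_gt(sum(ok), 40)
  expect_lt(max(abs(f$F[ok] - Fan[ok])), kT300)
})

test_that("time-dependent reweighting also recovers the double well", {
  tb <- toy_biased_run(barrier_kT = 3, n_steps = 3e5, seed = 41)
  en <- reweight(tb$run$colvar, tb$run$hills, 300,
                 scheme = "time_dependent")
  f <- weighted_fes(en, vars = "cv1", bins = 50,
                    limits = list(c(-0.9, 0.9)))
  Fan <- tb$pot$value(cbind(f$centers[[1]])); Fan <- Fan - min(Fan)
  ok <- !is.na(f$F)
  expect_lt(max(abs(f$F[ok] - Fan[ok])), kT300)
})

test_that("free-energy surfaces are correct for known distributions", {
  set.seed(6)
  n <- 1e5
  sx <- 0.2; sy <- 0.35
  d <- tibble::tibble(x = rnorm(n, 0, sx), y = rnorm(n, 0, sy))
  f <- weighted_fes(d, vars = c("x", "y"), bins = 40,
                    limits = list(c(-0.5, 0.5), c(-0.9, 0.9)))
  td <- tidy(f)
  ok <- !is.na(td$F) & abs(td$x) < 0.3 & abs(td$y) < 0.5
  fit <- lm(F ~ I(x^2) + I(y^2), data = td[ok, ])
  expect_equal(2 * coef(fit)[[2]], kT300 / sx^2, tolerance = 0.1)
  expect_equal(2 * coef(fit)[[3]], kT300 / sy^2, tolerance = 0.1)
  # single occupied bin: F = 0 there, everything else masked
  d1 <- tibble::tibble(x = rep(0.1, 10), y = rep(0.2, 10))
  f1 <- weighted_fes(d1, vars = c("x", "y"), bins = 10,
                     limits = list(c(0, 1), c(0, 1)))
  expect_identical(sum(!is.na(f1$F)), 1L)
  expect_equal(min(f1$F, na.rm = TRUE), 0)
  # scaling all weights leaves F unchanged
  fa <- weighted_fes(d, vars = c("x", "y"), bins = 20,
                     weights = rep(1, n))
  fb <- weighted_fes(d, vars = c("x", "y"), bins = 20,
                     weights = rep(2, n))
  expect_identical(fa$F, fb$F)
  expect_error(weighted_fes(d, vars = c("x", "y"), bins = 10,
                            limits = list(c(5, 6), c(5, 6))),
               "outside")
})

test_that("replica averaging averages probabilities with std/SEM", {
  tbs <- lapply(1:4, function(r)
    toy_biased_run(barrier_kT = 3, n_steps = 1e5, seed = 100 + r))
  lims <- list(c(-0.9, 0.9))
  fl <- lapply(tbs, function(tb)
    weighted_fes(reweight(tb$run$colvar, tb$run$hills, 300),
                 vars = "cv1", bins = 40, limits = lims))
  avg <- average_fes(fl)
  expect_identical(avg$n_replicas, 4L)
  expect_equal(avg$sem, avg$std / sqrt(4), tolerance = 0)
  kTf <- kB * avg$temperature
  pbar <- Reduce(`+`, lapply(fl, function(f) f$P)) / 4
  Fbar <- -kTf * log(pbar); Fbar <- Fbar - min(Fbar, na.rm = TRUE)
  occ <- !is.na(avg$F)
  expect_equal(avg$F[occ], Fbar[occ], tolerance = 1e-9)
  # identical replicas: zero scatter
  same <- average_fes(list(fl[[1]], fl[[1]], fl[[1]]))
  expect_equal(max(same$std, na.rm = TRUE), 0)
  expect_equal(max(same$sem, na.rm = TRUE), 0)
  expect_error(average_fes(list(fl[[1]],
    weighted_fes(reweight(tbs[[1]]$run$colvar, tbs[[1]]$run$hills, 300),
                 vars = "cv1", bins = 30, limits = lims))),
    "grid")
})

test_that("Shannon entropy and Bhattacharyya match closed forms", {
  expect_equal(shannon_entropy(rep(1 / 256, 256)), 8)
  expect_equal(shannon_entropy(c(1, rep(0, 9))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_error(shannon_entropy(c(0.5, 0.4)), "not normalized")
  expect_equal(bhattacharyya(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 0)
  g <- seq(-12, 14, length.out = 20001)
  pa <- dnorm(g, 0, 1); pa <- pa / sum(pa)
  pb <- dnorm(g, 2, 1); pb <- pb / sum(pb)
  expect_equal(bhattacharyya(pa, pb), exp(-0.5), tolerance = 1e-3)
  expect_error(bhattacharyya(pa, pb[1:100]), "same grid")
})

test_that("reweighting into a second coordinate preserves entropy", {
  # bias along the double-well x; reweight and histogram the harmonic y:
  # the recovered S2 matches direct biasing of y
  pot <- toy_potential("double_well_2d",
                       list(barrier = 3 * kT300, x0 = 0.5, ky = 60))
  rx <- toy_wt_metadynamics(pot, height = 1.2, sigma = 0.08,
                            pace = 250, bias_factor = 8,
                            n_steps = 3e5, dt = 0.002, friction = 5,
                            seed = 21, bias_dims = 1L)
  ry <- toy_wt_metadynamics(pot, height = 1.2, sigma = 0.05,
                            pace = 250, bias_factor = 8,
                            n_steps = 3e5, dt = 0.002, friction = 5,
                            seed = 22, bias_dims = 2L)
  lims <- list(c(-0.8, 0.8))
  f_direct <- weighted_fes(reweight(ry$colvar, ry$hills, 300),
                           vars = "cv2", bins = 50, limits = lims)
  f_rw <- weighted_fes(reweight(rx$colvar, rx$hills, 300),
                       vars = "cv2", bins = 50, limits = lims)
  expect_gt(shannon_entropy(f_rw) / shannon_entropy(f_direct), 0.85)
  expect_gt(bhattacharyya(f_direct, f_rw), 0.9)
})

test_that("state free-energy differences match their construction", {
  # symmetric well: dF ~ 0
  tb <- toy_biased_run(barrier_kT = 3, n_steps = 3e5, seed = 41)
  f <- weighted_fes(reweight(tb$run$colvar, tb$run$hills, 300),
                    vars = "cv1", bins = 50,
                    limits = list(c(-1, 1)))
  dF <- state_delta_f(f, list(kind = "rect", xlim = c(-1, 0)),
                      list(kind = "rect", xlim = c(0, 1)))
  expect_lt(abs(dF), 0.75 * kT300)
  # tilted well designed to dF = 2 kT (direct Boltzmann integration)
  tbt <- toy_biased_run(barrier_kT = 3, tilt = 5.5, n_steps = 6e5,
                        seed = 31)
  gr <- seq(-1.3, 1.3, length.out = 8001)
  pg <- exp(-tbt$pot$value(cbind(gr)) / kT300); pg <- pg / sum(pg)
  dF_design <- -kT300 * log(sum(pg[gr > 0]) / sum(pg[gr < 0]))
  expect_equal(dF_design / kT300, 2, tolerance = 0.05)
  ft <- weighted_fes(reweight(tbt$run$colvar, tbt$run$hills, 300),
                     vars = "cv1", bins = 50, limits = list(c(-1, 1)))
  dF_rec <- state_delta_f(ft, list(kind = "rect", xlim = c(-1, 0)),
                          list(kind = "rect", xlim = c(0, 1)))
  expect_lt(abs(dF_rec - dF_design), 0.3 * kT300)
  # empty regions are signalled distinctly
  expect_warning(
    dinf <- state_delta_f(ft, list(kind = "rect", xlim = c(-1, 0)),
                          list(kind = "ellipse", center = 99,
                               radii = 0.01)),
    "empty")
  expect_identical(dinf, Inf)
})

test_that("k-means microstates are deterministic and well placed", {
  set.seed(7)
  X <- rbind(cbind(rnorm(5000, -1, 0.1), rnorm(5000, 0, 0.1)),
             cbind(rnorm(5000, 1, 0.1), rnorm(5000, 0.5, 0.1)))
  km2 <- kmeans_microstates(X, 2, seed = 3)
  cen <- km2$centers[order(km2$centers[, 1]), ]
  expect_lt(max(abs(cen - rbind(c(-1, 0), c(1, 0.5)))), 0.01)
  km40 <- kmeans_microstates(X, 40, seed = 3)
  expect_identical(nrow(km40$centers), 40L)
  expect_identical(kmeans_microstates(X, 40, seed = 3)$centers,
                   km40$centers)
  expect_equal(kmeans_microstates(X[1:50, ], 50, seed = 1)$inertia, 0)
  expect_error(kmeans_microstates(X[1:10, ], 11), "exceeds")
})

test_that("minimum free-energy paths follow the valley floor", {
  gx <- seq(-1, 1, length.out = 41)
  gy <- seq(-0.5, 0.5, length.out = 31)
  FF <- outer(gx, gy, function(x, y)
    20 * (y - 0.2 * sin(pi * x))^2 + 2 * cos(pi * x) + 2)
  mk_fes <- function(Fm) {
    structure(list(
      vars = c("x", "y"),
      edges = list(seq(gx[1] - 0.025, gx[41] + 0.025,
                       length.out = 42),
                   seq(gy[1] - 1 / 60, gy[31] + 1 / 60,
                       length.out = 32)),
      centers = list(gx, gy), P = exp(-Fm) / sum(exp(-Fm)), F = Fm,
      counts = Fm * 0 + 10, n_eff = Fm * 0 + 10, temperature = 300,
      min_count = 5), class = "free_energy_surface")
  }
  fes <- mk_fes(FF)
  mp <- min_free_energy_path(fes, c(-1, 0), c(1, 0))
  expect_equal(unlist(mp[1, c("x", "y")], use.names = FALSE),
               c(-1, 0))
  expect_equal(unlist(mp[nrow(mp), c("x", "y")], use.names = FALSE),
               c(1, 0))
  expect_lt(max(abs(mp$y - 0.2 * sin(pi * mp$x))), gy[2] - gy[1])
  # flat surface: monotone straight path with constant profile
  f0 <- mk_fes(matrix(1, 41, 31))
  mp0 <- min_free_energy_path(f0, c(-1, 0), c(1, 0))
  expect_identical(nrow(mp0), 41L)
  expect_true(all(mp0$F == 1))
  # disconnected surfaces are an error
  Fcut <- FF; Fcut[21, ] <- NA
  expect_error(min_free_energy_path(mk_fes(Fcut), c(-1, 0), c(1, 0)),
               "no finite-F path")
})

test_that("geometric CVs compute distances and angles on bead groups", {
  pos <- array(0, c(2, 4, 3))
  pos[, 2, 3] <- 1           # bead 2 at (0,0,1)
  pos[, 3, 3] <- 2           # bead 3 at (0,0,2)
  pos[, 4, 1] <- 1; pos[, 4, 3] <- 2   # bead 4 at (1,0,2)
  tr <- trajectory(pos, dt = 1)
  g <- eval_geometric_cv(tr, list(
    geometric_cv("distance", list(1, 2), name = "d12"),
    geometric_cv("angle", list(1, 2, 3), name = "a123"),
    geometric_cv("angle", list(2, 3, 4), name = "a234"),
    geometric_cv("dihedral", list(1, 2, 3, 4), name = "t")))
  expect_equal(g$d12, c(1, 1))
  expect_equal(g$a123, c(180, 180))
  expect_equal(g$a234, c(90, 90))
  expect_error(eval_geometric_cv(tr,
    geometric_cv("distance", list(1, 9))), "out of range")
  expect_error(geometric_cv("distance", list(1, integer(0))), "empty")
  expect_error(geometric_cv("angle", list(1, 2)), "3 site groups")
})

test_that("biasing the transition mode at least doubles sampled motion", {
  sys <- two_state_system(n_beads = 6, barrier_kT = 8, q0 = 0.15,
                          seed = 5)
  un <- two_state_trajectory(sys, dt = 0.005, n_steps = 1e5, seed = 7,
                             output_stride = 10)
  bi <- two_state_metad_trajectory(sys, height = 1.5, sigma = 0.03,
                                   pace = 200, bias_factor = 10,
                                   dt = 0.005, n_steps = 1e5, seed = 7,
                                   output_stride = 10)
  # compare on a geometric variable tracking the transition: distance
  # between the centres of mass of the two bead groups that move in
  # opposite directions along the mode (the toy analogue of a
  # domain-opening distance).  Sampled extent = interquartile (box)
  # range, the consistently sampled region of a box-and-whisker summary.
  disp <- matrix(sys$transition_mode, ncol = 3, byrow = TRUE)
  e1 <- svd(disp)$v[, 1]
  grpA <- which(disp %*% e1 > 0)
  grpB <- which(disp %*% e1 <= 0)
  gdef <- geometric_cv("distance", list(grpA, grpB), name = "d")
  box_range <- function(tr) diff(quantile(
    eval_geometric_cv(tr, gdef, masses = sys$masses)$d, c(0.25, 0.75)))
  expect_gt(box_range(bi$traj) / box_range(un), 2)
})

test_that("FES grid files round-trip through the TSV format", {
  set.seed(8)
  d <- tibble::tibble(x = rnorm(5000, 0, 0.3), y = rnorm(5000, 0, 0.2))
  f <- weighted_fes(d, vars = c("x", "y"), bins = 20,
                    limits = list(c(-1, 1), c(-1, 1)))
  p <- tempfile(fileext = ".tsv")
  write_fes(f, p)
  rt <- read_fes(p)
  expect_equal(rt$P, f$P, tolerance = 0)
  expect_equal(rt$F, f$F, tolerance = 0)
  expect_equal(rt$centers, f$centers, tolerance = 1e-12)
  expect_equal(shannon_entropy(rt), shannon_entropy(f))
  expect_error(read_fes(tempfile()), "")
})
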