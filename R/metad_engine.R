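#' Analytic toy potentials for metadynamics post-processing oracles
#'
#' Bounded-below 1D/2D potentials with analytically known minima, used to
#' validate reweighting and free-energy reconstruction end to end:
#' \describe{
#'   \item{`double_well`}{1D, `V = B ((x/x0)^2 - 1)^2`: barrier `B`
#'     (kJ/mol) at 0, minima at +/- `x0`.}
#'   \item{`harmonic_valley`}{2D, `V = kx/2 x^2 + ky/2 y^2`.}
#'   \item{`double_well_2d`}{double well in x plus harmonic y.}
#'   \item{`mueller_brown`}{a Mueller-Brown-like sum of four anisotropic
#'     Gaussians, rescaled to kJ/mol.}
#' }
#'
#' @param form one of the identifiers above
#' @param params named list overriding the defaults (`barrier`, `x0`,
#'   `kx`, `ky`, `scale`)
#' @return object of class `toy_potential` with fields `value(x)`,
#'   `gradient(x)` (both take a row-vector/matrix of points), `dim`,
#'   `minima`
#' @export
toy_potential <- function(form = c("double_well", "harmonic_valley",
                                   "double_well_2d", "mueller_brown"),
                          params = list()) {
  form <- match.arg(form)
  p <- utils::modifyList(switch(form,
    double_well = list(barrier = 10, x0 = 1, tilt = 0),
    harmonic_valley = list(kx = 100, ky = 100),
    double_well_2d = list(barrier = 10, x0 = 1, ky = 100, tilt = 0),
    mueller_brown = list(scale = 0.05)
  ), params)
  obj <- switch(form,
    double_well = list(
      dim = 1L,
      value = function(x)
        p$barrier * ((x[, 1]^2 / p$x0^2) - 1)^2 + p$tilt * x[, 1],
      gradient = function(x)
        cbind(4 * p$barrier * x[, 1] * (x[, 1]^2 / p$x0^2 - 1) / p$x0^2 +
                p$tilt),
      minima = rbind(-p$x0, p$x0)),
    harmonic_valley = list(
      dim = 2L,
      value = function(x) 0.5 * p$kx * x[, 1]^2 + 0.5 * p$ky * x[, 2]^2,
      gradient = function(x) cbind(p$kx * x[, 1], p$ky * x[, 2]),
      minima = rbind(c(0, 0))),
    double_well_2d = list(
      dim = 2L,
      value = function(x)
        p$barrier * ((x[, 1]^2 / p$x0^2) - 1)^2 + p$tilt * x[, 1] +
          0.5 * p$ky * x[, 2]^2,
      gradient = function(x)
        cbind(4 * p$barrier * x[, 1] * (x[, 1]^2 / p$x0^2 - 1) / p$x0^2 +
                p$tilt,
              p$ky * x[, 2]),
      minima = rbind(c(-p$x0, 0), c(p$x0, 0))),
    mueller_brown = mueller_brown_potential(p$scale)
  )
  structure(c(obj, list(form = form, params = p)),
            class = "toy_potential")
}

mueller_brown_potential <- function(scale) {
  A <- c(-200, -100, -170, 15) * scale
  aa <- c(-1, -1, -6.5, 0.7); bb <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  xx <- c(1, 0, -0.5, -1); yy <- c(0, 0.5, 1.5, 1)
  val <- function(x) {
    out <- numeric(nrow(x))
    for (k in 1:4)
      out <- out + A[k] * exp(aa[k] * (x[, 1] - xx[k])^2 +
                              bb[k] * (x[, 1] - xx[k]) * (x[, 2] - yy[k]) +
                              cc[k] * (x[, 2] - yy[k])^2)
    out - (-146.6995 * scale)   # gauge: global minimum near 0
  }
  grad <- function(x) {
    gx <- numeric(nrow(x)); gy <- numeric(nrow(x))
    for (k in 1:4) {
      e <- A[k] * exp(aa[k] * (x[, 1] - xx[k])^2 +
                      bb[k] * (x[, 1] - xx[k]) * (x[, 2] - yy[k]) +
                      cc[k] * (x[, 2] - yy[k])^2)
      gx <- gx + e * (2 * aa[k] * (x[, 1] - xx[k]) +
                      bb[k] * (x[, 2] - yy[k]))
      gy <- gy + e * (bb[k] * (x[, 1] - xx[k]) +
                      2 * cc[k] * (x[, 2] - yy[k]))
    }
    cbind(gx, gy)
  }
  list(dim = 2L, value = val, gradient = grad,
       minima = rbind(c(-0.558, 1.442), c(0.623, 0.028)))
}

#' Toy well-tempered metadynamics engine
#'
#' Runs overdamped-regime Langevin dynamics (BAOAB, unit-mass particle) on
#' an analytic [toy_potential()] while depositing history-dependent
#' Gaussian bias with well-tempered height scaling
#' `h_t = h exp(-V_bias(s_t) / ((gamma - 1) kB T))`.  The bias and its
#' gradient are accumulated on a fine grid (as production codes do), so
#' per-step cost is O(1).  The collective variables are the particle
#' coordinates themselves.
#'
#' With `height = 0` the run is plain unbiased Langevin sampling of the
#' potential; with `gamma` large and long runs the deposited bias converges
#' to `-(1 - 1/gamma) F(s) + const`.
#'
#' @param potential a [toy_potential()]
#' @param height initial hill height (kJ/mol); 0 disables biasing
#' @param sigma hill width(s), one per CV dimension
#' @param pace deposit a hill every `pace` steps
#' @param bias_factor well-tempered bias factor gamma > 1
#' @param temperature K
#' @param n_steps number of integration steps
#' @param dt time step (ps)
#' @param friction 1/ps
#' @param mass particle mass (amu)
#' @param seed RNG seed; same seed gives identical COLVAR/HILLS output
#' @param x0 starting point (defaults to the first minimum)
#' @param colvar_stride record a COLVAR row every `colvar_stride` steps
#' @param grid_range list of `c(lo, hi)` per dimension for the bias grid
#'   (default: well region padded by 6 sigma)
#' @param grid_n grid points per dimension
#' @param bias_dims integer vector of coordinate indices the bias acts on
#'   (default: all); unbiased coordinates are still recorded in the COLVAR
#' @return list of class `toy_metad_run` with tibbles `colvar`
#'   (time, cv values, instantaneous bias) and `hills` (time, centers,
#'   sigmas, height, bias factor), plus the final bias grid
#' @export
toy_wt_metadynamics <- function(potential, height, sigma, pace = 500L,
                                bias_factor = 10, temperature = 300,
                                n_steps = 1e5L, dt = 0.002, friction = 5,
                                mass = 1, seed = 1, x0 = NULL,
                                colvar_stride = 10L, grid_range = NULL,
                                grid_n = 1024L, bias_dims = NULL) {
  stopifnot(inherits(potential, "toy_potential"))
  if (bias_factor <= 1) stop("bias_factor (gamma) must be > 1")
  if (height > 0 && any(sigma <= 0)) stop("sigma must be positive")
  if (pace < 1) stop("pace must be >= 1")
  dim <- potential$dim
  if (is.null(bias_dims)) bias_dims <- seq_len(dim)
  bdim <- length(bias_dims)
  sigma <- rep_len(sigma, bdim)
  set.seed(seed)
  kT <- kB * temperature
  if (is.null(grid_range)) {
    glo <- apply(potential$minima, 2, min) - 6 * max(sigma) - 1
    ghi <- apply(potential$minima, 2, max) + 6 * max(sigma) + 1
    grid_range <- lapply(bias_dims, function(a) c(glo[a], ghi[a]))
  }
  if (bdim == 1L) grid_n1 <- grid_n else grid_n1 <- min(grid_n, 256L)
  gx <- lapply(seq_len(bdim), function(a)
    seq(grid_range[[a]][1], grid_range[[a]][2], length.out = grid_n1))
  hgrid <- vapply(gx, function(g) g[2] - g[1], numeric(1))
  vbias <- if (bdim == 1L) numeric(grid_n1) else
    matrix(0, grid_n1, grid_n1)
  # linear interpolation of the bias and its (finite-difference) gradient
  bias_value <- function(s) {
    if (bdim == 1L) {
      g <- gx[[1]]
      i <- findInterval(s[1], g, all.inside = TRUE)
      t1 <- (s[1] - g[i]) / (g[i + 1] - g[i])
      t1 <- min(max(t1, 0), 1)
      (1 - t1) * vbias[i] + t1 * vbias[i + 1]
    } else {
      bilinear(gx, vbias, s)
    }
  }
  bias_grad <- function(s) {
    eps <- hgrid
    if (bdim == 1L) {
      (bias_value(s + eps[1]) - bias_value(s - eps[1])) / (2 * eps[1])
    } else {
      c((bilinear(gx, vbias, s + c(eps[1], 0)) -
         bilinear(gx, vbias, s - c(eps[1], 0))) / (2 * eps[1]),
        (bilinear(gx, vbias, s + c(0, eps[2])) -
         bilinear(gx, vbias, s - c(0, eps[2]))) / (2 * eps[2]))
    }
  }
  x <- if (is.null(x0)) potential$minima[1, ] else x0
  v <- stats::rnorm(dim) * sqrt(kT / mass)
  c1 <- exp(-friction * dt); c2 <- sqrt(1 - c1^2) * sqrt(kT / mass)
  force <- function(s) {
    g <- -potential$gradient(matrix(s, 1))[1, ]
    if (height > 0)
      g[bias_dims] <- g[bias_dims] - bias_grad(s[bias_dims])
    g
  }
  f <- force(x)
  nh <- if (height > 0) n_steps %/% pace else 0L
  hills <- matrix(0, nh, 2 * bdim + 2)
  nc <- n_steps %/% colvar_stride
  colvar <- matrix(0, nc, dim + 2)
  hcount <- 0L; ccount <- 0L
  for (s in seq_len(n_steps)) {
    v <- v + (0.5 * dt) * f / mass
    x <- x + (0.5 * dt) * v
    v <- c1 * v + c2 * stats::rnorm(dim)
    x <- x + (0.5 * dt) * v
    f <- force(x)
    v <- v + (0.5 * dt) * f / mass
    if (height > 0 && s %% pace == 0L) {
      sb <- x[bias_dims]
      h_t <- height * exp(-bias_value(sb) / ((bias_factor - 1) * kT))
      vbias <- add_hill(vbias, gx, sb, sigma, h_t)
      hcount <- hcount + 1L
      hills[hcount, ] <- c(s * dt, sb, sigma, h_t)
      f <- force(x)
    }
    if (s %% colvar_stride == 0L) {
      ccount <- ccount + 1L
      colvar[ccount, ] <- c(s * dt, x,
                            if (height > 0) bias_value(x[bias_dims])
                            else 0)
    }
  }
  cvn <- paste0("cv", seq_len(dim))
  bvn <- cvn[bias_dims]
  colvar <- tibble::as_tibble(as.data.frame(colvar))
  names(colvar) <- c("time", cvn, "metad.bias")
  hills <- tibble::as_tibble(as.data.frame(hills[seq_len(hcount), ,
                                                 drop = FALSE]))
  names(hills) <- c("time", bvn, paste0("sigma_", bvn), "height")
  hills$biasf <- rep(bias_factor, nrow(hills))
  class(colvar) <- c("colvar_series", class(colvar))
  class(hills) <- c("hills_record", class(hills))
  structure(list(colvar = colvar, hills = hills,
                 grid = gx, bias = vbias,
                 temperature = temperature, bias_factor = bias_factor,
                 cv_names = cvn),
            class = "toy_metad_run")
}

#' Well-tempered metadynamics on a two-state bead system
#'
#' Biases a [two_state_system()] along its declared transition coordinate
#' `Q` with the same grid-accumulated well-tempered protocol as
#' [toy_wt_metadynamics()], integrating the full 3n-dimensional bead
#' system with [langevin_dynamics()].  Returns the trajectory together
#' with COLVAR/HILLS records in `Q`.
#'
#' @param sys a [two_state_system()]
#' @param height,sigma,pace,bias_factor well-tempered parameters (see
#'   [toy_wt_metadynamics()]); `sigma` in units of `Q` (nm)
#' @param dt,n_steps,seed,output_stride integration controls
#' @return list with `traj` ([trajectory()]), `colvar`, `hills`
#' @export
two_state_metad_trajectory <- function(sys, height = 1, sigma = NULL,
                                       pace = 250L, bias_factor = 10,
                                       dt = 0.005, n_steps = 1e5L,
                                       seed = 1, output_stride = 10L) {
  stopifnot(inherits(sys, "two_state_system"))
  if (bias_factor <= 1) stop("bias_factor (gamma) must be > 1")
  if (is.null(sigma)) sigma <- sys$q0 / 5
  kT <- kB * sys$temperature
  grid <- seq(-4 * sys$q0 - 6 * sigma, 4 * sys$q0 + 6 * sigma,
              length.out = 1024L)
  h <- grid[2] - grid[1]
  env <- new.env()
  env$vbias <- numeric(length(grid))
  env$ncall <- 0L
  env$hills <- list()
  x0f <- as.numeric(t(sys$x0))
  d <- sys$transition_mode
  bias_val <- function(q) {
    i <- findInterval(q, grid, all.inside = TRUE)
    t1 <- min(max((q - grid[i]) / h, 0), 1)
    (1 - t1) * env$vbias[i] + t1 * env$vbias[i + 1]
  }
  force_fn <- function(x) {
    base <- sys$force_fn(x)
    q <- sum(d * (as.numeric(t(x)) - x0f))
    env$ncall <- env$ncall + 1L
    # deposit every `pace` force calls (one call per integration step)
    if (height > 0 && env$ncall %% pace == 0L) {
      h_t <- height * exp(-bias_val(q) / ((bias_factor - 1) * kT))
      env$vbias <- env$vbias +
        h_t * exp(-(grid - q)^2 / (2 * sigma^2))
      env$hills[[length(env$hills) + 1L]] <-
        c(env$ncall * dt, q, sigma, h_t)
    }
    if (height > 0) {
      g <- (bias_val(q + h) - bias_val(q - h)) / (2 * h)
      base <- base - matrix(g * d, ncol = 3, byrow = TRUE)
    }
    base
  }
  traj <- langevin_dynamics(force_fn, sys$masses, sys$minima[[1]], dt,
                            n_steps, friction = sys$friction,
                            temperature = sys$temperature, seed = seed,
                            output_stride = output_stride, burn_in = 0)
  q <- two_state_q(sys, traj)
  colvar <- tibble::tibble(time = traj$time, q = q,
                           `metad.bias` = vapply(q, bias_val,
                                                 numeric(1)))
  class(colvar) <- c("colvar_series", class(colvar))
  hm <- do.call(rbind, env$hills)
  hills <- if (is.null(hm)) {
    tibble::tibble(time = numeric(), q = numeric(),
                   sigma_q = numeric(), height = numeric(),
                   biasf = numeric())
  } else {
    tibble::tibble(time = hm[, 1], q = hm[, 2], sigma_q = hm[, 3],
                   height = hm[, 4], biasf = bias_factor)
  }
  class(hills) <- c("hills_record", class(hills))
  list(traj = traj, colvar = colvar, hills = hills)
}

bilinear <- function(gx, z, s) {
  i <- findInterval(s[1], gx[[1]], all.inside = TRUE)
  j <- findInterval(s[2], gx[[2]], all.inside = TRUE)
  tx <- (s[1] - gx[[1]][i]) / (gx[[1]][i + 1] - gx[[1]][i])
  ty <- (s[2] - gx[[2]][j]) / (gx[[2]][j + 1] - gx[[2]][j])
  tx <- min(max(tx, 0), 1); ty <- min(max(ty, 0), 1)
  (1 - tx) * (1 - ty) * z[i, j] + tx * (1 - ty) * z[i + 1, j] +
    (1 - tx) * ty * z[i, j + 1] + tx * ty * z[i + 1, j + 1]
}

add_hill <- function(vbias, gx, center, sigma, h) {
  if (length(gx) == 1L) {
    vbias + h * exp(-(gx[[1]] - center[1])^2 / (2 * sigma[1]^2))
  } else {
    ex <- exp(-(gx[[1]] - center[1])^2 / (2 * sigma[1]^2))
    ey <- exp(-(gx[[2]] - center[2])^2 / (2 * sigma[2]^2))
    vbias + h * outer(ex, ey)
  }
}
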