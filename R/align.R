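#' Reference frame for trajectory alignment
#'
#' Holds reference coordinates and per-site alignment weights (default:
#' masses).  All spectral analysis is done after rotating every frame into
#' this common coordinate system, so that rigid-body motion of the molecule
#' maps onto a fixed 6-dimensional subspace.
#'
#' @param coords `[n, 3]` reference coordinates (nm)
#' @param weights positive per-site weights; typically bead masses
#' @return an object of class `reference_frame`
#' @export
reference_frame <- function(coords, weights = rep(1, nrow(coords))) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(weights) == nrow(coords),
            all(weights >= 0), sum(weights > 0) >= 3)
  check_noncollinear(coords[weights > 0, , drop = FALSE])
  structure(list(coords = coords, weights = as.numeric(weights)),
            class = "reference_frame")
}

check_noncollinear <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  if (sum(svd(xc)$d > 1e-10 * max(1, max(abs(xc)))) < 2)
    stop("degenerate reference: sites are collinear (rotation undefined)")
  invisible(TRUE)
}

#' Weighted Kabsch superposition of one frame onto a reference
#'
#' Finds the proper rotation (det +1) and translation minimising the
#' weighted RMSD between a frame and the reference, and applies the same
#' rotation to the frame's velocities (velocities transform under rotation
#' only; the translation is a constant).
#'
#' @param pos `[n, 3]` positions (nm)
#' @param reference a [reference_frame()]
#' @param vel optional `[n, 3]` velocities (nm/ps)
#' @return list with `rotation` (3x3), `translation`, aligned `pos`
#'   (and `vel`), and the weighted `rmsd` (nm)
#' @export
kabsch_align <- function(pos, reference, vel = NULL) {
  stopifnot(inherits(reference, "reference_frame"))
  pos <- as.matrix(pos)
  if (nrow(pos) != nrow(reference$coords))
    stop("frame/reference size mismatch")
  w <- reference$weights / sum(reference$weights)
  mu_x <- colSums(pos * w)
  mu_y <- colSums(reference$coords * w)
  X <- sweep(pos, 2, mu_x)
  Y <- sweep(reference$coords, 2, mu_y)
  H <- crossprod(X * w, Y)             # 3x3 weighted covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps frame -> reference
  pos_al <- sweep(X %*% t(R), 2, mu_y, "+")
  rmsd <- sqrt(sum(w * rowSums((pos_al - reference$coords)^2)))
  list(rotation = R, translation = mu_y - c(R %*% mu_x),
       pos = pos_al,
       vel = if (!is.null(vel)) as.matrix(vel) %*% t(R),
       rmsd = rmsd)
}

#' Rotate a whole trajectory into a reference coordinate system
#'
#' Applies [kabsch_align()] frame-wise: positions are superposed on the
#' reference and velocities are rotated by the per-frame rotation.  The
#' operation is idempotent.
#'
#' @param traj a [trajectory()] (typically the coarse-grained one)
#' @param reference a [reference_frame()] with matching site count
#' @return the aligned trajectory, with per-frame RMSD (nm) in attribute
#'   `"rmsd"`
#' @export
align_trajectory <- function(traj, reference) {
  nf <- n_frames(traj)
  pos <- array(0, dim(traj$pos))
  vel <- if (has_velocities(traj)) array(0, dim(traj$pos))
  rmsd <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- kabsch_align(matrix(traj$pos[f, , ], ncol = 3), reference,
                       vel = if (!is.null(vel))
                         matrix(traj$vel[f, , ], ncol = 3))
    pos[f, , ] <- fr$pos
    if (!is.null(vel)) vel[f, , ] <- fr$vel
    rmsd[f] <- fr$rmsd
  }
  out <- trajectory(pos, vel, dt = traj$dt, time = traj$time)
  attr(out, "rmsd") <- rmsd
  out
}
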