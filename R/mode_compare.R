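#' Correlation between two mode vectors
#'
#' The sign-invariant absolute inner product `|a . b|` of two normalized
#' mode vectors (in mass-weighted space).  Self-correlation is 1 by
#' definition; orthogonal modes give 0.
#'
#' @param a,b mode vectors of equal length, unit norm
#' @param tol allowed deviation of the input norms from 1
#' @return scalar in `[0, 1]`
#' @export
mode_correlation <- function(a, b, tol = 1e-6) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("mode vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero mode vector")
  if (abs(na - 1) > tol || abs(nb - 1) > tol)
    stop("mode vectors must be normalized")
  min(abs(sum(a * b)), 1)
}

#' Subspace correlation (RMSIP) between two sets of modes
#'
#' Root-mean-square inner product between two orthonormal k-dimensional
#' mode sets, `sqrt( (1/k) sum_ij (a_i . b_j)^2 )`.  Invariant under any
#' orthogonal remixing within either set, so it measures whether the
#' *spans* agree — e.g. swapping or mixing modes 8 and 9 leaves the 3D
#' subspace correlation unchanged.  For random k-dim subspaces of a
#' d-dimensional space it concentrates near `sqrt(k/d)`.
#'
#' @param A,B `3n x k` matrices with orthonormal columns (equal k)
#' @param tol orthonormality tolerance
#' @return scalar in `[0, 1]`
#' @export
subspace_correlation <- function(A, B, tol = 1e-6) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B)))
    stop("mode sets must have identical dimensions")
  for (M in list(A, B)) {
    G <- crossprod(M)
    if (max(abs(G - diag(ncol(M)))) > tol)
      stop("mode set not orthonormal within tolerance")
  }
  k <- ncol(A)
  min(sqrt(sum(crossprod(A, B)^2) / k), 1)
}

#' Mass-weighted rigid-body basis at a reference geometry
#'
#' Builds the six orthonormal vectors of the translation/rotation subspace
#' in mass-weighted displacement space: translations `sqrt(m_i) e_alpha`
#' and rotations `sqrt(m_i) (r_i - r_com) x e_alpha`, Gram-Schmidt
#' orthonormalized.
#'
#' @param reference `[n, 3]` reference coordinates (nm)
#' @param masses bead masses (amu)
#' @return `3n x 6` matrix with orthonormal columns
#' @export
rigid_body_basis <- function(reference, masses) {
  reference <- as.matrix(reference)
  n <- nrow(reference)
  check_noncollinear(reference)
  sm <- sqrt(masses)
  com <- colSums(reference * masses) / sum(masses)
  r <- sweep(reference, 2, com)
  V <- matrix(0, 3 * n, 6)
  for (a in 1:3) {                 # translations
    v <- matrix(0, n, 3); v[, a] <- 1
    V[, a] <- as.numeric(t(v * sm))
  }
  for (a in 1:3) {                 # rotations about axis a: r x e_a
    e <- numeric(3); e[a] <- 1
    v <- cbind(r[, 2] * e[3] - r[, 3] * e[2],
               r[, 3] * e[1] - r[, 1] * e[3],
               r[, 1] * e[2] - r[, 2] * e[1])
    V[, 3 + a] <- as.numeric(t(v * sm))
  }
  # Gram-Schmidt: rotations against translations and each other
  for (k in 1:6) {
    v <- V[, k]
    if (k > 1) v <- v - V[, 1:(k - 1), drop = FALSE] %*%
        crossprod(V[, 1:(k - 1), drop = FALSE], v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("degenerate rigid-body basis (collinear body?)")
    V[, k] <- v / nv
  }
  V
}

#' Classify modes by overlap with the rigid-body subspace
#'
#' Projects each mode onto the six-dimensional mass-weighted
#' translation/rotation subspace of the reference geometry and reports the
#' projection norm; modes with overlap above `threshold` are flagged as
#' rigid-body modes.  For the standard zero-frequency protocol the six
#' leading modes of a diffusing molecule are rigid and are excluded from
#' collective-variable selection.
#'
#' @param modes a [mode_set()]
#' @param reference `[n, 3]` reference geometry; defaults to the one
#'   stored in the mode set
#' @param threshold overlap above which a mode counts as rigid
#' @return tibble with columns `mode`, `eigenvalue`, `rigid_overlap`,
#'   `is_rigid`
#' @export
classify_rigid_modes <- function(modes, reference = modes$reference,
                                 threshold = 0.8) {
  stopifnot(inherits(modes, "mode_set"))
  if (is.null(reference)) stop("no reference structure available")
  V <- rigid_body_basis(reference, modes$masses)
  ov <- sqrt(colSums(crossprod(V, modes$vectors)^2))
  tibble::tibble(mode = seq_len(n_modes(modes)),
                 eigenvalue = modes$values,
                 rigid_overlap = pmin(ov, 1),
                 is_rigid = ov > threshold)
}

#' Principal component (quasiharmonic) modes of aligned positions
#'
#' Eigendecomposition of the mass-weighted displacement covariance matrix
#' `cov(sqrt(m_i) (r_i - <r_i>))`, modes sorted by variance descending.
#' This is the classical quasiharmonic baseline against which
#' frequency-resolved modes are compared: its low-frequency eigenvectors
#' depend on rare excursions and reproduce poorly across replicas.
#'
#' @param traj an aligned [trajectory()]
#' @param masses per-site masses (amu)
#' @return a [mode_set()] with eigenvalues = variances (amu nm^2)
#' @export
principal_component_modes <- function(traj, masses) {
  X <- sweep(flatten_frames(traj$pos), 2, rep(sqrt(masses), each = 3),
             "*")
  if (nrow(X) < ncol(X))
    warning(sprintf(
      "only %d frames for %d dof: covariance is rank-deficient",
      nrow(X), ncol(X)))
  X <- sweep(X, 2, colMeans(X))
  Cv <- crossprod(X) / nrow(X)
  eig <- eigen((Cv + t(Cv)) / 2, symmetric = TRUE)
  ref <- apply(traj$pos, c(2, 3), mean)
  mode_set(eig$vectors, eig$values, masses, reference = ref,
           kind = "pca")
}

#' Replica reproducibility report for selected modes
#'
#' For every pair of replica mode sets, computes the matrix of pairwise
#' mode correlations among the selected mode indices plus the 2D subspace
#' correlation (first two indices) and the full k-D subspace correlation —
#' the replica-reproducibility statistics used to decide whether
#' low-frequency modes are trustworthy collective variables.
#'
#' @param mode_sets list of >= 2 [mode_set()]s of the same system
#' @param indices mode indices to compare (default 7:9: the three largest
#'   non-rigid zero-frequency contributions)
#' @return object of class `replica_report`: list with `pairs` (tibble:
#'   replica_a, replica_b, subspace_2d, subspace_kd) and `mode_cor`
#'   (named list of k x k correlation matrices per pair)
#' @export
replica_report <- function(mode_sets, indices = 7:9) {
  if (length(mode_sets) < 2) stop("need at least two replica mode sets")
  for (m in mode_sets) {
    stopifnot(inherits(m, "mode_set"))
    if (max(indices) > n_modes(m))
      stop(sprintf("mode index %d out of range (set has %d modes)",
                   max(indices), n_modes(m)))
  }
  k <- length(indices)
  pr <- utils::combn(length(mode_sets), 2)
  mode_cor <- list()
  pairs <- tibble::tibble(replica_a = integer(), replica_b = integer(),
                          subspace_2d = numeric(),
                          subspace_kd = numeric())
  for (p in seq_len(ncol(pr))) {
    i <- pr[1, p]; j <- pr[2, p]
    A <- mode_sets[[i]]$vectors[, indices, drop = FALSE]
    B <- mode_sets[[j]]$vectors[, indices, drop = FALSE]
    M <- abs(crossprod(A, B))
    dimnames(M) <- list(paste0("a", indices), paste0("b", indices))
    mode_cor[[sprintf("%d-%d", i, j)]] <- M
    pairs[nrow(pairs) + 1L, ] <- list(
      i, j,
      subspace_correlation(A[, 1:2, drop = FALSE],
                           B[, 1:2, drop = FALSE]),
      subspace_correlation(A, B))
  }
  structure(list(pairs = pairs, mode_cor = mode_cor, indices = indices),
            class = "replica_report")
}

#' @export
print.replica_report <- function(x, ...) {
  cat(sprintf("<replica_report> modes %s, %d replica pairs\n",
              paste(range(x$indices), collapse = "-"),
              nrow(x$pairs)))
  print(x$pairs)
  invisible(x)
}

#' @export
tidy.replica_report <- function(x, ...) x$pairs
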