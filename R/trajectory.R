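#' Trajectory objects
#'
#' A `fresean_traj` holds a time series of positions (and optionally
#' velocities) for a fixed set of sites (atoms or coarse-grained beads) on a
#' uniform time grid.  Positions are in nm, velocities in nm/ps, times in
#' ps.  Velocities are required for all spectral analysis; purely
#' structural operations (alignment, PCA) work on positions alone.
#'
#' @param pos numeric array `[n_frames, n_sites, 3]` of positions (nm)
#' @param vel optional numeric array of velocities, same shape (nm/ps)
#' @param dt sampling interval in ps (uniform grid)
#' @param time optional explicit frame times (ps); must be uniform.  When
#'   given, `dt` is inferred and checked.
#' @return an object of class `fresean_traj`
#' @export
trajectory <- function(pos, vel = NULL, dt = NULL, time = NULL) {
  if (length(dim(pos)) != 3L || dim(pos)[3] != 3L)
    stop("pos must be an [n_frames, n_sites, 3] array")
  nf <- dim(pos)[1]
  if (!is.null(vel) && !identical(dim(vel), dim(pos)))
    stop("vel must have the same dimensions as pos")
  if (is.null(time)) {
    if (is.null(dt)) stop("either dt or time must be given")
    time <- (seq_len(nf) - 1L) * dt
  } else {
    if (length(time) != nf) stop("length(time) must equal n_frames")
    if (nf > 1L) {
      steps <- diff(time)
      if (max(abs(steps - steps[1])) > 1e-6 * max(abs(steps[1]), 1e-12))
        stop("non-uniform time grid: frame times must be equally spaced")
      dt <- steps[1]
    } else if (is.null(dt)) dt <- NA_real_
  }
  structure(list(time = as.numeric(time), pos = pos, vel = vel,
                 dt = as.numeric(dt)),
            class = "fresean_traj")
}

#' @export
print.fresean_traj <- function(x, ...) {
  cat(sprintf("<fresean_traj> %d frames x %d sites, dt = %g ps, %s velocities\n",
              n_frames(x), n_sites(x), x$dt,
              if (has_velocities(x)) "with" else "without"))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `fresean_traj`
#' @export
n_frames <- function(traj) dim(traj$pos)[1]

#' @rdname trajectory
#' @export
n_sites <- function(traj) dim(traj$pos)[2]

#' @rdname trajectory
#' @export
has_velocities <- function(traj) !is.null(traj$vel)

#' Extract a single frame
#'
#' @param traj a `fresean_traj`
#' @param i frame index
#' @return list with matrices `pos` (and `vel` if present), `[n_sites, 3]`
#' @export
traj_frame <- function(traj, i) {
  list(pos = matrix(traj$pos[i, , ], ncol = 3),
       vel = if (has_velocities(traj)) matrix(traj$vel[i, , ], ncol = 3))
}

# Flatten [frames, sites, 3] -> [frames, 3*n] with dof order
# (x1,y1,z1,x2,...), the ordering used by all 3n x 3n matrices here.
flatten_frames <- function(arr) {
  nf <- dim(arr)[1]; n <- dim(arr)[2]
  out <- matrix(0, nf, 3L * n)
  for (a in 1:3) out[, seq(a, 3L * n, by = 3L)] <- arr[, , a]
  out
}

unflatten_frames <- function(mat) {
  nf <- nrow(mat); n <- ncol(mat) / 3L
  arr <- array(0, c(nf, n, 3L))
  for (a in 1:3) arr[, , a] <- mat[, seq(a, 3L * n, by = 3L)]
  arr
}

## ---------------------------------------------------------------------------
## Self-describing plain-text trajectory container
##
## Header lines start with '#'; datasets are whitespace-separated numbers at
## full (17 significant digit) precision, one frame per block.  The format
## stores time grid, masses and an optional atom->bead map alongside the
## coordinates so a file is interpretable on its own.

#' Read and write the native plain-text trajectory container
#'
#' A self-describing text format holding positions, optional velocities, the
#' time grid, per-site masses and an optional atom-to-bead map.  Round-trips
#' are bit-exact (values are written with 17 significant digits).
#'
#' @param traj a [trajectory()] object
#' @param path file path (conventionally `.vtrj`)
#' @param masses optional numeric vector of per-site masses (amu)
#' @param bead_map optional list of integer vectors (atom indices per bead)
#' @return `read_vtrj` returns a list with elements `traj`, `masses`,
#'   `bead_map`; `write_vtrj` returns `path` invisibly.
#' @export
write_vtrj <- function(traj, path, masses = NULL, bead_map = NULL) {
  stopifnot(inherits(traj, "fresean_traj"))
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj); n <- n_sites(traj)
  writeLines(c("#FRESEAN-TRAJ 1",
               sprintf("#nsites %d", n),
               sprintf("#nframes %d", nf),
               sprintf("#dt %.17g", traj$dt),
               sprintf("#velocities %d", as.integer(has_velocities(traj)))),
             con)
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  if (!is.null(masses)) {
    stopifnot(length(masses) == n)
    writeLines(c("#masses", fmt(masses)), con)
  }
  if (!is.null(bead_map)) {
    writeLines(sprintf("#bead_map %d", length(bead_map)), con)
    for (b in bead_map) writeLines(paste(b, collapse = " "), con)
  }
  for (i in seq_len(nf)) {
    writeLines(sprintf("#frame %.17g", traj$time[i]), con)
    p <- matrix(traj$pos[i, , ], ncol = 3)
    writeLines(apply(p, 1L, fmt), con)
    if (has_velocities(traj)) {
      writeLines("#vel", con)
      v <- matrix(traj$vel[i, , ], ncol = 3)
      writeLines(apply(v, 1L, fmt), con)
    }
  }
  invisible(path)
}

#' @rdname write_vtrj
#' @export
read_vtrj <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!startsWith(lines[1], "#FRESEAN-TRAJ"))
    stop("not a FRESEAN trajectory container: ", path)
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), lines, value = TRUE)[1]
    if (is.na(ln)) stop("container missing header field: ", key)
    sub(paste0("^#", key, " "), "", ln)
  }
  n <- as.integer(hdr("nsites"))
  nf <- as.integer(hdr("nframes"))
  dt <- as.numeric(hdr("dt"))
  has_vel <- as.integer(hdr("velocities")) == 1L
  masses <- NULL; bead_map <- NULL
  i <- which(lines == "#masses")
  if (length(i)) masses <- scan(text = lines[i[1] + 1L], quiet = TRUE)
  i <- grep("^#bead_map ", lines)
  if (length(i)) {
    nb <- as.integer(sub("^#bead_map ", "", lines[i[1]]))
    bead_map <- lapply(seq_len(nb), function(k)
      as.integer(scan(text = lines[i[1] + k], quiet = TRUE)))
  }
  fidx <- grep("^#frame ", lines)
  if (length(fidx) != nf) stop("frame count mismatch in ", path)
  time <- as.numeric(sub("^#frame ", "", lines[fidx]))
  pos <- array(0, c(nf, n, 3L))
  vel <- if (has_vel) array(0, c(nf, n, 3L))
  parse_block <- function(at) {
    matrix(scan(text = lines[at + seq_len(n)], quiet = TRUE),
           ncol = 3, byrow = TRUE)
  }
  for (f in seq_len(nf)) {
    pos[f, , ] <- parse_block(fidx[f])
    if (has_vel) vel[f, , ] <- parse_block(fidx[f] + n + 1L)
  }
  traj <- trajectory(pos, vel, dt = dt, time = time)
  list(traj = traj, masses = masses, bead_map = bead_map)
}

## ---------------------------------------------------------------------------
## GROMACS TRR (trn) dialect, big-endian XDR layout

trr_int <- function(con) readBin(con, "integer", 1, size = 4, endian = "big")

#' Read a GROMACS TRR trajectory
#'
#' Minimal reader for the GROMACS `trn` binary dialect (big-endian XDR):
#' per-frame header (magic 1993, "GMX_trn_file", block sizes, atom count,
#' step, time, lambda) followed by box, position, velocity and force blocks
#' in single or double precision, autodetected from the block sizes.
#'
#' @param path TRR file path
#' @param velocities_required error if the file has no velocity blocks
#'   (spectral analysis needs them)
#' @return a [trajectory()] object
#' @export
read_trr <- function(path, velocities_required = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  frames_pos <- list(); frames_vel <- list(); times <- numeric()
  repeat {
    magic <- readBin(con, "integer", 1, size = 4, endian = "big")
    if (length(magic) == 0L) break
    if (magic != 1993L) stop("bad TRR magic in ", path)
    slen <- trr_int(con)           # strlen+1 of version tag
    xlen <- trr_int(con)           # xdr string length
    readChar(con, xlen, useBytes = TRUE)
    pad <- (4L - xlen %% 4L) %% 4L
    if (pad) readBin(con, "raw", pad)
    sz <- vapply(1:10, function(i) trr_int(con), integer(1))
    names(sz) <- c("ir", "e", "box", "vir", "pres", "top", "sym",
                   "x", "v", "f")
    natoms <- trr_int(con)
    step <- trr_int(con)
    nre <- trr_int(con)
    rs <- if (sz["box"] > 0) sz["box"] / 9L else sz["x"] / (3L * natoms)
    rs <- as.integer(rs)           # 4 (float) or 8 (double)
    what <- "double"
    rd <- function(k) readBin(con, what, k, size = rs, endian = "big")
    t_lambda <- rd(2)
    if (sz["box"] > 0) rd(9)
    if (sz["vir"] > 0) rd(9)
    if (sz["pres"] > 0) rd(9)
    x <- if (sz["x"] > 0) matrix(rd(3 * natoms), ncol = 3, byrow = TRUE)
    v <- if (sz["v"] > 0) matrix(rd(3 * natoms), ncol = 3, byrow = TRUE)
    if (sz["f"] > 0) rd(3 * natoms)
    frames_pos[[length(frames_pos) + 1L]] <- x
    frames_vel[length(frames_pos)] <- list(v)   # may be NULL
    times <- c(times, t_lambda[1])
  }
  if (!length(frames_pos)) stop("no frames in ", path)
  has_vel <- !is.null(frames_vel[[1]])
  if (velocities_required && !has_vel)
    stop("TRR file has no velocity blocks: ", path)
  n <- nrow(frames_pos[[1]]); nf <- length(frames_pos)
  pos <- array(0, c(nf, n, 3L))
  vel <- if (has_vel) array(0, c(nf, n, 3L))
  for (f in seq_len(nf)) {
    pos[f, , ] <- frames_pos[[f]]
    if (has_vel) vel[f, , ] <- frames_vel[[f]]
  }
  trajectory(pos, vel, time = times)
}

#' Write a GROMACS TRR trajectory
#'
#' Emits the same big-endian `trn` layout that [read_trr()] consumes, in
#' double precision, with an identity box.
#'
#' @param traj a [trajectory()] object
#' @param path output file path
#' @param write_velocities include velocity blocks (default: when present)
#' @return `path`, invisibly
#' @export
write_trr <- function(traj, path, write_velocities = has_velocities(traj)) {
  stopifnot(inherits(traj, "fresean_traj"))
  if (write_velocities && !has_velocities(traj))
    stop("trajectory has no velocities to write")
  con <- file(path, "wb")
  on.exit(close(con))
  n <- n_sites(traj); rs <- 8L
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  wr <- function(x) writeBin(as.numeric(x), con, size = rs, endian = "big")
  for (f in seq_len(n_frames(traj))) {
    wi(1993L); wi(13L); wi(12L)
    writeChar("GMX_trn_file", con, nchars = 12L, eos = NULL)
    v_size <- if (write_velocities) 3L * n * rs else 0L
    wi(c(0L, 0L, 9L * rs, 0L, 0L, 0L, 0L, 3L * n * rs, v_size, 0L))
    wi(n); wi(f - 1L); wi(0L)
    wr(c(traj$time[f], 0))
    wr(diag(3))                              # box
    wr(t(matrix(traj$pos[f, , ], ncol = 3)))
    if (write_velocities) wr(t(matrix(traj$vel[f, , ], ncol = 3)))
  }
  invisible(path)
}

#' Read a trajectory file, dispatching on format
#'
#' Dispatches on file extension: `.trr` to [read_trr()], anything else to
#' the native text container via [read_vtrj()].  When a topology is given
#' the site count is checked against it.
#'
#' @param path trajectory file
#' @param topology optional [read_topology()] result used to validate the
#'   number of sites
#' @param velocities_required error when the file carries no velocities
#' @return a [trajectory()] object
#' @export
read_trajectory <- function(path, topology = NULL,
                            velocities_required = FALSE) {
  traj <- if (grepl("\\.trr$", path, ignore.case = TRUE)) {
    read_trr(path, velocities_required = velocities_required)
  } else {
    out <- read_vtrj(path)
    if (velocities_required && !has_velocities(out$traj))
      stop("trajectory file has no velocities: ", path)
    out$traj
  }
  if (!is.null(topology) && n_sites(traj) != nrow(topology$atoms))
    stop(sprintf("site count mismatch: trajectory has %d, topology has %d",
                 n_sites(traj), nrow(topology$atoms)))
  traj
}
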