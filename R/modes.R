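#' Mode sets: orthonormal displacement eigenvectors with eigenvalues
#'
#' A `mode_set` holds eigenvectors in mass-weighted displacement space
#' (columns of a `3n x k` matrix, dof order x1,y1,z1,x2,...), their
#' eigenvalues, the bead masses and a reference structure.  For
#' frequency-resolved (FRESEAN) modes the eigenvalues are the contribution
#' of each mode to the vibrational density of states at the tagged
#' frequency and are sorted descending; for analytic normal modes the
#' eigenvalues are mass-weighted Hessian eigenvalues sorted ascending, with
#' harmonic frequencies attached.
#'
#' @param vectors `3n x k` matrix, orthonormal columns
#' @param values length-`k` eigenvalues
#' @param masses length-`n` bead masses (amu)
#' @param freq_tag frequency (cm^-1) the modes were computed at, or `NA`
#' @param reference optional `[n, 3]` reference coordinates (nm)
#' @param window Gaussian spectral window FWHM (cm^-1), or `NA`
#' @param frequencies optional per-mode harmonic frequencies (cm^-1)
#' @param kind short string describing origin ("fresean", "hessian", "pca")
#' @return an object of class `mode_set`
#' @export
mode_set <- function(vectors, values, masses, freq_tag = NA_real_,
                     reference = NULL, window = NA_real_,
                     frequencies = NULL, kind = "fresean") {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L * length(masses))
    stop("vectors must have 3 * n_beads rows")
  if (ncol(vectors) != length(values))
    stop("one eigenvalue per eigenvector required")
  structure(list(vectors = fix_mode_signs(vectors), values = values,
                 masses = as.numeric(masses), freq_tag = freq_tag,
                 reference = reference, window = window,
                 frequencies = frequencies, kind = kind),
            class = "mode_set")
}

# Reproducible sign convention: the largest-magnitude component of each
# eigenvector is made positive (eigenvector signs are otherwise arbitrary).
fix_mode_signs <- function(vectors) {
  for (k in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  vectors
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes, %d beads, kind=%s",
              n_modes(x), length(x$masses), x$kind))
  if (is.finite(x$freq_tag))
    cat(sprintf(", frequency tag %g cm^-1", x$freq_tag))
  cat("\n")
  invisible(x)
}

#' @rdname mode_set
#' @param modes a `mode_set`
#' @export
n_modes <- function(modes) ncol(modes$vectors)

#' Check orthonormality of a mode set
#' @param modes a `mode_set`
#' @param tol maximum absolute deviation of the Gram matrix from identity
#' @return `TRUE` invisibly; error when violated
#' @export
check_orthonormal <- function(modes, tol = 1e-8) {
  G <- crossprod(modes$vectors)
  dev <- max(abs(G - diag(ncol(G))))
  if (dev > tol)
    stop(sprintf("mode set not orthonormal (max deviation %.3g)", dev))
  invisible(TRUE)
}

#' @export
tidy.mode_set <- function(x, ...) {
  tibble::tibble(
    mode = seq_len(n_modes(x)),
    eigenvalue = x$values,
    frequency_cm = if (is.null(x$frequencies)) NA_real_ else x$frequencies
  )
}

#' @export
glance.mode_set <- function(x, ...) {
  tibble::tibble(
    n_modes = n_modes(x), n_beads = length(x$masses), kind = x$kind,
    freq_tag = x$freq_tag, window = x$window,
    total_eigenvalue = sum(x$values)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

## ---------------------------------------------------------------------------
## Mode file format: versioned, self-describing text with a checksum.

#' Write / read mode sets as portable text files
#'
#' The mode file is a versioned text format holding the bead count, masses,
#' reference coordinates, frequency tag, spectral window and one record per
#' mode (eigenvalue + eigenvector), at 17 significant digits, with a
#' checksum over all numeric payload.  Round-trips are bit-exact.
#'
#' @param modes a [mode_set()]
#' @param path output path (conventionally `.modes`)
#' @return `read_mode_file` returns the [mode_set()]; `write_mode_file`
#'   returns `path` invisibly.
#' @export
write_mode_file <- function(modes, path) {
  stopifnot(inherits(modes, "mode_set"))
  n <- length(modes$masses)
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  payload <- c(modes$masses, as.numeric(modes$vectors), modes$values)
  lines <- c(
    "#FRESEAN-MODES 1",
    sprintf("#nbeads %d", n),
    sprintf("#nmodes %d", n_modes(modes)),
    sprintf("#freq %.17g", modes$freq_tag),
    sprintf("#window %.17g", modes$window),
    sprintf("#kind %s", modes$kind),
    sprintf("#checksum %.17g", mode_checksum(payload)),
    "#masses", fmt(modes$masses)
  )
  if (!is.null(modes$reference)) {
    lines <- c(lines, "#reference",
               apply(modes$reference, 1, fmt))
  }
  for (k in seq_len(n_modes(modes))) {
    lines <- c(lines, sprintf("#mode %d %.17g", k, modes$values[k]),
               fmt(modes$vectors[, k]))
  }
  writeLines(lines, path)
  invisible(path)
}

mode_checksum <- function(payload) {
  # order-sensitive, scale-robust checksum of the numeric payload
  sum(payload * seq_along(payload) %% 97)
}

#' @rdname write_mode_file
#' @export
read_mode_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!identical(lines[1], "#FRESEAN-MODES 1"))
    stop("unsupported mode file version in ", path,
         " (expected #FRESEAN-MODES 1)")
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), lines, value = TRUE)[1]
    if (is.na(ln))
      stop("truncated mode file: missing #", key, " near line ",
           length(lines), " of ", path)
    sub(paste0("^#", key, " "), "", ln)
  }
  num <- function(s) if (s %in% c("NA", "NaN")) NA_real_
                     else as.numeric(s)
  n <- as.integer(hdr("nbeads"))
  k <- as.integer(hdr("nmodes"))
  freq <- num(hdr("freq"))
  window <- num(hdr("window"))
  kind <- hdr("kind")
  checksum <- as.numeric(hdr("checksum"))
  masses <- scan(text = lines[which(lines == "#masses") + 1L],
                 quiet = TRUE)
  reference <- NULL
  ri <- which(lines == "#reference")
  if (length(ri))
    reference <- matrix(scan(text = lines[ri + seq_len(n)], quiet = TRUE),
                        ncol = 3, byrow = TRUE)
  midx <- grep("^#mode ", lines)
  if (length(midx) != k)
    stop(sprintf("truncated mode file: %d of %d mode records at line %d",
                 length(midx), k, if (length(midx)) midx[length(midx)]
                                  else length(lines)))
  values <- numeric(k)
  vectors <- matrix(0, 3L * n, k)
  for (j in seq_len(k)) {
    fields <- strsplit(sub("^#mode ", "", lines[midx[j]]), " ")[[1]]
    values[j] <- as.numeric(fields[2])
    vec <- scan(text = lines[midx[j] + 1L], quiet = TRUE)
    if (length(vec) != 3L * n)
      stop(sprintf("truncated mode file: mode %d has %d of %d components (line %d)",
                   j, length(vec), 3L * n, midx[j] + 1L))
    vectors[, j] <- vec
  }
  payload <- c(masses, as.numeric(vectors), values)
  if (abs(mode_checksum(payload) - checksum) >
      1e-8 * max(1, abs(checksum)))
    stop("mode file checksum mismatch in ", path)
  mode_set(vectors, values, masses, freq_tag = freq, reference = reference,
           window = window, kind = kind)
}

#' Export modes in NMD format for visualization
#'
#' Writes the NMD text format understood by common structure viewers
#' (names, resids, coordinates, one `mode` line per mode).  NMD uses
#' Angstrom; nm inputs are scaled by 10.
#'
#' @param modes a [mode_set()] with a reference structure
#' @param path output `.nmd` path
#' @param names,resids optional per-bead labels; defaults `CA`/`1..n`
#' @return `path`, invisibly
#' @export
export_nmd <- function(modes, path, names = NULL, resids = NULL) {
  stopifnot(inherits(modes, "mode_set"))
  if (is.null(modes$reference))
    stop("NMD export needs a reference structure in the mode set")
  n <- length(modes$masses)
  if (is.null(names)) names <- rep("CA", n)
  if (is.null(resids)) resids <- seq_len(n)
  lines <- c(
    "nmwiz_load generated.nmd",
    paste("names", paste(names, collapse = " ")),
    paste("resids", paste(resids, collapse = " ")),
    paste("coordinates",
          paste(sprintf("%.6f", as.numeric(t(modes$reference)) * 10),
                collapse = " "))
  )
  for (k in seq_len(n_modes(modes))) {
    lines <- c(lines, paste("mode", k,
                            paste(sprintf("%.6f", modes$vectors[, k]),
                                  collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back an NMD file written by [export_nmd()]
#' @param path `.nmd` file
#' @return list with `coordinates` (nm) and `modes` matrix
#' @export
read_nmd <- function(path) {
  lines <- readLines(path)
  co <- grep("^coordinates ", lines, value = TRUE)
  coords <- matrix(scan(text = sub("^coordinates ", "", co),
                        quiet = TRUE) / 10, ncol = 3, byrow = TRUE)
  ml <- grep("^mode ", lines, value = TRUE)
  modes <- vapply(ml, function(l) {
    v <- scan(text = l, what = character(), quiet = TRUE)
    as.numeric(v[-(1:2)])
  }, numeric(3 * nrow(coords)))
  colnames(modes) <- NULL
  list(coordinates = coords, modes = modes)
}
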