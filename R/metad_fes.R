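#' Read and write PLUMED-dialect COLVAR and HILLS files
#'
#' Text files with a `#! FIELDS ...` header naming whitespace-separated
#' columns.  `read_colvar`/`read_hills` map columns by name and return
#' classed tibbles; the writers emit the same dialect, so files round-trip.
#'
#' @param path file path
#' @param require_fields character vector of column names that must be
#'   present (error names the missing field)
#' @return a tibble of class `colvar_series` or `hills_record`
#' @export
read_colvar <- function(path, require_fields = character()) {
  out <- read_plumed_table(path, require_fields)
  class(out) <- c("colvar_series", class(out))
  out
}

#' @rdname read_colvar
#' @export
read_hills <- function(path, require_fields = character()) {
  out <- read_plumed_table(path, require_fields)
  if (is.unsorted(out$time))
    stop("HILLS deposit times are not increasing in ", path)
  class(out) <- c("hills_record", class(out))
  out
}

read_plumed_table <- function(path, require_fields = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#! FIELDS"))
    stop("missing '#! FIELDS' header in ", path)
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1])),
                     "[[:space:]]+")[[1]]
  miss <- setdiff(require_fields, fields)
  if (length(miss))
    stop("field(s) not present in ", path, ": ",
         paste(miss, collapse = ", "))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(lengths(rows) != length(fields))
  if (length(bad))
    stop(sprintf("malformed line %d in %s: %d fields, expected %d",
                 which(!startsWith(lines, "#"))[bad[1]], path,
                 lengths(rows)[bad[1]], length(fields)))
  m <- matrix(as.numeric(unlist(rows)), ncol = length(fields),
              byrow = TRUE)
  colnames(m) <- fields
  tibble::as_tibble(as.data.frame(m))
}

#' @rdname read_colvar
#' @param x a `colvar_series` or `hills_record` tibble
#' @export
write_plumed_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(x), collapse = " ")), con)
  df <- as.data.frame(x)
  body <- do.call(paste, c(lapply(df, function(col)
    sprintf("%.10g", col)), sep = " "))
  writeLines(body, con)
  invisible(path)
}

# cv column names of a hills record: everything between time and sigma_*
hills_cv_names <- function(hills) {
  nm <- names(hills)
  setdiff(nm, c("time", "height", "biasf", grep("^sigma_", nm,
                                                value = TRUE)))
}

#' Metadynamics bias potential from deposited hills
#'
#' Sums the deposited Gaussians (heights already carry the well-tempered
#' scaling) at one or more points in CV space, exactly (no grid
#' approximation).
#'
#' @param hills a `hills_record` tibble
#' @param points numeric vector (one point) or matrix `[m, d]` of points
#'   in CV space, columns ordered as the hills CV columns
#' @param up_to_time only hills deposited at `time <= up_to_time` count
#' @return bias in kJ/mol, one value per point
#' @export
bias_at <- function(hills, points, up_to_time = Inf) {
  cvn <- hills_cv_names(hills)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  h <- hills[hills$time <= up_to_time, , drop = FALSE]
  if (!nrow(h)) return(numeric(nrow(points)))
  V <- numeric(nrow(points))
  for (d in seq_along(cvn)) {
    dd <- outer(points[, d], h[[cvn[d]]], "-") /
      rep(h[[paste0("sigma_", cvn[d])]], each = nrow(points))
    V <- if (d == 1) dd^2 else V + dd^2
  }
  as.numeric(exp(-V / 2) %*% h$height)
}

#' Reweight a biased trajectory to the unbiased ensemble
#'
#' Assigns per-frame statistical weights that undo the metadynamics bias:
#' \describe{
#'   \item{`final_bias`}{`w_i` proportional to
#'     `exp(+V_bias(s_i, t_end) / kB T)` using the full deposited bias; an
#'     initial transient (first `discard_fraction` of the deposition time)
#'     is dropped.}
#'   \item{`time_dependent`}{Tiwary-Parrinello style:
#'     `w_i` proportional to `exp((V_bias(s_i, t_i) - c(t_i)) / kB T)`
#'     with the time-dependent offset
#'     `c(t) = kB T ln( <exp(gamma/(gamma-1) V/kT)> /
#'     <exp(1/(gamma-1) V/kT)> )` evaluated on a CV grid.}
#' }
#'
#' @param colvar a `colvar_series` tibble (time + CV columns)
#' @param hills a `hills_record` tibble with matching CV names
#' @param temperature K
#' @param scheme `"final_bias"` (default) or `"time_dependent"`
#' @param discard_fraction initial fraction of the deposition time whose
#'   frames are discarded (default 0.2)
#' @param grid_n grid resolution per dimension for the `c(t)` estimate
#' @return object of class `weighted_ensemble`: list with `samples`
#'   (tibble: all colvar columns) and normalized `weights`
#' @export
reweight <- function(colvar, hills, temperature = 300,
                     scheme = c("final_bias", "time_dependent"),
                     discard_fraction = 0.2, grid_n = 101L) {
  scheme <- match.arg(scheme)
  cvn <- hills_cv_names(hills)
  miss <- setdiff(cvn, names(colvar))
  if (length(miss))
    stop("COLVAR lacks CV column(s) present in HILLS: ",
         paste(miss, collapse = ", "))
  kT <- kB * temperature
  keep <- if (nrow(hills))
    colvar$time >= discard_fraction * max(hills$time)
  else rep(TRUE, nrow(colvar))
  samples <- colvar[keep, , drop = FALSE]
  pts <- as.matrix(samples[, cvn, drop = FALSE])
  if (!nrow(hills)) {
    w <- rep(1 / nrow(samples), nrow(samples))
  } else if (scheme == "final_bias") {
    v <- bias_at(hills, pts)
    w <- exp((v - max(v)) / kT)
    w <- w / sum(w)
  } else {
    w <- tiwary_parrinello_weights(samples, hills, cvn, kT, grid_n)
  }
  structure(list(samples = samples, weights = w,
                 temperature = temperature, cv_names = cvn),
            class = "weighted_ensemble")
}

tiwary_parrinello_weights <- function(samples, hills, cvn, kT, grid_n) {
  gamma <- hills$biasf[1]
  d <- length(cvn)
  gx <- lapply(cvn, function(nm) {
    rng <- range(c(samples[[nm]], hills[[nm]]))
    pad <- 0.05 * diff(rng)
    seq(rng[1] - pad, rng[2] + pad, length.out = grid_n)
  })
  grid_pts <- as.matrix(expand.grid(gx))
  Vg <- numeric(nrow(grid_pts))
  # incremental hill addition; c(t) piecewise-constant between deposits
  times <- c(hills$time, Inf)
  ct_at <- numeric(nrow(samples))
  Vsamp <- numeric(nrow(samples))
  ct <- 0
  for (hidx in seq_len(nrow(hills) + 1L)) {
    t_lo <- if (hidx == 1L) -Inf else times[hidx - 1L]
    t_hi <- times[hidx]
    in_win <- samples$time > t_lo & samples$time <= t_hi
    if (any(in_win)) {
      ct_at[in_win] <- ct
      Vsamp[in_win] <- bias_at(hills,
                               as.matrix(samples[in_win, cvn,
                                                 drop = FALSE]),
                               up_to_time = t_lo)
    }
    if (hidx > nrow(hills)) break
    h1 <- hills[hidx, , drop = FALSE]
    dd <- 0
    for (k in seq_len(d))
      dd <- dd + ((grid_pts[, k] - h1[[cvn[k]]]) /
                    h1[[paste0("sigma_", cvn[k])]])^2
    Vg <- Vg + h1$height * exp(-dd / 2)
    num <- log(mean(exp((gamma / (gamma - 1)) * (Vg - max(Vg)) / kT))) +
      (gamma / (gamma - 1)) * max(Vg) / kT
    den <- log(mean(exp((1 / (gamma - 1)) * (Vg - max(Vg)) / kT))) +
      (1 / (gamma - 1)) * max(Vg) / kT
    ct <- kT * (num - den)
  }
  w <- exp((Vsamp - ct_at - max(Vsamp - ct_at)) / kT)
  w / sum(w)
}

#' @export
print.weighted_ensemble <- function(x, ...) {
  cat(sprintf(
    "<weighted_ensemble> %d samples over (%s), effective n = %.0f\n",
    nrow(x$samples), paste(x$cv_names, collapse = ", "),
    1 / sum(x$weights^2) * sum(x$weights)^2))
  invisible(x)
}
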