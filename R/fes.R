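#' Gridded free-energy surfaces from weighted ensembles
#'
#' Histograms a weighted ensemble on a regular 1D or 2D grid and converts
#' the normalized probabilities to free energies,
#' `F = -kB T ln P`, gauge-fixed so the occupied minimum is 0.  Bins with
#' fewer than `min_count` effective samples (Kish effective sample size of
#' the weights falling in the bin) are masked in `F` and excluded from
#' entropy calculations; the probability array keeps their raw values so
#' replica averaging is unbiased.
#'
#' @param ensemble a [reweight()] result, or a tibble/data frame of
#'   samples (then `weights` may be given separately)
#' @param vars character vector of 1 or 2 column names to histogram
#' @param bins bins per dimension (default 50)
#' @param limits optional list of `c(lo, hi)` per dimension; default data
#'   range padded by 5%
#' @param temperature K (taken from the ensemble when available)
#' @param weights optional sample weights when `ensemble` is a plain table
#' @param min_count mask threshold in effective samples (default 5)
#' @return object of class `free_energy_surface`: list with `vars`,
#'   `edges`, `centers`, `P` (normalized), `F` (kJ/mol, masked bins NA),
#'   `counts`, `n_eff`, `temperature`; replica-averaged surfaces add
#'   `std`, `sem`, `n_replicas`
#' @export
weighted_fes <- function(ensemble, vars = NULL, bins = 50L,
                         limits = NULL, temperature = NULL,
                         weights = NULL, min_count = 5) {
  if (inherits(ensemble, "weighted_ensemble")) {
    samples <- ensemble$samples
    weights <- ensemble$weights
    if (is.null(temperature)) temperature <- ensemble$temperature
    if (is.null(vars)) vars <- ensemble$cv_names
  } else {
    samples <- tibble::as_tibble(ensemble)
    if (is.null(vars)) stop("vars must be given for plain sample tables")
    if (is.null(weights)) weights <- rep(1, nrow(samples))
    weights <- weights / sum(weights)
    if (is.null(temperature)) temperature <- 300
  }
  d <- length(vars)
  stopifnot(d %in% 1:2)
  X <- as.matrix(samples[, vars, drop = FALSE])
  if (!nrow(X)) stop("no samples to histogram")
  bins <- rep_len(bins, d)
  edges <- lapply(seq_len(d), function(a) {
    lim <- if (!is.null(limits)) limits[[a]] else {
      r <- range(X[, a]); pad <- 0.05 * max(diff(r), 1e-12)
      c(r[1] - pad, r[2] + pad)
    }
    seq(lim[1], lim[2], length.out = bins[a] + 1L)
  })
  idx <- lapply(seq_len(d), function(a)
    findInterval(X[, a], edges[[a]], rightmost.closed = TRUE))
  inside <- Reduce(`&`, lapply(seq_len(d), function(a)
    idx[[a]] >= 1L & idx[[a]] <= bins[a]))
  if (!any(inside)) stop("all samples fall outside the grid")
  lin <- idx[[1]][inside]
  if (d == 2L) lin <- lin + (idx[[2]][inside] - 1L) * bins[1]
  w <- weights[inside]
  nb <- prod(bins)
  wsum <- as.numeric(rowsum_safe(w, lin, nb))
  w2sum <- as.numeric(rowsum_safe(w^2, lin, nb))
  counts <- as.numeric(rowsum_safe(rep(1, length(w)), lin, nb))
  P <- wsum / sum(wsum)
  n_eff <- ifelse(w2sum > 0, wsum^2 / w2sum, 0)
  kT <- kB * temperature
  F <- -kT * log(P)
  F[n_eff < min_count] <- NA_real_
  F <- F - min(F, na.rm = TRUE)
  shape <- if (d == 2L) bins else NULL
  reshape <- function(v) if (d == 2L) matrix(v, bins[1], bins[2]) else v
  structure(list(
    vars = vars, edges = edges,
    centers = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
    P = reshape(P), F = reshape(F), counts = reshape(counts),
    n_eff = reshape(n_eff), temperature = temperature,
    min_count = min_count),
    class = "free_energy_surface")
}

rowsum_safe <- function(x, group, n) {
  out <- numeric(n)
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf(
    "<free_energy_surface> %s, %s bins, T = %g K, %d masked bins\n",
    paste(x$vars, collapse = " x "),
    paste(vapply(x$centers, length, integer(1)), collapse = " x "),
    x$temperature, sum(is.na(x$F))))
  invisible(x)
}

#' @export
tidy.free_energy_surface <- function(x, ...) {
  if (length(x$vars) == 2L) {
    out <- tibble::as_tibble(cbind(
      expand.grid(x$centers[[1]], x$centers[[2]]),
      P = as.numeric(x$P), F = as.numeric(x$F),
      count = as.numeric(x$counts),
      std = if (!is.null(x$std)) as.numeric(x$std) else NA_real_,
      sem = if (!is.null(x$sem)) as.numeric(x$sem) else NA_real_))
    names(out)[1:2] <- x$vars
  } else {
    out <- tibble::tibble(x$centers[[1]], P = x$P, F = x$F,
                          count = x$counts,
                          std = if (!is.null(x$std)) x$std else NA_real_,
                          sem = if (!is.null(x$sem)) x$sem else NA_real_)
    names(out)[1] <- x$vars
  }
  out
}

#' @export
glance.free_energy_surface <- function(x, ...) {
  tibble::tibble(
    n_bins = length(x$P), n_occupied = sum(!is.na(x$F)),
    f_max = max(x$F, na.rm = TRUE), temperature = x$temperature,
    entropy_bits = shannon_entropy(x),
    n_replicas = if (is.null(x$n_replicas)) 1L else x$n_replicas)
}

#' Replica-averaged free-energy surface with uncertainties
#'
#' Averages the *probability distributions* of replica surfaces (not their
#' free energies) and converts the mean to `F = -kB T ln(P_mean)`.  Per-bin
#' replica scatter is reported on the free-energy scale: each replica's
#' `F` is gauge-fixed to min 0, the per-bin standard deviation across
#' replicas estimates the uncertainty of a single run, and the standard
#' error of the mean is `std / sqrt(R)`.
#'
#' @param fes_list list of [weighted_fes()] results on identical grids
#' @return a `free_energy_surface` with `std`, `sem` and `n_replicas`
#' @export
average_fes <- function(fes_list) {
  stopifnot(length(fes_list) >= 2)
  f1 <- fes_list[[1]]
  for (f in fes_list[-1]) {
    if (!identical(lapply(f$edges, range), lapply(f1$edges, range)) ||
        !identical(vapply(f$edges, length, integer(1)),
                   vapply(f1$edges, length, integer(1))))
      stop("replica surfaces must share one grid")
  }
  R <- length(fes_list)
  Pbar <- Reduce(`+`, lapply(fes_list, function(f) f$P)) / R
  kT <- kB * f1$temperature
  Fbar <- -kT * log(Pbar)
  occupied <- Reduce(`+`, lapply(fes_list, function(f) !is.na(f$F)))
  Fbar[occupied == 0] <- NA_real_
  Fbar <- Fbar - min(Fbar, na.rm = TRUE)
  # per-bin scatter of gauge-fixed replica F
  Fs <- lapply(fes_list, function(f) f$F)
  Fmean <- Reduce(`+`, lapply(Fs, function(f) ifelse(is.na(f), 0, f))) /
    pmax(occupied, 1)
  sqdev <- Reduce(`+`, lapply(Fs, function(f)
    ifelse(is.na(f), 0, (f - Fmean)^2)))
  std <- sqrt(sqdev / pmax(occupied - 1, 1))
  std[occupied < 2] <- NA_real_
  out <- f1
  out$P <- Pbar
  out$F <- Fbar
  out$counts <- Reduce(`+`, lapply(fes_list, function(f) f$counts))
  out$n_eff <- Reduce(`+`, lapply(fes_list, function(f) f$n_eff))
  out$std <- std
  out$sem <- std / sqrt(R)
  out$n_replicas <- R
  out
}

#' Write / read a free-energy surface as a TSV grid with metadata header
#'
#' The format is a plain TSV of bin centres, probability, free energy,
#' counts and (when present) replica std/SEM, preceded by `#key value`
#' metadata lines, so surfaces can be exchanged with external plotting
#' tools and reloaded losslessly for further analysis.
#'
#' @param fes a [weighted_fes()] / [average_fes()] result
#' @param path output `.tsv` path
#' @return `read_fes` returns the `free_energy_surface`; `write_fes`
#'   returns `path` invisibly.
#' @export
write_fes <- function(fes, path) {
  stopifnot(inherits(fes, "free_energy_surface"))
  td <- tidy(fes)
  hdr <- c(
    "#FRESEAN-FES 1",
    sprintf("#vars %s", paste(fes$vars, collapse = " ")),
    sprintf("#bins %s", paste(vapply(fes$centers, length, integer(1)),
                              collapse = " ")),
    sprintf("#limits %s", paste(sprintf("%.17g", unlist(lapply(
      fes$edges, range))), collapse = " ")),
    sprintf("#temperature %.17g", fes$temperature),
    sprintf("#min_count %.17g", fes$min_count),
    sprintf("#n_replicas %d",
            if (is.null(fes$n_replicas)) 1L else fes$n_replicas),
    paste("#", paste(names(td), collapse = "\t"))
  )
  body <- apply(as.data.frame(td), 1, function(r)
    paste(sprintf("%.17g", as.numeric(r)), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!identical(lines[1], "#FRESEAN-FES 1"))
    stop("not a FES grid file: ", path)
  hdr <- function(key) sub(paste0("^#", key, " "), "",
                           grep(paste0("^#", key, " "), lines,
                                value = TRUE)[1])
  vars <- strsplit(hdr("vars"), " ")[[1]]
  bins <- as.integer(strsplit(hdr("bins"), " ")[[1]])
  lims <- as.numeric(strsplit(hdr("limits"), " ")[[1]])
  d <- length(vars)
  edges <- lapply(seq_len(d), function(a)
    seq(lims[2 * a - 1], lims[2 * a], length.out = bins[a] + 1L))
  body <- lines[!startsWith(lines, "#")]
  m <- matrix(suppressWarnings(as.numeric(unlist(strsplit(body, "\t")))),
              nrow = length(body), byrow = TRUE)   # "NA" -> NA (masked)
  reshape <- function(v) if (d == 2L) matrix(v, bins[1], bins[2]) else v
  nrep <- as.integer(hdr("n_replicas"))
  out <- structure(list(
    vars = vars, edges = edges,
    centers = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2),
    P = reshape(m[, d + 1]), F = reshape(m[, d + 2]),
    counts = reshape(m[, d + 3]),
    n_eff = reshape(m[, d + 3]),
    temperature = as.numeric(hdr("temperature")),
    min_count = as.numeric(hdr("min_count"))),
    class = "free_energy_surface")
  if (nrep > 1L) {
    out$std <- reshape(m[, d + 4])
    out$sem <- reshape(m[, d + 5])
    out$n_replicas <- nrep
  }
  out
}

## ---------------------------------------------------------------------------
## Information metrics

fes_probabilities <- function(x) {
  if (inherits(x, "free_energy_surface")) {
    p <- as.numeric(x$P)
    occ <- !is.na(as.numeric(x$F))
    p <- p * occ
    if (sum(p) <= 0) stop("no occupied bins")
    p / sum(p)
  } else {
    p <- as.numeric(x)
    if (any(p < -1e-12)) stop("negative probabilities")
    if (abs(sum(p) - 1) > 1e-6)
      stop(sprintf("distribution not normalized (sums to %.6g)", sum(p)))
    p
  }
}

#' Shannon entropy of a gridded distribution (bits)
#'
#' `S2 = -sum p log2 p` over occupied bins.  For a
#' [weighted_fes()] input the occupied-bin probabilities are renormalized
#' first; a plain numeric distribution must already be normalized.
#'
#' @param x a `free_energy_surface` or a normalized probability
#'   vector/matrix
#' @return entropy in bits
#' @export
shannon_entropy <- function(x) {
  p <- fes_probabilities(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Bhattacharyya coefficient of two gridded distributions
#'
#' `BC = sum sqrt(p_a p_b)` in `[0, 1]`; 1 for identical distributions, 0
#' for disjoint supports.  Inputs must live on the same grid.
#'
#' @param a,b `free_energy_surface` objects or normalized probability
#'   arrays on one grid
#' @return scalar in `[0, 1]`
#' @export
bhattacharyya <- function(a, b) {
  len <- function(x) if (inherits(x, "free_energy_surface"))
    length(x$P) else length(x)
  if (len(a) != len(b))
    stop("distributions are not on the same grid")
  pa <- fes_probabilities(a)
  pb <- fes_probabilities(b)
  min(sum(sqrt(pa * pb)), 1)
}

## ---------------------------------------------------------------------------
## States, microstates and paths

region_mask <- function(fes, region) {
  cx <- fes$centers[[1]]
  if (length(fes$vars) == 2L) {
    cy <- fes$centers[[2]]
    pts <- cbind(rep(cx, length(cy)), rep(cy, each = length(cx)))
  } else pts <- cbind(cx)
  inside <- if (is.function(region)) {
    if (ncol(pts) == 2L) region(pts[, 1], pts[, 2]) else region(pts[, 1])
  } else if (!is.null(region$kind) && region$kind == "ellipse") {
    rowSums(sweep(sweep(pts, 2, region$center), 2, region$radii,
                  "/")^2) <= 1
  } else if (!is.null(region$kind) && region$kind == "rect") {
    ok <- pts[, 1] >= region$xlim[1] & pts[, 1] <= region$xlim[2]
    if (ncol(pts) == 2L)
      ok <- ok & pts[, 2] >= region$ylim[1] & pts[, 2] <= region$ylim[2]
    ok
  } else stop("region must be a function, an ellipse or a rect spec")
  inside
}

#' Free-energy difference between two CV-space states
#'
#' `Delta F = -kB T ln(P_B / P_A)` with state probabilities integrated
#' over regions of CV space (rectangles, ellipses, or predicate
#' functions).  An empty region is signalled distinctly via an infinite
#' result and a warning.
#'
#' @param fes a [weighted_fes()] result
#' @param regionA,regionB region specs: `list(kind = "rect", xlim, ylim)`,
#'   `list(kind = "ellipse", center, radii)`, or a predicate
#'   `function(x, y)`
#' @param temperature K; defaults to the surface's
#' @return Delta F in kJ/mol (`+Inf`/`-Inf` when a region is empty)
#' @export
state_delta_f <- function(fes, regionA, regionB, temperature = NULL) {
  stopifnot(inherits(fes, "free_energy_surface"))
  if (is.null(temperature)) temperature <- fes$temperature
  p <- as.numeric(fes$P)
  pa <- sum(p[region_mask(fes, regionA)])
  pb <- sum(p[region_mask(fes, regionB)])
  if (pa <= 0 || pb <= 0) {
    warning("empty state region: free-energy difference is infinite")
    return(if (pb <= 0) Inf else -Inf)
  }
  -kB * temperature * log(pb / pa)
}

#' Representative microstates by k-means clustering in CV space
#'
#' Weighted ensembles restricted to a state are summarised by `k` cluster
#' centres (e.g. 40 representative conformations per state).
#' Deterministic for a given seed.
#'
#' @param x a [reweight()] ensemble, a `free_energy_surface` is not
#'   accepted (cluster samples, not bins), or a numeric matrix of samples
#' @param k number of microstates
#' @param region optional region spec to restrict samples first
#' @param seed RNG seed
#' @param vars columns to cluster on when `x` is an ensemble
#' @return list with `centers` (k x d), `assignment`, `inertia`
#' @export
kmeans_microstates <- function(x, k, region = NULL, seed = 1,
                               vars = NULL) {
  if (inherits(x, "weighted_ensemble")) {
    if (is.null(vars)) vars <- x$cv_names
    X <- as.matrix(x$samples[, vars, drop = FALSE])
  } else X <- as.matrix(x)
  if (!is.null(region)) {
    keep <- if (is.function(region)) {
      if (ncol(X) == 2L) region(X[, 1], X[, 2]) else region(X[, 1])
    } else if (region$kind == "ellipse") {
      rowSums(sweep(sweep(X, 2, region$center), 2, region$radii,
                    "/")^2) <= 1
    } else {
      ok <- X[, 1] >= region$xlim[1] & X[, 1] <= region$xlim[2]
      if (ncol(X) == 2L)
        ok <- ok & X[, 2] >= region$ylim[1] & X[, 2] <= region$ylim[2]
      ok
    }
    X <- X[keep, , drop = FALSE]
  }
  if (k > nrow(X))
    stop(sprintf("k = %d exceeds the %d available samples", k, nrow(X)))
  if (k == nrow(X))                 # one microstate per sample
    return(list(centers = X, assignment = seq_len(nrow(X)),
                inertia = 0))
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L)
  list(centers = km$centers, assignment = km$cluster,
       inertia = km$tot.withinss)
}

#' Minimum free-energy path between two points on a surface
#'
#' Finds the lowest-maximum (minimax) path on the 8-connected grid graph
#' of finite-F bins between the bins containing `start` and `end`
#' (Dijkstra-style search with the running maximum of `F` as path cost,
#' cumulative `F` as tie-break), and returns the free-energy profile along
#' it with per-bin replica uncertainties when available.
#'
#' @param fes a 2D [weighted_fes()] (or [average_fes()]) result
#' @param start,end length-2 CV coordinates
#' @return tibble: `step`, the two CV columns, `F`, `std`, `sem`
#' @export
min_free_energy_path <- function(fes, start, end) {
  stopifnot(inherits(fes, "free_energy_surface"),
            length(fes$vars) == 2L)
  nx <- length(fes$centers[[1]]); ny <- length(fes$centers[[2]])
  Fm <- fes$F
  bin_of <- function(pt) {
    i <- findInterval(pt[1], fes$edges[[1]], rightmost.closed = TRUE)
    j <- findInterval(pt[2], fes$edges[[2]], rightmost.closed = TRUE)
    if (i < 1 || i > nx || j < 1 || j > ny)
      stop("start/end point outside the grid")
    c(i, j)
  }
  s <- bin_of(start); e <- bin_of(end)
  if (is.na(Fm[s[1], s[2]]) || is.na(Fm[e[1], e[2]]))
    stop("start or end bin is unoccupied")
  id <- function(i, j) i + (j - 1L) * nx
  n <- nx * ny
  maxF <- rep(Inf, n); cumF <- rep(Inf, n)
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  finite <- !is.na(as.numeric(Fm))
  sF <- Fm[s[1], s[2]]
  maxF[id(s[1], s[2])] <- sF; cumF[id(s[1], s[2])] <- sF
  target <- id(e[1], e[2])
  repeat {
    cand <- which(!visited & finite & is.finite(maxF))
    if (!length(cand)) stop("no finite-F path connects start and end")
    u <- cand[order(maxF[cand], cumF[cand])[1]]
    if (u == target) break
    visited[u] <- TRUE
    ui <- (u - 1L) %% nx + 1L; uj <- (u - 1L) %/% nx + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      vi <- ui + di; vj <- uj + dj
      if (vi < 1 || vi > nx || vj < 1 || vj > ny) next
      v <- id(vi, vj)
      if (visited[v] || !finite[v]) next
      nm <- max(maxF[u], Fm[vi, vj])
      nc <- cumF[u] + Fm[vi, vj]
      if (nm < maxF[v] || (nm == maxF[v] && nc < cumF[v])) {
        maxF[v] <- nm; cumF[v] <- nc; prev[v] <- u
      }
    }
  }
  path <- integer(0); u <- target
  while (!is.na(u)) { path <- c(u, path); u <- prev[u] }
  pi <- (path - 1L) %% nx + 1L; pj <- (path - 1L) %/% nx + 1L
  out <- tibble::tibble(
    step = seq_along(path),
    x = fes$centers[[1]][pi], y = fes$centers[[2]][pj],
    F = Fm[cbind(pi, pj)],
    std = if (!is.null(fes$std)) fes$std[cbind(pi, pj)] else NA_real_,
    sem = if (!is.null(fes$sem)) fes$sem[cbind(pi, pj)] else NA_real_)
  names(out)[2:3] <- fes$vars
  out
}

## ---------------------------------------------------------------------------
## Generic geometric collective variables

#' Define and evaluate geometric collective variables
#'
#' Distances (nm), angles and dihedrals (degrees) between centres of mass
#' of named site groups, for projecting ensembles onto interpretable
#' coordinates.
#'
#' @param kind `"distance"`, `"angle"` or `"dihedral"`
#' @param groups list of 2, 3 or 4 integer vectors (site indices); each
#'   group's centre of mass is one geometric site
#' @param name column name in the output
#' @return object of class `geometric_cv`
#' @export
geometric_cv <- function(kind = c("distance", "angle", "dihedral"),
                         groups, name = kind) {
  kind <- match.arg(kind)
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  if (length(groups) != need)
    stop(sprintf("%s needs %d site groups", kind, need))
  if (any(lengths(groups) == 0L)) stop("empty site group")
  structure(list(kind = kind, groups = lapply(groups, as.integer),
                 name = name),
            class = "geometric_cv")
}

#' @rdname geometric_cv
#' @param traj a [trajectory()]
#' @param defs list of `geometric_cv` definitions
#' @param masses optional per-site masses for the centres of mass
#'   (default: unweighted means)
#' @return tibble with `time` and one column per definition
#' @export
eval_geometric_cv <- function(traj, defs, masses = NULL) {
  if (inherits(defs, "geometric_cv")) defs <- list(defs)
  n <- n_sites(traj)
  if (is.null(masses)) masses <- rep(1, n)
  out <- tibble::tibble(time = traj$time)
  for (def in defs) {
    if (max(unlist(def$groups)) > n) stop("site index out of range")
    coms <- lapply(def$groups, function(g) {
      w <- masses[g] / sum(masses[g])
      m <- sapply(1:3, function(a)
        as.numeric(matrix(traj$pos[, g, a], ncol = length(g)) %*% w))
      matrix(m, ncol = 3)
    })
    val <- switch(def$kind,
      distance = sqrt(rowSums((coms[[1]] - coms[[2]])^2)),
      angle = {
        v1 <- coms[[1]] - coms[[2]]; v2 <- coms[[3]] - coms[[2]]
        cosang <- rowSums(v1 * v2) /
          (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
        acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      },
      dihedral = {
        b1 <- coms[[2]] - coms[[1]]; b2 <- coms[[3]] - coms[[2]]
        b3 <- coms[[4]] - coms[[3]]
        n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
        m1 <- cross3(n1, b2 / sqrt(rowSums(b2^2)))
        atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
      })
    out[[def$name]] <- val
  }
  out
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
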