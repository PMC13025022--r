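#' Collective-variable definition from a mode vector
#'
#' A CV built from a vibrational mode: a frame is (i) aligned to the
#' reference structure, (ii) assumed coarse-grained, (iii) its displacement
#' vector relative to the reference is computed and (iv) projected onto
#' the mode vector.  With mass weighting (the default, consistent with the
#' eigenproblem) the projection is `sum_i sqrt(m_i) (r_i - r_ref_i) . e_i`
#' in nm amu^1/2; without it the plain Cartesian projection in nm.
#'
#' @param mode 3n unit vector (mass-weighted displacement space)
#' @param reference `[n, 3]` reference coordinates (nm)
#' @param masses bead masses (amu)
#' @param align_weights per-bead alignment weights (default: masses)
#' @param mass_weighted project mass-weighted displacements (default TRUE)
#' @return object of class `cv_definition`
#' @export
cv_definition <- function(mode, reference, masses,
                          align_weights = masses, mass_weighted = TRUE) {
  mode <- as.numeric(mode)
  reference <- as.matrix(reference)
  if (length(mode) != 3L * nrow(reference))
    stop("mode length inconsistent with reference bead count")
  if (abs(sqrt(sum(mode^2)) - 1) > 1e-6)
    stop("mode vector must be normalized")
  structure(list(mode = mode, reference = reference,
                 masses = as.numeric(masses),
                 ref_frame = reference_frame(reference, align_weights),
                 mass_weighted = mass_weighted),
            class = "cv_definition")
}

#' Evaluate a mode collective variable on a frame
#'
#' Deterministic and invariant under rigid rotation/translation of the
#' input frame (the frame is Kabsch-aligned to the CV's reference before
#' projection).
#'
#' @param pos `[n, 3]` bead positions (nm)
#' @param cv a [cv_definition()]
#' @param align align the frame before projecting (default TRUE)
#' @return scalar CV value (nm amu^1/2, or nm if unweighted)
#' @export
evaluate_cv <- function(pos, cv, align = TRUE) {
  stopifnot(inherits(cv, "cv_definition"))
  pos <- as.matrix(pos)
  if (nrow(pos) != nrow(cv$reference))
    stop(sprintf("frame has %d beads, CV expects %d",
                 nrow(pos), nrow(cv$reference)))
  if (align) pos <- kabsch_align(pos, cv$ref_frame)$pos
  delta <- as.numeric(t(pos - cv$reference))
  w <- if (cv$mass_weighted) rep(sqrt(cv$masses), each = 3) else 1
  sum(w * delta * cv$mode)
}

#' Cartesian displacement realising a unit step of a mode CV
#'
#' Returns the `[n, 3]` displacement whose mass-weighted image is the mode
#' vector, scaled by `scale`: adding it to the reference changes the CV by
#' exactly `scale`.
#'
#' @param cv a [cv_definition()]
#' @param scale CV increment
#' @return `[n, 3]` displacement (nm)
#' @export
mode_displacement <- function(cv, scale = 1) {
  w <- if (cv$mass_weighted) rep(sqrt(cv$masses), each = 3) else 1
  matrix(scale * cv$mode / w, ncol = 3, byrow = TRUE)
}

#' Evaluate a mode CV over a whole trajectory
#' @param traj a [trajectory()] on the CV's beads
#' @param cv a [cv_definition()]
#' @return numeric vector, one value per frame
#' @export
evaluate_cv_trajectory <- function(traj, cv) {
  vapply(seq_len(n_frames(traj)), function(f)
    evaluate_cv(matrix(traj$pos[f, , ], ncol = 3), cv), numeric(1))
}

## ---------------------------------------------------------------------------
## PLUMED export

#' Write a PLUMED input biasing two mode CVs
#'
#' Emits one valid PLUMED realization of the mode-projection CV: the frame
#' is aligned with `FIT_TO_TEMPLATE` (OPTIMAL) against an emitted
#' reference PDB, bead centres are built with `CENTER`, their positions
#' exposed with `POSITION`, and the projection is a `COMBINE` action whose
#' coefficients (`sqrt(m_i) e_i`) and offsets (reference coordinates) are
#' written at full precision.  A `METAD` action biases the two CVs.
#' Full-precision auxiliary mode files and the reference PDB are written
#' next to the input; all paths are relative.
#'
#' @param cvs list of exactly two [cv_definition()]s sharing a reference
#' @param params named list with `height` (kJ/mol), `sigma` (length 2),
#'   `pace` (steps), `bias_factor`, `temperature` (K)
#' @param dir output directory (created if needed)
#' @param bead_atoms optional list of atom-index vectors per bead; when
#'   given, `CENTER` actions over those atoms are emitted, otherwise sites
#'   are addressed as atoms 1..n directly
#' @param colvar_stride `PRINT` stride for the COLVAR file
#' @return path of the written `plumed.dat`, invisibly
#' @export
write_plumed_input <- function(cvs, params, dir = ".",
                               bead_atoms = NULL, colvar_stride = 100L) {
  if (length(cvs) != 2L) stop("exactly two CV definitions are required")
  for (cv in cvs) stopifnot(inherits(cv, "cv_definition"))
  if (max(abs(cvs[[1]]$reference - cvs[[2]]$reference)) > 0)
    stop("both CVs must share one reference structure")
  need <- c("height", "sigma", "pace", "bias_factor", "temperature")
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing metadynamics parameter(s): ",
         paste(miss, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nrow(cvs[[1]]$reference)
  ref_pdb <- "cv_reference.pdb"
  write_reference_pdb(cvs[[1]]$reference, cvs[[1]]$masses,
                      file.path(dir, ref_pdb))
  aux <- character(2)
  for (k in 1:2) {
    aux[k] <- sprintf("cv%d.modes", k)
    ms <- mode_set(matrix(cvs[[k]]$mode, ncol = 1), 0,
                   cvs[[k]]$masses, freq_tag = 0,
                   reference = cvs[[k]]$reference, kind = "fresean")
    # preserve the CV's exact sign: mode_set() normalises signs
    ms$vectors <- matrix(cvs[[k]]$mode, ncol = 1)
    write_mode_file(ms, file.path(dir, aux[k]))
  }
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = ",")
  lines <- c(
    "# PLUMED input generated by freseanr: metadynamics along two",
    "# frequency-resolved mode CVs (aligned displacement projection)",
    sprintf("# height=%g kJ/mol sigma=%s pace=%d biasfactor=%g temp=%g K",
            params$height, paste(params$sigma, collapse = ","),
            as.integer(params$pace), params$bias_factor,
            params$temperature),
    sprintf("# AUXFILE cv1 %s", aux[1]),
    sprintf("# AUXFILE cv2 %s", aux[2]),
    "UNITS LENGTH=nm ENERGY=kj/mol TIME=ps",
    sprintf("WHOLEMOLECULES ENTITY0=1-%d",
            if (is.null(bead_atoms)) n
            else max(unlist(bead_atoms))),
    sprintf("FIT_TO_TEMPLATE STRIDE=1 REFERENCE=%s TYPE=OPTIMAL",
            ref_pdb))
  bead_ids <- character(n)
  if (is.null(bead_atoms)) {
    bead_ids <- as.character(seq_len(n))
  } else {
    for (b in seq_len(n)) {
      lines <- c(lines, sprintf("b%d: CENTER ATOMS=%s MASS", b,
                                paste(bead_atoms[[b]], collapse = ",")))
      bead_ids[b] <- sprintf("b%d", b)
    }
  }
  args <- character(0)
  for (b in seq_len(n)) {
    lines <- c(lines, sprintf("p%d: POSITION ATOM=%s NOPBC",
                              b, bead_ids[b]))
    args <- c(args, sprintf("p%d.%s", b, c("x", "y", "z")))
  }
  for (k in 1:2) {
    coeff <- (if (cvs[[k]]$mass_weighted)
                rep(sqrt(cvs[[k]]$masses), each = 3) else 1) *
      cvs[[k]]$mode
    lines <- c(lines, sprintf(
      "cv%d: COMBINE ARG=%s COEFFICIENTS=%s PARAMETERS=%s PERIODIC=NO",
      k, paste(args, collapse = ","), fmt(coeff),
      fmt(as.numeric(t(cvs[[k]]$reference)))))
  }
  lines <- c(lines,
    sprintf(paste0("metad: METAD ARG=cv1,cv2 SIGMA=%s HEIGHT=%.17g ",
                   "PACE=%d BIASFACTOR=%.17g TEMP=%.17g FILE=HILLS"),
            fmt(params$sigma), params$height, as.integer(params$pace),
            params$bias_factor, params$temperature),
    sprintf("PRINT ARG=cv1,cv2,metad.bias STRIDE=%d FILE=COLVAR",
            as.integer(colvar_stride)))
  path <- file.path(dir, "plumed.dat")
  writeLines(lines, path)
  invisible(path)
}

write_reference_pdb <- function(reference, masses, path) {
  n <- nrow(reference)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(n), seq_len(n),
    reference[, 1] * 10, reference[, 2] * 10, reference[, 3] * 10,
    1.00, 0.00)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Re-parse an emitted PLUMED input into CV definitions
#'
#' Reads the `COMBINE` coefficients/parameters and the full-precision
#' auxiliary mode files referenced in the header, and reconstructs the two
#' [cv_definition()]s.  Used as the self-consistency oracle for
#' [write_plumed_input()]: the reconstructed CVs evaluate identically to
#' the originals.
#'
#' @param path `plumed.dat` written by [write_plumed_input()]
#' @return list of two [cv_definition()]s
#' @export
read_plumed_cv <- function(path) {
  lines <- readLines(path)
  dir <- dirname(path)
  aux <- sub("^# AUXFILE cv[12] ", "",
             grep("^# AUXFILE ", lines, value = TRUE))
  if (length(aux) != 2) stop("no auxiliary mode files referenced in ", path)
  out <- vector("list", 2)
  comb <- grep("^cv[12]: COMBINE ", lines, value = TRUE)
  for (k in 1:2) {
    ms <- read_mode_file(file.path(dir, aux[k]))
    cf <- regmatches(comb[k],
                     regexec("COEFFICIENTS=([^ ]+)", comb[k]))[[1]][2]
    coeff <- as.numeric(strsplit(cf, ",")[[1]])
    w <- rep(sqrt(ms$masses), each = 3)
    mode <- coeff / w
    mass_weighted <- TRUE
    if (abs(sqrt(sum(coeff^2)) - 1) < 1e-9) {   # plain Cartesian export
      mode <- coeff; mass_weighted <- FALSE
    }
    out[[k]] <- cv_definition(mode / sqrt(sum(mode^2)), ms$reference,
                              ms$masses, mass_weighted = mass_weighted)
    out[[k]]$mode <- mode            # keep exact sign/scale
  }
  out
}
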