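#' Standard atomic masses (amu) used to assign masses from element symbols
#' @keywords internal
element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.973762, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  "NA" = 22.98976928, CL = 35.45, K = 39.0983, CA = 40.078
)

# Infer the element symbol from a PDB/GRO atom name: strip digits and
# primes, prefer a two-letter match only for genuine two-letter elements.
guess_element <- function(name) {
  vapply(name, function(nm) {
    s <- toupper(gsub("[^A-Za-z]", "", nm))
    if (nchar(s) == 0L) return(NA_character_)
    two <- substr(s, 1, 2)
    # avoid mapping CA (alpha carbon), CL.. atom names inside residues to
    # metals: within amino acids a leading C/N/O/S/H/P is the element
    one <- substr(s, 1, 1)
    if (one %in% c("C", "N", "O", "S", "H", "P")) one else two
  }, character(1), USE.NAMES = FALSE)
}

three_letter_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common protonation/termination variants
  "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)

#' Read a topology from a PDB or GRO file
#'
#' Parses atom records, assigns element masses from a standard table, and
#' enumerates residues.  PDB files are read through bio3d when available;
#' GRO files use a fixed-column parser (no reader for the format exists in
#' the R ecosystem).
#'
#' @param path a `.pdb` or `.gro` file
#' @param mass_fallback mass (amu) to assign to atoms whose element is not
#'   in the internal table; `NULL` (default) makes unknown elements an error
#' @param require_protein error on residue names outside the amino-acid set
#' @return an object of class `fresean_topology`: a list with `atoms` (a
#'   tibble with columns name, element, mass, resid, resname) and `residues`
#'   (one row per residue)
#' @export
read_topology <- function(path, mass_fallback = NULL,
                          require_protein = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    atoms <- parse_gro(path)
  } else if (ext == "pdb") {
    atoms <- parse_pdb(path)
  } else stop("unsupported topology format: .", ext)
  atoms$element <- guess_element(atoms$name)
  atoms$mass <- unname(element_masses[atoms$element])
  if (anyNA(atoms$mass)) {
    bad <- unique(atoms$element[is.na(atoms$mass)])
    if (is.null(mass_fallback))
      stop("unknown element(s): ", paste(bad, collapse = ", "),
           " (supply mass_fallback to accept them)")
    atoms$mass[is.na(atoms$mass)] <- mass_fallback
  }
  if (require_protein) {
    bad <- setdiff(unique(atoms$resname), three_letter_aa)
    if (length(bad))
      stop("non-protein residue(s) in topology: ",
           paste(bad, collapse = ", "))
  }
  # renumber residues consecutively in order of appearance
  key <- paste(atoms$resid, atoms$resname)
  atoms$resid <- match(key, unique(key))
  residues <- tibble::tibble(
    resid = unique(atoms$resid),
    resname = atoms$resname[!duplicated(atoms$resid)]
  )
  structure(list(atoms = tibble::as_tibble(atoms), residues = residues,
                 source = path),
            class = "fresean_topology")
}

parse_gro <- function(path) {
  lines <- readLines(path)
  natoms <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + natoms)]
  tibble::tibble(
    resid = as.integer(substr(rec, 1, 5)),
    resname = trimws(substr(rec, 6, 10)),
    name = trimws(substr(rec, 11, 15)),
    x = as.numeric(substr(rec, 21, 28)),
    y = as.numeric(substr(rec, 29, 36)),
    z = as.numeric(substr(rec, 37, 44))
  )
}

parse_pdb <- function(path) {
  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), ]
    return(tibble::tibble(
      resid = a$resno, resname = a$resid, name = a$elety,
      x = a$x / 10, y = a$y / 10, z = a$z / 10  # A -> nm
    ))
  }
  lines <- grep("^(ATOM|HETATM)", readLines(path), value = TRUE)
  tibble::tibble(
    resid = as.integer(substr(lines, 23, 26)),
    resname = trimws(substr(lines, 18, 20)),
    name = trimws(substr(lines, 13, 16)),
    x = as.numeric(substr(lines, 31, 38)) / 10,
    y = as.numeric(substr(lines, 39, 46)) / 10,
    z = as.numeric(substr(lines, 47, 54)) / 10
  )
}

#' @export
print.fresean_topology <- function(x, ...) {
  cat(sprintf("<fresean_topology> %d atoms, %d residues (%s)\n",
              nrow(x$atoms), nrow(x$residues), x$source))
  invisible(x)
}

#' Reference coordinates of a topology (nm), if the file carried them
#' @param topology a `fresean_topology`
#' @return an `[n_atoms, 3]` matrix
#' @export
topology_coords <- function(topology) {
  as.matrix(topology$atoms[, c("x", "y", "z")])
}

## ---------------------------------------------------------------------------
## Coarse-graining: one bead for glycines, two beads (backbone/sidechain)
## for every other amino acid.

# default backbone atom set; everything else in a residue is sidechain
backbone_atom_names <- c(
  "N", "H", "HN", "H1", "H2", "H3", "CA", "HA", "HA1", "HA2", "HA3",
  "C", "O", "OXT", "OT1", "OT2", "O1", "O2"
)

#' Build the two-beads-per-residue coarse-grained mapping
#'
#' Glycine residues map to a single bead; every other amino acid maps to a
#' backbone bead (N, CA, C, O and their hydrogens, plus terminal oxygens)
#' and a sidechain bead (all remaining atoms).  Bead mass is the sum of the
#' member atom masses, so total mass is conserved exactly.
#'
#' @param topology a [read_topology()] result
#' @param backbone_atoms character vector of atom names assigned to the
#'   backbone bead (configurable; the split is a convention, not physics)
#' @return a `cg_topology`: list with `beads` (tibble: mass, resid, resname,
#'   role) and `map` (list of atom-index vectors, one per bead)
#' @export
cg_mapping <- function(topology, backbone_atoms = backbone_atom_names) {
  atoms <- topology$atoms
  map <- list()
  mass <- numeric(); resid <- integer(); resname <- character()
  role <- character()
  add_bead <- function(idx, r, rn, rl) {
    map[[length(map) + 1L]] <<- idx
    mass[length(mass) + 1L] <<- sum(atoms$mass[idx])
    resid[length(resid) + 1L] <<- r
    resname[length(resname) + 1L] <<- rn
    role[length(role) + 1L] <<- rl
  }
  for (r in topology$residues$resid) {
    idx <- which(atoms$resid == r)
    rn <- atoms$resname[idx[1]]
    if (rn == "GLY") {
      add_bead(idx, r, rn, "backbone")
      next
    }
    bb <- idx[atoms$name[idx] %in% backbone_atoms]
    sc <- setdiff(idx, bb)
    if (length(sc) == 0L) {
      warning("residue ", r, " (", rn,
              ") has no sidechain atoms; mapped to a single bead")
      add_bead(idx, r, rn, "backbone")
      next
    }
    add_bead(bb, r, rn, "backbone")
    add_bead(sc, r, rn, "sidechain")
  }
  beads <- tibble::tibble(mass = mass, resid = resid, resname = resname,
                          role = role)
  structure(list(beads = beads, map = map), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %d beads (%d backbone, %d sidechain)\n",
              nrow(x$beads), sum(x$beads$role == "backbone"),
              sum(x$beads$role == "sidechain")))
  invisible(x)
}

#' Coarse-grain an atomistic trajectory onto beads
#'
#' Bead positions and velocities are mass-weighted means of the member
#' atoms, so the bead velocity carries the group momentum divided by the
#' group mass: total momentum is conserved exactly per frame.
#'
#' @param traj an atomistic [trajectory()]
#' @param topology matching [read_topology()] result
#' @param mapping optional precomputed [cg_mapping()]; built from
#'   `topology` when absent
#' @return list with elements `cg_top` (the mapping) and `traj` (the bead
#'   trajectory)
#' @export
coarse_grain <- function(traj, topology, mapping = NULL) {
  if (is.null(mapping)) mapping <- cg_mapping(topology)
  if (n_sites(traj) != nrow(topology$atoms))
    stop("trajectory/topology size mismatch")
  masses <- topology$atoms$mass
  nb <- length(mapping$map)
  # sparse aggregation matrix W [n_atoms, n_beads]: column b has m_i / M_b
  W <- matrix(0, n_sites(traj), nb)
  for (b in seq_len(nb)) {
    idx <- mapping$map[[b]]
    W[idx, b] <- masses[idx] / sum(masses[idx])
  }
  agg <- function(arr) {
    nf <- dim(arr)[1]
    out <- array(0, c(nf, nb, 3L))
    for (a in 1:3) out[, , a] <- arr[, , a] %*% W
    out
  }
  cg_pos <- agg(traj$pos)
  cg_vel <- if (has_velocities(traj)) agg(traj$vel)
  list(cg_top = mapping,
       traj = trajectory(cg_pos, cg_vel, dt = traj$dt, time = traj$time))
}
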