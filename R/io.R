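#' Read a bead/residue naming configuration
#'
#' The naming configuration maps topology residue names to lipid species and
#' identifies each species' reference headgroup bead, plus the residue names
#' to treat as protein.  Format (YAML):
#' \preformatted{
#' lipids:
#'   POPC: {species: POPC, head_bead: PO4}
#'   CHOL: {species: CHOL, head_bead: ROH}
#' protein:
#'   residues: [PROT, ALA, GLY, ...]
#' }
#'
#' @param path path to a YAML naming file.
#' @return a list with elements `lipids` and `protein`.
#' @export
read_naming_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$lipids) || is.null(cfg$protein$residues))
    stop("naming config needs `lipids` and `protein: residues` entries")
  cfg
}

#' Default naming configuration (MARTINI-style names)
#'
#' Covers the five species handled by the standard analyses (POPC, POPS,
#' POPE, SM under residue names PSM/DPSM, CHOL) with phosphate (PO4) or
#' hydroxyl (ROH) reference beads, the 20 amino-acid residue names and the
#' generic `PROT` name used by the synthetic generator.
#'
#' @return a naming configuration list.
#' @export
default_naming_config <- function() {
  read_naming_config(
    system.file("extdata", "naming_martini.yaml", package = "annulipid",
                mustWork = TRUE)
  )
}

# ---- GRO ------------------------------------------------------------------

#' Read a GRO single-frame topology file
#'
#' Fixed-width GROMACS GRO format, coordinates in nm.  Velocities, if
#' present, are ignored.  Only orthorhombic boxes (3 box numbers) are
#' supported.
#'
#' @param path file path.
#' @return list with `atoms` (data.frame: resid, resname, atomname),
#'   `coords` (n x 3 matrix, nm) and `box` (length 3, nm).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a GRO file: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || length(lines) < natoms + 3L)
    stop("malformed GRO file: ", path)
  al <- lines[3:(2 + natoms)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  atomname <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[natoms + 3L]), "\\s+")[[1]])
  if (length(box) > 3L)
    stop("triclinic boxes are not supported")
  list(
    atoms = data.frame(resid = resid, resname = resname, atomname = atomname,
                       stringsAsFactors = FALSE),
    coords = cbind(x, y, z),
    box = box
  )
}

#' Write a GRO single-frame topology file
#'
#' @param path output file path.
#' @param atoms data.frame with `resid`, `resname`, `atomname`.
#' @param coords n x 3 coordinate matrix (nm).
#' @param box length-3 box (nm).
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(path, atoms, coords, box, title = "annulipid") {
  n <- nrow(atoms)
  lines <- c(
    title,
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            atoms$resid %% 100000L, atoms$resname, atoms$atomname,
            seq_len(n) %% 100000L,
            coords[, 1], coords[, 2], coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- DCD ------------------------------------------------------------------

#' Write a CHARMM-format DCD trajectory
#'
#' Writes single-precision coordinates in Angstrom with a per-frame unit-cell
#' block, the layout `bio3d::read.dcd()` (and common MD tools) expect.
#' Input coordinates are in nm and converted on output.
#'
#' @param path output file path.
#' @param coords n x 3 x n_frames coordinate array (nm).
#' @param box n_frames x 3 matrix of box lengths (nm).
#' @return `path`, invisibly.
#' @export
write_dcd <- function(path, coords, box) {
  n <- dim(coords)[1]
  nf <- dim(coords)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L)
  # header record (84 bytes): magic + 20 control ints, slot 10 is a float
  wint(84L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  wint(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  writeBin(1, con, size = 4L)            # delta (unused float slot)
  wint(c(1L, rep(0L, 8L), 24L))          # crystal flag on, CHARMM version
  wint(84L)
  # title record
  wint(84L); wint(1L)
  writeChar(formatC("Written by annulipid", width = -80), con,
            nchars = 80L, eos = NULL)
  wint(84L)
  # natom record
  wint(4L); wint(n); wint(4L)
  for (f in seq_len(nf)) {
    # unit cell: a, cos(gamma), b, cos(beta), cos(alpha), c (orthorhombic)
    wint(48L)
    writeBin(c(box[f, 1] * 10, 0, box[f, 2] * 10, 0, 0, box[f, 3] * 10),
             con, size = 8L)
    wint(48L)
    for (ax in 1:3) {
      wint(4L * n)
      writeBin(as.numeric(coords[, ax, f]) * 10, con, size = 4L)
      wint(4L * n)
    }
  }
  invisible(path)
}

# ---- loading --------------------------------------------------------------

# classify topology atoms against a naming config; errors list offenders
.classify_atoms <- function(atoms, naming) {
  prot_res <- naming$protein$residues
  lipid_map <- naming$lipids
  known <- c(prot_res, names(lipid_map))
  unknown <- setdiff(unique(atoms$resname), known)
  if (length(unknown))
    stop("unmapped residue names in topology: ",
         paste(sort(unknown), collapse = ", "))
  n <- nrow(atoms)
  is_prot <- atoms$resname %in% prot_res
  species <- character(n)
  role <- character(n)
  species[is_prot] <- "PROTEIN"
  role[is_prot] <- "protein-residue"
  for (rn in names(lipid_map)) {
    sel <- atoms$resname == rn
    if (!any(sel)) next
    species[sel] <- lipid_map[[rn]]$species
    role[sel] <- ifelse(atoms$atomname[sel] == lipid_map[[rn]]$head_bead,
                        "lipid-headgroup", "lipid-tail")
  }
  if (!any(!is_prot)) stop("no lipid molecules in topology")
  # consecutive-resid molecule numbering for lipids (GRO resids may wrap)
  mol <- integer(n)
  lip_idx <- which(!is_prot)
  newmol <- c(TRUE, diff(atoms$resid[lip_idx]) != 0L |
                diff(lip_idx) != 1L)
  mol[lip_idx] <- cumsum(newmol)
  species_table(
    particle_id = seq_len(n),
    molecule_id = mol,
    species = species,
    role = role,
    residue_id = ifelse(is_prot, atoms$resid, NA_integer_)
  )
}

#' Load a trajectory and classify its particles
#'
#' Reads a GRO or PDB topology frame, classifies every particle into species
#' and roles via the naming configuration, and (optionally) reads a DCD
#' trajectory.  Coordinates are converted to nm internally.
#'
#' @param topology_path GRO or PDB file.
#' @param trajectory_path optional DCD file; when absent the topology frame
#'   becomes a single-frame trajectory.
#' @param naming_config naming configuration (see [read_naming_config()]);
#'   defaults to [default_naming_config()].
#' @param dt_frame time between trajectory frames (ns); the DCD header does
#'   not carry a reliable time base, so it must be supplied.
#' @return list with `trajectory` (a [lipid_trajectory()]) and `species`
#'   (a [species_table()]).
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL,
                            naming_config = default_naming_config(),
                            dt_frame = 1) {
  if (!file.exists(topology_path)) stop("no such topology: ", topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  if (ext == "gro") {
    top <- read_gro(topology_path)
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(topology_path, verbose = FALSE)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
    abc <- pdb$cryst1$abc
    if (is.null(abc)) stop("PDB topology lacks a CRYST1 box record")
    top <- list(
      atoms = data.frame(resid = pdb$atom$resno, resname = pdb$atom$resid,
                         atomname = pdb$atom$elety, stringsAsFactors = FALSE),
      coords = xyz, box = abc / 10
    )
  } else stop("unsupported topology format: .", ext)

  species <- .classify_atoms(top$atoms, naming_config)
  n <- nrow(top$atoms)

  if (is.null(trajectory_path)) {
    coords <- array(top$coords, dim = c(n, 3, 1))
    traj <- lipid_trajectory(coords, matrix(top$box, 1, 3), dt_frame)
    return(list(trajectory = traj, species = species))
  }
  if (!file.exists(trajectory_path))
    stop("no such trajectory: ", trajectory_path)
  if (tolower(tools::file_ext(trajectory_path)) != "dcd")
    stop("unsupported trajectory format (DCD expected): ", trajectory_path)
  xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
  if (ncol(xyz) != 3L * n)
    stop(sprintf(
      "particle-count mismatch: topology has %d particles, trajectory has %d",
      n, ncol(xyz) / 3))
  cell <- bio3d::read.dcd(trajectory_path, verbose = FALSE, cell = TRUE)
  nf <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3, n, nf)), c(2, 1, 3)) / 10
  traj <- lipid_trajectory(coords, cell[, 1:3, drop = FALSE] / 10, dt_frame)
  list(trajectory = traj, species = species)
}
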