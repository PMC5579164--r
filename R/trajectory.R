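#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames of particle coordinates together
#' with per-frame orthorhombic box lengths and a time base.  Coordinates are
#' in nm and are assumed wrapped into the box; displacement arithmetic uses
#' the minimum-image convention rather than unwrapping.
#'
#' @param coords numeric array `n_particles x 3 x n_frames` (nm).
#' @param box numeric matrix `n_frames x 3` of box lengths (nm), or a length-3
#'   vector recycled to all frames.  Only orthorhombic boxes are supported.
#' @param dt_frame time between stored frames (ns).
#' @param time optional per-frame times (ns); defaults to
#'   `(0:(n_frames-1)) * dt_frame`.
#' @return an object of class `lipid_trajectory` with elements `coords`,
#'   `box`, `time`, `dt_frame`.
#' @export
lipid_trajectory <- function(coords, box, dt_frame, time = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("`coords` must be an n_particles x 3 x n_frames array")
  if (!all(is.finite(coords)))
    stop("trajectory coordinates must be finite")
  n_frames <- dim(coords)[3]
  if (is.null(dim(box))) {
    if (length(box) == 9L)
      stop("triclinic boxes are not supported; supply orthorhombic lengths")
    if (length(box) != 3L)
      stop("`box` must be a length-3 vector or an n_frames x 3 matrix")
    box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  }
  if (nrow(box) != n_frames || ncol(box) != 3L)
    stop("`box` must have one row of 3 lengths per frame")
  if (any(box <= 0)) stop("box lengths must be positive")
  if (!is.numeric(dt_frame) || length(dt_frame) != 1L || dt_frame <= 0)
    stop("`dt_frame` must be a single positive number (ns)")
  if (is.null(time)) time <- (seq_len(n_frames) - 1) * dt_frame
  structure(
    list(coords = coords, box = box, time = time, dt_frame = dt_frame),
    class = "lipid_trajectory"
  )
}

#' @export
print.lipid_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf(
    "<lipid_trajectory> %d particles, %d frames, dt = %g ns, box = %.2f x %.2f x %.2f nm\n",
    d[1], d[3], x$dt_frame, x$box[1, 1], x$box[1, 2], x$box[1, 3]
  ))
  invisible(x)
}

#' Number of frames / particles of a trajectory
#' @param traj a `lipid_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[1]

#' Extract a contiguous (or arbitrary) set of frames
#'
#' Used by block-error estimation to slice a trajectory into contiguous
#' sub-trajectories.  The time base of the subset keeps the original frame
#' spacing.
#'
#' @param traj a `lipid_trajectory`.
#' @param idx frame indices to keep.
#' @return a `lipid_trajectory` with `length(idx)` frames.
#' @export
subset_frames <- function(traj, idx) {
  lipid_trajectory(
    coords = traj$coords[, , idx, drop = FALSE],
    box = traj$box[idx, , drop = FALSE],
    dt_frame = traj$dt_frame,
    time = traj$time[idx]
  )
}

#' Build a species table
#'
#' The species table classifies every particle of a trajectory: which molecule
#' it belongs to, which lipid species (or `PROTEIN`), and its role.  Each lipid
#' molecule must expose exactly one reference headgroup bead (the phosphate
#' bead for phospholipids and sphingomyelin, the hydroxyl ROH bead for
#' cholesterol); all per-lipid analyses track that bead.
#'
#' @param particle_id integer particle indices (1-based, matching the
#'   trajectory's first dimension).
#' @param molecule_id integer molecule index (0 for protein particles).
#' @param species character; one of `POPC`, `POPS`, `POPE`, `SM`, `CHOL`,
#'   `PROTEIN` (other lipid names are allowed but the standard analyses
#'   expect these).
#' @param role character; `protein-residue`, `lipid-headgroup` or
#'   `lipid-tail`.
#' @param residue_id integer residue index for protein particles (NA for
#'   lipids).
#' @return a `data.frame` of class `species_table`.
#' @export
species_table <- function(particle_id, molecule_id, species, role,
                          residue_id = NA_integer_) {
  df <- data.frame(
    particle_id = as.integer(particle_id),
    molecule_id = as.integer(molecule_id),
    species = as.character(species),
    role = as.character(role),
    residue_id = as.integer(residue_id),
    stringsAsFactors = FALSE
  )
  bad_role <- setdiff(unique(df$role),
                      c("protein-residue", "lipid-headgroup", "lipid-tail"))
  if (length(bad_role))
    stop("unknown roles: ", paste(bad_role, collapse = ", "))
  heads <- df[df$role == "lipid-headgroup", ]
  if (nrow(heads)) {
    per_mol <- table(heads$molecule_id)
    if (any(per_mol != 1L))
      stop("each lipid molecule must have exactly one reference headgroup bead")
  }
  class(df) <- c("species_table", "data.frame")
  df
}

#' Reference headgroup beads of a lipid species
#'
#' @param species a `species_table`.
#' @param species_name lipid species name, or NULL for all lipid species.
#' @return data.frame subset of the species table (one row per molecule).
#' @export
head_beads <- function(species, species_name = NULL) {
  h <- species[species$role == "lipid-headgroup", , drop = FALSE]
  if (!is.null(species_name)) {
    h <- h[h$species %in% species_name, , drop = FALSE]
    if (!nrow(h))
      stop("no lipids of species ", paste(species_name, collapse = "/"),
           " in the species table")
  }
  h[order(h$molecule_id), , drop = FALSE]
}

#' Minimum-image displacement between two points
#'
#' Each component of the returned displacement (from `a` to `b`) lies in
#' `[-L/2, L/2)`.
#'
#' @param a,b numeric vectors (or matrices with points in rows) of equal shape.
#' @param box box lengths, one per coordinate column.
#' @return displacement of the same shape as the inputs.
#' @export
min_image_displacement <- function(a, b, box) {
  if (any(box <= 0)) stop("box lengths must be positive")
  d <- b - a
  if (is.matrix(d)) {
    box <- matrix(box, nrow = nrow(d), ncol = ncol(d), byrow = TRUE)
  }
  d - box * floor(d / box + 0.5)
}

# minimum-image wrap of a displacement array given scalar box lengths per axis
.wrap_disp <- function(d, L) d - L * floor(d / L + 0.5)

#' Shared reference frame: protein lateral centre and bilayer midplane
#'
#' The protein lateral centre is the per-frame xy centre of mass of a protein
#' selection (by default all protein particles; pass the TM-region residues to
#' follow the transmembrane convention).  Because the box is periodic, the
#' centre is computed with the circular-mean construction, which is exact for
#' clusters smaller than half the box even when they straddle the boundary.
#' The bilayer midplane is the per-frame mean z of all lipid reference
#' headgroup beads (protein positions never bias leaflet assignment).
#'
#' @param traj a `lipid_trajectory`.
#' @param species a `species_table`.
#' @param protein_selection optional integer vector of protein `residue_id`s
#'   defining the reference selection (e.g. the TM region); default all
#'   protein residues.
#' @return list of class `reference_frame` with `protein_center_xy`
#'   (`n_frames x 2`) and `midplane_z` (length `n_frames`).
#' @export
reference_frame <- function(traj, species, protein_selection = NULL) {
  prot <- species[species$role == "protein-residue", , drop = FALSE]
  if (!nrow(prot)) stop("species table contains no protein particles")
  if (!is.null(protein_selection)) {
    prot <- prot[prot$residue_id %in% protein_selection, , drop = FALSE]
    if (!nrow(prot)) stop("protein selection matches no residues")
  }
  heads <- head_beads(species)
  nf <- n_frames(traj)
  center <- matrix(NA_real_, nf, 2)
  for (ax in 1:2) {
    xs <- traj$coords[prot$particle_id, ax, , drop = FALSE]
    dim(xs) <- c(nrow(prot), nf)
    L <- traj$box[, ax]
    theta <- sweep(xs, 2, 2 * pi / L, "*")
    mean_sin <- colMeans(sin(theta))
    mean_cos <- colMeans(cos(theta))
    ang <- atan2(mean_sin, mean_cos)
    center[, ax] <- (ang %% (2 * pi)) * L / (2 * pi)
  }
  zs <- traj$coords[heads$particle_id, 3, , drop = FALSE]
  dim(zs) <- c(nrow(heads), nf)
  structure(
    list(protein_center_xy = center, midplane_z = colMeans(zs)),
    class = "reference_frame"
  )
}

#' Lateral (xy) minimum-image distance of particles from the protein centre
#'
#' @param traj a `lipid_trajectory`.
#' @param ref a `reference_frame`.
#' @param particles integer particle ids (rows of the coordinate array).
#' @return numeric matrix `length(particles) x n_frames` of distances (nm).
#' @export
lateral_distance_to_protein <- function(traj, ref, particles) {
  nf <- n_frames(traj)
  np <- length(particles)
  x <- traj$coords[particles, 1, , drop = FALSE]; dim(x) <- c(np, nf)
  y <- traj$coords[particles, 2, , drop = FALSE]; dim(y) <- c(np, nf)
  dx <- sweep(x, 2, ref$protein_center_xy[, 1], "-")
  dy <- sweep(y, 2, ref$protein_center_xy[, 2], "-")
  Lx <- matrix(traj$box[, 1], np, nf, byrow = TRUE)
  Ly <- matrix(traj$box[, 2], np, nf, byrow = TRUE)
  dx <- dx - Lx * floor(dx / Lx + 0.5)
  dy <- dy - Ly * floor(dy / Ly + 0.5)
  sqrt(dx^2 + dy^2)
}

#' z-distance between a selection and the bilayer centre of mass
#'
#' Per frame, the z component of (centre of mass of `selection`) minus
#' (centre of mass of all lipid particles), sign preserved so positive values
#' lie above the bilayer centre.  Useful e.g. to follow an ectodomain segment
#' relative to the membrane.
#'
#' @param traj a `lipid_trajectory`.
#' @param selection integer particle ids of the selection.
#' @param species a `species_table` (defines the bilayer as all lipid
#'   particles).
#' @return numeric vector of length `n_frames` (nm).
#' @export
com_z_distance <- function(traj, selection, species) {
  if (!length(selection)) stop("empty selection")
  lip <- species$particle_id[species$role != "protein-residue"]
  if (!length(lip)) stop("no lipid particles in species table")
  nf <- n_frames(traj)
  zsel <- traj$coords[selection, 3, , drop = FALSE]
  dim(zsel) <- c(length(selection), nf)
  zlip <- traj$coords[lip, 3, , drop = FALSE]
  dim(zlip) <- c(length(lip), nf)
  colMeans(zsel) - colMeans(zlip)
}
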