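#' Count protein residue / lipid contacts
#'
#' A residue-lipid contact is counted once per frame per lipid molecule when
#' any selected bead pair comes within `cutoff` (3D minimum-image distance):
#' counting per molecule rather than per bead pair avoids biasing species
#' with more beads.  Counts are summed over frames.  The cutoff is a free
#' parameter of the analysis (0.6 nm is common coarse-grained practice) and
#' is recorded in the result's attributes.
#'
#' @param traj a [lipid_trajectory()].
#' @param species a [species_table()].
#' @param lipid_species character vector of lipid species to count against.
#' @param bead_scope `"headgroup_only"` (reference beads; cholesterol's ROH)
#'   or `"all_lipid_beads"`.
#' @param cutoff contact distance (nm).
#' @return data.frame of class `contact_table` with `residue_id`, `species`,
#'   `count`; attributes `cutoff`, `bead_scope`, `n_frames`.
#' @export
count_contacts <- function(traj, species, lipid_species,
                           bead_scope = c("headgroup_only",
                                          "all_lipid_beads"),
                           cutoff = 0.6) {
  bead_scope <- match.arg(bead_scope)
  if (cutoff <= 0) stop("cutoff must be > 0")
  prot <- species[species$role == "protein-residue", , drop = FALSE]
  if (!nrow(prot)) stop("empty protein selection")
  lip <- species[species$species %in% lipid_species &
                   species$role != "protein-residue", , drop = FALSE]
  if (bead_scope == "headgroup_only")
    lip <- lip[lip$role == "lipid-headgroup", , drop = FALSE]
  if (!nrow(lip)) stop("empty lipid selection for species ",
                       paste(lipid_species, collapse = ", "))

  residues <- sort(unique(prot$residue_id))
  res_of_bead <- match(prot$residue_id, residues)
  mols <- sort(unique(lip$molecule_id))
  mol_of_bead <- match(lip$molecule_id, mols)
  mol_species <- lip$species[match(mols, lip$molecule_id)]

  nf <- n_frames(traj)
  cut2 <- cutoff^2
  counts <- matrix(0, length(residues), length(lipid_species),
                   dimnames = list(NULL, lipid_species))
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    d2 <- 0
    for (ax in 1:3) {
      d <- outer(traj$coords[prot$particle_id, ax, f],
                 traj$coords[lip$particle_id, ax, f], "-")
      d <- .wrap_disp(d, box[ax])
      d2 <- d2 + d * d
    }
    pair <- d2 <= cut2
    # any bead pair within cutoff -> one contact per (residue, molecule)
    by_res <- rowsum(pair + 0, res_of_bead) > 0
    by_mol <- t(rowsum(t(by_res) + 0, mol_of_bead) > 0)
    for (s in lipid_species) {
      cols <- which(mol_species[as.integer(colnames(by_mol))] == s)
      if (length(cols))
        counts[, s] <- counts[, s] +
          rowSums(by_mol[, cols, drop = FALSE])
    }
  }
  out <- data.frame(
    residue_id = rep(residues, length(lipid_species)),
    species = rep(lipid_species, each = length(residues)),
    count = as.vector(counts),
    stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "bead_scope") <- bead_scope
  attr(out, "n_frames") <- nf
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Normalize a contact table by its global maximum
#'
#' Every entry is divided by the single highest raw count across all residues
#' and species of the complex (one shared scale, not per-domain or
#' per-species), so the most contacted residue maps to exactly 1.
#' Normalizing an already-normalized table is a no-op (the raw counts are
#' retained).
#'
#' @param table a [count_contacts()] result.
#' @return the table with a `normalized` column in `[0, 1]`.
#' @export
normalize_contacts <- function(table) {
  if (!nrow(table)) stop("empty contact table")
  m <- max(table$count)
  if (m == 0) {
    warning("all contact counts are zero")
    table$normalized <- 0
  } else {
    table$normalized <- table$count / m
  }
  table
}

#' Standard deviation of normalized contacts across simulation systems
#'
#' Given normalized contact tables from several independent systems (e.g.
#' replicate simulations with different bilayers or seeds), returns the
#' per-(residue, species) population standard deviation — the error-bar
#' convention for cross-system contact comparisons.
#'
#' @param tables list of >= 2 normalized contact tables sharing the same
#'   (residue, species) indexing.
#' @return data.frame with `residue_id`, `species`, `mean`, `sd`.
#' @export
contact_sd_across_systems <- function(tables) {
  if (length(tables) < 2) stop("need at least two contact tables")
  key <- function(t) paste(t$residue_id, t$species)
  k1 <- key(tables[[1]])
  for (i in seq_along(tables)[-1]) {
    ki <- key(tables[[i]])
    if (!identical(sort(k1), sort(ki))) {
      diffs <- c(setdiff(k1, ki), setdiff(ki, k1))
      stop("contact tables disagree on (residue, species) entries: ",
           paste(unique(diffs), collapse = "; "))
    }
    if (is.null(tables[[i]]$normalized))
      stop("table ", i, " is not normalized; run normalize_contacts()")
  }
  if (is.null(tables[[1]]$normalized))
    stop("table 1 is not normalized; run normalize_contacts()")
  vals <- vapply(tables, function(t) t$normalized[match(k1, key(t))],
                 numeric(length(k1)))
  data.frame(
    residue_id = tables[[1]]$residue_id,
    species = tables[[1]]$species,
    mean = rowMeans(vals),
    sd = apply(vals, 1, .pop_sd),
    stringsAsFactors = FALSE
  )
}

#' Map normalized contacts onto a structure as B-factors
#'
#' Writes a PDB in which every atom's B-factor holds its residue's
#' normalized contact value (residues absent from the table get 0), enabling
#' blue-white-red contact rendering in any molecular viewer.
#'
#' @param table a normalized [count_contacts()] result for one lipid species
#'   (or pass `species_name` to select one).
#' @param topology_path GRO or PDB topology whose protein residues are
#'   annotated.
#' @param out_path output PDB path.
#' @param species_name lipid species column of the table to map; defaults to
#'   the only species present.
#' @param naming_config naming configuration used to identify protein
#'   residues.
#' @return `out_path`, invisibly.
#' @export
map_contacts_to_structure <- function(table, topology_path, out_path,
                                      species_name = NULL,
                                      naming_config =
                                        default_naming_config()) {
  if (is.null(table$normalized))
    stop("table is not normalized; run normalize_contacts()")
  if (is.null(species_name)) {
    species_name <- unique(table$species)
    if (length(species_name) != 1)
      stop("table holds several species; pick one via `species_name`")
  }
  tab <- table[table$species == species_name, , drop = FALSE]

  ext <- tolower(tools::file_ext(topology_path))
  if (ext == "gro") {
    top <- read_gro(topology_path)
    coords <- top$coords
  } else if (ext == "pdb") {
    pdb <- bio3d::read.pdb(topology_path, verbose = FALSE)
    top <- list(atoms = data.frame(resid = pdb$atom$resno,
                                   resname = pdb$atom$resid,
                                   atomname = pdb$atom$elety,
                                   stringsAsFactors = FALSE))
    coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
  } else stop("unsupported topology format: .", ext)

  is_prot <- top$atoms$resname %in% naming_config$protein$residues
  missing <- setdiff(tab$residue_id, top$atoms$resid[is_prot])
  if (length(missing))
    stop("residues not resolvable in topology: ",
         paste(missing, collapse = ", "))
  b <- rep(0, nrow(top$atoms))
  hit <- is_prot & top$atoms$resid %in% tab$residue_id
  b[hit] <- tab$normalized[match(top$atoms$resid[hit], tab$residue_id)]

  bio3d::write.pdb(
    file = out_path,
    xyz = as.vector(t(coords * 10)),
    resno = top$atoms$resid,
    # PDB residue-name field is 3 characters; longer CG names are truncated
    resid = substr(top$atoms$resname, 1, 3),
    elety = top$atoms$atomname,
    b = b
  )
  invisible(out_path)
}
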