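# Hand-built toy systems and small cached simulations shared across tests.

# trajectory with explicit coordinates: coords_list is a list of n x 3
# matrices (one per frame)
toy_trajectory <- function(coords_list, box = c(19, 19, 10), dt_frame = 1) {
  n <- nrow(coords_list[[1]])
  arr <- array(NA_real_, dim = c(n, 3, length(coords_list)))
  for (f in seq_along(coords_list)) arr[, , f] <- coords_list[[f]]
  lipid_trajectory(arr, box, dt_frame)
}

# species table for a toy with np protein beads followed by nl single-bead
# lipids of the given species
toy_species <- function(np, lipid_species) {
  nl <- length(lipid_species)
  species_table(
    particle_id = seq_len(np + nl),
    molecule_id = c(rep(0L, np), seq_len(nl)),
    species = c(rep("PROTEIN", np), lipid_species),
    role = c(rep("protein-residue", np), rep("lipid-headgroup", nl)),
    residue_id = c(seq_len(np), rep(NA_integer_, nl))
  )
}

# single-species uniform-diffusion spec (no obstacle, no well, no flips)
uniform_spec <- function(n_per_leaflet = 100, n_frames = 500, D = 0.01,
                         seed = 1, species = "POPC", ...) {
  comp <- list(outer = setNames(n_per_leaflet, species),
               inner = setNames(n_per_leaflet, species))
  membrane_spec(composition = comp, protein_radius = 0, protein_beads = 1,
                d_profile = setNames(list(D), species),
                enrichment_well = list(), flip_rate = c(),
                n_frames = n_frames, seed = seed, ...)
}

# cache mid-sized simulations across tests within a file run
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, spec_fn) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- simulate_membrane(spec_fn)
  .sim_cache[[key]]
}
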