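test_that("a single stationary lipid yields 1/area in its bin, mass 1", {
  f <- rbind(c(9.5, 9.5, 0), c(3.05, 7.13, 2), c(15, 15, -2))
  traj <- toy_trajectory(list(f, f, f), box = c(19, 19, 10))
  sp <- toy_species(1, c("POPC", "POPS"))
  ref <- reference_frame(traj, sp)
  asg <- assign_leaflets(traj, sp)
  g <- density_map_2d(traj, sp, "POPC", "outer", asg, ref, bin_size = 0.2)
  a <- g$metadata$bin_area
  expect_equal(max(g$density), 1 / a)
  expect_equal(sum(g$density > 0), 1)
  expect_equal(density_mass(g), 1, tolerance = 1e-12)
  expect_error(density_map_2d(traj, sp, "POPS", "outer", asg, ref),
               "absent")
  expect_error(density_map_2d(traj, sp, "POPC", "outer", asg, ref,
                              bin_size = 0.23), "divide")
})

test_that("density normalization conserves mass to 1e-12 for all species", {
  sim <- cached_sim("dens_mix", membrane_spec(
    composition = list(outer = c(POPC = 60, SM = 50, CHOL = 40),
                       inner = c(POPC = 50, POPS = 40, POPE = 30, CHOL = 40)),
    protein_radius = 0.5,
    d_profile = list(POPC = 0.01, SM = 0.009, CHOL = 0.01, POPS = 0.008,
                     POPE = 0.008),
    enrichment_well = list(), flip_rate = c(),
    n_frames = 200, seed = 23))
  ref <- reference_frame(sim$trajectory, sim$species)
  asg <- assign_leaflets(sim$trajectory, sim$species)
  combos <- unique(sim$truth$molecules[c("species", "leaflet0")])
  for (i in seq_len(nrow(combos))) {
    g <- density_map_2d(sim$trajectory, sim$species, combos$species[i],
                        combos$leaflet0[i], asg, ref)
    expect_equal(density_mass(g), 1, tolerance = 1e-12)
  }
})

test_that("flip-flopping cholesterol mass equals mean/last count ratio", {
  sim <- simulate_membrane(membrane_spec(
    composition = list(outer = c(CHOL = 60), inner = c(CHOL = 60)),
    protein_radius = 0, protein_beads = 1, d_profile = list(CHOL = 0.01),
    enrichment_well = list(), flip_rate = c(CHOL = 3e-3),
    n_frames = 300, seed = 29))
  asg <- assign_leaflets(sim$trajectory, sim$species)
  ref <- reference_frame(sim$trajectory, sim$species)
  g <- density_map_2d(sim$trajectory, sim$species, "CHOL", "outer",
                      asg, ref)
  mean_ct <- mean(colSums(asg$labels == 1L))
  last_ct <- sum(asg$labels[, ncol(asg$labels)] == 1L)
  expect_equal(density_mass(g), mean_ct / last_ct, tolerance = 1e-12)
})

test_that("a synthetic enrichment well shows up in the density map", {
  spec <- membrane_spec(
    composition = list(outer = c(POPS = 300), inner = c(POPS = 300)),
    protein_radius = 0.5, d_profile = list(POPS = 0.01),
    enrichment_well = list(POPS = list(depth = 1, range = 2)),
    flip_rate = c(), n_frames = 800, seed = 31)
  sim <- cached_sim("dens_well", spec)
  ref <- reference_frame(sim$trajectory, sim$species)
  asg <- assign_leaflets(sim$trajectory, sim$species)
  g <- density_map_2d(sim$trajectory, sim$species, "POPS", "outer",
                      asg, ref, bin_size = 0.5)
  cx <- (g$x_edges[-1] + g$x_edges[-length(g$x_edges)]) / 2
  r <- sqrt(outer(cx^2, cx^2, "+"))
  inside <- r > 0.7 & r < 2.3
  far <- r > 5 & r < 8
  ratio <- mean(g$density[inside]) / mean(g$density[far])
  expect_gt(ratio, exp(1) * 0.75)
  expect_lt(ratio, exp(1) * 1.25)
})

test_that("ideal-gas RDF is flat at 1 and integrates to the lipid count", {
  # density modes on the box scale decay over L^2/(4D) >> any affordable
  # run, so the honest standard error comes from independent replicate
  # generations, not from time blocks of a single run
  reps <- 10
  gs <- NULL
  for (i in seq_len(reps)) {
    sim <- simulate_membrane(uniform_spec(250, 120, seed = 600 + i))
    ref <- reference_frame(sim$trajectory, sim$species)
    rdf <- rdf_lateral(sim$trajectory, sim$species, "POPC", ref,
                       "whole_bilayer")
    if (i == 1) {
      # shell counts integrate back to the total per frame (pre-bulk-norm)
      expect_equal(sum(rdf$count), 500)
      keep <- rdf$area > 0.1
    }
    gs <- cbind(gs, rdf$g[keep])
  }
  se <- apply(gs, 1, sd) / sqrt(reps)
  z <- abs(rowMeans(gs) - 1) / se
  # multiplicity-aware flatness: among ~65 shells a couple of isolated 3-SE
  # exceedances are expected by chance, gross ones are not
  expect_lte(sum(z > 3), 3)
  expect_lt(max(z), 7)
  expect_equal(mean(rowMeans(gs)), 1, tolerance = 0.02)
})

test_that("RDF sees the excluded obstacle and the Boltzmann well", {
  sim <- cached_sim("dens_well", membrane_spec(
    composition = list(outer = c(POPS = 300), inner = c(POPS = 300)),
    protein_radius = 0.5, d_profile = list(POPS = 0.01),
    enrichment_well = list(POPS = list(depth = 1, range = 2)),
    flip_rate = c(), n_frames = 800, seed = 31))
  ref <- reference_frame(sim$trajectory, sim$species)
  rdf <- rdf_lateral(sim$trajectory, sim$species, "POPS", ref,
                     "whole_bilayer")
  expect_equal(attr(rdf, "protein_radius"), 0.5, tolerance = 1e-9)
  expect_true(all(rdf$g[rdf$r_outer <= 0.5] == 0))
  core <- mean(rdf$g[rdf$r_inner >= 0.8 & rdf$r_outer <= 2.2])
  plat <- mean(rdf$g[rdf$r_inner >= 4.5 & rdf$r_outer <= 8])
  expect_equal(core / plat, exp(1), tolerance = 0.15)
})

test_that("cholesterol RDFs must span the whole bilayer", {
  sim <- cached_sim("dens_mix", membrane_spec(
    composition = list(outer = c(POPC = 60, SM = 50, CHOL = 40),
                       inner = c(POPC = 50, POPS = 40, POPE = 30, CHOL = 40)),
    protein_radius = 0.5,
    d_profile = list(POPC = 0.01, SM = 0.009, CHOL = 0.01, POPS = 0.008,
                     POPE = 0.008),
    enrichment_well = list(), flip_rate = c(),
    n_frames = 200, seed = 23))
  ref <- reference_frame(sim$trajectory, sim$species)
  asg <- assign_leaflets(sim$trajectory, sim$species)
  expect_error(rdf_lateral(sim$trajectory, sim$species, "CHOL", ref,
                           "outer", asg), "whole_bilayer")
  rdf <- rdf_lateral(sim$trajectory, sim$species, "CHOL", ref,
                     "whole_bilayer", asg)
  expect_equal(sum(rdf$count), 80)
})

test_that("density maps and RDFs are mutually consistent", {
  sim <- cached_sim("dens_well", membrane_spec(
    composition = list(outer = c(POPS = 300), inner = c(POPS = 300)),
    protein_radius = 0.5, d_profile = list(POPS = 0.01),
    enrichment_well = list(POPS = list(depth = 1, range = 2)),
    flip_rate = c(), n_frames = 800, seed = 31))
  ref <- reference_frame(sim$trajectory, sim$species)
  asg <- assign_leaflets(sim$trajectory, sim$species)
  g <- density_map_2d(sim$trajectory, sim$species, "POPS", "outer",
                      asg, ref, bin_size = 0.2)
  rdf <- rdf_lateral(sim$trajectory, sim$species, "POPS", ref, "outer",
                     asg, shell_width = 0.5)
  cx <- (g$x_edges[-1] + g$x_edges[-length(g$x_edges)]) / 2
  r <- sqrt(outer(cx^2, cx^2, "+"))
  bulk <- attr(rdf, "bulk_density")
  for (shell in c(3, 6, 10)) {
    sel <- r >= rdf$r_inner[shell] & r < rdf$r_outer[shell]
    # density map is per lipid per frame; x300 lipids to compare with g*bulk
    radial_avg <- mean(g$density[sel]) * 300
    expect_equal(radial_avg, rdf$g[shell] * bulk, tolerance = 0.15)
  }
})
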