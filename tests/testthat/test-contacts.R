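test_that("contacts respect the cutoff", {
  f <- rbind(c(5, 5, 0), c(5.5, 5, 0), c(12, 12, 2))
  traj <- toy_trajectory(list(f))
  sp <- toy_species(1, c("POPS", "POPS"))
  hit <- count_contacts(traj, sp, "POPS", cutoff = 0.6)
  expect_equal(hit$count[hit$residue_id == 1], 1)
  miss <- count_contacts(traj, sp, "POPS", cutoff = 0.4)
  expect_equal(miss$count[miss$residue_id == 1], 0)
  expect_error(count_contacts(traj, sp, "SM"), "empty lipid")
  expect_error(count_contacts(traj, sp, "POPS", cutoff = -1), "cutoff")
})

test_that("contact counts match exhaustive pair enumeration on a toy", {
  set.seed(55)
  np <- 4; nl <- 6; nfr <- 5
  frames <- lapply(1:nfr, function(f)
    cbind(runif(np + nl, 0, 4), runif(np + nl, 0, 4),
          runif(np + nl, -1, 1)))
  traj <- toy_trajectory(frames, box = c(19, 19, 10))
  sp <- toy_species(np, rep(c("POPS", "POPC"), c(3, 3)))
  cutoff <- 1.2
  got <- count_contacts(traj, sp, c("POPS", "POPC"), cutoff = cutoff)
  # brute force: triple loop over frames, residues, lipid molecules
  for (res in 1:np) for (s in c("POPS", "POPC")) {
    lip <- which(sp$species == s)
    want <- 0
    for (f in 1:nfr) for (l in lip) {
      d <- sqrt(sum(min_image_displacement(frames[[f]][res, ],
                                           frames[[f]][l, ],
                                           c(19, 19, 10))^2))
      if (d <= cutoff) want <- want + 1
    }
    expect_equal(got$count[got$residue_id == res & got$species == s], want)
  }
})

test_that("contact counts are monotone in the cutoff", {
  set.seed(56)
  frames <- lapply(1:3, function(f)
    cbind(runif(10, 0, 5), runif(10, 0, 5), runif(10, -1, 1)))
  traj <- toy_trajectory(frames)
  sp <- toy_species(3, rep("POPC", 7))
  cuts <- c(0.4, 0.8, 1.2, 2)
  counts <- vapply(cuts, function(cc)
    count_contacts(traj, sp, "POPC", cutoff = cc)$count,
    numeric(3))
  expect_true(all(diff(t(counts)) >= 0))
})

test_that("normalization uses one global maximum and is idempotent", {
  tab <- data.frame(residue_id = 1:3, species = "POPS", count = c(2, 4, 8))
  class(tab) <- c("contact_table", "data.frame")
  n1 <- normalize_contacts(tab)
  expect_equal(n1$normalized, c(0.25, 0.5, 1))
  expect_equal(normalize_contacts(n1)$normalized, n1$normalized)
  one <- data.frame(residue_id = 1:2, species = "SM", count = c(0, 7))
  expect_equal(normalize_contacts(one)$normalized, c(0, 1))
  zero <- data.frame(residue_id = 1, species = "SM", count = 0)
  expect_warning(nz <- normalize_contacts(zero), "zero")
  expect_equal(nz$normalized, 0)
  # one shared scale across species, not per-species
  two <- data.frame(residue_id = c(1, 1), species = c("POPS", "POPC"),
                    count = c(10, 5))
  expect_equal(normalize_contacts(two)$normalized, c(1, 0.5))
})

test_that("cross-system contact SDs follow the population convention", {
  mk <- function(v) {
    t <- data.frame(residue_id = 1:3, species = "POPS", count = v)
    normalize_contacts(t)
  }
  tabs <- list(mk(c(0, 1, 2)), mk(c(0, 1, 2)), mk(c(0, 1, 2)))
  sd0 <- contact_sd_across_systems(tabs)
  expect_equal(sd0$sd, rep(0, 3))
  # values {0, 0.5, 1} at one residue -> population SD
  t1 <- mk(c(0, 9, 9)); t1$normalized <- c(0, 1, 1)
  t2 <- mk(c(0, 9, 9)); t2$normalized <- c(0.5, 1, 1)
  t3 <- mk(c(0, 9, 9)); t3$normalized <- c(1, 1, 1)
  out <- contact_sd_across_systems(list(t1, t2, t3))
  expect_equal(out$sd[out$residue_id == 1],
               sqrt(mean((c(0, 0.5, 1) - 0.5)^2)))
  bad <- mk(c(1, 2, 3)); bad$residue_id <- c(1, 2, 9)
  expect_error(contact_sd_across_systems(list(t1, bad)), "9")
})

test_that("replicate synthetic systems give positive SDs at contacted residues", {
  tabs <- lapply(1:3, function(sd_) {
    spec <- membrane_spec(
      composition = list(outer = c(POPS = 120), inner = c(POPS = 120)),
      protein_radius = 0.5, d_profile = list(POPS = 0.01),
      enrichment_well = list(POPS = list(depth = 1, range = 2)),
      flip_rate = c(), n_frames = 150, seed = 500 + sd_)
    sim <- simulate_membrane(spec)
    normalize_contacts(count_contacts(sim$trajectory, sim$species, "POPS",
                                      cutoff = 0.8))
  })
  out <- contact_sd_across_systems(tabs)
  expect_true(all(out$mean > 0))
  expect_true(all(out$sd > 0))
})

test_that("contacts map onto a structure as B-factors and round-trip", {
  sim <- cached_sim("io_ring", membrane_spec(
    composition = list(outer = c(POPC = 10), inner = c(POPC = 10)),
    protein_radius = 0.5, protein_beads = 4,
    d_profile = list(POPC = 0.01), enrichment_well = list(),
    flip_rate = c(), n_frames = 5, seed = 3))
  d <- tempfile()
  paths <- write_fixture(sim, d)
  tab <- data.frame(residue_id = 1L, species = "POPC", count = 4)
  tab <- normalize_contacts(rbind(tab,
    data.frame(residue_id = 2L, species = "POPC", count = 2)))
  out <- file.path(d, "contacts.pdb")
  map_contacts_to_structure(tab, paths[["topology"]], out)
  pdb <- bio3d::read.pdb(out, verbose = FALSE)
  b1 <- pdb$atom$b[pdb$atom$resno == 1 & pdb$atom$resid == "PRO"]
  expect_equal(unique(b1), 1, tolerance = 5e-3)
  b2 <- pdb$atom$b[pdb$atom$resno == 2 & pdb$atom$resid == "PRO"]
  expect_equal(unique(b2), 0.5, tolerance = 5e-3)
  # lipids and unlisted residues carry 0
  expect_true(all(pdb$atom$b[pdb$atom$resid != "PRO"] == 0))
  bad <- tab; bad$residue_id <- c(98L, 99L)
  expect_error(map_contacts_to_structure(bad, paths[["topology"]],
                                         out), "98")
})
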