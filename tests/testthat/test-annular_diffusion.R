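test_that("MSD matches brute-force enumeration on a hand-built toy", {
  # 2 particles over 3 frames: per-frame displacements (1,0) and (0,2) nm
  f1 <- rbind(c(9.5, 9.5, 0), c(1, 1, 2), c(5, 5, -2))
  f2 <- rbind(c(9.5, 9.5, 0), c(2, 1, 2), c(5, 7, -2))
  f3 <- rbind(c(9.5, 9.5, 0), c(3, 1, 2), c(5, 9, -2))
  traj <- toy_trajectory(list(f1, f2, f3))
  sp <- toy_species(1, c("POPC", "POPC"))
  msd <- msd_lateral(traj, 2:3, c(1, 2))
  # brute force over all origins and particles:
  # dt=1: (1 + 1 + 4 + 4)/4 = 2.5 ; dt=2: (4 + 16)/2 = 10
  expect_equal(msd$msd_nm2, c(2.5, 10))
  expect_equal(msd$n_windows, c(4L, 2L))
  # stationary particles
  still <- toy_trajectory(list(f1, f1, f1))
  expect_equal(msd_lateral(still, 2:3, c(1, 2))$msd_nm2, c(0, 0))
  expect_error(msd_lateral(traj, 2:3, 5), "shorter")
  expect_error(msd_lateral(traj, 2:3, 0.5), "multiple")
})

test_that("MSD uses minimum-image displacements across the boundary", {
  f1 <- rbind(c(9.5, 9.5, 0), c(0.5, 5, 2))
  f2 <- rbind(c(9.5, 9.5, 0), c(18.5, 5, 2))  # moved -1, not +18
  traj <- toy_trajectory(list(f1, f2))
  expect_equal(msd_lateral(traj, 2, 1)$msd_nm2, 1)
})

test_that("the Einstein relation converts MSD to D in both unit systems", {
  tab <- data.frame(dt_ns = 6, msd_nm2 = 0.24, n_windows = 10L)
  d <- d_of_dt(tab)
  expect_equal(d$D_nm2_ns, 0.01)
  expect_equal(d$D_cm2_s, 1e-7)
  expect_equal(d_of_dt(data.frame(dt_ns = 2, msd_nm2 = 0,
                                  n_windows = 1L))$D_nm2_ns, 0)
  expect_error(d_of_dt(data.frame(dt_ns = 0, msd_nm2 = 1)), "dt")
})

test_that("windows are assigned to the annulus of their start frame only", {
  # protein at centre; particle starts 0.5 nm out (annulus 0) and jumps to
  # 3.5 nm (annulus 3) in the next frame
  f1 <- rbind(c(9.5, 9.5, 0), c(10.0, 9.5, 2), c(9.5, 14.5, -2))
  f2 <- rbind(c(9.5, 9.5, 0), c(13.0, 9.5, 2), c(9.5, 14.5, -2))
  traj <- toy_trajectory(list(f1, f2))
  sp <- toy_species(1, c("POPC", "POPC"))
  ref <- reference_frame(traj, sp)
  prof <- d_annular(traj, sp, "POPC", ref, "whole_bilayer", dt_values = 1)
  expect_equal(prof$n_windows[prof$annulus == 0], 1L)
  expect_equal(prof$n_windows[prof$annulus == 3], 0L)
  expect_true(is.na(prof$D_nm2_ns[prof$annulus == 3]))  # missing, not 0
  expect_equal(prof$D_nm2_ns[prof$annulus == 0], 3^2 / 4)
  # window conservation: counted + discarded = all windows
  expect_equal(sum(prof$n_windows) + attr(prof, "n_discarded"), 2L)
})

test_that("uniform-D data recover a flat annular profile and ratios of 1", {
  spec <- membrane_spec(
    composition = list(outer = c(POPC = 220), inner = c(POPC = 220)),
    protein_radius = 0.5, d_profile = list(POPC = 0.01),
    enrichment_well = list(), flip_rate = c(),
    n_frames = 1500, seed = 41)
  sim <- cached_sim("diff_uniform", spec)
  ref <- reference_frame(sim$trajectory, sim$species)
  prof <- d_ratio_profile(
    d_annular(sim$trajectory, sim$species, "POPC", ref, "whole_bilayer",
              dt_values = 2), 5)
  expect_true(all(abs(prof$ratio_to_bulk - 1) < 0.1, na.rm = TRUE))
  expect_equal(mean(prof$D_nm2_ns, na.rm = TRUE), 0.01, tolerance = 0.02)
})

test_that("a two-level D(r) profile is recovered in-place", {
  spec <- membrane_spec(
    composition = list(outer = c(POPC = 250), inner = c(POPC = 250)),
    protein_radius = 0.5,
    d_profile = list(POPC = list(breaks = 3, D = c(0.005, 0.01))),
    enrichment_well = list(), flip_rate = c(),
    n_frames = 2500, seed = 43)
  sim <- cached_sim("diff_twolevel", spec)
  ref <- reference_frame(sim$trajectory, sim$species)
  prof <- d_ratio_profile(
    d_annular(sim$trajectory, sim$species, "POPC", ref, "whole_bilayer",
              dt_values = 2), 5)
  a0 <- prof$ratio_to_bulk[prof$annulus == 0]
  expect_equal(a0, 0.5, tolerance = 0.1)
  # monotone (two-level) recovery: inner annuli slow, outer fast
  expect_lt(max(prof$D_nm2_ns[prof$annulus <= 1]), 0.0062)
  expect_gt(min(prof$D_nm2_ns[prof$annulus >= 4]), 0.009)
})

test_that("leaflet scopes restrict windows by start-frame membership", {
  sim <- cached_sim("diff_uniform", uniform_spec(1, 1))
  ref <- reference_frame(sim$trajectory, sim$species)
  asg <- assign_leaflets(sim$trajectory, sim$species)
  p_out <- d_annular(sim$trajectory, sim$species, "POPC", ref, "outer",
                     assign = asg, dt_values = 2)
  p_in <- d_annular(sim$trajectory, sim$species, "POPC", ref, "inner",
                    assign = asg, dt_values = 2)
  p_all <- d_annular(sim$trajectory, sim$species, "POPC", ref,
                     "whole_bilayer", dt_values = 2)
  expect_equal(p_out$n_windows + p_in$n_windows, p_all$n_windows)
  expect_error(d_annular(sim$trajectory, sim$species, "POPC", ref,
                         "outer", dt_values = 2), "assignment")
})

test_that("block errors follow the population-SD convention", {
  # 5 'blocks' engineered to give per-block means 1..5
  vals <- rep(1:5, each = 4)
  coords <- array(0, c(2, 3, 20))
  coords[1, 1, ] <- vals
  coords[2, 1, ] <- -vals + 10
  traj <- lipid_trajectory(coords %% 19, c(19, 19, 10), 1)
  be <- block_errors(traj, function(tb) {
    c(m = mean(tb$coords[1, 1, ]))
  }, 5)
  expect_equal(unname(be$mean["m"]), 3)
  expect_equal(unname(be$sd["m"]), sqrt(2))  # population SD of {1..5}
  # identical blocks -> zero SD (periodic tiling)
  tiled <- lipid_trajectory(
    array(rep(coords[, , 1:4], 5), c(2, 3, 20)), c(19, 19, 10), 1)
  be2 <- block_errors(tiled, function(tb) c(m = mean(tb$coords[1, 1, ])), 5)
  expect_equal(unname(be2$sd["m"]), 0)
  expect_error(block_errors(traj, function(tb) 1, 1), "n_blocks")
  # a block shorter than the requested timescale propagates an error
  expect_error(
    block_errors(traj, function(tb)
      msd_lateral(tb, 1, 10)$msd_nm2, 5),
    "shorter")
})

test_that("block SDs are commensurate with seed-to-seed scatter", {
  # same-length independent runs: the 4-block SD of D and the across-seed SD
  # must agree in order of magnitude
  ds <- vapply(1:6, function(sd_) {
    sim <- simulate_membrane(uniform_spec(80, 400, seed = 300 + sd_))
    d_of_dt(msd_lateral(sim$trajectory,
                        head_beads(sim$species)$particle_id, 2))$D_nm2_ns
  }, 0)
  sim <- simulate_membrane(uniform_spec(80, 1600, seed = 299))
  ids <- head_beads(sim$species)$particle_id
  be <- block_errors(sim$trajectory, function(tb)
    c(D = d_of_dt(msd_lateral(tb, ids, 2))$D_nm2_ns), 4)
  ratio <- unname(be$sd["D"]) / sd(ds)
  expect_gt(ratio, 1 / 5)
  expect_lt(ratio, 5)
})
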