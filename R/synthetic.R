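#' Specify a synthetic two-leaflet membrane patch
#'
#' Defines the conditions for the Brownian-dynamics membrane generator: a
#' periodic rectangular patch with two flat leaflet planes, a static
#' cylindrical protein obstacle at the box centre, per-species
#' position-dependent lateral diffusivity, per-species radial enrichment
#' wells, and stochastic leaflet exchange (flip-flop) for selected species.
#' Every parameter becomes ground truth against which the estimators are
#' validated.
#'
#' The integration step must satisfy
#' `sqrt(2 * max(D) * dt_sim) < 0.2 * w`, where `w` is the narrowest radial
#' feature (profile piece, well range, or the 1 nm analysis annulus);
#' violating this inflates discretization bias at radial boundaries and is
#' rejected.
#'
#' @param composition list with numeric named vectors `outer` and `inner`
#'   giving lipid counts per species per leaflet.
#' @param box_xy lateral box lengths (nm).
#' @param leaflet_z named length-2 vector: z planes of the outer and inner
#'   leaflet (nm); the midplane sits between them.
#' @param protein_radius radius of the reflective protein disc (nm);
#'   0 disables the obstacle (a single centre marker bead is still written).
#' @param protein_beads number of ring positions marking the obstacle; each
#'   position is one protein residue of three stacked static beads (outer
#'   leaflet plane, midplane, inner leaflet plane), so contact analyses see
#'   a transmembrane span.
#' @param d_profile named list (per species) of either a single diffusivity
#'   (nm^2/ns) or `list(breaks =, D =)` with `breaks` the outer radii of a
#'   piecewise-constant radial profile measured from the protein centre and
#'   `D` one value per piece (`length(breaks) + 1`). Species absent from the
#'   list get `d_default`.
#' @param d_default fallback diffusivity (nm^2/ns).
#' @param enrichment_well named list (per species) of `list(depth =, range =)`
#'   square wells: depth in kT (attractive, > 0), spanning
#'   `protein_radius < r <= protein_radius + range` (nm).
#' @param flip_rate named vector of leaflet-swap rates (ns^-1); species not
#'   named never flip.
#' @param dt_sim Brownian integration step (ns).
#' @param frame_stride integration steps per stored frame.
#' @param n_frames stored frames (the first holds the initial state).
#' @param seed RNG seed realized by [simulate_membrane()].
#' @return an object of class `membrane_spec`.
#' @export
membrane_spec <- function(composition,
                          box_xy = c(19, 19),
                          leaflet_z = c(outer = 2, inner = -2),
                          protein_radius = 0.5,
                          protein_beads = 12,
                          d_profile = list(),
                          d_default = 0.01,
                          enrichment_well = list(),
                          flip_rate = c(CHOL = 1e-3),
                          dt_sim = 0.05,
                          frame_stride = 20,
                          n_frames = 10000,
                          seed = 1) {
  stopifnot(length(box_xy) == 2, all(box_xy > 0), length(leaflet_z) == 2)
  for (lf in c("outer", "inner")) {
    cc <- composition[[lf]]
    if (!is.null(cc) && (is.null(names(cc)) || any(cc < 0) ||
                         any(cc != round(cc))))
      stop("composition$", lf, " must be a named vector of counts >= 0")
  }
  n_lipids <- sum(unlist(composition))
  if (is.na(n_lipids) || n_lipids < 1) stop("composition has no lipids")
  if (protein_radius < 0 || protein_radius >= min(box_xy) / 4)
    stop("protein_radius must lie in [0, min(box_xy)/4)")
  if (dt_sim <= 0 || frame_stride < 1 || n_frames < 1)
    stop("dt_sim, frame_stride and n_frames must be positive")
  spp <- unique(names(c(composition$outer, composition$inner)))
  prof <- lapply(setNames(spp, spp), function(s) {
    p <- d_profile[[s]]
    if (is.null(p)) p <- d_default
    if (is.numeric(p) && length(p) == 1L) p <- list(breaks = numeric(), D = p)
    if (length(p$D) != length(p$breaks) + 1L)
      stop("d_profile for ", s, ": need one D value per piece (breaks + 1)")
    if (any(p$D <= 0)) stop("d_profile for ", s, ": D values must be > 0")
    if (is.unsorted(p$breaks, strictly = TRUE) && length(p$breaks) > 1)
      stop("d_profile for ", s, ": breaks must be strictly increasing")
    p
  })
  for (s in names(enrichment_well)) {
    w <- enrichment_well[[s]]
    if (is.null(w$depth) || is.null(w$range) || w$depth < 0 || w$range <= 0)
      stop("enrichment_well for ", s, " needs depth >= 0 and range > 0")
  }
  d_max <- max(vapply(prof, function(p) max(p$D), 0))
  widths <- c(1, unlist(lapply(prof, function(p)
    if (length(p$breaks)) diff(c(0, p$breaks)) else NULL)),
    vapply(enrichment_well, function(w) w$range, 0))
  if (sqrt(2 * d_max * dt_sim) >= 0.2 * min(widths))
    stop(sprintf(
      "integration step too coarse: rms substep %.3g nm >= 0.2 x narrowest radial feature (%.3g nm); reduce dt_sim",
      sqrt(2 * d_max * dt_sim), min(widths)))
  structure(
    list(composition = composition, box_xy = box_xy, leaflet_z = leaflet_z,
         protein_radius = protein_radius, protein_beads = protein_beads,
         d_profile = prof, enrichment_well = enrichment_well,
         flip_rate = flip_rate, dt_sim = dt_sim, frame_stride = frame_stride,
         n_frames = n_frames, seed = seed),
    class = "membrane_spec"
  )
}

#' Preset bilayer compositions
#'
#' Post-protein-insertion lipid counts of the three ~19 x 19 nm model
#' bilayers: the asymmetric plasma-membrane mimic (`Asymm`: outer leaflet
#' PC/SM/CHOL ~1:1:1, inner leaflet PC/PE/PS/CHOL), and the two symmetric
#' bilayers matching its outer (`Symm_O`) and inner (`Symm_I`) leaflet
#' compositions.  Symmetric bilayer totals are split evenly between leaflets
#' (the outer leaflet takes the extra molecule of odd counts).
#'
#' Default dynamics emulate the measured behaviour of these systems: bulk
#' diffusivities of order 0.01 nm^2/ns (1e-7 cm^2/s), a slowed annulus
#' within 2.5 nm of the protein surface (strongest for PS), an anionic-lipid
#' enrichment well, a weaker cholesterol well, and cholesterol leaflet
#' exchange at 1e-3 ns^-1.
#'
#' @param name one of `"Asymm"`, `"Symm_O"`, `"Symm_I"`.
#' @param n_frames,seed passed through to [membrane_spec()].
#' @param ... further overrides passed to [membrane_spec()].
#' @return a `membrane_spec`.
#' @export
preset_bilayer <- function(name = c("Asymm", "Symm_O", "Symm_I"),
                           n_frames = 10000, seed = 1, ...) {
  name <- match.arg(name)
  split_even <- function(tot) {
    outer <- ceiling(tot / 2)
    list(outer = outer, inner = tot - outer)
  }
  comp <- switch(name,
    Asymm = list(
      outer = c(POPC = 193, SM = 261, CHOL = 220),
      inner = c(POPC = 240, POPS = 123, POPE = 139, CHOL = 121)
    ),
    Symm_O = {
      s <- lapply(c(POPC = 452, SM = 459, CHOL = 474), split_even)
      list(outer = vapply(s, `[[`, 0, "outer"),
           inner = vapply(s, `[[`, 0, "inner"))
    },
    Symm_I = {
      s <- lapply(c(POPC = 379, POPS = 248, POPE = 313, CHOL = 254),
                  split_even)
      list(outer = vapply(s, `[[`, 0, "outer"),
           inner = vapply(s, `[[`, 0, "inner"))
    }
  )
  rp <- 0.5
  slow_edge <- rp + 2.5
  two_level <- function(bulk, factor)
    list(breaks = slow_edge, D = c(bulk * factor, bulk))
  defaults <- list(
    composition = comp,
    protein_radius = rp,
    d_profile = list(
      POPC = two_level(0.0085, 0.65),
      SM   = two_level(0.0090, 0.67),
      POPS = two_level(0.0080, 0.50),
      POPE = two_level(0.0080, 0.60),
      CHOL = two_level(0.0100, 0.60)
    ),
    enrichment_well = list(
      POPS = list(depth = 1.0, range = 2.0),
      CHOL = list(depth = 0.7, range = 1.0)
    ),
    flip_rate = c(CHOL = 1e-3),
    n_frames = n_frames,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(membrane_spec, args)
}

# evaluate a piecewise profile/well on the union break grid of all species
.union_profile <- function(prof) {
  breaks <- sort(unique(unlist(lapply(prof, `[[`, "breaks"))))
  m <- length(breaks)
  mids <- if (m) c((c(0, breaks[-m]) + breaks) / 2, breaks[m] + 1) else 0
  vals <- matrix(0, nrow = length(prof), ncol = length(mids))
  for (i in seq_along(prof))
    vals[i, ] <- prof[[i]]$D[findInterval(mids, prof[[i]]$breaks) + 1L]
  list(breaks = breaks, values = vals)
}

#' Simulate a synthetic membrane trajectory with known ground truth
#'
#' Each lipid is a single reference bead performing overdamped 2D Brownian
#' motion in its leaflet plane: Gaussian proposals with variance
#' `2 D(r) dt_sim` per axis (D evaluated at the step start), radial
#' reflection at the protein disc, Metropolis acceptance against the
#' square-well potential, periodic wrapping in xy.  Species with a positive
#' flip rate swap leaflet planes as a Poisson process sampled at frame
#' resolution; every event is logged.  Initial positions are drawn from the
#' analytic stationary density of the well (`exp(depth)` enrichment inside),
#' so well-related observables need no burn-in.  Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [membrane_spec()].
#' @return an object of class `membrane_sim`: list with `trajectory`
#'   ([lipid_trajectory()]), `species` ([species_table()]) and `truth`
#'   (spec, molecule table with initial leaflets, leaflet-label matrix,
#'   flip-event log, analytic enrichment factors).
#' @export
simulate_membrane <- function(spec) {
  stopifnot(inherits(spec, "membrane_spec"))
  set.seed(spec$seed)
  lx <- spec$box_xy[1]; ly <- spec$box_xy[2]
  rp <- spec$protein_radius
  cx <- lx / 2; cy <- ly / 2

  mols <- do.call(rbind, lapply(c("outer", "inner"), function(lf) {
    cc <- spec$composition[[lf]]
    cc <- cc[cc > 0]
    if (!length(cc)) return(NULL)
    data.frame(species = rep(names(cc), cc), leaflet0 = lf,
               stringsAsFactors = FALSE)
  }))
  mols$molecule_id <- seq_len(nrow(mols))
  n_mol <- nrow(mols)

  # initial xy from the stationary density of each species' well
  xy <- matrix(NA_real_, n_mol, 2)
  for (s in unique(mols$species)) {
    idx <- which(mols$species == s)
    w <- spec$enrichment_well[[s]]
    depth <- if (is.null(w)) 0 else w$depth
    edge <- if (is.null(w)) rp else rp + w$range
    todo <- idx
    while (length(todo)) {
      px <- runif(length(todo), 0, lx)
      py <- runif(length(todo), 0, ly)
      r <- sqrt((px - cx)^2 + (py - cy)^2)
      acc <- r >= rp & (r <= edge | runif(length(todo)) < exp(-depth))
      xy[todo[acc], ] <- cbind(px[acc], py[acc])
      todo <- todo[!acc]
    }
  }

  up <- .union_profile(spec$d_profile)
  sp_names <- names(spec$d_profile)
  sp_idx <- match(mols$species, sp_names) - 1L
  depth <- vapply(sp_names, function(s) {
    w <- spec$enrichment_well[[s]]; if (is.null(w)) 0 else w$depth
  }, 0)
  range_ <- vapply(sp_names, function(s) {
    w <- spec$enrichment_well[[s]]; if (is.null(w)) 0 else w$range
  }, 0)

  coords_xy <- brownian_patch_cpp(
    xy, sp_idx, up$breaks, up$values, depth, range_,
    lx, ly, rp, spec$dt_sim, spec$frame_stride, spec$n_frames
  )

  nf <- spec$n_frames
  dt_frame <- spec$dt_sim * spec$frame_stride

  # leaflet exchange as a frame-resolution Poisson process
  lf0 <- ifelse(mols$leaflet0 == "outer", 1L, 2L)
  labels <- matrix(lf0, n_mol, nf)
  events <- NULL
  rates <- spec$flip_rate[mols$species]
  rates[is.na(rates)] <- 0
  flipper <- which(rates > 0)
  if (length(flipper) && nf > 1) {
    p <- 1 - exp(-rates[flipper] * dt_frame)
    draws <- matrix(
      rbinom(length(flipper) * (nf - 1), 1L, rep(p, nf - 1)),
      nrow = length(flipper)
    )
    parity <- if (ncol(draws) == 1L) draws %% 2L else
      t(apply(draws, 1, cumsum)) %% 2L
    labels[flipper, -1] <- ifelse(
      parity == 1L, 3L - lf0[flipper],
      matrix(lf0[flipper], length(flipper), nf - 1)
    )
    ev <- which(draws == 1L, arr.ind = TRUE)
    if (nrow(ev)) {
      mol <- mols$molecule_id[flipper[ev[, 1]]]
      frame <- ev[, 2] + 1L
      from <- labels[cbind(flipper[ev[, 1]], frame - 1L)]
      events <- data.frame(
        molecule_id = mol,
        species = mols$species[match(mol, mols$molecule_id)],
        frame = frame,
        direction = ifelse(from == 1L, "outer->inner", "inner->outer"),
        stringsAsFactors = FALSE
      )
      events <- events[order(events$molecule_id, events$frame), ]
      rownames(events) <- NULL
    }
  }
  if (is.null(events))
    events <- data.frame(molecule_id = integer(), species = character(),
                         frame = integer(), direction = character(),
                         stringsAsFactors = FALSE)

  # assemble the full particle set: protein first, then lipid beads.  Each
  # ring position is one residue of three stacked beads spanning the
  # membrane (outer leaflet plane, midplane, inner leaflet plane) so that
  # headgroup-level contact analyses see the transmembrane span.
  nres <- if (rp > 0) spec$protein_beads else 1L
  ang <- 2 * pi * (seq_len(nres) - 1) / nres
  z_levels <- c(spec$leaflet_z[["outer"]], 0, spec$leaflet_z[["inner"]])
  prot_xy <- cbind(cx + rp * cos(ang), cy + rp * sin(ang))
  nb <- nres * 3L
  prot_res <- rep(seq_len(nres), each = 3L)
  n_part <- nb + n_mol
  coords <- array(NA_real_, dim = c(n_part, 3, nf))
  coords[seq_len(nb), 1, ] <- prot_xy[prot_res, 1]
  coords[seq_len(nb), 2, ] <- prot_xy[prot_res, 2]
  coords[seq_len(nb), 3, ] <- rep(z_levels, nres)
  coords[nb + seq_len(n_mol), 1:2, ] <- coords_xy
  z_planes <- c(spec$leaflet_z[["outer"]], spec$leaflet_z[["inner"]])
  coords[nb + seq_len(n_mol), 3, ] <- z_planes[labels]

  lz <- max(abs(spec$leaflet_z)) * 2 + 4
  traj <- lipid_trajectory(coords, c(lx, ly, lz), dt_frame)

  species <- species_table(
    particle_id = seq_len(n_part),
    molecule_id = c(rep(0L, nb), mols$molecule_id),
    species = c(rep("PROTEIN", nb), mols$species),
    role = c(rep("protein-residue", nb), rep("lipid-headgroup", n_mol)),
    residue_id = c(prot_res, rep(NA_integer_, n_mol))
  )

  truth <- list(
    spec = spec,
    molecules = mols,
    leaflet_labels = labels,
    flip_events = events,
    enrichment_factor = setNames(exp(depth), sp_names),
    well_edge = setNames(rp + range_, sp_names),
    protein_center = c(cx, cy),
    head_particles = setNames(nb + seq_len(n_mol), mols$molecule_id)
  )
  structure(list(trajectory = traj, species = species, truth = truth),
            class = "membrane_sim")
}

#' @export
print.membrane_sim <- function(x, ...) {
  cat(sprintf("<membrane_sim> %d lipids, %d frames, %d flip events\n",
              nrow(x$truth$molecules), n_frames(x$trajectory),
              nrow(x$truth$flip_events)))
  invisible(x)
}

#' Write a simulated membrane as on-disk fixture files
#'
#' Emits `topology.gro`, `traj.dcd`, `ground_truth.yaml` (the realized
#' generator parameters) and `flip_events.csv`.  [load_trajectory()]
#' round-trips the pair to format precision.
#'
#' @param sim a `membrane_sim`.
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "membrane_sim"))
  if (!nrow(sim$truth$molecules)) stop("refusing to write: no lipid molecules")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- sim$truth$spec
  resname <- c(POPC = "POPC", POPS = "POPS", POPE = "POPE",
               SM = "PSM", CHOL = "CHOL")
  st <- sim$species
  is_prot <- st$role == "protein-residue"
  rn <- ifelse(is_prot, "PROT", resname[st$species])
  if (anyNA(rn)) stop("no GRO residue name for species: ",
                      paste(unique(st$species[is.na(rn)]), collapse = ", "))
  atoms <- data.frame(
    resid = ifelse(is_prot, st$residue_id, sum(is_prot) + st$molecule_id),
    resname = rn,
    atomname = ifelse(is_prot, "BB",
                      ifelse(st$species == "CHOL", "ROH", "PO4")),
    stringsAsFactors = FALSE
  )
  topo <- file.path(out_dir, "topology.gro")
  trj <- file.path(out_dir, "traj.dcd")
  gt <- file.path(out_dir, "ground_truth.yaml")
  fe <- file.path(out_dir, "flip_events.csv")
  write_gro(topo, atoms, sim$trajectory$coords[, , 1],
            sim$trajectory$box[1, ], title = "synthetic membrane patch")
  write_dcd(trj, sim$trajectory$coords, sim$trajectory$box)
  yaml::write_yaml(list(
    synthetic = TRUE,
    seed = spec$seed,
    box_xy = as.numeric(spec$box_xy),
    leaflet_z = as.list(spec$leaflet_z),
    protein_radius = spec$protein_radius,
    composition = lapply(spec$composition, as.list),
    d_profile = lapply(spec$d_profile, function(p)
      list(breaks = as.numeric(p$breaks), D = as.numeric(p$D))),
    enrichment_well = spec$enrichment_well,
    flip_rate = as.list(spec$flip_rate),
    dt_sim = spec$dt_sim,
    frame_stride = spec$frame_stride,
    dt_frame = spec$dt_sim * spec$frame_stride,
    n_frames = spec$n_frames,
    n_lipids = nrow(sim$truth$molecules)
  ), gt)
  write.csv(sim$truth$flip_events, fe, row.names = FALSE)
  c(topology = topo, trajectory = trj, ground_truth = gt, flip_events = fe)
}
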