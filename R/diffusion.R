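# population (n-denominator) standard deviation; the convention used for all
# block/sub-trajectory and cross-system error bars
.pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Lateral mean-squared displacement over a grid of timescales
#'
#' `MSD(dt)` is the mean over particles and window origins of the squared
#' minimum-image xy displacement across `dt`.  Window origins advance by
#' `origin_stride` frames (overlapping windows allowed; temporal correlation
#' is handled downstream by block errors, not by the naive standard error).
#' Wrapped coordinates are valid input because frame spacing is much shorter
#' than a box traversal: this is asserted by checking that no particle moves
#' more than L/4 between consecutive frames.
#'
#' @param traj a [lipid_trajectory()].
#' @param particles integer particle ids to track.
#' @param dt_values timescales (ns); each must be a multiple of the frame
#'   interval and shorter than the trajectory.
#' @param origin_stride frames between successive window origins.
#' @param check_step if TRUE, verify the L/4 per-frame-step displacement
#'   assumption.
#' @return data.frame with `dt_ns`, `msd_nm2`, `n_windows`.
#' @export
msd_lateral <- function(traj, particles, dt_values, origin_stride = 1,
                        check_step = TRUE) {
  stopifnot(origin_stride >= 1, length(particles) > 0)
  box <- .constant_box(traj)
  nf <- n_frames(traj)
  np <- length(particles)
  x <- traj$coords[particles, 1, , drop = FALSE]; dim(x) <- c(np, nf)
  y <- traj$coords[particles, 2, , drop = FALSE]; dim(y) <- c(np, nf)

  if (check_step && nf > 1) {
    step <- pmax(abs(.wrap_disp(x[, -1, drop = FALSE] - x[, -nf, drop = FALSE],
                                box[1])),
                 abs(.wrap_disp(y[, -1, drop = FALSE] - y[, -nf, drop = FALSE],
                                box[2])))
    if (max(step) > min(box[1:2]) / 4)
      warning("per-frame displacements exceed L/4: wrapped-coordinate ",
              "minimum-image displacements may be aliased")
  }

  ks <- dt_values / traj$dt_frame
  if (any(abs(ks - round(ks)) > 1e-6))
    stop("every dt must be a multiple of the frame interval (",
         traj$dt_frame, " ns)")
  ks <- as.integer(round(ks))
  if (any(ks < 1) || any(ks >= nf))
    stop("dt values must be positive and shorter than the trajectory")

  res <- lapply(seq_along(ks), function(j) {
    k <- ks[j]
    o <- seq.int(1L, nf - k, by = origin_stride)
    dx <- .wrap_disp(x[, o + k, drop = FALSE] - x[, o, drop = FALSE], box[1])
    dy <- .wrap_disp(y[, o + k, drop = FALSE] - y[, o, drop = FALSE], box[2])
    d2 <- dx * dx + dy * dy
    data.frame(dt_ns = dt_values[j], msd_nm2 = mean(d2),
               n_windows = length(d2))
  })
  do.call(rbind, res)
}

#' Diffusion coefficient from an MSD table (2D Einstein relation)
#'
#' `D(dt) = MSD(dt) / (4 dt)`, reported both in nm^2/ns and cm^2/s
#' (1 nm^2/ns = 1e-5 cm^2/s).  Estimating D on a grid of timescales
#' separates short-timescale (local, caged) from long-timescale modes of
#' lipid motion.
#'
#' @param msd_table output of [msd_lateral()] (or any data.frame with
#'   `dt_ns` and `msd_nm2`).
#' @return the table with `D_nm2_ns` and `D_cm2_s` columns appended.
#' @export
d_of_dt <- function(msd_table) {
  if (any(msd_table$dt_ns <= 0)) stop("dt must be > 0")
  msd_table$D_nm2_ns <- msd_table$msd_nm2 / (4 * msd_table$dt_ns)
  msd_table$D_cm2_s <- msd_table$D_nm2_ns * NM2_NS_TO_CM2_S
  msd_table
}

#' Annulus-resolved lateral diffusion around the protein
#'
#' The space around the protein lateral centre is divided into concentric
#' annuli (default width 1 nm) and a timescale-dependent diffusion
#' coefficient is estimated in each annulus from windows assigned by the
#' lipid's position at the window's START frame — the one convention that
#' never discards windows and that the synthetic generator can reproduce
#' exactly.  The first annulus is labelled 0 and spans 0-1 nm.  Annuli with
#' zero observations report `NA` (missing), never 0.  Windows starting
#' beyond the outermost annulus are discarded (count kept as an attribute).
#'
#' @param traj a [lipid_trajectory()].
#' @param species a [species_table()].
#' @param species_name lipid species to analyse.
#' @param ref a [reference_frame()].
#' @param scope `"whole_bilayer"`, `"outer"` or `"inner"`; leaflet membership
#'   is evaluated at the window start frame.
#' @param assign a [assign_leaflets()] result (required for leaflet scopes).
#' @param annulus_width annulus width (nm).
#' @param dt_values timescales (ns).
#' @param origin_stride frames between successive window origins.
#' @param r_max outer edge of the last annulus (nm); default
#'   `floor(min(box)/2)` rounded down to a whole annulus.
#' @return data.frame of class `diffusion_profile` with columns `species`,
#'   `scope`, `annulus` (0-based), `r_inner`, `r_outer`, `dt_ns`, `msd_nm2`,
#'   `n_windows`, `D_nm2_ns`, `D_cm2_s`; attribute `n_discarded` counts
#'   windows starting beyond the last annulus.
#' @export
d_annular <- function(traj, species, species_name, ref,
                      scope = c("whole_bilayer", "outer", "inner"),
                      assign = NULL, annulus_width = 1,
                      dt_values = c(1, 2, 4, 6, 10, 20),
                      origin_stride = 1, r_max = NULL) {
  scope <- match.arg(scope)
  stopifnot(annulus_width > 0)
  box <- .constant_box(traj)
  nf <- n_frames(traj)
  heads <- head_beads(species, species_name)
  np <- nrow(heads)

  if (is.null(r_max))
    r_max <- floor(min(box[1:2]) / 2 / annulus_width) * annulus_width
  n_ann <- as.integer(round(r_max / annulus_width))

  rel <- .rel_xy(traj, ref, heads$particle_id)
  r <- sqrt(rel[[1]]^2 + rel[[2]]^2)
  ann <- floor(r / annulus_width)  # 0-based annulus index, may exceed n_ann-1

  if (scope == "whole_bilayer") {
    mask <- matrix(TRUE, np, nf)
  } else {
    if (is.null(assign)) stop("leaflet scopes need a leaflet assignment")
    mask <- assign$labels[match(heads$molecule_id, assign$molecule_id), ,
                          drop = FALSE] == .leaflet_code(scope)
  }

  x <- traj$coords[heads$particle_id, 1, , drop = FALSE]; dim(x) <- c(np, nf)
  y <- traj$coords[heads$particle_id, 2, , drop = FALSE]; dim(y) <- c(np, nf)

  ks <- dt_values / traj$dt_frame
  if (any(abs(ks - round(ks)) > 1e-6))
    stop("every dt must be a multiple of the frame interval")
  ks <- as.integer(round(ks))
  if (any(ks < 1) || any(ks >= nf))
    stop("dt values must be positive and shorter than the trajectory")

  n_discarded <- 0L
  res <- lapply(seq_along(ks), function(j) {
    k <- ks[j]
    o <- seq.int(1L, nf - k, by = origin_stride)
    dx <- .wrap_disp(x[, o + k, drop = FALSE] - x[, o, drop = FALSE], box[1])
    dy <- .wrap_disp(y[, o + k, drop = FALSE] - y[, o, drop = FALSE], box[2])
    d2 <- dx * dx + dy * dy
    a0 <- ann[, o, drop = FALSE]
    valid <- mask[, o, drop = FALSE] & a0 < n_ann
    n_discarded <<- n_discarded + sum(mask[, o, drop = FALSE] & a0 >= n_ann)
    grp <- a0[valid] + 1L
    sums <- rowsum(d2[valid], grp)
    nobs <- tabulate(grp, n_ann)
    msd <- rep(NA_real_, n_ann)
    msd[as.integer(rownames(sums))] <-
      sums[, 1] / nobs[as.integer(rownames(sums))]
    data.frame(
      species = species_name, scope = scope,
      annulus = seq_len(n_ann) - 1L,
      r_inner = (seq_len(n_ann) - 1L) * annulus_width,
      r_outer = seq_len(n_ann) * annulus_width,
      dt_ns = dt_values[j], msd_nm2 = msd, n_windows = nobs,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$D_nm2_ns <- out$msd_nm2 / (4 * out$dt_ns)
  out$D_cm2_s <- out$D_nm2_ns * NM2_NS_TO_CM2_S
  attr(out, "n_discarded") <- n_discarded
  attr(out, "annulus_width") <- annulus_width
  class(out) <- c("diffusion_profile", "data.frame")
  out
}

#' Diffusion ratios relative to the bulk plateau
#'
#' The bulk diffusion coefficient is the observation-weighted mean over all
#' annuli whose inner edge lies at or beyond `bulk_min` (default 5 nm, the
#' onset of the far-field plateau); each annulus is then reported as
#' `D(annulus) / D_bulk`, separately per timescale.
#'
#' @param profile a [d_annular()] result.
#' @param bulk_min inner-edge distance (nm) from which annuli count as bulk.
#' @return the profile with `D_bulk_nm2_ns` and `ratio_to_bulk` appended.
#' @export
d_ratio_profile <- function(profile, bulk_min = 5) {
  out <- lapply(split(profile, profile$dt_ns), function(p) {
    b <- p$r_inner >= bulk_min & p$n_windows > 0 & is.finite(p$D_nm2_ns)
    if (!any(b)) stop("no populated bulk annuli at or beyond ", bulk_min,
                      " nm")
    d_bulk <- weighted.mean(p$D_nm2_ns[b], p$n_windows[b])
    p$D_bulk_nm2_ns <- d_bulk
    p$ratio_to_bulk <- p$D_nm2_ns / d_bulk
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  for (a in c("n_discarded", "annulus_width"))
    attr(out, a) <- attr(profile, a)
  class(out) <- c("diffusion_profile", "data.frame")
  out
}

#' Block (sub-trajectory) errors for any trajectory analysis
#'
#' Splits the trajectory into `n_blocks` equal contiguous sub-trajectories
#' (remainder frames are dropped), recomputes the analysis on each block and
#' returns the across-block mean and population standard deviation per
#' reported quantity.  This is the error convention for diffusion profiles
#' (e.g. five 2-us sub-trajectories of a 10-us run).
#'
#' @param traj a [lipid_trajectory()].
#' @param fun analysis closure: called as `fun(block_trajectory)` or, if it
#'   accepts two arguments, `fun(block_trajectory, frame_idx)` so that
#'   companion objects (leaflet assignments, reference frames) can be sliced
#'   to the same frames.  Must return a numeric vector (consistent length and
#'   names across blocks).
#' @param n_blocks number of contiguous blocks (>= 2).
#' @return list with `mean`, `sd` (population convention) and `values`
#'   (`n_blocks` x n_quantities matrix).
#' @export
block_errors <- function(traj, fun, n_blocks = 5) {
  stopifnot(n_blocks >= 2)
  nf <- n_frames(traj)
  len <- floor(nf / n_blocks)
  if (len < 2) stop("trajectory too short for ", n_blocks, " blocks")
  two_arg <- length(formals(fun)) >= 2
  vals <- lapply(seq_len(n_blocks), function(b) {
    idx <- seq.int((b - 1L) * len + 1L, b * len)
    v <- if (two_arg) fun(subset_frames(traj, idx), idx)
         else fun(subset_frames(traj, idx))
    unlist(v)
  })
  values <- do.call(rbind, vals)
  list(mean = colMeans(values),
       sd = apply(values, 2, .pop_sd),
       values = values)
}
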