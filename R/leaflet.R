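#' Assign every lipid to a leaflet in every frame
#'
#' A lipid is `outer` when its reference headgroup bead lies above the
#' per-frame bilayer midplane (the mean z of all lipid reference beads) and
#' `inner` otherwise; a bead exactly at the midplane is assigned `inner`
#' (deterministic tie-break).  The midplane is computed from lipids only, so
#' the protein position never biases the assignment.
#'
#' @param traj a [lipid_trajectory()].
#' @param species a [species_table()].
#' @return object of class `leaflet_assignment`: list with `labels` (integer
#'   matrix molecules x frames; 1 = outer, 2 = inner), `molecule_id`,
#'   `species` (per molecule), and `dt_frame`.
#' @export
assign_leaflets <- function(traj, species) {
  heads <- head_beads(species)
  nf <- n_frames(traj)
  z <- traj$coords[heads$particle_id, 3, , drop = FALSE]
  dim(z) <- c(nrow(heads), nf)
  mid <- colMeans(z)
  labels <- ifelse(sweep(z, 2, mid, ">"), 1L, 2L)
  one_sided <- colSums(labels == 1L) %in% c(0L, nrow(heads))
  if (any(one_sided))
    warning(sum(one_sided),
            " frame(s) have every lipid on one side of the midplane")
  structure(
    list(labels = labels, molecule_id = heads$molecule_id,
         species = heads$species, dt_frame = traj$dt_frame),
    class = "leaflet_assignment"
  )
}

.leaflet_code <- function(leaflet) {
  switch(leaflet, outer = 1L, inner = 2L,
         stop("leaflet must be 'outer' or 'inner'"))
}

#' Detect leaflet flip-flop events with hysteresis
#'
#' A flip is recorded only when the new leaflet label persists for at least
#' `min_dwell` consecutive frames, which suppresses midplane-crossing
#' chatter.  Event rates are reported per species.  Because a genuine flip
#' followed by a return flip within the dwell window is censored (both events
#' are lost), the expected detected count is deflated by about
#' `exp(-2 r tau)` for true rate `r` and dwell time `tau`; the reported
#' `rate_per_ns` inverts this censoring (fixed point of
#' `r = r_raw * exp(2 r tau)`), and `rate_raw_per_ns` keeps the uncorrected
#' value.
#'
#' @param assign a [assign_leaflets()] result.
#' @param min_dwell minimum persistence (frames) for a confirmed flip.
#' @return object of class `flipflop_events`: list with `events` (data.frame:
#'   molecule_id, species, frame, direction) and `rates` (per-species counts
#'   and rates in events/ns and events/us).
#' @export
detect_flipflops <- function(assign, min_dwell = 10) {
  stopifnot(inherits(assign, "leaflet_assignment"), min_dwell >= 1)
  labels <- assign$labels
  nf <- ncol(labels)
  ev_list <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    runs <- rle(labels[i, ])
    if (length(runs$values) < 2L) next
    confirmed <- runs$values[1]
    starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
    keep <- integer()
    for (j in seq_along(runs$values)[-1]) {
      if (runs$values[j] != confirmed && runs$lengths[j] >= min_dwell) {
        keep <- c(keep, j)
        confirmed <- runs$values[j]
      }
    }
    if (length(keep))
      ev_list[[i]] <- data.frame(
        molecule_id = assign$molecule_id[i],
        species = assign$species[i],
        frame = starts[keep],
        direction = ifelse(labels[i, starts[keep]] == 1L,
                           "inner->outer", "outer->inner"),
        stringsAsFactors = FALSE
      )
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(molecule_id = integer(), species = character(),
                         frame = integer(), direction = character(),
                         stringsAsFactors = FALSE)
  tau <- min_dwell * assign$dt_frame
  t_eff <- max(nf - min_dwell, 1L) * assign$dt_frame
  rates <- do.call(rbind, lapply(unique(assign$species), function(s) {
    n_mol <- sum(assign$species == s)
    k <- sum(events$species == s)
    raw <- k / (n_mol * t_eff)
    r <- raw
    for (it in 1:30) r <- raw * exp(2 * r * tau)
    data.frame(species = s, n_molecules = n_mol, n_events = k,
               rate_raw_per_ns = raw, rate_per_ns = r,
               rate_per_us = r * 1000, stringsAsFactors = FALSE)
  }))
  rownames(rates) <- NULL
  structure(list(events = events, rates = rates, min_dwell = min_dwell,
                 dt_frame = assign$dt_frame),
            class = "flipflop_events")
}

#' Lipid counts per species and leaflet
#'
#' Under `last_frame` the counts of the final frame are returned — the
#' convention used to normalize cholesterol densities, since flip-flop makes
#' its per-leaflet population time-dependent.  Under `per_frame` the
#' time-average over all frames is returned.
#'
#' @param assign a [assign_leaflets()] result.
#' @param frame_policy `"per_frame"` or `"last_frame"`.
#' @return data.frame with `species`, `leaflet`, `count`.
#' @export
leaflet_counts <- function(assign, frame_policy = c("last_frame",
                                                    "per_frame")) {
  frame_policy <- match.arg(frame_policy)
  labels <- assign$labels
  grid <- expand.grid(species = unique(assign$species),
                      leaflet = c("outer", "inner"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$species, match(grid$leaflet, c("outer", "inner"))), ]
  rownames(grid) <- NULL
  grid$count <- mapply(function(s, lf) {
    rows <- assign$species == s
    code <- .leaflet_code(lf)
    if (frame_policy == "last_frame")
      sum(labels[rows, ncol(labels)] == code)
    else
      mean(colSums(labels[rows, , drop = FALSE] == code))
  }, grid$species, grid$leaflet, USE.NAMES = FALSE)
  grid
}
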