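# area of the intersection of a radius-r disc with a centred Lx x Ly
# rectangle (both centred on the same point); used to correct shell areas
# that extend beyond the inscribed circle of the periodic box
.circle_box_area <- function(r, Lx, Ly) {
  a <- Lx / 2
  b <- Ly / 2
  vapply(r, function(ri) {
    if (ri <= 0) return(0)
    if (ri * ri >= a * a + b * b) return(4 * a * b)
    G <- function(x) (x * sqrt(pmax(ri^2 - x^2, 0)) + ri^2 * asin(x / ri)) / 2
    x1 <- min(a, sqrt(max(ri^2 - b^2, 0)))
    x2 <- min(a, ri)
    4 * (b * x1 + G(x2) - G(x1))
  }, 0)
}

# constant-box accessor: density maps and RDFs assume a fixed box
.constant_box <- function(traj) {
  box <- traj$box
  if (any(abs(sweep(box, 2, box[1, ], "-")) > 1e-9 * box[1, 1]))
    stop("density/RDF analyses require a constant box across frames")
  box[1, ]
}

# molecules x frames minimum-image xy offsets from the protein centre
.rel_xy <- function(traj, ref, particles) {
  nf <- n_frames(traj)
  np <- length(particles)
  out <- vector("list", 2)
  for (ax in 1:2) {
    v <- traj$coords[particles, ax, , drop = FALSE]
    dim(v) <- c(np, nf)
    d <- sweep(v, 2, ref$protein_center_xy[, ax], "-")
    L <- matrix(traj$box[, ax], np, nf, byrow = TRUE)
    out[[ax]] <- d - L * floor(d / L + 0.5)
  }
  out
}

#' Protein-centred 2D lipid headgroup density map
#'
#' Histogram of reference-bead xy positions, translated each frame so the
#' protein lateral centre sits at the grid origin, accumulated over frames
#' and divided by (bin area x number of frames x number of lipids of that
#' species in the leaflet).  The lipid count uses the last-frame leaflet
#' populations ([leaflet_counts()]), the convention required for cholesterol
#' because flip-flop changes its per-leaflet population; for non-flipping
#' species this equals the fixed composition.  With that normalization the
#' map integrates to 1 over the box for any species that never leaves the
#' leaflet.
#'
#' @param traj a [lipid_trajectory()].
#' @param species a [species_table()].
#' @param species_name lipid species to map.
#' @param leaflet `"outer"` or `"inner"`.
#' @param assign a [assign_leaflets()] result.
#' @param ref a [reference_frame()].
#' @param bin_size requested bin size (nm); must divide both box lengths to
#'   within one part in 1e3 (edges are snapped to the box).
#' @param n_lipids optional explicit normalization count, overriding the
#'   last-frame leaflet count.
#' @return object of class `density_grid`: list with `x_edges`, `y_edges`
#'   (protein-centred, nm), `density` (nm^-2 per lipid per frame) and
#'   `metadata`.
#' @export
density_map_2d <- function(traj, species, species_name,
                           leaflet = c("outer", "inner"),
                           assign, ref, bin_size = 0.2, n_lipids = NULL) {
  leaflet <- match.arg(leaflet)
  box <- .constant_box(traj)
  nb <- round(box[1:2] / bin_size)
  if (any(nb < 1) || any(abs(box[1:2] / bin_size - nb) > 1e-3 * nb))
    stop("bin_size must divide the box lengths to within one part in 1e3")
  bx <- box[1] / nb[1]
  by <- box[2] / nb[2]

  heads <- head_beads(species, species_name)
  rel <- .rel_xy(traj, ref, heads$particle_id)
  code <- .leaflet_code(leaflet)
  mask <- assign$labels[match(heads$molecule_id, assign$molecule_id), ,
                        drop = FALSE] == code
  if (!any(mask))
    stop("species ", species_name, " absent from the ", leaflet, " leaflet")

  ix <- pmin(floor((rel[[1]][mask] + box[1] / 2) / bx) + 1L, nb[1])
  iy <- pmin(floor((rel[[2]][mask] + box[2] / 2) / by) + 1L, nb[2])
  counts <- matrix(tabulate(ix + (iy - 1L) * nb[1], nb[1] * nb[2]),
                   nb[1], nb[2])

  if (is.null(n_lipids)) {
    lc <- leaflet_counts(assign, "last_frame")
    n_lipids <- lc$count[lc$species == species_name & lc$leaflet == leaflet]
    if (!length(n_lipids) || n_lipids == 0)
      stop("species ", species_name, " absent from the ", leaflet,
           " leaflet in the last frame; supply `n_lipids` explicitly")
  }
  nf <- n_frames(traj)
  structure(
    list(
      x_edges = seq(-box[1] / 2, box[1] / 2, length.out = nb[1] + 1),
      y_edges = seq(-box[2] / 2, box[2] / 2, length.out = nb[2] + 1),
      density = counts / (bx * by * nf * n_lipids),
      metadata = list(species = species_name, leaflet = leaflet,
                      n_frames = nf, n_lipids = n_lipids,
                      bin_area = bx * by,
                      normalization = "count / (bin area * n_frames * n_lipids[last-frame leaflet count])")
    ),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(
    "<density_grid> %s/%s, %d x %d bins, %d frames, mass = %.6f\n",
    m$species, m$leaflet, length(x$x_edges) - 1, length(x$y_edges) - 1,
    m$n_frames, sum(x$density) * m$bin_area))
  invisible(x)
}

#' Integrated mass of a density grid
#'
#' `sum(density * bin area)`; equals 1 for a species that stays in the
#' mapped leaflet throughout (conservation check of the normalization).
#'
#' @param grid a `density_grid`.
#' @return a number.
#' @export
density_mass <- function(grid) sum(grid$density) * grid$metadata$bin_area

#' Lateral radial distribution function around the protein
#'
#' Reference beads are binned into radial shells around the per-frame protein
#' lateral centre (minimum-image xy distances).  `g(r)` is the shell density
#' divided by the bulk density, where shell areas are corrected for the part
#' of the shell that falls outside the periodic box and the bulk density is
#' the scope's lipid count over the box area minus the protein disc area
#' (otherwise `g` cannot plateau at 1 in an obstructed box).  Cholesterol
#' must be analysed with `scope = "whole_bilayer"` because flip-flop moves it
#' between leaflets.
#'
#' @param traj a [lipid_trajectory()].
#' @param species a [species_table()].
#' @param species_name lipid species.
#' @param ref a [reference_frame()].
#' @param scope `"outer"`, `"inner"` or `"whole_bilayer"`.
#' @param assign a [assign_leaflets()] result (needed for leaflet scopes).
#' @param shell_width radial shell width (nm).
#' @param r_max outermost shell edge (nm); defaults to the half-diagonal of
#'   the box so that every bead is counted.
#' @param protein_radius radius of the protein cross-section used for the
#'   bulk-density area correction (nm); estimated from the protein beads'
#'   maximal lateral extent when NULL.
#' @return data.frame of class `rdf_curve` with columns `r_inner`, `r_outer`,
#'   `r_mid`, `count` (mean beads per frame), `area`, `g`; attributes
#'   `bulk_density`, `protein_radius`, `species`, `scope`.
#' @export
rdf_lateral <- function(traj, species, species_name,
                        ref, scope = c("outer", "inner", "whole_bilayer"),
                        assign = NULL, shell_width = 0.2, r_max = NULL,
                        protein_radius = NULL) {
  scope <- match.arg(scope)
  if (shell_width <= 0) stop("shell_width must be > 0")
  if (species_name == "CHOL" && scope != "whole_bilayer")
    stop("CHOL undergoes flip-flop: use scope = 'whole_bilayer'")
  box <- .constant_box(traj)
  heads <- head_beads(species, species_name)
  r <- lateral_distance_to_protein(traj, ref, heads$particle_id)

  if (scope == "whole_bilayer") {
    mask <- matrix(TRUE, nrow(r), ncol(r))
  } else {
    if (is.null(assign))
      stop("leaflet scopes need a leaflet assignment")
    mask <- assign$labels[match(heads$molecule_id, assign$molecule_id), ,
                          drop = FALSE] == .leaflet_code(scope)
    if (!any(mask))
      stop("species ", species_name, " absent from scope ", scope)
  }

  if (is.null(protein_radius)) {
    prot <- species$particle_id[species$role == "protein-residue"]
    protein_radius <- if (length(prot) > 1)
      max(lateral_distance_to_protein(traj, ref, prot)) else 0
  }

  if (is.null(r_max)) r_max <- sqrt(sum((box[1:2] / 2)^2))
  n_shell <- ceiling(r_max / shell_width)
  edges <- seq(0, n_shell * shell_width, by = shell_width)

  idx <- findInterval(r[mask], edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & idx <= n_shell]
  counts <- tabulate(idx, n_shell)

  nf <- n_frames(traj)
  area <- .circle_box_area(edges[-1], box[1], box[2]) -
    .circle_box_area(edges[-length(edges)], box[1], box[2])
  usable_area <- box[1] * box[2] - pi * protein_radius^2
  bulk <- mean(colSums(mask)) / usable_area
  out <- data.frame(
    r_inner = edges[-length(edges)],
    r_outer = edges[-1],
    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
    count = counts / nf,
    area = area,
    g = ifelse(area > 0, (counts / nf) / area / bulk, NA_real_)
  )
  attr(out, "bulk_density") <- bulk
  attr(out, "protein_radius") <- protein_radius
  attr(out, "species") <- species_name
  attr(out, "scope") <- scope
  class(out) <- c("rdf_curve", "data.frame")
  out
}
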