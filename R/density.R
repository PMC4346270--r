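#' Per-leaflet lateral density map
#'
#' Every frame is rigidly superposed on the first frame via the protein
#' backbone beads (for a static or recentred protein this is the identity),
#' the same transform is applied to the lipids, and head-group positions of
#' the requested species/leaflet are histogrammed on a square (x, y) grid.
#' Division by frame count and cell area gives a time-averaged number
#' density in nm^-2. Cells whose center falls inside the protein footprint
#' (a disc of \code{footprint_radius} around the protein center of mass) are
#' masked and excluded from annulus means downstream.
#'
#' @param traj a \code{membrane_trajectory}.
#' @param system a \code{membrane_system}.
#' @param species lipid species.
#' @param leaflet "INNER" or "OUTER".
#' @param cell_size grid cell edge (nm); the 0.2 nm default resolves the
#'   ~0.5 nm concentric lipid packing rings around a protein.
#' @param footprint_radius nm; default = radius of the minimal enclosing
#'   circle of the protein backbone beads' lateral coordinates.
#' @param superpose superpose frames on the protein before histogramming?
#' @return object of class \code{density_map}: list with \code{grid}
#'   (matrix nx x ny, nm^-2), \code{x}, \code{y} (cell centers), \code{mask}
#'   (TRUE = inside footprint), \code{center} (protein COM),
#'   \code{cell_size}, \code{species}, \code{leaflet}, \code{n_frames}.
#' @export
density_map <- function(traj, system, species, leaflet,
                        cell_size = 0.2, footprint_radius = NULL,
                        superpose = TRUE) {
  beads <- system$beads
  ca_idx <- protein_ca_index(system)
  if (!length(ca_idx)) stop("no protein backbone beads for superposition")
  box <- traj$box[1, ]
  nx <- max(1L, floor(box[1] / cell_size))
  ny <- max(1L, floor(box[2] / cell_size))
  cs_x <- box[1] / nx; cs_y <- box[2] / ny
  hg_idx <- headgroup_index(system, species)
  la <- assign_leaflets(get_frame(traj, 1L), system)
  keep_mol <- names(la$leaflet)[la$leaflet == leaflet]
  hg_idx <- hg_idx[beads$molecule_id[hg_idx] %in% as.integer(keep_mol)]
  counts <- matrix(0, nx, ny)
  ref_ca <- frame_coords(traj, ca_idx, 1L)
  com <- colMeans(ref_ca)[1:2]
  nf <- n_frames(traj)
  if (length(hg_idx)) {
    for (f in seq_len(nf)) {
      hg <- frame_coords(traj, hg_idx, f)
      if (superpose && f > 1L) {
        fit <- superpose_rmsd(frame_coords(traj, ca_idx, f), ref_ca)
        hg <- apply_transform(hg, fit$transform)
      }
      ix <- pmin(nx, pmax(1L, 1L + floor((hg[, 1] %% box[1]) / cs_x)))
      iy <- pmin(ny, pmax(1L, 1L + floor((hg[, 2] %% box[2]) / cs_y)))
      counts <- counts + tabulate(ix + nx * (iy - 1L), nbins = nx * ny)
    }
  } else {
    warning("no ", species, " head groups on the ", leaflet, " leaflet; ",
            "returning an all-zero map")
  }
  xc <- (seq_len(nx) - 0.5) * cs_x
  yc <- (seq_len(ny) - 0.5) * cs_y
  if (is.null(footprint_radius))
    footprint_radius <- protein_footprint(ref_ca[, 1:2, drop = FALSE])$radius
  rad <- sqrt(outer((xc - com[1])^2, (yc - com[2])^2, `+`))
  structure(list(grid = counts / (nf * cs_x * cs_y), x = xc, y = yc,
                 radius = rad, mask = rad <= footprint_radius,
                 center = com, cell_size = c(cs_x, cs_y), species = species,
                 leaflet = leaflet, n_frames = nf,
                 footprint_radius = footprint_radius),
            class = "density_map")
}

#' Annular lipid enrichment ratio S
#'
#' S = mean head-group density in the annulus adjacent to the protein
#' (radial distance from the protein center of mass inside
#' \code{annulus_near}) divided by the mean density in the bulk annulus
#' (\code{annulus_bulk}); S > 1 means enrichment, S < 1 depletion. Given a
#' \code{density_map}, means are taken over grid cells (masked footprint
#' cells excluded when \code{mask_footprint}); given a trajectory, densities
#' are computed directly as time-averaged counts over the exact annulus
#' areas (footprint disc area subtracted from the near annulus when
#' masking), which avoids grid discretization bias.
#'
#' @param x a \code{density_map}, or a \code{membrane_trajectory} (then
#'   \code{system}, \code{species}, \code{leaflet} are required).
#' @param annulus_near radial interval (nm) next to the protein.
#' @param annulus_bulk radial interval (nm) representing bulk.
#' @param mask_footprint exclude the protein footprint from the near
#'   annulus? Masking is the default; with it a uniform bilayer gives S = 1,
#'   without it the footprint dilutes the near annulus and S < 1.
#' @param system,species,leaflet used when \code{x} is a trajectory.
#' @param footprint_radius protein footprint radius (nm); default = the
#'   minimal enclosing circle of the protein backbone beads.
#' @return object of class \code{enrichment_result}: list(S, species,
#'   leaflet, annulus_near, annulus_bulk, variant, density_near,
#'   density_bulk, flag).
#' @export
enrichment_ratio <- function(x, annulus_near = c(0, 3.0),
                             annulus_bulk = c(3.5, 6.0),
                             mask_footprint = TRUE,
                             system = NULL, species = NULL, leaflet = NULL,
                             footprint_radius = NULL) {
  if (inherits(x, "density_map")) {
    sel_near <- x$radius > annulus_near[1] & x$radius <= annulus_near[2]
    sel_bulk <- x$radius > annulus_bulk[1] & x$radius <= annulus_bulk[2]
    if (mask_footprint) sel_near <- sel_near & !x$mask
    if (!any(sel_bulk)) stop("bulk annulus has no accessible cells")
    dens_near <- mean(x$grid[sel_near])
    dens_bulk <- mean(x$grid[sel_bulk])
    sp <- x$species; lf <- x$leaflet
  } else {
    traj <- x
    stopifnot(!is.null(system), !is.null(species), !is.null(leaflet))
    counts <- annulus_counts(traj, system, species, leaflet,
                             list(near = annulus_near, bulk = annulus_bulk))
    ca_idx <- protein_ca_index(system)
    ref_ca <- frame_coords(traj, ca_idx, 1L)
    if (is.null(footprint_radius))
      footprint_radius <- protein_footprint(ref_ca[, 1:2, drop = FALSE])$radius
    area_near <- pi * (annulus_near[2]^2 - annulus_near[1]^2)
    if (mask_footprint)
      area_near <- area_near -
        pi * (min(footprint_radius, annulus_near[2])^2 -
                max(annulus_near[1], min(footprint_radius, annulus_near[1]))^2)
    area_bulk <- pi * (annulus_bulk[2]^2 - annulus_bulk[1]^2)
    dens_near <- counts$near / (counts$n_frames * area_near)
    dens_bulk <- counts$bulk / (counts$n_frames * area_bulk)
    sp <- species; lf <- leaflet
  }
  flag <- NULL
  if (dens_bulk == 0) {
    flag <- "zero bulk density: S undefined"
    S <- NA_real_
  } else S <- dens_near / dens_bulk
  structure(list(S = S, species = sp, leaflet = lf,
                 annulus_near = annulus_near, annulus_bulk = annulus_bulk,
                 variant = "annulus", density_near = dens_near,
                 density_bulk = dens_bulk, flag = flag),
            class = "enrichment_result")
}

# Lateral protein footprint as the (approximate) minimal enclosing circle
# of the backbone beads, via the Badoiu-Clarkson iteration. More robust than
# (COM, max distance) when the backbone bead distribution is lopsided.
protein_footprint <- function(ca_xy) {
  c0 <- colMeans(ca_xy)
  for (k in seq_len(300)) {
    d2 <- (ca_xy[, 1] - c0[1])^2 + (ca_xy[, 2] - c0[2])^2
    i <- which.max(d2)
    c0 <- c0 + (ca_xy[i, ] - c0) / (k + 1)
  }
  list(center = c0,
       radius = sqrt(max((ca_xy[, 1] - c0[1])^2 + (ca_xy[, 2] - c0[2])^2)))
}

# Time-summed head-group counts in radial annuli around the protein COM.
annulus_counts <- function(traj, system, species, leaflet, annuli) {
  beads <- system$beads
  hg_idx <- headgroup_index(system, species)
  la <- assign_leaflets(get_frame(traj, 1L), system)
  keep_mol <- as.integer(names(la$leaflet)[la$leaflet == leaflet])
  hg_idx <- hg_idx[beads$molecule_id[hg_idx] %in% keep_mol]
  ca_idx <- protein_ca_index(system)
  com <- colMeans(frame_coords(traj, ca_idx, 1L))[1:2]
  out <- stats::setNames(numeric(length(annuli)), names(annuli))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    hg <- frame_coords(traj, hg_idx, f)[, 1:2, drop = FALSE]
    box <- traj$box[f, 1:2]
    d <- sweep(hg, 2L, com)
    d <- min_image(d, box)
    r <- sqrt(rowSums(d * d))
    for (nm in names(annuli))
      out[nm] <- out[nm] + sum(r > annuli[[nm]][1] & r <= annuli[[nm]][2])
  }
  c(as.list(out), list(n_frames = nf))
}

#' Site-local enrichment ratio
#'
#' Like \code{\link{enrichment_ratio}} but the numerator is the mean
#' head-group density inside the binding-site capture discs only (lateral
#' discs of \code{capture_radius} around each site anchor on the analyzed
#' leaflet), capturing the raised density at discrete sites that an annulus
#' average washes out.
#'
#' @param traj a \code{membrane_trajectory}.
#' @param system a \code{membrane_system}.
#' @param sites list of \code{site_definition} (only those on
#'   \code{leaflet} are used).
#' @param species lipid species.
#' @param leaflet leaflet to analyze.
#' @param capture_radius site disc radius (nm).
#' @param annulus_bulk bulk annulus (nm).
#' @return an \code{enrichment_result} with variant "site_local".
#' @export
site_local_enrichment <- function(traj, system, sites, species, leaflet,
                                  capture_radius = 0.8,
                                  annulus_bulk = c(3.5, 6.0)) {
  sites <- Filter(function(s) s$leaflet == leaflet, sites)
  if (!length(sites)) stop("no sites on the ", leaflet, " leaflet")
  beads <- system$beads
  hg_idx <- headgroup_index(system, species)
  la <- assign_leaflets(get_frame(traj, 1L), system)
  keep_mol <- as.integer(names(la$leaflet)[la$leaflet == leaflet])
  hg_idx <- hg_idx[beads$molecule_id[hg_idx] %in% keep_mol]
  ca_idx <- protein_ca_index(system)
  com <- colMeans(frame_coords(traj, ca_idx, 1L))[1:2]
  anchors <- lapply(sites, function(s) {
    idx <- site_anchor_bead_index(system, s)
    colMeans(traj$coords[idx, 1:2, 1L, drop = FALSE])
  })
  nf <- n_frames(traj)
  n_site <- 0; n_bulk <- 0
  for (f in seq_len(nf)) {
    hg <- frame_coords(traj, hg_idx, f)[, 1:2, drop = FALSE]
    box <- traj$box[f, 1:2]
    in_any <- rep(FALSE, nrow(hg))
    for (a in anchors) {
      d <- min_image(sweep(hg, 2L, a), box)
      in_any <- in_any | rowSums(d * d) <= capture_radius^2
    }
    n_site <- n_site + sum(in_any)
    db <- min_image(sweep(hg, 2L, com), box)
    r <- sqrt(rowSums(db * db))
    n_bulk <- n_bulk + sum(r > annulus_bulk[1] & r <= annulus_bulk[2])
  }
  # Disc areas may be clipped by the protein footprint; use the accessible
  # part (half-moon outside the footprint circle) when anchors sit on the rim.
  fp <- protein_footprint(frame_coords(traj, ca_idx, 1L)[, 1:2, drop = FALSE])
  area_site <- sum(vapply(anchors, function(a) {
    d0 <- sqrt(sum((a - fp$center)^2))
    disc_accessible_area(capture_radius, d0, fp$radius)
  }, numeric(1)))
  area_bulk <- pi * (annulus_bulk[2]^2 - annulus_bulk[1]^2)
  dens_site <- n_site / (nf * area_site)
  dens_bulk <- n_bulk / (nf * area_bulk)
  S <- if (dens_bulk > 0) dens_site / dens_bulk else NA_real_
  structure(list(S = S, species = species, leaflet = leaflet,
                 annulus_near = NULL, annulus_bulk = annulus_bulk,
                 variant = "site_local", density_near = dens_site,
                 density_bulk = dens_bulk,
                 flag = if (is.na(S)) "zero bulk density: S undefined"),
            class = "enrichment_result")
}

# Area of a disc of radius rc centered at distance d0 from the origin that
# lies OUTSIDE the circle of radius R (protein footprint). Standard
# two-circle intersection area.
disc_accessible_area <- function(rc, d0, R) {
  full <- pi * rc^2
  if (d0 >= R + rc) return(full)       # disjoint
  if (d0 <= abs(R - rc)) {             # one contains the other
    return(if (R >= rc) 0 else full - pi * R^2)
  }
  a1 <- rc^2 * acos((d0^2 + rc^2 - R^2) / (2 * d0 * rc))
  a2 <- R^2 * acos((d0^2 + R^2 - rc^2) / (2 * d0 * R))
  a3 <- 0.5 * sqrt((-d0 + rc + R) * (d0 + rc - R) * (d0 - rc + R) *
                     (d0 + rc + R))
  full - (a1 + a2 - a3)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment S = %.4g (%s, %s leaflet, %s variant)\n",
              x$S, x$species, x$leaflet, x$variant))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}
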