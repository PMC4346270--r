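#' Sphere-fitting pore-radius profile along the transport axis
#'
#' At each position z along the transport axis, the profile radius is the
#' radius of the largest sphere centered in that plane that touches no
#' protein bead: the objective f(x, y) = min over beads of
#' (|center - bead| - bead_radius) is maximized over the plane, starting
#' from the axis (or the previous plane's optimum, for channel continuity)
#' with a coarse 0.5 A grid followed by local refinement to better than
#' 0.05 A. Only beads within +/- 10 A (plus their own radius) of the plane
#' constrain it; full 3D distances are used. Radii are reported in Angstrom
#' and banded with the conventional open/closed thresholds: RED below
#' 1.15 A (closed), GREEN from 1.15 to 2.3 A (water-passable), BLUE above
#' 2.3 A.
#'
#' @param frame n_beads x 3 coordinates (nm) or a \code{get_frame} list.
#' @param system a \code{membrane_system} (protein beads must carry vdw
#'   radii).
#' @param axis_point point on the axis (nm, length 3); default = protein
#'   center of mass.
#' @param axis_direction axis direction (default +z).
#' @param z_range range along the axis (nm, relative to axis_point);
#'   default spans the protein.
#' @param step plane spacing in Angstrom.
#' @param search_radius max lateral distance of the center from the running
#'   seed, Angstrom.
#' @param slab half-thickness of the influence slab, Angstrom.
#' @return object of class \code{pore_profile}: data.frame (z_A, radius_A,
#'   x_A, y_A, band, flagged) with the banding thresholds in attributes.
#' @export
pore_profile <- function(frame, system, axis_point = NULL,
                         axis_direction = c(0, 0, 1), z_range = NULL,
                         step = 0.5, search_radius = 5, slab = 10) {
  pos_nm <- as_coord_matrix(frame, nrow(system$beads))
  prot <- system$beads$species == "PROTEIN"
  if (!any(prot)) stop("no protein beads")
  xyz <- pos_nm[prot, , drop = FALSE] * 10          # nm -> Angstrom
  radii <- system$beads$vdw_radius_A[prot]
  if (any(is.na(radii))) stop("protein beads lack vdw radii")
  # Rotate so the axis is +z.
  a <- axis_direction / sqrt(sum(axis_direction^2))
  R <- rotation_onto_z(a)
  xyz <- xyz %*% t(R)
  origin <- if (is.null(axis_point)) colMeans(xyz) else
    as.numeric(R %*% (axis_point * 10))
  xyz <- sweep(xyz, 2L, origin)
  if (is.null(z_range)) z_range <- range(xyz[, 3]) / 10  # back to nm
  zs <- seq(z_range[1] * 10, z_range[2] * 10, by = step)
  n <- length(zs)
  radius <- numeric(n); cx <- numeric(n); cy <- numeric(n)
  flagged <- logical(n)
  seed <- c(0, 0)
  objective <- function(x, y, z, sub, sub_r) {
    d <- sqrt((sub[, 1] - x)^2 + (sub[, 2] - y)^2 + (sub[, 3] - z)^2)
    min(d - sub_r)
  }
  for (i in seq_len(n)) {
    z <- zs[i]
    in_slab <- abs(xyz[, 3] - z) <= slab + radii
    if (!any(in_slab)) {
      radius[i] <- search_radius
      cx[i] <- seed[1]; cy[i] <- seed[2]
      flagged[i] <- TRUE
      next
    }
    sub <- xyz[in_slab, , drop = FALSE]; sub_r <- radii[in_slab]
    g <- seq(-search_radius, search_radius, by = 0.5)
    best <- c(seed, objective(seed[1], seed[2], z, sub, sub_r))
    for (gx in g) for (gy in g) {
      if (gx * gx + gy * gy > search_radius^2) next
      v <- objective(seed[1] + gx, seed[2] + gy, z, sub, sub_r)
      if (v > best[3]) best <- c(seed[1] + gx, seed[2] + gy, v)
    }
    # refinement stays inside the search disc around the running seed
    opt <- stats::optim(best[1:2], function(p) {
      if ((p[1] - seed[1])^2 + (p[2] - seed[2])^2 > search_radius^2)
        return(1e9)
      -objective(p[1], p[2], z, sub, sub_r)
    }, method = "Nelder-Mead",
       control = list(reltol = 1e-10, maxit = 400))
    if (-opt$value >= best[3]) best <- c(opt$par, -opt$value)
    radius[i] <- best[3]
    cx[i] <- best[1]; cy[i] <- best[2]
    seed <- best[1:2]
  }
  band <- pore_band(radius)
  out <- data.frame(z_A = zs, radius_A = radius, x_A = cx, y_A = cy,
                    band = band, flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds_A") <- c(closed = 1.15, open = 2.3)
  attr(out, "min_radius_A") <- min(radius)
  attr(out, "min_z_A") <- zs[which.min(radius)]
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' Band label for a pore radius
#'
#' RED below 1.15 A (occluded), GREEN from 1.15 A up to and including
#' 2.3 A, BLUE above 2.3 A; negative (fully occluded) radii are clamped to
#' zero first. The boundaries are read strictly: exactly 1.15 A is GREEN,
#' exactly 2.3 A is GREEN.
#'
#' @param radius_A numeric vector of radii in Angstrom.
#' @return character vector of band labels.
#' @export
pore_band <- function(radius_A) {
  clamped <- pmax(radius_A, 0)
  ifelse(clamped < 1.15, "RED", ifelse(clamped <= 2.3, "GREEN", "BLUE"))
}

# Rotation matrix taking unit vector a onto +z (Rodrigues).
rotation_onto_z <- function(a) {
  z <- c(0, 0, 1)
  v <- c(a[2] * z[3] - a[3] * z[2], a[3] * z[1] - a[1] * z[3],
         a[1] * z[2] - a[2] * z[1])
  c_ <- sum(a * z)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))          # antiparallel: flip about x
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Is the pore closed over a z window?
#'
#' Closed means the minimum profile radius in the window falls strictly
#' below the 1.15 A occlusion threshold (a plane at exactly 1.15 A is not
#' closed).
#'
#' @param profile a \code{pore_profile}.
#' @param z_window window along the axis in Angstrom (default: whole
#'   profile).
#' @return list(closed, min_radius_A, z_at_min_A).
#' @export
pore_is_closed <- function(profile, z_window = NULL) {
  if (is.null(z_window)) z_window <- range(profile$z_A)
  sel <- profile$z_A >= z_window[1] & profile$z_A <= z_window[2]
  if (!any(sel)) stop("empty z window")
  r <- pmax(profile$radius_A[sel], 0)
  m <- min(r)
  list(closed = m < 1.15, min_radius_A = m,
       z_at_min_A = profile$z_A[sel][which.min(r)])
}
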