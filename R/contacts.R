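#' Contact-analysis configuration
#'
#' Per-species contact cutoffs and the sampling rule. Defaults follow the
#' standard coarse-grained practice for these lipids: 0.7 nm for POPE/POPG,
#' 0.8 nm for cardiolipin at residue level (its head group is larger), and
#' 1.1 nm for cardiolipin site-level occupancy (which must also tolerate the
#' rattling-in-a-cage motion of a bound CL). Trajectories are resampled to
#' the stated interval by nearest-frame selection; no smoothing is ever
#' applied, so fast binding/unbinding events are preserved.
#'
#' @param delta named per-species residue-contact cutoffs (nm).
#' @param delta_site named per-species site-occupancy cutoffs (nm).
#' @param interval sampling interval (ns).
#' @return object of class \code{contact_config}.
#' @export
contact_config <- function(delta = c(POPE = 0.7, POPG = 0.7, CL = 0.8,
                                     POPC = 0.7),
                           delta_site = c(POPE = 0.7, POPG = 0.7, CL = 1.1,
                                          POPC = 0.7),
                           interval = 0.3) {
  if (any(delta <= 0) || any(delta_site <= 0) || interval <= 0)
    stop("cutoffs and interval must be positive")
  structure(list(delta = delta, delta_site = delta_site, interval = interval,
                 smoothing = "none"),
            class = "contact_config")
}

species_delta <- function(config, species, site = FALSE) {
  tab <- if (site) config$delta_site else config$delta
  if (is.na(tab[species]))
    stop("no cutoff configured for species ", species)
  unname(tab[species])
}

#' Define a binding site by two anchor residues
#'
#' @param site_id integer id.
#' @param leaflet "INNER" or "OUTER".
#' @param anchor_residues integer pair of PROTEIN residue_ids (e.g. the
#'   arginine pair of a cardiolipin site).
#' @return object of class \code{site_definition}.
#' @export
site_definition <- function(site_id, leaflet, anchor_residues) {
  stopifnot(length(anchor_residues) == 2L, leaflet %in% c("INNER", "OUTER"))
  structure(list(site_id = as.integer(site_id), leaflet = leaflet,
                 anchor_residues = as.integer(anchor_residues)),
            class = "site_definition")
}

#' Site definitions carried by a synthetic ground truth
#' @param truth the \code{truth} element returned by
#'   \code{\link{generate_membrane}}.
#' @return list of \code{site_definition}.
#' @export
sites_from_truth <- function(truth) {
  lapply(truth$params$sites, function(s) {
    lab <- s$anchor_labels
    site_definition(s$site_id, s$leaflet, lab$residue_id)
  })
}

site_anchor_bead_index <- function(system, site) {
  idx <- which(system$beads$species == "PROTEIN" &
                 system$beads$residue_id %in% site$anchor_residues)
  if (!length(idx))
    stop("anchor residues ", paste(site$anchor_residues, collapse = ","),
         " not found among PROTEIN residues")
  idx
}

#' Site occupancy series
#'
#' For each sampled frame, the site-to-lipid distance d(t) is the minimum
#' (minimum-image) distance between any bead of the two anchor residues and
#' any head-group bead of the species; the occupancy indicator is
#' zeta(t) = 1 when d(t) <= delta and 0 otherwise (the boundary d = delta
#' counts as contact). The occupant set holds the molecule_ids of every
#' lipid of the species with a head-group bead within delta.
#'
#' @param traj a \code{membrane_trajectory}.
#' @param system a \code{membrane_system}.
#' @param site a \code{site_definition}.
#' @param species lipid species name.
#' @param config a \code{contact_config}; the site-level cutoff
#'   \code{delta_site[species]} is used unless \code{delta} is given.
#' @param delta optional explicit cutoff (nm) overriding the config.
#' @return object of class \code{occupancy_series}: list with \code{time},
#'   \code{d} (nm), \code{zeta} (0/1), \code{occupants} (list of
#'   molecule_id vectors), \code{site}, \code{species}, \code{delta},
#'   \code{interval}.
#' @export
occupancy_series <- function(traj, system, site, species, config = contact_config(),
                             delta = NULL) {
  if (!species %in% system$beads$species)
    stop("species ", species, " absent from system")
  if (is.null(delta)) delta <- species_delta(config, species, site = TRUE)
  traj <- resample_trajectory(traj, config$interval)
  anchor_idx <- site_anchor_bead_index(system, site)
  hg_idx <- headgroup_index(system, species)
  if (!length(hg_idx))
    stop("species ", species, " has no HEADGROUP beads")
  hg_mol <- system$beads$molecule_id[hg_idx]
  nf <- n_frames(traj)
  n_hg <- length(hg_idx)
  # Vectorized over frames: squared min-image distance of every head-group
  # bead to the nearest anchor bead, as an n_hg x nf matrix.
  d2min <- matrix(Inf, n_hg, nf)
  for (a in anchor_idx) {
    acc <- matrix(0, n_hg, nf)
    for (k in 1:3) {
      dk <- matrix(traj$coords[hg_idx, k, ], nrow = n_hg) -
        matrix(traj$coords[a, k, ], nrow = n_hg, ncol = nf, byrow = TRUE)
      Bk <- matrix(traj$box[, k], nrow = n_hg, ncol = nf, byrow = TRUE)
      dk <- dk - Bk * round(dk / Bk)
      acc <- acc + dk * dk
    }
    d2min <- pmin(d2min, acc)
  }
  mols <- unique(hg_mol)
  mol_min <- matrix(Inf, length(mols), nf)
  for (i in seq_along(mols)) {
    rows <- which(hg_mol == mols[i])
    mol_min[i, ] <- if (length(rows) == 1L) d2min[rows, ] else
      do.call(pmin, asplit(d2min[rows, , drop = FALSE], 1L))
  }
  d <- as.vector(sqrt(do.call(pmin, asplit(mol_min, 1L))))
  occm <- mol_min <= delta^2
  zeta <- as.integer(colSums(occm) > 0L)
  occupants <- lapply(seq_len(nf), function(f) mols[occm[, f]])
  structure(list(time = traj$times, d = d, zeta = zeta, occupants = occupants,
                 site = site, species = species, delta = delta,
                 interval = if (nf > 1L) traj$interval else NA_real_),
            class = "occupancy_series")
}

#' Per-residue contact profile
#'
#' Raw contact count of a (protein residue, species) pair: over all sampled
#' frames, the number of lipids of the species whose nearest head-group bead
#' lies within the species cutoff of any bead of the residue, each lipid
#' counted at most once per residue per frame. Two normalizations are
#' offered: \code{per_lipid_frame_volume} divides by the number of lipids of
#' the species, the number of frames, and the ratio of cutoff volumes
#' \code{(delta_species/delta_ref)^3} (so species with a larger cutoff are
#' not overcounted); \code{max_residue} divides by the largest raw count the
#' species makes with any residue, so the most-contacted residue scores
#' exactly 1 and residues with no contacts score 0.
#'
#' @param traj a \code{membrane_trajectory}.
#' @param system a \code{membrane_system}.
#' @param config a \code{contact_config}.
#' @param mode "per_lipid_frame_volume" or "max_residue".
#' @param species species to profile (default: lipid species present).
#' @param delta_ref reference cutoff (nm) for the volume ratio.
#' @return data.frame (residue_id, residue_name, species, raw, normalized,
#'   mode).
#' @export
residue_contact_profile <- function(traj, system, config = contact_config(),
                                    mode = c("per_lipid_frame_volume",
                                             "max_residue"),
                                    species = NULL, delta_ref = 0.7) {
  mode <- match.arg(mode)
  traj <- resample_trajectory(traj, config$interval)
  nf <- n_frames(traj)
  if (nf == 0L) stop("trajectory has zero frames")
  beads <- system$beads
  prot_idx <- which(beads$species == "PROTEIN")
  if (!length(prot_idx)) stop("no PROTEIN beads in system")
  res_ids <- unique(beads$residue_id[prot_idx])
  if (is.null(species))
    species <- intersect(LIPID_SPECIES, unique(beads$species))
  out <- list()
  for (sp in species) {
    dlt <- species_delta(config, sp)
    hg_idx <- headgroup_index(system, sp)
    hg_mol <- beads$molecule_id[hg_idx]
    n_lip <- length(unique(hg_mol))
    raw <- stats::setNames(numeric(length(res_ids)), res_ids)
    if (n_lip > 0L) {
      for (f in seq_len(nf)) {
        box <- traj$box[f, ]
        hg <- frame_coords(traj, hg_idx, f)
        for (r in seq_along(res_ids)) {
          ridx <- prot_idx[beads$residue_id[prot_idx] == res_ids[r]]
          dmin <- rep(Inf, length(hg_idx))
          for (a in ridx)
            dmin <- pmin(dmin, min_image_dist(traj$coords[a, , f], hg, box))
          mol_min <- tapply(dmin, hg_mol, min)
          raw[r] <- raw[r] + sum(mol_min <= dlt)
        }
      }
    }
    norm <- switch(mode,
      per_lipid_frame_volume =
        raw / (max(n_lip, 1L) * nf * (dlt / delta_ref)^3),
      max_residue = if (max(raw) > 0) raw / max(raw) else raw)
    rn <- beads$residue_name[match(res_ids, beads$residue_id)]
    out[[sp]] <- data.frame(residue_id = res_ids, residue_name = rn,
                            species = sp, raw = unname(raw),
                            normalized = unname(norm), mode = mode,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Lipids in contact with the protein, per frame
#'
#' A lipid counts as in contact in a frame when any of its head-group beads
#' lies within the species cutoff of any protein bead; each lipid counts
#' once per frame however many beads touch.
#'
#' @param traj a \code{membrane_trajectory}.
#' @param system a \code{membrane_system}.
#' @param config a \code{contact_config}.
#' @param species species to count (default: lipid species present).
#' @return list with \code{counts} (data.frame frame x species),
#'   \code{time}, and \code{mean} (named time-average per species).
#' @export
lipids_in_contact <- function(traj, system, config = contact_config(),
                              species = NULL) {
  traj <- resample_trajectory(traj, config$interval)
  beads <- system$beads
  prot_idx <- which(beads$species == "PROTEIN")
  if (is.null(species))
    species <- intersect(LIPID_SPECIES, unique(beads$species))
  nf <- n_frames(traj)
  counts <- matrix(0L, nf, length(species),
                   dimnames = list(NULL, species))
  for (sp in species) {
    hg_idx <- headgroup_index(system, sp)
    if (!length(hg_idx) || !length(prot_idx)) next
    dlt <- species_delta(config, sp)
    hg_mol <- beads$molecule_id[hg_idx]
    for (f in seq_len(nf)) {
      box <- traj$box[f, ]
      hg <- frame_coords(traj, hg_idx, f)
      dmin <- rep(Inf, length(hg_idx))
      for (a in prot_idx)
        dmin <- pmin(dmin, min_image_dist(traj$coords[a, , f], hg, box))
      touched <- tapply(dmin, hg_mol, min) <= dlt
      counts[f, sp] <- sum(touched)
    }
  }
  counts <- as.data.frame(counts)
  list(counts = counts, time = traj$times, mean = colMeans(counts))
}
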