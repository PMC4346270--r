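# Fixture builders and independent oracles shared across the suite.

# Minimal bead table row constructor.
bead_row <- function(id, name, resid, resname, mol, species, roles,
                     r = 2.3) {
  data.frame(bead_id = id, name = name, residue_id = resid,
             residue_name = resname, molecule_id = mol, species = species,
             roles = roles, vdw_radius_A = r, stringsAsFactors = FALSE)
}

# A system with one point-like binding site (two co-located anchor residues
# at `anchor`) and `n_lip` single-bead lipids of one species.
site_system <- function(anchor = c(0, 5, 1), n_lip = 1, species = "POPE",
                        box = c(10, 10, 5)) {
  beads <- rbind(
    bead_row(1L, "BB", 4L, "ARG", 1L, "PROTEIN", "BACKBONE_CA"),
    bead_row(2L, "BB", 299L, "ARG", 1L, "PROTEIN", "BACKBONE_CA"),
    do.call(rbind, lapply(seq_len(n_lip), function(i)
      bead_row(2L + i, "PO4", 1000L + i, species, 1L + i, species,
               "HEADGROUP"))))
  sys <- membrane_system(beads, box)
  sys$positions <- rbind(matrix(rep(anchor, 2), 2, 3, byrow = TRUE),
                         matrix(rep(anchor, n_lip), n_lip, 3, byrow = TRUE))
  sys
}

# Trajectory in which lipid 1 of a site_system sits at the given distances
# (along +x) from the anchor; other lipids stay far away at `park`.
distance_trajectory <- function(sys, distances, anchor = c(0, 5, 1),
                                interval = 0.3, park = c(5, 9, 1)) {
  nb <- nrow(sys$beads)
  nf <- length(distances)
  co <- array(0, c(nb, 3, nf))
  for (f in seq_len(nf)) {
    pos <- sys$positions
    pos[3, ] <- anchor + c(distances[f], 0, 0)
    if (nb > 3L) pos[4:nb, ] <- matrix(rep(park, nb - 3L), ncol = 3,
                                       byrow = TRUE)
    co[, , f] <- pos
  }
  membrane_trajectory(seq(0, by = interval, length.out = nf), co, sys$box)
}

# Independent minimum-image distance (coded separately from the package).
oracle_dist <- function(a, b, box) {
  d <- abs(a - b)
  d <- pmin(d %% box, box - d %% box)
  sqrt(sum(d^2))
}

# All-pairs brute-force lipids-in-contact count for one frame.
oracle_lipids_in_contact <- function(pos, sys, delta_by_species) {
  beads <- sys$beads
  prot <- which(beads$species == "PROTEIN")
  out <- integer(0)
  for (sp in unique(beads$species[beads$species %in%
                                    c("POPE", "POPG", "CL", "POPC")])) {
    hg <- which(beads$species == sp & grepl("HEADGROUP", beads$roles))
    n <- 0L
    for (m in unique(beads$molecule_id[hg])) {
      mine <- hg[beads$molecule_id[hg] == m]
      touch <- FALSE
      for (i in mine) for (j in prot)
        if (oracle_dist(pos[i, ], pos[j, ], sys$box) <= delta_by_species[sp])
          touch <- TRUE
      n <- n + touch
    }
    out[sp] <- n
  }
  out
}

# Brute-force per-residue raw contact counts for one species over a
# trajectory.
oracle_residue_raw <- function(traj, sys, sp, delta) {
  beads <- sys$beads
  prot <- which(beads$species == "PROTEIN")
  res_ids <- unique(beads$residue_id[prot])
  hg <- which(beads$species == sp & grepl("HEADGROUP", beads$roles))
  raw <- setNames(numeric(length(res_ids)), res_ids)
  for (f in seq_len(n_frames(traj))) {
    pos <- traj$coords[, , f]
    for (r in seq_along(res_ids)) {
      ridx <- prot[beads$residue_id[prot] == res_ids[r]]
      for (m in unique(beads$molecule_id[hg])) {
        mine <- hg[beads$molecule_id[hg] == m]
        dmin <- Inf
        for (i in mine) for (j in ridx)
          dmin <- min(dmin, oracle_dist(pos[i, ], pos[j, ], traj$box[f, ]))
        if (dmin <= delta) raw[r] <- raw[r] + 1
      }
    }
  }
  raw
}

# Exhaustive single-lipid exchange oracle, per the counting rule: keep only
# single-occupant samples, count identity changes between consecutive kept
# samples; fraction = kept / occupied.
oracle_exchanges <- function(occ_seq) {
  ids <- integer(0)
  occupied <- 0L
  for (s in occ_seq) {
    if (length(s) > 0L) occupied <- occupied + 1L
    if (length(s) == 1L) ids <- c(ids, s)
  }
  ex <- 0L
  if (length(ids) > 1L)
    for (i in 2:length(ids)) if (ids[i] != ids[i - 1L]) ex <- ex + 1L
  list(exchanges = ex,
       single_fraction = if (occupied) length(ids) / occupied else NA_real_)
}

random_occupant_seq <- function(len, n_ids = 3L) {
  lapply(seq_len(len), function(i) {
    k <- sample(0:2, 1L, prob = c(0.3, 0.5, 0.2))
    sort(sample.int(n_ids, k))
  })
}

# Brute-force rigid superposition RMSD: random rotation search plus local
# refinement over the rotation vector (independent of the SVD path).
oracle_rmsd <- function(mobile, reference, n_random = 20000L) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rotvec_to_R <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    a <- v / th
    K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  f <- function(v) {
    R <- rotvec_to_R(v)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- c(0, 0, 0); best_val <- f(best)
  for (i in seq_len(n_random)) {
    v <- stats::runif(3, -pi, pi)
    val <- f(v)
    if (val < best_val) { best <- v; best_val <- val }
  }
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  opt$value
}

# Toy 6-bead GRO fixture + matching annotation CSV; returns the two paths.
write_toy_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  gro <- file.path(dir, "toy.gro")
  ann <- file.path(dir, "toy.csv")
  lines <- c(
    "toy membrane", "    6",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 4L, "ARG", "BB", 1L, 1.0, 1.0, 1.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 299L, "ARG", "BB", 2L, 1.5, 1.0, 1.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1001L, "POPE", "PO4", 3L, 3.0, 3.0, 2.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1001L, "POPE", "C1A", 4L, 3.0, 3.0, 1.5),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1002L, "CL", "PO1", 5L, 5.0, 5.0, 2.0),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1002L, "CL", "PO2", 6L, 5.2, 5.0, 2.0),
    sprintf("%10.5f%10.5f%10.5f", 10, 10, 5))
  writeLines(lines, gro)
  writeLines(c("residue_name,bead_name,species,roles,vdw_radius_A",
               "ARG,BB,PROTEIN,BACKBONE_CA,2.3",
               "POPE,PO4,POPE,HEADGROUP,2.3",
               "POPE,C1A,POPE,TAIL,2.3",
               "CL,PO1,CL,HEADGROUP,2.3",
               "CL,PO2,CL,HEADGROUP,2.3"), ann)
  list(gro = gro, ann = ann)
}

# Contiguous frame slice of a trajectory (for block averaging).
slice_traj <- function(traj, idx) {
  membrane_trajectory(traj$times[idx], traj$coords[, , idx, drop = FALSE],
                      traj$box[idx, , drop = FALSE])
}

# Ring-of-beads system for pore fixtures (radius and bead radius in nm/A).
ring_system <- function(ring_radius_A = 5, bead_radius_A = 2, n = 24,
                        center = c(2, 2, 2), box = c(4, 4, 4)) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  beads <- do.call(rbind, lapply(seq_len(n), function(i)
    bead_row(i, "BB", i, "GLY", 1L, "PROTEIN", "BACKBONE_CA",
             r = bead_radius_A)))
  sys <- membrane_system(beads, box)
  sys$positions <- cbind(center[1] + ring_radius_A / 10 * cos(ang),
                         center[2] + ring_radius_A / 10 * sin(ang),
                         center[3])
  sys
}
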