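#' Parameters for the synthetic bilayer generator
#'
#' The generator emulates a three-species bilayer (a zwitterionic majority
#' lipid plus two anionic species, one of them the bulky doubly charged
#' cardiolipin) diffusing laterally around a static transmembrane protein
#' rendered as a disc, with discrete sticky binding sites on the rim. The
#' defaults are a reduced-scale bacterial inner-membrane mimic: a 14 x 14 nm
#' box, 75/20/5 % POPE/POPG/CL per leaflet (400 lipids total), protein-free
#' lateral diffusion constants of 6.2, 5.9 and 4.5 x 1e-7 cm^2/s, two
#' cytosolic (INNER) sites and one periplasmic (OUTER) site whose mean
#' cardiolipin residences order site 1 > site 2 > site 3, and a shallow
#' annular well that enriches the anionic species and depletes the
#' zwitterionic one.
#'
#' @param box_xy lateral box lengths (Lx, Ly) in nm.
#' @param leaflet_z leaflet plane offset z0 (nm); head groups sit at -z0
#'   (INNER) and +z0 (OUTER).
#' @param protein_radius protein disc radius R_p (nm), centered in the box.
#' @param counts named list \code{list(INNER = c(...), OUTER = c(...))} of
#'   per-species lipid counts per leaflet.
#' @param D named per-species free diffusion constants (cm^2/s).
#' @param dt time step (ns).
#' @param n_steps number of dynamics steps.
#' @param record_every record a frame every this many steps (frame 1 is the
#'   initial state at t = 0).
#' @param sites list of binding sites; each a list with \code{site_id},
#'   \code{leaflet} ("INNER"/"OUTER"), \code{angle} (anchor angle on the
#'   protein rim, radians), \code{r_c} (capture radius, nm), \code{tau}
#'   (named per-species mean residence, ns), \code{p_on} (named per-species
#'   capture probability per step), and optionally \code{anchor_labels}, a
#'   2-row data.frame (residue_id, residue_name) naming the two rim residues
#'   that carry the site.
#' @param well list \code{(inner, outer, eps)}: annulus radii (nm) and well
#'   depth in kT. \code{eps} may be a single number (applied to every
#'   species) or a named per-species vector; positive values attract.
#' @param seed integer RNG seed; the whole run is deterministic given it.
#' @return object of class \code{synth_params}.
#' @export
synth_params <- function(box_xy = c(14, 14),
                         leaflet_z = 2.0,
                         protein_radius = 2.0,
                         counts = list(INNER = c(POPE = 150, POPG = 40, CL = 10),
                                       OUTER = c(POPE = 150, POPG = 40, CL = 10)),
                         D = c(POPE = 6.2e-7, POPG = 5.9e-7, CL = 4.5e-7),
                         dt = 0.3,
                         n_steps = 5000,
                         record_every = 1,
                         sites = default_sites(),
                         well = list(inner = protein_radius, outer = 3.0,
                                     eps = c(POPE = -0.35, POPG = 0.25,
                                             CL = 0.15)),
                         seed = 1L) {
  p <- list(box_xy = as.numeric(box_xy), leaflet_z = leaflet_z,
            protein_radius = protein_radius, counts = counts, D = D, dt = dt,
            n_steps = as.integer(n_steps),
            record_every = as.integer(record_every), sites = sites,
            well = well, seed = as.integer(seed))
  class(p) <- "synth_params"
  validate_synth_params(p)
  p
}

default_sites <- function() {
  lab <- function(id, nm) data.frame(residue_id = id, residue_name = nm,
                                     stringsAsFactors = FALSE)
  list(
    list(site_id = 1L, leaflet = "INNER", angle = 0, r_c = 0.8,
         tau = c(POPE = 10, POPG = 30, CL = 300),
         p_on = c(POPE = 0.05, POPG = 0.15, CL = 0.3),
         anchor_labels = lab(c(4L, 299L), c("ARG", "ARG"))),
    list(site_id = 2L, leaflet = "INNER", angle = 2 * pi / 3, r_c = 0.8,
         tau = c(POPE = 8, POPG = 25, CL = 200),
         p_on = c(POPE = 0.05, POPG = 0.15, CL = 0.3),
         anchor_labels = lab(c(109L, 265L), c("LYS", "ARG"))),
    list(site_id = 3L, leaflet = "OUTER", angle = 4 * pi / 3, r_c = 0.8,
         tau = c(POPE = 6, POPG = 20, CL = 120),
         p_on = c(POPE = 0.05, POPG = 0.15, CL = 0.3),
         anchor_labels = lab(c(321L, 212L), c("LYS", "TRP"))))
}

validate_synth_params <- function(p) {
  if (p$protein_radius >= min(p$box_xy) / 2)
    stop("protein_radius must be smaller than half the box")
  if (p$dt <= 0 || p$n_steps < 1 || p$record_every < 1)
    stop("dt, n_steps and record_every must be positive")
  species <- names(p$D)
  for (lf in c("INNER", "OUTER")) {
    cs <- p$counts[[lf]]
    if (is.null(cs)) stop("counts must have INNER and OUTER entries")
    if (!all(names(cs) %in% species))
      stop("counts name species without a diffusion constant")
  }
  for (s in p$sites) {
    if (!s$leaflet %in% c("INNER", "OUTER")) stop("site leaflet invalid")
    if (any(s$tau <= 0)) stop("site residence times tau must be > 0")
    if (any(s$p_on < 0 | s$p_on > 1)) stop("p_on must lie in [0, 1]")
    if (s$r_c <= 0) stop("capture radius must be > 0")
  }
  eps <- well_eps(p, species)
  if (p$well$inner < 0 || p$well$outer <= p$well$inner)
    stop("well radii must satisfy 0 <= inner < outer")
  invisible(p)
}

# Per-species well depth vector (a scalar eps applies to every species).
well_eps <- function(p, species) {
  eps <- p$well$eps
  if (length(eps) == 1L && is.null(names(eps)))
    eps <- stats::setNames(rep(as.numeric(eps), length(species)), species)
  miss <- setdiff(species, names(eps))
  if (length(miss)) stop("well eps missing species: ", paste(miss, collapse = ", "))
  eps[species]
}

#' Disable binding sites (the in-silico mutant mimic)
#'
#' Mutating away the basic anchor residues of a site abolishes capture; the
#' generator's analogue sets the site's per-species capture probabilities to
#' zero and leaves everything else (geometry, seed, other sites) unchanged.
#'
#' @param params a \code{synth_params}.
#' @param site_ids integer ids of sites to knock out (may be empty).
#' @return modified \code{synth_params}.
#' @export
knockout_sites <- function(params, site_ids) {
  if (!length(site_ids)) return(params)
  have <- vapply(params$sites, `[[`, integer(1), "site_id")
  unknown <- setdiff(site_ids, have)
  if (length(unknown))
    stop("unknown site_id(s): ", paste(unknown, collapse = ", "))
  for (i in seq_along(params$sites))
    if (have[i] %in% site_ids)
      params$sites[[i]]$p_on[] <- 0
  params
}

# Build the static protein + lipid bead roster for a parameter set.
synth_system <- function(p) {
  L <- p$box_xy
  z0 <- p$leaflet_z
  cx <- L[1] / 2; cy <- L[2] / 2
  n_ring <- 12L
  zoff <- 1 + z0            # bilayer midplane height; 1 nm solvent pad below
  ring_z <- c(-z0, 0, z0)
  ang <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  prot <- data.frame(
    name = "BB",
    residue_id = 500L + seq_len(n_ring * length(ring_z)),
    residue_name = "GLY",
    x = rep(cx + p$protein_radius * cos(ang), length(ring_z)),
    y = rep(cy + p$protein_radius * sin(ang), length(ring_z)),
    z = zoff + rep(ring_z, each = n_ring),
    stringsAsFactors = FALSE)
  # Two co-located rim residues per site carry the site's labels; placing
  # them exactly at the anchor point makes the two-residue site
  # representation coincide with the generator's capture geometry.
  for (s in p$sites) {
    lz <- zoff + if (s$leaflet == "OUTER") z0 else -z0
    lab <- s$anchor_labels
    if (is.null(lab))
      lab <- data.frame(residue_id = 900L + 2L * s$site_id + 0:1,
                        residue_name = c("ARG", "ARG"))
    prot <- rbind(prot, data.frame(
      name = "BB", residue_id = lab$residue_id,
      residue_name = lab$residue_name,
      x = cx + p$protein_radius * cos(s$angle),
      y = cy + p$protein_radius * sin(s$angle),
      z = lz, stringsAsFactors = FALSE))
  }
  species <- names(p$D)
  lip <- do.call(rbind, lapply(c("INNER", "OUTER"), function(lf) {
    cs <- p$counts[[lf]]
    cs <- cs[cs > 0]
    if (!length(cs)) return(NULL)
    data.frame(species = rep(names(cs), cs), leaflet = lf,
               stringsAsFactors = FALSE)
  }))
  n_prot <- nrow(prot)
  n_lip <- if (is.null(lip)) 0L else nrow(lip)
  beads <- data.frame(
    bead_id = seq_len(n_prot + n_lip),
    name = c(prot$name, rep("PO4", n_lip)),
    residue_id = c(prot$residue_id, 1000L + seq_len(n_lip)),
    residue_name = c(prot$residue_name, lip$species),
    molecule_id = c(rep(1L, n_prot), 1L + seq_len(n_lip)),
    species = c(rep("PROTEIN", n_prot), lip$species),
    roles = c(rep("BACKBONE_CA", n_prot), rep("HEADGROUP", n_lip)),
    vdw_radius_A = 2.3,
    stringsAsFactors = FALSE)
  list(beads = beads, prot_xyz = cbind(prot$x, prot$y, prot$z),
       lip_species = lip$species, lip_leaflet = lip$leaflet)
}

#' Generate a ground-truth synthetic membrane trajectory
#'
#' Each lipid is a single head-group bead confined to its leaflet plane.
#' Unbound lipids take Metropolis-adjusted Brownian steps: a Gaussian
#' displacement with variance 2*D*dt per axis is proposed, rejected if it
#' enters the protein disc, and otherwise accepted with probability
#' min(1, exp(-dU)) against the annular well potential u(r) = -eps inside
#' the well annulus and 0 outside, then wrapped periodically. Because the
#' dynamics satisfy detailed balance, the long-run lateral density obeys the
#' Boltzmann ratio exp(eps) inside the well, which the enrichment estimators
#' must recover. An unbound lipid within the capture radius of a free site
#' on its leaflet binds with probability p_on per step; while bound it
#' rattles in the cage (position resampled uniformly within r_c of the
#' anchor each step) and escapes each step with probability 1 - exp(-dt/tau),
#' upon which it is relocated uniformly into the r_c..2*r_c shell around the
#' anchor so that a fresh capture requires a fresh approach. A site holds at
#' most one lipid at a time. Initial lipid positions are drawn directly from
#' the single-lipid equilibrium density, so no burn-in is needed for
#' density-based estimators.
#'
#' @param params a \code{synth_params}.
#' @return list with \code{system} (a \code{membrane_system}),
#'   \code{trajectory} (a \code{membrane_trajectory}; recorded every
#'   \code{record_every} steps) and \code{truth}, a ground-truth list:
#'   the params, site anchor coordinates, per-species expected well density
#'   ratio exp(eps), per-site/species tau, per-species D, the true leaflet of
#'   every lipid molecule and the complete log of binding events
#'   (\code{t_off} is \code{NA} for events still open at the end).
#' @export
generate_membrane <- function(params) {
  p <- validate_synth_params(params)
  set.seed(p$seed)
  L <- p$box_xy
  cx <- L[1] / 2; cy <- L[2] / 2
  z0 <- p$leaflet_z
  sys0 <- synth_system(p)
  species <- names(p$D)
  eps_sp <- well_eps(p, species)
  sp_idx <- match(sys0$lip_species, species)
  n <- length(sp_idx)
  if (n == 0L) stop("no lipids requested")
  lf <- sys0$lip_leaflet
  # nm^2/ns from cm^2/s
  D_nm <- p$D * 1e5
  sigma <- sqrt(2 * D_nm[sp_idx] * p$dt)
  eps <- eps_sp[sp_idx]
  w_in <- p$well$inner; w_out <- p$well$outer
  Rp <- p$protein_radius

  # Site geometry/kinetics tables.
  ns <- length(p$sites)
  site_xy <- matrix(0, max(ns, 1L), 2L)
  site_lf <- character(max(ns, 1L))
  site_rc <- numeric(max(ns, 1L))
  tau_m <- matrix(Inf, max(ns, 1L), length(species),
                  dimnames = list(NULL, species))
  pon_m <- matrix(0, max(ns, 1L), length(species),
                  dimnames = list(NULL, species))
  for (k in seq_len(ns)) {
    s <- p$sites[[k]]
    site_xy[k, ] <- c(cx + Rp * cos(s$angle), cy + Rp * sin(s$angle))
    site_lf[k] <- s$leaflet
    site_rc[k] <- s$r_c
    tau_m[k, names(s$tau)] <- s$tau
    pon_m[k, names(s$p_on)] <- s$p_on
  }

  # Area check: can the lipids be placed without (disc) overlap at all?
  acc_area <- prod(L) - pi * Rp^2
  per_leaf <- table(factor(lf, c("INNER", "OUTER")))
  if (any(per_leaf * 0.2 > acc_area))  # ~0.2 nm^2 minimal footprint
    stop("lipid count too large to place in the accessible area")

  # Equilibrium initial positions: rejection sampling against exp(eps).
  x <- numeric(n); y <- numeric(n)
  todo <- seq_len(n)
  wmax <- pmax(1, exp(eps))
  while (length(todo)) {
    xt <- stats::runif(length(todo), 0, L[1])
    yt <- stats::runif(length(todo), 0, L[2])
    r <- sqrt((xt - cx)^2 + (yt - cy)^2)
    w <- exp(eps[todo] * (r > w_in & r <= w_out)) / wmax[todo]
    ok <- r >= Rp & stats::runif(length(todo)) < w
    x[todo[ok]] <- xt[ok]; y[todo[ok]] <- yt[ok]
    todo <- todo[!ok]
  }

  bound <- integer(n)                     # 0 = free, else site index
  site_occ <- integer(max(ns, 1L))        # 0 = empty, else lipid index
  lf_num <- ifelse(lf == "OUTER", 2L, 1L)
  site_lf_num <- ifelse(site_lf == "OUTER", 2L, 1L)

  n_rec <- 1L + p$n_steps %/% p$record_every
  nb <- nrow(sys0$beads)
  n_prot <- nrow(sys0$prot_xyz)
  coords <- array(NA_real_, c(nb, 3L, n_rec))
  times <- numeric(n_rec)
  lip_z <- (1 + z0) + ifelse(lf_num == 2L, z0, -z0)
  record <- function(slot, t_now) {
    coords[seq_len(n_prot), , slot] <<- sys0$prot_xyz
    coords[n_prot + seq_len(n), 1L, slot] <<- x
    coords[n_prot + seq_len(n), 2L, slot] <<- y
    coords[n_prot + seq_len(n), 3L, slot] <<- lip_z
    times[slot] <<- t_now
  }
  record(1L, 0)

  # Event log (grown geometrically).
  ev_cap <- 256L; ev_n <- 0L
  ev_site <- integer(ev_cap); ev_lip <- integer(ev_cap)
  ev_on <- numeric(ev_cap); ev_off <- numeric(ev_cap)
  open_ev <- integer(max(ns, 1L))         # event row currently open per site
  push_event <- function(site, lipid, t_on) {
    if (ev_n == ev_cap) {
      ev_cap <<- ev_cap * 2L
      length(ev_site) <<- ev_cap; length(ev_lip) <<- ev_cap
      length(ev_on) <<- ev_cap; length(ev_off) <<- ev_cap
    }
    ev_n <<- ev_n + 1L
    ev_site[ev_n] <<- site; ev_lip[ev_n] <<- lipid
    ev_on[ev_n] <<- t_on; ev_off[ev_n] <<- NA_real_
    ev_n
  }

  q_unbind <- 1 - exp(-p$dt / tau_m)      # per-step escape probability
  slot <- 1L
  for (step in seq_len(p$n_steps)) {
    t_now <- step * p$dt
    free <- bound == 0L
    if (any(free)) {
      iw <- which(free)
      xp <- x[iw] + stats::rnorm(length(iw)) * sigma[iw]
      yp <- y[iw] + stats::rnorm(length(iw)) * sigma[iw]
      xp <- xp %% L[1]; yp <- yp %% L[2]
      r_old <- sqrt((x[iw] - cx)^2 + (y[iw] - cy)^2)
      r_new <- sqrt((xp - cx)^2 + (yp - cy)^2)
      e <- eps[iw]
      du <- -e * (r_new > w_in & r_new <= w_out) +
             e * (r_old > w_in & r_old <= w_out)
      acc <- r_new >= Rp & stats::runif(length(iw)) < exp(-du)
      x[iw[acc]] <- xp[acc]; y[iw[acc]] <- yp[acc]
    }
    if (ns) {
      ib <- which(bound > 0L)
      if (length(ib)) {
        sget <- bound[ib]
        out <- stats::runif(length(ib)) < q_unbind[cbind(sget, sp_idx[ib])]
        if (any(out)) {
          rel <- ib[out]; srel <- sget[out]
          # escape: relocate into the r_c..2 r_c shell, outside the disc
          todo <- seq_along(rel)
          while (length(todo)) {
            rc <- site_rc[srel[todo]]
            rho <- sqrt(stats::runif(length(todo), rc^2, (2 * rc)^2))
            phi <- stats::runif(length(todo), 0, 2 * pi)
            xt <- (site_xy[srel[todo], 1L] + rho * cos(phi)) %% L[1]
            yt <- (site_xy[srel[todo], 2L] + rho * sin(phi)) %% L[2]
            ok <- sqrt((xt - cx)^2 + (yt - cy)^2) >= Rp
            x[rel[todo[ok]]] <- xt[ok]; y[rel[todo[ok]]] <- yt[ok]
            todo <- todo[!ok]
          }
          bound[rel] <- 0L
          site_occ[srel] <- 0L
          ev_off[open_ev[srel]] <- t_now
          open_ev[srel] <- 0L
        }
        stay <- ib[!out]
        if (length(stay)) {
          sstay <- bound[stay]
          todo <- seq_along(stay)
          while (length(todo)) {
            rc <- site_rc[sstay[todo]]
            rho <- rc * sqrt(stats::runif(length(todo)))
            phi <- stats::runif(length(todo), 0, 2 * pi)
            xt <- (site_xy[sstay[todo], 1L] + rho * cos(phi)) %% L[1]
            yt <- (site_xy[sstay[todo], 2L] + rho * sin(phi)) %% L[2]
            ok <- sqrt((xt - cx)^2 + (yt - cy)^2) >= Rp
            x[stay[todo[ok]]] <- xt[ok]; y[stay[todo[ok]]] <- yt[ok]
            todo <- todo[!ok]
          }
        }
      }
      for (k in seq_len(ns)) {
        if (site_occ[k] != 0L) next
        cand <- which(bound == 0L & lf_num == site_lf_num[k])
        if (!length(cand)) next
        dx <- x[cand] - site_xy[k, 1L]
        dx <- dx - L[1] * round(dx / L[1])
        dy <- y[cand] - site_xy[k, 2L]
        dy <- dy - L[2] * round(dy / L[2])
        d2 <- dx * dx + dy * dy
        near <- d2 <= site_rc[k]^2
        if (!any(near)) next
        cand <- cand[near]; d2 <- d2[near]
        hit <- stats::runif(length(cand)) < pon_m[cbind(k, sp_idx[cand])]
        if (!any(hit)) next
        winner <- cand[hit][which.min(d2[hit])]
        bound[winner] <- k
        site_occ[k] <- winner
        open_ev[k] <- push_event(k, winner, t_now)
      }
    }
    if (step %% p$record_every == 0L) {
      slot <- slot + 1L
      record(slot, t_now)
    }
  }

  box3 <- c(L, 2 * z0 + 2)
  system <- membrane_system(sys0$beads, box3)
  system$positions <- coords[, , 1L]
  traj <- membrane_trajectory(times, coords, box3)
  lip_mol <- sys0$beads$molecule_id[sys0$beads$species != "PROTEIN"]
  events <- if (ev_n) data.frame(
    site_id = vapply(p$sites, `[[`, integer(1), "site_id")[ev_site[seq_len(ev_n)]],
    molecule_id = lip_mol[ev_lip[seq_len(ev_n)]],
    species = species[sp_idx[ev_lip[seq_len(ev_n)]]],
    t_on = ev_on[seq_len(ev_n)], t_off = ev_off[seq_len(ev_n)],
    stringsAsFactors = FALSE)
  else data.frame(site_id = integer(), molecule_id = integer(),
                  species = character(), t_on = numeric(), t_off = numeric())
  truth <- list(
    params = p,
    site_anchor_xy = site_xy[seq_len(ns), , drop = FALSE],
    site_leaflet = site_lf[seq_len(ns)],
    density_ratio = exp(eps_sp),
    tau = tau_m[seq_len(ns), , drop = FALSE],
    D = p$D,
    leaflet = stats::setNames(lf, lip_mol),
    events = events)
  list(system = system, trajectory = traj, truth = truth)
}
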