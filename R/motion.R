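#' Lateral diffusion from mean square displacement
#'
#' Head-group trajectories are unwrapped (minimum-image displacement between
#' consecutive frames, accumulated), the lateral MSD over (x, y) is averaged
#' over lipids and sliding time origins, and the diffusion constant follows
#' from the Einstein relation MSD = 4 D tau by a least-squares slope over
#' the fit window. The default window, 10-50 % of the maximum lag, skips the
#' short-lag regime and the poorly averaged tail. A residual diagnostic
#' flags fits whose MSD curve is visibly non-linear (e.g. ballistic drift,
#' MSD ~ tau^2).
#'
#' @param traj a \code{membrane_trajectory} with frames close enough in time
#'   that no lipid hops more than half a box between frames.
#' @param system a \code{membrane_system}.
#' @param species lipid species.
#' @param leaflet optional leaflet restriction ("INNER"/"OUTER").
#' @param fit_window lag-time window as fractions of the maximum lag.
#' @param n_lags number of lag times evaluated (evenly spaced).
#' @return object of class \code{diffusion_result}: list with \code{lag_ns},
#'   \code{msd_nm2}, \code{D_cm2_s}, \code{D_se_cm2_s} (standard error of
#'   the fitted slope), \code{fit_window_ns}, \code{r_squared},
#'   \code{poor_linearity} flag, \code{species}, \code{leaflet}.
#' @export
msd_diffusion <- function(traj, system, species, leaflet = NULL,
                          fit_window = c(0.1, 0.5), n_lags = 60L) {
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames")
  hg_idx <- headgroup_index(system, species)
  if (!length(hg_idx)) stop("species ", species, " has no HEADGROUP beads")
  if (!is.null(leaflet)) {
    la <- assign_leaflets(get_frame(traj, 1L), system)
    keep <- as.integer(names(la$leaflet)[la$leaflet == leaflet])
    hg_idx <- hg_idx[system$beads$molecule_id[hg_idx] %in% keep]
    if (!length(hg_idx)) stop("no ", species, " on the ", leaflet, " leaflet")
  }
  # Molecule lateral position = head-group centroid (single bead for CG).
  mol <- system$beads$molecule_id[hg_idx]
  mol_f <- match(mol, unique(mol))
  n_mol <- max(mol_f)
  n_hg <- length(hg_idx)
  # Unwrap: accumulate min-image steps per bead, then average per molecule.
  unwrap_axis <- function(k) {
    W <- matrix(traj$coords[hg_idx, k, ], nrow = n_hg)
    if (nf > 1L) {
      dW <- W[, -1L, drop = FALSE] - W[, -nf, drop = FALSE]
      B <- matrix(traj$box[-1L, k], nrow = n_hg, ncol = nf - 1L, byrow = TRUE)
      dW <- dW - B * round(dW / B)
      cs <- apply(dW, 1L, cumsum)               # (nf-1) x n_hg, or a vector
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
      W <- cbind(W[, 1L], W[, 1L] + t(cs))
    }
    rowsum(W, mol_f) / as.vector(table(mol_f))
  }
  X <- unwrap_axis(1L)
  Y <- unwrap_axis(2L)
  max_lag <- nf - 1L
  lags <- unique(pmax(1L, round(seq(1L, max_lag, length.out = min(n_lags,
                                                                  max_lag)))))
  msd <- vapply(lags, function(L) {
    dx <- X[, (1L + L):nf, drop = FALSE] - X[, 1L:(nf - L), drop = FALSE]
    dy <- Y[, (1L + L):nf, drop = FALSE] - Y[, 1L:(nf - L), drop = FALSE]
    mean(dx * dx + dy * dy)
  }, numeric(1))
  dt_frame <- mean(diff(traj$times))
  lag_ns <- lags * dt_frame
  win <- fit_window * max_lag * dt_frame
  sel <- lag_ns >= win[1] & lag_ns <= win[2]
  if (sum(sel) < 2L) stop("fit window contains fewer than 2 lag points")
  fit <- stats::lm(msd[sel] ~ lag_ns[sel])
  slope <- stats::coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  r2 <- summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 1  # zero-variance MSD (immobile): perfect line
  structure(list(lag_ns = lag_ns, msd_nm2 = msd,
                 D_cm2_s = unname(slope) / 4 * 1e-5,   # nm^2/ns -> cm^2/s
                 D_se_cm2_s = se / 4 * 1e-5,
                 fit_window_ns = win, r_squared = r2,
                 poor_linearity = r2 < 0.99,
                 species = species, leaflet = leaflet),
            class = "diffusion_result")
}

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Least-squares superposition of a mobile coordinate set onto a reference
#' by SVD of the covariance matrix, with the determinant correction that
#' forbids reflections. Returns the transform (rotation applied about the
#' mobile centroid, then translation onto the reference centroid) and the
#' post-fit RMSD.
#'
#' @param mobile,reference n x 3 coordinate matrices (same n >= 3,
#'   non-collinear).
#' @param selection optional row indices applied to both.
#' @return list(transform = list(R, center_mobile, center_reference),
#'   rmsd).
#' @export
superpose_rmsd <- function(mobile, reference, selection = NULL) {
  mobile <- as_coord_matrix(mobile)
  reference <- as_coord_matrix(reference)
  if (!is.null(selection)) {
    mobile <- mobile[selection, , drop = FALSE]
    reference <- reference[selection, , drop = FALSE]
  }
  if (nrow(mobile) != nrow(reference))
    stop("selections differ in length")
  if (nrow(mobile) < 3L)
    stop("need at least 3 points to superpose")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  if (qr(P)$rank < 2L) stop("degenerate (collinear) selection")
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(transform = list(R = R, center_mobile = cm, center_reference = cr),
       rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param transform the \code{transform} element of
#'   \code{\link{superpose_rmsd}}.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- as_coord_matrix(coords)
  sweep(sweep(coords, 2L, transform$center_mobile) %*% t(transform$R),
        2L, transform$center_reference, `+`)
}

#' Root mean square fluctuation per residue
#'
#' Each frame is superposed (over the selection) onto the trajectory mean
#' structure — computed by superposing on the first frame, averaging, and
#' refining once against that mean — and the RMSF of each selected bead is
#' the root mean square deviation about its mean position.
#'
#' @param traj a \code{membrane_trajectory}.
#' @param selection bead indices (default: protein backbone beads, requires
#'   \code{system}).
#' @param system optional \code{membrane_system} for the default selection
#'   and residue labels.
#' @return data.frame (bead, residue_id, rmsf_nm).
#' @export
rmsf <- function(traj, selection = NULL, system = NULL) {
  if (is.null(selection)) {
    if (is.null(system)) stop("give a selection or a system")
    selection <- protein_ca_index(system)
  }
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames")
  get_sel <- function(f) matrix(traj$coords[selection, , f], ncol = 3)
  ref <- get_sel(1L)
  aligned <- array(0, c(length(selection), 3L, nf))
  for (pass in 1:2) {
    for (f in seq_len(nf)) {
      fr <- get_sel(f)
      fit <- superpose_rmsd(fr, ref)
      aligned[, , f] <- apply_transform(fr, fit$transform)
    }
    ref <- apply(aligned, c(1, 2), mean)   # refine against the mean
  }
  mean_pos <- ref
  dev2 <- matrix(0, length(selection), nf)
  for (f in seq_len(nf))
    dev2[, f] <- rowSums((aligned[, , f] - mean_pos)^2)
  out <- data.frame(bead = selection, rmsf_nm = sqrt(rowMeans(dev2)))
  if (!is.null(system))
    out$residue_id <- system$beads$residue_id[selection]
  out
}

#' RMSD time series against a reference frame
#'
#' @param traj a \code{membrane_trajectory}.
#' @param reference n x 3 matrix (or frame index into \code{traj}).
#' @param selection bead indices used both for the fit and the RMSD.
#' @return data.frame (time, rmsd_nm).
#' @export
rmsd_series <- function(traj, reference = 1L, selection) {
  ref <- if (is.numeric(reference) && length(reference) == 1L)
    matrix(traj$coords[selection, , reference], ncol = 3)
  else as_coord_matrix(reference)[selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    superpose_rmsd(matrix(traj$coords[selection, , f], ncol = 3), ref)$rmsd
  }, numeric(1))
  data.frame(time = traj$times, rmsd_nm = vals)
}

#' Gate-motion probe distance after core-domain fit
#'
#' Per frame, the core-domain backbone selection is superposed onto the
#' reference structure and the Euclidean distance between the probe
#' residue's backbone bead (transformed with the core fit) and its
#' reference position is reported — the standard probe for rigid-body gate
#' motion relative to a fixed core. The default probe is residue 350.
#'
#' @param traj a \code{membrane_trajectory}.
#' @param system a \code{membrane_system}.
#' @param reference n_beads x 3 reference coordinates (nm), e.g. the
#'   crystal-structure frame.
#' @param fit_selection bead indices of the core-domain backbone beads.
#' @param probe_residue residue_id of the probe (default 350).
#' @return data.frame (time, distance_nm).
#' @export
domain_fit_distance <- function(traj, system, reference, fit_selection,
                                probe_residue = 350L) {
  reference <- as_coord_matrix(reference, nrow(system$beads))
  probe_idx <- which(system$beads$residue_id == probe_residue &
                       system$beads$species == "PROTEIN" &
                       bead_has_role(system$beads, "BACKBONE_CA"))
  if (length(probe_idx) != 1L)
    stop("probe residue ", probe_residue, " has no unique backbone bead")
  ref_fit <- reference[fit_selection, , drop = FALSE]
  ref_probe <- reference[probe_idx, ]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fit <- superpose_rmsd(matrix(traj$coords[fit_selection, , f], ncol = 3),
                          ref_fit)
    moved <- apply_transform(matrix(traj$coords[probe_idx, , f], ncol = 3),
                             fit$transform)
    sqrt(sum((moved - ref_probe)^2))
  }, numeric(1))
  data.frame(time = traj$times, distance_nm = vals)
}
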