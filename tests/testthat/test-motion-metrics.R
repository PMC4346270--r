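test_that("superposition recovers rigid transforms to machine precision", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(ref, ref)$rmsd, 0, tolerance = 1e-12)
  th <- 1.1; ax <- c(1, 2, 0.5) / sqrt(5.25)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mob <- ref %*% t(R) + matrix(rep(c(3, -2, 7), each = 10), 10, 3)
  expect_lt(superpose_rmsd(mob, ref)$rmsd, 1e-6)
})

test_that("fitted RMSD never exceeds unfitted RMSD", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(4:20, 1)
    ref <- matrix(rnorm(3 * n), n, 3)
    mob <- ref + matrix(rnorm(3 * n, sd = runif(1, 0.01, 1)), n, 3)
    unfitted <- sqrt(mean(rowSums((mob - ref)^2)))
    expect_lte(superpose_rmsd(mob, ref)$rmsd, unfitted + 1e-12)
  }
})

test_that("SVD superposition matches brute-force and bio3d oracles", {
  set.seed(8)
  ref <- matrix(c(0, 0, 0, 2, 0, 0, 0, 1, 0, 0.5, 0.5, 1.5), 4, 3,
                byrow = TRUE)
  mob <- ref + matrix(rnorm(12, sd = 0.15), 4, 3)
  got <- superpose_rmsd(mob, ref)$rmsd
  expect_equal(got, oracle_rmsd(mob, ref), tolerance = 1e-6)
  b3 <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(mob)), fit = TRUE)
  expect_lt(abs(got - b3), 6e-4)   # bio3d reports values rounded to 3 digits
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_rmsd(line, line + 1), "collinear")
  expect_error(superpose_rmsd(matrix(0, 2, 3), matrix(0, 2, 3)), "3 points")
})

test_that("RMSF: static zero, jitter recovers sigma*sqrt(3), rotation removed", {
  set.seed(9)
  nb <- 40; nf <- 1500; sig <- 0.05
  base <- 2 * matrix(rnorm(nb * 3), nb, 3)
  co <- array(rep(base, nf), c(nb, 3, nf))
  tr_static <- membrane_trajectory(seq(0, by = 0.3, length.out = nf),
                                   co, c(20, 20, 20))
  expect_equal(max(rmsf(tr_static, selection = 1:nb)$rmsf_nm), 0,
               tolerance = 1e-12)
  co[5, , ] <- co[5, , ] + rnorm(3 * nf, sd = sig)
  tr <- membrane_trajectory(tr_static$times, co, c(20, 20, 20))
  rf <- rmsf(tr, selection = 1:nb)
  # the rigid fit absorbs a small share of a single bead's motion
  expect_equal(rf$rmsf_nm[5], sig * sqrt(3), tolerance = 0.12)
  expect_lt(max(rf$rmsf_nm[-5]), sig)
  # pure global rotation leaves no fluctuation after fitting
  co2 <- array(0, c(nb, 3, 50))
  for (f in 1:50) {
    th <- 0.02 * f
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    co2[, , f] <- base %*% t(R)
  }
  tr2 <- membrane_trajectory(seq(0, by = 0.3, length.out = 50), co2,
                             c(20, 20, 20))
  expect_lt(max(rmsf(tr2, selection = 1:nb)$rmsf_nm), 1e-8)
})

test_that("MSD: Brownian recovery, immobile control and drift diagnostic", {
  p <- synth_params(box_xy = c(18, 18), protein_radius = 0.3,
                    counts = list(INNER = c(POPG = 40), OUTER = c(POPG = 40)),
                    D = c(POPG = 5.9e-7), n_steps = 3000, sites = list(),
                    well = list(inner = 0.3, outer = 1, eps = 0), seed = 6)
  g <- generate_membrane(p)
  dr <- msd_diffusion(g$trajectory, g$system, "POPG",
                      fit_window = c(0.01, 0.1), n_lags = 80)
  expect_equal(dr$D_cm2_s, 5.9e-7, tolerance = 0.08)
  expect_false(dr$poor_linearity)
  expect_equal(dr$msd_nm2[1], 4 * 5.9e-7 * 1e5 * dr$lag_ns[1],
               tolerance = 0.1)   # Einstein relation at the first lag
  # immobile lipids
  co <- g$trajectory$coords[, , rep(1, 40)]
  tr0 <- membrane_trajectory(seq(0, by = 0.3, length.out = 40), co,
                             g$system$box)
  dr0 <- msd_diffusion(tr0, g$system, "POPG")
  expect_equal(dr0$D_cm2_s, 0)
  # constant-velocity drift: quadratic MSD flagged by the residual check
  beads <- do.call(rbind, lapply(1:4, function(i)
    bead_row(i, "PO4", 1000L + i, "POPE", i, "POPE", "HEADGROUP")))
  sysd <- membrane_system(beads, c(500, 500, 10))
  nfd <- 400
  cod <- array(0, c(4, 3, nfd))
  for (f in 1:nfd)
    cod[, , f] <- cbind(0.05 * f + c(1, 2, 3, 4), c(1, 2, 3, 4), 1)
  trd <- membrane_trajectory(seq(0, by = 0.3, length.out = nfd), cod,
                             sysd$box)
  dd <- msd_diffusion(trd, sysd, "POPE")
  expect_true(dd$poor_linearity)
})

test_that("time-origin averaging agrees with the single-origin estimator in expectation", {
  p <- synth_params(box_xy = c(18, 18), protein_radius = 0.3,
                    counts = list(INNER = c(POPE = 60), OUTER = c(POPE = 60)),
                    n_steps = 2000, sites = list(),
                    well = list(inner = 0.3, outer = 1, eps = 0), seed = 16)
  g <- generate_membrane(p)
  dr <- msd_diffusion(g$trajectory, g$system, "POPE", n_lags = 30)
  # naive single-origin MSD at the same lags
  hg <- which(g$system$beads$species == "POPE")
  nf <- n_frames(g$trajectory)
  acc <- matrix(0, length(hg), 2)
  naive <- numeric(length(dr$lag_ns))
  lags <- round(dr$lag_ns / 0.3)
  pos0 <- g$trajectory$coords[hg, 1:2, 1]
  prev <- pos0
  unwrapped <- array(0, c(length(hg), 2, nf)); unwrapped[, , 1] <- pos0
  for (f in 2:nf) {
    cur <- g$trajectory$coords[hg, 1:2, f]
    d <- cur - prev
    for (k in 1:2) d[, k] <- d[, k] - 18 * round(d[, k] / 18)
    unwrapped[, , f] <- unwrapped[, , f - 1] + d
    prev <- cur
  }
  for (i in seq_along(lags)) {
    dx <- unwrapped[, , 1 + lags[i]] - unwrapped[, , 1]
    naive[i] <- mean(rowSums(dx^2))
  }
  # same expectation; compare slopes loosely (single-origin is noisy)
  ratio <- sum(naive * dr$lag_ns) / sum(dr$msd_nm2 * dr$lag_ns)
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("domain-fit probe distance isolates gate motion from the core", {
  # 20 core residues + 5 gate residues + probe residue 350
  nb <- 26L
  beads <- do.call(rbind, lapply(seq_len(nb), function(i)
    bead_row(i, "BB", if (i <= 20L) i else if (i < nb) 330L + i else 350L,
             "GLY", 1L, "PROTEIN", "BACKBONE_CA")))
  sys <- membrane_system(beads, c(50, 50, 50))
  set.seed(21)
  ref <- matrix(rnorm(nb * 3), nb, 3)
  nf <- 3L
  co <- array(rep(ref, nf), c(nb, 3, nf))
  shift <- c(1, 0, 0)                     # move the gate 1 nm, core untouched
  for (f in 2:nf) co[21:nb, , f] <- co[21:nb, , f] +
      matrix(rep(shift * (f - 1L), each = 6), 6, 3)
  traj <- membrane_trajectory(c(0, 0.3, 0.6), co, sys$box)
  d <- domain_fit_distance(traj, sys, ref, fit_selection = 1:20,
                           probe_residue = 350L)
  expect_equal(d$distance_nm, c(0, 1, 2), tolerance = 1e-9)
  # whole-body translation: core fit removes it entirely
  co2 <- co
  for (f in 1:nf) co2[, , f] <- ref + matrix(rep(c(0, 2, 0), each = nb), nb, 3)
  traj2 <- membrane_trajectory(c(0, 0.3, 0.6), co2, sys$box)
  d2 <- domain_fit_distance(traj2, sys, ref, fit_selection = 1:20)
  expect_equal(max(d2$distance_nm), 0, tolerance = 1e-9)
  expect_error(domain_fit_distance(traj, sys, ref, 1:20, probe_residue = 999L),
               "probe")
})

test_that("rmsd series is zero against itself and positive after perturbation", {
  set.seed(30)
  nb <- 12L
  beads <- do.call(rbind, lapply(seq_len(nb), function(i)
    bead_row(i, "BB", i, "GLY", 1L, "PROTEIN", "BACKBONE_CA")))
  sys <- membrane_system(beads, c(20, 20, 20))
  base <- matrix(rnorm(nb * 3), nb, 3)
  co <- array(rep(base, 3), c(nb, 3, 3))
  co[, , 3] <- co[, , 3] + matrix(rnorm(nb * 3, sd = 0.2), nb, 3)
  traj <- membrane_trajectory(c(0, 0.3, 0.6), co, sys$box)
  rs <- rmsd_series(traj, 1L, seq_len(nb))
  expect_equal(rs$rmsd_nm[1:2], c(0, 0), tolerance = 1e-12)
  expect_gt(rs$rmsd_nm[3], 0.05)
})
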