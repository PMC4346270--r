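# A protein ring plus lipids placed by a caller-supplied function of frame.
ring_membrane <- function(n_lip, placer, n_frames = 1L, box = c(14, 14, 6),
                          ring_radius = 2, species = "POPE") {
  n_ring <- 12L
  ang <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  beads <- rbind(
    do.call(rbind, lapply(seq_len(n_ring), function(i)
      bead_row(i, "BB", i, "GLY", 1L, "PROTEIN", "BACKBONE_CA"))),
    do.call(rbind, lapply(seq_len(n_lip), function(i)
      bead_row(n_ring + i, "PO4", 1000L + i, species, 1L + i, species,
               "HEADGROUP"))))
  sys <- membrane_system(beads, box)
  ring <- cbind(box[1] / 2 + ring_radius * cos(ang),
                box[2] / 2 + ring_radius * sin(ang), 1)
  co <- array(0, c(nrow(beads), 3, n_frames))
  for (f in seq_len(n_frames)) {
    co[seq_len(n_ring), , f] <- ring
    co[n_ring + seq_len(n_lip), , f] <- placer(f)
  }
  traj <- membrane_trajectory(seq(0, by = 0.3, length.out = n_frames), co, box)
  list(sys = sys, traj = traj)
}

test_that("density map integrates back to the lipid count", {
  set.seed(6)
  n_lip <- 60
  m <- ring_membrane(n_lip, function(f) {
    # uniform outside the ring footprint
    out <- matrix(0, n_lip, 3)
    todo <- seq_len(n_lip)
    while (length(todo)) {
      x <- runif(length(todo), 0, 14); y <- runif(length(todo), 0, 14)
      ok <- (x - 7)^2 + (y - 7)^2 >= 4
      out[todo[ok], ] <- cbind(x[ok], y[ok], 1)
      todo <- todo[!ok]
    }
    out
  }, n_frames = 20L)
  dm <- density_map(m$traj, m$sys, "POPE", "INNER")
  total <- sum(dm$grid) * prod(dm$cell_size)
  expect_equal(total, n_lip, tolerance = 1e-9)
  # all mass outside the masked footprint (up to boundary cells)
  outside <- sum(dm$grid[!dm$mask]) * prod(dm$cell_size)
  expect_gt(outside / total, 0.97)
})

test_that("a static lipid puts all its mass in one cell", {
  m <- ring_membrane(1, function(f) cbind(10.05, 3.05, 1), n_frames = 5L)
  dm <- density_map(m$traj, m$sys, "POPE", "INNER", cell_size = 0.2)
  expect_equal(sum(dm$grid > 0), 1L)
  expect_equal(max(dm$grid) * prod(dm$cell_size), 1)
})

test_that("uniform bilayer: S is 1 with footprint masking and below 1 without", {
  p <- synth_params(box_xy = c(14, 14),
                    counts = list(INNER = c(POPE = 150), OUTER = c(POPE = 150)),
                    n_steps = 3000, record_every = 3, sites = list(),
                    well = list(inner = 2, outer = 3, eps = 0), seed = 19)
  g <- generate_membrane(p)
  masked <- enrichment_ratio(g$trajectory, system = g$system,
                             species = "POPE", leaflet = "INNER")
  unmasked <- enrichment_ratio(g$trajectory, system = g$system,
                               species = "POPE", leaflet = "INNER",
                               mask_footprint = FALSE)
  expect_equal(masked$S, 1, tolerance = 0.08)
  expect_lt(unmasked$S, masked$S)
  expect_lt(unmasked$S, 0.8)   # footprint pi*2^2 dilutes the 0-3 nm disc
  # grid-map route agrees with the exact-count route
  dm <- density_map(g$trajectory, g$system, "POPE", "INNER")
  masked_dm <- enrichment_ratio(dm)
  expect_equal(masked_dm$S, masked$S, tolerance = 0.1)
})

test_that("S recovers the Boltzmann factor and is density-scale invariant", {
  run <- function(n, seed) {
    p <- synth_params(box_xy = c(14, 14),
                      counts = list(INNER = c(POPG = n), OUTER = c(POPG = n)),
                      n_steps = 3000, record_every = 3, sites = list(),
                      well = list(inner = 2, outer = 3, eps = log(2)),
                      seed = seed)
    g <- generate_membrane(p)
    enrichment_ratio(g$trajectory, system = g$system, species = "POPG",
                     leaflet = "INNER")$S
  }
  s_half <- run(75, 23)
  s_full <- run(150, 24)
  expect_equal(s_half, 2, tolerance = 0.12)
  expect_equal(s_full, 2, tolerance = 0.12)
  expect_equal(s_half, s_full, tolerance = 0.15)
})

test_that("lipids confined to the bulk annulus give S = 0 and an empty bulk flags", {
  m <- ring_membrane(24, function(f) {
    ang <- seq(0, 2 * pi, length.out = 25)[-25]
    cbind(7 + 4.5 * cos(ang), 7 + 4.5 * sin(ang), 1)
  }, n_frames = 3L)
  er <- enrichment_ratio(m$traj, system = m$sys, species = "POPE",
                         leaflet = "INNER")
  expect_equal(er$S, 0)
  # everything near, bulk empty -> undefined and flagged
  m2 <- ring_membrane(8, function(f) {
    ang <- seq(0, 2 * pi, length.out = 9)[-9]
    cbind(7 + 2.5 * cos(ang), 7 + 2.5 * sin(ang), 1)
  })
  er2 <- enrichment_ratio(m2$traj, system = m2$sys, species = "POPE",
                          leaflet = "INNER")
  expect_true(is.na(er2$S))
  expect_match(er2$flag, "undefined")
})

test_that("site-local S exceeds annulus S for a strongly bound species", {
  site <- list(site_id = 1L, leaflet = "INNER", angle = 0, r_c = 0.6,
               tau = c(CL = 60), p_on = c(CL = 1),
               anchor_labels = data.frame(residue_id = c(4L, 299L),
                                          residue_name = c("ARG", "ARG")))
  p <- synth_params(box_xy = c(14, 14),
                    counts = list(INNER = c(CL = 60), OUTER = numeric()),
                    D = c(CL = 4.5e-7), n_steps = 6000, record_every = 3,
                    sites = list(site),
                    well = list(inner = 2, outer = 3, eps = 0), seed = 29)
  g <- generate_membrane(p)
  sites <- sites_from_truth(g$truth)
  s_ann <- enrichment_ratio(g$trajectory, system = g$system, species = "CL",
                            leaflet = "INNER")$S
  s_loc <- site_local_enrichment(g$trajectory, g$system, sites, "CL",
                                 "INNER", capture_radius = 0.6)$S
  expect_gt(s_loc, s_ann)
  expect_gt(s_loc, 2)
  # with the site knocked out, the site disc is just another patch of annulus
  g0 <- generate_membrane(knockout_sites(p, 1L))
  s_loc0 <- site_local_enrichment(g0$trajectory, g0$system, sites, "CL",
                                  "INNER", capture_radius = 0.6)$S
  s_ann0 <- enrichment_ratio(g0$trajectory, system = g0$system,
                             species = "CL", leaflet = "INNER")$S
  expect_lt(abs(s_loc0 - s_ann0), 0.45)
  # empty site disc throughout -> 0
  m3 <- ring_membrane(6, function(f) cbind(rep(1, 6), rep(1, 6), 1))
  sd3 <- site_definition(1L, "INNER", c(1L, 2L))
  s3 <- site_local_enrichment(m3$traj, m3$sys, list(sd3), "POPE", "INNER",
                              capture_radius = 0.5)
  expect_equal(s3$density_near, 0)
})
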