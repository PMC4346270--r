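test_that("occupancy follows the cutoff inequality, boundary inclusive", {
  sys <- site_system()
  site <- site_definition(1L, "INNER", c(4L, 299L))
  traj <- distance_trajectory(sys, c(0.6, 0.7, 0.70001))
  os <- occupancy_series(traj, sys, site, "POPE", delta = 0.7)
  expect_equal(os$zeta, c(1L, 1L, 0L))       # d = delta counts as contact
  expect_equal(os$d, c(0.6, 0.7, 0.70001), tolerance = 1e-9)
  # zeta = 1 <=> occupant set nonempty
  expect_equal(lengths(os$occupants) > 0L, os$zeta == 1L)
})

test_that("hand-built five-frame distance fixture gives the expected zeta", {
  sys <- site_system()
  site <- site_definition(1L, "INNER", c(4L, 299L))
  traj <- distance_trajectory(sys, c(0.5, 0.65, 0.72, 0.69, 1.0))
  os <- occupancy_series(traj, sys, site, "POPE", delta = 0.7)
  expect_equal(os$zeta, c(1L, 1L, 0L, 1L, 0L))
})

test_that("occupancy errors on absent species and missing anchors", {
  sys <- site_system()
  traj <- distance_trajectory(sys, 0.5)
  expect_error(occupancy_series(traj, sys, site_definition(1L, "INNER", c(4L, 299L)),
                                "CL"), "absent")
  expect_error(occupancy_series(traj, sys, site_definition(1L, "INNER", c(7L, 8L)),
                                "POPE"), "not found")
})

test_that("occupancy is invariant under rigid translation and periodic wrap", {
  p <- synth_params(counts = list(INNER = c(CL = 6), OUTER = c(CL = 6)),
                    n_steps = 150, seed = 14)
  g <- generate_membrane(p)
  site <- sites_from_truth(g$truth)[[1]]
  os0 <- occupancy_series(g$trajectory, g$system, site, "CL")
  shift <- c(3.1, -1.2, 0.4)
  co <- g$trajectory$coords
  for (k in 1:3) co[, k, ] <- (co[, k, ] + shift[k]) %% g$system$box[k]
  traj2 <- membrane_trajectory(g$trajectory$times, co, g$system$box)
  os1 <- occupancy_series(traj2, g$system, site, "CL")
  expect_equal(os1$zeta, os0$zeta)
  expect_equal(os1$d, os0$d, tolerance = 1e-9)
})

test_that("contact counts agree exactly with the all-pairs brute-force oracle", {
  set.seed(77)
  beads <- rbind(
    bead_row(1L, "BB", 1L, "GLY", 1L, "PROTEIN", "BACKBONE_CA"),
    bead_row(2L, "SC", 1L, "GLY", 1L, "PROTEIN", ""),
    bead_row(3L, "BB", 2L, "LYS", 1L, "PROTEIN", "BACKBONE_CA"),
    do.call(rbind, lapply(1:6, function(i)
      bead_row(3L + i, "PO4", 1000L + i, "POPE", 1L + i, "POPE", "HEADGROUP"))),
    do.call(rbind, lapply(1:2, function(i) rbind(
      bead_row(9L + 2L * i, "PO1", 1100L + i, "CL", 10L + i, "CL", "HEADGROUP"),
      bead_row(10L + 2L * i, "PO2", 1100L + i, "CL", 10L + i, "CL", "HEADGROUP")))))
  sys <- membrane_system(beads, c(6, 6, 6))
  nf <- 4L
  co <- array(runif(nrow(beads) * 3 * nf, 0, 6), c(nrow(beads), 3, nf))
  traj <- membrane_trajectory(seq(0, by = 0.3, length.out = nf), co, sys$box)
  cc <- contact_config(delta = c(POPE = 1.2, CL = 1.5),
                       delta_site = c(POPE = 1.2, CL = 1.5))
  lic <- lipids_in_contact(traj, sys, cc)
  for (f in seq_len(nf)) {
    oc <- oracle_lipids_in_contact(co[, , f], sys, c(POPE = 1.2, CL = 1.5))
    expect_identical(as.integer(lic$counts[f, "POPE"]), as.integer(oc["POPE"]))
    expect_identical(as.integer(lic$counts[f, "CL"]), as.integer(oc["CL"]))
  }
  prof <- residue_contact_profile(traj, sys, cc, mode = "max_residue",
                                  species = c("POPE", "CL"))
  for (sp in c("POPE", "CL")) {
    ora <- oracle_residue_raw(traj, sys, sp, if (sp == "POPE") 1.2 else 1.5)
    got <- prof$raw[prof$species == sp]
    names(got) <- prof$residue_id[prof$species == sp]
    expect_equal(got[names(ora)], ora)
  }
})

test_that("raw contact counts are monotone in the cutoff", {
  p <- synth_params(counts = list(INNER = c(POPE = 12, CL = 3),
                                  OUTER = c(POPE = 12, CL = 3)),
                    n_steps = 60, seed = 2)
  g <- generate_membrane(p)
  prev_raw <- NULL
  prev_lic <- NULL
  for (dlt in c(0.5, 0.8, 1.2, 1.6)) {
    cc <- contact_config(delta = c(POPE = dlt, POPG = dlt, CL = dlt),
                         delta_site = c(POPE = dlt, POPG = dlt, CL = dlt))
    prof <- residue_contact_profile(g$trajectory, g$system, cc,
                                    mode = "max_residue", species = "POPE")
    lic <- lipids_in_contact(g$trajectory, g$system, cc, species = "POPE")
    if (!is.null(prev_raw)) {
      expect_true(all(prof$raw >= prev_raw))
      expect_true(all(lic$counts$POPE >= prev_lic))
    }
    prev_raw <- prof$raw
    prev_lic <- lic$counts$POPE
  }
})

test_that("max-residue normalization puts the top residue at exactly 1 and untouched residues at 0", {
  # one residue close to the lipid most frames, one sometimes, one never
  beads <- rbind(
    bead_row(1L, "BB", 10L, "ARG", 1L, "PROTEIN", "BACKBONE_CA"),
    bead_row(2L, "BB", 11L, "LYS", 1L, "PROTEIN", "BACKBONE_CA"),
    bead_row(3L, "BB", 12L, "GLY", 1L, "PROTEIN", "BACKBONE_CA"),
    bead_row(4L, "PO4", 1001L, "POPE", 2L, "POPE", "HEADGROUP"))
  sys <- membrane_system(beads, c(20, 20, 20))
  nf <- 4L
  co <- array(0, c(4, 3, nf))
  for (f in seq_len(nf)) {
    co[1, , f] <- c(5, 5, 5)
    co[2, , f] <- c(5.9, 5, 5)
    co[3, , f] <- c(15, 15, 15)
    co[4, , f] <- c(5 + 0.1 * f, 5, 5)    # 5.1..5.4: always near res 10
  }
  traj <- membrane_trajectory(seq(0, by = 0.3, length.out = nf), co, sys$box)
  prof <- residue_contact_profile(traj, sys, mode = "max_residue",
                                  species = "POPE")
  expect_equal(prof$normalized[prof$residue_id == 10L], 1)
  expect_equal(prof$raw[prof$residue_id == 10L], 4)
  expect_equal(prof$normalized[prof$residue_id == 12L], 0)
  expect_lt(prof$normalized[prof$residue_id == 11L], 1)
})

test_that("volume-ratio normalization divides by (delta/delta_ref)^3", {
  sys <- site_system(n_lip = 1, species = "CL")
  sys$beads$species[3] <- "CL"; sys$beads$residue_name[3] <- "CL"
  traj <- distance_trajectory(sys, c(0.5, 0.5), anchor = c(0, 5, 1))
  prof <- residue_contact_profile(traj, sys, mode = "per_lipid_frame_volume",
                                  species = "CL", delta_ref = 0.7)
  # raw = 2 frames x 1 lipid for both co-located anchor residues (delta = 0.8)
  expect_equal(unique(prof$raw), 2)
  expect_equal(prof$normalized, prof$raw / (1 * 2 * (0.8 / 0.7)^3))
  expect_equal((0.8 / 0.7)^3, 1.4927, tolerance = 1e-4)
})

test_that("lipids-in-contact counts molecules once however many beads touch", {
  beads <- rbind(
    bead_row(1L, "BB", 1L, "GLY", 1L, "PROTEIN", "BACKBONE_CA"),
    bead_row(2L, "PO1", 1001L, "CL", 2L, "CL", "HEADGROUP"),
    bead_row(3L, "PO2", 1001L, "CL", 2L, "CL", "HEADGROUP"),
    bead_row(4L, "PO4", 1002L, "POPE", 3L, "POPE", "HEADGROUP"),
    bead_row(5L, "PO4", 1003L, "POPE", 4L, "POPE", "HEADGROUP"),
    bead_row(6L, "PO4", 1004L, "POPE", 5L, "POPE", "HEADGROUP"))
  sys <- membrane_system(beads, c(20, 20, 20))
  co <- array(0, c(6, 3, 1))
  co[1, , 1] <- c(5, 5, 5)
  co[2, , 1] <- c(5.3, 5, 5)     # CL: both beads within delta
  co[3, , 1] <- c(5.5, 5, 5)
  co[4, , 1] <- c(5.6, 5, 5)     # POPE in contact
  co[5, , 1] <- c(5.65, 5, 5)    # POPE in contact
  co[6, , 1] <- c(9, 9, 9)       # POPE far away
  traj <- membrane_trajectory(0, co, sys$box)
  lic <- lipids_in_contact(traj, sys)
  expect_equal(as.integer(lic$counts$CL), 1L)
  expect_equal(as.integer(lic$counts$POPE), 2L)
  # empty bilayer gives zero
  sys0 <- site_system(n_lip = 1)
  traj0 <- distance_trajectory(sys0, 4.0)
  expect_equal(as.integer(lipids_in_contact(traj0, sys0)$counts$POPE), 0L)
})
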