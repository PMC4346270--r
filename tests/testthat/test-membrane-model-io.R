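test_that("toy GRO fixture loads with correct annotation and molecule grouping", {
  fx <- write_toy_fixture()
  sys <- load_system(fx$gro, fx$ann)
  expect_s3_class(sys, "membrane_system")
  expect_equal(nrow(sys$beads), 6L)
  expect_equal(sum(sys$beads$species == "PROTEIN"), 2L)
  # 2 protein residues, one molecule; 2 lipid molecules (POPE + CL)
  expect_equal(length(unique(sys$beads$residue_id[sys$beads$species == "PROTEIN"])), 2L)
  expect_equal(length(unique(sys$beads$molecule_id[sys$beads$species != "PROTEIN"])), 2L)
  expect_equal(length(unique(sys$beads$molecule_id[sys$beads$species == "PROTEIN"])), 1L)
  # residue numbering verbatim from the structure
  expect_setequal(sys$beads$residue_id[sys$beads$species == "PROTEIN"], c(4L, 299L))
  # CL carries two head-group beads, one molecule
  cl <- sys$beads[sys$beads$species == "CL", ]
  expect_equal(nrow(cl), 2L)
  expect_equal(length(unique(cl$molecule_id)), 1L)
  expect_equal(sys$box, c(10, 10, 5))
})

test_that("GRO write/read round-trips the bead roster and coordinates", {
  fx <- write_toy_fixture()
  sys <- load_system(fx$gro, fx$ann)
  out <- file.path(withr::local_tempdir(), "rt.gro")
  write_gro(sys, out)
  sys2 <- load_system(out, fx$ann)
  expect_equal(sys2$beads$residue_id, sys$beads$residue_id)
  expect_equal(sys2$beads$name, sys$beads$name)
  expect_equal(sys2$beads$species, sys$beads$species)
  expect_equal(sys2$positions, sys$positions, tolerance = 1e-8)
})

test_that("structure residues missing from the annotation are a named hard error", {
  fx <- write_toy_fixture()
  gro2 <- file.path(withr::local_tempdir(), "bad.gro")
  lines <- readLines(fx$gro)
  lines[3] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 4L, "XXX", "BB", 1L,
                      1.0, 1.0, 1.0)
  writeLines(lines, gro2)
  expect_error(load_system(gro2, fx$ann), "XXX")
})

test_that("malformed GRO files fail with a line number", {
  fx <- write_toy_fixture()
  gro2 <- file.path(withr::local_tempdir(), "bad.gro")
  lines <- readLines(fx$gro)
  substr(lines[4], 21, 28) <- "  badnum"
  writeLines(lines, gro2)
  expect_error(load_system(gro2, fx$ann), "line 4")
})

test_that("text trajectory round-trips coordinates and times", {
  fx <- write_toy_fixture()
  sys <- load_system(fx$gro, fx$ann)
  nf <- 3L
  set.seed(1)
  co <- array(runif(6 * 3 * nf, 0, 5), c(6, 3, nf))
  traj <- membrane_trajectory(c(0, 0.3, 0.6), co, sys$box)
  path <- file.path(withr::local_tempdir(), "t.trj")
  write_trajectory_text(traj, path)
  traj2 <- load_trajectory(path, sys)
  expect_equal(traj2$times, traj$times)
  expect_equal(traj2$coords, traj$coords, tolerance = 1e-7)
  expect_equal(traj2$interval, 0.3)
})

test_that("degenerate and malformed trajectories are handled", {
  fx <- write_toy_fixture()
  sys <- load_system(fx$gro, fx$ann)
  dir <- withr::local_tempdir()
  one <- file.path(dir, "one.trj")
  co <- array(1, c(6, 3, 1))
  write_trajectory_text(membrane_trajectory(0, co, sys$box), one)
  t1 <- load_trajectory(one, sys)
  expect_equal(n_frames(t1), 1L)
  expect_true(is.na(t1$interval))
  # frame with wrong atom count
  bad <- file.path(dir, "bad.trj")
  writeLines(c("NBEADS 6", "FRAME 0 10 10 5",
               paste(1:5, 1, 1, 1)), bad)
  expect_error(load_trajectory(bad, sys), "6 bead lines")
  # bead count mismatch with system
  five <- file.path(dir, "five.trj")
  writeLines(c("NBEADS 5", "FRAME 0 10 10 5", paste(1:5, 1, 1, 1)), five)
  expect_error(load_trajectory(five, sys), "5 beads")
  # non-monotonic times
  nm <- file.path(dir, "nm.trj")
  writeLines(c("NBEADS 6",
               "FRAME 0.3 10 10 5", paste(1:6, 1, 1, 1),
               "FRAME 0.0 10 10 5", paste(1:6, 1, 1, 1)), nm)
  expect_error(load_trajectory(nm, sys), "non-monotonic")
})

test_that("leaflet assignment splits lipids about the head-group midplane", {
  beads <- rbind(
    bead_row(1L, "PO4", 1001L, "POPE", 2L, "POPE", "HEADGROUP"),
    bead_row(2L, "PO4", 1002L, "POPE", 3L, "POPE", "HEADGROUP"))
  sys <- membrane_system(beads, c(10, 10, 10))
  pos <- rbind(c(5, 5, 7), c(5, 5, 3))   # z = +2 / -2 about midplane 5
  la <- assign_leaflets(pos, sys)
  expect_equal(unname(la$leaflet[c("2", "3")]), c("OUTER", "INNER"))
  expect_equal(la$midplane_z, 5)
  # invariance under global z translation
  la2 <- assign_leaflets(pos + matrix(rep(c(0, 0, 1.7), 2), 2, byrow = TRUE), sys)
  expect_equal(la2$leaflet, la$leaflet)
  # with >= 2 distinct z there is at least one lipid on each side
  expect_true(all(c("INNER", "OUTER") %in% la$leaflet))
})

test_that("leaflet assignment matches generator ground truth", {
  p <- synth_params(counts = list(INNER = c(POPE = 20, CL = 3),
                                  OUTER = c(POPE = 25, CL = 2)),
                    n_steps = 50, sites = list(), seed = 5)
  g <- generate_membrane(p)
  la <- assign_leaflets(get_frame(g$trajectory, 25L), g$system)
  expect_equal(la$leaflet[names(g$truth$leaflet)], g$truth$leaflet)
})

test_that("system invariants are enforced", {
  beads <- bead_row(1L, "C1A", 1001L, "POPE", 2L, "POPE", "TAIL")
  expect_error(membrane_system(beads, c(10, 10, 10)), "HEADGROUP")
  beads2 <- rbind(
    bead_row(1L, "BB", 1L, "GLY", 1L, "PROTEIN", "BACKBONE_CA"),
    bead_row(2L, "BB", 1L, "GLY", 1L, "PROTEIN", "BACKBONE_CA"))
  expect_error(membrane_system(beads2, c(10, 10, 10)), "exactly one BACKBONE_CA")
  beads3 <- bead_row(c(1L, 1L), "BB", c(1L, 2L), "GLY", 1L, "PROTEIN",
                     "BACKBONE_CA")
  expect_error(membrane_system(beads3, c(10, 10, 10)), "unique")
})
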