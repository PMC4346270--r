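#!/usr/bin/env Rscript
# Stage 6: pore-radius profile and system-composition accounting.
#
# The sphere-fitting profiler is run on the stage-1 protein (a hollow ring,
# so its lumen is wide open) and on a reference hollow-cylinder geometry
# with a known closed-form radius; the composition helpers reproduce the
# lipid-exchange bookkeeping (two POPC consumed per cardiolipin) and the
# neutralizing-ion arithmetic for the standard bacterial mixture.

suppressPackageStartupMessages(library(memlip))
dir.create("results", showWarnings = FALSE)

sys <- load_system("results/data/bilayer.gro", "results/data/annotation.csv")
traj <- load_trajectory("results/data/bilayer.trj", sys)
frame1 <- get_frame(traj, 1L)
com <- colMeans(frame1$positions[sys$beads$species == "PROTEIN", ])
pp <- pore_profile(frame1, sys, axis_point = com, z_range = c(-2, 2),
                   step = 0.5)
write.csv(as.data.frame(pp), "results/pore_profile.csv", row.names = FALSE)
cl <- pore_is_closed(pp)
cat("Ring-protein lumen: min radius", format(cl$min_radius_A, digits = 3),
    "A at z =", cl$z_at_min_A, "A; closed:", cl$closed, "\n")

# Reference geometry: beads of radius 2 A on a 5 A ring -> pore radius 3 A
ref <- local({
  n <- 24; ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  beads <- data.frame(bead_id = seq_len(n), name = "BB",
                      residue_id = seq_len(n), residue_name = "GLY",
                      molecule_id = 1L, species = "PROTEIN",
                      roles = "BACKBONE_CA", vdw_radius_A = 2,
                      stringsAsFactors = FALSE)
  s <- membrane_system(beads, c(4, 4, 4))
  pore_profile(cbind(2 + 0.5 * cos(ang), 2 + 0.5 * sin(ang), 2), s,
               axis_point = c(2, 2, 2), z_range = c(0, 0), step = 0.5)
})
cat("Hollow-cylinder reference radius:", format(ref$radius_A, digits = 4),
    "A (closed form: 3.0 A)\n")

# Composition accounting: build the 75/20/5 mixture from a POPC template
plan <- plan_lipid_exchange(
  list(INNER = 1:200, OUTER = 201:400),
  list(INNER = c(POPE = 150, POPG = 40, CL = 5),
       OUTER = c(POPE = 150, POPG = 40, CL = 5)),
  seed = 2024)
comp <- do.call(rbind, lapply(names(plan$counts), function(lf)
  data.frame(leaflet = lf, t(plan$counts[[lf]]))))
write.csv(comp, "results/exchange_plan_counts.csv", row.names = FALSE)
cat("\nLipid exchange per leaflet (200 POPC -> 150 PE + 40 PG + 5 CL):\n")
print(comp)

ions <- neutralizing_ions(c(-84, -42, 6), n_cl = 176)
cat("\nNeutralization: charges (-84, -42, +6) e with 176 Cl- require",
    ions$n_na, "Na+ (residual", ions$residual_charge_e, "e)\n")
write.csv(data.frame(n_na = ions$n_na, n_cl = ions$n_cl,
                     residual_e = ions$residual_charge_e),
          "results/neutralization.csv", row.names = FALSE)
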