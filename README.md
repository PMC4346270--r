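# memlip

Lipid–protein interaction analysis for membrane trajectories.

Membrane transporters in bacterial inner membranes sit in a mixed bilayer
(typically ~75% POPE, 20% POPG, 5% cardiolipin), and the anionic species —
cardiolipin above all — bind discrete basic sites on the protein surface
rather than mixing ideally. Characterizing that behavior from a coordinate
trajectory is a standard but fiddly pipeline: contact detection with
per-species cutoffs, residence-time extraction, annular enrichment,
lateral diffusion, superposition metrics, and pore-radius profiling.
memlip implements that pipeline as tested, reusable R functions for
computational membrane biophysicists, together with a synthetic-bilayer
generator with exactly known ground truth so every estimator can be
validated against closed-form expectations instead of irreproducible
simulation output.

## The quantities it computes

* **Occupancy** ζ<sub>ij</sub>(t) = 1 if d<sub>ij</sub>(t) ≤ δ, else 0,
  where d<sub>ij</sub> is the minimum-image distance between binding site
  *i* (a two-residue anchor representation) and the nearest head-group
  bead of lipid species *j*. Defaults: δ = 0.7 nm (POPE/POPG), 0.8 nm
  (cardiolipin, residue level), 1.1 nm (cardiolipin, site level);
  sampling every 0.3 ns, no smoothing.
* **Binding events and residence**: maximal runs of ζ = 1 (species-level
  continuity), with censoring flags, top-k longest stretches, a
  cutoff-sensitivity scan over δ = 0.8–1.6 nm, and single-lipid exchange
  counts (identity changes between consecutive single-occupant samples).
* **Enrichment ratio** S = mean density (0–3 nm) / mean density
  (3.5–6 nm) around the protein center of mass, per leaflet and species,
  with the protein footprint masked; plus a site-local variant over the
  binding-site capture discs.
* **Lateral diffusion** D from the Einstein relation MSD = 4Dτ on
  unwrapped, time-origin-averaged lateral displacements.
* **Superposition metrics**: Kabsch (SVD) RMSD, RMSF about the trajectory
  mean, and the gate-motion probe distance after a core-domain-only fit.
* **Pore profile**: at each position along the transport axis, the radius
  of the largest sphere that fits without overlapping any protein bead;
  RED/GREEN/BLUE bands at 1.15 and 2.3 Å (below 1.15 Å the path is
  closed).
* **Composition accounting**: a seeded lipid-exchange plan from a POPC
  template (two POPC consumed per cardiolipin) and neutralizing-ion
  arithmetic.

## Worked example

Generate the default reduced-scale inner-membrane mimic (400 lipids,
75/20/5% POPE/POPG/CL, three cardiolipin sites on a static protein disc)
and run the core analyses:

```r
library(memlip)
params <- synth_params(n_steps = 5000, record_every = 5, seed = 42)
gen <- generate_membrane(params)
gen$system
#> membrane_system: 442 beads, box 14 x 14 x 6 nm
#>   species: CL=20, POPE=300, POPG=80, PROTEIN=42

sites <- sites_from_truth(gen$truth)
os <- occupancy_series(gen$trajectory, gen$system, sites[[1]], "CL")
mean(os$zeta)                       # fraction of frames site 1 holds a CL
#> 0.723
ev <- extract_events(os)
mean_residence(ev)
#> $mean_ns: 58.3   $n_events: 15
longest_events(ev, 3)[, c("start_ns", "end_ns", "duration_ns", "exchanges")]
#>    start_ns end_ns duration_ns exchanges
#> 14    921.0 1303.5       384.0         0
#> 9     573.0  849.0       277.5         0
#> 7     367.5  558.0       192.0         0

enrichment_ratio(gen$trajectory, system = gen$system,
                 species = "POPG", leaflet = "INNER")
#> enrichment S = 1.506 (POPG, INNER leaflet, annulus variant)

dr <- msd_diffusion(gen$trajectory, gen$system, "POPE")
dr$D_cm2_s                          # input was 6.2e-7 cm^2/s
#> 5.7e-07

neutralizing_ions(c(-84, -42, 6), n_cl = 176)$n_na
#> 296
```

Site 1 is occupied by a cardiolipin most of the time and its longest
continuous stretches run to hundreds of ns with no exchange of the bound
lipid — the signature of a specific site rather than annular crowding —
while POPG shows diffuse annular enrichment (S > 1). The short run
deliberately under-samples residence (15 events); the validation suite
uses ~1000 events.

## The analysis workflow

`analysis/` contains the numbered end-to-end study on the synthetic
system; each stage reads the previous stage's files and writes tables
under `results/`:

1. `01_simulate_bilayer.R` — generate and write structure/annotation/
   trajectory/ground truth.
2. `02_contacts_occupancy.R` — occupancy series, residue contact
   profiles (both normalizations), lipids-in-contact counts.
3. `03_residence_exchange.R` — binding events, residence summaries,
   longest stretches, cutoff sensitivity, exchange statistics.
4. `04_density_enrichment.R` — density maps and annulus/site-local S.
5. `05_motion_metrics.R` — MSD/diffusion, RMSD/RMSF, gate-probe demo.
6. `06_pore_composition.R` — pore profile and composition accounting.

`run_pipeline()` exposes the same stages as one configurable call.

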