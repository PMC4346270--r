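---
title: "Methods: lipid-protein interaction analysis on membrane trajectories"
author: "memlip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid-protein interaction analysis on membrane trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

memlip quantifies how individual lipid species interact with a membrane
protein in a coordinate trajectory: binding-site occupancy and residence,
per-residue contacts, annular enrichment, lateral diffusion, rigid-body
superposition metrics, and the pore-radius profile along the transport
axis. Because public trajectory data for this class of problem is scarce,
the package ships a synthetic bilayer generator with exactly known ground
truth; every estimator is validated against closed-form expectations of
that generator rather than against irreproducible simulation output.

Internal units are nm and ns throughout. Van der Waals radii and pore radii
are expressed in Angstrom at the reporting boundary only, which is how pore
profiles are conventionally printed.

# The occupancy model

A binding site is represented by two anchor residues (for example the
arginine pair of a cardiolipin site on a transporter's cytosolic face). For
a site $i$ and lipid species $j$, the site-lipid distance $d_{ij}(t)$ is
the minimum over all beads of the two anchor residues and all head-group
beads of the species, using minimum-image distances in the periodic box.
The occupancy indicator is

$$\zeta_{ij}(t) = \begin{cases}1 & d_{ij}(t) \le \delta \\ 0 &
d_{ij}(t) > \delta\end{cases}$$

with the boundary counting as contact. Default cutoffs follow
coarse-grained practice: $\delta = 0.7$ nm for POPE/POPG; for cardiolipin
0.8 nm at residue level and 1.1 nm for site occupancy, the larger value
accommodating both its two-phosphate head group and the rattling-in-a-cage
motion of a bound lipid. Trajectories are resampled to a 0.3 ns interval by
nearest-frame selection — never interpolation — and no smoothing is ever
applied, so fast binding/unbinding events survive unaltered. Which beads
constitute a "head group" is a per-species annotation decision: the
phosphate bead for POPE/POPG/POPC, and both phosphate beads (plus the
central glycerol, when present) for cardiolipin.

A binding event is a maximal run of $\zeta = 1$ samples. Occupant identity
may change within an event: continuity is at the species level, which is
the convention that makes residence comparable across species with very
different exchange rates. Duration is the number of samples times the
interval, so an isolated one-sample contact lasts 0.3 ns. Events touching
the first or last frame are flagged censored and excluded from
mean-residence estimates (their true length is unknown; exclusion avoids
downward bias at the cost of discarding the longest events in short runs).
The mean-residence estimator subtracts one sampling interval from each
completed duration: a capture is first seen on the sample at which it
occurs, so under exponential escape with mean $\tau$ the expected number
of occupied samples is $1/(1 - e^{-\Delta t/\tau})$, and the subtraction
brings the estimator within half an interval of $\tau$.

Single-lipid exchanges within an event are counted on the subsequence of
samples with exactly one occupant: each identity change between
consecutive such samples is one exchange, and the single-occupancy
fraction is single-occupant samples over occupied samples. Multi-occupant
samples are excluded because an exchange is only well defined between sole
occupants.

The cutoff-sensitivity scan recomputes events over a grid of cutoffs
(default 0.8 to 1.6 nm, the range over which cardiolipin site lifetimes
are conventionally examined). Since enlarging $\delta$ can only add
contact frames, the longest-event duration is non-decreasing in $\delta$
— a structural property the tests assert.

# Contact profiles

The raw contact count of a (residue, species) pair counts, over sampled
frames, the lipids whose nearest head-group bead is within the species
cutoff of any bead of the residue, at most once per lipid per residue per
frame. Two normalizations are provided. The per-lipid-frame-volume mode
divides by the number of lipids of the species, the number of frames, and
the cutoff-volume ratio $(\delta_s/\delta_{\mathrm{ref}})^3$; the
reference cutoff is fixed at 0.7 nm (the PE/PG value), so that the PE/PG
divisor is one and cardiolipin's larger search volume does not inflate its
counts. The max-residue mode divides by the species' largest per-residue
count, putting the most-contacted residue at exactly 1 and untouched
residues at 0. The lipids-in-contact counter is the molecule-level
variant: a lipid is in contact when any head-group bead is within the
species cutoff of any protein bead, counted once per frame.

# Density maps and the enrichment ratio S

Lateral number-density maps are accumulated per leaflet and species after
rigidly superposing each frame's protein backbone onto the first frame, on
a 0.2 nm grid (fine enough to resolve the roughly 0.5 nm concentric
packing rings around a protein). Leaflets are assigned from head-group
height about the bilayer midplane (the mean head-group $z$); a lipid
exactly on the midplane falls back to its molecule-mean $z$, and a
remaining tie goes to the inner leaflet.

The enrichment ratio divides mean densities in two annuli around the
protein center of mass:

$$S = \frac{\bar\rho(0\text{–}3\ \mathrm{nm})}
           {\bar\rho(3.5\text{–}6\ \mathrm{nm})}$$

with $S > 1$ indicating enrichment. Two implementation choices matter and
are exposed as options. First, the protein footprint — modeled as the
minimal enclosing circle of the backbone beads' lateral coordinates — is
excluded from the near annulus by default, because lipids cannot occupy
it; with masking on, a uniform bilayer gives $S = 1$, while without
masking the footprint dilutes the near annulus and $S < 1$. Both modes are
tested so the choice is documented behavior, not an accident. Second, when
computed directly from a trajectory, $S$ uses exact counts over exact
annulus areas rather than grid cells, avoiding discretization bias at the
annulus edges; the grid route exists for map-based workflows and agrees
within grid resolution. The site-local variant replaces the near annulus
with the capture discs of the binding sites (clipped to the accessible
region outside the footprint circle, via the two-circle lens formula),
which isolates the raised density at discrete sites from diffuse annular
enrichment.

# Diffusion, superposition, and the gate probe

Lateral mean square displacement is computed on unwrapped head-group
centroids (minimum-image displacements between consecutive frames,
accumulated), averaged over lipids and all time origins, and the
diffusion constant follows from $\mathrm{MSD} = 4D\tau$ by least squares.
The default fit window is 10–50 % of the maximum lag, the standard
compromise that avoids the poorly averaged tail; recovery benchmarks use
an earlier window (1–8 % of maximum lag) because overdamped dynamics have
no ballistic regime to avoid and early lags carry many more independent
intervals, making the slope estimate much tighter at the same cost. A
residual diagnostic flags visibly non-linear MSD curves (linear-fit
$R^2 < 0.99$), which catches ballistic drift ($\mathrm{MSD} \propto
\tau^2$).

Rigid superposition is the SVD solution of the orthogonal Procrustes
problem with the determinant correction that forbids reflections; it is
cross-checked in the tests against an independent brute-force rotation
search and against an established structural-bioinformatics
implementation. RMSF superposes every frame on the trajectory mean
(computed by aligning to the first frame, averaging, then refining once
against that mean). The gate probe fits only the core-domain backbone to a
reference structure and reports the probe residue's displacement from its
reference position — the standard readout for rigid-body gate motion; the
default probe residue is 350, the conventional choice on the transporter
this analysis style comes from, and the core/gate selections are
user-supplied configuration.

# Pore profile

At each plane along the transport axis the profiler maximizes
$f(x, y) = \min_k (\lVert c - b_k \rVert - r_k)$ over plane positions
$c = (x, y, z)$, i.e. the radius of the largest sphere centered in the
plane touching no protein bead. Only beads within 10 A of the plane (plus
their own radius) constrain it, but full 3D distances are used, matching
the spherical-probe formulation. The search is a 0.5 A coarse grid within
5 A of the previous plane's optimum (channel continuity; seeded on the
axis), followed by Nelder-Mead refinement confined to the same disc —
unconstrained refinement would escape through any occlusion. The fixture
tests verify the closed-form hollow-cylinder answer to 0.05 A. Radii map
to bands at 1.15 and 2.3 A (below 1.15 A the path is effectively closed;
above 2.3 A it passes water); the boundaries are read strictly, so a
plane at exactly 1.15 A is not closed. Radii can be negative where beads
overlap the whole search region; they are clamped to zero for banding but
reported raw.

# The synthetic bilayer generator

The generator is the package's ground-truth instrument, built so that
every analysis target has a closed-form expectation:

* **Geometry.** A lateral box (default 14 x 14 nm) with two leaflet planes
  at $\pm z_0$ (default 2 nm) about the midplane; a static protein disc of
  radius 2 nm at the center, rendered as three stacked rings of backbone
  beads plus two co-located anchor residues per site carrying
  crystal-style labels (R4/R299, K109/R265, K321/W212). Co-locating the
  anchor pair at the site anchor point makes the two-residue site
  representation exact with respect to the capture geometry.
* **Composition.** Default 75/20/5 % POPE/POPG/CL per leaflet, 400 lipids
  — the canonical bacterial inner-membrane mixture at reduced scale. Each
  lipid is a single head-group bead confined to its leaflet plane.
* **Free dynamics.** Metropolis-adjusted Brownian steps: Gaussian
  proposals with variance $2 D_s \Delta t$ per axis, rejection inside the
  protein disc, acceptance $\min(1, e^{-\Delta u})$ against an annular
  well $u(r) = -\varepsilon_s$ for $r$ in the well annulus (default: the
  accessible near annulus, 2–3 nm). Metropolis rather than Langevin
  dynamics is a deliberate choice: detailed balance gives the exact
  equilibrium density $\rho \propto e^{-u}$, so the enrichment estimator
  has the closed-form target $S = e^{\varepsilon}$, while the free
  diffusion constant remains $\approx D_s$ for small steps (the
  acceptance-derived bias at the default step is below the estimator's
  resolution away from obstacles). Default diffusion constants are 6.2,
  5.9 and 4.5 x 1e-7 cm^2/s for POPE, POPG and CL, the protein-free
  values typical of coarse-grained bilayers of this composition; the time
  step is 0.3 ns, matching the analysis sampling interval.
* **Well depth.** The well accepts a per-species depth (a scalar is
  recycled). Defaults $\varepsilon$ = -0.35, +0.25, +0.15 kT for
  POPE/POPG/CL give flat-potential enrichment targets
  $e^{\varepsilon} \approx$ 0.70, 1.28, 1.16 — anionic enrichment and
  zwitterionic depletion, the qualitative annulus pattern of a bacterial
  membrane around a basic-belted protein.
* **Binding.** An unbound lipid within the capture radius $r_c$ (default
  0.8 nm) of a free site on its leaflet binds with probability
  $p_\mathrm{on}$ per step — capture needs both proximity and the coin,
  decoupling on-rate from off-rate. A bound lipid is resampled uniformly
  in the accessible part of the cage disc each step (the rattling motion)
  and escapes with probability $1 - e^{-\Delta t/\tau_s}$, giving
  exponential, species- and site-specific residence. One occupant per
  site at a time; multi-occupancy still reaches the analysis through
  crowding near sites. On escape the lipid is relocated uniformly into
  the $r_c$–$2 r_c$ shell around the anchor: it has left the cage, and a
  fresh capture requires a fresh approach. Without this relocation an
  escaped lipid would still sit inside the capture zone and rebind almost
  surely, merging consecutive dwells and making the occupancy-derived
  residence unboundedly larger than $\tau$; the shell is the smallest
  displacement that restores the renewal structure the estimator assumes.
  Default site kinetics order cardiolipin residence site 1 > site 2 >
  site 3 (300/200/120 ns) above POPG (30/25/20 ns) above POPE
  (10/8/6 ns).
* **Initialization and determinism.** Initial positions are drawn from
  the exact single-lipid equilibrium by rejection sampling, so
  density-based estimators need no burn-in. Everything downstream of the
  seed is deterministic; the full binding-event log is returned as ground
  truth alongside anchor coordinates, leaflet labels, $e^{\varepsilon}$
  and the $\tau$ table.

What the generator deliberately does not emulate: lipid shape and tails,
lipid-lipid interactions and packing correlations, protein flexibility,
electrostatics, solvent, and inter-leaflet motion. Passing tests therefore
demonstrate estimator correctness — that the analysis recovers known
dynamical and thermodynamic parameters from trajectories with the assumed
statistical structure — not the fidelity of any force field. On real
trajectories the same estimators carry the usual caveats of their field:
residence times from coarse-grained dynamics are indicative rather than
absolute, and cutoff sensitivity should always be reported alongside
lifetimes.

# Validation problem sizes

The test suite validates against ground truth at sizes where the
closed-form expectations are statistically sharp, chosen as study
conditions in their own right: enrichment recovery uses 1000 lipids for
50,000 steps with a $\ln 2$ well (target $S = 2$ within 5 %, and a flat
control within three block-averaged standard errors of 1); residence
recovery uses eight sites at moderate lipid density collecting about a
thousand completed events ($\tau = 30$ ns recovered within 10 %; the
density is kept low because a second lipid wandering through an occupied
site extends species-level events and would bias the mean upward);
diffusion recovery uses 200 lipids for 8,000 steps with a negligible
protein footprint (input recovered within 5 %; the footprint is removed
because obstructed diffusion is genuinely slower than free diffusion —
an excluded-area effect, not an estimator error). The knockout experiment
runs wild-type, single-knockout and all-knockout systems for 100,000
steps and checks that a knocked-out site's occupancy collapses to the
passage background while the untouched site's mean residence is
unchanged within sampling error — the in-silico mutant logic.

# Composition accounting

The lipid-exchange planner converts a POPC template bilayer to a target
mixture by uniformly random replacement under a seed, consuming one POPC
per POPE/POPG and two per cardiolipin (its two diacylphosphatidic-acid
moieties each take a slot), so molecule count shrinks by one per CL. The
neutralizing-ion helper balances integer charge contributions with
monovalent salt: with a fixed anion count the cation count follows
exactly, and with a molarity specification the anion count is
$\mathrm{round}(M \cdot N_\mathrm{water}/55.5)$ first. The worked
composition — POPG $-84\,e$, CL $-42\,e$, protein $+6\,e$, 176 Cl$^-$,
hence 296 Na$^+$ — is asserted exactly.

# Known limitations

* Only the plain-text trajectory format and GRO/PDB structures are read;
  compressed binary trajectory formats (XTC/TRR/DCD) have no reader in
  this environment and must be converted externally.
* The density-map grid route inherits edge bias from cells straddling the
  footprint and annulus boundaries; the count-based route is exact and is
  the default for $S$.
* The footprint is modeled as a disc (minimal enclosing circle); strongly
  non-circular proteins would need a polygonal mask.
* Event censoring discards information; for runs much shorter than the
  residence time, a survival-model treatment would be preferable and is
  out of scope.
* The per-frame superposition in the density map assumes the protein is
  rigid enough for a backbone fit; large conformational changes would
  smear the map.
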