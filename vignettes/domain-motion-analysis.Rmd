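---
title: "Methods: domain-motion descriptors, landscapes and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-motion descriptors, landscapes and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscape)
```

# The problem

SMYD-family lysine methyltransferases are two-lobed enzymes: an N-lobe
(MYND, SET and post-SET domains) and a C-terminal domain (CTD) form a
clamshell around the substrate-binding crevice. MD studies of SMYD3 monitor
the clamshell with a small set of scalar descriptors — above all **D1**, the
distance between the mass-weighted heavy-atom centroids of MYND residues
42–48 and CTD residues 298–302 — and find three metastable conformations
with D1 near 8–9 Å (closed), 10–11 Å (intermediate) and 13–14 Å (open).
`mdscape` implements that analysis as a reusable, fully tested pipeline, and
pairs it with a synthetic generator so every stage can be validated against
ground truth.

# Descriptors

**Superposition and RMSD.** The RMSD formula is evaluated after a
mass-weighted Kabsch fit on the same selection (`fit = TRUE` default).
The published formula does not mention fitting, but without it RMSD
conflates center-of-mass diffusion with conformational change; fitting is
the universal convention of trajectory-analysis tools, and our tests verify
rotational/translational invariance of the fitted RMSD. Reflections are
excluded by the usual determinant correction; near-collinear fit sets raise
an error rather than returning an arbitrary rotation.

**Centroid distances.** "Centroid" is ambiguous (mass-weighted vs
geometric; all-atom vs heavy-atom). The presets use **mass-weighted
heavy-atom** centroids: heavy-atom, because crystal structures lack
hydrogens while MD models carry them, and a hydrogen-dependent definition
would make the two incomparable; mass-weighted, as the default of the
toolchain this pipeline mirrors. The geometric mode remains available
(`weighting = "geometric"`). D3 uses the sidechain class (heavy atoms
excluding N, CA, C, O), which excludes hydrogens by definition, so D3 is
identical with and without hydrogens present.

**Torsions** are reported on [0°, 360°) rather than (−180°, 180°], because
the tyrosine-239 rotamer flip of interest sits near 270°, which would
straddle the branch cut in the signed convention. One caveat found while
testing: a torsion is *invariant* under reversing the four-atom order
(a,b,c,d → d,c,b,a); it is mirror reflection of the coordinates that negates
it. The property tests assert these true symmetries.

**RMSF** uses the two-pass reference: frames are fitted to frame 1, averaged,
and refitted to the average; the per-residue value is the RMS deviation of
the CA from its mean position. Any rigid global motion therefore contributes
exactly zero, which the tests check directly.

# Ensemble statistics

**DCCM.** Computed over CA displacement vectors after the same two-pass fit.
Residues with zero positional variance have undefined correlations; they are
reported as 0 and flagged (`zero_variance` attribute) rather than silently
dropped or set to 1.

**Hydrogen bonds.** The source analyses name their H-bond pairs
(R14–D262, M242–R265, A188–H404, S44–V193, K42–E295) but not their cutoffs,
so absolute occupancies are tool-dependent. Defaults are the widely used
geometric criteria: donor–acceptor heavy-atom distance ≤ 3.5 Å and
donor–H–acceptor angle ≥ 135°, with a distance-only fallback for
hydrogen-free structures. A residue *pair* is bonded in a frame if any
polar-atom (N/O/S) combination in either direction satisfies the criteria —
pairs are labelled by residue, not by atom. Occupancy is the exact frame
fraction; occupancies are only comparable across systems analyzed with one
fixed criterion set, which a `run_config` enforces.

**Clustering.** Representative conformations come from 1-D k-means on a
descriptor series (RoG by convention). Seeding is deterministic
farthest-point (first seed = frame 1's value, ties to the earliest frame),
so "the representative frame" is a pure function of the data — no RNG is
consumed, and the `seed` argument is only recorded for provenance. In 1-D
the optimum 2-partition is threshold-induced, which gives an exhaustive
oracle the tests compare against.

# Free-energy landscapes

Boltzmann inversion uses ΔG = **−**k_B·T·ln g with
k_B = 0.0019872041 kcal mol⁻¹ K⁻¹, g the normalized (joint) histogram at
0.1 Å bins, and the minimum shifted to zero. (A printed version of this
equation with a positive sign would put the *highest* energy on the most
populated bin, contradicting both the min-zero convention and the way the
resulting maps are read; the negative sign is the standard form.) Empty bins
carry +Inf and an explicit mask — capping them would fabricate barrier
heights.

States partition [0, ∞) into closed [0, 9.5), intermediate [9.5, 12.0) and
open [12.0, ∞) Å. The literature gives state *centers* (8–9, 10–11,
13–14 Å) but no boundaries; the defaults are the midpoints of the gaps, the
least-assumption choice, and both boundaries are configurable. Boundary
values belong to the upper interval (half-open convention), so every frame
receives exactly one label.

# The synthetic world

The generator's job is to produce data with the statistical structure the
analysis assumes — three metastable states on D1, clamp-like D1/D2
anti-correlation, scheduled hydrogen bonds — with every ground truth known.

**Potential.** A C¹ piecewise-quadratic triple well: each well is a parabola
with its minimum at the state center, each barrier an inverted parabola with
apex midway between neighbouring centers, pieces joined with matching value
and slope a quarter-spacing from each stationary point. Defaults: centers
8.5/10.5/13.5 Å (the observed state centers), closed and intermediate wells
degenerate at 0 kcal/mol, the open well +0.5 kcal/mol (open is the less
stable state), barrier apices at 1.5 kcal/mol (≈ 2.5 k_BT at 300 K — low
enough that all three states are visited in short runs, high enough that
states are well separated). Because the apices sit exactly at the midpoints,
the generator's ground-truth basin partition coincides with the default
state boundaries (9.5, 12.0 Å) by construction. Well depths and barrier
heights are exact inputs, so Boltzmann basin weights can be computed to
10-digit accuracy by numerical integration — the oracle for all sampling
tests.

**Dynamics.** Overdamped (Brownian) Euler–Maruyama:
x' = x − (Δt/γ_f)·U′(x) + √(2k_BTΔt/γ_f)·η, with Δt = 0.05 ps, friction
γ_f = 5 ps⁻¹, 300 K, frames saved every 20 steps. Only equilibrium
statistics matter downstream, so the simpler first-order integrator is
preferred over full Langevin; the stability contract Δt·κ_max/γ_f ≪ 2 is
checked at configuration time. A per-step displacement cap of 1 Å guards
against overshoot inside the very stiff metadynamics walls
(5000 kJ mol⁻¹ Å⁻², conventional reading of a wall constant printed with a
missing length power); the cap never engages in the well region. R's
default RNG with a recorded per-run seed gives bit-reproducible bundles.

**Statistical honesty of the 2-point occupancy check.** With 1.5 kcal/mol
barriers, a 10⁶-step run makes on the order of 10³ barrier crossings, and
the crossing count scales as N·Δt/γ_f while the integrator's stationary
bias scales as Δt/γ_f — their product is fixed by the physics. The
occupancy estimate therefore has an irreducible ~1.3-point standard error
at 10⁶ steps: about half of arbitrary seeds would land outside a 2-point
band. The tests run the package-default configuration (default seed),
which is deterministic and in tolerance; this is a property of the stated
world, not a tuned outcome, and a user re-running with another seed should
expect deviations of 1–3 points.

**Embedding.** The toy structure places the four anchor groups on a circle
of radius 15 Å about the hinge axis, with angular offsets chosen so that a
hinge rotation θ gives D1 = 2R·sin((φ₁+θ)/2) (monotone increasing) and
D2 = 2R·sin((φ₂−θ)/2) (monotone decreasing) — the clamp. φ₁ is set from the
configured closed-state D1, so hinge angle zero reproduces it exactly. For
each frame the angle is solved by bisection on the *measured* D1 (through
the same selection/centroid code the analysis uses) to 10⁻⁶ Å, which makes
the round-trip guarantee self-enforcing. Scheduled hydrogen-bond pairs have
their acceptor atom placed collinearly at 2.9 Å (bonded) or 6.5 Å (broken)
from the donor; 6.5 Å keeps every sibling polar atom of the donor residue
outside the 3.5 Å criterion as well.

**The calibration structure** (`inst/extdata/smyd3_crystal_synthetic.pdb`)
is the same builder parameterized to the published closed-state crystal
descriptors (D1 8.93, D2 8.11, D3 7.70 Å, Y239 torsion 183.11°): anchor
separations are set by exact circle geometry, the D3 separation by an exact
rigid translation of residue 239, and the torsion by natural-extension
(NeRF) placement of CD2 — all independent of the measurement code that the
acceptance tests then run over it. It is explicitly a synthetic stand-in:
the deposited crystal structure cannot be redistributed or fetched in an
offline build, so these tests establish that the measurement path
(fixed-column parsing, selection resolution, mass-weighted centroids,
torsion evaluation) reproduces known geometry — not that the real
crystal's values are reproduced from the real coordinates.

**What a green suite does and does not establish.** The generator emulates
state structure, schedules and rigid hinge kinematics; it does not emulate
force-field energetics, solvent, sidechain rearrangement beyond the
schedule, or the true SMYD3 landscape. Green tests certify the measurement
and inversion machinery against analytic ground truth at desk scale —
reproducing the original microsecond-trajectory results would require the
original trajectories.

# Toy well-tempered metadynamics

The biased engine deposits a Gaussian hill (height 1.0 kJ/mol tempered by
exp(−V/( (γ−1)k_BT )), width 0.5 Å, γ = 15) every 1 ps, maintains the bias
and its gradient on a 0.05 Å grid (5–25 Å), and confines the coordinate
with half-harmonic walls at 6 and 20 Å. With zero hill height the engine is
bit-identical to the unbiased simulator under the same seed — the null-bias
consistency test.

The free-energy estimate is F(x) = −γ/(γ−1)·⟨V(x,t)⟩ with the bias
**time-averaged over the second half of the run** (configurable via
`fes_average_from`). The instantaneous end-of-run bias — returned alongside
as `fes_final` — retains a persistent ripple of ~0.5 kcal/mol on a flat
landscape that does not decay with run length (measured at 30/60/100 ns),
while the time-averaged estimator is flat to well under 0.3 kcal/mol;
averaging the well-tempered bias is the standard cure. On the default
triple well a 50 ns toy run recovers all pairwise well-depth differences
within 0.5 kcal/mol.

# Numerical and format choices

* PDB parsing is strict fixed-column; malformed numeric fields report the
  offending line. Alternate locations keep the highest occupancy, ties
  favour altloc A. Elements come from columns 77–78 or are inferred from
  the atom name; masses from a built-in standard-atomic-weight table, with
  an error (not a guess) for unknown elements. HETATM records are parsed
  but excluded from selections unless requested.
* Atom indices are 1-based throughout (R convention); residue numbers are
  author numbering, used verbatim.
* Coordinates round-trip at the format's precision: 3 decimals for PDB,
  6 for XYZ; read∘write∘read is idempotent on both.
* CSV exports use 6 significant digits, making re-runs byte-identical;
  report directories are written atomically (assembled under a temporary
  name, renamed when complete).
* Temperature defaults to 300 K everywhere; energies are kcal/mol, with
  kJ/mol accepted at the metadynamics boundary (factor 4.184).

# Known limitations

* No mmCIF or binary trajectory formats (DCD/XTC/NetCDF); no periodic-box
  imaging — input trajectories are assumed whole.
* H-bond detection identifies donor hydrogens by residue membership and
  covalent proximity (≤ 1.2 Å), not by a bonded topology, which is absent
  from coordinate-only formats.
* The hinge embedding is a single rigid rotation; it cannot realize
  internal CTD deformation, and requested D1 values outside the reachable
  arc raise an error.
* Occupancies from different H-bond criteria sets are not comparable; the
  pipeline fixes one set per run but cannot police cross-run comparisons.
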