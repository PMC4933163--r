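---
title: "Models and methods behind cetransit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cetransit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetransit)
```

`cetransit` analyses cholesteryl-ester (CE) transit through the
hydrophobic tunnel of CETP: the geometry and chemistry of the transfer
pathway, the kinetics of forced transfer, and the biophysical model that
links lipoprotein particle physics to a physiological transfer rate.
This vignette is the package's own account of those models — what is
assumed, which parameters matter, how the numerics are done, and what
the synthetic-data generators do and do not establish.

## The transfer-pathway model

A transfer path is an ordered sequence of 3-D points with cumulative
arclength, spaced at most 2 Å apart — typically the ligand centroid
track through the tunnel, or the axis of a synthetic barrel. Three
profiles are computed along it.

**Diameter.** At each path point `p`, the local clearance is the radius
of the largest sphere that fits at any center `c` within the probe
radius of `p`:

```
r(p) = max_{|c - p| <= probe} min_i ( |c - x_i| - r_i )
```

where `x_i`, `r_i` are atom centers and van der Waals radii. The
diameter is `2 r(p)`, clamped at zero. A point is *open* when
`r(p) >= interior_threshold`. The defaults — probe radius 3.0 Å,
interior threshold 1.25 Å — are the standard channel-profiling settings
for a CE-sized cargo; the threshold is read as the minimum sphere radius
for a position to count as channel interior, which is how
channel-profiling tools conventionally use it.

The maximisation is deterministic: candidate centers on a 0.25 Å cubic
lattice inside the probe ball, followed by one refinement pass on a
five-fold finer lattice around the best coarse candidate, constrained to
the ball. Refinement can only improve the coarse value, and the path
point itself is always a candidate, so the refined clearance never drops
below the unrefined point clearance. The 0.25 Å lattice matches the
grid resolution used elsewhere in the package for molecular volumes.
Because the probe center may move anywhere in its ball, a constriction
narrower along the axis than the probe radius is "seen past": only
constrictions that outspan the ball register their full depth. Path
points farther than 50 Å from every atom are flagged `outside` rather
than profiled.

**Pathway search.** `path_search()` is a greedy step-by-step tracer:
from the current point, candidate points one step length away within a
cone about the previous direction are scored by their point clearance,
and the walker moves to the best one. The search succeeds when the exit
predicate holds and declares a dead end when no candidate keeps
clearance at or above the interior threshold, returning the partial path
flagged `terminated_early`. Candidate directions come from a
deterministic Fibonacci sphere (400 directions by default); ties break
toward the first candidate in that fixed order, so runs are exactly
reproducible. The cone half-angle (default 45°) is the only memory the
walker has; it prevents immediate backtracking but limits traceable
bends to the cone angle per step. The first step needs a direction: the
caller may supply one, otherwise the direction from the entry point to
the atom centroid is used — a reasonable default for an entry at a
tunnel mouth, and a documented arbitrary choice everywhere else.

**Contacts and hydrophobicity.** A residue contacts the ligand when any
of its atoms lies strictly within 2.4 Å (center-to-center) of any
ligand atom. The cutoff is the diameter of a hydrogen van der Waals
surface — two hydrogens touch when their centers are 2.4 Å apart —
which is the reading consistent with a center-to-center criterion.
Whether hydrogens participate in contact distances is a genuine open
choice when structures come from different preparation pipelines; the
`include_hydrogens` flag (default `TRUE`, since the cutoff is itself a
hydrogen diameter) makes the choice explicit.

The hydrophobicity profile assigns each 1 Å arclength bin the
SASA-weighted mean Kyte-Doolittle hydropathy of the contact residues:

```
value(bin) = sum_r w_r KD(r),   w_r = SASA(r) / sum_{r' in contacts} SASA(r')
```

Solvent-accessible surface areas are computed once, on the ligand-free
structure, by the Shrake-Rupley method: each atom's expanded sphere
(vdW + 1.4 Å water probe) is sampled with a deterministic
Fibonacci-spiral point set (960 points per atom by default; fewer than
50 is refused as an accuracy floor), and the accessible fraction scales
the analytic sphere area. Computing weights on the ligand-free
reference, rather than per conformation, treats the weights as intrinsic
residue exposures; the per-conformation alternative would couple the
profile to the ligand pose and is deliberately not the default. Values
are convex combinations of the contributing residues' scale values, so
they always lie within [−4.5, +4.5]. Bins whose frames make no contact
are flagged undefined rather than interpolated; multiple frames in a bin
are averaged first, then repeated trajectories are averaged with their
spread reported as `sd`.

**Orientation.** The cargo's orientation is tracked by a designated
reference bond (for a CE, the steroid-ring long axis). The reported
angle is `asin(|v . n|)` between the bond direction `v` and a reference
plane with unit normal `n`: 0° in-plane, 90° along the normal. The
default normal is the global path direction, so the default angle
measures how far the bond tilts out of the tunnel cross-sectional plane
toward the axis; any other convention is one explicit argument away. A
plane *containing* the axis — the "side view" convention of projection
figures — is rotationally underdetermined about the axis, which is why
it is not the default.

## Transfer kinetics

Forced-transfer times follow a power law in the driving force,
`t = A F^{-b}`. The fit is ordinary least squares of `log t` on
`log F` (natural logs; the slope is base-invariant): `b` is the negated
slope, `A` the exponentiated intercept, and `r` the Pearson correlation
of the log-log pairs. With replicate rows, every replicate enters the
fit (the default); with only per-force means available, one point per
force is used. The packaged 18-force summary table (forces 6-23
kcal/mol/Å, four pulls each, mean ± SD in ns) fits to `b = 2.80`,
`|r| = 0.989` under per-force means — close to, but not identical with,
the 2.75 and 0.96 obtained from the 72 individual replicate times, which
are not published. Exact replicate-level reproduction is therefore not
attainable from public data, and the package does not pretend
otherwise.

`predict_time()` evaluates the law at any positive force and flags
forces outside the fitted range as extrapolation — never silently,
because the physiological projection below extrapolates three orders of
magnitude.

## The Young-Laplace driving force

A lipoprotein particle is modelled as a curved monolayer of surface
tension `alpha` with internal excess pressure `P = 2 alpha / R`. Between
a donor HDL (R = 50 Å) and an acceptor LDL (R = 110 Å) at common
surface tension, the pressure difference is
`dP = 2 alpha (1/R_HDL - 1/R_LDL)`; acting on the tunnel's circular
cross-section of diameter 6 Å it produces a force
`F = dP pi (d/2)^2`, converted to kcal/mol/Å via
`1 kcal/mol/Å = 4184 / (N_A × 10^-10) N ≈ 6.948 × 10^-11 N`. Physical
constants are fixed, not configurable.

Assumptions worth stating: the cross-section is treated as a circular
disc of the measured 6 Å tunnel diameter — this reproduces the
0.018-0.029 kcal/mol/Å span at surface tensions 0.020-0.033 N/m,
whereas a 6 × 4 Å rectangular cargo cross-section would not, so the disc
is an inference, not a measurement; the low and high ends of the span
pair the low and high surface tension across *both* particles (a
common-tension assumption); and entropic contributions to the chemical
potential difference are outside the model. Forces are reported to two
significant figures, times to one, matching how such estimates are
meaningfully quoted; full precision is kept internally.

At those forces the fitted law predicts 0.008-0.03 s per CE molecule
(33-125 molecules/s per CETP). The radiolabel route — specific activity
75.7 nmol/h/µg with a 73 kDa CETP mass, or plasma flux 64 µg/h/ml with
1.75 µg/ml CETP and 651 Da CE — gives 1.14-1.54 CE molecules/s/CETP
(0.65-0.88 s per molecule), slower than the tunnel-transit prediction,
as expected when particle binding and penetration are not part of the
simulated step.

## Trajectory metrics

RMSD uses the Kabsch algorithm with the reflection guard: the smallest
singular direction is sign-flipped when needed so the rotation is always
proper (molecules are chiral; a mirror image is not a superposition).
Fewer than three points leaves the rotation underdetermined and is an
error. RMSF uses a two-pass reference: all frames are superposed onto
the first frame, the time-mean structure is formed, frames are
re-superposed onto that mean, and per-label fluctuations are measured
about it — so rigid-body motion contributes nothing. Molecular volume
counts 0.25 Å grid-cell centers inside the vdW union (overlaps counted
once). The radial-distribution first peak normalises the pair-distance
histogram by shell area (2-D) or volume (3-D) and returns the first
interior local maximum above the mean pair density; only the peak
*location* feeds downstream consumers, so the normalisation constant is
irrelevant to results but implemented anyway for interpretability.

## What the synthetic generators emulate

The generators exist so that every analysis step has a fixture with a
known answer:

- `make_barrel()` places staggered atom rings so that the clearance at
  the axis equals the requested inner radius *by construction* — ring
  atom centers sit at `inner_radius + atom_vdw`. The 1 Å ring spacing
  and 16 atoms per ring keep the between-ring and between-atom sag of
  the clearance below 0.05 Å, so `diameter_profile()` must recover the
  specified profile within 0.1 Å. This is the package's strongest
  oracle: the expected value comes from geometry, not from the code
  under test.
- `make_ligand_trajectory()` moves a rigid ligand along a path with a
  scheduled reference-bond orientation, giving `orientation_angle()`
  step-function ground truth.
- `sample_transfer_times()` draws replicate times
  `A F^{-b} exp(eps)`, `eps ~ N(0, sigma^2)`. The noise is
  multiplicative log-normal because in the published summary table the
  replicate SDs scale roughly with the means (≈0.4 at 5 ns down to
  ≈0.01 at 0.1 ns); `sigma = 0.3` reproduces that pattern at the
  published design (18 forces, 4 replicates). Under those conditions
  the fitted exponent lands within ±0.3 of truth in ≥95% of seeded
  repetitions.
- `langevin_first_passage()` is a 1-D overdamped surrogate for a
  steered pull: `x <- x + (F/gamma) dt + sqrt(2 kBT dt / gamma) N(0,1)`,
  reflecting at the entry (the cargo cannot leave backwards), absorbing
  at the exit, `kBT` computed from the temperature (0.616 kcal/mol at
  310 K). Walkers that exceed `max_steps` are flagged non-passages and
  excluded with a count, not silently dropped. Its closed forms anchor
  the tests: mean passage `gamma L / F` in the drift regime
  (`F L >> kBT`) and `L^2 gamma / (2 kBT)` at zero force. Note the
  surrogate's force exponent is 1 (drift-dominated), not the ≈2.75 of
  the all-atom tunnel — the surrogate validates the *pipeline*, not the
  physics of CE transfer.
- `make_monolayer_lattice()` jitters a hexagonal lattice of
  headgroup-like points so the RDF first peak has a known location.

Passing these tests shows the geometry, statistics and plumbing are
correct on structures whose answer is known. It does *not* show that a
real CETP structure yields a 6 Å neck, nor that real steered simulations
yield `b = 2.75`: those quantities require the all-atom system, which is
out of scope here. The published per-force summary table is the one
piece of real data the package ships and refits.

## Numerical choices and degenerate inputs

- All internal lengths are in Å; no unit conversion happens inside
  geometry code. Unit conversions live exclusively in the biophysics
  layer.
- PDB I/O is fixed-column v3.3: ATOM and HETATM records only (tunnel
  cargo and lipids are HETATM), altLoc other than blank/'A' skipped,
  coordinates written to 3 decimals (magnitudes ≥ 10^5 Å refuse to
  write rather than overflow columns), malformed numeric fields error
  with the offending line number, and unknown elements error rather
  than receiving a silent default radius. The default radius set is
  Bondi's compilation — the de-facto standard — overridable by any
  named table, including one read from a two-column text file.
- Random-number use is seeded everywhere and generator calls restore
  the caller's RNG state, so pipeline reruns are byte-identical
  (manifests contain no timestamps for the same reason).
- Hydropathy lookups of unknown residue codes are errors, never a
  silent zero: a misnamed residue should fail loudly, not dilute a
  profile.
- Degenerate inputs are first-class: empty structures, single-frame
  trajectories (RMSF), single-force tables (fits), zero-length bonds
  (orientation), nonpositive forces, times, tensions, radii and
  concentrations all raise immediately with named causes.

## Problem sizes used in the test suite

The suite exercises barrels of 10-20 Å with 16-atom rings (a few
hundred atoms), trajectories of 5-21 frames, Langevin ensembles of up to
2000 walkers, and 500-seed fit-recovery sweeps — sizes chosen so the
full suite completes in well under a minute on a single core while still
leaving the statistical assertions (±5%, ±10%, ≥95% recovery) far from
their noise floors.

## Known limitations

- The diameter profiler is a probe-ball maximiser, not a full
  Voronoi-based channel finder: it reports the profile along a *given*
  path and can overestimate diameters near sharp axial features, as
  noted above. Cavity enumeration and branch detection are non-goals.
- The greedy pathway search has one-step memory; tunnels that double
  back more sharply than the cone half-angle per step will dead-end.
- SASA accuracy at the default 960 points is about 1% per residue;
  heavily occluded atoms converge more slowly, which is why the
  accuracy floor and the convergence test exist.
- The Langevin surrogate is 1-D, overdamped and barrier-free; it shares
  no physics with the tunnel beyond boundary semantics.
- The physiological projection is an extrapolation of a power law
  fitted over 6-23 kcal/mol/Å down to ~0.02 kcal/mol/Å, and every
  output that crosses the fitted range says so.
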