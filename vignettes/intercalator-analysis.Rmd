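---
title: "Quantifying intercalator binding to DNA: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intercalator binding to DNA: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helipose)
```

## The problem

Planar polycyclic drugs such as doxorubicin bind double-stranded DNA in
several geometrically distinct ways: stacking on the terminal base pair,
full or partial intercalation between base-pair steps, and embedding in the
minor or major groove without base-pair separation. On G-quadruplexes the
analogous platform is the terminal G-tetrad. Telling these modes apart in a
molecular-dynamics trajectory, quantifying how the duplex deforms (the rise
of the host step roughly doubles on full intercalation), locating
deformation-prone regions along bent nucleosomal DNA, and turning
umbrella-sampling time series into binding free energies are the four
analysis tasks this package automates.

Everything operates on plain multi-model PDB input (an extension point
accepts pluggable readers for binary formats), and everything is validated
against synthetic geometries whose ground truth is known by construction —
the generator is a first-class module, not a test afterthought.

## Reference frames and helical parameters

Each base is assigned the standard reference frame of the Tsukuba
convention by least-squares rigid superposition (Kabsch) of an embedded
standard base template onto the observed ring heavy atoms: x toward the
major groove, y toward the reference-strand backbone, z along the local
helix advance. The template coordinates are embedded once and shared by the
fitting code and the synthetic builders, so builder output round-trips
exactly. The fit RMSD is attached to every frame as a quality flag;
deformed or flipped-out bases are *fitted and flagged, never dropped* —
broken pairs are exactly where intercalation chemistry happens.

The complementary base's frame is flipped (y and z negated) so paired
frames are comparable; the pair frame is the halfway rotation between the
two at the midpoint of their origins. Step parameters (shift, slide, rise;
tilt, roll, twist) come from the CEHS/3DNA-style mid-frame decomposition:
the two z-axes are symmetrically rotated onto their bisector about the
hinge axis, twist is measured about the common z, the roll/tilt split is
set by the hinge phase, and translations are read in the mid-frame. Pair
parameters (shear, stretch, stagger; buckle, propeller, opening) use the
identical decomposition with the intra-pair naming. The decomposition has
an exact closed-form inverse (`compose_step()`), which is what the
builders use — so compose-then-decompose round-trips to 1e-6 over a
bounded box of parameters, a property the test suite asserts for 200
random 6-tuples.

This convention was chosen because the rise/twist values it produces are
comparable to the widely used 3DNA-family tools; conventions differ by a
few hundredths of an angstrom for strongly deformed steps, which we
document rather than resolve.

The glycosidic state is `anti` iff chi (O4'-C1'-N9-C4 for purines,
O4'-C1'-N1-C2 for pyrimidines) lies in [90, 270) degrees mod 360, with the
boundary closed on the anti side — a deterministic tie-break.

## The five pose collective variables

Once stacked or intercalated, essentially the only motion left to the
ligand is in-plane sliding and rotation on its platform, so the pose is
tracked with five collective variables relative to the platform frame
(pair mid-frame or tetrad frame): in-plane displacement (dx, dy) of the
geometric center of anthraquinone ring C, in-plane orientation theta of
the ring C to ring A vector, signed out-of-plane height z, and the
sidedness s of the daunosamine sugar (-1 toward the platform along z, +1
away). Ring C's center (not the whole-ligand centroid) defines the
position because that is the quantity the orientation-density maps plot;
the whole-anthraquinone centroid is emitted as a convenience column.
Whether the sugar's disposition is best treated as a continuous height or
a binary orientation is ambiguous; we emit both z (continuous) and s
(binary) and let downstream summaries choose.

`orientation_map()` aggregates records on a square grid (default 0.5
angstrom — fine enough to resolve sub-ring-sized repositioning; no
binning is inherent in the method) with per-bin occupancy, circular
mean direction with resultant length, and the fraction of sugar-down
frames. A bin whose orientations cancel (resultant length ~ 0) reports an
undefined direction, flagged as NA rather than a fabricated 0. Merging two
maps is exactly the map of the pooled records. Direction arrows are drawn
only above an occupancy floor of 1/n — a noise gate, not a statistic.

## Binding-mode classification

The mode taxonomy — terminal stacking, tetrad stacking, full/partial
intercalation, minor-groove embedding, major-groove contact, unbound —
is usually assigned in simulation studies by visual inspection; the
cascade here is a *formalization with package-chosen thresholds*, not
established cutoffs. All thresholds are exposed via `mode_thresholds()`:

| threshold | default | rationale |
|---|---|---|
| stacking gap | 3.0–4.5 Å | canonical aromatic stacking (~3.4 Å) with slack |
| plane angle | ≤ 30° | parallel-displaced stacking tolerance |
| groove radius | ≤ 7 Å from the helical-axis polyline | groove width scale |
| unbound cutoff | > 5 Å nearest heavy-atom distance | beyond direct contact |
| footprint inflation | 1.0 Å | vdW margin on the base hull |

The cascade (first match wins): full intercalation requires the
anthraquinone centroid between two consecutive pair planes with stacking
contact on both sides and footprint overlap with *both* strands; partial
intercalation overlaps one strand; then one-sided terminal/tetrad
stacking; then groove assignment by the sign of the x-coordinate in the
nearest pair frame (x points to the major groove); else unbound. A
nearest-atom distance above the unbound cutoff short-circuits everything.
Footprint overlap is decided by whether *any of the three ring centers*
falls inside the inflated convex hull of the strand's flanking bases
projected into the step mid-frame: ring centers give ~1.5 angstrom
separation margins on planted fixtures versus ~0.5 for the bare centroid,
which matters at the 0.3 angstrom noise level the recovery tests run at.

Episode segmentation majority-smooths the label series with a centered
window, then absorbs episodes shorter than the minimum duration into their
flanking episode (ties toward the preceding one), so episodes always tile
the trajectory.

## Torsional-stress hotspots

`stress_profile()` time-averages the per-step rise first and then applies
a centered 5-step sliding mean along the duplex (truncated at the edges,
no padding); for the mean these two operations commute, but not for other
statistics, so the order is fixed and documented. Steps are flagged HIGH
above 3.5 angstrom and LOW below 3.2 — defaults chosen for presentation contrast,
not validated cutoffs. Twist stress is reported as deviation
from the profile median because bent DNA has no meaningful fixed 36-degree
baseline. When frame times are available the default time slice is the
final 200 ns.

`hotspot_overlap()` asks whether intercalation events anchor
preferentially in HIGH regions: the observed fraction of events within
±1 step of a HIGH flag is compared against a null that places the same
number of events independently and uniformly over the eligible steps
(the two terminal steps at each end are excluded — terminal stacking, not
intercalation, dominates there). The empirical one-sided p is the plain
fraction of permutations at or above the observed overlap, which converges
to the closed-form product for independent placements; with 10,000
permutations the Monte-Carlo standard error is ~0.002 at p ~ 0.03.

## Umbrella sampling and WHAM

The biased collective variable is the center-of-mass distance between the
ligand and the interacting DNA bases, in nm. Window tables are filtered to
the final 20 ns (production segment) before estimation. The PMF is
obtained by direct iteration of the standard WHAM equations

$$p(x_k) \propto \frac{\sum_i h_i(x_k)}{\sum_j n_j\, e^{(f_j - w_j(x_k))/k_BT}},
\qquad f_j = -k_BT \ln \sum_k p(x_k)\, e^{-w_j(x_k)/k_BT},$$

from $f_j = 0$ to a tolerance of 1e-7 kcal/mol on the window constants
(cap 100,000 iterations; exceeding it is an error, never a silent return).
Direct iteration was chosen over accelerated schemes for auditability.
The zero of free energy is pinned to the mean over a bulk-solvent
reference region, by default the top 0.2 nm of the sampled range.

Two numerical choices matter at stiff spring constants
(2000 kJ mol⁻¹ nm⁻² makes the bias vary by ~kT across a 0.01 nm bin):
the Boltzmann factor of the bias is averaged over each bin by 5-point
midpoint quadrature, and the coupled equations are iterated on an internal
sub-grid of a quarter of the requested bin width, with the profile
reported on the requested grid by mass aggregation. Without these, the
window constants shift by ~0.05 kcal/mol between bin widths; with them,
bin-halving changes the aggregated profile by well under 0.02 kcal/mol.

On the spring-constant unit: umbrella constants are occasionally quoted
per nm (first power), almost certainly a typo for the conventional
per-nm² harmonic constant. The config key is named `k_kj_mol_nm2` so the
expected unit is explicit, and user input is never silently
reinterpreted.

Uncertainty comes from a per-window resampling bootstrap (default 50
replicates, seeded; the SD of a single replicate is defined as 0 and
logged). `landmark_report()` extracts per-interval minima and watershed
barriers (profile maximum between adjacent minima, measured from the
shallower one).

## The synthetic generator: what it emulates and what it does not

`build_duplex()` composes the embedded base templates along a chain of
step parameters (B-form defaults rise 3.38 Å, twist 36°) with per-step and
per-pair overrides and per-frame isotropic Gaussian coordinate noise;
`build_tetrad_stack()` makes C4-symmetric coplanar guanine layers;
`plant_ligand()` poses a rigid three-ring scaffold with a pseudo-sugar
group to realize each binding mode, opening the host step to 0.52 nm for
fully intercalated segments (0.48 nm is used for partially intercalated
fixtures); `sample_biased()` draws exact, autocorrelation-free samples
from known 1-D potentials under harmonic biases by inverse-CDF on a fine
grid (with the CDF centered on the grid nodes — a naive cumsum shifts every
sample by half a grid cell, which stiff biases integrate into a visible
PMF drift). Noise is applied after pose placement, so the schedule remains
the ground-truth label definition. The ligand template is deliberately not
chemically exact doxorubicin: classification and CVs depend only on ring
centers and group centroids, and a rigid scaffold exercises every
geometric code path without importing force-field chemistry.

The validation fixture for the free-energy machinery is an analytic
double-well on the distance axis, built as a piecewise-monotone Hermite
spline through landmark control points (deep minimum −9.0 kcal/mol at
0.43 nm, saddle −2.5 at 1.1, shallow minimum −5.7 at 2.0, flat bulk at 0)
so the watershed barrier is exactly 3.2 kcal/mol by construction. These
landmark values parameterize the fixture's shape; they are not recomputed
molecular results, and passing tests say nothing about real MD
observables.

What the generator does *not* emulate: thermodynamically realistic DNA
dynamics, sequence-dependent elasticity, solvent and ions, correlated
(autocorrelated) sampling, or ligand flexibility. Consequently, green
tests demonstrate that the geometry, classification, profile, and
estimator code is correct on data satisfying its assumptions — not that
the thresholds are optimal for any particular force field's trajectories.

## Problem sizes and statistical limits

The test suite runs on 6–8 bp duplexes, 60-frame planted schedules, and
umbrella ladders of 11–56 windows with 300–50,000 samples per window;
the full suite completes in under two minutes on one CPU and the
end-to-end pipeline fixture in well under a minute. One statistical limit
is worth stating plainly: with windows spaced 0.05 nm under a
2000 kJ mol⁻¹ nm⁻² bias (bias width ~0.035 nm) and 2,000 independent
samples per window, each neighbor-pair free-energy increment carries a
standard error of ~0.015 kcal/mol, and these accumulate along the ladder
as a random walk — a typical maximum profile deviation of ~0.2 kcal/mol
over a 56-window ladder even for a perfect estimator. The suite therefore
asserts unbiasedness (exact-histogram input reproduces the window
constants to ~0.002 kcal/mol) and consistency (error below 0.15 kcal/mol
at 50,000 samples per window) rather than pretending the protocol-depth
data contain more information than they do.

## Known limitations

- Automatic pair detection (C1'-C1' distance + axis test) is a fallback;
  strongly deformed nucleosomal pairs defeat it, and an explicit pair list
  should be supplied for such systems.
- The mid-frame decomposition is undefined at a 180-degree relative twist
  or antiparallel z-axes; these raise errors rather than returning
  garbage.
- No periodicity handling in WHAM: the CV is a distance.
- Kinetics (rates, transition models) and hydrogen-bond inventories are
  out of scope; the mode labels carry the interaction information this
  package is designed to extract.
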