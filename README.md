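# helipose

Trajectory analysis for planar intercalators binding DNA duplexes and
G-quadruplex tetrads: helical parameters, ligand-pose collective
variables, binding-mode classification, torsional-stress hotspot
profiles, and umbrella-sampling free energies.

## Who this is for

Molecular-modelling groups studying how drugs like doxorubicin engage
nucleic acids in MD simulations. The questions the package answers:

- **How deformed is the duplex?** Base, base-pair and tetrad reference
  frames (standard/Tsukuba convention, fitted by least-squares
  superposition of embedded standard base templates) and the full set of
  helical parameters from a CEHS/3DNA-style mid-frame decomposition:
  rise, twist, roll, tilt, slide, shift between steps; buckle, propeller,
  opening within pairs; glycosidic anti/syn states. Full intercalation
  roughly doubles the host step's rise (to ~0.52 nm), which these tables
  quantify per frame.
- **Where is the ligand and how is it oriented?** Five collective
  variables per frame — in-plane displacement (dx, dy) of the
  anthraquinone ring-C center in the platform frame, in-plane orientation
  θ of the ring C→A vector, signed height z, and the daunosamine
  sidedness s — aggregated into orientation density maps (occupancy +
  circular mean direction + resultant length per spatial bin).
- **Which binding mode is it?** A per-frame geometric cascade over
  stacking gaps, plane angles, strand-footprint overlap and groove
  proximity assigns one of: `STACKED_TERMINAL`, `TETRAD_STACKED`,
  `INTERCALATED_FULL`, `INTERCALATED_PARTIAL`, `MINOR_GROOVE_EMBEDDED`,
  `MAJOR_GROOVE_CONTACT`, `UNBOUND`; episodes are segmented with
  flicker suppression.
- **Which regions invite intercalation?** Sliding-window (5-step) rise
  profiles with HIGH/LOW flags (defaults 3.5 / 3.2 Å) and a seeded
  permutation test for enrichment of intercalation events in
  high-rise regions.
- **How strong is the binding?** 1-D potentials of mean force from
  umbrella-window time series by self-consistently iterated WHAM
  (bias `w_j(x) = K/2 (x − x_j)²`; window constants
  `f_j = −kT ln Σ_k p(x_k) e^{−w_j(x_k)/kT}`), with last-20-ns
  production filtering, bulk-water zero referencing, bootstrap
  uncertainties, and a landmark report (well depths, watershed barriers).

A synthetic-geometry module (`build_duplex()`, `build_tetrad_stack()`,
`plant_ligand()`, `sample_biased()`) generates idealized B-DNA, tetrad
stacks, planted ligand poses for every mode, and exact inverse-CDF
samples from known potentials under harmonic biases — every analysis is
validated against constructions whose ground truth is known exactly.

## Worked example

Plant a ligand that stacks on the terminal pair for 20 frames and then
fully intercalates at step 4 for 30 frames, and recover both the
geometry and the labels:

```r
library(helipose)
library(dplyr)

sched <- pose_schedule(c("STACKED_TERMINAL", "INTERCALATED_FULL"),
                       n_frames = c(20, 30), anchor = c(8, 4),
                       jitter_sigma = 0.1)
traj <- plant_ligand("GCGCATGC", sched, noise_sigma = 0.2, seed = 42)

hp <- helical_parameters(traj, duplex_pairs(traj))
hp$steps %>%
  filter(step_index == 4) %>%
  group_by(intercalated = frame > 20) %>%
  summarise(mean_rise_A = mean(rise_A), mean_twist_deg = mean(twist_deg))
#> # A tibble: 2 × 3
#>   intercalated mean_rise_A mean_twist_deg
#>   <lgl>              <dbl>          <dbl>
#> 1 FALSE               3.39           36.5
#> 2 TRUE                5.20           35.8

segment_modes(classify_modes(traj), min_duration = 3)
#> # A tibble: 2 × 4
#>   label             first_frame last_frame duration
#>   <chr>                   <dbl>      <int>    <int>
#> 1 STACKED_TERMINAL            1         20       20
#> 2 INTERCALATED_FULL          21         50       30
```

The rise at the host step opens from 3.39 Å (B-form) to 5.20 Å while the
ligand is intercalated, and the classifier recovers the planted episode
boundaries exactly.

Reconstruct a free-energy profile from exactly sampled umbrella windows
over the analytic double-well validation potential (56 windows spaced
0.05 nm, K = 2000 kJ mol⁻¹ nm⁻², 2000 samples per window):

```r
tabs <- sample_biased(double_well_potential, seq(0.25, 3, 0.05),
                      k = 2000, n_per_window = 2000, seed = 42)
pmf <- solve_wham(tabs, bin_width = 0.01)
pmf
#> <pmf_profile> 284 bins over [0.303, 3.132] nm, 7195 iterations
#>   min G: -8.80 kcal/mol at 0.433 nm (reference: [2.928, 3.128] nm)

landmark_report(pmf, list(intercalated = c(0.25, 0.8),
                          stacked = c(1.5, 2.5)))
#> $minima
#>   interval      x_nm G_kcal_mol depth_kcal_mol
#> 1 intercalated 0.433      -8.80           8.80
#> 2 stacked      1.99       -5.64           5.64
#> $barriers
#>   from         to       x_nm barrier_kcal_mol
#> 1 intercalated stacked  1.12             3.34
```

The generating potential has its deep minimum of −9.0 kcal/mol at
0.43 nm, a shallow minimum of −5.7 at 2.0, and a 3.2 kcal/mol watershed
barrier at 1.1 nm; the reconstruction recovers positions and energies to
within the statistical resolution of 2000 samples per window
(`bootstrap_error()` quantifies it per bin).

A pipeline layer (`run_simulate()`, `run_analyze()`, `run_hotspot()`,
`run_pmf()`) chains these stages from YAML configs and writes CSV/JSON
outputs plus the fully resolved config; `inst/cli/helipose.R` wraps them
as shell subcommands.

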