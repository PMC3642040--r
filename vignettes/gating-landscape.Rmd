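---
title: "Mapping channel activation gating: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping channel activation gating: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatedyn)
```

# The problem

Potassium channels of the KcsA fold open and close by an iris-like
motion of the four inner (TM2) helices at the helix-bundle crossing.
Crystal structures capture the end states but not the pathway or its
energetics.  `gatedyn` implements the standard computational route from
a pair of end-state structures to a one-dimensional free-energy profile
of gating, together with the structural observables used to interpret
it, and provides synthetic systems with exact ground truth so that
every stage can be validated at desk scale.

# The reaction coordinate

Given closed and open structures trimmed to a common residue range
(29–118 for the KcsA pore domain; note the inclusive interval holds 90
residues per chain — the per-chain count is always reported so users
can reconcile against other conventions), atoms are selected as the
backbone (default atom set N, CA, C, O — configurable, since
conventions for "backbone" differ) of the transmembrane segments with
loops excluded.  The shipped segment preset is TM1 29–51, P-helix
62–74, selectivity filter 75–79, TM2 86–118, with loops 52–61 and
80–85; all ranges are configurable per structure.

A covariance PCA of the two fitted conformations has rank one by
construction; the single non-trivial eigenvector is the normalized
coordinate difference and is used as the reaction coordinate.
`build_difference_ev()` orients it so that the open state projects
positive, anchors projection zero at the fitted closed coordinates, and
records the path length.  `project_cv()` applies a Kabsch fit before
projecting, so the coordinate is exactly invariant to rigid-body motion
of the input; the fit selection defaults to the same backbone set.
Mass weighting of the covariance is available behind a flag but
defaults to uniform weights: for a two-conformation PCA the mode
direction differs only through the weighting of the difference vector,
and uniform weights keep the coordinate identical to the plain
coordinate difference.

The eigen-rank tolerance (1e-10 nm²) decides which eigenvalues count
as non-zero; it is exposed because trajectory PCA on noisy data needs a
scale-aware cutoff.

# Essential-dynamics driving

`run_ed()` interleaves one unconstrained Brownian-dynamics step of all
coordinates with a projection constraint: the collective vector's atoms
are displaced along the (fitted) direction until the projection equals
the step's target.  Because the displacement itself perturbs the
optimal superposition slightly, the correction is iterated; it
converges to |s − target| below 1e-10 nm in one or two passes, and the
constraint-exactness invariant (< 1e-9 nm at every step) is asserted in
the test suite.  The target advances by a fixed increment per step.
With auto pacing the increment is chosen so the end state is reached
after two thirds of the steps, and the final third relaxes at a fixed
constraint — the customary pacing rule for such drives, preserved
rather than any atomistic increment value (of order 1e-6 nm per 2 fs
step for a four-subunit drive), which is meaningless for the toy
system's path length.  The implied total displacement (steps × increment) is
reported per run for transparency.

Success is judged by backbone RMSD to the target structure: 0.2 nm for
opening, 0.23 nm for closing, both configurable.  An optional harmonic
position restraint stands in for the helical restraints a user would
place on the C-terminal helix turns to prevent unwinding; true
dihedral restraints are out of scope at bead resolution.

Cooperativity protocols restrict the eigenvector to one, two or three
chains (subunit-restricted PCA); the remaining chains evolve freely.
`cooperativity_scan()` reports, per driven-subunit count, the final
whole-channel RMSD to the open target and the opposite-subunit gate
distance.

# The synthetic systems

Passing tests on these systems demonstrates that the machinery is
correct at these operating points; it does not certify behaviour
on experimental structures or atomistic force fields, which differ in
ruggedness, anisotropy and degeneracy from any synthetic stand-in.

## Coarse-grained two-state tetramer

`make_toy_channel()` builds four C4-symmetric subunits of two six-bead
helix rods (chain ids A–D; bead pseudo-residue numbers spread over the
TM1/TM2 presets so every selection mechanism works unchanged).  The
closed and open endpoint geometries differ by a radial splay of the
TM2 C-terminal beads scaled so that the end-state CA RMSD is exactly
0.40 nm — the 4 Å difference of the modelled transition — and the gate
bead (residue 112 analogue) ring doubles its radius.

The energy is a smooth two-state blend of harmonic tether networks:
U = −ε ln(e^(−U_closed/ε) + e^(−(U_open+b)/ε)).  Design choices, in
order of consequence:

* **Spring constant k = 800 kJ mol⁻¹ nm⁻²** keeps the thermal RMSD
  amplitude at 310 K, √(3kT/k) ≈ 0.1 nm, well under the 0.2 nm
  success threshold — the role tight packing plays in a real protein.
* **Open-state offset b** defaults to the per-subunit reorganization
  energy c = (k/2)·‖x_o − x_c‖²/4.  This single choice produces both
  target behaviours of the architecture: the closed basin is deeper
  (by b), and the global switch tips exactly between two and three
  driven subunits — with two subunits held open the closed branch is
  still favoured by b, with three the open branch is favoured by
  2c − b = c — so at least three subunits must move to open the gate,
  with symmetric ≈ 4σ margins against the thermal fluctuations of the
  branch-energy difference (σ = √(k·kT·‖Δx‖²) ≈ 80 kJ/mol).
* **Mixing scale ε = 4 kJ/mol** makes the switch sharp on the thermal
  scale without creating numerically stiff gradients.
* The subunit coupling is realized through this shared two-state
  switch rather than explicit inter-subunit springs: it is the minimal
  mechanism that makes partial drives be resisted by the undriven
  remainder, and it keeps the energy exactly C4-invariant.

The propagator is overdamped Euler–Maruyama Brownian dynamics
(`run_bd()`): no masses or thermostats are needed for
stationary-distribution correctness, which is what the tests assert
(harmonic variance kT/k; at zero temperature, plain gradient descent).
The discretization inflates the stationary variance by 1/(1 − k·dt/2γ),
which bounds the usable time step; defaults (dt = 5e-4 ps, γ = 1) keep
the inflation under ~20 % for the stiffest default spring, and the
umbrella presets use dt = 4e-5 ps to resolve their stiffest bias.

## Analytic landscapes

`analytic_landscape()` sums Gaussian features (positive = well,
negative = barrier hump) and exposes both U(s) and the exactly
normalized Boltzmann density.  The bundled
`triple_well_landscape()` places wells near 1.2, 5.4 and 10.1 nm and
barrier humps at 4 and 9 nm — the closed well deepest, a small barrier
before a broad intermediate well, then a larger barrier before a
compact open well, the canonical layout of this channel's gating
profile.  Well depths (20/13/11 kJ/mol) and barrier amplitudes
(3/5 kJ/mol) are package defaults: the layout, not the absolute
heights, is the modelled feature; absolute barrier heights for this
transition are not established.  Pure three-well Gaussian mixtures cannot
place both maxima at the stated positions (the maxima slide toward the
shallower wells), hence the explicit humps.

`sample_biased_1d()` draws i.i.d. samples of the biased density by
rejection under a piecewise-constant grid envelope; the envelope adds
a second-difference (curvature) slack so that stiff biases cannot
overshoot it, and every acceptance evaluates the exact density, so the
sampler is exact up to the envelope check it performs itself.

## Synthetic full-backbone stand-ins

`synthetic_kcsa_models()` builds closed/intermediate/open full-backbone
(N, CA, C, O) tetramers whose gating observables are **designed** at
the literature operating points for this channel family: gate
constriction diameters 5.9 / 8.3 / 11.8 Å (governed by the
carbonyl-oxygen ring at residue 112), opposite-subunit CA–CA distances
12 / 14 / 22 Å, and a closed↔open backbone-without-loops RMSD of
exactly 4 Å, obtained by solving for the amplitude of an iris-like
azimuthal twist of the TM2 C-terminal half (the radial gate
displacements alone are local and insufficient).  Opening is
two-phasic by construction: the intermediate carries most of the local
gate-ring change but only a fifth of the global TM2 splay.  These are
synthetic models — idealized helix rods, not crystal coordinates — and
are labelled as such; they exist so the full measurement pipeline (PDB
round trip, trimming, selection, superposition, profiling, gate
metrics) can be verified end-to-end against known ground truth.

# Umbrella sampling and WHAM

`wham()` implements the standard self-consistent histogram equations
on a fixed bin grid (default 200 bins over the pooled sample range; a
`range` argument pins the grid when profiles must be compared
bin-for-bin).  Iteration stops when the window free-energy constants
move less than `tol` (default 1e-7 kJ/mol).  Unvisited bins are NaN;
adjacent-window overlap is diagnosed and gaps produce a warning rather
than silent nonsense.  Design choices:

* **Whole-window bootstrap** (resample each window's samples with
  replacement, re-solve, align each replicate at its minimum, take the
  per-bin SD over replicates; default 50 replicates).  Alignment at
  the minimum reflects that WHAM fixes only relative free energies.
  The recovery test interprets "the error estimate brackets the truth"
  as |F̂ − F| ≤ 1.96·SE on at least 80 % of doubly-covered bins — a
  95 % normal interval, under which the 80 % floor is a meaningful
  bound rather than a coin toss.
* **Force constants.**  The atomistic-scale defaults of
  `make_windows()` for user systems are k = 1 kJ mol⁻¹ nm⁻² with six
  barrier windows boosted to 100.  The desk-scale
  presets use stiffer windows (30, boosted to 100, for the analytic
  landscape; 4000 with a dense 40000 set bridging the two-state switch
  for the toy channel in `toy_umbrella_pmf()`) because the toy
  profiles are steeper by orders of magnitude than a membrane-protein
  PMF; the boosted-window trick is the same, only the scale differs.
  Window sampling on the toy system can skip the per-step rigid-body
  fit (`fit = FALSE`): position tethers prevent drift, so the fit is
  an identity that costs a Kabsch decomposition per step.
* Umbrella biases act on the scalar projection; forces on the toy
  system follow by the chain rule through the projection, neglecting
  the derivative of the fit rotation (standard practice; exact when
  the fit is skipped).

`shade_states()` projects unbiased state ensembles onto the coordinate
and reports min/max plus 5–95 % quantile intervals; the well lookup
uses the quantile interval so that rare cross-barrier excursions in a
state ensemble do not mis-attribute its well.

# Pore profiling

`pore_profile()` is a HOLE-style largest-sphere search: per z-slab,
maximize over in-plane centers the minimal
(distance − hard-sphere radius) over atoms.  The optimizer is
simulated annealing seeded from the previous slab's center — the
spec'd algorithm and a good tracker of a continuous pore — backed by a
deterministic coarse polar grid scan (the per-slab surface can hold
several near-degenerate off-axis pockets, e.g. between the tight
selectivity-filter rings, and the global maximum is wanted) and
finished by a multiscale compass search, which is reliable on the
ridged max–min surface where simplex polishing stalls.  Profiles are
reproducible per seed; across seeds and under rigid rotation the
per-slab agreement is bounded by the ~0.02 nm spacing of competing
pockets, while constriction radii agree to a few thousandths of a nm.

The default radii table (C 0.185, N 0.175, O 0.165 nm, configurable)
is a plain element-based hard-sphere set; reported gate diameters are
radii-table dependent at the ±0.3 Å level, which is the tolerance used
throughout.  The default gate window is the intracellular half
(z < 0 for a channel built or aligned with the extracellular face at
positive z): a window reaching closer to the selectivity filter would
read the 3-D distance to the filter rings rather than the activation
gate.  Atoms more than 1.2 nm from a slab are skipped; this is safe
while pore radii stay below ~1 nm, which holds for every system here.

# Rotamer and distance metrics

`classify_rotamer()` implements the printed basin ranges with circular
interpretation of the down basin (−185° wraps to +175°).  The strict
mode returns "unassigned" outside both ranges; because two-state
percentages imply a two-state denominator, `state_fractions()` excludes
unassigned frames from the up/down denominator and reports their share
separately, and a nearest-center mode (centers −63.5° and −175.5°) is
provided for the two-state convention.  Both modes agree on every
angle inside the printed ranges (asserted as a property test).
`opposite_distance()` returns both diagonal pairs and their mean — the
mean is the default gate metric (conventions differ on which diagonal
pair is reported) and both are emitted.  Hydrogen bonds use the
common geometric rule (donor–acceptor ≤ 0.35 nm, H–D–A ≤ 30°,
configurable); the package treats these as configuration, not as a claim
about any particular study's criteria.

# Workflows, configuration, reproducibility

`run_opening()`, `run_landscape()` and `run_cooperativity()` are the
package's orchestration layer (this package's interface is R functions
plus this vignette; there is no shell executable).  A single nested
configuration (`default_config()`, overridable by list or YAML file)
holds every tunable; unknown keys fail loudly by name.  Every workflow
writes tidy CSVs plus a JSON manifest with the seed, the full config
snapshot, per-stage timings and MD5 digests of outputs; with the same
seed, reruns are byte-identical (asserted in the tests).  All
stochastic stages take explicit integer seeds; nothing reads global
RNG state implicitly.

Problem sizes used by the default tests and the acceptance script —
2000-step drives, 39 windows × 1e4 landscape samples, 48 toy umbrella
windows × 1500 steps, 50 bootstrap replicates — were chosen as the
smallest sizes at which the statistical assertions have comfortable
margins (e.g. WHAM RMSE ≈ 0.15 kJ/mol against a 0.5 kJ/mol bound, and
a ~4σ cooperativity margin).

# Known limitations

* The toy channel has no solvent, membrane, ions or side chains; its
  cooperativity arises from a single designed switch, so it validates
  the driving/analysis machinery, not any biological coupling
  mechanism.
* The pore profiler assumes a straight axis (default z); curved pores
  need external re-axis-ing per segment.
* WHAM here is 1-D; no MBAR, no replica exchange, no 2-D profiles.
* The ED constraint is positional, not force-based steering;
  observables that depend on the work performed along the path are out
  of scope.
* On real crystal inputs, gate diameters inherit the uncertainty of
  the hard-sphere radii table (± a few tenths of an Å).
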