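# gatedyn

Tools for mapping the activation-gating energy landscape of tetrameric
potassium channels — the conformational transition by which the bundle
crossing of the four inner (TM2) helices widens to open the pore.  The
package is aimed at structural bioinformaticians and simulation
scientists who have end-state structures of a channel (closed and open
crystal conformations, or models) and want to

1. build a **reaction coordinate** between them,
2. **drive** the transition along it and watch the gating observables,
3. compute a **free-energy profile** along it with honest errors, and
4. quantify gating with **pore radii, rotamer states, gate distances
   and hydrogen-bond counts**.

Everything is exercisable at desk scale: the package ships a
coarse-grained two-state toy tetramer with a Brownian-dynamics engine,
analytic multi-well landscapes with exact Boltzmann densities, and
synthetic full-backbone channel models, so every stage of the pipeline
is validated against known ground truth in seconds to minutes.

## The methods at the core

**Difference eigenvector.** For two conformations x_c (closed) and x_o
(open), superposed by a Kabsch least-squares fit over the backbone of
the transmembrane helices (loops excluded), the covariance matrix of
positional fluctuations of a two-frame "trajectory" has exactly one
non-zero eigenvalue; its eigenvector is the normalized difference
v = (x_o − x_c)/‖x_o − x_c‖.  The scalar coordinate is the projection
s(x) = v · (fit(x) − x_c), with s = 0 at the closed and s = ‖Δx‖ at the
open state.

**Essential-dynamics (ED) driving.** A free simulation is run with one
constraint: after every integration step the projection is reset to a
target that advances by a fixed increment δ per step (all other degrees
of freedom relax freely).  The increment is paced so the target
structure is reached after two thirds of the run.  Success is judged by
the backbone RMSD to the target (≈ 2 Å for opening, 2.3 Å for
closing).  Restricting the eigenvector to 1–3 subunits probes gating
cooperativity.

**Umbrella sampling + WHAM.** Windows along s are sampled with a
harmonic bias k/2 (s − s₀)²; a self-consistent weighted-histogram
solver (written from scratch, with per-window free-energy constants
iterated to tolerance) unbiases them into a potential of mean force
F(s) = −kT ln p(s), and whole-window bootstrap (default 50 replicates)
gives per-bin standard errors.

**HOLE-style pore profiling.** For each slab along the channel axis the
largest sphere touching no atom is found
(max over centers of min over atoms of ‖c − x_a‖ − R_a) by simulated
annealing plus a deterministic grid scan and compass polish; the gate
diameter is twice the minimal radius in the intracellular half.

**Rotamer metrics.** χ1 (N–CA–CB–CG) dihedrals of the aromatic gate
residues are classified into the "up" (−55° to −72°) and "down"
(−166° to −185°, circularly wrapped) states, with per-frame state
percentages across subunits and replicas.

## Worked example

```r
library(gatedyn)

toy <- make_toy_channel()                 # C4 two-state bead tetramer
cv  <- build_difference_ev(toy$closed, toy$open, toy$selection)
attr(cv, "path_length")                   # 2.771 nm end-to-end

prot <- ed_protocol(cv, n_steps = 2000, success_rmsd = 0.2)
run  <- run_ed(toy$energy, toy$closed, prot, reference = toy$open,
               seed = 42)
run$final_rmsd * 10                       # 1.16 A -> success TRUE

cooperativity_scan(toy$energy, toy$closed, toy$open,
                   spec = toy$selection, n_steps = 2000, seed = 42)
#>   k final_rmsd gate_distance success
#> 1 1      0.402          12.6   FALSE
#> 2 2      0.317          18.1   FALSE
#> 3 3      0.117          27.5    TRUE
#> 4 4      0.116          27.2    TRUE
```

Driving one or two subunits leaves the channel closed (final RMSD to
the open target stays near the 4 Å end-state difference and the gate
barely moves); driving three or four opens it — the cooperative
pattern expected for a concerted iris-like gate.

On the synthetic full-backbone models the pore profiler reads off the
designed constriction:

```r
m <- synthetic_kcsa_models()
p <- pore_profile(m$closed, selection_spec(include_loops = TRUE),
                  seed = 1)
gate_diameter(p)                          # 5.9 A (closed-state gate)
```

The landscape machinery validates against an analytic triple-well
oracle (`triple_well_landscape()`, wells near 1.2, 5.4 and 10.1 nm
with barriers near 4 and 9 nm and the closed well deepest):
`run_landscape()` samples 39 windows, solves WHAM and typically
recovers the true profile with an RMSE near 0.15 kJ/mol.

End-to-end workflows with CSV reports and JSON run manifests:
`run_opening()`, `run_landscape()`, `run_cooperativity()`; see
`vignette("gating-landscape")` sources under `vignettes/`.

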