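# memorient

Orientation-state and membrane-structure analysis for peripheral membrane
proteins, written for structural biologists and simulators who need to
quantify *how a lipid-anchored protein sits on a bilayer* from multi-frame
coordinate data. The motivating system is farnesylated, GTP-bound KRas-4B on
anionic model membranes, where the accessibility of the effector-binding
loop — and hence signalling competence — depends on which orientation state
the catalytic domain occupies and on the membrane's cholesterol content.

## What it computes

**Membrane structure.** Per-frame area per lipid
`A = Lx·Ly / N_leaflet` (the lateral box area per leaflet amphiphile,
sterols included) and bilayer thickness
`Δz = ⟨z_P⟩_upper − ⟨z_P⟩_lower` (mean inter-leaflet phosphorus separation),
with time averages and block-averaged standard errors, plus percent-change
reporting for condensation comparisons.

**Insertion depth.** Signed distance of a moiety's geometric centre (e.g.
the farnesyl anchor FAR, or GTP) from the bilayer centre `z₀ = ⟨z_P⟩` along
the membrane normal, with "preferred localisations" as the modes of the
0.1 nm depth histogram.

**Conformation.** RMSD of the 5-aa HVR motif (backbone of residues
180–184) against a reference frame after optimal (Kabsch) superposition:

    RMSD = sqrt( (1/n) Σᵢ dᵢ² )

over the n atom pairs, so only internal conformational change contributes.

**Orientation states.** Per frame, the order parameters

- `z` — distance between the Cα atoms of residues 132 (lobe 2) and 183 (HVR),
- `Θ` — angle between the membrane normal and the β1-strand vector (Cα5→Cα9),
- `Φ` — angle between the membrane normal and the α5-helix vector (Cα156→Cα163),

2D density maps over (z, cos Θ) and (Θ, Φ) with marginals and modal bins,
and nearest-centre classification into the literature orientation states
OS1 (1.86 nm, −0.5; active, loop exposed), OS0 (3.33, 0.9; intermediate)
and OS2 (4.97, 1; occluded), with occupancy fractions.

**Pair structure.** Radial distribution functions g(r) under orthorhombic
periodic boundaries (minimum-image convention, ideal-gas shell
normalisation).

**Synthetic ground truth.** A generator that builds two-leaflet
pseudo-phosphate slabs at exact area-per-lipid/thickness targets and places
a rigid pseudo-protein at *exactly* requested (Θ, Φ) and anchor depth —
with optional Gaussian positional noise, stationary orientational
fluctuation, and two-state (anchored/solvated) Markov anchor dynamics — so
every pipeline stage is validated against known truth without running MD.

## Worked example

The `onc_chol30` preset emulates the oncogenic protein on a 30%-cholesterol
membrane: area per lipid 0.525 nm², thickness 4.23 nm, orientation
fluctuating around the active-state centre (Θ, Φ) = (80°, 105°), anchor
held at 1.30 nm:

```r
library(memorient)
cfg <- run_config(preset = "onc_chol30", seed = 42, n_bins = 25)
rep <- run_pipeline(cfg)
rep
#> run_report over 1000 frames (window 50%)
#>   area per lipid: 0.5250 (0.0000) nm^2
#>   thickness:      4.230 (0.000) nm
#>   FAR depth mean 1.30 nm; modes 1.25 nm
#>   (Theta, Phi) mode: (83.6, 105.4) deg
#>   OS occupancy: OS1 0.93, OS0 0.07, OS2 0.00 -> OS1
```

The analysis window is the final 50% of frames. The recovered bilayer
metrics match the generator targets (the lateral box is constructed from
the target, so A is exact; Δz is exact up to the 0.05 nm head-group
jitter). The modal (Θ, Φ) bin sits within the sampling noise of the
configured (80°, 105°) centre, and the run is classified as
predominantly OS1 — the orientation with the effector-binding loop exposed.
Condensation reporting works on any pair of areas:

```r
percent_change(0.679, 0.524)
#> $percent 22.83  $percent_rounded 23  $difference 0.155
```

Real trajectories enter through `read_trajectory()` (multi-frame GRO or
multi-model PDB, orthorhombic boxes, coordinates handled in nm) with atom
roles resolved from a YAML selection config
(`inst/extdata/selections_charmm.yaml` shows CHARMM-style naming);
`run_config(input = "traj.gro", selection = "my_roles.yaml")` runs the same
pipeline unchanged.

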