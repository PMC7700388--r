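---
title: "Quantifying membrane-protein orientation states: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-protein orientation states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memorient)
```

## The problem

Small GTPases such as KRas-4B signal only while anchored to the inner
membrane leaflet, and *how* the catalytic domain sits on the bilayer
decides whether the effector-binding loop is solvent-accessible (the active
OS1 orientation), occluded by the membrane (OS2), or intermediate (OS0).
Membrane composition — cholesterol in particular — shifts the balance
between these states. memorient implements the trajectory-analysis layer
needed to quantify this: bilayer structural metrics, moiety insertion
depths, motif RMSD, orientation order parameters with state classification,
and radial distribution functions, all exercised against a synthetic
generator with exact ground truth.

## Models and conventions

**Units and frames.** All coordinates are held in nm (PDB Å are divided by
10 on read); times in ps; angles reported in degrees. Boxes are
orthorhombic only — triclinic records raise an explicit unsupported-format
error rather than being truncated, because all periodic arithmetic here
(minimum image, RDF shells) assumes independent box axes.

**Bilayer metrics.** Leaflets are split at the *median* z of the
phosphorus atoms, which stays correct if the bilayer drifts off the box
centre; the bilayer centre z₀ is the mean phosphorus z. Thickness is the
mean inter-leaflet phosphorus separation. Area per lipid divides the
lateral box area by the number of amphiphiles per leaflet with sterols
*included* in the denominator: a cholesterol-containing membrane is
reported as a single condensed area, matching how per-system areas are
conventionally tabulated; a per-species decomposition is out of scope, and
this convention is recorded here rather than guessed silently (the
`amphiphile` selection role makes it explicit and overridable).

**Errors by block averaging.** MD-like series are serially correlated, so
the naive standard error underestimates uncertainty. `block_average()`
reports the standard error of the means of (default) 10 contiguous blocks;
for correlated series this is conservative relative to the i.i.d. formula,
and the tests verify both the i.i.d. calibration and the AR(1) inflation.
The analysis window defaults to the final 50% of frames — the standard
"discard the first half as equilibration" convention — and is configurable.

**Orientation order parameters.** z is the Cα132–Cα183 separation; the
default is the literal 3D Euclidean distance, with a normal-projection
mode available (`z_mode = "projection"`) because the source definition does
not disambiguate the two; the choice is carried in the run config. Θ and Φ
measure the β1-strand (Cα5→Cα9) and α5-helix (Cα156→Cα163) vectors against
the membrane normal, both in the N→C backbone direction — the one
convention consistent across both vectors; flipping a vector maps an angle
to its supplement, so the convention matters and is fixed. These are
*internal* protein vectors: they are computed on whole (unwrapped)
molecules and never minimum-imaged, since wrapping an internal vector
across the periodic boundary would corrupt the angles. Lipid–protein
*distances* (RDFs), by contrast, always use the minimum image.

**OS classification.** Only the three state *centres* are established in
the (z, cos Θ) plane — (1.86, −0.5), (3.33, 0.9), (4.97, 1) — not region
boundaries. Classification is therefore nearest-centre under a normalised
metric, (Δz/5 nm)² + (Δcos Θ/2)², the scales being a plausible z span and
the full cosine range; both are configurable in `os_region_model()`. Ties
break deterministically in the order OS1, OS0, OS2. The tests confirm each
centre classifies to itself and that labels are stable under perturbations
smaller than half the normalised inter-centre gap.

**Density maps.** 2D histograms are probability-normalised (bin counts
divided by the number of records; the alternative per-bin-count convention
is not used, and the choice is visible in the output since probabilities
sum to 1). Default 50×50 bins over the data range padded 5%; the mode is
the first maximal bin in column-major order — an arbitrary but
deterministic tie-break. Marginals are exact row/column sums.

**Depth and RMSD profiles.** Moiety centres are unweighted geometric means
of the selected atoms (heavy-atom pseudo-particles in the synthetic
system). Depth histograms use 0.1 nm bins — fine enough to separate
localisations 0.4 nm apart, coarse enough to be stable at a few hundred
frames. The 5-aa HVR motif RMSD uses backbone atoms (N, CA, C, O) of
residues 180–184 — the common convention for short-peptide conformational
RMSD — superposed per frame onto the first frame of the analysis window
(a deterministic reference, since "the" reference structure is otherwise
underdetermined). Kabsch superposition is SVD-based with the determinant
correction, so reflections are never returned.

**RDF normalisation.** g(r) divides per-frame pair counts by the
ideal-gas shell expectation N_A·ρ_B·(4/3)π(r₂³−r₁³) with ρ_B = N_B/V, or
(N_B−1)/V when the two selections are identical (self-pairs excluded);
r_max is capped at half the smallest box edge, the validity limit of the
minimum-image convention.

## The synthetic generator

The generator's job is to produce trajectories whose *statistical
structure* matches what the analyses assume, with every target known
exactly:

- **Slab:** two square lattices of single-particle pseudo-phosphates at
  ±thickness/2 around the box mid-plane; the lateral edge is constructed
  as L = √(N·A_target), so the area-per-lipid estimator recovers the
  target exactly by construction. A sterol fraction relabels evenly spaced
  particles (`CHL`) and rescales the target area by a condensation factor.
  Gaussian jitter (default σ = 0.05 nm, a realistic head-group roughness
  scale) is applied per frame; jitter approaching half the leaflet spacing
  is rejected outright since leaflets would stop being identifiable.
  Defaults (152 lipids/leaflet, A = 0.679 nm², Δz = 3.84 nm) are the
  sterol-free study conditions; presets cover all four
  wild-type/oncogenic × 0%/30%-cholesterol systems with their reported
  per-system targets.
- **Protein:** a fixed rigid scaffold carrying exactly the atoms the
  analyses read (six marker Cα, 20 HVR backbone atoms, 5-atom FAR and GTP
  clusters). Its β1/α5 inter-vector angle is exactly 45°, and the
  Cα132–Cα183 separation exactly 1.86 nm, so the rigid body reports the
  OS1 z value. Placement solves the α5 direction in the orthonormal frame
  of the β1 axis: requested (Θ, Φ) are *realised to machine precision* or
  rejected with the attainable Φ interval ([|Θ−45°|, min(Θ+45°, 315°−Θ)]) —
  never clamped. Since a single rigid body couples FAR and GTP depths, an
  optional GTP depth is honoured by shifting only the 5-atom GTP cluster
  along z, leaving every orientation marker and the HVR motif untouched
  (physically: the nucleotide's association with the membrane interface
  varies semi-independently of the scaffold tilt).
- **Dynamics:** anchor depth follows either a fixed value or a
  discrete-time two-state Markov switch (default levels 1.73/3.90 nm,
  switch probability 0.02/frame) — the simplest process reproducing the
  bimodal anchored/solvated farnesyl localisation. Orientation angles
  follow either fixed values or a *stationary mean-reverting* AR(1)
  fluctuation (long-run SD `angle_sigma`, default 8°; autocorrelation
  0.95) reflected into the feasible range. A pure (non-reverting) random
  walk was deliberately not used: it has no stationary mode, whereas the
  systems being emulated fluctuate around modal orientations.

What the generator does **not** emulate: lipid chain order, undulations,
solvent, electrostatics, any real kinetics, or internal protein
flexibility (the scaffold is rigid, so the z order parameter varies only
through marker noise). Passing tests therefore demonstrate that the
*analysis pipeline* is correct and well-calibrated on data with known
truth — not that any biological conclusion transfers to real trajectories.

## Numerical choices and degenerate inputs

- Leaflet assignment errors on all-one-side inputs ("degenerate bilayer");
  selections error when a required role matches nothing, naming the role;
  `ca_marker` with a residue number must match exactly one atom.
- `minimum_image` maps into the half-open interval [−box/2, box/2); the
  half-box point maps to the negative side.
- Angle cosines are clamped to [−1, 1] before `acos` to absorb rounding.
- Kabsch requires ≥3 non-collinear points; collinear sets are rejected.
- Histogram modes: local maxima of the binned counts ordered by occupancy;
  a flat histogram falls back to the global maximum.
- `density_map` widens a zero-width axis symmetrically so a constant
  series still occupies one bin with probability 1.
- Generation is bitwise deterministic in (spec, seed); the caller's RNG
  state is saved and restored.

## Problem sizes and test calibration

The test suite generates trajectories of 4–2000 frames (one 5000-frame
two-state run for the bimodal-depth check) over ~340 particles; the full
suite runs in about a minute. Two calibration points worth recording:

- With fixed angles and 0.05 nm marker jitter, the induced angular noise
  is ≈ √2·0.05/1.2 rad ≈ 3.4°, so angle-mode recovery is checked on
  histograms with ~3°-wide bins (bins matched to the noise scale); "within
  one bin" is asserted as ≤1.5 bin widths, i.e. the target may sit in a
  bin adjacent to the modal bin.
- For the AR(1) orientation process, a 500-frame window at autocorrelation
  0.95 contains only ~10–30 effectively independent samples, so the
  empirical 2D mode carries sampling noise of order half the fluctuation
  amplitude; preset-level mode checks are therefore made at the 1σ (8°)
  scale. This is a property of estimating modes from short correlated
  series, not of the implementation.

## Limitations

- Orthorhombic boxes only; no triclinic periodicity.
- No topology or bond perception: selections are purely name/number rules.
- The OS region model is nearest-centre with configurable scales — a
  classification convention, not a free-energy-based state definition.
- RDFs assume an isotropic ideal-gas reference; for quasi-2D layered
  systems g(r) → 1 at large r holds only approximately.
- The synthetic generator validates analysis correctness, not force-field
  realism (see above).
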