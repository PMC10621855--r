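---
title: "Modeling the PFA electric field in a heterogeneous ventricular wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the PFA electric field in a heterogeneous ventricular wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfafield)
```

## The physical model and its assumptions

Pulsed field ablation delivers microsecond high-voltage pulses through a
catheter electrode; cells die by irreversible electroporation wherever the
field magnitude exceeds a lethal threshold, taken here as a single value of
1000 V/cm for all tissues. Because the pulses are short and membrane
charging transients are fast compared to the pulse length, the field is
treated as **quasi-static**: the potential obeys the generalized Laplace
equation ∇·(σ∇φ) = 0, with **E** = −∇φ and **J** = σ**E**. Thermal effects
(Joule heating and its feedback on conductivity) and conductivity
anisotropy are outside the model's scope, and results are independent of
any specific pulse train or generator protocol: the delivered current (or
voltage) amplitude is the only electrical input.

The geometry is axisymmetric: a blunt-tip catheter (7 Fr = 7/3 mm diameter,
3.5 mm long active electrode, insulated shaft above) perpendicular to the
endocardium and inserted 0.5 mm, with the tissue conforming to the
electrode wall (no gap, no tenting). The wall is a stack of layers in z
(z = 0 at the undisturbed endocardial surface, +z into the tissue):
myocardium to 7 mm, epicardial fat to 9 mm, connective tissue below; blood
fills the chamber above. Monopolar delivery is represented by grounding all
outer boundaries of a finite domain.

Electroporation feeds back on conductivity. Before pores open, current
avoids the intact cell membranes and the tissue shows its low-frequency
(sub-beta-dispersion) conductivity σ0; once electroporated it conducts at
its high-frequency value σ1. The transition follows a sigmoid in the local
field magnitude (V/m):

σ(E) = σ0 + (σ1 − σ0) / (1 + 10 · exp(−(|E| − 58000)/3000))

Only viable myocardium has σ1 > σ0 (0.4 → 0.6 S/m). Collagen-dominated
scar (0.85 S/m), fat (0.08 S/m), blood (0.6 S/m) and the muscle/fat
connective mix (0.115 S/m) have no membrane response worth modeling and
stay constant; the implementation short-circuits the sigmoid for them.
Published tabulations disagree on fat — 0.015 S/m appears in one table
against 0.08 S/m with explicit in-vivo provenance — and the package
defaults to 0.08 S/m with the alternative available as
`tissue_properties(fat_sigma = 0.015)` for sensitivity runs.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| lethal threshold | 1000 | V/cm | cardiomyocyte lethality from in-vitro suspension data |
| delivered currents | 19, 22, 25 | A | focal-PFA generator settings; voltage is matched per wall |
| wall / epicardial fat | 7 / 2 | mm | mid-diastolic LV wall from CT angiography |
| electrode diameter / length / insertion | 7/3 / 3.5 / 0.5 | mm | standard focal ablation catheter, firm contact |
| σ0, σ1 myocardium | 0.4, 0.6 | S/m | pig ventricle below/above beta dispersion |
| sigmoid center / slope / prefactor | 58000 / 3000 / 10 | V/m, V/m, – | electroporation transition of σ(E) |
| domain radius / blood / connective | 40 / 20 / 20 | mm | truncation; fields are negligible at these distances |
| `h_fine`, `h_lesion`, `h_coarse` | 0.05, 0.15, 1.5 | mm | mesh sizes at electrode / isoline region / far field |
| resampling cell | 0.025 | mm | isoline extraction grid |

The domain extents deserve a note: they are a modeling choice, not a
published value. The axial profiles computed by `axis_profile()` show the
potential decaying to a few percent of the electrode voltage within 15 mm,
and the mesh-refinement and domain tests in the suite back the truncation:
lesion metrics are insensitive at the stated tolerances.

## Numerical scheme

**Mesh.** A graded tensor-product grid in (r, z), each rectangle split into
two triangles with alternating diagonals. Grid lines are placed exactly on
every planar interface (endocardial surface, layer boundaries, scar and
slab boundaries, electrode radius, tip plane), so all layered interfaces
are conforming; the elliptical fat blobs are voxelized at the local
resolution. Spacing is `h_fine` at the electrode surface, `h_lesion`
throughout the region swept by the lethal isoline, growing to `h_coarse`
at the boundaries. Elements inside the electrode and shaft are removed
from the conductive domain; electrode-surface nodes carry the Dirichlet
voltage, shaft and axis are natural (zero-flux) boundaries.

**Tip corner.** The electrode rim is left as a sharp corner. The corner
field singularity is integrable and sits ~3 mm from the 1000 V/cm isoline;
a dedicated test asserts that halving the mesh changes lesion depth by
less than 2%, which is the property a fillet would otherwise be needed
for. (A rounded corner cannot be represented better than a staircase on
this mesh anyway.)

**Nonlinear iteration.** Per-element conductivities are evaluated from the
element-mean field of the previous iterate and relaxed with damping 0.5
(Picard). The contrast is modest (0.4 → 0.6 S/m), so the damped fixed
point converges in ~5–15 iterations to a relative σ-change below 1e−4.
The sparse SPD systems are solved by CHOLMOD Cholesky with the symbolic
factorization reused across iterations.

**Current.** The delivered current is the stiffness action on the
converged solution summed over the electrode nodes (the volume-consistent
discrete flux), which is mesh-robust and makes the electrode/ground
balance exact to round-off — the balance check in the suite guards the
wiring rather than the quadrature. The voltage matching a target current
is found by secant iteration; since I(V) is mildly superlinear (σ grows
with E), 2–4 voltage solves suffice, each warm-started from the previous
conductivity state.

**Field evaluation.** The FEM field is element-constant. For resampling it
is recovered to nodes by volume-weighted averaging **separately per tissue
label**, so the physical jump of |E| across conductivity interfaces is
preserved instead of smeared; a query point is interpolated bilinearly
from its own tissue's recovery. This is what lets the lesion boundary
coincide exactly with a fat boundary when the field saturates the deposit.

**Lesion metrics.** |E| is resampled on a 0.025 mm grid over the tissue
half-plane; the lethal superlevel set is labeled by connected components
and only the component in contact with the electrode counts as *the*
lesion. Distant superlevel pockets — typically inside far fat deposits,
where the local field is amplified by σ_fat ≪ σ_scar — are reported
separately as satellites. Depth is the maximum z of the lesion component
(measured from the undisturbed surface, whatever tissue the isoline ends
in); surface width is twice its maximum radius in the first tissue row at
z = 0⁺. Isolines are extracted by marching-squares interpolation.

## The synthetic heterogeneous geometry

Real fat-deposition walls are described by histological imaging that is
not reproducible here; the package's model D is an explicitly
**synthetic, parametric stand-in**: a fibrotic scar (18 mm wide, 6 mm
deep, 1 mm viable subendocardial rim) containing one dominant fat slab
(r ≤ 3.5 mm, 2.6–4.59 mm deep) plus six seeded elliptical blobs with
0.3–1.0 mm semi-axes scattered lateral to and above the slab. The slab's
lower boundary at 4.59 mm is the feature that matters mechanistically:
fields inside fat are amplified by roughly σ_scar/σ_fat at the entry
face, so the whole slab exceeds the lethal threshold while the tissue
just below it does not, and the lesion depth clamps to the slab bottom
independent of current. The blobs reproduce the patchy-deposit morphology
around which hot/cold points form; their exact positions are seeded and
deterministic.

Blob placement draws the semi-axes, then places blobs largest-first at
the best of 250 candidate positions (widest clearance margin, with
ellipse separation bounded by support radii along the center line),
restarting the configuration if it jams; an extreme draw that is
geometrically unpackable shrinks the semi-axes by 7% per 40 restarts so
the requested count is always honoured. What the generator does *not*
emulate: irregular (non-elliptical) deposit shapes, fibro-fatty
interdigitation, and any correlation between deposit position and scar
architecture — passing tests on model D therefore demonstrate the
clamping and hot/cold mechanisms, not histological realism.

## Verification

The suite checks the solver against problems with independent answers:
a staircase-centered hemispherical electrode against its closed-form
current and potential (2–3%), an insulating sphere in a uniform field
against the 3σm/(2σm+σf) interior-field factor (2%) with cold poles and a
hot equator, tangential-E/normal-J continuity across the epicardial fat
interface (5%), exact voltage scaling in the all-linear configuration,
strict I(V) monotonicity, charge balance, and mesh- and
resampling-refinement stability of the lesion metrics. The end-to-end
lesion table is asserted against its published reference values at the
tolerances stated in the acceptance tests (±10% on sizes, ±25% on pooled
slopes); the observed headline numbers live in `results/` after running
the analysis scripts, not in this text.

## Problem sizes and runtime

The reference mesh (`h_fine` 0.05 mm, `h_lesion` 0.15 mm) has ~14k nodes
and 28k triangles per model; a current-matched nonlinear solve takes a few
seconds on one core and the full 6 × 3 experiment about half a minute.
The test suite uses the reference mesh for the quantitative models A/B and
a mildly coarser profile (0.06/0.18 mm) for the qualitative scar models;
the interface-continuity check refines to 0.075 mm through the epicardial
boundary, where the one-sided recovery error is O(h).

## Known limitations

- Single lethal threshold for all tissues and pulse protocols; no
  dose/number-of-pulses dependence.
- No thermal or electro-thermal coupling; no conductivity anisotropy.
- Perpendicular catheter with rigid conforming contact only.
- Voxelized blob boundaries: sub-resolution blobs would need a locally
  finer mesh.
- The model-D geometry is a parametric surrogate — quantitative lesion
  sizes for heterogeneous walls should be read as mechanism
  demonstrations, not predictions for a specific patient substrate.
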