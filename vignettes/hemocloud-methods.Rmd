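---
title: "hemocloud: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemocloud: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hemocloud` is a desk-scale, fully self-contained pipeline for learning to
predict steady hemodynamics — per-point velocity and pressure — in idealized
side-wall cerebral aneurysms, before and after placement of a
flow-diverting (FD) stent represented as a thin Darcy–Forchheimer porous
layer across the aneurysm neck. No external data are required: geometry,
flow fields, point clouds, network training and evaluation are all
generated and executed by the package, seeded end to end. This vignette
records the models, the tunable parameters, and the design decisions,
including the places where the design was genuinely open and what we chose.

## 1. Parametric geometry

Each model is the union of a tube (parent artery, diameter `DP`) swept
along a constant-curvature planar centerline and a sphere (aneurysm sac,
diameter `DA`) whose center sits at distance `CC` from the centerline.
Five morphological parameters are sampled independently and uniformly
within the ranges

| parameter | meaning | range | units |
|---|---|---|---|
| DA | sac diameter | 8–12 | mm |
| CC | sac center to centerline | 6–8 | mm |
| DP | parent artery diameter | 8–12 | mm |
| CP | centerline curvature (type 2) | 0.01–0.033 | 1/mm |
| LA | angular sac location (type 2) | 0–180 | degrees |

Uniform sampling is the maximum-entropy reading of "randomly selected
within a reasonable range"; nothing in the source design constrains the
shape of the distribution. Draws violating `CC < (DA+DP)/2` (sac must
reach the wall) or `CC + DA/2 > DP/2` (sac must protrude from the lumen)
are rejected and resampled; these inequalities are ours, added because the
sampled `CC` range overlaps the sampled lumen radius range.

**Centerline extent and the role of LA.** Fully developed inflow requires
a long upstream run; we build 10 parent diameters of artery upstream of
the sac and 5 downstream. For a constant-curvature arc, the angular
station of the sac is a rigid motion — it does not change the intrinsic
shape — and for strongly curved, wide arteries a fixed 0–180° arc can be
shorter than 10 diameters. We therefore always anchor the sac 10·DP
downstream of the inlet and treat `LA` as a sampled morphological label
that is geometrically inert in this construction. The total swept angle is
capped (4.5 rad, and always below the self-contact limit
`2π − 2·asin(r_tube/R)`) by shortening the downstream run, so the tube can
never intersect itself. The practical consequence: the surrogate's neck
inflow is modelled from quantities observable in the geometry (`DP`,
`CP`, neck orifice width) and *not* from `LA` — an inflow that depended on
a geometrically inert label would be unlearnable from shape alone.

The sac attaches to the outer wall of the bend by default
(`sac_side = 1`); the convention is exposed because the source imagery
does not fix it.

Points are classified `aneurysm_sac` iff they are inside the sphere and
outside the tube; neck-interior points (inside both) count as
`parent_artery`, which keeps sac-region statistics independent of the
through-flow in the lumen.

**Point sampling.** Boundary (model-cloud) points are drawn uniformly on
the lateral tube wall and the exposed sphere; interior (query-cloud)
points are drawn uniformly in the volume with the expected density doubled
within `0.1·DP` of the wall, emulating the boundary-refined node
distribution of the CFD meshes the clouds stand in for. A handful of
points are placed inside the 150 µm porous-layer shell at the neck; they
carry no special label, matching the principle that the learner never
needs to know which points belong to the stent domain.

## 2. Flow surrogate

The package replaces the commercial CFD stage with a semi-analytic steady
surrogate whose contract is the set of flow features the CFD fields
exhibit. It is **not** a Navier–Stokes solver; it is the training-data
generator, and the learning stack is agnostic to where fields come from
(externally computed fields can be attached to clouds through
`extract_clouds(flow_fun = ...)`).

With blood density ρ = 1050 kg/m³, viscosity μ = 0.0035 Pa·s, inlet mass
flow 0.004375 kg/s and zero outlet pressure:

* **Parent artery.** Poiseuille profile
  `v(r) = 2 v_mean (1 − (r/R)²)`, `v_mean = ṁ/(ρπR²)`. Curvature skews
  the profile toward the outer wall by a factor
  `1 + δ ρ cos ψ` with `δ = min(0.2, 1.2·DP·CP)`; the skew integrates to
  zero so mass flux is preserved exactly. The cap at 0.2 is the largest
  skew compatible with the no-slip decay contract (speed < 10 % of
  `v_mean` within 2 % of the wall). A weak two-cell in-plane secondary
  circulation (stream function `∝ ρ²(1−ρ²)² sin ψ`) with Dean-like
  amplitude `∝ √(R·CP)·Re` reproduces the curvature-driven secondary flow;
  it has no axial component and vanishes at the wall.
* **Sac.** A single vortex about the axis `t̂ × n̂`:
  `v = Ω (t̂×n̂) × (p − c) (1 − ρ²)`, zero at the wall and the core, with
  peak speed ≈ 0.9× the neck inflow speed. Fluid sweeps along the neck
  and turns into the sac at the distal edge. The neck inflow scale is
  `0.55 v_mean (1 + DP·CP)(0.5 + 0.5 w/r_sac)` where `w` is the orifice
  half-width — a modelling choice, set once, reflecting that inflow jets
  scale with parent near-wall momentum and orifice size.
* **Stent (post-operative).** The FD stent is the porous layer: thickness
  150 µm, permeability K = 0.001489 mm², inertial coefficient
  C = 7665 m⁻¹. Its Darcy–Forchheimer momentum sink
  `S = −(μ/K v + C ½ρ|v|v)` integrates across the thin layer to a
  pressure-jump law `ΔP(v) = t(μ/K v + C ½ρ v²)`. The neck inflow is
  attenuated by the transmission factor `v_through/v_approach`, where
  `v_through` is the closed-form positive root of `ΔP(v) = ½ρ v_approach²`
  (the stagnation pressure of the arrested jet). With the default
  coefficients this yields roughly a 20-fold reduction of sac speeds —
  the shunt effect.
* **Pressure.** Hagen–Poiseuille axial gradient `8μ v_mean/R²` anchored to
  zero at the outlet; the sac sits at the neck-station pressure with a
  stagnation-scale dip toward the core, and post-operatively the whole sac
  is offset by the layer pressure drop at the transmitted speed.
* **Noise.** A smooth random field (32 Gaussian bumps, amplitude
  normalized) perturbs velocity by at most 2 % of the *local* speed and
  pressure by the same fraction of the local dynamic pressure. This keeps
  the learning task full-rank without violating no-slip. Zero noise
  reproduces the analytic composition exactly.

What the surrogate does **not** reproduce: boundary-layer development,
secondary-flow feedback on the axial profile, unsteadiness, non-Newtonian
rheology, wall shear stress, and any LA-dependence of sac inflow. Passing
tests demonstrate that the learning stack recovers fields with this
structure at desk scale; they do not certify accuracy on real CFD data.

## 3. Data sets and splits

Every model contributes one boundary cloud and one interior cloud, shared
by all four data-set variants (preop/postop × velocity/pressure); variants
differ only in the attached targets. The canonical pose — inlet at the
origin, inlet tangent +x, centerline in the z = 0 plane — removes pose
ambiguity. Serialization is ASCII legacy-VTK polydata or PLY with arrays
named `velocity` and `pressure`, plus a JSON manifest of every seed and
parameter draw; these writers are hand-rolled because no installed R
package provides the formats.

The 9:1 train/test split is stratified by model type with a per-stratum
floor on the test count, which reproduces the 450/50 (90 type 1 + 360
type 2 train) design exactly. Every stage seed derives from one master
seed via `derive_seed()`, so any stage can be deleted and regenerated
bit-for-bit.

Scale presets: `ci` (8 models, hundreds of points, smoke tests), `desk`
(50 models per variant at ≈ 2,000 query points each — the scale at which
all quantitative results in this package are computed) and
`full_scale` (500 models, ~5·10⁴-point model clouds, ~2.6·10⁵-point
query clouds; provided for completeness, intended for long offline runs).

## 4. The double-input point network

Architecture (per point, fully connected, ReLU):

* shared primary stage 64–64–128 applied to both clouds (weights shared,
  realizing the shared FC1/FC2 design; an option disables sharing);
* global channel 256–512 on the model cloud, reduced by coordinate-wise
  max pooling to one 512-d geometry vector (the symmetric function that
  makes the result order-independent), standardized across its dimensions
  (parameter-free) so the output stack sees between-model contrast;
* local channel 128 on the query cloud;
* stitching to 640 = 512 + 128 per query point;
* output stack 256–128–(3 or 1).

Training: mean absolute error, Adam (lr 0.001, β₁ 0.9, β₂ 0.999,
ε 10⁻⁸), one model per optimization step, model order shuffled per epoch,
10 % of training pairs held out for validation, patience-based
checkpointing of the best validation weights. Per step the query and
model clouds may be row-subsampled (desk preset: 384 query / 192 model
points) purely for CPU throughput; validation always uses all points.
Training is bit-deterministic for a fixed seed.

**Input canonicalization.** The widths above follow the PointNet lineage,
but two desk-scale realities forced deliberate extensions, both applied
identically to the two clouds and all deterministic functions of the
network's own inputs (the external interface remains two coordinate
clouds):

1. *Tube-fitted canonical frame.* Under the pose convention, the parent
   artery projects to a circle or line in the x–y plane. A robust,
   progressively trimmed circle fit (with orthogonal-distance refinement,
   and a capped-loss comparison against a line fit to decide
   curved vs. straight) recovers the centerline from the model cloud
   alone; the sac is located as the boundary region farthest from the
   centerline, and the inlet is identified as the tube end farther from
   the sac. Every point is then encoded as (s/L, a_n/r̂, b/r̂) — arc
   length, radial offset, binormal offset — with two per-pair constants
   (total bend, radius/length aspect). Velocity targets are rotated into
   the local (tangent, normal, binormal) frame and predictions rotated
   back. Rationale: with raw coordinates the identical flow structure
   appears at a different place in every model, and the optimizer —
   fixed by design at Adam/0.001 with batch 1 — could not converge within
   CPU budgets (validation MAE stalled near 0.33 after 27,000 steps;
   canonicalization halves it in a fifth of the steps).
2. *Sinusoidal positional encoding.* Six octaves of sin/cos per canonical
   coordinate (3 → 39 + 2 dims). Flow varies across the thin lumen on
   ~5 % of the model's extent; with raw coordinates the first-layer
   weights would have to grow two orders of magnitude beyond their
   initialization, which Adam at lr 0.001 cannot do in any reasonable
   number of steps (measured: single-model 200-step memorization reaches
   34 % of the initial loss without the encoding, 2 % with it).

Both extensions preserve the permutation invariance (model cloud),
permutation equivariance (query cloud), duplication invariance (max
reduction + deduplicated frame estimation) and translation invariance
that the architecture promises, and all of these are tested.

**Target scaling.** Before any transform, each pair's targets are divided
by a laminar-scaling amplitude evaluated from cloud-estimated quantities:
velocity by `(r̂/5 mm)⁻²` and pressure by `(L̂/150 mm)(r̂/5 mm)⁻⁴`
(the Poiseuille mean-speed and pressure-drop laws). The scale is inverted
at prediction, so it is an invertible per-pair affine map, like the
coordinate normalization. Without it the pressure network simply
memorized the training clouds through the pooled geometry vector
(training MAE 0.10 vs validation 0.48): a fourth-power amplitude law is
not identifiable from 40 training geometries by gradient descent, while
dividing it out reduces the learning task to the field's shape.

**Target transform.** The scaled targets are mapped through `asinh(Y/s0)` with
`s0 = 10⁻³·max|Y|` (training set), then standardized per data set; the
inverse is applied at prediction. The asinh makes the MAE loss resolve
slow sac flow and near-outlet pressure as well as the fast lumen core —
with plain standardization the trained network had a flat ≈ 7·10⁻³ m/s
absolute error at all speeds, which is invisible to NMAE but ruinous to
per-point relative error. The knee is aligned with the relative-error
metric's exclusion floor (see below).

## 5. Error functionals

For scalarized fields (velocity is scored on its magnitude |V| by
default; a per-component mode exists):

* `NMAE = 100 · mean|Q − Q̂| / (max|Q| − min|Q|)`, normalized per model;
* `MRE = 100 · mean(|Q − Q̂|/|Q|)` over points with
  `|Q| ≥ 10⁻³·max|Q|`; the excluded count is always reported. The floor
  is ours: as printed, the per-point relative error is unbounded as the
  true value approaches zero, and interior points arbitrarily close to a
  no-slip wall make the bare mean meaningless.

Reports give mean ± sd across test models, for the whole model and for
the sac region separately; the ± is across models, not points.

**A desk-scale limitation worth stating plainly.** MRE is pointwise
relative, and near-wall query points (deliberately over-sampled, as CFD
meshes are) have true speeds that vanish at the wall. Predicting such a
point to within, say, 15 % relative error requires localizing the wall to
a fraction of the point's wall distance. The information for that comes
from the boundary cloud: at desk scale (≈ 350 boundary points, ≈ 4 mm
spacing) the wall is only localizable to a few percent of the radius,
while full-scale clouds (5·10⁴ points) pin it two orders of magnitude
better. Sac fields compound this: their amplitude is set by geometry
quantities (orifice width, curvature) that must themselves be inferred
from the sparse cloud. Whole-model NMAE is insensitive to this (the
affected speeds are small absolute numbers); MRE is dominated by it. The
package therefore reaches full-scale-like NMAE at desk scale, while
desk-scale MRE — especially in the sac — remains well above the
full-scale figure, by an amount that shrinks with cloud density rather
than with training effort.

## 6. Numerical choices and degenerate inputs

* Rejection sampling for parameters is bounded (1,000 attempts) and an
  exhaustion signals a configuration error rather than looping.
* The signed distance uses exact tube/sphere distances; tube end caps are
  spherical (distance to the clamped centerline), which only affects
  points beyond the artery ends.
* `transmission_factor` uses the closed-form positive quadratic root; a
  property test confirms `pressure_drop(v_through) = driving_dp` to
  10⁻⁹ relative.
* Max-pool argmax ties break to the first index; training is therefore
  bit-reproducible under a fixed seed.
* NMAE refuses degenerate fields (zero magnitude range); MRE refuses
  all-below-floor inputs.
* The stratified split uses `floor(n(1−ratio) + 10⁻⁹)` per stratum —
  the epsilon guards against binary floating point (40 × 0.1 is slightly
  below 4).
* Post-operative networks are warm-started from the corresponding
  pre-operative network in the pipeline: the fields differ only through
  the porous-layer attenuation, and the warm start roughly halves the
  training cost of the second network of each quantity.

## 7. Problem sizes used in the shipped analyses

All quantitative statements produced by the test-suite and the acceptance
script use: 50 models per variant (10 type 1, 40 type 2), 9:1 stratified
split (45/5), ≈ 350-point model clouds, ≈ 1,900-point query clouds, 2 %
field noise, and the training configuration of the `desk` preset. The
mesh-independence analogue (sampling-density stability) and the
split-robustness property use reduced configurations documented in the
tests themselves. These sizes are the package's chosen desk-scale study
conditions; the `full_scale` preset exists for users who want to
approach the original design's scale.
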