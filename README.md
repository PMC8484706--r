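# hemocloud

Point-cloud deep learning for cerebral aneurysm hemodynamics, before and
after flow-diverting (FD) stent placement, as a fully self-contained R
package: parametric side-wall aneurysm geometry synthesis, a steady-flow
surrogate with a Darcy–Forchheimer porous stent layer, dual
(model/query) point-cloud data sets, a double-input point-cloud
regression network written from scratch (forward, backprop, Adam), and
NMAE/MRE evaluation with region-wise reporting. Everything is generated
in code and seeded; no external data are needed.

## The problem and the method

Computing aneurysm hemodynamics with CFD is accurate but slow, and
modelling the stent (either wire-resolved or as a porous medium) makes it
slower still. The approach implemented here learns the mapping from
vascular *geometry* to the steady flow field directly, using two point
clouds per model:

* a **model cloud** `{M_i}` — boundary coordinates only, encoding the
  geometry;
* a **query cloud** `{Q_i}` — interior points at which velocity
  `(Vx, Vy, Vz)` or pressure `P` is defined (training) or requested
  (prediction).

The network processes both clouds with a shared per-point stage
(64–64–128), reduces the model-cloud features with a symmetric
max-pooling to one 512-d global geometry vector, computes a 128-d local
feature per query point, stitches them to 640 = 512 + 128 dimensions and
decodes per-point predictions through a 256–128–(3 or 1) stack. The max
reduction makes the result independent of point order; the per-point
head makes it equivariant to query order. Training uses mean absolute
error with Adam (learning rate 0.001, β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸),
one model per step.

The stent is a thin porous layer across the aneurysm neck
(thickness 150 µm, permeability K = 0.001489 mm², inertial loss
C = 7665 m⁻¹) exerting the Darcy–Forchheimer momentum sink

    S_i = -( μ/K · v_i + C · ρ/2 · |v| · v_i )

which integrates across the layer to the pressure-jump law
ΔP(v) = t·(μ/K·v + C·ρ/2·v²); the closed-form root of this law gives the
transmitted neck speed and hence the post-operative shunt (sac speeds
drop roughly twenty-fold with the default coefficients).

Accuracy is scored with the normalized mean absolute error and the mean
relative error, in percent, per model and per region (whole model vs.
aneurysm sac):

    NMAE = 100 · mean|Q - Q̂| / (max|Q| - min|Q|)
    MRE  = 100 · mean( |Q - Q̂| / |Q| )   over points with |Q| ≥ 1e-3·max|Q|

See `vignette("hemocloud-methods")` for the full model description,
parameter tables, and the design decisions (canonical tube frame,
positional encoding, asinh target transform, physics target scaling) with
their rationale — including an honest account of which metric desk-scale
runs can and cannot reach.

## Worked example

```r
library(hemocloud)

# one curved-artery aneurysm, sampled from the morphological ranges
params <- sample_params("type2", seed = 3)
params
#> aneurysm_params [type2]: DA=8.672 mm  CC=7.615 mm  DP=9.540 mm  CP=0.0175 1/mm  LA=108.4 deg

geom <- build_geometry(params)
qc   <- sample_interior_points(geom, density = 0.05, seed = 2)
pre  <- generate_flow(geom, qc, operative_state = "preop",  seed = 5)
post <- generate_flow(geom, qc, operative_state = "postop",
                      layer = porous_layer(), seed = 5)
pre
#> flow_field [preop]: 719 points (24 sac), speed 0.0001-0.1175 m/s, P 0.007-10.254 Pa
sac <- pre$region == "aneurysm_sac"
mean(sqrt(rowSums(pre$V[sac, ]^2)))   # mean sac speed before stenting
#> [1] 0.01212466
mean(sqrt(rowSums(post$V[sac, ]^2)))  # and after: the shunt effect
#> [1] 0.0005911547
```

The sac-average speed drops about 20× after the porous layer is placed —
the flow-diversion effect the stent exists to produce.

An end-to-end run (generate → simulate → extract → split → train →
evaluate, four data-set variants) at smoke-test scale:

```r
res <- run_pipeline(run_config("ci", seed = 3))
res$reports$preop_velocity
#> error_report [preop/velocity]: 1 test models
#>   aneurysm  NMAE 31.17 +/-   NA %   MRE 199.20 +/-   NA %
#>   whole     NMAE 20.68 +/-   NA %   MRE 197.31 +/-   NA %
```

(`ci` is intentionally tiny; the `desk` preset — 50 models per variant,
roughly 2,000 query points each — is where the quantitative results
below come from.)

A thin command-line front end is installed under
`system.file("cli", "hemocloud", package = "hemocloud")` with verbs
`run`, `stent`, `dataset` and `evaluate`.

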