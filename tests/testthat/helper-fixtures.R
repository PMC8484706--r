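# Small shared fixtures, built in code. Kept deliberately tiny so the whole
# suite stays fast; heavier end-to-end runs live in test-acceptance.R.

fix_geom_type1 <- function(seed = 7) build_geometry(sample_params("type1", seed))

fix_geom_type2 <- function(seed = 3) build_geometry(sample_params("type2", seed))

# one-model dataset with surrogate targets attached
fix_tiny_dataset <- function(quantity = "velocity", state = "preop",
                             seed = 3, surface_density = 0.01,
                             interior_density = 0.01, noise = 0) {
  g <- build_geometry(sample_params("type2", seed))
  mc <- sample_surface_points(g, surface_density, seed = seed + 1)
  qc <- sample_interior_points(g, interior_density, seed = seed + 2)
  ff <- generate_flow(g, qc, operative_state = state,
                      layer = if (state == "postop") porous_layer(),
                      noise_fraction = noise, seed = seed + 3)
  pair <- list(model_cloud = mc, query_cloud = qc,
               target = if (quantity == "velocity") ff$V else
                 matrix(ff$P, ncol = 1),
               region = ff$region, params = g$params)
  hemocloud:::new_hemo_dataset(list(pair), c(state, quantity))
}
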