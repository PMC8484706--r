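test_that("configuration enforces the stitched-dimension and batch anchors", {
  cfg <- network_config()
  expect_identical(cfg$stitched_dim, 640)
  expect_identical(cfg$local_dim + cfg$global_dim, cfg$stitched_dim)
  expect_identical(cfg$batch_models, 1)
  expect_error(network_config(batch_models = 4))
})

test_that("output is invariant to model-cloud order and duplication,
           equivariant to query order", {
  set.seed(5)
  net <- init_network(network_config(), seed = 2)
  M <- matrix(rnorm(90, sd = 0.01), 30, 3)
  Q <- matrix(rnorm(120, sd = 0.01), 40, 3)
  base <- forward_network(net, M, Q)
  expect_identical(dim(base), c(40L, 3L))
  for (i in 1:5) {
    pm <- sample(nrow(M))
    expect_lt(max(abs(forward_network(net, M[pm, ], Q) - base)), 1e-5)
    pq <- sample(nrow(Q))
    expect_identical(forward_network(net, M, Q[pq, ]), base[pq, ])
  }
  # duplicating every model point leaves the max reduction unchanged
  expect_lt(max(abs(forward_network(net, rbind(M, M), Q) - base)), 1e-5)
})

test_that("normalization makes outputs invariant to rigid translation", {
  net <- init_network(network_config(output_dim = 1), seed = 6)
  set.seed(8)
  M <- matrix(rnorm(60, sd = 0.02), 20, 3)
  Q <- matrix(rnorm(45, sd = 0.02), 15, 3)
  base <- forward_network(net, M, Q)
  shift <- c(0.4, -1.2, 3.3)
  moved <- forward_network(net, sweep(M, 2, shift, "+"), sweep(Q, 2, shift, "+"))
  expect_lt(max(abs(moved - base)), 1e-5)
})

test_that("empty or malformed clouds are rejected", {
  net <- init_network(network_config(), seed = 1)
  Q <- matrix(rnorm(9), 3, 3)
  expect_error(forward_network(net, matrix(numeric(0), 0, 3), Q), "empty")
  expect_error(forward_network(net, matrix(rnorm(8), 2, 4), Q), "n x 3")
})

test_that("training is seed-deterministic and refuses mismatched targets", {
  d <- fix_tiny_dataset("pressure", seed = 9, surface_density = 0.004,
                        interior_density = 0.004)
  cfg <- network_config(output_dim = 1, max_epochs = 5, patience = 5,
                        val_frac = 0)
  t1 <- train_network(d, cfg, seed = 3)
  t2 <- train_network(d, cfg, seed = 3)
  expect_identical(t1$net, t2$net)
  t3 <- train_network(d, cfg, seed = 4)
  expect_false(identical(t1$net, t3$net))
  expect_error(train_network(d, network_config(output_dim = 3, max_epochs = 2)),
               "output_dim")
})

test_that("single-model training memorizes the pressure field rapidly", {
  d <- fix_tiny_dataset("pressure", seed = 3)
  cfg <- network_config(output_dim = 1, max_epochs = 200, patience = 200,
                        val_frac = 0)
  tm <- train_network(d, cfg, seed = 11)
  h <- tm$history$train
  expect_lt(h[length(h)] / h[1], 0.2)
  # smoothed loss history is non-increasing (window 10, small transient
  # Adam bumps tolerated)
  sm <- stats::filter(h, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.05 * sm[1]))
  # prediction on the training model is consistent with the overfit loss
  pair <- d$pairs[[1]]
  pred <- predict_network(tm, pair$model_cloud, pair$query_cloud)
  expect_identical(dim(pred), dim(pair$target))
  # far better than a predict-the-mean baseline on the memorized model
  mae_phys <- mean(abs(pred - pair$target))
  expect_lt(mae_phys / mean(abs(pair$target - mean(pair$target))), 0.35)
})

test_that("velocity memorization succeeds with a longer budget", {
  d <- fix_tiny_dataset("velocity", seed = 3)
  cfg <- network_config(output_dim = 3, max_epochs = 400, patience = 400,
                        val_frac = 0)
  tm <- train_network(d, cfg, seed = 11)
  h <- tm$history$train
  expect_lt(h[length(h)] / h[1], 0.2)
  pair <- d$pairs[[1]]
  pred <- predict_network(tm, pair$model_cloud, pair$query_cloud)
  expect_identical(dim(pred), c(nrow(pair$query_cloud), 3L))
})

test_that("checkpoints round-trip through save_model/load_model", {
  d <- fix_tiny_dataset("pressure", seed = 2, surface_density = 0.004,
                        interior_density = 0.004)
  cfg <- network_config(output_dim = 1, max_epochs = 3, patience = 3,
                        val_frac = 0)
  tm <- train_network(d, cfg, seed = 5)
  f <- tempfile(fileext = ".rds")
  save_model(tm, f)
  back <- load_model(f)
  expect_identical(back$net, tm$net)
  expect_identical(back$variant, tm$variant)
  pair <- d$pairs[[1]]
  expect_identical(predict_network(back, pair$model_cloud, pair$query_cloud),
                   predict_network(tm, pair$model_cloud, pair$query_cloud))
})
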