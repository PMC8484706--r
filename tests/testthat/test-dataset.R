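test_that("extracted clouds have the contracted shapes and labels", {
  g <- fix_geom_type2()
  ff_fun <- function(pts) generate_flow(g, pts, seed = 3)
  cl <- extract_clouds(g, 0.02, 0.01, seed = 4, flow_fun = ff_fun)
  expect_identical(ncol(cl$model_cloud), 3L)      # coordinates only
  expect_gt(nrow(cl$model_cloud), 0)
  expect_gt(nrow(cl$query_cloud), 0)
  expect_identical(nrow(cl$velocity), nrow(cl$query_cloud))
  expect_length(cl$pressure, nrow(cl$query_cloud))
  expect_length(cl$region, nrow(cl$query_cloud))
  expect_true(all(signed_distance(g, cl$query_cloud) < 1e-7))
  expect_error(extract_clouds(g, 1e-9, 1e-9, seed = 1), "empty cloud")
})

test_that("the four variants share clouds and differ only in targets", {
  ds <- build_datasets(1, 2, seed = 77, surface_density = 0.01,
                       interior_density = 0.008)
  expect_named(ds, c("preop_velocity", "preop_pressure",
                     "postop_velocity", "postop_pressure"))
  for (d in ds) expect_length(d$pairs, 3)
  p_vel <- ds$preop_velocity$pairs[[1]]
  p_pre <- ds$preop_pressure$pairs[[1]]
  p_post <- ds$postop_velocity$pairs[[1]]
  expect_identical(p_vel$query_cloud, p_pre$query_cloud)
  expect_identical(p_vel$model_cloud, p_post$model_cloud)
  expect_identical(ncol(p_vel$target), 3L)
  expect_identical(ncol(p_pre$target), 1L)
  # postop sac targets are attenuated relative to preop
  sac <- p_vel$region == "aneurysm_sac"
  expect_lt(mean(sqrt(rowSums(p_post$target[sac, ]^2))),
            mean(sqrt(rowSums(p_vel$target[sac, ]^2))))
  # full determinism
  ds2 <- build_datasets(1, 2, seed = 77, surface_density = 0.01,
                        interior_density = 0.008)
  expect_identical(ds$postop_pressure$pairs, ds2$postop_pressure$pairs)
})

test_that("stratified 9:1 split reproduces the 450/50 design exactly", {
  types <- c(rep("type1", 100), rep("type2", 400))
  si <- split_indices(types, ratio = 0.9, seed = 42)
  expect_length(si$train, 450)
  expect_length(si$test, 50)
  expect_identical(sum(types[si$train] == "type1"), 90L)
  expect_identical(sum(types[si$train] == "type2"), 360L)
  expect_identical(sum(types[si$test] == "type1"), 10L)
  expect_identical(sum(types[si$test] == "type2"), 40L)
  # partition + determinism
  expect_setequal(c(si$train, si$test), seq_along(types))
  expect_length(intersect(si$train, si$test), 0)
  expect_identical(split_indices(types, 0.9, seed = 42), si)
  # per-stratum floor rounding on a small set
  si2 <- split_indices(c(rep("type1", 10), rep("type2", 10)), 0.9, seed = 1)
  expect_length(si2$train, 18)
  expect_length(si2$test, 2)
})

test_that("dataset split partitions pairs by stratum", {
  ds <- build_datasets(2, 4, seed = 5, surface_density = 0.008,
                       interior_density = 0.005)
  sp <- split_dataset(ds$preop_velocity, ratio = 0.75, seed = 9)
  n_tr <- length(sp$train$pairs); n_te <- length(sp$test$pairs)
  expect_identical(n_tr + n_te, 6L)
  expect_identical(n_te, 1L)   # floor(2*0.25) + floor(4*0.25), floors per stratum
})

test_that("point clouds round-trip through legacy VTK and PLY", {
  set.seed(31)
  pts <- matrix(rnorm(60, sd = 0.01), 20, 3)
  vel <- matrix(rnorm(60), 20, 3)
  prs <- rnorm(20)
  for (fmt in c("vtk", "ply")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_point_cloud(pts, f, velocity = vel, pressure = prs)
    rt <- read_point_cloud(f)
    expect_equal(rt$points, pts, tolerance = 1e-7)
    expect_equal(rt$velocity, vel, tolerance = 1e-7)
    expect_equal(rt$pressure, prs, tolerance = 1e-7)
    expect_false(rt$prediction_only)
    # coordinates-only file is flagged prediction-only
    f2 <- tempfile(fileext = paste0(".", fmt))
    write_point_cloud(pts, f2)
    rt2 <- read_point_cloud(f2)
    expect_true(rt2$prediction_only)
    expect_equal(rt2$points, pts, tolerance = 1e-7)
  }
})

test_that("VTK output carries the standard header and named arrays", {
  pts <- matrix(1:9 / 100, 3, 3)
  f <- tempfile(fileext = ".vtk")
  write_point_cloud(pts, f, velocity = pts * 2, pressure = 1:3)
  lines <- readLines(f)
  expect_match(lines[1], "^# vtk DataFile Version")
  expect_true(any(lines == "DATASET POLYDATA"))
  expect_true(any(grepl("^POINTS 3", lines)))
  expect_true(any(grepl("^VECTORS velocity", lines)))
  expect_true(any(grepl("^SCALARS pressure", lines)))
})

test_that("whole data sets round-trip through a directory with manifest", {
  ds <- build_datasets(1, 1, seed = 13, surface_density = 0.008,
                       interior_density = 0.005)
  dir <- file.path(tempdir(), "ds_rt")
  write_dataset(ds$postop_pressure, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dataset(dir)
  expect_identical(back$variant, c("postop", "pressure"))
  expect_length(back$pairs, 2)
  for (i in 1:2) {
    a <- ds$postop_pressure$pairs[[i]]; b <- back$pairs[[i]]
    expect_equal(b$model_cloud, a$model_cloud, tolerance = 1e-7)
    expect_equal(b$query_cloud, a$query_cloud, tolerance = 1e-7)
    expect_equal(b$target, a$target, tolerance = 1e-7)
    expect_identical(b$params$model_type, a$params$model_type)
  }
  unlink(dir, recursive = TRUE)
})

test_that("sac statistics are stable under doubling of sampling density", {
  g <- fix_geom_type2(seed = 21)
  mean_sac_speed <- function(density) {
    qc <- sample_interior_points(g, density, seed = 90)
    ff <- generate_flow(g, qc, noise_fraction = 0, seed = 1)
    sac <- ff$region == "aneurysm_sac"
    mean(sqrt(rowSums(ff$V[sac, , drop = FALSE]^2)))
  }
  m1 <- mean_sac_speed(4)
  m2 <- mean_sac_speed(8)
  expect_lt(abs(m2 - m1) / m1, 0.02)
})
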