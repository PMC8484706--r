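#' Extract model and query point clouds for one aneurysm
#'
#' The model cloud samples the solid boundary (coordinates only); the query
#' cloud samples the interior with near-wall refinement, plus a few points
#' inside the porous-layer shell at the neck (carrying no special label).
#' If `flow_fun` is supplied it is called on the query points to attach
#' per-point field values.
#'
#' @param geom an `aneurysm_geometry`.
#' @param surface_density boundary sampling density, points per mm^2.
#' @param interior_density interior sampling density, points per mm^3.
#' @param seed RNG seed.
#' @param include_sac sample the sac interior (default TRUE).
#' @param layer_points number of extra points in the neck porous-layer
#'   shell (0 disables).
#' @param flow_fun optional `function(points)` returning a `flow_field` at
#'   the query points.
#' @return list with `model_cloud` (N1 x 3), `query_cloud` (N2 x 3),
#'   `region` (length N2), and when `flow_fun` is given `velocity`
#'   (N2 x 3) and `pressure` (N2).
#' @export
extract_clouds <- function(geom, surface_density, interior_density,
                           seed = NULL, include_sac = TRUE,
                           layer_points = 8L, flow_fun = NULL) {
  mc <- sample_surface_points(geom, surface_density, seed = seed)
  qc <- sample_interior_points(geom, interior_density,
                               seed = if (is.null(seed)) NULL else seed + 1L,
                               include_sac = include_sac)
  if (layer_points > 0 && include_sac) {
    lp <- sample_layer_points(geom, layer_points,
                              seed = if (is.null(seed)) NULL else seed + 2L)
    qc <- rbind(qc, lp)
  }
  if (nrow(mc) == 0 || nrow(qc) == 0)
    stop("extract_clouds: empty cloud; increase the sampling densities")
  out <- list(model_cloud = mc, query_cloud = qc,
              region = point_region(geom, qc))
  if (!is.null(flow_fun)) {
    ff <- flow_fun(qc)
    out$velocity <- ff$V
    out$pressure <- ff$P
    out$region <- ff$region
  }
  out
}

new_hemo_dataset <- function(pairs, variant, config = list()) {
  structure(list(pairs = pairs, variant = variant, config = config),
            class = "hemo_dataset")
}

#' Build the four hemodynamic point-cloud data sets
#'
#' For every model: draw morphological parameters, build the geometry,
#' extract the clouds once, generate the pre- and post-operative surrogate
#' flow fields on the shared query points, and assemble the four variants
#' (preop/postop x velocity/pressure). Every stage seed derives from the
#' master seed via [derive_seed()], so identical seeds give identical data.
#'
#' @param n_type1,n_type2 model counts per type.
#' @param seed master seed.
#' @param surface_density,interior_density sampling densities (per mm^2 /
#'   per mm^3).
#' @param noise_fraction smooth field perturbation amplitude.
#' @param bc,props,layer boundary conditions, fluid properties, porous
#'   layer.
#' @param sac_side sac placement side, see [build_geometry()].
#' @return named list of four `hemo_dataset` objects:
#'   `preop_velocity`, `preop_pressure`, `postop_velocity`,
#'   `postop_pressure`.
#' @export
build_datasets <- function(n_type1, n_type2, seed,
                           surface_density = 0.06,
                           interior_density = 0.02,
                           noise_fraction = 0.02,
                           bc = boundary_conditions(),
                           props = fluid_props(),
                           layer = porous_layer(),
                           sac_side = 1) {
  stopifnot(n_type1 >= 1, n_type2 >= 1)
  types <- c(rep("type1", n_type1), rep("type2", n_type2))
  base <- lapply(seq_along(types), function(i) {
    params <- sample_params(types[i], seed = derive_seed(seed, paste0("params/", i)))
    geom <- build_geometry(params, sac_side = sac_side)
    cl <- extract_clouds(geom, surface_density, interior_density,
                         seed = derive_seed(seed, paste0("clouds/", i)))
    pre <- generate_flow(geom, cl$query_cloud, bc, props, "preop",
                         noise_fraction = noise_fraction,
                         seed = derive_seed(seed, paste0("flow/pre/", i)))
    post <- generate_flow(geom, cl$query_cloud, bc, props, "postop", layer,
                          noise_fraction = noise_fraction,
                          seed = derive_seed(seed, paste0("flow/post/", i)))
    list(params = params, model_cloud = cl$model_cloud,
         query_cloud = cl$query_cloud, region = pre$region,
         pre = pre, post = post)
  })
  make <- function(state, quantity) {
    pairs <- lapply(base, function(b) {
      ff <- if (state == "preop") b$pre else b$post
      list(model_cloud = b$model_cloud, query_cloud = b$query_cloud,
           target = if (quantity == "velocity") ff$V else
             matrix(ff$P, ncol = 1),
           region = b$region, params = b$params)
    })
    new_hemo_dataset(pairs, variant = c(state, quantity),
                     config = list(seed = seed, n_type1 = n_type1,
                                   n_type2 = n_type2,
                                   surface_density = surface_density,
                                   interior_density = interior_density,
                                   noise_fraction = noise_fraction))
  }
  list(preop_velocity = make("preop", "velocity"),
       preop_pressure = make("preop", "pressure"),
       postop_velocity = make("postop", "velocity"),
       postop_pressure = make("postop", "pressure"))
}

#' Stratified train/test split indices
#'
#' Per model-type stratum the test count is `floor(n * (1 - ratio))` with
#' the remainder going to training, so a 9:1 split of 100 + 400 models
#' yields exactly 90 + 360 training and 10 + 40 test models.
#'
#' @param types character vector of model types, one per model.
#' @param ratio training fraction in (0, 1).
#' @param seed RNG seed; the same seed reproduces the split.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_indices <- function(types, ratio = 0.9, seed = 1) {
  stopifnot(ratio > 0, ratio < 1)
  local_seed(seed, {
    test <- integer(0)
    for (ty in unique(types)) {
      idx <- which(types == ty)
      n_test <- floor(length(idx) * (1 - ratio) + 1e-9)
      if (n_test > 0)
        test <- c(test, idx[sample.int(length(idx), n_test)])
    }
    list(train = setdiff(seq_along(types), test), test = sort(test))
  })
}

#' Split a data set into training and test portions
#'
#' @param dataset a `hemo_dataset`.
#' @inheritParams split_indices
#' @return list of two `hemo_dataset`s, `train` and `test`.
#' @export
split_dataset <- function(dataset, ratio = 0.9, seed = 1) {
  stopifnot(inherits(dataset, "hemo_dataset"))
  types <- vapply(dataset$pairs, function(p) p$params$model_type, "")
  si <- split_indices(types, ratio, seed)
  list(train = new_hemo_dataset(dataset$pairs[si$train], dataset$variant,
                                dataset$config),
       test = new_hemo_dataset(dataset$pairs[si$test], dataset$variant,
                               dataset$config))
}

#' @export
print.hemo_dataset <- function(x, ...) {
  n2 <- vapply(x$pairs, function(p) nrow(rbind(p$query_cloud)), 1L)
  cat(sprintf("hemo_dataset [%s]: %d pairs, query points %d-%d\n",
              paste(x$variant, collapse = "/"), length(x$pairs),
              if (length(n2)) min(n2) else 0L, if (length(n2)) max(n2) else 0L))
  invisible(x)
}

## ---- point cloud serialization (legacy VTK polydata / ASCII PLY) ----

fmt_num <- function(x) formatC(x, format = "e", digits = 9)

#' Write a point cloud to legacy-VTK polydata or ASCII PLY
#'
#' Coordinates in meters; optional point-data arrays named `velocity`
#' (3 components) and `pressure` (scalar), readable by standard VTK
#' viewers.
#'
#' @param points n x 3 coordinate matrix.
#' @param path output file.
#' @param format `"vtk"` or `"ply"` (default from the file extension).
#' @param velocity optional n x 3 matrix.
#' @param pressure optional length-n vector.
#' @export
write_point_cloud <- function(points, path, format = NULL,
                              velocity = NULL, pressure = NULL) {
  points <- rbind(points)
  n <- nrow(points)
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("vtk", "ply"))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0",
                 "hemocloud point cloud", "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", n)), con)
    writeLines(apply(points, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
    writeLines(sprintf("VERTICES %d %d", n, 2L * n), con)
    writeLines(paste("1", seq_len(n) - 1L), con)
    if (!is.null(velocity) || !is.null(pressure))
      writeLines(sprintf("POINT_DATA %d", n), con)
    if (!is.null(velocity)) {
      writeLines("VECTORS velocity double", con)
      writeLines(apply(rbind(velocity), 1,
                       function(r) paste(fmt_num(r), collapse = " ")), con)
    }
    if (!is.null(pressure)) {
      writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(as.numeric(pressure)), con)
    }
  } else {
    props <- c("x", "y", "z")
    dat <- points
    if (!is.null(velocity)) { props <- c(props, "vx", "vy", "vz"); dat <- cbind(dat, rbind(velocity)) }
    if (!is.null(pressure)) { props <- c(props, "pressure"); dat <- cbind(dat, as.numeric(pressure)) }
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", n),
                 paste("property double", props), "end_header"), con)
    writeLines(apply(dat, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a point cloud written by [write_point_cloud()]
#'
#' @param path input file.
#' @param format `"vtk"` or `"ply"` (default from the extension).
#' @return list with `points` and, when present in the file, `velocity`
#'   and `pressure`; `prediction_only` is TRUE when no field arrays were
#'   found.
#' @export
read_point_cloud <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("vtk", "ply"))
  lines <- readLines(path)
  out <- list(points = NULL, velocity = NULL, pressure = NULL)
  if (format == "vtk") {
    parse_block <- function(start, n, ncol) {
      block <- lines[start:(start + n - 1L)]
      matrix(scan(text = block, quiet = TRUE), n, ncol, byrow = TRUE)
    }
    i_pts <- grep("^POINTS ", lines)[1]
    n <- as.integer(strsplit(lines[i_pts], " +")[[1]][2])
    out$points <- parse_block(i_pts + 1L, n, 3L)
    i_vel <- grep("^VECTORS velocity", lines)
    if (length(i_vel)) out$velocity <- parse_block(i_vel[1] + 1L, n, 3L)
    i_pr <- grep("^SCALARS pressure", lines)
    if (length(i_pr)) out$pressure <- as.numeric(
      scan(text = lines[(i_pr[1] + 2L):(i_pr[1] + 1L + n)], quiet = TRUE))
  } else {
    i_end <- grep("^end_header", lines)[1]
    hdr <- lines[seq_len(i_end)]
    n <- as.integer(sub("element vertex ", "",
                        hdr[grep("^element vertex", hdr)]))
    props <- sub("property double ", "", hdr[grep("^property", hdr)])
    dat <- matrix(scan(text = lines[(i_end + 1L):(i_end + n)], quiet = TRUE),
                  n, length(props), byrow = TRUE)
    colnames(dat) <- props
    out$points <- unname(dat[, c("x", "y", "z"), drop = FALSE])
    if (all(c("vx", "vy", "vz") %in% props))
      out$velocity <- unname(dat[, c("vx", "vy", "vz"), drop = FALSE])
    if ("pressure" %in% props) out$pressure <- unname(dat[, "pressure"])
  }
  out$prediction_only <- is.null(out$velocity) && is.null(out$pressure)
  out
}

#' Write a data set to disk
#'
#' One model- and one query-cloud file per pair (legacy-VTK or PLY) plus a
#' JSON manifest recording the variant, counts, seeds and parameter draws.
#' Optionally bundles the directory into a `.tar.gz` archive.
#'
#' @param dataset a `hemo_dataset`.
#' @param dir output directory (created).
#' @param format `"vtk"` (default) or `"ply"`.
#' @param archive also create `<dir>.tar.gz`.
#' @export
write_dataset <- function(dataset, dir, format = "vtk", archive = FALSE) {
  stopifnot(inherits(dataset, "hemo_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  quantity <- dataset$variant[2]
  manifest <- list(variant = dataset$variant, n_pairs = length(dataset$pairs),
                   config = dataset$config, format = format, models = list())
  for (i in seq_along(dataset$pairs)) {
    p <- dataset$pairs[[i]]
    mf <- file.path(dir, sprintf("model_%03d_model.%s", i, format))
    qf <- file.path(dir, sprintf("model_%03d_query.%s", i, format))
    write_point_cloud(p$model_cloud, mf)
    tgt <- rbind(p$target)
    write_point_cloud(p$query_cloud, qf,
                      velocity = if (quantity == "velocity") tgt,
                      pressure = if (quantity == "pressure") as.numeric(tgt))
    manifest$models[[i]] <- list(index = i, params = unclass(p$params),
                                 n_model = nrow(rbind(p$model_cloud)),
                                 n_query = nrow(rbind(p$query_cloud)),
                                 region_sac = sum(p$region == "aneurysm_sac"))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (archive) {
    old <- setwd(dirname(dir)); on.exit(setwd(old))
    utils::tar(paste0(basename(dir), ".tar.gz"), basename(dir),
               compression = "gzip")
  }
  invisible(dir)
}

#' Read a data set written by [write_dataset()]
#'
#' @param dir data set directory.
#' @return a `hemo_dataset`. Regions are reconstructed from the stored
#'   parameter draws.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  variant <- unlist(manifest$variant)
  fmt <- manifest$format %||% "vtk"
  pairs <- lapply(seq_len(manifest$n_pairs), function(i) {
    m <- read_point_cloud(file.path(dir, sprintf("model_%03d_model.%s", i, fmt)))
    q <- read_point_cloud(file.path(dir, sprintf("model_%03d_query.%s", i, fmt)))
    pr <- manifest$models[[i]]
    params <- aneurysm_params(pr$params$model_type, pr$params$DA, pr$params$CC,
                              pr$params$DP, pr$params$CP, pr$params$LA)
    geom <- build_geometry(params)
    target <- if (variant[2] == "velocity") q$velocity else
      if (!is.null(q$pressure)) matrix(q$pressure, ncol = 1) else NULL
    list(model_cloud = m$points, query_cloud = q$points, target = target,
         region = point_region(geom, q$points), params = params,
         prediction_only = q$prediction_only)
  })
  new_hemo_dataset(pairs, variant, config = lapply(manifest$config, unlist))
}
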