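#' Network architecture and training configuration
#'
#' The double-input point-cloud regression network: a shared primary stage
#' of per-point fully connected layers applied to both clouds, a global
#' channel that deepens the model-cloud features and reduces them with a
#' symmetric max-pooling over points to one 512-d geometry vector, a local
#' channel producing a 128-d feature per query point, feature stitching to
#' 640 = 512 + 128 dimensions, and a per-point output stack. Trained with
#' mean-absolute-error loss and Adam, one model per step.
#'
#' @param output_dim 3 (velocity) or 1 (pressure).
#' @param primary_widths widths of the shared primary stage.
#' @param global_widths widths of the global channel after the shared stage
#'   (last width is the global feature dimension).
#' @param local_widths widths of the local channel after the shared stage
#'   (last width is the local feature dimension).
#' @param head_widths hidden widths of the output stack.
#' @param share_primary share the primary-stage weights across the two
#'   channels (default TRUE).
#' @param posenc_freqs number of octaves of the fixed sinusoidal positional
#'   encoding applied to the (normalized) coordinates before the first
#'   learned layer: each axis `x` is expanded with `sin(2^k pi x)`,
#'   `cos(2^k pi x)` for `k = 0, ..., posenc_freqs - 1`. The encoding is
#'   deterministic and per-point, so it preserves all permutation
#'   properties; it lets the per-point layers resolve the fine radial
#'   variation of the flow across the thin lumen at the configured
#'   learning rate. 0 disables it.
#' @param global_norm standardize the max-pooled global vector across its
#'   dimensions (parameter-free) before stitching, so the output stack sees
#'   between-model shape contrast rather than the common mode shared by all
#'   geometries (default TRUE).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param batch_models models per optimization step (fixed at 1).
#' @param max_epochs,patience training length and early-stopping patience
#'   (epochs without validation improvement).
#' @param val_frac fraction of training pairs held out for validation
#'   checkpointing.
#' @param query_batch,model_cap optional per-step subsample sizes for query
#'   and model points (NULL = use all points of the model).
#' @param target_transform `"asinh"` (default) trains on
#'   `asinh(target / s0)` with `s0 = s0_frac * max|target|` over the
#'   training set, standardized per data set and inverted at prediction.
#'   The inverse-hyperbolic-sine compresses the dynamic range so the MAE
#'   loss resolves the slow sac flow as well as the fast parent-artery
#'   core (absolute below `s0`, logarithmic above). `"standard"` trains on
#'   plainly standardized targets.
#' @param s0_frac scale knee of the asinh transform as a fraction of the
#'   training-set maximum magnitude.
#' @param physics_scale divide each pair's targets by a laminar-scaling
#'   amplitude computed from the cloud-estimated lumen radius r and length
#'   L (velocity ~ r^-2, pressure ~ L r^-4) before standardization, and
#'   multiply predictions back. Removes the dominant between-model
#'   amplitude variation, which would otherwise have to be inferred from
#'   the pooled geometry vector (default TRUE; only active with
#'   `canonical`).
#' @param wall_feats augment the per-point encoding with fixed geometric
#'   features computed from the model cloud itself: the distance to the
#'   nearest boundary point (with sinusoidal harmonics) and the unit offset
#'   to it. These are deterministic functions of the two input clouds --
#'   the external coordinates-only interface is unchanged -- and they let
#'   the network resolve no-slip wall structure without having to infer
#'   the wall location from scratch (default TRUE).
#' @return a `network_config` list.
#' @export
network_config <- function(output_dim = 3,
                           primary_widths = c(64, 64, 128),
                           global_widths = c(256, 512),
                           local_widths = 128,
                           head_widths = c(256, 128),
                           share_primary = TRUE,
                           posenc_freqs = 6,
                           global_norm = TRUE,
                           lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                           batch_models = 1,
                           max_epochs = 100, patience = 15, val_frac = 0.1,
                           query_batch = NULL, model_cap = NULL,
                           target_transform = c("asinh", "standard"),
                           s0_frac = 1e-3,
                           wall_feats = FALSE,
                           canonical = TRUE,
                           physics_scale = TRUE) {
  target_transform <- match.arg(target_transform)
  stopifnot(batch_models == 1)
  local_dim <- local_widths[length(local_widths)]
  global_dim <- global_widths[length(global_widths)]
  structure(list(
    output_dim = output_dim, primary_widths = primary_widths,
    global_widths = global_widths, local_widths = local_widths,
    head_widths = head_widths, share_primary = share_primary,
    posenc_freqs = posenc_freqs,
    global_norm = global_norm,
    input_dim = 3L + 6L * posenc_freqs +
      (if (wall_feats) 8L else 0L) + (if (canonical) 4L else 0L),
    local_dim = local_dim, global_dim = global_dim,
    stitched_dim = local_dim + global_dim,
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
    batch_models = batch_models, max_epochs = max_epochs,
    patience = patience, val_frac = val_frac,
    query_batch = query_batch, model_cap = model_cap,
    target_transform = target_transform, s0_frac = s0_frac,
    wall_feats = wall_feats, canonical = canonical,
    physics_scale = physics_scale
  ), class = "network_config")
}

new_layer <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

stack_layers <- function(n_in, widths) {
  out <- list()
  for (w in widths) { out[[length(out) + 1L]] <- new_layer(n_in, w); n_in <- w }
  out
}

#' Initialize network weights
#'
#' @param config a [network_config()].
#' @param seed RNG seed for the (He-scaled Gaussian) initialization.
#' @return object of class `point_network`.
#' @export
init_network <- function(config = network_config(), seed = 1) {
  d_in <- config$input_dim %||% 3L
  local_seed(seed, {
    prim <- stack_layers(d_in, config$primary_widths)
    last_prim <- config$primary_widths[length(config$primary_widths)]
    net <- list(
      prim = prim,
      prim_m = if (config$share_primary) NULL else stack_layers(d_in, config$primary_widths),
      glob = stack_layers(last_prim, config$global_widths),
      loc = stack_layers(last_prim, config$local_widths),
      head = stack_layers(config$stitched_dim,
                          c(config$head_widths, config$output_dim)),
      config = config
    )
    structure(net, class = "point_network")
  })
}

relu <- function(z) z * (z > 0)

# forward through a layer stack with ReLU on every layer except (optionally)
# the last; returns activations per layer for backprop.
fwd_stack <- function(x, layers, final_linear = FALSE) {
  acts <- vector("list", length(layers) + 1L)
  zs <- vector("list", length(layers))
  acts[[1L]] <- x
  for (i in seq_along(layers)) {
    z <- acts[[i]] %*% layers[[i]]$W
    z <- sweep(z, 2, layers[[i]]$b, "+")
    zs[[i]] <- z
    acts[[i + 1L]] <- if (final_linear && i == length(layers)) z else relu(z)
  }
  list(acts = acts, zs = zs)
}

# gradient through a layer stack; dout is the gradient at the stack output.
# Returns per-layer dW/db and the gradient at the stack input.
bwd_stack <- function(dout, fw, layers, final_linear = FALSE) {
  grads <- vector("list", length(layers))
  da <- dout
  for (i in rev(seq_along(layers))) {
    dz <- if (final_linear && i == length(layers)) da
          else da * (fw$zs[[i]] > 0)
    grads[[i]] <- list(W = crossprod(fw$acts[[i]], dz), b = colSums(dz))
    da <- tcrossprod(dz, layers[[i]]$W)
  }
  list(grads = grads, din = da)
}

# Center both clouds on the model-cloud centroid and scale by its bounding
# radius; applied identically to both inputs.
normalize_pair <- function(M, Q) {
  ctr <- colMeans(M)
  Mc <- sweep(M, 2, ctr)
  sc <- max(vec_norm(Mc))
  if (sc == 0) sc <- 1
  list(M = Mc / sc, Q = sweep(Q, 2, ctr) / sc, center = ctr, scale = sc)
}

# Fixed sinusoidal positional encoding of (normalized) coordinates.
posenc <- function(X, n_freq) {
  if (n_freq < 1) return(X)
  out <- vector("list", 1L + 2L * n_freq)
  out[[1L]] <- X
  for (k in seq_len(n_freq)) {
    out[[2L * k]] <- sin(2^(k - 1) * pi * X)
    out[[2L * k + 1L]] <- cos(2^(k - 1) * pi * X)
  }
  do.call(cbind, out)
}

# Fixed per-point geometric features derived from the two input clouds:
# distance from each point to the nearest model-cloud (boundary) point and
# the unit offset to it (a local wall-normal estimate), plus sinusoidal
# harmonics of the wall distance. Deterministic functions of the network's
# own inputs, so the coordinate-only interface and the permutation /
# duplication / translation symmetries are preserved.
wall_features <- function(P, M, freqs = 4:7, k = 6L) {
  n <- nrow(P)
  d2 <- outer(rowSums(P^2), rep(1, nrow(M))) +
    outer(rep(1, n), rowSums(M^2)) - 2 * tcrossprod(P, M)
  d2[d2 < 0] <- 0
  k <- min(k, ncol(d2))
  d <- numeric(n)
  u <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])[seq_len(k)]
    off <- P[i, ] - t(M[ord, , drop = FALSE])        # 3 x k offsets
    len <- sqrt(colSums(off^2))
    keep <- len > 1e-12
    if (!any(keep)) next
    dirs <- off[, keep, drop = FALSE] / rep(len[keep], each = 3)
    ubar <- rowMeans(dirs)
    nu <- sqrt(sum(ubar^2))
    if (nu < 1e-12) { d[i] <- min(len); next }
    ubar <- ubar / nu
    # averaging the neighbor directions cancels the tangential sampling
    # noise of the boundary cloud; project offsets on the mean direction
    d[i] <- max(0, mean(colSums(off[, keep, drop = FALSE] * ubar)))
    u[i, ] <- ubar
  }
  harm <- vapply(freqs, function(f) sin(2^f * pi * d), numeric(n))
  cbind(d, rbind(harm), u)
}

point_features <- function(P, M, cfg, const = NULL) {
  X <- posenc(P, cfg$posenc_freqs %||% 0L)
  if (isTRUE(cfg$wall_feats %||% FALSE)) {
    M <- M[!duplicated(M), , drop = FALSE]   # duplication invariance
    X <- cbind(X, wall_features(P, M))
  }
  if (!is.null(const))
    X <- cbind(X, matrix(const, nrow(X), length(const), byrow = TRUE))
  X
}

# Encode a model/query cloud pair into network inputs. With the canonical
# frame enabled (default) both clouds are mapped to tube-fitted coordinates
# estimated from the model cloud; otherwise the isotropic centering/scaling
# normalization is used. Returns the encoded matrices plus the query-point
# frame needed to rotate velocity vectors.
prepare_inputs <- function(cfg, M, Q) {
  M <- rbind(M); Q <- rbind(Q)
  if (isTRUE(cfg$canonical %||% FALSE)) {
    frame <- canonical_frame(M)
    ccM <- canonical_coords(frame, M)
    ccQ <- canonical_coords(frame, Q)
    # per-pair target scales from laminar-flow scaling laws, evaluated
    # with cloud-estimated lumen radius and length (dimensionless,
    # relative to a 10 mm / 150 mm reference): velocity ~ 1/r^2, pressure
    # ~ L/r^4. Dividing targets by these removes the dominant
    # between-model amplitude factor the network would otherwise have to
    # infer from the geometry vector alone.
    rr <- frame$r_hat / 5e-3
    ll <- frame$L_hat / 0.15
    list(Mx = point_features(ccM$coords, ccM$coords, cfg, ccM$const),
         Qx = point_features(ccQ$coords, ccM$coords, cfg, ccM$const),
         ccQ = ccQ,
         tscale = if (isTRUE(cfg$physics_scale %||% TRUE))
           c(velocity = rr^-2, pressure = ll * rr^-4) else
           c(velocity = 1, pressure = 1))
  } else {
    np <- normalize_pair(M, Q)
    list(Mx = point_features(np$M, np$M, cfg),
         Qx = point_features(np$Q, np$M, cfg),
         ccQ = NULL, tscale = c(velocity = 1, pressure = 1))
  }
}

pair_tscale <- function(pi_, output_dim) {
  unname(pi_$tscale[if (output_dim == 3) "velocity" else "pressure"]) %||% 1
}

# world-frame targets -> (local-frame, for 3-vectors) training targets
targets_local <- function(Y, ccQ) {
  Y <- rbind(Y)
  if (ncol(Y) == 3 && !is.null(ccQ)) to_local_vec(ccQ, Y) else Y
}

# Full forward pass with cache. M, Q: already-encoded feature matrices
# (see point_features); rows correspond to model / query points.
forward_pass <- function(net, M, Q) {
  cfg <- net$config
  prim_m_layers <- if (cfg$share_primary) net$prim else net$prim_m
  fw_qp <- fwd_stack(Q, net$prim)
  fw_mp <- fwd_stack(M, prim_m_layers)
  fw_g <- fwd_stack(fw_mp$acts[[length(fw_mp$acts)]], net$glob)
  gm <- fw_g$acts[[length(fw_g$acts)]]                      # N1 x global_dim
  arg <- max.col(t(gm), ties.method = "first")              # argmax per feature
  g_raw <- gm[cbind(arg, seq_len(ncol(gm)))]
  if (isTRUE(cfg$global_norm)) {
    # parameter-free standardization of the pooled geometry vector: removes
    # the common mode shared by all models so the head sees shape contrast
    g_mu <- mean(g_raw)
    g_sd <- sqrt(mean((g_raw - g_mu)^2) + 1e-8)
    g <- (g_raw - g_mu) / g_sd
  } else {
    g <- g_raw; g_sd <- 1
  }
  fw_l <- fwd_stack(fw_qp$acts[[length(fw_qp$acts)]], net$loc)
  loc <- fw_l$acts[[length(fw_l$acts)]]                     # N2 x local_dim
  stitched <- cbind(loc, matrix(g, nrow(Q), length(g), byrow = TRUE))
  fw_h <- fwd_stack(stitched, net$head, final_linear = TRUE)
  list(out = fw_h$acts[[length(fw_h$acts)]],
       fw_qp = fw_qp, fw_mp = fw_mp, fw_g = fw_g, fw_l = fw_l, fw_h = fw_h,
       arg = arg, g = g, g_sd = g_sd, n1 = nrow(M), n2 = nrow(Q))
}

backward_pass <- function(net, cache, dout) {
  cfg <- net$config
  bh <- bwd_stack(dout, cache$fw_h, net$head, final_linear = TRUE)
  d_st <- bh$din
  d_loc <- d_st[, seq_len(cfg$local_dim), drop = FALSE]
  d_g <- colSums(d_st[, cfg$local_dim + seq_len(cfg$global_dim), drop = FALSE])
  if (isTRUE(cfg$global_norm)) {
    y <- cache$g
    d_g <- (d_g - mean(d_g) - y * mean(d_g * y)) / cache$g_sd
  }
  bl <- bwd_stack(d_loc, cache$fw_l, net$loc)
  d_gm <- matrix(0, cache$n1, cfg$global_dim)
  d_gm[cbind(cache$arg, seq_len(cfg$global_dim))] <- d_g
  bg <- bwd_stack(d_gm, cache$fw_g, net$glob)
  bqp <- bwd_stack(bl$din, cache$fw_qp, net$prim)
  prim_m_layers <- if (cfg$share_primary) net$prim else net$prim_m
  bmp <- bwd_stack(bg$din, cache$fw_mp, prim_m_layers)
  if (cfg$share_primary) {
    prim <- mapply(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                   bqp$grads, bmp$grads, SIMPLIFY = FALSE)
    list(prim = prim, prim_m = NULL, glob = bg$grads, loc = bl$grads,
         head = bh$grads)
  } else {
    list(prim = bqp$grads, prim_m = bmp$grads, glob = bg$grads,
         loc = bl$grads, head = bh$grads)
  }
}

net_groups <- function(net) {
  g <- c("prim", "glob", "loc", "head")
  if (!net$config$share_primary) g <- c(g, "prim_m")
  g
}

adam_init <- function(net) {
  st <- list(t = 0)
  for (grp in net_groups(net)) {
    st[[grp]] <- lapply(net[[grp]], function(l)
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
  }
  st
}

adam_step <- function(net, grads, state) {
  cfg <- net$config
  state$t <- state$t + 1
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (grp in net_groups(net)) {
    for (i in seq_along(net[[grp]])) {
      g <- grads[[grp]][[i]]
      s <- state[[grp]][[i]]
      s$mW <- cfg$beta1 * s$mW + (1 - cfg$beta1) * g$W
      s$vW <- cfg$beta2 * s$vW + (1 - cfg$beta2) * g$W^2
      s$mb <- cfg$beta1 * s$mb + (1 - cfg$beta1) * g$b
      s$vb <- cfg$beta2 * s$vb + (1 - cfg$beta2) * g$b^2
      net[[grp]][[i]]$W <- net[[grp]][[i]]$W -
        cfg$lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + cfg$eps)
      net[[grp]][[i]]$b <- net[[grp]][[i]]$b -
        cfg$lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + cfg$eps)
      state[[grp]][[i]] <- s
    }
  }
  list(net = net, state = state)
}

#' Forward pass of the point network
#'
#' Produces one prediction row per query point. The output is equivariant
#' under permutations of the query cloud (per-point head) and invariant
#' under permutations or duplications of the model cloud (symmetric max
#' reduction of the global feature).
#'
#' @param net a `point_network` (initialized or the weights of a trained
#'   model).
#' @param model_cloud N1 x 3 matrix of boundary coordinates.
#' @param query_coords N2 x 3 matrix of interior coordinates.
#' @param normalize center/scale both clouds by the model cloud (default
#'   TRUE, as used in training).
#' @return N2 x output_dim matrix of raw network outputs.
#' @export
forward_network <- function(net, model_cloud, query_coords, normalize = TRUE) {
  M <- rbind(model_cloud); Q <- rbind(query_coords)
  if (nrow(M) == 0 || nrow(Q) == 0)
    stop("forward_network: empty point cloud")
  if (ncol(M) != 3 || ncol(Q) != 3)
    stop("forward_network: clouds must be n x 3 coordinate matrices")
  cfg <- net$config
  pi_ <- if (normalize) prepare_inputs(cfg, M, Q) else {
    cst <- if (isTRUE(cfg$canonical)) c(0, 0, 0, 0)
    list(Mx = point_features(M, M, cfg, cst),
         Qx = point_features(Q, M, cfg, cst))
  }
  forward_pass(net, pi_$Mx, pi_$Qx)$out
}

target_stats <- function(target_list, config) {
  all_t <- do.call(rbind, lapply(target_list, rbind))
  transform <- config$target_transform %||% "standard"
  s0 <- 1
  if (transform == "asinh") {
    s0 <- (config$s0_frac %||% 1e-3) * max(abs(all_t))
    if (s0 == 0) s0 <- 1
    all_t <- asinh(all_t / s0)
  }
  mu <- colMeans(all_t)
  sd <- apply(all_t, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mean = mu, sd = sd, transform = transform, s0 = s0)
}

# physical targets -> standardized training space, and back
encode_target <- function(Y, stats) {
  Y <- rbind(Y)
  if (identical(stats$transform, "asinh")) Y <- asinh(Y / stats$s0)
  sweep(sweep(Y, 2, stats$mean), 2, stats$sd, "/")
}

decode_target <- function(out, stats) {
  Y <- sweep(sweep(out, 2, stats$sd, "*"), 2, stats$mean, "+")
  if (identical(stats$transform, "asinh")) Y <- stats$s0 * sinh(Y)
  Y
}

pair_loss <- function(net, enc) {
  mean(abs(forward_pass(net, enc$Mx, enc$Qx)$out - enc$y))
}

#' Train the point network
#'
#' Mean-absolute-error loss on standardized targets, Adam optimizer, one
#' model per optimization step (all or a seeded subsample of its points),
#' shuffled model order per epoch, and patience-based checkpointing of the
#' weights with the lowest validation loss. Fully deterministic for a fixed
#' seed.
#'
#' @param train_set a `hemo_dataset` (single variant, targets present).
#' @param config a [network_config()]; `output_dim` must match the variant.
#' @param seed RNG seed covering initialization, shuffling and subsampling.
#' @param init optional pre-initialized `point_network` (e.g. for warm
#'   starts); defaults to a fresh [init_network()].
#' @param verbose print per-epoch losses.
#' @return object of class `trained_model` with elements `net`, `config`,
#'   `variant`, `stats` (target standardization), `history` (per-epoch
#'   train/validation loss), `best_epoch`.
#' @export
train_network <- function(train_set, config = network_config(), seed = 1,
                          init = NULL, verbose = FALSE) {
  stopifnot(inherits(train_set, "hemo_dataset"))
  pairs <- train_set$pairs
  if (length(pairs) == 0) stop("train_network: empty training set")
  dims <- unique(vapply(pairs, function(p) ncol(rbind(p$target)), 1L))
  if (length(dims) != 1 || dims != config$output_dim)
    stop("train_network: target dimension ", dims[1],
         " does not match config output_dim ", config$output_dim,
         " (variant mismatch?)")
  local_seed(seed, {
    net <- init %||% init_network(config, seed = stats::runif(1, 1, 1e8))
    net$config <- config
    pis <- lapply(pairs, function(p)
      prepare_inputs(config, p$model_cloud, p$query_cloud))
    y_local <- lapply(seq_along(pairs), function(i)
      targets_local(pairs[[i]]$target, pis[[i]]$ccQ) /
        pair_tscale(pis[[i]], config$output_dim))
    stats <- target_stats(y_local, config)
    n_val <- floor(config$val_frac * length(pairs))
    val_idx <- if (n_val >= 1) sample(seq_along(pairs), n_val) else integer(0)
    tr_idx <- setdiff(seq_along(pairs), val_idx)
    if (length(tr_idx) == 0) { tr_idx <- seq_along(pairs); val_idx <- integer(0) }
    state <- adam_init(net)
    enc <- lapply(seq_along(pairs), function(i)
      list(Mx = pis[[i]]$Mx, Qx = pis[[i]]$Qx,
           y = encode_target(y_local[[i]], stats)))
    best <- list(loss = Inf, net = net, epoch = 0)
    history <- data.frame(epoch = integer(0), train = numeric(0),
                          val = numeric(0))
    stall <- 0
    for (epoch in seq_len(config$max_epochs)) {
      ep_loss <- 0
      for (i in tr_idx[sample.int(length(tr_idx))]) {
        e <- enc[[i]]
        Mx <- e$Mx; Qx <- e$Qx; Y <- e$y
        if (!is.null(config$model_cap) && nrow(Mx) > config$model_cap)
          Mx <- Mx[sample(nrow(Mx), config$model_cap), , drop = FALSE]
        if (!is.null(config$query_batch) && nrow(Qx) > config$query_batch) {
          qi <- sample(nrow(Qx), config$query_batch)
          Qx <- Qx[qi, , drop = FALSE]; Y <- Y[qi, , drop = FALSE]
        }
        cache <- forward_pass(net, Mx, Qx)
        err <- cache$out - Y
        ep_loss <- ep_loss + mean(abs(err))
        dout <- sign(err) / length(err)
        grads <- backward_pass(net, cache, dout)
        if (!all(vapply(grads$head, function(g) all(is.finite(g$W)), TRUE)))
          stop("train_network: non-finite gradients at epoch ", epoch)
        upd <- adam_step(net, grads, state)
        net <- upd$net; state <- upd$state
      }
      ep_loss <- ep_loss / length(tr_idx)
      val_loss <- if (length(val_idx) > 0)
        mean(vapply(enc[val_idx], function(e) pair_loss(net, e), 0))
      else ep_loss
      history <- rbind(history,
                       data.frame(epoch = epoch, train = ep_loss, val = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, ep_loss, val_loss))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, net = net, epoch = epoch)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= config$patience) break
      }
    }
    structure(list(net = best$net, config = config,
                   variant = train_set$variant, stats = stats,
                   history = history, best_epoch = best$epoch),
              class = "trained_model")
  })
}

#' Predict hemodynamics for new clouds
#'
#' Runs the trained network on a model/query cloud pair and returns the
#' predictions on the physical scale (target standardization inverted).
#' Inputs are never modified.
#'
#' @param trained a `trained_model`.
#' @param model_cloud N1 x 3 boundary coordinates, m.
#' @param query_coords N2 x 3 interior coordinates, m.
#' @return N2 x output_dim matrix (velocity components m/s, or pressure Pa).
#' @export
predict_network <- function(trained, model_cloud, query_coords) {
  stopifnot(inherits(trained, "trained_model"))
  pi_ <- prepare_inputs(trained$net$config, model_cloud, query_coords)
  out <- forward_pass(trained$net, pi_$Mx, pi_$Qx)$out
  Y <- decode_target(out, trained$stats) *
    pair_tscale(pi_, trained$config$output_dim)
  if (ncol(Y) == 3 && !is.null(pi_$ccQ)) Y <- from_local_vec(pi_$ccQ, Y)
  Y
}

#' Save / load a trained model
#'
#' Portable checkpoint: weights, configuration, variant tag, target
#' statistics and training history in one RDS file.
#'
#' @param trained a `trained_model`.
#' @param path checkpoint file path.
#' @export
save_model <- function(trained, path) {
  saveRDS(unclass(trained), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "trained_model [%s]: output_dim %d, best epoch %d (val loss %.5f), %d epochs run\n",
    paste(x$variant, collapse = "/"), x$config$output_dim, x$best_epoch,
    min(x$history$val), nrow(x$history)))
  invisible(x)
}
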