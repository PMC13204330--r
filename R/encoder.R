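# Partially-shared multi-modal encoder.
#
# Architecture: each modality has its own patch stem (a dense layer applied to
# non-overlapping spatial patches, i.e. a strided convolution); the resulting
# patch embeddings pass through a shared residual trunk (one parameter set
# used by every modality path); a per-modality residual head plus global
# average pooling over patches and a per-modality linear output produce the
# pooled vector z_i(m). Two feature levels are exposed: "patch" (trunk
# output, one embedding per spatial patch) and "pooled" (one vector per
# sample/modality). All passes are hand-differentiated; gradients propagate
# both to parameters (for contrastive pretraining) and to input pixels (for
# synthetic-sample optimization).

#' Encoder configuration
#'
#' @param n_modalities number of modalities M (>= 2).
#' @param spatial_shape spatial dims of one modality image (length 2 or 3).
#' @param patch patch edge length; must divide every spatial dim.
#' @param width channel width of stems, trunk and heads.
#' @param n_shared_stages number of shared residual trunk stages (>= 1).
#' @param n_specific_stages number of per-modality residual head stages (>= 1).
#' @param pooled_dim dimension of the pooled per-modality output vector.
#' @param pooling how the per-modality head turns patch features into one
#'   vector: `"flatten"` (concatenate patch features, then linear — keeps
#'   spatial layout, the standard small-CNN transition) or `"mean"` (global
#'   average pooling, as in large residual backbones).
#' @param preset `"tiny2d"` (default desk-scale) or `"paper3d"`
#'   (deep 3-shared-stage configuration for volumetric inputs).
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(n_modalities = 2, spatial_shape = c(16, 16),
                           patch = 4, width = 16,
                           n_shared_stages = 2, n_specific_stages = 1,
                           pooled_dim = width,
                           pooling = c("flatten", "mean"), preset = NULL) {
  pooling <- match.arg(pooling)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tiny2d", "paper3d"))
    if (preset == "paper3d") {
      if (missing(spatial_shape)) spatial_shape <- c(32, 32, 32)
      if (missing(width)) width <- 64
      n_shared_stages <- 3
      n_specific_stages <- 1
      if (missing(pooled_dim)) pooled_dim <- 2048
      pooling <- "mean"
    }
  }
  stopifnot(n_modalities >= 2, n_shared_stages >= 1, n_specific_stages >= 1,
            pooled_dim > 0, width > 0, patch >= 1)
  if (any(spatial_shape %% patch != 0)) {
    stopf("patch edge %d must divide every spatial dim (%s)", patch,
          paste(spatial_shape, collapse = "x"))
  }
  if (any(spatial_shape / patch < 2)) {
    stopf("spatial shape %s too small for patch %d: need >= 2 patches per axis",
          paste(spatial_shape, collapse = "x"), patch)
  }
  structure(list(n_modalities = as.integer(n_modalities),
                 spatial_shape = as.integer(spatial_shape),
                 spatial_ndim = length(spatial_shape),
                 patch = as.integer(patch), width = as.integer(width),
                 n_shared_stages = as.integer(n_shared_stages),
                 n_specific_stages = as.integer(n_specific_stages),
                 pooled_dim = as.integer(pooled_dim), pooling = pooling),
            class = "encoder_config")
}

# Patch geometry: number of patches and, for each patch, the linear indices of
# its pixels within one modality's flattened (column-major) spatial block.
patch_index <- function(config) {
  sh <- config$spatial_shape; pp <- config$patch
  grid <- sh %/% pp
  n_patch <- prod(grid)
  # coordinates of every voxel, column-major
  coord <- as.matrix(expand.grid(lapply(sh, seq_len)))
  pid <- 1L
  patch_of_voxel <- integer(nrow(coord))
  cell <- (coord - 1L) %/% pp # 0-based patch cell per axis
  mult <- cumprod(c(1L, grid[-length(grid)]))
  patch_of_voxel <- as.integer(cell %*% mult) + 1L
  idx <- split(seq_len(nrow(coord)), patch_of_voxel)
  list(n_patch = n_patch, pixels_per_patch = pp^length(sh), idx = idx)
}

he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
}

#' Build an encoder with random (He) initialization
#'
#' Stems and heads are per-modality parameter sets; trunk stages are a single
#' shared parameter set referenced by all modality paths.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed for the parameter draw.
#' @return an `mm_encoder`.
#' @export
build_encoder <- function(config, seed = 1) {
  stopifnot(inherits(config, "encoder_config"))
  w <- config$width; M <- config$n_modalities
  pinfo <- patch_index(config)
  ppix <- pinfo$pixels_per_patch
  enc <- with_seed(derive_seed(seed, "encoder"), {
    stems <- lapply(seq_len(M), function(m) {
      list(W = he_init(ppix, w), b = numeric(w))
    })
    trunk <- lapply(seq_len(config$n_shared_stages), function(l) {
      list(W = he_init(w, w), b = numeric(w))
    })
    heads <- lapply(seq_len(M), function(m) {
      lapply(seq_len(config$n_specific_stages), function(l) {
        list(W = he_init(w, w), b = numeric(w))
      })
    })
    pool_in <- if (config$pooling == "flatten") pinfo$n_patch * w else w
    pool_proj <- lapply(seq_len(M), function(m) {
      list(W = he_init(pool_in, config$pooled_dim),
           b = numeric(config$pooled_dim))
    })
    # learnable positional embedding per patch, shared across modalities
    # (modalities are registered, so location means the same thing in each)
    pos <- matrix(stats::rnorm(pinfo$n_patch * w, 0, 0.1), pinfo$n_patch, w)
    list(stems = stems, trunk = trunk, heads = heads, pool_proj = pool_proj,
         pos = pos)
  })
  enc$config <- config
  enc$seed <- as.integer(seed)
  enc$patch_info <- pinfo
  class(enc) <- "mm_encoder"
  enc
}

#' Analytic parameter count of an encoder configuration
#' @param config an [encoder_config()].
#' @return named vector with per-component and total counts.
#' @export
encoder_param_count <- function(config) {
  w <- config$width; M <- config$n_modalities
  ppix <- config$patch^config$spatial_ndim
  stems <- M * (ppix * w + w)
  trunk <- config$n_shared_stages * (w * w + w)
  heads <- M * config$n_specific_stages * (w * w + w)
  np <- prod(config$spatial_shape %/% config$patch)
  pool_in <- if (config$pooling == "flatten") np * w else w
  pool <- M * (pool_in * config$pooled_dim + config$pooled_dim)
  pos <- np * w
  c(stems = stems, trunk = trunk, heads = heads, pool = pool, pos = pos,
    total = stems + trunk + heads + pool + pos)
}

#' @export
print.mm_encoder <- function(x, ...) {
  pc <- encoder_param_count(x$config)
  cat(sprintf(
    "mm_encoder: M=%d, width=%d, %d shared + %d specific stages, %d params\n",
    x$config$n_modalities, x$config$width, x$config$n_shared_stages,
    x$config$n_specific_stages, pc["total"]))
  invisible(x)
}

# ---- parameter (un)flattening, canonical order ----

encoder_params <- function(enc) {
  unlist(list(
    lapply(enc$stems, function(s) c(s$W, s$b)),
    lapply(enc$trunk, function(s) c(s$W, s$b)),
    lapply(enc$heads, function(h) lapply(h, function(s) c(s$W, s$b))),
    lapply(enc$pool_proj, function(s) c(s$W, s$b)),
    list(as.numeric(enc$pos))
  ), use.names = FALSE)
}

encoder_set_params <- function(enc, vec) {
  pos <- 0L
  take <- function(n) {
    out <- vec[(pos + 1):(pos + n)]
    pos <<- pos + n
    out
  }
  take_layer <- function(layer) {
    layer$W <- matrix(take(length(layer$W)), nrow(layer$W), ncol(layer$W))
    layer$b <- take(length(layer$b))
    layer
  }
  enc$stems <- lapply(enc$stems, take_layer)
  enc$trunk <- lapply(enc$trunk, take_layer)
  enc$heads <- lapply(enc$heads, function(h) lapply(h, take_layer))
  enc$pool_proj <- lapply(enc$pool_proj, take_layer)
  enc$pos <- matrix(take(length(enc$pos)), nrow(enc$pos), ncol(enc$pos))
  stopifnot(pos == length(vec))
  enc
}

# ---- forward ----

# Accepts a pixel array (B x M x spatial) or a flat matrix (B x M*P,
# modality-major blocks); returns flat matrix.
as_flat_batch <- function(enc, x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) < 3 || d[2] != enc$config$n_modalities) {
    stopf("encode: expected %d modalities, got %s", enc$config$n_modalities,
          if (length(d) >= 2) d[2] else "a non-array input")
  }
  flatten_pixels(x)
}

#' Encode a batch of multi-modal samples
#'
#' @param enc an `mm_encoder`.
#' @param x pixel array `(B, M, spatial...)` or flat pixel matrix.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return an `mm_features` list: `pooled` (list of B x pooled_dim matrices,
#'   one per modality), `patch` (list of (B*n_patch) x width matrices, sample
#'   index varying fastest), `batch_index`, `n_patch`.
#' @export
encode <- function(enc, x, keep_cache = FALSE) {
  stopifnot(inherits(enc, "mm_encoder"))
  xf <- as_flat_batch(enc, x)
  M <- enc$config$n_modalities
  P <- prod(enc$config$spatial_shape)
  if (ncol(xf) != M * P) {
    stopf("encode: expected %d modalities of %d pixels (got %d columns)",
          M, P, ncol(xf))
  }
  B <- nrow(xf)
  pinfo <- enc$patch_info
  np <- pinfo$n_patch
  pooled <- vector("list", M)
  patch_feats <- vector("list", M)
  cache <- if (keep_cache) vector("list", M) else NULL
  for (m in seq_len(M)) {
    block <- xf[, ((m - 1) * P + 1):(m * P), drop = FALSE]
    # rows: sample fastest, then patch
    Xp <- do.call(rbind, lapply(pinfo$idx, function(ix) {
      block[, ix, drop = FALSE]
    }))
    # do.call(rbind, ...) stacks patch-blocks: rows (patch-1)*B + b -> sample
    # fastest within each patch block, as required.
    pre0 <- sweep(Xp %*% enc$stems[[m]]$W, 2, enc$stems[[m]]$b, `+`)
    A <- relu(pre0) + enc$pos[rep(seq_len(np), each = B), , drop = FALSE]
    trunk_in <- vector("list", length(enc$trunk))
    trunk_pre <- vector("list", length(enc$trunk))
    for (l in seq_along(enc$trunk)) {
      trunk_in[[l]] <- A
      pre <- sweep(A %*% enc$trunk[[l]]$W, 2, enc$trunk[[l]]$b, `+`)
      trunk_pre[[l]] <- pre
      A <- A + relu(pre)
    }
    patch_feats[[m]] <- A
    H <- A
    head_in <- vector("list", length(enc$heads[[m]]))
    head_pre <- vector("list", length(enc$heads[[m]]))
    for (l in seq_along(enc$heads[[m]])) {
      head_in[[l]] <- H
      pre <- sweep(H %*% enc$heads[[m]][[l]]$W, 2, enc$heads[[m]][[l]]$b, `+`)
      head_pre[[l]] <- pre
      H <- H + relu(pre)
    }
    if (enc$config$pooling == "flatten") {
      w_ <- enc$config$width
      pool <- matrix(0, B, np * w_)
      for (k in seq_len(np)) {
        pool[, ((k - 1) * w_ + 1):(k * w_)] <-
          H[((k - 1) * B + 1):(k * B), , drop = FALSE]
      }
    } else {
      grp <- rep(seq_len(B), times = np)
      pool <- rowsum(H, grp) / np
    }
    z <- sweep(pool %*% enc$pool_proj[[m]]$W, 2, enc$pool_proj[[m]]$b, `+`)
    pooled[[m]] <- z
    if (keep_cache) {
      cache[[m]] <- list(Xp = Xp, pre0 = pre0, trunk_in = trunk_in,
                         trunk_pre = trunk_pre, head_in = head_in,
                         head_pre = head_pre, pool = pool)
    }
  }
  structure(list(pooled = pooled, patch = patch_feats,
                 batch_index = seq_len(B), n_patch = np, B = B,
                 cache = cache),
            class = "mm_features")
}

# ---- backward ----

# d_pooled: list per modality (B x pooled_dim) or NULL; d_patch: list per
# modality ((B*n_patch) x width) or NULL. Returns gradient w.r.t. the flat
# input batch and w.r.t. all parameters (same canonical flat order as
# encoder_params()).
encoder_backward <- function(enc, feats, d_pooled = NULL, d_patch = NULL) {
  stopifnot(!is.null(feats$cache))
  M <- enc$config$n_modalities
  P <- prod(enc$config$spatial_shape)
  B <- feats$B; np <- feats$n_patch
  pinfo <- enc$patch_info
  dX <- matrix(0, B, M * P)
  g_stems <- lapply(enc$stems, function(s) list(W = 0 * s$W, b = 0 * s$b))
  g_trunk <- lapply(enc$trunk, function(s) list(W = 0 * s$W, b = 0 * s$b))
  g_heads <- lapply(enc$heads, function(h) {
    lapply(h, function(s) list(W = 0 * s$W, b = 0 * s$b))
  })
  g_pool <- lapply(enc$pool_proj, function(s) list(W = 0 * s$W, b = 0 * s$b))
  g_pos <- 0 * enc$pos

  res_backward <- function(g, pre, a_in, W) {
    gp <- g * (pre > 0)
    list(g_in = g + gp %*% t(W), gW = t(a_in) %*% gp, gb = colSums(gp))
  }

  for (m in seq_len(M)) {
    cc <- feats$cache[[m]]
    gH <- NULL
    if (!is.null(d_pooled) && !is.null(d_pooled[[m]])) {
      dz <- d_pooled[[m]]
      g_pool[[m]]$W <- g_pool[[m]]$W + t(cc$pool) %*% dz
      g_pool[[m]]$b <- g_pool[[m]]$b + colSums(dz)
      dpool <- dz %*% t(enc$pool_proj[[m]]$W)
      if (enc$config$pooling == "flatten") {
        w_ <- enc$config$width
        gH <- matrix(0, B * np, w_)
        for (k in seq_len(np)) {
          gH[((k - 1) * B + 1):(k * B), ] <-
            dpool[, ((k - 1) * w_ + 1):(k * w_), drop = FALSE]
        }
      } else {
        gH <- dpool[rep(seq_len(B), times = np), , drop = FALSE] / np
      }
    }
    if (is.null(gH)) gH <- matrix(0, B * np, enc$config$width)
    for (l in rev(seq_along(enc$heads[[m]]))) {
      rb <- res_backward(gH, cc$head_pre[[l]], cc$head_in[[l]],
                         enc$heads[[m]][[l]]$W)
      g_heads[[m]][[l]]$W <- g_heads[[m]][[l]]$W + rb$gW
      g_heads[[m]][[l]]$b <- g_heads[[m]][[l]]$b + rb$gb
      gH <- rb$g_in
    }
    if (!is.null(d_patch) && !is.null(d_patch[[m]])) {
      gH <- gH + d_patch[[m]]
    }
    for (l in rev(seq_along(enc$trunk))) {
      rb <- res_backward(gH, cc$trunk_pre[[l]], cc$trunk_in[[l]],
                         enc$trunk[[l]]$W)
      g_trunk[[l]]$W <- g_trunk[[l]]$W + rb$gW
      g_trunk[[l]]$b <- g_trunk[[l]]$b + rb$gb
      gH <- rb$g_in
    }
    g_pos <- g_pos + rowsum(gH, rep(seq_len(np), each = B))
    g0 <- gH * (cc$pre0 > 0)
    g_stems[[m]]$W <- g_stems[[m]]$W + t(cc$Xp) %*% g0
    g_stems[[m]]$b <- g_stems[[m]]$b + colSums(g0)
    dXp <- g0 %*% t(enc$stems[[m]]$W)
    for (k in seq_len(np)) {
      rows <- ((k - 1) * B + 1):(k * B)
      cols <- (m - 1) * P + pinfo$idx[[k]]
      dX[, cols] <- dX[, cols] + dXp[rows, , drop = FALSE]
    }
  }
  g_vec <- unlist(list(
    lapply(g_stems, function(s) c(s$W, s$b)),
    lapply(g_trunk, function(s) c(s$W, s$b)),
    lapply(g_heads, function(h) lapply(h, function(s) c(s$W, s$b))),
    lapply(g_pool, function(s) c(s$W, s$b)),
    list(as.numeric(g_pos))
  ), use.names = FALSE)
  list(d_input = dX, d_params = g_vec)
}

# ---- projection head ----

#' Build a two-layer MLP projection head
#'
#' Maps features to the low-dimensional space used for similarity
#' computation; outputs are L2-normalized to unit norm (epsilon-guarded).
#'
#' @param in_dim input feature dimension.
#' @param hidden hidden width.
#' @param out_dim projected dimension (128 under the paper-scale preset,
#'   smaller for desk-scale configurations).
#' @param seed integer seed.
#' @export
build_projection <- function(in_dim, hidden = 2 * in_dim, out_dim = in_dim,
                             seed = 1) {
  with_seed(derive_seed(seed, "proj"), {
    structure(list(W1 = he_init(in_dim, hidden), b1 = numeric(hidden),
                   W2 = he_init(hidden, out_dim), b2 = numeric(out_dim),
                   in_dim = in_dim, hidden = hidden, out_dim = out_dim),
              class = "mm_projection")
  })
}

projection_params <- function(p) c(p$W1, p$b1, p$W2, p$b2)

projection_set_params <- function(p, vec) {
  pos <- 0L
  take <- function(n) { out <- vec[(pos + 1):(pos + n)]; pos <<- pos + n; out }
  p$W1 <- matrix(take(length(p$W1)), nrow(p$W1), ncol(p$W1))
  p$b1 <- take(length(p$b1))
  p$W2 <- matrix(take(length(p$W2)), nrow(p$W2), ncol(p$W2))
  p$b2 <- take(length(p$b2))
  stopifnot(pos == length(vec))
  p
}

#' Project features to unit-norm embeddings
#'
#' @param proj an `mm_projection`.
#' @param z feature matrix (rows = items) whose column count equals the
#'   head's input dimension, or an `mm_features` object (pooled vectors of
#'   all modalities are stacked).
#' @param keep_cache keep intermediates for the backward pass.
#' @param eps norm guard for zero vectors.
#' @return matrix of unit-norm row embeddings (with attribute `cache` when
#'   requested).
#' @export
project <- function(proj, z, keep_cache = FALSE, eps = 1e-8) {
  stopifnot(inherits(proj, "mm_projection"))
  if (inherits(z, "mm_features")) z <- do.call(rbind, z$pooled)
  if (ncol(z) != proj$in_dim) {
    stopf("projection head expects %d-dim input, got %d", proj$in_dim, ncol(z))
  }
  pre <- sweep(z %*% proj$W1, 2, proj$b1, `+`)
  h <- relu(pre)
  v <- sweep(h %*% proj$W2, 2, proj$b2, `+`)
  nrm <- pmax(sqrt(rowSums(v^2)), eps)
  e <- v / nrm
  if (keep_cache) {
    attr(e, "cache") <- list(z = z, pre = pre, h = h, v = v, nrm = nrm)
  }
  e
}

# Backward through projection + normalization. dE is the upstream gradient on
# the normalized embeddings. Returns gradient on input z and on parameters.
projection_backward <- function(proj, e, dE) {
  cc <- attr(e, "cache")
  stopifnot(!is.null(cc))
  # e = v / ||v||; dv = (dE - e * <e, dE>) / ||v||
  inner <- rowSums(e * dE)
  dv <- (dE - e * inner) / cc$nrm
  gW2 <- t(cc$h) %*% dv
  gb2 <- colSums(dv)
  dh <- dv %*% t(proj$W2)
  dpre <- dh * (cc$pre > 0)
  gW1 <- t(cc$z) %*% dpre
  gb1 <- colSums(dpre)
  dz <- dpre %*% t(proj$W1)
  list(d_input = dz, d_params = c(gW1, gb1, gW2, gb2))
}

# ---- checkpointing ----

#' Save an encoder (and optional projection head) to a checkpoint directory
#'
#' Writes a JSON header (config, seed, format version) plus the parameter
#' vector as a flat little-endian float64 file.
#'
#' @param enc an `mm_encoder`.
#' @param path checkpoint directory.
#' @param proj optional `mm_projection`.
#' @export
save_encoder <- function(enc, path, proj = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(format_version = 1L,
                 config = unclass(enc$config), seed = enc$seed,
                 has_projection = !is.null(proj),
                 projection = if (!is.null(proj)) {
                   list(in_dim = proj$in_dim, hidden = proj$hidden,
                        out_dim = proj$out_dim)
                 })
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  params <- encoder_params(enc)
  if (!is.null(proj)) params <- c(params, projection_params(proj))
  con <- file(file.path(path, "params.bin"), "wb")
  writeBin(as.numeric(params), con, size = 8, endian = "little")
  close(con)
  invisible(path)
}

#' Load an encoder checkpoint written by [save_encoder()]
#' @param path checkpoint directory.
#' @return list(encoder, projection or NULL).
#' @export
load_encoder <- function(path) {
  header <- jsonlite::read_json(file.path(path, "header.json"),
                                simplifyVector = TRUE)
  cfgl <- header$config
  config <- encoder_config(n_modalities = cfgl$n_modalities,
                           spatial_shape = cfgl$spatial_shape,
                           patch = cfgl$patch, width = cfgl$width,
                           n_shared_stages = cfgl$n_shared_stages,
                           n_specific_stages = cfgl$n_specific_stages,
                           pooled_dim = cfgl$pooled_dim,
                           pooling = cfgl$pooling %||% "flatten")
  enc <- build_encoder(config, seed = header$seed)
  n_enc <- length(encoder_params(enc))
  con <- file(file.path(path, "params.bin"), "rb")
  on.exit(close(con))
  total <- n_enc
  proj <- NULL
  if (isTRUE(header$has_projection)) {
    proj <- build_projection(header$projection$in_dim,
                             header$projection$hidden,
                             header$projection$out_dim, seed = 1)
    total <- total + length(projection_params(proj))
  }
  vec <- readBin(con, "double", n = total, size = 8, endian = "little")
  enc <- encoder_set_params(enc, vec[seq_len(n_enc)])
  if (!is.null(proj)) {
    proj <- projection_set_params(proj, vec[(n_enc + 1):total])
  }
  list(encoder = enc, projection = proj)
}
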