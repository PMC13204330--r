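# Hierarchical cross-modal contrastive loss.
#
# Positives are embeddings of the same sample and spatial location in two
# different modalities (modalities are registered, so the pooled level treats
# the whole sample as one location and the patch level uses grid cells).
# Negatives come from up to three sources: other samples in the batch
# (inter-instance), other locations of the same sample (intra-instance
# spatial, patch level), and distorted views of the anchor (augmentation
# negatives, off by default). The per-pair loss is InfoNCE; the total loss
# averages over batch samples, ordered modality pairs, locations, and encoder
# levels with fixed level weights.

#' Contrastive configuration
#'
#' @param temperature InfoNCE temperature tau (> 0).
#' @param level_weights named nonnegative weights over encoder levels
#'   (`patch`, `pooled`); must sum to 1.
#' @param use_inter_instance use other samples' features as negatives.
#' @param use_intra_spatial use other locations of the same sample as
#'   negatives (patch level).
#' @param n_spatial_patches number of patch locations subsampled per step at
#'   the patch level (0 = all).
#' @param use_augmentation_negatives treat distorted views of the anchor as
#'   negatives.
#' @param aug_kind augmentation used for those views.
#' @param aug_noise_sd noise sd for the `"noise"` augmentation.
#' @param queue_size optional momentum memory queue length (0 = in-batch
#'   negatives only; 4096 under the paper-scale configuration).
#' @param queue_momentum momentum of the queue's running-average update.
#' @param mode which data feed the loss during distillation: real batches,
#'   synthetic batches, or their concatenation.
#' @param strict error (rather than warn) when no negative source is enabled.
#' @return a `contrastive_config` list.
#' @export
contrastive_config <- function(temperature = 0.07,
                               level_weights = c(patch = 0.5, pooled = 0.5),
                               use_inter_instance = TRUE,
                               use_intra_spatial = TRUE,
                               n_spatial_patches = 4,
                               use_augmentation_negatives = FALSE,
                               aug_kind = c("noise", "rotation"),
                               aug_noise_sd = 0.25,
                               queue_size = 0, queue_momentum = 0.5,
                               mode = c("joint", "d-only", "s-only"),
                               strict = TRUE) {
  aug_kind <- match.arg(aug_kind)
  mode <- match.arg(mode)
  if (temperature <= 0) stopf("temperature must be > 0")
  if (is.null(names(level_weights)) ||
      !all(names(level_weights) %in% c("patch", "pooled"))) {
    stopf("level_weights must be named with levels 'patch' and/or 'pooled'")
  }
  if (any(level_weights < 0) || abs(sum(level_weights) - 1) > 1e-8) {
    stopf("level_weights must be nonnegative and sum to 1")
  }
  if (queue_size < 0) stopf("queue_size must be >= 0")
  structure(list(temperature = temperature, level_weights = level_weights,
                 use_inter_instance = use_inter_instance,
                 use_intra_spatial = use_intra_spatial,
                 n_spatial_patches = as.integer(n_spatial_patches),
                 use_augmentation_negatives = use_augmentation_negatives,
                 aug_kind = aug_kind, aug_noise_sd = aug_noise_sd,
                 queue_size = as.integer(queue_size),
                 queue_momentum = queue_momentum,
                 mode = mode, strict = strict),
            class = "contrastive_config")
}

#' Cosine similarity of two vectors
#' @param u,v numeric vectors of equal length.
#' @param eps guard against zero norms.
#' @return similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v, eps = 1e-8) {
  sum(u * v) / max(sqrt(sum(u^2)) * sqrt(sum(v^2)), eps)
}

#' InfoNCE loss for one anchor and its candidate set
#'
#' `-log( exp(sim(a, pos)/tau) / sum_k exp(sim(a, k)/tau) )` where the sum
#' runs over the positive and all negatives, computed with a stable
#' log-sum-exp.
#'
#' @param anchor anchor embedding vector.
#' @param positive positive embedding vector.
#' @param negatives matrix of negative embeddings (rows), possibly 0 rows.
#' @param tau temperature (> 0).
#' @return nonnegative scalar loss.
#' @export
infonce_pair_loss <- function(anchor, positive, negatives, tau) {
  if (tau <= 0) stopf("tau must be > 0")
  negatives <- rbind(negatives)
  sims <- c(cosine_similarity(anchor, positive),
            if (nrow(negatives) > 0) {
              apply(negatives, 1, cosine_similarity, v = anchor)
            })
  unname(-(sims[1] / tau) + log_sum_exp(sims / tau))
}

# ---- level embedding tables ----

# Stack per-modality feature matrices into one table with (sample, modality,
# loc) ids. Patch rows in encoder output are ordered (patch-1)*B + sample.
level_tables <- function(feats, config, seed) {
  B <- feats$B
  M <- length(feats$pooled)
  out <- list()
  if (!is.na(config$level_weights["pooled"]) &&
      config$level_weights["pooled"] > 0) {
    out$pooled <- list(
      raw = do.call(rbind, feats$pooled),
      sample = rep(seq_len(B), times = M),
      modality = rep(seq_len(M), each = B),
      loc = rep(1L, B * M))
  }
  if (!is.na(config$level_weights["patch"]) &&
      config$level_weights["patch"] > 0) {
    np <- feats$n_patch
    locs <- if (config$n_spatial_patches > 0 &&
                config$n_spatial_patches < np) {
      with_seed(derive_seed(seed, "patch-locs"),
                sort(sample(np, config$n_spatial_patches)))
    } else seq_len(np)
    rows <- as.vector(outer(seq_len(B), (locs - 1) * B, `+`)) # (loc-major)
    raw <- do.call(rbind, lapply(seq_len(M), function(m) {
      feats$patch[[m]][rows, , drop = FALSE]
    }))
    nl <- length(locs)
    out$patch <- list(
      raw = raw,
      sample = rep(rep(seq_len(B), times = nl), times = M),
      modality = rep(seq_len(M), each = B * nl),
      loc = rep(rep(locs, each = B), times = M),
      locs = locs, rows = rows)
  }
  out
}

#' Enumerate candidate sets for the contrastive loss
#'
#' For every anchor (sample i, modality m, level, location) and every other
#' modality n != m there is exactly one positive (same sample and location,
#' modality n); negatives are drawn from the enabled sources. Returned row
#' indices refer to the per-level embedding tables that
#' [contrastive_loss()] operates on.
#'
#' @param feats an `mm_features` from [encode()].
#' @param config a [contrastive_config()].
#' @param seed seed for the patch-location subsample.
#' @return list of candidate sets, each with `level`, `anchor` (row),
#'   `anchor_id` (sample, modality, loc), `positive` (row), `negatives`
#'   (rows), and `n` (candidate count = 1 + number of negatives).
#' @export
build_candidate_sets <- function(feats, config, seed = 1) {
  M <- length(feats$pooled)
  if (M < 2) stopf("cross-modal positives require >= 2 modalities")
  if (!config$use_inter_instance && !config$use_intra_spatial &&
      !config$use_augmentation_negatives && config$queue_size == 0) {
    msg <- "no negative source enabled"
    if (config$strict) stopf(msg) else warning(msg)
  }
  if (config$use_inter_instance && feats$B < 2) {
    stopf("inter-instance negatives require a batch of >= 2 samples")
  }
  tabs <- level_tables(feats, config, seed)
  sets <- list()
  for (lev in names(tabs)) {
    tb <- tabs[[lev]]
    K <- nrow(tb$raw)
    for (r in seq_len(K)) {
      negs <- integer(0)
      if (config$use_inter_instance) {
        negs <- c(negs, which(tb$sample != tb$sample[r]))
      }
      if (lev == "patch" && config$use_intra_spatial) {
        negs <- c(negs, which(tb$sample == tb$sample[r] &
                                tb$loc != tb$loc[r]))
      }
      negs <- sort(unique(negs))
      for (n_mod in setdiff(seq_len(M), tb$modality[r])) {
        pos <- which(tb$sample == tb$sample[r] & tb$loc == tb$loc[r] &
                       tb$modality == n_mod)
        sets[[length(sets) + 1]] <- list(
          level = lev, anchor = r,
          anchor_id = c(sample = tb$sample[r], modality = tb$modality[r],
                        loc = tb$loc[r]),
          positive = pos, negatives = negs, n = 1L + length(negs))
      }
    }
  }
  sets
}

# Core per-level loss and gradient on unit-norm embeddings E with ids.
# Returns sum of pair losses over anchors, anchor count, and dE (gradient of
# the SUM, not yet normalized).
level_infonce <- function(E, sample, modality, loc, config,
                          queue_emb = NULL, aug_emb = NULL,
                          use_intra = FALSE, want_grad = TRUE) {
  tau <- config$temperature
  K <- nrow(E); M <- max(modality)
  S <- tcrossprod(E) / tau
  expS <- exp(S)
  same_sample <- outer(sample, sample, `==`)
  neg_mask <- matrix(FALSE, K, K)
  if (config$use_inter_instance) neg_mask <- neg_mask | !same_sample
  if (use_intra && config$use_intra_spatial) {
    neg_mask <- neg_mask | (same_sample & outer(loc, loc, `!=`))
  }
  diag(neg_mask) <- FALSE
  neg_sum <- rowSums(expS * neg_mask)
  aug_diag <- NULL
  if (!is.null(aug_emb)) {
    aug_diag <- exp(rowSums(E * aug_emb) / tau)
    neg_sum <- neg_sum + aug_diag
  }
  expSq <- NULL
  if (!is.null(queue_emb) && nrow(queue_emb) > 0) {
    expSq <- exp(E %*% t(queue_emb) / tau)
    neg_sum <- neg_sum + rowSums(expSq)
  }
  # positive column for (row r, target modality n): same sample & loc
  key <- paste(sample, loc)
  loss_sum <- 0
  n_anchors <- 0L
  f <- numeric(K) # sum over n of 1/denom per anchor row
  pos_entries <- list()
  for (r in seq_len(K)) {
    pos_cols <- which(key == key[r] & modality != modality[r])
    for (cpos in pos_cols) {
      denom <- expS[r, cpos] + neg_sum[r]
      loss_sum <- loss_sum + log(denom) - S[r, cpos]
      n_anchors <- n_anchors + 1L
      if (want_grad) {
        f[r] <- f[r] + 1 / denom
        pos_entries[[length(pos_entries) + 1]] <-
          c(r, cpos, expS[r, cpos] / denom - 1)
      }
    }
  }
  dE <- NULL
  if (want_grad) {
    G <- expS * neg_mask * f
    for (pe in pos_entries) G[pe[1], pe[2]] <- G[pe[1], pe[2]] + pe[3]
    dE <- (G %*% E + crossprod(G, E)) / tau
    if (!is.null(aug_emb)) dE <- dE + (aug_diag * f / tau) * aug_emb
    if (!is.null(expSq)) dE <- dE + ((expSq * f) %*% queue_emb) / tau
  }
  list(loss_sum = loss_sum, n_anchors = n_anchors, dE = dE)
}

# Distort a flat pixel batch for augmentation negatives.
augment_batch <- function(xf, config, shape, M, seed) {
  if (config$aug_kind == "noise") {
    with_seed(derive_seed(seed, "augment"), {
      xf + matrix(stats::rnorm(length(xf), 0, config$aug_noise_sd),
                  nrow(xf), ncol(xf))
    })
  } else {
    # 90-degree rotation of each 2D modality block
    if (length(shape) != 2) stopf("rotation augmentation requires 2D images")
    P <- prod(shape)
    idx <- as.vector(t(matrix(seq_len(P), shape[1], shape[2]))[, shape[1]:1])
    # rotate indices within each modality block
    cols <- unlist(lapply(seq_len(M), function(m) (m - 1) * P + idx))
    xf[, cols, drop = FALSE]
  }
}

#' Hierarchical cross-modal contrastive loss (and gradients)
#'
#' Encodes a batch, projects each level's features to unit-norm embeddings,
#' and evaluates the multi-level InfoNCE objective: the per-level losses
#' (averaged over batch samples, ordered modality pairs and locations) are
#' combined with the configured level weights. Optionally returns gradients
#' with respect to input pixels and/or encoder+projection parameters.
#'
#' @param enc an `mm_encoder`.
#' @param projs named list of projection heads per level (`patch`, `pooled`).
#' @param x pixel array `(B, M, spatial...)` or flat pixel matrix.
#' @param config a [contrastive_config()].
#' @param seed seed for patch-location subsampling and augmentation draws.
#' @param grad one of `"none"`, `"input"`, `"params"`, `"both"`.
#' @param queue optional momentum queue (see [new_queue()]); used as extra
#'   constant negatives at the pooled level.
#' @return list with `loss`, per-level losses, and (when requested)
#'   `d_input` (same layout as the flat batch), `d_enc_params`,
#'   `d_proj_params` (named list per level).
#' @export
contrastive_loss <- function(enc, projs, x, config, seed = 1,
                             grad = c("none", "input", "params", "both"),
                             queue = NULL) {
  grad <- match.arg(grad)
  want_grad <- grad != "none"
  M <- enc$config$n_modalities
  if (M < 2) stopf("cross-modal positives require >= 2 modalities")
  xf <- as_flat_batch(enc, x)
  B <- nrow(xf)
  feats <- encode(enc, xf, keep_cache = want_grad)
  tabs <- level_tables(feats, config, seed)
  if (config$use_inter_instance && B < 2) {
    stopf("inter-instance negatives require a batch of >= 2 samples")
  }

  aug_tabs <- NULL
  if (config$use_augmentation_negatives) {
    x_aug <- augment_batch(xf, config, enc$config$spatial_shape, M, seed)
    feats_aug <- encode(enc, x_aug, keep_cache = FALSE)
    aug_tabs <- level_tables(feats_aug, config, seed)
  }

  total <- 0
  per_level <- numeric(0)
  d_pooled <- NULL; d_patch <- NULL
  d_proj <- list()
  for (lev in names(tabs)) {
    tb <- tabs[[lev]]
    proj <- projs[[lev]]
    if (is.null(proj)) stopf("no projection head for level '%s'", lev)
    E <- project(proj, tb$raw, keep_cache = want_grad)
    aug_emb <- if (!is.null(aug_tabs)) {
      project(proj, aug_tabs[[lev]]$raw, keep_cache = FALSE)
    }
    q_emb <- if (lev == "pooled" && !is.null(queue)) queue_entries(queue)
    res <- level_infonce(E, tb$sample, tb$modality, tb$loc, config,
                         queue_emb = q_emb, aug_emb = aug_emb,
                         use_intra = (lev == "patch"), want_grad = want_grad)
    w <- config$level_weights[[lev]]
    lev_loss <- res$loss_sum / res$n_anchors
    per_level[lev] <- lev_loss
    total <- total + w * lev_loss
    if (want_grad) {
      scale <- w / res$n_anchors
      pb <- projection_backward(proj, E, res$dE * scale)
      d_proj[[lev]] <- pb$d_params
      dz <- pb$d_input
      if (lev == "pooled") {
        d_pooled <- lapply(seq_len(M), function(m) {
          dz[((m - 1) * B + 1):(m * B), , drop = FALSE]
        })
      } else {
        nl <- length(tb$locs)
        d_patch <- lapply(seq_len(M), function(m) {
          out <- matrix(0, B * feats$n_patch, enc$config$width)
          block <- dz[((m - 1) * B * nl + 1):(m * B * nl), , drop = FALSE]
          out[tb$rows, ] <- block
          out
        })
      }
    }
  }

  out <- list(loss = total, per_level = per_level, B = B)
  if (want_grad) {
    eb <- encoder_backward(enc, feats, d_pooled = d_pooled, d_patch = d_patch)
    if (grad %in% c("input", "both")) out$d_input <- eb$d_input
    if (grad %in% c("params", "both")) {
      out$d_enc_params <- eb$d_params
      out$d_proj_params <- d_proj
    }
  }
  out$pooled_embeddings <- if ("pooled" %in% names(tabs)) {
    project(projs$pooled, tabs$pooled$raw)
  }
  out
}

# ---- momentum memory queue ----

#' Create a momentum memory queue of negative embeddings
#' @param size maximum number of stored embeddings.
#' @param dim embedding dimension.
#' @export
new_queue <- function(size, dim) {
  structure(list(size = as.integer(size), dim = as.integer(dim),
                 entries = matrix(0, 0, dim), ema = numeric(dim)),
            class = "mm_queue")
}

#' Entries currently stored in a queue
#' @param queue an `mm_queue`.
#' @export
queue_entries <- function(queue) queue$entries

#' Push a batch of embeddings into the queue
#'
#' Each pushed entry is the momentum-updated running average of the stream of
#' embeddings seen so far (`ema <- momentum * ema + (1 - momentum) * e`),
#' re-normalized to unit norm. Oldest entries are evicted FIFO.
#'
#' @param queue an `mm_queue`.
#' @param emb matrix of unit-norm embeddings (rows).
#' @param momentum momentum coefficient in `[0, 1)`.
#' @return the updated queue.
#' @export
queue_push <- function(queue, emb, momentum = 0.5) {
  for (r in seq_len(nrow(emb))) {
    queue$ema <- momentum * queue$ema + (1 - momentum) * emb[r, ]
    e <- queue$ema / max(sqrt(sum(queue$ema^2)), 1e-8)
    queue$entries <- unname(rbind(queue$entries, e))
  }
  if (nrow(queue$entries) > queue$size) {
    keep <- (nrow(queue$entries) - queue$size + 1):nrow(queue$entries)
    queue$entries <- queue$entries[keep, , drop = FALSE]
  }
  queue
}

#' Cross-modal retrieval top-1 accuracy
#'
#' For every sample and ordered modality pair (m, n), the pooled embedding
#' z_i(m) retrieves its match among all samples' modality-n embeddings by
#' cosine similarity; ties break to the lowest index.
#'
#' @param feats an `mm_features` (or list of per-modality pooled matrices).
#' @return fraction of anchors whose top-1 retrieval is the correct sample.
#' @export
retrieval_top1 <- function(feats) {
  pooled <- if (inherits(feats, "mm_features")) feats$pooled else feats
  M <- length(pooled)
  B <- nrow(pooled[[1]])
  normed <- lapply(pooled, l2_normalize_rows)
  hits <- 0L; tot <- 0L
  for (m in seq_len(M)) {
    for (n in setdiff(seq_len(M), m)) {
      S <- normed[[m]] %*% t(normed[[n]])
      pred <- apply(S, 1, which.max) # which.max breaks ties at lowest index
      hits <- hits + sum(pred == seq_len(B))
      tot <- tot + B
    }
  }
  hits / tot
}

#' Contrastive pretraining of the encoder and projection heads
#'
#' Minimizes the hierarchical contrastive loss over mini-batches of a real
#' cohort with Adam, MoCo-style optional memory queue.
#'
#' @param cohort an `mm_cohort`.
#' @param enc an `mm_encoder`.
#' @param projs named list of projection heads per level.
#' @param config a [contrastive_config()].
#' @param steps number of optimization steps.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed seed controlling batches and augmentation.
#' @return list(encoder, projs, trace) where `trace` is the per-step loss.
#' @export
pretrain_encoder <- function(cohort, enc, projs, config, steps = 200,
                             batch_size = 16, lr = 5e-3, seed = 1) {
  n <- n_samples(cohort)
  flat <- flatten_pixels(cohort$pixels)
  theta <- c(encoder_params(enc),
             unlist(lapply(projs, projection_params), use.names = FALSE))
  n_enc <- length(encoder_params(enc))
  proj_lens <- vapply(projs, function(p) length(projection_params(p)),
                      numeric(1))
  opt <- adam_init(length(theta))
  trace <- numeric(steps)
  queue <- if (config$queue_size > 0) {
    new_queue(config$queue_size, projs$pooled$out_dim)
  }
  for (s in seq_len(steps)) {
    idx <- with_seed(derive_seed(seed, "pretrain-batch", s),
                     sample(n, min(batch_size, n)))
    cl <- contrastive_loss(enc, projs, flat[idx, , drop = FALSE], config,
                           seed = derive_seed(seed, "pretrain-step", s),
                           grad = "params", queue = queue)
    g <- c(cl$d_enc_params,
           unlist(cl$d_proj_params[names(projs)], use.names = FALSE))
    st <- adam_step(opt, g, lr)
    opt <- st$state
    theta <- theta - st$delta
    enc <- encoder_set_params(enc, theta[seq_len(n_enc)])
    pos <- n_enc
    for (lv in names(projs)) {
      projs[[lv]] <- projection_set_params(
        projs[[lv]], theta[(pos + 1):(pos + proj_lens[lv])])
      pos <- pos + proj_lens[lv]
    }
    if (!is.null(queue) && !is.null(cl$pooled_embeddings)) {
      queue <- queue_push(queue, cl$pooled_embeddings, config$queue_momentum)
    }
    trace[s] <- cl$loss
  }
  list(encoder = enc, projs = projs, trace = trace)
}
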