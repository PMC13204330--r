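# Gradient-matching dataset distillation.
#
# The synthetic dataset S holds learnable pixel arrays with fixed labels. A
# freshly initialized proxy classifier (multinomial logistic regression on
# flattened multi-modal pixels; parameter groups: weights, bias) is trained
# for a short trajectory; at each step the task-loss gradients computed on a
# real batch and a synthetic batch at the SAME parameters are compared with a
# per-group cosine distance, and the synthetic pixels receive the exact
# analytic gradient of that distance (the real-batch gradient is a constant).

#' Initialize a learnable synthetic dataset
#'
#' @param cohort the real `mm_cohort` the distilled set will stand in for.
#' @param ipc images (synthetic samples) per class.
#' @param init_mode `"gaussian"` (N(0, sigma^2) with sigma the per-modality
#'   empirical sd of the cohort's pixels), `"real_sample"` (random real
#'   images), or `"class_mean"`.
#' @param seed integer seed.
#' @param lr_synthetic Adam learning rate for the pixel updates.
#' @return an `mm_synthetic`: `pixels` (ipc*n_classes x M x spatial),
#'   `labels` (hard, class-balanced), optional `labels_soft`, `init_sd`,
#'   `ipc`, plus Adam state.
#' @export
init_synthetic <- function(cohort, ipc,
                           init_mode = c("gaussian", "real_sample",
                                         "class_mean"),
                           seed = 1, lr_synthetic = 0.01) {
  init_mode <- match.arg(init_mode)
  stopifnot(inherits(cohort, "mm_cohort"), ipc >= 1)
  K <- cohort$n_classes
  ns <- ipc * K
  if (ns > n_samples(cohort)) {
    stopf("ipc = %d gives %d synthetic samples > cohort size %d",
          ipc, ns, n_samples(cohort))
  }
  counts <- tabulate(cohort$labels, K)
  if (any(counts == 0)) {
    stopf("cohort has no samples for class %s", which(counts == 0)[1])
  }
  M <- n_modalities(cohort)
  P <- prod(cohort$shape)
  flat_real <- flatten_pixels(cohort$pixels)
  sigma <- vapply(seq_len(M), function(m) {
    stats::sd(flat_real[, ((m - 1) * P + 1):(m * P)])
  }, numeric(1))
  labels <- rep(seq_len(K), each = ipc)
  flat <- with_seed(derive_seed(seed, "synthetic-init"), {
    switch(init_mode,
      gaussian = {
        f <- matrix(0, ns, M * P)
        for (m in seq_len(M)) {
          f[, ((m - 1) * P + 1):(m * P)] <-
            stats::rnorm(ns * P, 0, sigma[m])
        }
        f
      },
      real_sample = {
        rows <- unlist(lapply(seq_len(K), function(c_id) {
          sample(which(cohort$labels == c_id), ipc)
        }))
        flat_real[rows, , drop = FALSE]
      },
      class_mean = {
        do.call(rbind, lapply(labels, function(c_id) {
          colMeans(flat_real[cohort$labels == c_id, , drop = FALSE])
        }))
      })
  })
  structure(list(pixels = unflatten_pixels(flat, M, cohort$shape),
                 labels = labels, labels_soft = NULL,
                 n_classes = K, ipc = as.integer(ipc),
                 modality_names = cohort$modality_names,
                 shape = cohort$shape, init_sd = sigma,
                 init_mode = init_mode, seed = as.integer(seed),
                 lr_synthetic = lr_synthetic,
                 opt = adam_init(ns * M * P)),
            class = c("mm_synthetic", "mm_cohort"))
}

#' @export
print.mm_synthetic <- function(x, ...) {
  cat(sprintf("mm_synthetic: %d samples (ipc=%d, %d classes), %d modalities, %s labels\n",
              n_samples(x), x$ipc, x$n_classes, n_modalities(x),
              if (is.null(x$labels_soft)) "hard" else "soft"))
  invisible(x)
}

#' Assign (and freeze) synthetic labels
#'
#' With a teacher model trained on the original dataset, each synthetic
#' sample receives the teacher's predicted class distribution as a frozen
#' soft label; without a teacher the class-balanced hard labels from
#' initialization are kept. Labels never receive gradients.
#'
#' @param synthetic an `mm_synthetic`.
#' @param teacher optional classifier from [train_downstream()].
#' @return the updated `mm_synthetic`.
#' @export
assign_labels <- function(synthetic, teacher = NULL) {
  if (is.null(teacher)) return(synthetic)
  probs <- predict_proba(teacher, synthetic)
  if (ncol(probs) != synthetic$n_classes) {
    stopf("teacher predicts %d classes but synthetic set has %d",
          ncol(probs), synthetic$n_classes)
  }
  synthetic$labels_soft <- probs
  synthetic
}

# One-hot (or stored soft) label matrix of a dataset.
label_matrix <- function(x, n_classes = x$n_classes) {
  if (!is.null(x$labels_soft)) return(x$labels_soft)
  Y <- matrix(0, length(x$labels), n_classes)
  Y[cbind(seq_along(x$labels), x$labels)] <- 1
  Y
}

#' Cosine distance between two gradient (or any) arrays
#'
#' `1 - <g1, g2> / max(||g1|| ||g2||, eps)`, flattened; lies in `[0, 2]`.
#' The epsilon guard only engages for degenerate near-zero gradients, so the
#' distance of a gradient to itself is exactly 0 whenever its norm is
#' non-negligible (gradient groups such as the bias can be arbitrarily small
#' on class-balanced batches).
#'
#' @param g1,g2 numeric arrays of identical shape.
#' @param eps stability constant.
#' @export
cosine_distance <- function(g1, g2, eps = 1e-8) {
  if (length(g1) != length(g2)) {
    stopf("gradient shapes differ: %d vs %d", length(g1), length(g2))
  }
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  1 - sum(g1 * g2) / max(sqrt(sum(g1^2)) * sqrt(sum(g2^2)), eps)
}

# d cosine_distance / d g1 (g2 constant).
cosine_distance_grad <- function(g1, g2, eps = 1e-8) {
  n1 <- sqrt(sum(g1^2)); n2 <- sqrt(sum(g2^2))
  raw <- n1 * n2
  b <- max(raw, eps)
  dot <- sum(g1 * g2)
  if (raw <= eps) return(-(g2 / b)) # guard active: denominator constant
  -(g2 / b) + dot * (n2 / max(n1, 1e-300)) * g1 / b^2
}

# ---- proxy classifier ----

#' Initialize a proxy classifier
#'
#' Multinomial logistic regression on flattened multi-modal pixels; its two
#' parameter groups (weights, bias) are the groups the gradient-matching
#' loss compares.
#'
#' @param d_in input dimension (M * prod(spatial shape)).
#' @param n_classes number of classes.
#' @param seed integer seed (small-Gaussian weight init).
#' @export
proxy_init <- function(d_in, n_classes, seed = 1) {
  with_seed(derive_seed(seed, "proxy"), {
    structure(list(W = matrix(stats::rnorm(d_in * n_classes, 0, 0.01),
                              d_in, n_classes),
                   b = numeric(n_classes),
                   d_in = d_in, n_classes = n_classes),
              class = "mm_proxy")
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# Cross-entropy loss, probabilities, and parameter-group gradients of the
# proxy on a flat batch.
proxy_loss_grad <- function(proxy, X, Y) {
  logits <- sweep(X %*% proxy$W, 2, proxy$b, `+`)
  p <- softmax_rows(logits)
  B <- nrow(X)
  loss <- -sum(Y * log(pmax(p, 1e-12))) / B
  diff <- (p - Y) / B
  list(loss = loss, probs = p,
       grads = list(W = t(X) %*% diff, b = colSums(diff)))
}

#' One gradient-matching step
#'
#' Computes the task-loss gradients on a real batch and on a synthetic batch
#' at the same proxy parameters, sums per-group cosine distances, returns the
#' exact gradient of that loss with respect to the synthetic batch pixels
#' (the real-batch gradient is treated as a constant), then advances the
#' proxy one SGD step on the chosen batch.
#'
#' @param proxy an `mm_proxy`.
#' @param Xd,Yd real flat pixel batch and label matrix.
#' @param Xs,Ys synthetic flat pixel batch and label matrix.
#' @param eta_theta proxy (inner-loop) learning rate.
#' @param inner_on which batch trains the proxy: `"synthetic"` (default, so
#'   training on S replicates the dynamics being matched) or `"real"`.
#' @param eps cosine-distance stability constant.
#' @param want_grad compute the synthetic-pixel gradient.
#' @return list(loss, d_Xs, proxy, per_group).
#' @export
gradient_match_step <- function(proxy, Xd, Yd, Xs, Ys, eta_theta = 1e-3,
                                inner_on = c("synthetic", "real"),
                                eps = 1e-8, want_grad = TRUE,
                                advance = TRUE) {
  inner_on <- match.arg(inner_on)
  if (nrow(Xd) == 0 || nrow(Xs) == 0) stopf("empty batch in gradient matching")
  d_res <- proxy_loss_grad(proxy, Xd, Yd)
  s_res <- proxy_loss_grad(proxy, Xs, Ys)
  gD <- d_res$grads; gS <- s_res$grads
  per_group <- c(W = cosine_distance(gS$W, gD$W, eps),
                 b = cosine_distance(gS$b, gD$b, eps))
  loss <- sum(per_group)
  d_Xs <- NULL
  if (want_grad) {
    U <- cosine_distance_grad(gS$W, gD$W, eps)        # d_in x K
    u_b <- cosine_distance_grad(gS$b, gD$b, eps)      # K
    Bs <- nrow(Xs)
    Ps <- s_res$probs
    Ys_m <- Ys
    A <- Xs %*% U + matrix(u_b, Bs, length(u_b), byrow = TRUE)
    R <- Ps * A - Ps * rowSums(A * Ps)
    d_Xs <- ((Ps - Ys_m) %*% t(U) + R %*% t(proxy$W)) / Bs
  }
  inner <- if (inner_on == "synthetic") s_res$grads else d_res$grads
  if (advance) proxy <- proxy_advance(proxy, inner, eta_theta)
  list(loss = loss, per_group = per_group, d_Xs = d_Xs, proxy = proxy,
       inner_grads = inner)
}

# One SGD step of the proxy on a gradient group list.
proxy_advance <- function(proxy, grads, eta_theta) {
  proxy$W <- proxy$W - eta_theta * grads$W
  proxy$b <- proxy$b - eta_theta * grads$b
  proxy
}

# Class-conditionally paired batch indices for D and S.
paired_batches <- function(labels_d, labels_s, batch_d, batch_s, n_classes,
                           seed, class_match = TRUE) {
  with_seed(seed, {
    if (class_match) {
      sidx <- unlist(lapply(seq_len(n_classes), function(c_id) {
        ids <- which(labels_s == c_id)
        per <- max(1, min(length(ids), ceiling(batch_s / n_classes)))
        if (length(ids) <= per) ids else sample(ids, per)
      }))
      counts <- tabulate(labels_s[sidx], n_classes)
      scale <- batch_d / length(sidx)
      didx <- unlist(lapply(seq_len(n_classes), function(c_id) {
        if (counts[c_id] == 0) return(integer(0))
        ids <- which(labels_d == c_id)
        sample(ids, min(length(ids), max(1, round(counts[c_id] * scale))))
      }))
    } else {
      sidx <- sample(length(labels_s), min(batch_s, length(labels_s)))
      didx <- sample(length(labels_d), min(batch_d, length(labels_d)))
    }
    list(d = didx, s = sidx)
  })
}

#' Distillation loss over one short proxy trajectory
#'
#' Re-initializes the proxy at random parameters, runs `T` gradient-matching
#' steps with freshly sampled (class-matched) mini-batches, and returns the
#' summed step losses — one realization of the trajectory expectation.
#'
#' @param cohort real `mm_cohort`.
#' @param synthetic an `mm_synthetic`.
#' @param T_steps number of inner-loop steps.
#' @param batch_d,batch_s mini-batch sizes for D and S.
#' @param eta_theta inner-loop learning rate.
#' @param seed integer seed (proxy init and batch sampling).
#' @param inner_on which batch trains the proxy.
#' @param class_match pair batches class-conditionally.
#' @param want_grad also accumulate the pixel gradient of the loss.
#' @return list(loss, d_pixels (flat NS x M*P or NULL), trace).
#' @export
accumulate_distillation_loss <- function(cohort, synthetic, T_steps = 5,
                                         batch_d = 16, batch_s = 64,
                                         eta_theta = 1e-3, seed = 1,
                                         inner_on = "synthetic",
                                         class_match = TRUE,
                                         want_grad = FALSE) {
  stopifnot(T_steps >= 1)
  Xd_all <- flatten_pixels(cohort$pixels)
  Xs_all <- flatten_pixels(synthetic$pixels)
  Yd_all <- label_matrix(cohort)
  Ys_all <- label_matrix(synthetic)
  proxy <- proxy_init(ncol(Xd_all), cohort$n_classes,
                      seed = derive_seed(seed, "theta0"))
  total <- 0
  trace <- numeric(T_steps)
  d_pix <- if (want_grad) matrix(0, nrow(Xs_all), ncol(Xs_all))
  for (t in seq_len(T_steps)) {
    bt <- paired_batches(cohort$labels, synthetic$labels, batch_d, batch_s,
                         cohort$n_classes, derive_seed(seed, "batch", t),
                         class_match)
    st <- gradient_match_step(proxy,
                              Xd_all[bt$d, , drop = FALSE],
                              Yd_all[bt$d, , drop = FALSE],
                              Xs_all[bt$s, , drop = FALSE],
                              Ys_all[bt$s, , drop = FALSE],
                              eta_theta = eta_theta,
                              want_grad = want_grad)
    proxy <- st$proxy
    total <- total + st$loss
    trace[t] <- st$loss
    if (want_grad) {
      d_pix[bt$s, ] <- d_pix[bt$s, ] + st$d_Xs
    }
  }
  list(loss = total, d_pixels = d_pix, trace = trace)
}

#' Update synthetic pixels with an Adam step
#'
#' Labels are untouched; non-finite gradients abort with a diagnostic;
#' optional clipping to a value range.
#'
#' @param synthetic an `mm_synthetic`.
#' @param grad_pixels gradient array or flat matrix matching the pixel shape.
#' @param clip optional length-2 numeric range to clip pixels to.
#' @return the updated `mm_synthetic`.
#' @export
update_synthetic <- function(synthetic, grad_pixels, clip = NULL) {
  g <- as.numeric(grad_pixels)
  if (length(g) != length(synthetic$pixels)) {
    stopf("gradient length %d does not match pixel count %d",
          length(g), length(synthetic$pixels))
  }
  if (!all(is.finite(g))) {
    stopf("non-finite synthetic-pixel gradient (%d bad entries)",
          sum(!is.finite(g)))
  }
  # grad arrives in flat (modality-major) layout when it came from the flat
  # matrix; accept both by converting arrays through the same flattening.
  if (!is.null(dim(grad_pixels)) && length(dim(grad_pixels)) > 2) {
    g <- as.numeric(flatten_pixels(grad_pixels))
  } else if (is.matrix(grad_pixels)) {
    g <- as.numeric(grad_pixels)
  }
  flat <- flatten_pixels(synthetic$pixels)
  st <- adam_step(synthetic$opt, g, synthetic$lr_synthetic)
  synthetic$opt <- st$state
  flat <- flat - matrix(st$delta, nrow(flat), ncol(flat))
  if (!is.null(clip)) {
    flat[flat < clip[1]] <- clip[1]
    flat[flat > clip[2]] <- clip[2]
  }
  synthetic$pixels <- unflatten_pixels(flat, n_modalities(synthetic),
                                       synthetic$shape)
  synthetic
}

#' Write a distilled dataset to disk
#'
#' Directory container with a JSON manifest (ipc, compression ratio, seed,
#' init mode, sigma, schedule and encoder-config hash, format version),
#' the pixel tensor as one flat float64 file, and hard/soft labels.
#'
#' @param synthetic an `mm_synthetic`.
#' @param path output directory.
#' @param extra named list merged into the manifest (e.g. schedule config,
#'   encoder config hash, cr).
#' @export
write_synthetic <- function(synthetic, path, extra = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  flat <- flatten_pixels(synthetic$pixels)
  con <- file(file.path(path, "pixels.bin"), "wb")
  writeBin(as.numeric(flat), con, size = 8, endian = "little")
  close(con)
  manifest <- c(list(format_version = 1L, kind = "distilled",
                     n_samples = n_samples(synthetic),
                     n_classes = synthetic$n_classes,
                     n_modalities = n_modalities(synthetic),
                     shape = synthetic$shape,
                     modality_names = synthetic$modality_names,
                     labels = synthetic$labels,
                     ipc = synthetic$ipc, init_mode = synthetic$init_mode,
                     sigma = synthetic$init_sd, seed = synthetic$seed,
                     lr_synthetic = synthetic$lr_synthetic,
                     dtype = "float64"),
                if (!is.null(synthetic$labels_soft)) {
                  list(labels_soft = synthetic$labels_soft)
                },
                extra)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a distilled dataset written by [write_synthetic()]
#' @param path directory.
#' @return an `mm_synthetic` (with a fresh optimizer state).
#' @export
read_synthetic <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest.json under %s", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (field in c("labels", "shape", "n_modalities", "n_samples", "ipc")) {
    if (is.null(mf[[field]])) stopf("manifest missing field '%s'", field)
  }
  n <- mf$n_samples; m <- mf$n_modalities
  shape <- as.integer(mf$shape); P <- prod(shape)
  con <- file(file.path(path, "pixels.bin"), "rb")
  on.exit(close(con))
  flat <- matrix(readBin(con, "double", n = n * m * P, size = 8,
                         endian = "little"), n, m * P)
  structure(list(pixels = unflatten_pixels(flat, m, shape),
                 labels = as.integer(mf$labels),
                 labels_soft = if (length(mf$labels_soft) > 0) {
                   as.matrix(mf$labels_soft)
                 },
                 n_classes = as.integer(mf$n_classes),
                 ipc = as.integer(mf$ipc),
                 modality_names = mf$modality_names,
                 shape = shape, init_sd = mf$sigma,
                 init_mode = mf$init_mode, seed = as.integer(mf$seed %||% NA),
                 lr_synthetic = mf$lr_synthetic %||% 0.01,
                 opt = adam_init(n * m * P)),
            class = c("mm_synthetic", "mm_cohort"))
}
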