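# Downstream training and evaluation protocols: accuracy / macro-F1,
# upper-bound and random-subset baselines, ablation variants, compression and
# label-ratio sweeps, missing-modality robustness, cross-architecture
# generalization.

#' Downstream classifier architecture presets
#'
#' A family of small multilayer perceptrons on flattened multi-modal pixels
#' with strictly increasing parameter counts: `linear` (softmax regression),
#' `mlp16`, `mlp32` (default), `mlp64_32`.
#'
#' @param name preset name, or a numeric vector of hidden widths.
#' @return list(name, hidden).
#' @export
downstream_arch <- function(name = "mlp32") {
  if (is.numeric(name)) return(list(name = "custom", hidden = name))
  presets <- list(linear = integer(0), mlp16 = 16L, mlp32 = 32L,
                  mlp64_32 = c(64L, 32L))
  if (!name %in% names(presets)) {
    stopf("unknown architecture '%s' (have: %s)", name,
          paste(names(presets), collapse = ", "))
  }
  list(name = name, hidden = presets[[name]])
}

#' Parameter count of a downstream architecture
#' @param arch a [downstream_arch()].
#' @param d_in input dimension.
#' @param n_classes number of classes.
#' @export
arch_param_count <- function(arch, d_in, n_classes) {
  dims <- c(d_in, arch$hidden, n_classes)
  sum(dims[-length(dims)] * dims[-1] + dims[-1])
}

mlp_init <- function(d_in, hidden, n_classes, seed) {
  dims <- c(d_in, hidden, n_classes)
  with_seed(derive_seed(seed, "mlp"), {
    lapply(seq_len(length(dims) - 1), function(l) {
      list(W = he_init(dims[l], dims[l + 1]), b = numeric(dims[l + 1]))
    })
  })
}

mlp_forward <- function(layers, X, keep = FALSE) {
  acts <- list(X)
  A <- X
  nl <- length(layers)
  for (l in seq_len(nl)) {
    Z <- sweep(A %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    A <- if (l < nl) relu(Z) else Z
    if (keep) acts[[l + 1]] <- A
  }
  if (keep) list(logits = A, acts = acts) else list(logits = A)
}

mlp_grad <- function(layers, X, Y) {
  fw <- mlp_forward(layers, X, keep = TRUE)
  p <- softmax_rows(fw$logits)
  B <- nrow(X)
  loss <- -sum(Y * log(pmax(p, 1e-12))) / B
  delta <- (p - Y) / B
  nl <- length(layers)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    A_in <- fw$acts[[l]]
    grads[[l]] <- list(W = t(A_in) %*% delta, b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (fw$acts[[l]] > 0)
    }
  }
  list(loss = loss, grads = grads)
}

mlp_params <- function(layers) {
  unlist(lapply(layers, function(l) c(l$W, l$b)), use.names = FALSE)
}

mlp_set_params <- function(layers, vec) {
  pos <- 0L
  lapply(layers, function(l) {
    nW <- length(l$W); nb <- length(l$b)
    l$W <- matrix(vec[(pos + 1):(pos + nW)], nrow(l$W), ncol(l$W))
    pos <<- pos + nW
    l$b <- vec[(pos + 1):(pos + nb)]
    pos <<- pos + nb
    l
  })
}

#' Train a downstream classifier
#'
#' Adam-trained MLP (cross-entropy; soft labels are trained against the full
#' distribution). Input is either flattened pixels or, with an encoder,
#' concatenated pooled per-modality features.
#'
#' @param data an `mm_cohort` or `mm_synthetic`.
#' @param arch preset name or [downstream_arch()].
#' @param epochs passes over the data (0 returns the initialized model).
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param seed seed for initialization and batch order.
#' @param encoder optional `mm_encoder`; switches input to pooled features.
#' @param weight_decay L2 penalty coefficient (decoupled, AdamW-style).
#' @return an `mm_classifier`.
#' @export
train_downstream <- function(data, arch = "mlp32", epochs = 150, lr = 1e-2,
                             batch_size = 32, seed = 1, encoder = NULL,
                             weight_decay = 1e-3) {
  if (n_samples(data) == 0) stopf("empty training set")
  if (is.character(arch) || is.numeric(arch)) arch <- downstream_arch(arch)
  X <- if (is.null(encoder)) flatten_pixels(data$pixels) else {
    featurize(encoder, data)
  }
  Y <- label_matrix(data)
  K <- data$n_classes
  layers <- mlp_init(ncol(X), arch$hidden, K, seed)
  theta <- mlp_params(layers)
  opt <- adam_init(length(theta))
  n <- nrow(X)
  bs <- min(batch_size, n)
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      ord <- with_seed(derive_seed(seed, "epoch", ep), sample(n))
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        gr <- mlp_grad(layers, X[idx, , drop = FALSE],
                       Y[idx, , drop = FALSE])
        g <- unlist(lapply(gr$grads, function(l) c(l$W, l$b)),
                    use.names = FALSE)
        st <- adam_step(opt, g, lr)
        opt <- st$state
        theta <- theta - st$delta - lr * weight_decay * theta
        layers <- mlp_set_params(layers, theta)
      }
    }
  }
  structure(list(layers = layers, arch = arch, n_classes = K,
                 d_in = ncol(X), encoder = encoder,
                 modality_names = data$modality_names, shape = data$shape),
            class = "mm_classifier")
}

#' Predicted class probabilities
#' @param model an `mm_classifier`.
#' @param data an `mm_cohort`/`mm_synthetic` or flat pixel matrix.
#' @export
predict_proba <- function(model, data) {
  X <- if (is.matrix(data)) data else if (is.null(model$encoder)) {
    flatten_pixels(data$pixels)
  } else featurize(model$encoder, data)
  if (ncol(X) != model$d_in) {
    stopf("classifier expects %d inputs, got %d", model$d_in, ncol(X))
  }
  softmax_rows(mlp_forward(model$layers, X)$logits)
}

#' Predicted class labels (ties break to the lowest class index)
#' @inheritParams predict_proba
#' @export
predict_class <- function(model, data) {
  apply(predict_proba(model, data), 1, which.max)
}

#' Concatenated pooled encoder features of a dataset
#' @param encoder an `mm_encoder`.
#' @param data an `mm_cohort`/`mm_synthetic` or flat pixel matrix.
#' @export
featurize <- function(encoder, data) {
  x <- if (is.matrix(data)) data else flatten_pixels(data$pixels)
  do.call(cbind, encode(encoder, x)$pooled)
}

#' Accuracy and macro-F1 of predictions
#'
#' Per-class F1 from one-vs-rest precision/recall; a class with no true and
#' no predicted instances contributes F1 = 0; macro-F1 is the unweighted
#' mean.
#'
#' @param truth integer true labels (1..n_classes).
#' @param pred integer predicted labels.
#' @param n_classes number of classes.
#' @return list(accuracy, macro_f1, per_class_f1).
#' @export
classification_metrics <- function(truth, pred, n_classes) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  acc <- mean(truth == pred)
  f1 <- vapply(seq_len(n_classes), function(c_id) {
    tp <- sum(truth == c_id & pred == c_id)
    fp <- sum(truth != c_id & pred == c_id)
    fn <- sum(truth == c_id & pred != c_id)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(accuracy = acc, macro_f1 = mean(f1), per_class_f1 = f1)
}

#' Evaluate a classifier on a test cohort
#'
#' @param model an `mm_classifier`.
#' @param test_cohort held-out `mm_cohort` (disjoint from training data).
#' @param tags named list of condition tags carried into the report.
#' @return an `eval_report`: accuracy, macro_f1, per_class_f1, n_test, tags.
#' @export
evaluate_model <- function(model, test_cohort, tags = list()) {
  if (n_samples(test_cohort) == 0) stopf("empty test set")
  pred <- predict_class(model, test_cohort)
  met <- classification_metrics(test_cohort$labels, pred,
                                test_cohort$n_classes)
  structure(c(met, list(n_test = n_samples(test_cohort), tags = tags)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: Acc=%.3f  Macro-F1=%.3f  (n=%d)\n",
              x$accuracy, x$macro_f1, x$n_test))
  invisible(x)
}

#' Stratified random subset of a given compression ratio
#' @param cohort an `mm_cohort`.
#' @param cr compression ratio in (0, 1].
#' @param seed seed.
#' @export
random_subset <- function(cohort, cr, seed = 1) {
  stopifnot(cr > 0, cr <= 1)
  ns <- ceiling(cr * n_samples(cohort))
  per <- max(1, round(ns / cohort$n_classes))
  idx <- with_seed(derive_seed(seed, "subset"), {
    unlist(lapply(seq_len(cohort$n_classes), function(c_id) {
      ids <- which(cohort$labels == c_id)
      sample(ids, min(per, length(ids)))
    }))
  })
  subset_cohort(cohort, sort(idx))
}

#' Drop unlabeled samples under a label-availability ratio
#'
#' Labels are removed uniformly at random, stratified by class; samples
#' without labels are excluded from the returned cohort.
#'
#' @param cohort an `mm_cohort`.
#' @param label_ratio fraction of labels available, in (0, 1].
#' @param seed seed.
#' @export
reduce_labels <- function(cohort, label_ratio, seed = 1) {
  stopifnot(label_ratio > 0, label_ratio <= 1)
  if (label_ratio == 1) return(cohort)
  idx <- with_seed(derive_seed(seed, "labels"), {
    unlist(lapply(seq_len(cohort$n_classes), function(c_id) {
      ids <- which(cohort$labels == c_id)
      sample(ids, max(1, round(label_ratio * length(ids))))
    }))
  })
  subset_cohort(cohort, sort(idx))
}

#' Compare distillation against baselines under one compression ratio
#'
#' Methods: `upper_bound` (full training cohort), `random_subset`
#' (stratified subset of the same size as the synthetic set), `only_hc2l`
#' (contrastively pretrained encoder + classifier on the random subset's
#' features), `only_ddg` (distillation with lambda_c = 0), and `cgmdd` (the
#' full joint method). All methods share splits and seeds.
#'
#' @param train_cohort,test_cohort disjoint `mm_cohort`s.
#' @param methods character subset of the five methods.
#' @param cr compression ratio in (0, 1].
#' @param seeds integer vector of replicate seeds.
#' @param config a [trainer_config()] template (its `ipc` is overridden by
#'   `cr`).
#' @param contrastive_cfg a [contrastive_config()].
#' @param arch downstream architecture preset.
#' @param epochs downstream training epochs.
#' @return data.frame with one row per (method, seed).
#' @export
run_method_comparison <- function(train_cohort, test_cohort,
                                  methods = c("upper_bound", "random_subset",
                                              "only_hc2l", "only_ddg",
                                              "cgmdd"),
                                  cr = 0.05, seeds = 1:3,
                                  config = trainer_config(),
                                  contrastive_cfg = contrastive_config(),
                                  arch = "mlp32", epochs = 150) {
  stopifnot(cr > 0, cr <= 1)
  nd <- n_samples(train_cohort)
  ns <- ceiling(cr * nd)
  ipc <- max(1, round(ns / train_cohort$n_classes))
  rows <- list()
  add <- function(method, seed, rep, extra = list()) {
    rows[[length(rows) + 1]] <<- data.frame(
      method = method, seed = seed, cr = cr, ipc = ipc,
      accuracy = rep$accuracy, macro_f1 = rep$macro_f1,
      n_test = rep$n_test)
  }
  for (seed in seeds) {
    if ("upper_bound" %in% methods) {
      mod <- train_downstream(train_cohort, arch, epochs = epochs, seed = seed)
      add("upper_bound", seed, evaluate_model(mod, test_cohort))
    }
    if ("random_subset" %in% methods || "only_hc2l" %in% methods) {
      sub <- random_subset(train_cohort, cr, seed = seed)
    }
    if ("random_subset" %in% methods) {
      mod <- train_downstream(sub, arch, epochs = epochs, seed = seed)
      add("random_subset", seed, evaluate_model(mod, test_cohort))
    }
    if ("only_hc2l" %in% methods) {
      setup <- default_encoder_setup(train_cohort, contrastive_cfg,
                                     derive_seed(seed, "hc2l"))
      pt <- pretrain_encoder(train_cohort, setup$encoder, setup$projs,
                             contrastive_cfg,
                             steps = config$pretrain_steps,
                             batch_size = config$pretrain_batch,
                             lr = config$pretrain_lr,
                             seed = derive_seed(seed, "hc2l"))
      mod <- train_downstream(sub, "linear", epochs = epochs, seed = seed,
                              encoder = pt$encoder)
      add("only_hc2l", seed, evaluate_model(mod, test_cohort))
    }
    if ("only_ddg" %in% methods) {
      cfg <- config
      cfg$ipc <- ipc
      cfg$lambda_c_init <- 0
      run <- distill(train_cohort, cfg, contrastive_cfg, seed = seed)
      mod <- train_downstream(run$synthetic, arch, epochs = epochs,
                              seed = seed)
      add("only_ddg", seed, evaluate_model(mod, test_cohort))
    }
    if ("cgmdd" %in% methods) {
      cfg <- config
      cfg$ipc <- ipc
      run <- distill(train_cohort, cfg, contrastive_cfg, seed = seed)
      mod <- train_downstream(run$synthetic, arch, epochs = epochs,
                              seed = seed)
      add("cgmdd", seed, evaluate_model(mod, test_cohort))
    }
  }
  do.call(rbind, rows)
}

#' Accuracy curve over compression ratios
#'
#' One row per (cr, method, seed) plus per-condition mean and sd over seeds
#' (three seeded re-splits realize the repeated cross-validation convention).
#'
#' @inheritParams run_method_comparison
#' @param cr_values compression ratios to sweep.
#' @return list(runs, summary).
#' @export
sweep_cr <- function(train_cohort, test_cohort, cr_values = c(0.025, 0.05, 0.1),
                     methods = c("random_subset", "cgmdd"), seeds = 1:3,
                     config = trainer_config(),
                     contrastive_cfg = contrastive_config(),
                     arch = "mlp32", epochs = 150) {
  runs <- do.call(rbind, lapply(cr_values, function(cr) {
    run_method_comparison(train_cohort, test_cohort, methods, cr, seeds,
                          config, contrastive_cfg, arch, epochs)
  }))
  summary <- stats::aggregate(accuracy ~ method + cr, data = runs,
                              FUN = function(a) c(mean = mean(a), sd = stats::sd(a)))
  summary <- data.frame(method = summary$method, cr = summary$cr,
                        mean_acc = summary$accuracy[, "mean"],
                        sd_acc = summary$accuracy[, "sd"])
  list(runs = runs, summary = summary)
}

#' Accuracy grid over images-per-class and label ratios
#'
#' Unlabeled samples are dropped from the cohort before distillation; the
#' summary table has one row per IPC and one column per label ratio
#' (`ipc = "full"` trains on the full distilled set at the method's default
#' compression).
#'
#' @inheritParams run_method_comparison
#' @param ipc_values synthetic images per class to sweep.
#' @param label_ratios label availability fractions in (0, 1].
#' @return list(runs, summary) where `summary` is the IPC x label-ratio
#'   matrix of median accuracies.
#' @export
sweep_ipc <- function(train_cohort, test_cohort, ipc_values = c(1, 2, 5),
                      label_ratios = c(0.5, 1.0), seeds = 1:3,
                      config = trainer_config(),
                      contrastive_cfg = contrastive_config(),
                      arch = "mlp32", epochs = 150) {
  rows <- list()
  for (lr_frac in label_ratios) {
    for (ipc in ipc_values) {
      for (seed in seeds) {
        cohort_l <- reduce_labels(train_cohort, lr_frac,
                                  seed = derive_seed(seed, "lr"))
        cfg <- config
        cfg$ipc <- as.integer(ipc)
        run <- distill(cohort_l, cfg, contrastive_cfg, seed = seed)
        mod <- train_downstream(run$synthetic, arch, epochs = epochs,
                                seed = seed)
        rep <- evaluate_model(mod, test_cohort)
        rows[[length(rows) + 1]] <- data.frame(
          ipc = ipc, label_ratio = lr_frac, seed = seed,
          accuracy = rep$accuracy, macro_f1 = rep$macro_f1)
      }
    }
  }
  runs <- do.call(rbind, rows)
  summary <- matrix(NA_real_, length(ipc_values), length(label_ratios),
                    dimnames = list(paste0("ipc", ipc_values),
                                    paste0("label", label_ratios * 100)))
  for (i in seq_along(ipc_values)) {
    for (j in seq_along(label_ratios)) {
      sel <- runs$ipc == ipc_values[i] & runs$label_ratio == label_ratios[j]
      summary[i, j] <- stats::median(runs$accuracy[sel])
    }
  }
  list(runs = runs, summary = summary)
}

#' Fill selected modalities of a cohort
#' @param cohort an `mm_cohort`.
#' @param missing modality names or indices to replace.
#' @param fill `"zeros"` or `"noise"`.
#' @param seed seed for the noise fill.
#' @export
fill_modalities <- function(cohort, missing, fill = c("zeros", "noise"),
                            seed = 1) {
  fill <- match.arg(fill)
  M <- n_modalities(cohort)
  miss_idx <- if (is.character(missing)) {
    match(missing, cohort$modality_names)
  } else as.integer(missing)
  if (any(is.na(miss_idx)) || any(miss_idx < 1 | miss_idx > M)) {
    stopf("unknown modality in missing set")
  }
  if (length(miss_idx) >= M) stopf("cannot remove all %d modalities", M)
  flat <- flatten_pixels(cohort$pixels)
  P <- prod(cohort$shape)
  for (m in miss_idx) {
    cols <- ((m - 1) * P + 1):(m * P)
    flat[, cols] <- if (fill == "zeros") 0 else {
      with_seed(derive_seed(seed, "fill", m), {
        matrix(stats::rnorm(nrow(flat) * P), nrow(flat), P)
      })
    }
  }
  out <- cohort
  out$pixels <- unflatten_pixels(flat, M, cohort$shape)
  out
}

#' Missing-modality robustness of a trained model
#'
#' Replaces the given modalities with fill values at inference and reports
#' the accuracy drop in percentage points.
#'
#' @param model an `mm_classifier`.
#' @param test_cohort held-out `mm_cohort`.
#' @param missing modality names or indices (proper, non-empty allowed to be
#'   empty for the zero-drop control).
#' @param fill `"zeros"` (default) or `"noise"`.
#' @param seed seed for the noise fill.
#' @return a `robustness_report`: baseline_acc, acc_with_missing, acc_drop
#'   (pp; may be negative), missing_set, fill_policy.
#' @export
robustness_missing <- function(model, test_cohort, missing,
                               fill = c("zeros", "noise"), seed = 1) {
  fill <- match.arg(fill)
  base <- evaluate_model(model, test_cohort)
  acc_miss <- if (length(missing) == 0) base$accuracy else {
    evaluate_model(model,
                   fill_modalities(test_cohort, missing, fill, seed))$accuracy
  }
  structure(list(baseline_acc = base$accuracy, acc_with_missing = acc_miss,
                 acc_drop = (base$accuracy - acc_miss) * 100,
                 missing_set = missing, fill_policy = fill),
            class = "robustness_report")
}

#' Robustness gain of one method over another
#'
#' Table convention: `gain = drop_other - drop_this` in percentage points; a
#' positive gain means this method degrades less.
#'
#' @param drop_this,drop_other accuracy drops in percentage points.
#' @export
robustness_gain <- function(drop_other, drop_this) drop_other - drop_this

#' Cross-architecture generalization of a distilled dataset
#'
#' @param distilled an `mm_synthetic` (or any training `mm_cohort`).
#' @param archs character vector of architecture presets.
#' @param test_cohort held-out `mm_cohort`.
#' @param seeds replicate seeds.
#' @param epochs downstream training epochs.
#' @return data.frame with one row per (arch, seed), including parameter
#'   counts.
#' @export
cross_architecture <- function(distilled, archs = c("linear", "mlp16",
                                                    "mlp32", "mlp64_32"),
                               test_cohort, seeds = 1:3, epochs = 150) {
  d_in <- n_modalities(distilled) * prod(distilled$shape)
  rows <- list()
  for (a in archs) {
    arch <- downstream_arch(a)
    for (seed in seeds) {
      mod <- train_downstream(distilled, a, epochs = epochs, seed = seed)
      rep <- evaluate_model(mod, test_cohort)
      rows[[length(rows) + 1]] <- data.frame(
        arch = a, seed = seed, accuracy = rep$accuracy,
        macro_f1 = rep$macro_f1,
        n_params = arch_param_count(arch, d_in, distilled$n_classes))
    }
  }
  do.call(rbind, rows)
}

#' Ridge linear probe accuracy on flattened pixels
#'
#' Closed-form one-vs-all ridge regression on a stratified train/test split;
#' a fast, deterministic measure of a cohort's linear separability.
#'
#' @param cohort an `mm_cohort`.
#' @param test_frac held-out fraction.
#' @param seed split seed.
#' @param lambda ridge penalty.
#' @export
linear_probe_accuracy <- function(cohort, test_frac = 0.5, seed = 1,
                                  lambda = 100) {
  sp <- split_cohort(cohort, test_frac, seed)
  X <- flatten_pixels(sp$train$pixels)
  Y <- label_matrix(sp$train)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ctr <- attr(Xc, "scaled:center")
  W <- solve(crossprod(Xc) + lambda * diag(ncol(X)), crossprod(Xc, Y))
  Xt <- sweep(flatten_pixels(sp$test$pixels), 2, ctr)
  pred <- apply(Xt %*% W, 1, which.max)
  mean(pred == sp$test$labels)
}
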