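# Bi-level joint optimization: gradient-matched distillation guided by the
# hierarchical cross-modal contrastive loss under cosine-annealed weights.
#
# Outer iteration k: re-initialize the proxy at theta_0, evaluate the
# schedule weights; inner steps t = 1..T: sample paired mini-batches D_t and
# S_t, compute the task-loss gradients at the same theta_t and their
# per-group cosine distances, compute the contrastive loss on features of
# D_t, S_t or their union, then advance theta one step. After the loop,
# L_d is the sum of step losses, L_contrast the per-step aggregate, and the
# synthetic pixels receive an Adam step on the gradient of
# lambda_d * L_d + lambda_c * L_contrast.

#' Trainer configuration for the bi-level distillation loop
#'
#' Desk-scale defaults (K_total = 300, T = 5) keep a full run inside minutes
#' on one CPU; `paper_scale = TRUE` restores the full-scale values
#' (K_total = 10000, T = 10).
#'
#' @param K_total outer iterations.
#' @param T_steps inner gradient-matching steps per outer iteration.
#' @param eta_theta proxy (inner) learning rate.
#' @param eta_s synthetic-pixel Adam learning rate.
#' @param batch_d,batch_s mini-batch sizes for D and S in the
#'   gradient-matching term.
#' @param contrast_batch maximum number of real samples (drawn from the
#'   current D batch) fed to the contrastive term per inner step; keeps the
#'   contrastive cost independent of `batch_d`.
#' @param ipc synthetic images per class.
#' @param init_mode synthetic initialization, see [init_synthetic()].
#' @param lambda_c_init,lambda_d_init,lambda_d_final schedule parameters.
#' @param fixed_lambda optional constant `c(lambda_c, lambda_d)` replacing
#'   the schedules (fixed-weight ablations).
#' @param contrast_agg how per-step contrastive values form L_contrast:
#'   `"mean"`, `"last"`, or `"sum"`.
#' @param inner_on batch used for the proxy's own update.
#' @param class_match pair D/S batches class-conditionally.
#' @param train_encoder keep training the encoder during distillation
#'   (default: frozen after pretraining).
#' @param pretrain_steps contrastive pretraining steps for the encoder
#'   (0 = none).
#' @param pretrain_lr,pretrain_batch pretraining Adam settings.
#' @param clip optional pixel clipping range after updates.
#' @param paper_scale use the full-scale preset.
#' @export
trainer_config <- function(K_total = 300, T_steps = 5, eta_theta = 1e-3,
                           eta_s = 0.01, batch_d = 16, batch_s = 64,
                           contrast_batch = 16,
                           ipc = 5, init_mode = "class_mean",
                           lambda_c_init = 1.0, lambda_d_init = 0.1,
                           lambda_d_final = 1.0, fixed_lambda = NULL,
                           contrast_agg = c("mean", "last", "sum"),
                           inner_on = c("synthetic", "real"),
                           class_match = TRUE, train_encoder = FALSE,
                           pretrain_steps = 200, pretrain_lr = 5e-3,
                           pretrain_batch = 16, clip = NULL,
                           paper_scale = FALSE) {
  contrast_agg <- match.arg(contrast_agg)
  inner_on <- match.arg(inner_on)
  if (paper_scale) {
    K_total <- 10000L
    T_steps <- 10L
    if (missing(init_mode)) init_mode <- "gaussian"
  }
  stopifnot(K_total >= 0, T_steps >= 1, eta_theta > 0, eta_s > 0,
            batch_d >= 1, batch_s >= 1, ipc >= 1)
  structure(list(K_total = as.integer(K_total), T_steps = as.integer(T_steps),
                 eta_theta = eta_theta, eta_s = eta_s,
                 batch_d = as.integer(batch_d), batch_s = as.integer(batch_s),
                 contrast_batch = as.integer(contrast_batch),
                 ipc = as.integer(ipc), init_mode = init_mode,
                 lambda_c_init = lambda_c_init,
                 lambda_d_init = lambda_d_init,
                 lambda_d_final = lambda_d_final,
                 fixed_lambda = fixed_lambda,
                 contrast_agg = contrast_agg, inner_on = inner_on,
                 class_match = class_match, train_encoder = train_encoder,
                 pretrain_steps = as.integer(pretrain_steps),
                 pretrain_lr = pretrain_lr,
                 pretrain_batch = as.integer(pretrain_batch),
                 clip = clip, paper_scale = paper_scale),
            class = "trainer_config")
}

# Default desk-scale encoder + per-level projection heads for a cohort.
default_encoder_setup <- function(cohort, contrastive_cfg, seed,
                                  width = 16, proj_dim = 16) {
  patch <- max(Filter(function(p) all(cohort$shape %% p == 0) &&
                        all(cohort$shape %/% p >= 2), c(4, 2, 1)))
  cfg <- encoder_config(n_modalities = n_modalities(cohort),
                        spatial_shape = cohort$shape, patch = patch,
                        width = width, n_shared_stages = 2,
                        n_specific_stages = 1, pooled_dim = width)
  enc <- build_encoder(cfg, seed = derive_seed(seed, "enc-init"))
  projs <- list()
  for (lev in names(contrastive_cfg$level_weights)) {
    if (contrastive_cfg$level_weights[[lev]] > 0) {
      in_dim <- if (lev == "pooled") cfg$pooled_dim else cfg$width
      projs[[lev]] <- build_projection(in_dim, hidden = 2 * in_dim,
                                       out_dim = proj_dim,
                                       seed = derive_seed(seed, "proj", lev))
    }
  }
  list(encoder = enc, projs = projs)
}

#' Distill a cohort into a synthetic dataset
#'
#' Runs the full bi-level loop. Three named seed streams derived from `seed`
#' control proxy initialization, batch sampling, and synthetic
#' initialization; the run is bit-reproducible under (seed, configs).
#'
#' @param cohort a labeled `mm_cohort` with >= 2 classes.
#' @param config a [trainer_config()].
#' @param contrastive_cfg a [contrastive_config()]; its `mode` selects
#'   whether real batches, synthetic batches, or their union feed the
#'   contrastive term.
#' @param encoder optional pre-built/pretrained `mm_encoder` (one is built
#'   and contrastively pretrained when omitted and lambda_c is active).
#' @param projs optional named list of projection heads per level.
#' @param teacher optional classifier trained on `cohort`; its predicted
#'   class distributions become the frozen soft labels of the synthetic set.
#' @param seed master seed.
#' @param event_hook optional `function(event, ...)` called at each algorithm
#'   stage (used by conformance tests).
#' @return a `cgmdd_run`: list(synthetic, log, encoder, projs, config,
#'   contrastive_cfg, seed). `log` has one row per outer iteration with
#'   (k, lambda_c, lambda_d, L_d, L_contrast, L_total).
#' @export
distill <- function(cohort, config = trainer_config(),
                    contrastive_cfg = contrastive_config(),
                    encoder = NULL, projs = NULL, teacher = NULL,
                    seed = 1, event_hook = NULL, log_file = NULL) {
  stopifnot(inherits(cohort, "mm_cohort"))
  if (cohort$n_classes < 2) stopf("distillation needs >= 2 classes")
  emit <- function(...) if (!is.null(event_hook)) event_hook(...)

  seed_model <- derive_seed(seed, "stream-model")
  seed_batch <- derive_seed(seed, "stream-batch")
  seed_synth <- derive_seed(seed, "stream-synthetic")

  use_contrast <- if (!is.null(config$fixed_lambda)) {
    config$fixed_lambda[1] > 0
  } else config$lambda_c_init > 0

  if (use_contrast && is.null(encoder)) {
    setup <- default_encoder_setup(cohort, contrastive_cfg, seed_model)
    encoder <- setup$encoder
    projs <- setup$projs
    if (config$pretrain_steps > 0) {
      pt <- pretrain_encoder(cohort, encoder, projs, contrastive_cfg,
                             steps = config$pretrain_steps,
                             batch_size = config$pretrain_batch,
                             lr = config$pretrain_lr, seed = seed_model)
      encoder <- pt$encoder
      projs <- pt$projs
    }
  }

  synthetic <- init_synthetic(cohort, config$ipc, config$init_mode,
                              seed = seed_synth,
                              lr_synthetic = config$eta_s)
  synthetic <- assign_labels(synthetic, teacher)
  emit("init_synthetic")

  Xd_all <- flatten_pixels(cohort$pixels)
  Yd_all <- label_matrix(cohort)
  K_tot <- config$K_total
  log_df <- data.frame(k = integer(0), lambda_c = numeric(0),
                       lambda_d = numeric(0), L_d = numeric(0),
                       L_contrast = numeric(0), L_total = numeric(0))
  if (K_tot == 0) {
    return(structure(list(synthetic = synthetic, log = log_df,
                          encoder = encoder, projs = projs, config = config,
                          contrastive_cfg = contrastive_cfg, seed = seed),
                     class = "cgmdd_run"))
  }

  enc_theta <- NULL; enc_opt <- NULL; n_enc <- 0; proj_lens <- NULL
  if (use_contrast && config$train_encoder) {
    enc_theta <- c(encoder_params(encoder),
                   unlist(lapply(projs, projection_params), use.names = FALSE))
    n_enc <- length(encoder_params(encoder))
    proj_lens <- vapply(projs, function(p) length(projection_params(p)),
                        numeric(1))
    enc_opt <- adam_init(length(enc_theta))
  }

  for (k in seq_len(K_tot)) {
    emit("outer_start", k = k)
    proxy <- proxy_init(ncol(Xd_all), cohort$n_classes,
                        seed = derive_seed(seed_model, "theta0", k))
    emit("theta_init")
    sch <- schedule_state(k, K_tot, config$lambda_c_init,
                          config$lambda_d_init, config$lambda_d_final,
                          fixed = config$fixed_lambda)
    emit("schedule")
    Xs_all <- flatten_pixels(synthetic$pixels)
    Ys_all <- label_matrix(synthetic)
    L_d <- 0
    g_Ld <- matrix(0, nrow(Xs_all), ncol(Xs_all))
    lc_vals <- numeric(config$T_steps)
    g_Lc_steps <- matrix(0, nrow(Xs_all), ncol(Xs_all))
    g_Lc_last <- NULL
    for (t in seq_len(config$T_steps)) {
      emit("inner_step", t = t)
      bt <- paired_batches(cohort$labels, synthetic$labels,
                           config$batch_d, config$batch_s,
                           cohort$n_classes,
                           derive_seed(seed_batch, "batch", k, t),
                           config$class_match)
      emit("sample_batch")
      Xs_b <- Xs_all[bt$s, , drop = FALSE]
      gm <- gradient_match_step(proxy,
                                Xd_all[bt$d, , drop = FALSE],
                                Yd_all[bt$d, , drop = FALSE],
                                Xs_b, Ys_all[bt$s, , drop = FALSE],
                                eta_theta = config$eta_theta,
                                inner_on = config$inner_on,
                                want_grad = sch$lambda_d > 0,
                                advance = FALSE)
      emit("grad_match")
      L_d <- L_d + gm$loss
      if (!is.null(gm$d_Xs)) {
        g_Ld[bt$s, ] <- g_Ld[bt$s, ] + gm$d_Xs
      }
      if (use_contrast) {
        d_sub <- if (length(bt$d) > config$contrast_batch) {
          with_seed(derive_seed(seed_batch, "contrast-sub", k, t),
                    sort(sample(bt$d, config$contrast_batch)))
        } else bt$d
        x_in <- switch(contrastive_cfg$mode,
                       "joint" = rbind(Xd_all[d_sub, , drop = FALSE], Xs_b),
                       "d-only" = Xd_all[d_sub, , drop = FALSE],
                       "s-only" = Xs_b)
        want <- if (config$train_encoder) "both" else {
          if (contrastive_cfg$mode == "d-only") "none" else "input"
        }
        cl <- contrastive_loss(encoder, projs, x_in, contrastive_cfg,
                               seed = derive_seed(seed_batch, "cl", k, t),
                               grad = want)
        lc_vals[t] <- cl$loss
        if (!is.null(cl$d_input) && contrastive_cfg$mode != "d-only") {
          s_rows <- if (contrastive_cfg$mode == "joint") {
            (length(d_sub) + 1):nrow(x_in)
          } else seq_len(nrow(x_in))
          g_step <- matrix(0, nrow(Xs_all), ncol(Xs_all))
          g_step[bt$s, ] <- cl$d_input[s_rows, , drop = FALSE]
          g_Lc_steps <- g_Lc_steps + g_step
          g_Lc_last <- g_step
        }
        if (config$train_encoder) {
          g <- c(cl$d_enc_params,
                 unlist(cl$d_proj_params[names(projs)], use.names = FALSE))
          st <- adam_step(enc_opt, g, config$pretrain_lr)
          enc_opt <- st$state
          enc_theta <- enc_theta - st$delta
          encoder <- encoder_set_params(encoder, enc_theta[seq_len(n_enc)])
          pos <- n_enc
          for (lv in names(projs)) {
            projs[[lv]] <- projection_set_params(
              projs[[lv]], enc_theta[(pos + 1):(pos + proj_lens[lv])])
            pos <- pos + proj_lens[lv]
          }
        }
        emit("contrast")
      }
      proxy <- proxy_advance(proxy, gm$inner_grads, config$eta_theta)
      emit("theta_update")
    }
    emit("compute_Ld")
    L_c <- if (!use_contrast) 0 else switch(config$contrast_agg,
      mean = mean(lc_vals), last = lc_vals[config$T_steps],
      sum = sum(lc_vals))
    emit("compute_Lcontrast")
    L_tot <- total_loss(L_d, L_c, sch)
    emit("total_loss")
    if (!is.finite(L_tot)) {
      stopf(paste0("divergence at outer iteration %d: L_d=%g, L_contrast=%g,",
                   " lambda_c=%g, lambda_d=%g"),
            k, L_d, L_c, sch$lambda_c, sch$lambda_d)
    }
    g_Lc <- if (!use_contrast || contrastive_cfg$mode == "d-only") {
      0
    } else switch(config$contrast_agg,
                  mean = g_Lc_steps / config$T_steps,
                  last = g_Lc_last %||% 0,
                  sum = g_Lc_steps)
    g_total <- sch$lambda_d * g_Ld + sch$lambda_c * g_Lc
    emit("pixel_grad")
    synthetic <- update_synthetic(synthetic, g_total, clip = config$clip)
    emit("update_S")
    log_df[nrow(log_df) + 1, ] <- list(k, sch$lambda_c, sch$lambda_d,
                                       L_d, L_c, L_tot)
    if (!is.null(log_file)) {
      rec <- jsonlite::toJSON(list(k = k, lambda_c = sch$lambda_c,
                                   lambda_d = sch$lambda_d, L_d = L_d,
                                   L_contrast = L_c, L_total = L_tot,
                                   seed = seed),
                              auto_unbox = TRUE, digits = NA)
      cat(rec, "\n", sep = "", file = log_file, append = TRUE)
    }
  }
  structure(list(synthetic = synthetic, log = log_df, encoder = encoder,
                 projs = projs, config = config,
                 contrastive_cfg = contrastive_cfg, seed = seed),
            class = "cgmdd_run")
}

#' @export
print.cgmdd_run <- function(x, ...) {
  cat(sprintf("cgmdd_run: %d outer iterations, %d synthetic samples (ipc=%d)\n",
              nrow(x$log), n_samples(x$synthetic), x$synthetic$ipc))
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final: L_d=%.4f  L_contrast=%.4f  L_total=%.4f\n",
                last$L_d, last$L_contrast, last$L_total))
  }
  invisible(x)
}
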