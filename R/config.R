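# Experiment configuration: one flat human-editable YAML file with blocks
# mirroring each module's config type. Unknown keys are rejected by name;
# every run writes the fully resolved configuration next to its outputs.

#' Default experiment configuration
#'
#' @return nested list with blocks `data`, `encoder`, `contrastive`,
#'   `distillation`, `schedule`, `evaluation` plus global `seed` and
#'   `format_version`.
#' @export
default_experiment_config <- function() {
  list(
    format_version = 1L,
    seed = 1L,
    data = list(n_per_class = 100L, n_classes = 2L, n_modalities = 2L,
                shape = c(16L, 16L), noise_sd = 0.7, margin = 0.8,
                test_frac = 0.5),
    encoder = list(width = 16L, patch = 4L, n_shared_stages = 2L,
                   n_specific_stages = 1L, pooled_dim = 16L,
                   proj_dim = 16L),
    contrastive = list(temperature = 0.07,
                       level_weights = c(patch = 0.5, pooled = 0.5),
                       use_inter_instance = TRUE, use_intra_spatial = TRUE,
                       n_spatial_patches = 4L,
                       use_augmentation_negatives = FALSE,
                       aug_kind = "noise", aug_noise_sd = 0.25,
                       queue_size = 0L, queue_momentum = 0.5,
                       mode = "joint"),
    distillation = list(ipc = 5L, init_mode = "class_mean", T_steps = 5L,
                        eta_theta = 1e-3, eta_s = 0.01, batch_d = 16L,
                        batch_s = 64L, contrast_batch = 16L,
                        inner_on = "synthetic",
                        class_match = TRUE, pretrain_steps = 200L,
                        pretrain_lr = 5e-3, pretrain_batch = 16L,
                        train_encoder = FALSE),
    schedule = list(K_total = 300L, lambda_c_init = 1.0,
                    lambda_d_init = 0.1, lambda_d_final = 1.0,
                    fixed_lambda = NULL, contrast_agg = "mean",
                    paper_scale = FALSE),
    evaluation = list(arch = "mlp32", epochs = 150L, cr = 0.05,
                      seeds = c(1L, 2L, 3L))
  )
}

# Recursively overlay user values onto defaults, rejecting unknown keys.
merge_config <- function(defaults, user, block = "top level") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stopf("config block '%s' must be a mapping", block)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stopf("unknown config key '%s' in block '%s'", unknown[1], block)
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], key)
    } else {
      val <- user[[key]]
      if (!is.null(defaults[[key]]) && is.numeric(defaults[[key]]) &&
          !is.numeric(val)) {
        stopf("config key '%s' in block '%s' must be numeric", key, block)
      }
      defaults[[key]] <- if (is.list(val)) unlist(val) else val
    }
  }
  defaults
}

#' Load and validate an experiment configuration file
#'
#' YAML file with any subset of the default blocks; missing values take
#' defaults, unknown keys are rejected naming the key and block. Loading a
#' fully resolved config is idempotent.
#'
#' @param path YAML file path, or `NULL`/nonexistent-empty for all defaults.
#' @return resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_experiment_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  cfg <- merge_config(defaults, user)
  # restore named level weights lost by YAML round-trips
  lw <- unlist(cfg$contrastive$level_weights)
  if (is.null(names(lw)) || any(names(lw) == "")) {
    names(lw) <- c("patch", "pooled")[seq_along(lw)]
  }
  cfg$contrastive$level_weights <- lw
  cfg
}

#' Write a resolved configuration beside run outputs
#' @param cfg resolved configuration list.
#' @param dir output directory.
#' @export
write_resolved_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(dir, "config_resolved.yaml"))
  invisible(file.path(dir, "config_resolved.yaml"))
}

#' Short stable hash of a configuration (for output manifests)
#' @param cfg configuration list.
#' @export
config_hash <- function(cfg) {
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, function(v) is.null(v) || (is.list(v) && length(v) == 0),
                   logical(1))]
    lapply(x, drop_nulls)
  }
  s <- jsonlite::toJSON(drop_nulls(cfg), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  sprintf("%08x", h)
}

# Build module config objects from a resolved experiment config.
config_to_contrastive <- function(cfg) {
  cc <- cfg$contrastive
  contrastive_config(temperature = cc$temperature,
                     level_weights = cc$level_weights,
                     use_inter_instance = cc$use_inter_instance,
                     use_intra_spatial = cc$use_intra_spatial,
                     n_spatial_patches = cc$n_spatial_patches,
                     use_augmentation_negatives = cc$use_augmentation_negatives,
                     aug_kind = cc$aug_kind, aug_noise_sd = cc$aug_noise_sd,
                     queue_size = cc$queue_size,
                     queue_momentum = cc$queue_momentum,
                     mode = cc$mode)
}

config_to_trainer <- function(cfg) {
  d <- cfg$distillation; s <- cfg$schedule
  trainer_config(K_total = s$K_total, T_steps = d$T_steps,
                 eta_theta = d$eta_theta, eta_s = d$eta_s,
                 batch_d = d$batch_d, batch_s = d$batch_s,
                 contrast_batch = d$contrast_batch, ipc = d$ipc,
                 init_mode = d$init_mode,
                 lambda_c_init = s$lambda_c_init,
                 lambda_d_init = s$lambda_d_init,
                 lambda_d_final = s$lambda_d_final,
                 fixed_lambda = s$fixed_lambda,
                 contrast_agg = s$contrast_agg, inner_on = d$inner_on,
                 class_match = d$class_match,
                 train_encoder = d$train_encoder,
                 pretrain_steps = d$pretrain_steps,
                 pretrain_lr = d$pretrain_lr,
                 pretrain_batch = d$pretrain_batch,
                 paper_scale = isTRUE(s$paper_scale))
}

config_to_cohort <- function(cfg, seed = cfg$seed) {
  dt <- cfg$data
  generate_cohort(n_per_class = dt$n_per_class, n_classes = dt$n_classes,
                  n_modalities = dt$n_modalities, shape = dt$shape,
                  noise_sd = dt$noise_sd, seed = seed,
                  params = phantom_params(margin = dt$margin))
}
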