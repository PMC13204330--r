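# Synthetic multi-modal cohort generator.
#
# Every sample is built from one latent "anatomy" phantom: a smooth background
# plus a class-conditioned geometric structure (a Gaussian blob whose peak
# intensity and radius depend on the class). Each modality is a distinct
# monotone intensity transform of that same phantom plus i.i.d. Gaussian
# noise, so modalities are spatially registered by construction and features
# at the same spatial index across modalities describe the same structure.

# Per-modality monotone transform presets (gamma/scale/offset) and relative
# noise levels, recycled for arbitrary M. Modality 1 is the identity
# transform; acquisition noise differs across modalities (as across MRI
# sequences), which makes them partially complementary: the cleaner
# modality carries more usable signal, and cross-modal information
# compensation has something to compensate for.
.modality_gamma  <- c(1.0, 1.6, 0.7, 1.3, 0.85, 1.45)
.modality_scale  <- c(1.0, 0.9, 1.1, 0.95, 1.05, 0.9)
.modality_offset <- c(0.0, 0.15, 0.05, 0.2, 0.1, 0.25)
.modality_noise  <- c(1.0, 2.0, 0.75, 1.5, 0.9, 1.75)

#' Default class-structure parameters of the phantom generator
#'
#' The class signal is a Gaussian blob whose peak intensity grows by `margin`
#' per class and whose radius (as a fraction of the smallest spatial extent)
#' grows by `radius_step`. These defaults define the study conditions used
#' throughout the test suite; `margin` was fixed once so that a linear probe
#' on flattened pixels of a default cohort exceeds 0.9 accuracy.
#'
#' @param margin peak-intensity separation between consecutive classes.
#' @param base_intensity blob peak intensity of class 1.
#' @param radius_frac blob radius of class 1, fraction of min spatial extent.
#' @param radius_step per-class radius increment (fraction).
#' @param background_amp amplitude of the smooth nonnegative background.
#' @param background_harmonics number of random cosine harmonics mixed into
#'   the background; more harmonics give each sample a more distinctive
#'   (but still smooth) background.
#' @param center_range range (fractions of each extent) the class blob
#'   center is drawn from.
#' @param radius_jitter log-normal sd of the per-sample radius jitter.
#' @param intensity_jitter log-normal sd of the per-sample blob peak
#'   intensity jitter (within-class variability of the class structure).
#' @param n_distractors number of class-independent nuisance blobs per
#'   phantom. Distractors are part of the shared anatomy (rendered in every
#'   modality, so they carry instance identity across modalities) but their
#'   position, size and intensity are independent of the class, which makes
#'   small training samples easy to mislead.
#' @param distractor_intensity mean of the distractor peak intensity.
#' @param distractor_sd sd of the distractor peak intensity.
#' @param distractor_radius_frac distractor radius fraction.
#' @param diffuse_margin amplitude of the faint class-specific smooth
#'   template added over the whole field. This spreads part of the class
#'   signal across many weak pixels: estimable from a large sample, hard to
#'   separate from noise in a handful of images.
#' @param template_seed seed fixing the per-class templates (shared by all
#'   samples of a class).
#' @return named list of structure parameters.
#' @export
phantom_params <- function(margin = 0.8, base_intensity = 1.0,
                           radius_frac = 0.22, radius_step = 0.06,
                           background_amp = 0.8,
                           background_harmonics = 4,
                           center_range = c(0.25, 0.75),
                           radius_jitter = 0.35,
                           intensity_jitter = 0.25,
                           n_distractors = 5,
                           distractor_intensity = 1.4,
                           distractor_sd = 0.4,
                           distractor_radius_frac = 0.12,
                           diffuse_margin = 0.12,
                           template_seed = 777) {
  stopifnot(margin > 0, base_intensity > 0, radius_frac > 0,
            background_amp >= 0, length(center_range) == 2,
            center_range[1] < center_range[2], radius_jitter >= 0,
            n_distractors >= 0)
  list(margin = margin, base_intensity = base_intensity,
       radius_frac = radius_frac, radius_step = radius_step,
       background_amp = background_amp,
       background_harmonics = as.integer(background_harmonics),
       center_range = center_range,
       radius_jitter = radius_jitter, intensity_jitter = intensity_jitter,
       n_distractors = n_distractors,
       distractor_intensity = distractor_intensity,
       distractor_sd = distractor_sd,
       distractor_radius_frac = distractor_radius_frac,
       diffuse_margin = diffuse_margin,
       template_seed = as.integer(template_seed))
}

#' Generate a latent phantom
#'
#' @param class_id integer class label (1-based).
#' @param shape integer vector of spatial dims (length 2 or 3, each >= 8).
#' @param rng_seed integer seed; output is a deterministic function of
#'   (class_id, shape, rng_seed, params).
#' @param params see [phantom_params()].
#' @return object of class `latent_phantom`: list with `field` (nonnegative
#'   finite array), `class_id`, and `structure_params` (center, radius,
#'   intensity).
#' @export
generate_phantom <- function(class_id, shape, rng_seed,
                             params = phantom_params()) {
  if (!is.numeric(class_id) || length(class_id) != 1 || class_id < 1 ||
      class_id != round(class_id)) {
    stopf("class_id must be a positive integer, got %s", format(class_id))
  }
  if (!length(shape) %in% c(2L, 3L) || any(shape < 8)) {
    stopf("shape must have 2 or 3 dims, each >= 8 (got: %s)",
          paste(shape, collapse = "x"))
  }
  shape <- as.integer(shape)
  nd <- length(shape)

  # Smooth nonnegative background, independent of class.
  bg <- with_seed(derive_seed(rng_seed, "bg"), {
    coords <- lapply(shape, function(n) seq(0, 1, length.out = n))
    f <- array(0, dim = shape)
    for (h in seq_len(params$background_harmonics %||% 2)) {
      phase <- stats::runif(nd, 0, 2 * pi)
      freq <- sample(1:3, nd, replace = TRUE)
      wave <- Reduce(`+`, lapply(seq_len(nd), function(a) {
        slice_dim(cos(2 * pi * freq[a] * coords[[a]] + phase[a]), a, shape)
      }))
      f <- f + wave / (1 + h)
    }
    params$background_amp * (f - min(f)) / max(f - min(f) + 1e-12)
  })

  # Class-conditioned blob: intensity and radius shift by class; center is
  # drawn from a shared distribution (within-class variability).
  blob <- with_seed(derive_seed(rng_seed, "blob", class_id), {
    center <- vapply(shape, function(n) {
      stats::runif(1, params$center_range[1] * n, params$center_range[2] * n)
    }, numeric(1))
    radius <- (params$radius_frac + (class_id - 1) * params$radius_step) *
      min(shape) * exp(stats::rnorm(1, 0, params$radius_jitter))
    intensity <- (params$base_intensity + (class_id - 1) * params$margin) *
      exp(stats::rnorm(1, 0, params$intensity_jitter %||% 0))
    d2 <- Reduce(`+`, lapply(seq_len(nd), function(a) {
      slice_dim((seq_len(shape[a]) - center[a])^2, a, shape)
    }))
    list(field = intensity * exp(-d2 / (2 * radius^2)),
         center = center, radius = radius, intensity = intensity)
  })

  # class-independent nuisance blobs, part of the shared anatomy
  distract <- with_seed(derive_seed(rng_seed, "distract"), {
    f <- array(0, dim = shape)
    for (j in seq_len(params$n_distractors)) {
      # peripheral placement: rejection-sample until outside the central
      # region reserved for the class structure
      repeat {
        ctr <- vapply(shape, function(n) stats::runif(1, 0.05 * n, 0.95 * n),
                      numeric(1))
        if (any(ctr < 0.3 * shape | ctr > 0.7 * shape)) break
      }
      rad <- params$distractor_radius_frac * min(shape) *
        exp(stats::rnorm(1, 0, 0.2))
      amp <- max(0, stats::rnorm(1, params$distractor_intensity,
                                 params$distractor_sd))
      d2 <- Reduce(`+`, lapply(seq_len(nd), function(a) {
        slice_dim((seq_len(shape[a]) - ctr[a])^2, a, shape)
      }))
      f <- f + amp * exp(-d2 / (2 * rad^2))
    }
    f
  })

  # faint class-specific smooth template, identical for all samples of a
  # class (diffuse part of the class signal)
  tpl <- if (params$diffuse_margin > 0) {
    with_seed(derive_seed(params$template_seed, "template", class_id), {
      f <- array(0, dim = shape)
      for (h in 1:3) {
        phase <- stats::runif(nd, 0, 2 * pi)
        freq <- sample(1:4, nd, replace = TRUE)
        coords <- lapply(shape, function(n) seq(0, 1, length.out = n))
        wave <- Reduce(`*`, lapply(seq_len(nd), function(a) {
          slice_dim(cos(2 * pi * freq[a] * coords[[a]] + phase[a]), a, shape)
        }))
        f <- f + wave
      }
      f <- params$diffuse_margin * f / stats::sd(f)
      f - min(f) # keep the total field nonnegative for the gamma transforms
    })
  } else 0

  structure(list(field = bg + blob$field + distract + tpl,
                 class_id = as.integer(class_id),
                 structure_params = list(center = blob$center,
                                         radius = blob$radius,
                                         intensity = blob$intensity)),
            class = "latent_phantom")
}

# Broadcast a 1-d profile along axis `a` of an array of dims `shape`.
slice_dim <- function(v, a, shape) {
  perm <- seq_along(shape)
  perm[c(1, a)] <- perm[c(a, 1)]
  aperm(array(v, dim = shape[perm]), perm)
}

#' Render one modality from a phantom
#'
#' Applies a modality-specific strictly monotone intensity transform
#' (`scale * field^gamma + offset`, modality 1 being the identity) and adds
#' i.i.d. Gaussian noise.
#'
#' @param phantom a `latent_phantom`.
#' @param modality_index 1-based modality index.
#' @param noise_sd nonnegative Gaussian noise standard deviation.
#' @param rng_seed integer seed for the noise draw.
#' @return numeric array with the phantom's spatial shape.
#' @export
render_modality <- function(phantom, modality_index, noise_sd, rng_seed) {
  stopifnot(inherits(phantom, "latent_phantom"))
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stopf("noise_sd must be nonnegative, got %s", format(noise_sd))
  }
  if (modality_index < 1 || modality_index != round(modality_index)) {
    stopf("modality_index must be a positive integer")
  }
  i <- ((modality_index - 1) %% length(.modality_gamma)) + 1
  out <- .modality_scale[i] * phantom$field^.modality_gamma[i] +
    .modality_offset[i]
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(rng_seed, "noise", modality_index), {
      array(stats::rnorm(length(out), 0, noise_sd), dim = dim(phantom$field))
    })
    out <- out + noise
  }
  out
}

#' Generate a registered multi-modal labeled cohort
#'
#' All modalities of a sample are rendered from the same phantom, so they are
#' spatially registered by construction. Classes are exactly balanced.
#'
#' @param n_per_class samples per class.
#' @param n_classes number of classes (>= 1).
#' @param n_modalities number of modalities M (>= 2).
#' @param shape spatial dims (length 2 or 3).
#' @param noise_sd base additive Gaussian noise sd; each modality applies
#'   its preset relative noise factor (modality 1 the cleanest by default),
#'   overridable via `modality_noise_scale`.
#' @param modality_noise_scale optional numeric vector of per-modality
#'   noise factors (recycled preset when `NULL`).
#' @param seed master seed; the cohort is a deterministic function of all
#'   arguments.
#' @param params phantom structure parameters, see [phantom_params()].
#' @param modality_names optional character vector of length `n_modalities`.
#' @return object of class `mm_cohort` with fields `pixels` (array
#'   `n_samples x M x shape`), `labels` (integer in 1..n_classes),
#'   `n_classes`, `modality_names`, `shape`, `seed`.
#' @export
generate_cohort <- function(n_per_class = 100, n_classes = 2,
                            n_modalities = 3, shape = c(16, 16),
                            noise_sd = 0.7, seed = 1,
                            params = phantom_params(),
                            modality_names = NULL,
                            modality_noise_scale = NULL) {
  if (is.null(modality_noise_scale)) {
    modality_noise_scale <- .modality_noise[
      ((seq_len(n_modalities) - 1) %% length(.modality_noise)) + 1]
  }
  stopifnot(length(modality_noise_scale) == n_modalities)
  stopifnot(n_per_class >= 1, n_classes >= 1, n_modalities >= 2)
  n <- n_per_class * n_classes
  if (is.null(modality_names)) modality_names <- paste0("m", seq_len(n_modalities))
  stopifnot(length(modality_names) == n_modalities)
  pixels <- array(0, dim = c(n, n_modalities, shape))
  labels <- integer(n)
  idx <- 0L
  flat <- prod(shape)
  for (c_id in seq_len(n_classes)) {
    for (r in seq_len(n_per_class)) {
      idx <- idx + 1L
      s_seed <- derive_seed(seed, "sample", c_id, r)
      ph <- generate_phantom(c_id, shape, s_seed, params)
      for (m in seq_len(n_modalities)) {
        arr <- render_modality(ph, m, noise_sd * modality_noise_scale[m],
                               derive_seed(s_seed, "mod", m))
        pixels[idx + n * (m - 1) + n * n_modalities * (seq_len(flat) - 1)] <-
          as.numeric(arr)
      }
      labels[idx] <- c_id
    }
  }
  structure(list(pixels = pixels, labels = labels,
                 n_classes = as.integer(n_classes),
                 modality_names = modality_names,
                 shape = as.integer(shape), seed = as.integer(seed),
                 noise_sd = noise_sd),
            class = "mm_cohort")
}

#' @export
print.mm_cohort <- function(x, ...) {
  cat(sprintf("mm_cohort: %d samples, %d classes, %d modalities (%s), shape %s\n",
              n_samples(x), x$n_classes, n_modalities(x),
              paste(x$modality_names, collapse = ", "),
              paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Number of samples in a cohort or synthetic dataset
#' @param x an `mm_cohort` or `mm_synthetic`.
#' @export
n_samples <- function(x) dim(x$pixels)[1]

#' Number of modalities
#' @param x an `mm_cohort` or `mm_synthetic`.
#' @export
n_modalities <- function(x) dim(x$pixels)[2]

#' Extract one multi-modal sample as a list of modality arrays
#' @param x an `mm_cohort` or `mm_synthetic`.
#' @param i sample index.
#' @export
get_sample <- function(x, i) {
  m <- n_modalities(x)
  sh <- x$shape
  mods <- lapply(seq_len(m), function(j) {
    array(extract_sample_modality(x$pixels, i, j), dim = sh)
  })
  names(mods) <- x$modality_names
  list(modalities = mods, modality_names = x$modality_names,
       label = x$labels[i])
}

# Fast slice pixels[i, j, ...] regardless of spatial rank. Array layout puts
# element (i, j, s) at linear index i + n*(j-1) + n*m*(s-1).
extract_sample_modality <- function(pixels, i, j) {
  d <- dim(pixels)
  n <- d[1]; m <- d[2]; p <- prod(d[-(1:2)])
  pixels[i + n * (j - 1) + n * m * (seq_len(p) - 1)]
}

# Flatten cohort pixels to a (n_samples x M*prod(shape)) matrix, modality-major
# blocks: columns 1..P are modality 1, etc.
flatten_pixels <- function(pixels) {
  d <- dim(pixels)
  n <- d[1]; m <- d[2]; p <- prod(d[-(1:2)])
  out <- matrix(0, n, m * p)
  pm <- matrix(pixels, nrow = n) # columns vary modality fastest then spatial
  # array layout: index = i + n*(j-1) + n*m*(spatial-1) -> column of pm is
  # (j, spatial) with j fastest. Reorder to modality-major blocks.
  for (j in seq_len(m)) {
    out[, ((j - 1) * p + 1):(j * p)] <- pm[, j + m * (seq_len(p) - 1)]
  }
  out
}

# Inverse of flatten_pixels.
unflatten_pixels <- function(mat, m, shape) {
  n <- nrow(mat); p <- prod(shape)
  pm <- matrix(0, n, m * p)
  for (j in seq_len(m)) {
    pm[, j + m * (seq_len(p) - 1)] <- mat[, ((j - 1) * p + 1):(j * p)]
  }
  array(pm, dim = c(n, m, shape))
}

#' Write a cohort to disk
#'
#' Directory container: a JSON manifest (labels, modality names, shapes,
#' dtype, seed, format version) plus one flat little-endian float64 array file
#' per sample/modality; with `format = "nifti"` the arrays are written as
#' NIfTI volumes instead (requires the RNifti package).
#'
#' @param cohort an `mm_cohort`.
#' @param path output directory (created if missing).
#' @param format `"dir"` (flat binary arrays) or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("dir", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "mm_cohort"))
  dir.create(file.path(path, "samples"), recursive = TRUE, showWarnings = FALSE)
  n <- n_samples(cohort); m <- n_modalities(cohort)
  ext <- if (format == "nifti") ".nii.gz" else ".bin"
  if (format == "nifti" && !requireNamespace("RNifti", quietly = TRUE)) {
    stopf("NIfTI export requires the RNifti package")
  }
  files <- matrix("", n, m)
  flat <- flatten_pixels(cohort$pixels)
  p <- prod(cohort$shape)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      rel <- file.path("samples", sprintf("s%05d_m%d%s", i, j, ext))
      files[i, j] <- rel
      arr <- array(flat[i, ((j - 1) * p + 1):(j * p)], dim = cohort$shape)
      if (format == "nifti") {
        RNifti::writeNifti(RNifti::asNifti(arr), file.path(path, rel))
      } else {
        con <- file(file.path(path, rel), "wb")
        writeBin(as.numeric(arr), con, size = 8, endian = "little")
        close(con)
      }
    }
  }
  manifest <- list(format_version = 1L, container = format,
                   n_samples = n, n_classes = cohort$n_classes,
                   n_modalities = m, shape = cohort$shape,
                   modality_names = cohort$modality_names,
                   labels = cohort$labels, dtype = "float64",
                   seed = cohort$seed, noise_sd = cohort$noise_sd,
                   files = as.vector(t(files)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param path cohort directory.
#' @return an `mm_cohort`.
#' @export
read_cohort <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest.json under %s", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (field in c("labels", "shape", "n_classes", "modality_names", "files",
                  "n_modalities", "n_samples")) {
    if (is.null(mf[[field]])) stopf("manifest missing field '%s'", field)
  }
  n <- mf$n_samples; m <- mf$n_modalities; shape <- as.integer(mf$shape)
  p <- prod(shape)
  flat <- matrix(0, n, m * p)
  files <- matrix(mf$files, n, m, byrow = TRUE)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      f <- file.path(path, files[i, j])
      arr <- if (grepl("\\.nii(\\.gz)?$", f)) {
        if (!requireNamespace("RNifti", quietly = TRUE)) {
          stopf("reading NIfTI cohorts requires the RNifti package")
        }
        as.numeric(RNifti::readNifti(f))
      } else {
        con <- file(f, "rb")
        on.exit(close(con), add = TRUE)
        v <- readBin(con, "double", n = p, size = 8, endian = "little")
        close(con); on.exit()
        v
      }
      flat[i, ((j - 1) * p + 1):(j * p)] <- arr
    }
  }
  structure(list(pixels = unflatten_pixels(flat, m, shape),
                 labels = as.integer(mf$labels),
                 n_classes = as.integer(mf$n_classes),
                 modality_names = mf$modality_names,
                 shape = shape, seed = as.integer(mf$seed %||% NA),
                 noise_sd = mf$noise_sd %||% NA_real_),
            class = "mm_cohort")
}

#' Subset a cohort by sample indices
#' @param cohort an `mm_cohort`.
#' @param idx integer sample indices.
#' @export
subset_cohort <- function(cohort, idx) {
  flat <- flatten_pixels(cohort$pixels)[idx, , drop = FALSE]
  out <- cohort
  out$pixels <- unflatten_pixels(flat, n_modalities(cohort), cohort$shape)
  out$labels <- cohort$labels[idx]
  out
}

#' Per-modality intensity-normalization statistics of a cohort
#'
#' Global per-modality mean and standard deviation, the normalization
#' constants that accompany a dataset through preprocessing (and ship with a
#' distilled dataset derived from it).
#'
#' @param cohort an `mm_cohort`.
#' @return list(center, scale), one value per modality.
#' @export
cohort_stats <- function(cohort) {
  flat <- flatten_pixels(cohort$pixels)
  P <- prod(cohort$shape)
  M <- n_modalities(cohort)
  ctr <- vapply(seq_len(M), function(m) {
    mean(flat[, ((m - 1) * P + 1):(m * P)])
  }, numeric(1))
  scl <- vapply(seq_len(M), function(m) {
    stats::sd(flat[, ((m - 1) * P + 1):(m * P)])
  }, numeric(1))
  list(center = ctr, scale = pmax(scl, 1e-12))
}

#' Standardize a cohort's intensities per modality
#'
#' Z-scores every modality with the supplied statistics (by default the
#' cohort's own, see [cohort_stats()]). Distillation operates on
#' intensity-normalized inputs; held-out data must be standardized with the
#' training cohort's constants.
#'
#' @param cohort an `mm_cohort`.
#' @param stats list(center, scale) from [cohort_stats()].
#' @export
standardize_cohort <- function(cohort, stats = cohort_stats(cohort)) {
  flat <- flatten_pixels(cohort$pixels)
  P <- prod(cohort$shape)
  for (m in seq_len(n_modalities(cohort))) {
    cols <- ((m - 1) * P + 1):(m * P)
    flat[, cols] <- (flat[, cols] - stats$center[m]) / stats$scale[m]
  }
  cohort$pixels <- unflatten_pixels(flat, n_modalities(cohort), cohort$shape)
  cohort$standardized <- TRUE
  cohort
}

#' Stratified train/test split of a cohort
#' @param cohort an `mm_cohort`.
#' @param test_frac fraction held out per class.
#' @param seed split seed.
#' @return list(train, test) of `mm_cohort`s with disjoint samples.
#' @export
split_cohort <- function(cohort, test_frac = 0.5, seed = 1) {
  test_idx <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(seq_len(cohort$n_classes), function(c_id) {
      ids <- which(cohort$labels == c_id)
      sample(ids, max(1, round(test_frac * length(ids))))
    }))
  })
  test_idx <- sort(test_idx)
  list(train = subset_cohort(cohort, setdiff(seq_len(n_samples(cohort)), test_idx)),
       test = subset_cohort(cohort, test_idx))
}
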