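# Independent oracles and shared fixtures for the test suite.

# Explicit-softmax InfoNCE (no log-sum-exp trick): brute-force reference.
brute_infonce <- function(anchor, positive, negatives, tau) {
  sims <- c(cosine_similarity(anchor, positive))
  if (length(negatives) > 0 && nrow(rbind(negatives)) > 0) {
    negatives <- rbind(negatives)
    for (r in seq_len(nrow(negatives))) {
      sims <- c(sims, cosine_similarity(anchor, negatives[r, ]))
    }
  }
  e <- exp(sims / tau)
  -log(e[1] / sum(e))
}

# Brute-force multi-level contrastive loss: enumerate candidate sets and
# average explicit-softmax pair losses per level, then weight.
brute_hc2l <- function(enc, projs, x, config, seed) {
  feats <- encode(enc, x)
  sets <- build_candidate_sets(feats, config, seed = seed)
  tabs <- cgmdd:::level_tables(feats, config, seed)
  E <- list()
  for (lev in names(tabs)) E[[lev]] <- project(projs[[lev]], tabs[[lev]]$raw)
  per_level <- sapply(names(tabs), function(lev) {
    ls <- Filter(function(s) s$level == lev, sets)
    mean(vapply(ls, function(s) {
      brute_infonce(E[[lev]][s$anchor, ], E[[lev]][s$positive, ],
                    E[[lev]][s$negatives, , drop = FALSE],
                    config$temperature)
    }, numeric(1)))
  })
  sum(config$level_weights[names(tabs)] * per_level)
}

# Confusion-matrix-based accuracy / macro-F1 reference.
oracle_metrics <- function(truth, pred, n_classes) {
  cm <- matrix(0, n_classes, n_classes)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1
  acc <- sum(diag(cm)) / sum(cm)
  f1 <- numeric(n_classes)
  for (k in seq_len(n_classes)) {
    prec_den <- sum(cm[, k]); rec_den <- sum(cm[k, ])
    if (prec_den == 0 && rec_den == 0) { f1[k] <- 0; next }
    prec <- if (prec_den == 0) 0 else cm[k, k] / prec_den
    rec <- if (rec_den == 0) 0 else cm[k, k] / rec_den
    f1[k] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  list(accuracy = acc, macro_f1 = mean(f1))
}

# Small standardized cohort for fast tests.
make_std_cohort <- function(n_per_class = 20, n_classes = 2, n_modalities = 2,
                            shape = c(16, 16), seed = 1, ...) {
  standardize_cohort(generate_cohort(n_per_class, n_classes, n_modalities,
                                     shape, seed = seed, ...))
}

# Standardized train/test pair at the toy study scale (built once per run).
toy_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(n_per_class = 200, n_classes = 2,
                            n_modalities = 2, seed = 1)
      sp <- split_cohort(co, 0.5, seed = 1)
      st <- cohort_stats(sp$train)
      cache <<- list(train = standardize_cohort(sp$train, st),
                     test = standardize_cohort(sp$test, st))
    }
    cache
  }
})

running_mean <- function(x, w = 20) {
  s <- stats::filter(x, rep(1 / w, w), sides = 1)
  as.numeric(s[!is.na(s)])
}

tiny_encoder_setup <- function(M = 2, shape = c(8, 8), width = 6,
                               proj_dim = 5, seed = 2) {
  cfg <- encoder_config(n_modalities = M, spatial_shape = shape, patch = 4,
                        width = width, pooled_dim = width)
  enc <- build_encoder(cfg, seed = seed)
  projs <- list(pooled = build_projection(width, 2 * width, proj_dim,
                                          seed = seed + 1),
                patch = build_projection(width, 2 * width, proj_dim,
                                         seed = seed + 2))
  list(enc = enc, projs = projs)
}
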