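# Cross-modal contrastive machinery: similarity, InfoNCE, candidate
# construction, brute-force equivalence, queue, and the learning signal.

test_that("cosine similarity satisfies its identities", {
  u <- c(0.3, -1.2, 2)
  expect_equal(cosine_similarity(u, u), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(u, -u), -1)
  expect_equal(cosine_similarity(2 * u, 5 * u), 1) # scale invariance
})

test_that("InfoNCE pair loss matches closed forms", {
  # all candidate similarities equal -> uniform softmax -> log N
  v <- c(1, 0, 0)
  negs <- rbind(v, v, v)
  expect_equal(infonce_pair_loss(v, v, negs, tau = 0.5), log(4))
  # sims {pos: +1, neg: -1}, tau = 1 -> log(1 + e^-2)
  expect_equal(infonce_pair_loss(c(1, 0), c(1, 0), rbind(c(-1, 0)), 1),
               log(1 + exp(-2)))
  # temperature sharpening drives a separated pair's loss toward zero
  l_sharp <- infonce_pair_loss(c(1, 0), c(1, 0), rbind(c(-1, 0)), 0.05)
  expect_lt(l_sharp, 1e-10)
  expect_error(infonce_pair_loss(v, v, negs, tau = 0), "tau")
})

test_that("candidate sets enumerate positives and negatives correctly", {
  setup <- tiny_encoder_setup()
  x <- matrix(rnorm(2 * 2 * 64), 2, 128)
  feats <- encode(setup$enc, x)
  cfg <- contrastive_config(level_weights = c(pooled = 1),
                            use_intra_spatial = FALSE)
  sets <- build_candidate_sets(feats, cfg, seed = 1)
  # B=2, M=2 -> 4 anchors; each has 1 positive and the other sample's two
  # modalities as negatives, N = 3
  expect_length(sets, 4)
  for (s in sets) {
    expect_equal(s$n, 3L)
    expect_length(s$negatives, 2)
    expect_false(s$positive %in% s$negatives)
    expect_false(s$anchor %in% s$negatives)
  }
  # strict mode errors when every negative source is disabled
  cfg_none <- contrastive_config(use_inter_instance = FALSE,
                                 use_intra_spatial = FALSE)
  expect_error(build_candidate_sets(feats, cfg_none, 1), "negative source")
  # patch-location subsampling is seed-deterministic
  cfg_p <- contrastive_config(n_spatial_patches = 2)
  s1 <- build_candidate_sets(feats, cfg_p, seed = 3)
  s2 <- build_candidate_sets(feats, cfg_p, seed = 3)
  expect_identical(s1, s2)
})

test_that("vectorized loss equals brute-force enumeration to 1e-6", {
  for (M in 2:3) {
    setup <- tiny_encoder_setup(M = M)
    for (B in c(2, 4)) {
      x <- matrix(rnorm(B * M * 64), B, M * 64)
      for (cfg in list(contrastive_config(n_spatial_patches = 2),
                       contrastive_config(level_weights = c(pooled = 1)),
                       contrastive_config(use_intra_spatial = FALSE,
                                          n_spatial_patches = 2))) {
        fast <- contrastive_loss(setup$enc, setup$projs, x, cfg,
                                 seed = 11)$loss
        slow <- brute_hc2l(setup$enc, setup$projs, x, cfg, seed = 11)
        expect_equal(fast, slow, tolerance = 1e-6)
        expect_gte(fast, 0)
      }
    }
  }
})

test_that("uniform-similarity point gives log N and alignment is monotone", {
  # identical embeddings: every pair loss is log(1 + #negatives)
  E <- matrix(rep(c(1, 0, 0), 4), 4, 3, byrow = TRUE)
  res <- cgmdd:::level_infonce(E, sample = c(1, 2, 1, 2),
                               modality = c(1, 1, 2, 2), loc = rep(1, 4),
                               contrastive_config(), want_grad = FALSE)
  expect_equal(res$loss_sum / res$n_anchors, log(3))

  # increasing anchor-positive similarity strictly decreases the pair loss
  negs <- rbind(c(0, 1), c(-1, 0))
  sims <- seq(-0.9, 0.9, by = 0.3)
  losses <- vapply(sims, function(s) {
    pos <- c(s, sqrt(1 - s^2))
    infonce_pair_loss(c(1, 0), pos, negs, tau = 0.2)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("batch-size normalization keeps the loss on one scale", {
  set.seed(42)
  # gentle temperature so similarity noise does not dominate the comparison
  cfg_t <- contrastive_config(temperature = 0.5)
  mk <- function(B) {
    E <- matrix(rnorm(B * 2 * 64), B * 2, 64)
    E <- E / sqrt(rowSums(E^2))
    cgmdd:::level_infonce(E, sample = rep(seq_len(B), 2),
                          modality = rep(1:2, each = B), loc = rep(1, 2 * B),
                          cfg_t, want_grad = FALSE)
  }
  r8 <- mk(8); r16 <- mk(16)
  l8 <- r8$loss_sum / r8$n_anchors
  l16 <- r16$loss_sum / r16$n_anchors
  # per-anchor averaging: doubling B changes the loss only through the
  # log-growth of the candidate set, not linearly
  expect_lt(abs(l16 - l8), 1)
})

test_that("momentum queue caps its size and contributes negatives", {
  q <- new_queue(5, 3)
  E <- l2_normalize_rows(matrix(rnorm(12), 4, 3))
  q <- queue_push(q, E, momentum = 0.5)
  expect_equal(nrow(queue_entries(q)), 4)
  q <- queue_push(q, E, momentum = 0.5)
  expect_equal(nrow(queue_entries(q)), 5) # FIFO cap
  expect_equal(unname(sqrt(rowSums(queue_entries(q)^2))), rep(1, 5),
               tolerance = 1e-8)

  setup <- tiny_encoder_setup(proj_dim = 3)
  x <- matrix(rnorm(3 * 128), 3, 128)
  cfg <- contrastive_config(level_weights = c(pooled = 1), queue_size = 5)
  l0 <- contrastive_loss(setup$enc, setup$projs, x, cfg, seed = 1)$loss
  lq <- contrastive_loss(setup$enc, setup$projs, x, cfg, seed = 1,
                         queue = q)$loss
  expect_gt(lq, l0) # extra negatives increase the denominator
})

test_that("augmentation negatives are applied as written when enabled", {
  setup <- tiny_encoder_setup()
  x <- matrix(rnorm(3 * 128), 3, 128)
  base <- contrastive_loss(setup$enc, setup$projs, x,
                           contrastive_config(), seed = 2)$loss
  aug <- contrastive_loss(setup$enc, setup$projs, x,
                          contrastive_config(use_augmentation_negatives = TRUE),
                          seed = 2)$loss
  expect_true(is.finite(aug))
  expect_gt(aug, base)
  rot <- contrastive_loss(setup$enc, setup$projs, x,
                          contrastive_config(use_augmentation_negatives = TRUE,
                                             aug_kind = "rotation"),
                          seed = 2)$loss
  expect_true(is.finite(rot))
})

test_that("fewer than two modalities is rejected with a clear message", {
  setup <- tiny_encoder_setup()
  feats <- encode(setup$enc, matrix(rnorm(2 * 128), 2, 128))
  feats$pooled <- feats$pooled[1]
  expect_error(build_candidate_sets(feats, contrastive_config(), 1),
               "2 modalities")
})

test_that("contrastive pretraining aligns modalities for retrieval", {
  # 200 optimization steps on a default cohort raise cross-modal top-1
  # retrieval well above chance (median over 3 seeds)
  co <- standardize_cohort(generate_cohort(seed = 1))
  X <- cgmdd:::flatten_pixels(co$pixels)
  idx <- with(list(), { set.seed(1); sample(n_samples(co), 16) })
  acc <- vapply(1:3, function(s) {
    setup <- cgmdd:::default_encoder_setup(co, contrastive_config(), s)
    pt <- pretrain_encoder(co, setup$encoder, setup$projs,
                           contrastive_config(), steps = 200,
                           batch_size = 16, seed = s)
    retrieval_top1(encode(pt$encoder, X[idx, , drop = FALSE]))
  }, numeric(1))
  expect_gt(median(acc), 0.8)
})

test_that("retrieval ties break to the lowest index", {
  pooled <- list(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE),
                 matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))
  # identical embeddings: every anchor retrieves sample 1
  expect_equal(retrieval_top1(pooled), 0.5)
})
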