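# Partially-shared encoder: parameter partition, forward contracts, exact
# hand-written gradients, checkpointing.

test_that("parameter counts are analytic and per-modality parts scale with M", {
  cfg2 <- encoder_config(n_modalities = 2, spatial_shape = c(16, 16))
  cfg3 <- encoder_config(n_modalities = 3, spatial_shape = c(16, 16))
  pc2 <- encoder_param_count(cfg2)
  pc3 <- encoder_param_count(cfg3)
  enc2 <- build_encoder(cfg2, seed = 1)
  expect_equal(length(cgmdd:::encoder_params(enc2)), unname(pc2["total"]))
  # adding one modality adds exactly one stem + one specific head + one
  # pooling projection; shared trunk and positional embedding are unchanged
  per_mod <- (pc2[c("stems", "heads", "pool")] / 2)
  expect_equal(unname(pc3["total"] - pc2["total"]), sum(per_mod))
  expect_equal(pc3[["trunk"]], pc2[["trunk"]])
  expect_equal(pc3[["pos"]], pc2[["pos"]])
})

test_that("trunk parameters are shared across modalities, heads are not", {
  cfg <- encoder_config(n_modalities = 2, spatial_shape = c(16, 16), width = 8)
  enc <- build_encoder(cfg, seed = 3)
  x <- matrix(rnorm(4 * 512), 4, 512)
  base <- encode(enc, x)

  enc_t <- enc
  enc_t$trunk[[1]]$W <- enc_t$trunk[[1]]$W + 0.5
  out_t <- encode(enc_t, x)
  expect_false(isTRUE(all.equal(base$pooled[[1]], out_t$pooled[[1]])))
  expect_false(isTRUE(all.equal(base$pooled[[2]], out_t$pooled[[2]])))

  enc_h <- enc
  enc_h$heads[[1]][[1]]$W <- enc_h$heads[[1]][[1]]$W + 0.5
  out_h <- encode(enc_h, x)
  expect_false(isTRUE(all.equal(base$pooled[[1]], out_h$pooled[[1]])))
  expect_equal(base$pooled[[2]], out_h$pooled[[2]])
})

test_that("encode obeys the shape contract and determinism", {
  cfg <- encoder_config(n_modalities = 3, spatial_shape = c(16, 16), width = 8)
  enc <- build_encoder(cfg, seed = 1)
  enc_b <- build_encoder(cfg, seed = 1)
  expect_identical(cgmdd:::encoder_params(enc), cgmdd:::encoder_params(enc_b))

  x <- matrix(rnorm(5 * 3 * 256), 5, 3 * 256)
  f <- encode(enc, x)
  expect_length(f$pooled, 3)
  expect_equal(dim(f$pooled[[1]]), c(5, 8))
  # identical samples give identical pooled vectors
  x2 <- rbind(x[1, ], x[1, ])
  f2 <- encode(enc, x2)
  expect_equal(f2$pooled[[2]][1, ], f2$pooled[[2]][2, ])

  expect_error(encode(enc, matrix(0, 2, 2 * 256)), "3 modalities")
})

test_that("modality permutation equivariance holds", {
  cfg <- encoder_config(n_modalities = 2, spatial_shape = c(16, 16), width = 8)
  enc <- build_encoder(cfg, seed = 5)
  enc_sw <- enc
  enc_sw$stems <- enc$stems[c(2, 1)]
  enc_sw$heads <- enc$heads[c(2, 1)]
  enc_sw$pool_proj <- enc$pool_proj[c(2, 1)]
  x <- matrix(rnorm(3 * 512), 3, 512)
  x_sw <- cbind(x[, 257:512], x[, 1:256])
  f <- encode(enc, x)
  f_sw <- encode(enc_sw, x_sw)
  expect_equal(f$pooled[[1]], f_sw$pooled[[2]])
  expect_equal(f$pooled[[2]], f_sw$pooled[[1]])
})

test_that("encoder and projection gradients match finite differences", {
  setup <- tiny_encoder_setup()
  enc <- setup$enc; projs <- setup$projs
  ccfg <- contrastive_config(n_spatial_patches = 0)
  set.seed(1)
  X <- matrix(rnorm(4 * 2 * 64), 4, 128)
  cl <- contrastive_loss(enc, projs, X, ccfg, seed = 5, grad = "both")
  h <- 1e-5
  # input pixels
  for (idx in c(1, 37, 100)) {
    Xp <- X; Xp[idx] <- Xp[idx] + h
    Xm <- X; Xm[idx] <- Xm[idx] - h
    fd <- (contrastive_loss(enc, projs, Xp, ccfg, seed = 5)$loss -
             contrastive_loss(enc, projs, Xm, ccfg, seed = 5)$loss) / (2 * h)
    expect_equal(cl$d_input[idx], fd, tolerance = 1e-4)
  }
  # encoder parameters, including the positional embedding at the tail
  th <- cgmdd:::encoder_params(enc)
  for (idx in c(2, 151, length(th))) {
    tp <- th; tp[idx] <- tp[idx] + h
    tm <- th; tm[idx] <- tm[idx] - h
    fd <- (contrastive_loss(cgmdd:::encoder_set_params(enc, tp), projs, X,
                            ccfg, seed = 5)$loss -
             contrastive_loss(cgmdd:::encoder_set_params(enc, tm), projs, X,
                              ccfg, seed = 5)$loss) / (2 * h)
    expect_equal(cl$d_enc_params[idx], fd, tolerance = 1e-4)
  }
  # projection head parameters
  pp <- cgmdd:::projection_params(projs$pooled)
  for (idx in c(1, length(pp))) {
    pr <- projs
    v <- pp; v[idx] <- v[idx] + h
    pr$pooled <- cgmdd:::projection_set_params(projs$pooled, v)
    fp <- contrastive_loss(enc, pr, X, ccfg, seed = 5)$loss
    v[idx] <- pp[idx] - h
    pr$pooled <- cgmdd:::projection_set_params(projs$pooled, v)
    fm <- contrastive_loss(enc, pr, X, ccfg, seed = 5)$loss
    expect_equal(cl$d_proj_params$pooled[idx], (fp - fm) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("projection outputs are unit-norm with a degenerate-input guard", {
  proj <- build_projection(8, 16, 6, seed = 1)
  z <- matrix(rnorm(10 * 8), 10, 8)
  e <- project(proj, z)
  expect_equal(sqrt(rowSums(e^2)), rep(1, 10), tolerance = 1e-6)
  e0 <- project(proj, matrix(0, 2, 8))
  expect_true(all(is.finite(e0)))
  expect_error(project(proj, matrix(0, 2, 5)), "8-dim")
})

test_that("desk-scale forward pass is fast on a 64-sample batch", {
  cfg <- encoder_config(n_modalities = 2, spatial_shape = c(16, 16),
                        width = 16)
  enc <- build_encoder(cfg, seed = 1)
  x <- matrix(rnorm(64 * 512), 64, 512)
  elapsed <- system.time(encode(enc, x))["elapsed"]
  expect_lt(elapsed, 1)
})

test_that("encoder checkpoints round-trip through the binary container", {
  cfg <- encoder_config(n_modalities = 2, spatial_shape = c(16, 16), width = 8)
  enc <- build_encoder(cfg, seed = 2)
  proj <- build_projection(8, 16, 8, seed = 3)
  d <- withr::local_tempdir()
  save_encoder(enc, d, proj = proj)
  lt <- load_encoder(d)
  expect_identical(cgmdd:::encoder_params(enc),
                   cgmdd:::encoder_params(lt$encoder))
  expect_identical(cgmdd:::projection_params(proj),
                   cgmdd:::projection_params(lt$projection))
  header <- jsonlite::read_json(file.path(d, "header.json"))
  expect_equal(header$format_version, 1)
})
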