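# Downstream training, metrics, baselines, sweeps, robustness,
# cross-architecture generalization.

test_that("architecture presets have strictly increasing analytic counts", {
  d_in <- 512; K <- 2
  counts <- vapply(c("linear", "mlp16", "mlp32", "mlp64_32"), function(a) {
    arch_param_count(downstream_arch(a), d_in, K)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
  # analytic count equals the actual parameter vector length
  co <- make_std_cohort(n_per_class = 4, seed = 1)
  mod <- train_downstream(co, "mlp16", epochs = 0, seed = 1)
  expect_equal(length(cgmdd:::mlp_params(mod$layers)),
               unname(counts["mlp16"]))
  expect_error(downstream_arch("resnet"), "unknown architecture")
})

test_that("training is deterministic and fits separable data", {
  co <- make_std_cohort(n_per_class = 20, seed = 2)
  m1 <- train_downstream(co, "mlp32", epochs = 40, seed = 3)
  m2 <- train_downstream(co, "mlp32", epochs = 40, seed = 3)
  expect_identical(cgmdd:::mlp_params(m1$layers),
                   cgmdd:::mlp_params(m2$layers))
  expect_gt(evaluate_model(m1, co)$accuracy, 0.95) # train accuracy
  m0 <- train_downstream(co, "mlp32", epochs = 0, seed = 3)
  expect_identical(cgmdd:::mlp_params(m0$layers),
                   cgmdd:::mlp_params(cgmdd:::mlp_init(512, 32L, 2, 3)))
})

test_that("accuracy and macro-F1 match hand computations", {
  # perfect predictions
  m <- classification_metrics(c(1, 2, 1, 2), c(1, 2, 1, 2), 2)
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  # truth [0,0,1,1], predictions [0,1,1,1] in 1-based labels
  m <- classification_metrics(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$per_class_f1, c(2 / 3, 0.8))
  expect_equal(m$macro_f1, (2 / 3 + 0.8) / 2)
  # constant predictor on balanced two-class data
  m <- classification_metrics(c(1, 1, 2, 2), c(1, 1, 1, 1), 2)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$macro_f1, 1 / 3)
})

test_that("metrics agree with a confusion-matrix oracle on random vectors", {
  set.seed(99)
  for (i in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(5:40, 1)
    truth <- sample(seq_len(K), n, replace = TRUE)
    pred <- sample(seq_len(K), n, replace = TRUE)
    got <- classification_metrics(truth, pred, K)
    ref <- oracle_metrics(truth, pred, K)
    expect_equal(got$accuracy, ref$accuracy, tolerance = 1e-12)
    expect_equal(got$macro_f1, ref$macro_f1, tolerance = 1e-12)
  }
})

test_that("random subsets are stratified; cr = 1 recovers the full set", {
  co <- make_std_cohort(n_per_class = 10, seed = 3)
  sub <- random_subset(co, 0.2, seed = 1)
  expect_equal(as.integer(table(sub$labels)), c(2, 2))
  full <- random_subset(co, 1, seed = 1)
  expect_identical(full$pixels, co$pixels)
})

test_that("label reduction is stratified and the full ratio is the identity", {
  co <- make_std_cohort(n_per_class = 10, seed = 4)
  red <- reduce_labels(co, 0.5, seed = 1)
  expect_equal(as.integer(table(red$labels)), c(5, 5))
  expect_identical(reduce_labels(co, 1, seed = 1), co)
})

test_that("missing-modality robustness reports drops in percentage points", {
  co <- make_std_cohort(n_per_class = 15, seed = 5)
  mod <- train_downstream(co, "mlp16", epochs = 30, seed = 1)
  r0 <- robustness_missing(mod, co, integer(0))
  expect_equal(r0$acc_drop, 0)
  r1 <- robustness_missing(mod, co, "m1")
  expect_equal(r1$acc_drop, (r1$baseline_acc - r1$acc_with_missing) * 100)
  rn <- robustness_missing(mod, co, 1, fill = "noise", seed = 2)
  expect_true(is.finite(rn$acc_drop))
  expect_error(robustness_missing(mod, co, c(1, 2)), "all")
  expect_error(robustness_missing(mod, co, "nope"), "unknown modality")
  expect_equal(robustness_gain(10.4, 3.6), 6.8)
})

test_that("training with a zero-filled modality makes its absence harmless", {
  co <- make_std_cohort(n_per_class = 25, seed = 6)
  sp <- split_cohort(co, 0.4, seed = 1)
  tr0 <- fill_modalities(sp$train, 2, fill = "zeros")
  mod <- train_downstream(tr0, "mlp16", epochs = 60, seed = 1)
  rep <- robustness_missing(mod, sp$test, 2)
  expect_lte(abs(rep$acc_drop), 2)
})

test_that("method comparison runs every method on shared splits", {
  study <- toy_study()
  tr <- random_subset(study$train, 0.3, seed = 42)
  te <- random_subset(study$test, 0.2, seed = 42)
  cfg <- trainer_config(K_total = 8, T_steps = 2, pretrain_steps = 8)
  runs <- run_method_comparison(tr, te, cr = 0.1, seeds = 1:2,
                                config = cfg, epochs = 25)
  expect_setequal(unique(runs$method),
                  c("upper_bound", "random_subset", "only_hc2l", "only_ddg",
                    "cgmdd"))
  expect_equal(nrow(runs), 10)
  expect_true(all(runs$accuracy >= 0 & runs$accuracy <= 1))
  expect_true(all(runs$n_test == 40))
  smry <- summarize_methods(runs, dataset = "toy")
  expect_equal(nrow(smry), 5)
})

test_that("sweeps produce the requested grids with dispersion summaries", {
  study <- toy_study()
  tr <- random_subset(study$train, 0.3, seed = 42)
  te <- random_subset(study$test, 0.2, seed = 42)
  cfg <- trainer_config(K_total = 8, T_steps = 2, pretrain_steps = 8)
  sw <- sweep_cr(tr, te, cr_values = c(0.1, 0.2),
                 methods = c("random_subset", "cgmdd"), seeds = 1:2,
                 config = cfg, epochs = 25)
  expect_equal(nrow(sw$summary), 4)
  expect_true(all(c("mean_acc", "sd_acc") %in% names(sw$summary)))

  si <- sweep_ipc(tr, te, ipc_values = c(1, 2), label_ratios = c(1),
                  seeds = 1, config = cfg, epochs = 25)
  expect_equal(dim(si$summary), c(2, 1))
  # the full-label column equals the unrestricted run
  cfg1 <- cfg; cfg1$ipc <- 1L
  direct <- distill(tr, cfg1, contrastive_config(), seed = 1)
  acc <- evaluate_model(train_downstream(direct$synthetic, "mlp32",
                                         epochs = 25, seed = 1), te)$accuracy
  expect_equal(si$runs$accuracy[si$runs$ipc == 1], acc)
})

test_that("the IPC x label-ratio grid is stable and monotone up to noise", {
  study <- toy_study()
  cfg <- trainer_config(K_total = 60, T_steps = 3, pretrain_steps = 50)
  si <- sweep_ipc(study$train, study$test, ipc_values = c(1, 2, 5),
                  label_ratios = c(0.3, 1), seeds = 1:3,
                  config = cfg, epochs = 100)
  s <- si$summary
  # median accuracy is non-decreasing in IPC at fixed label ratio and in
  # label ratio at fixed IPC, allowing one noise inversion (> 1 pp) per
  # row/column
  inversions <- function(v) sum(diff(v) < -0.01)
  for (j in seq_len(ncol(s))) expect_lte(inversions(s[, j]), 1)
  for (i in seq_len(nrow(s))) expect_lte(inversions(s[i, ]), 1)
  expect_true(all(s > 0.5)) # every condition clearly above chance
})

test_that("any preset architecture learns from distilled data", {
  study <- toy_study()
  cfg <- trainer_config(K_total = 30, T_steps = 3, pretrain_steps = 20)
  run <- distill(study$train, cfg, seed = 1)
  tbl <- cross_architecture(run$synthetic,
                            c("linear", "mlp16", "mlp32", "mlp64_32"),
                            study$test, seeds = 1:2, epochs = 60)
  expect_equal(nrow(tbl), 8)
  expect_true(all(c("arch", "n_params") %in% names(tbl)))
  med <- tapply(tbl$accuracy, tbl$arch, median)
  expect_true(all(med > 0.5)) # above chance for every architecture
  counts <- unique(tbl[, c("arch", "n_params")])
  expect_true(all(diff(sort(counts$n_params)) > 0))
})

test_that("soft labels train against the full distribution", {
  co <- make_std_cohort(n_per_class = 10, seed = 8)
  syn <- init_synthetic(co, 3, "class_mean", seed = 1)
  syn$labels_soft <- cbind(c(rep(0.9, 3), rep(0.2, 3)),
                           c(rep(0.1, 3), rep(0.8, 3)))
  mod <- train_downstream(syn, "linear", epochs = 50, seed = 1)
  expect_true(all(is.finite(predict_proba(mod, co))))
  pred <- predict_class(mod, syn)
  expect_equal(pred, syn$labels)
})
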