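# cgmdd — contrast-guided multi-modal dataset distillation

`cgmdd` compresses a labeled multi-modal image dataset (for example
multi-sequence MRI, where every sample has M spatially registered modality
images) into a small *learnable* synthetic dataset on which downstream
classifiers train to near-full-data performance. It is aimed at
researchers studying data-efficient and privacy-conscious learning for
multi-modal medical imaging, and at anyone who wants a compact, fully
reproducible CPU implementation of gradient-matched dataset distillation
with cross-modal contrastive guidance.

## The method

Given a cohort $D = \{(x_i, y_i)\}_{i=1}^{N_D}$ with
$x_i = \{x_i^{(1)}, \dots, x_i^{(M)}\}$, the package optimizes the pixels of
a synthetic set $S = \{(\tilde x_j, \tilde y_j)\}_{j=1}^{N_S}$
($N_S \ll N_D$; labels fixed) under

$$L_{\mathrm{total}} = \lambda_d(k)\,L_d + \lambda_c(k)\,L_{\mathrm{contrast}}$$

* **Gradient matching** ($L_d$): a freshly initialized proxy classifier is
  trained for a short trajectory; at each step the cross-entropy gradients
  on a real batch and a synthetic batch, taken at the same parameters, are
  compared by per-parameter-group cosine distance
  $d(g_1,g_2) = 1 - g_1\!\cdot\! g_2 / \max(\lVert g_1\rVert\,\lVert g_2\rVert, \epsilon)$,
  and the synthetic pixels receive the exact analytic gradient of the sum.
* **Hierarchical cross-modal contrastive loss** ($L_{\mathrm{contrast}}$):
  InfoNCE over a partially shared encoder (modality-specific stems, shared
  residual trunk, modality-specific heads). Positives are embeddings of the
  same sample and spatial location in different modalities; negatives come
  from other samples, other locations, and optional augmented views or a
  momentum queue; losses are averaged over batch, ordered modality pairs,
  locations, and encoder levels.
* **Cosine-annealed weights**: $\lambda_c(k)$ decays from 1 to 0 while
  $\lambda_d(k)$ rises from 0.1 to 1.0 over the outer iterations, so
  representation alignment dominates early and compression dominates late;
  the two weights cross exactly once.

A bundled synthetic multi-modal cohort generator (registered modality
renderings of a shared latent "anatomy" with controllable class
separability) makes the whole pipeline runnable and testable without any
external data. See the vignette `vignettes/cgmdd-methods.Rmd` for models,
defaults, and design choices.

## Worked example

```r
library(cgmdd)

# a registered 2-modality cohort: 400 samples, 2 classes, 16x16 pixels
cohort <- generate_cohort(n_per_class = 200, n_classes = 2,
                          n_modalities = 2, seed = 1)
sp    <- split_cohort(cohort, test_frac = 0.5, seed = 1)
stats <- cohort_stats(sp$train)                  # normalization constants
train <- standardize_cohort(sp$train, stats)
test  <- standardize_cohort(sp$test,  stats)

# distill 200 training samples into 10 synthetic ones (ipc = 5, CR = 5%)
run <- distill(train, trainer_config(), seed = 1)
print(run)

# classifiers trained on 10 synthetic vs 10 random real vs all 200 samples
for (data in list(distilled = run$synthetic,
                  random10  = random_subset(train, 0.05, seed = 1),
                  full200   = train)) {
  model <- train_downstream(data, "mlp32", epochs = 150, seed = 1)
  print(evaluate_model(model, test))
}
```

```
cgmdd_run: 300 outer iterations, 10 synthetic samples (ipc=5)
  final: L_d=7.5331  L_contrast=1.8816  L_total=7.5331
eval_report: Acc=0.765  Macro-F1=0.764  (n=200)
eval_report: Acc=0.665  Macro-F1=0.657  (n=200)
eval_report: Acc=0.860  Macro-F1=0.860  (n=200)
```

Reading the output: after 300 outer iterations the contrastive weight has
annealed to zero (`L_total = L_d`). A classifier trained on the **10
distilled images** reaches 0.765 accuracy on the held-out half — close to
the 0.860 of the full-data upper bound and well above the 0.665 of a
random real subset of the same size. The same protocols are available for
compression-ratio sweeps (`sweep_cr`), images-per-class × label-ratio
grids (`sweep_ipc`), missing-modality robustness (`robustness_missing`),
and cross-architecture generalization (`cross_architecture`); a
command-line interface (`inst/exec/cgmdd`, or `cgmdd_main()` from R) ties
them together with YAML configs and line-delimited JSON logs.

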