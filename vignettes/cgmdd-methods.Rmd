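---
title: "Contrast-guided multi-modal dataset distillation: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-guided multi-modal dataset distillation: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cgmdd)
```

## The problem

A multi-modal imaging cohort $D = \{(x_i, y_i)\}_{i=1}^{N_D}$ holds, for
every sample, $M \ge 2$ spatially registered modality images (in MRI:
different sequences or contrast phases of the same anatomy) and a class
label. Dataset distillation compresses $D$ into a small *learnable*
synthetic set $S = \{(\tilde{x}_j, \tilde{y}_j)\}_{j=1}^{N_S}$,
$N_S \ll N_D$, such that a classifier trained on $S$ approaches the
performance of one trained on $D$. The package implements a contrast-guided
variant: the pixels of $S$ are optimized under a joint objective

$$L_{\mathrm{total}} = \lambda_d(k)\, L_d + \lambda_c(k)\, L_{\mathrm{contrast}},$$

where $L_d$ is a gradient-matching distillation loss, $L_{\mathrm{contrast}}$
is a hierarchical cross-modal InfoNCE loss, and the weights follow cosine
annealing schedules over the outer iterations $k = 1, \dots, K_{\mathrm{total}}$:

$$\lambda_c(k) = \tfrac{\lambda_{c,\mathrm{init}}}{2}\bigl(1 + \cos\tfrac{k\pi}{K}\bigr),
\qquad
\lambda_d(k) = \lambda_{d,\mathrm{init}} +
\tfrac{\lambda_{d,\mathrm{final}} - \lambda_{d,\mathrm{init}}}{2}\bigl(1 - \cos\tfrac{k\pi}{K}\bigr).$$

With the default initialization ($\lambda_{c,\mathrm{init}} = 1.0$,
$\lambda_{d,\mathrm{init}} = 0.1$, $\lambda_{d,\mathrm{final}} = 1.0$) the
contrastive term dominates early — aligning cross-modal representations —
and the distillation term dominates late; the two weights cross exactly
once.

## Gradient matching

Each outer iteration draws a fresh proxy classifier at random parameters
$\theta_0$ and simulates a short trajectory of $T$ steps. At every step,
class-matched mini-batches $D_t$ and $S_t$ are sampled, the task-loss
(cross-entropy) gradients are computed *at the same* $\theta_t$, and their
discrepancy is the per-parameter-group cosine distance

$$d(g_1, g_2) = 1 - \frac{g_1 \cdot g_2}{\lVert g_1\rVert_2\,\lVert g_2\rVert_2 + \epsilon},
\qquad \epsilon = 10^{-8}.$$

$L_d$ is the sum of the step losses; the real-batch gradient is a constant,
and the synthetic pixels receive the exact analytic gradient of $L_d$
through the synthetic-batch gradient. Pixels are updated with Adam at rate
$\eta_S$; labels are fixed (class-balanced hard labels, or a teacher's
predicted distributions via `assign_labels()`).

**Proxy model.** The proxy is multinomial logistic regression on flattened
multi-modal pixels, with two parameter groups (weights, bias). For this
proxy the second-order term — the derivative of the gradient-matching loss
with respect to the synthetic pixels — is available in closed form, which
keeps the bi-level loop exact and fast on one CPU. A deeper proxy would
require Hessian-vector products; at the spatial scales this package targets
the linear proxy preserves the structure of the method (short trajectories,
fresh $\theta_0$ per outer iteration, per-group cosine matching) while every
gradient is verified against finite differences in the test suite.

**First-order scheme.** No gradients flow through the $\theta$ updates
across inner steps: each step's matching term is differentiated with respect
to $S$ only through the synthetic gradient at the current $\theta_t$. The
inner $\theta$ update uses the synthetic batch by default (`inner_on`), so
training on $S$ replicates the dynamics being matched; the real-batch
alternative is a flag.

## The encoder and the contrastive loss

The encoder is partially shared: per-modality *patch stems* (a dense layer
on non-overlapping $4 \times 4$ patches — a strided convolution), a
*shared residual trunk* applied to patch embeddings (one parameter set used
by every modality path), a shared learnable *positional embedding* added to
the stem output, and per-modality residual heads with a flatten-then-linear
transition to the pooled vector $z_i^{(m)}$. Two feature levels are exposed:
`patch` (trunk output per grid cell) and `pooled`.

Two desk-scale choices deserve explanation:

- *Flatten transition instead of global average pooling.* Mean pooling of
  patch embeddings with an additive positional code cancels the positional
  information in the pooled vector, which removes precisely the spatial
  configuration signal that identifies an instance across modalities; the
  cross-modal retrieval signal then cannot be learned. The flatten-then-
  linear transition (the standard small-CNN head) preserves it. Global
  average pooling remains available (`pooling = "mean"`) and is used by the
  `paper3d` preset, where deep stacks of strided stages make spatial
  information survive pooling.
- *Per-modality trunk passes.* The shared trunk is applied once per
  modality path with the same weights. A concatenated-trunk variant cannot
  emit the per-modality pooled vectors the contrastive loss is defined on
  without an arbitrary split rule, so it is not implemented.

For every anchor embedding (sample $i$, modality $m$, level, location), the
positive is the embedding of the *same sample and location in another
modality* — registration makes "the same location" well defined — and the
negatives come from other samples in the batch (inter-instance), other
locations of the same sample (intra-instance spatial, patch level), and
optionally distorted views of the anchor (augmentation negatives) and a
momentum memory queue. The per-pair loss is InfoNCE at temperature
$\tau = 0.07$; the total averages over batch samples, the $M(M-1)$ ordered
modality pairs, locations, and levels (uniform level weights by default).
Embeddings are projected by a two-layer MLP head and unit-normalized before
any similarity is computed.

Augmentation negatives treat distorted views of the anchor as negatives.
This is the written definition of that negative source, but it conflicts
with standard contrastive practice (augmented views are usually positives),
so the source is **off by default** behind
`use_augmentation_negatives = TRUE`. Queue entries and augmentation
embeddings are constants in the backward pass (MoCo-style stop-gradient).
Whether level weights are learned is left open in the method's description;
they are fixed here. At the patch level a random subset of
`n_spatial_patches = 4` grid cells is used per step — a stochastic
location subsample that bounds the cost and adds variance like any
mini-batch estimate.

During distillation the contrastive term sees the union of the current real
and synthetic batches (`mode = "joint"`; `d-only` / `s-only` are
selectable), with at most `contrast_batch = 16` real samples per step so
the contrastive cost does not scale with the matching batch.

## Preprocessing: intensity normalization

Distillation operates on per-modality z-scored intensities
(`standardize_cohort()`); held-out data are standardized with the *training*
cohort's constants, which ship with the distilled output. This mirrors
routine MRI intensity normalization, and it is load-bearing here: the
Gaussian initialization $\tilde{x}_j \sim N(0, \sigma^2 I)$ is zero-mean,
and the cosine gradient-matching signal of a linear proxy is blind to the
common intensity offset — on unnormalized data the synthetic set would be
learned at the wrong offset and downstream classifiers would fail at test
time.

## Desk-scale defaults and why

| parameter | full scale | desk default | rationale |
|---|---|---|---|
| $K_{\mathrm{total}}$ | 10000 | 300 | minutes, not hours, on one CPU |
| $T$ | 10 | 5 | same |
| $\eta_\theta$ | $10^{-3}$ | $10^{-3}$ | kept |
| $\eta_S$ | 0.01 | 0.01 | kept |
| $\tau$ | 0.07 | 0.07 | kept |
| queue | 4096, momentum 0.5 | off | in-batch negatives suffice at batch 16 |
| projection head | 2048–1024–128 | 32–16 widths | matches encoder width |
| synthetic init | `gaussian` | `class_mean` | see below |

`trainer_config(paper_scale = TRUE)` restores the full-scale values.

*Synthetic initialization.* The method defines three initializations —
Gaussian noise with $\sigma$ matched to the data, random real samples, and
class-wise means — reported as performing comparably at full scale. At
$K_{\mathrm{total}} = 300$ the Gaussian start is still far from converged
(the iteration budget is 33× smaller than full scale), so the desk-scale
default is `class_mean`; `paper_scale = TRUE` switches back to `gaussian`.
All three remain available and tested.

## The synthetic cohort generator

Every sample is rendered from one latent phantom so that modalities are
registered by construction. The phantom is the sum of

- a smooth nonnegative background (amplitude 0.8, four random cosine
  harmonics — enough degrees of freedom that every sample's background is
  distinctive while remaining smooth),
- a **class blob**: a Gaussian bump whose peak intensity steps by
  `margin = 0.8` per class and whose radius steps by 6%, with substantial
  per-sample jitter of its center (anywhere in the central half of the
  field), radius (log-normal sd 0.35) and peak intensity (log-normal sd
  0.25). The jitter makes the blob's configuration a large part of each
  sample's *identity*, so the cross-modal alignment signal the contrastive
  encoder learns is class-relevant rather than orthogonal nuisance,
- a **diffuse class template**: a faint class-specific smooth pattern
  (amplitude 0.12 in field units) identical for all samples of a class —
  a signal spread over many weak pixels that a large sample can estimate
  but a handful of images cannot separate from noise,
- **distractor blobs**: 5 nuisance bumps (peak $1.4 \pm 0.4$) at random
  peripheral positions, independent of the class — shared anatomy that
  misleads classifiers trained on few samples.

Each modality applies a distinct strictly monotone intensity transform
($\text{scale} \cdot v^{\gamma} + \text{offset}$, modality 1 being the
identity) plus i.i.d. Gaussian noise at a modality-specific level
(base `noise_sd = 0.7` times factors 1.0, 2.0, 0.75, ... — MRI sequences
differ markedly in SNR, and this partial complementarity is what
missing-modality compensation acts on).

These defaults were calibrated once, jointly, so that the default cohort is
(i) linearly separable (a ridge probe on flattened pixels exceeds 0.9
accuracy on a 50/50 split), (ii) cross-modally alignable (200 contrastive
steps push cross-modal retrieval above 0.8), and (iii) representative of
the regime dataset distillation is for — a stratified random subset of the
distilled set's size falls far below the full-data upper bound, as the
published benchmarks show for real multi-modal MRI. After calibration the
values were frozen; the test suite runs entirely at these conditions. An
early design iteration concentrated the shared structure in bright
class-independent distractors; that made contrastive guidance
class-orthogonal (it shaped nuisance structure), and was revised so the
jittered class blob dominates the shared instance signal.

What the generator does **not** emulate: MRI physics (bias fields, partial
volume, coil inhomogeneity), anatomical atlases, inter-modality
misregistration, 3-D context at realistic resolution, or label noise.
Passing tests therefore demonstrate the correctness and the qualitative
behavior of the optimization machinery, not clinical performance.

## Numerical choices

- All similarity computations are $\epsilon$-guarded ($10^{-8}$); InfoNCE
  uses a log-sum-exp; cosine distances lie in $[0, 2]$ by construction.
- Every hand-written backward pass (encoder, projection head, InfoNCE,
  the second-order gradient-matching term) is checked against central
  finite differences in the unit tests.
- Retrieval and prediction ties break to the lowest index; batches are
  class-conditionally paired between $D$ and $S$ so that label-distribution
  mismatch cannot dominate the matching loss (flag to disable).
- Three named seed streams (model initialization, batch sampling, synthetic
  initialization) are derived from the master seed and logged; runs are
  bit-reproducible.
- Divergence guard: a non-finite $L_{\mathrm{total}}$ aborts with the
  iteration and loss values.

## Monitoring the optimization

Under the annealing schedules the weighted objective is *non-stationary by
design*: $\lambda_d$ ramps from 0.1 to 1.0 onto the (larger) distillation
term, so $L_{\mathrm{total}}$ can rise over a run even while both unweighted
terms behave. Monotone-decrease and no-oscillation diagnostics are therefore
meaningful for the *fixed-weight* configuration ($\lambda_c = \lambda_d =
0.5$), which the test suite uses; under annealing one monitors the per-term
traces $(L_d, L_{\mathrm{contrast}})$ that every run logs. Similarly,
optimizer-progress checks on $L_d$ start from the Gaussian initialization
(the class-mean start sits essentially at the matching noise floor) and
widen the real-side batch to 64 so that mini-batch noise in the matching
target does not mask progress.

## Evaluation protocols

Downstream classifiers are small MLPs on flattened pixels (presets
`linear`, `mlp16`, `mlp32`, `mlp64_32` with strictly increasing parameter
counts), trained with Adam and mild decoupled weight decay; soft labels are
trained against the full distribution. Metrics are accuracy and macro-F1
(unweighted mean of one-vs-rest F1; a class with no true and no predicted
instances contributes 0 — a conservative convention). Protocols:

- `run_method_comparison()`: upper bound (full data), stratified random
  subset, contrastive-pretraining-only (`only_hc2l`: frozen pretrained
  encoder + linear head on the subset), distillation without contrastive
  guidance (`only_ddg`, $\lambda_c = 0$), and the full method, all on shared
  splits and seeds.
- `sweep_cr()` / `sweep_ipc()`: compression-ratio curves and
  IPC × label-ratio grids; label reduction drops unlabeled samples
  (stratified), with repeated seeded re-splits providing dispersion.
- `robustness_missing()`: selected modalities are replaced by zeros (or
  noise) at inference; the report is the accuracy drop in percentage
  points, and method comparisons use the drop difference.
- `cross_architecture()`: one distilled set, several downstream
  architectures.

The test suite runs these at reduced sizes: the toy study uses 2 classes,
$M = 2$, $16 \times 16$ pixels, $N_D = 200$ training samples, ipc 5
($N_S = 10$, a 5% compression ratio), $K_{\mathrm{total}} = 300$, $T = 5$,
with medians over three seeds — sizes chosen so the full suite completes in
minutes on a single CPU while leaving every qualitative comparison intact.

## Known limitations

- The linear proxy cannot express feature hierarchies; gradient matching
  therefore constrains first- and second-order class statistics of the
  synthetic set rather than deep-feature trajectories.
- The contrastive term treats other samples as negatives regardless of
  class, so in joint mode synthetic anchors are repelled from same-class
  real samples; with an informative encoder the alignment benefit
  dominates, but with an encoder trained on very low-SNR data the guidance
  degrades toward noise.
- Schedules, not adaptive weighting: the crossover point is fixed by
  $K_{\mathrm{total}}$.
- Anonymization of distilled pixels is qualitative; no formal privacy
  guarantee is computed.
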