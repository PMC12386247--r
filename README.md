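# pestfuse

Multimodal detection of crop pests and their natural enemies from paired
RGB + thermal infrared imagery and environmental sensor streams, in pure R.

## The problem

Field pest monitoring has to distinguish six pest classes from two visually
similar predator classes (lady beetles, lacewings) under dusk light, fog and
occlusion — conditions where RGB-only detectors fail. `pestfuse` implements a
multimodal detector that exploits the complementarity of three streams:

* **RGB** frames carry colour and texture (class identity);
* **thermal infrared** frames show insects as warm blobs regardless of
  lighting (localization);
* a **1 Hz environmental series** (temperature °C, relative humidity %,
  normalized light intensity) tells the model which visual stream to trust.

## The model

Three modality encoders feed two fusion mechanisms and a set-prediction head:

* **Cross-modal attention fusion (CMA).** Local activation histograms per
  modality are compared with the Kullback–Leibler divergence
  `D_KL(P_rgb ‖ P_ir) = Σᵢ P_rgb(i) log(P_rgb(i)/P_ir(i))`; alignment weights
  `exp(−D_KL/τ)` down-weight inconsistent regions before channel reduction to
  `C′ = 32`, spatial gating, bidirectional cross attention
  (`Softmax(QKᵀ/√d)V` over spatial tokens) and residual-gated merging.
* **Environment-guided modality attention (EMA).** The normalized environment
  history runs through a depth-3 state-space (SS1D) stack
  (`h_t = A h_{t−1} + B x_t`, `y_t = C h_t`) whose output is expanded into a
  modulation gate `g ∈ (0,1)^{32×32×64}`, applied as
  `F_fused = g · [α F_RGB + (1−α) F_IR]` with learnable `α ∈ [0,1]`.
* **Decoupled dual-target head.** DETR-style transformer encoder/decoder
  (`d_model = 256`, 8 heads, 6+6 layers) with two independent 100-query sets
  (pest / predator), Hungarian matching, and the loss
  `L = λ_cls·L_cls + λ_bbox·L_bbox + λ_giou·L_giou + μ·L_contrastive`, where
  `L_cls = −Σ ωᵢ yᵢ log pᵢ` uses inverse-frequency class weights and the
  contrastive term separates pest from predator embeddings.

Evaluation implements precision, recall, `F1 = 2PR/(P+R)`, IoU, per-class AP
at IoU ≥ 0.5 (PASCAL-VOC greedy matching, all-point interpolation) and
mAP@50.

Everything — including a reverse-mode autodiff engine, the transformer, and
the Hungarian solver — is implemented in R with no deep-learning framework,
and trains end-to-end on one CPU at the bundled `tiny` preset. A synthetic
scene generator (COCO-style annotations, PNG image pairs, CSV sensor
streams) makes the whole pipeline reproducible without any download.

## Worked example

```r
library(pestfuse)

# 1. a synthetic multimodal dataset (in memory; generate_dataset() writes PNG/CSV/JSON)
scenes <- sample_dataset(8, scene_spec(image_size = 64, n_targets = 2, seed = 0), seed = 0)
scenes[[1]]$boxes
#> # A tibble: 2 × 6
#>   class_id group  xmin  ymin  xmax  ymax
#>      <int> <chr> <dbl> <dbl> <dbl> <dbl>
#> 1        3 pest   24.8  39.3  45.5  60.0
#> 2        3 pest   39.9  27.9  61.7  49.7

# 2. train the tiny-preset model for a short smoke run
fit <- pd_train(pf_config("tiny"), scenes, steps = 50)
glance(fit)
#> # A tibble: 1 × 5
#>   steps loss_first loss_final alpha config_hash
#>   <int>      <dbl>      <dbl> <dbl> <chr>
#> 1    50       7.79       2.65 0.500 00446277

# 3. evaluate on the training scenes
report <- pd_evaluate(fit, scenes)
report
#> Detection metrics over 8 image(s)
#>   TP 6  FP 186  FN 10
#>   Precision 3.1%  Recall 37.5%  F1 5.8%  mAP@50 3.0%

# 4. single-frame inference: top detections after the 50-step smoke run
sc <- scenes[[1]]
d <- pd_infer(fit, sc$rgb, sc$thermal, sc$env, sc$timestamp, score_threshold = 0)
dplyr::slice_max(d, score, n = 3)
#> # A tibble: 3 × 8
#>   image_id class_id group score  xmin  ymin  xmax  ymax
#>      <int>    <int> <chr> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1        1        3 pest  0.133  9.35  35.3  31.4  56.5
#> 2        1        3 pest  0.128 23.8   37.7  46.2  58.6
#> 3        1        3 pest  0.128 42.8   33.1  64    53.4
```

The boxes are pixel corner coordinates; `class_id` 0–5 are pests, 6 is the
lady beetle and 7 the lacewing. Fifty steps is only a smoke run — the total
loss has fallen from 7.8 to 2.7 and the top-scoring detections already sit on
the true class near the two ground-truth boxes, but scores are still low and
mAP@50 near zero; the bundled 500-step experiment (below) trains much
further, and the methods vignette discusses how far desk-scale budgets carry
this architecture. `report` prints TP/FP/FN counts, precision/recall/F1 and
mAP@50; `tidy(report)` returns per-class AP and `autoplot(report)` draws it.

A command-line front-end wrapping the same functions lives at
`inst/cli/pest-detect.R`
(`generate | train | evaluate | infer`, each with `--config`, `--seed`,
`--out`).

## Scope

The published field study (3249 RGB frames, GPU training, mAP@50 = 88.0 % on
real imagery) is not reproducible at desk scale; this package reproduces the
*mathematics and mechanics* of the method — preprocessing, fusion modules,
state-space gating, set-prediction head, losses and metrics — at a scale
where every component is verifiable on one CPU. See the methods vignette
(`vignettes/pestfuse-methods.Rmd`) for model assumptions, parameter
defaults and known limitations.
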