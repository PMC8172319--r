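# vbmnet

Multitask 3D convolutional networks for voxel-based morphometry (VBM).

`vbmnet` is for neuroimaging researchers who want to estimate **age**,
**gender**, and **diagnostic status** jointly from VBM-preprocessed
structural MRI — pairs of gray-matter (GM) and white-matter (WM)
tissue-density volumes on a common grid — and then ask the trained network
*which brain regions* drove each prediction. The package implements the
whole workflow as tested, reusable pieces:

* a **synthetic VBM-like cohort generator** (volumes + phenotypes + atlas)
  with injectable regional effects, so every stage is verifiable against
  known ground truth without downloading any data;
* **volume I/O**: NIfTI read/write, background masking to −1, centred
  pad/trim to a cube (e.g. 121×145×121 → 128³), two-channel GM/WM stacking,
  and a streaming binary record container;
* a **from-scratch multitask 3D CNN engine** (RcppArmadillo kernels:
  batch-norm, 3×3×3 convolutions, max-pooling, dropout, Adam, full
  backpropagation including input gradients);
* the **custom stratified k-fold** scheme (per round: 1 test partition,
  then cyclically the first k−2 partitions train and the last validates);
* a **training loop** with per-task model checkpointing and custom early
  stopping (stop after `patience` epochs in which no task's validation loss
  improves);
* the **metric suite** (MAE, Pearson r + p, prediction R²; precision,
  recall, F1, AUC-ROC) with ROC **operating-point selection** maximising the
  harmonic mean of sensitivity and specificity on validation data;
* **SmoothGrad attention maps** (absolute input gradients averaged over
  noisy perturbations), fold aggregation, atlas intersection and **ROI
  ranking**, plus NIfTI overlay export.

## The model

The shared body is `conv_blocks` repetitions of
*batch-norm → conv 3×3×3 (ReLU, same padding) → max-pool 3×3×3 stride 2*,
then *flatten → dropout(0.5) → dense*. Three heads
(*dense → batch-norm → output*) emit a linear age estimate and sigmoid
probabilities for gender (1 = female) and diagnosis (1 = disorder). Training
minimises

```
L = w1 · MSE(age) + w2 · BCE(gender) + w3 · BCE(diagnosis)      (w = 1, untuned)
```

plus an L2 penalty (1e-3) on all conv/dense kernels, with Adam
(lr 1e-3, β = 0.9/0.999, batch 32). At every epoch the model is scored on
the fold's validation set and the best parameters *per task* are
checkpointed, yielding three model versions per training round.

## Worked example

```r
library(vbmnet)

# a cohort with known structure: GM density falls 0.02/year in ROI 2,
# females have +0.04 GM density in ROI 5
atlas <- generate_atlas(c(32, 32, 32), n_rois = 6, seed = 11)
spec <- cohort_spec(400, shape = c(32, 32, 32),
                    effects = list(effect_spec("age", 2, -0.02, "GM"),
                                   effect_spec("gender", 5, 0.04, "GM")),
                    seed = 11)
ss <- as_sample_set(generate_cohort(spec, atlas))

folds <- make_folds(setNames(ss$phenotypes$diagnosis, ss$phenotypes$subject_id),
                    k = 3, seed = 7)
fit <- train_fold(ss, folds[[1]],
                  model_config(2, c(4, 8), dense_units = 32, head_units = 16),
                  train_config(max_epochs = 30, patience = 8, seed = 5))
fit
#> Multitask CNN fold fit (round 0): stopped at epoch 30 (max_epochs)
#>   best age      : epoch 28, validation loss 0.39342
#>   best gender   : epoch 28, validation loss 0.35849
#>   best diagnosis: epoch 15, validation loss 0.65445

test_i <- match(folds[[1]]$test_ids, ss$phenotypes$subject_id)
test <- subset_sample_set(ss, test_i)
preds <- predict(checkpoint_model(fit, "age"), test)
regression_metrics(ss$phenotypes$age[test_i], preds$age)
#> Regression report (n = 134)
#>   MAE      : 0.5009
#>   Pearson r: 0.9952 (p = <2e-16)
#>   R2-score : 0.9733

map <- fold_attention_map(checkpoint_model(fit, "age"), ss, test_i, "age", seed = 5)
rank_rois(aggregate_maps(list(map), mask = atlas$labels > 0), atlas, top_k = 3)
#>   roi_id roi_name  statistic rank
#> 1      2  ROI_002 0.27407603    1
#> 2      3  ROI_003 0.09949669    2
#> 3      5  ROI_005 0.07705883    3
```

The best-age checkpoint's test MAE of 0.50 years beats the predict-the-mean
baseline (3.67 years on this cohort) by an order of magnitude, the
best-gender checkpoint reaches a test AUC of 1.0, and the attribution places
the age-coupled ROI 2 at rank 1.

A full cross-validated run — folds, training, per-fold test reports with
validation-chosen thresholds, mean ± SD summaries, aggregated attention
maps and ROI tables written to disk — is one call:

```r
run <- pipeline_run(run_config(cohort = spec), "runs/demo")
```

or, from a shell, via the thin CLI wrapper
`Rscript inst/cli/vbmnet.R run --config run.yaml --outdir runs/demo`.

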