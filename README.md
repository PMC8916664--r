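# protogait

Explainable open-set gait recognition from multimodal insole recordings
(plantar pressure, acceleration, rotation), for researchers in wearable
biometrics and human-movement analysis who need a recognition pipeline that
can also say *which parts of a walking cycle* carry the identity signal.

## What it implements

A sensorized insole samples 28 channels every 0.01 s: 16 plantar-pressure
sensors, 6 accelerometer and 6 gyroscope axes. Continuous recordings are
segmented into **unit steps** (one stance + swing cycle, resampled to
T = 100 rows) using the fact that pressure vanishes during swing.

* **Prototyping encoder–decoder.** An encoder f maps a unit step to a
  unit-norm 128-d embedding through three modality-specific conv stacks
  (32/64/128 filters) and dense 256/128 layers. Training minimizes
  `L = L_triplet + λ·L_proto`: a hinged multimodal triplet loss
  `max(0, ‖v_a−v_p‖² − ‖v_a−v_n‖² + α)` (α = 1.25) plus a prototype loss —
  the decoder must reconstruct the *subject's mean cycle* from the
  embedding, compared per channel after unit normalization (λ = 1).
* **Few-shot open-set recognizer.** Subjects split 20/10/10 into
  training / known / unknown groups; each known subject is enrolled from
  n = 10 shot embeddings via its centroid `D_a` and a one-class SVM
  (RBF kernel, `min ½αᵀKα` s.t. `0 ≤ α_i ≤ 1/(νn)`, `Σα_i = 1`; γ = 2.2,
  ν = 0.06). A query is assigned to the nearest centroid and accepted iff
  the decision value `h_p(v) = Σ α_i K(v_i, v) − δ_p` is ≥ τ (= −0.1);
  otherwise it is rejected as unknown. TPR/TNR/ACC are averaged over 10
  split repetitions.
* **Attribution.** Sensitivity analysis (|input gradient|) and LRP-ε
  (layer-wise relevance redistribution,
  `R_i = Σ_j x_i w_ij / (Σ_i x_i w_ij + ε·sign) · R_j`) per embedding
  component, averaged over the 128 components and over all training steps
  into a **common attribution map**, evaluated by **region perturbation**:
  occlude the map's relevance quintiles O1…O5 (and a random baseline) in
  every test step and watch TPR/ACC degrade.
* **Synthetic generator.** The real 40-subject dataset is private, so the
  package generates subject-specific multimodal templates (pressure zero
  in swing, harmonic acceleration/rotation signatures) with timing jitter
  and noise — enough statistical structure to exercise and test every
  stage end to end.

The conv/ReLU/Adam kernels are implemented in C++ (RcppArmadillo); training
the default configuration takes about a minute per split repetition on one
CPU core.

## Worked example

```r
library(protogait)

# synthetic cohort: 10 subjects, 30 unit steps each
ds   <- generate_dataset(generation_config(n_subjects = 10,
                                           steps_per_subject = 30, seed = 1))
spec <- split_spec(n_train = 4, n_known = 3, n_unknown = 3,
                   n_shots = 5, repetitions = 2, seed = 2)
res  <- run_protocol(ds, spec, encoder_config(seed = 3),
                     gamma = 2.2, nu = 0.2, tau = -0.1,
                     keep_first_pipeline = TRUE)
res$per_repetition
#>   repetition TP FN TN FP       TPR TNR       ACC
#> 1          1 73  2 90  0 0.9733333   1 0.9878788
#> 2          2 75  0 90  0 1.0000000   1 1.0000000
```

Every known-test step accepted under its true identity is a TP; the
recognizer rejected all 90 unknown-test steps in both repetitions
(TNR = 1) while identifying 97–100% of known steps.

```r
pl   <- res$pipeline         # first repetition: encoder + recognizer + split
cm   <- common_map(unlist(pl$split$training, recursive = FALSE)[1:40],
                   pl$model$encoder, method = "lrp")
plan <- make_occlusion_plan(cm)
perturbation_curve(plan, pl$model$encoder, pl$recognizer,
                   pl$split$known_test, pl$split$unknown_test,
                   tau = -0.1, seed = 4)
#>   subset n_occluded   TPR TNR   ACC baseline
#> 1     O1        560 0.280   1 0.673    FALSE
#> 2     O2        560 0.400   1 0.727    FALSE
#> 3     O3        560 0.533   1 0.788    FALSE
#> 4     O4        560 0.947   1 0.976    FALSE
#> 5     O5        560 0.973   1 0.988    FALSE
#> 6 random        560 0.720   1 0.873     TRUE
```

Occluding the top relevance quintile (O1) drops TPR to 0.28 — far below
the 560-position random baseline (0.72) — and the degradation is monotone
in relevance order, i.e. the LRP-ε common map really does point at the
unit-step regions the recognizer relies on. `plot_attribution_map(cm)`
renders the map as a channels × time heat map.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/protogait.R simulate --subjects 10 --steps 30 --out dataset
Rscript inst/cli/protogait.R train    --dataset dataset --out model.rds
Rscript inst/cli/protogait.R evaluate --dataset dataset --out metrics
Rscript inst/cli/protogait.R perturb  --dataset dataset --checkpoint model.rds
```

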