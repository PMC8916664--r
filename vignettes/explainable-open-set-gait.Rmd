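---
title: "Explainable open-set gait recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable open-set gait recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A sensorized insole records 28 channels while a person walks: 16 three-level
plantar-pressure sensors (8 per foot), 6 accelerometer axes and 6 gyroscope
axes, sampled every 0.01 s. Because pressure vanishes while the foot is in
the air, a continuous recording can be cut into *unit steps* — one full
walking cycle each (stance followed by swing) — and resampled to a fixed
length T. Gait is a behavioural biometric: the shape of these multichannel
cycles identifies the walker.

The recognition problem here is *open set* and *few shot*: at test time a
unit step may come from a person the system has never seen, and enrolled
("known") subjects are represented by only n = 10 unit steps each. The
system must both identify known walkers and reject unknown ones, and — the
second goal — explain *which parts* of a unit step carry the identity
information.

# The model

## Prototyping encoder–decoder

The encoder f(·) maps a unit step s = [s^pre, s^acc, s^rot] to a
128-dimensional embedding v with ‖v‖₂ = 1. Each modality block passes
through its own sub-encoder (three 1-D convolutions with 32, 64 and 128
filters; parameters are *not* shared across modalities), the flattened
outputs are concatenated and fed through dense layers of 256 and 128 units,
and the result is L2-normalized. The decoder g(·) mirrors this: one dense
256 layer, then per-modality sub-decoders of stride-2 transposed
convolutions mirroring the filter counts, ending in a projection to the
modality's channel count.

Training minimizes

  L = L_triplet + λ · L_proto ,  λ = 1 by default,

with two terms:

* **Multimodal triplet loss.** For an anchor and positive from one subject
  and a negative from another,
  L_triplet = max(0, ‖v_a − v_p‖² − ‖v_a − v_n‖² + α) with margin
  α = 1.25. The hinge at zero follows the standard metric-learning
  formulation; an unclamped difference would be unbounded below.
* **Prototype loss.** The per-subject *prototype* c_a is the element-wise
  mean of all of subject a's training unit steps. The decoder is asked to
  reproduce it from the embedding:
  L_proto = (1/28) Σ_m ‖ĝ_m − ĉ_m‖², where for each of the 28 channels m
  the reconstruction g(f(s))_m and the prototype channel c_m (both length-T
  vectors) are normalized to unit L2 norm before differencing. The
  normalization is per *channel*, matching the per-channel sum: with 28
  normalized pairs each squared distance lies in [0, 4], so L_proto ∈
  [0, 4]. Reconstructing the subject's *mean* cycle (rather than the input
  itself) regularizes the embedding against within-subject variation.

## Few-shot open-set recognition

For each repetition of the evaluation protocol the subjects are split
20/10/10 into *training* (all steps train the encoder–decoder), *known*
(n = 10 shot steps fit the recognizer; the remainder are the known test
set) and *unknown* (all steps are the unknown test set). A query step s is
recognized in two stages:

1. **Provisional identity.** p = argmin_a ‖D_a − f(s)‖², where D_a is the
   arithmetic mean (not re-normalized) of subject a's n shot embeddings.
   Ties go to the smallest subject id.
2. **Accept or reject.** A per-subject one-class SVM with RBF kernel
   K(v, v′) = exp(−γ‖v − v′‖²) is fitted on the n shots by solving
   min_α ½ αᵀKα subject to 0 ≤ α_i ≤ 1/(νn), Σα_i = 1. The decision value
   h_p(v) = Σ_i α_i K(v_i, v) − δ_p is thresholded at τ: the query is
   accepted as subject p iff h_p(v) ≥ τ. The offset δ_p is the kernel
   expansion evaluated at a *margin* support vector (0 < α_h < 1/(νn));
   when no strictly interior multiplier exists (possible at small n) we
   fall back to the mean expansion over all support vectors.

Defaults γ = 2.2, ν = 0.06, τ = −0.1. A known-test step counts as a true
positive only when it is accepted *and* attributed to its true subject;
misidentification and rejection both count as false negatives. An
unknown-test step is a true negative when rejected. TPR, TNR and ACC are
averaged over 10 random split repetitions.

The dual program is solved by a pairwise (SMO-style) coordinate method:
repeatedly pick the most violating pair under the equality constraint,
solve the one-dimensional sub-problem in closed form, and clip to the box;
iteration stops when the KKT gap falls below 1e-10. At n = 10 this takes
microseconds, and the test suite checks the optimum against an independent
dense interior-point solve.

## Attribution

Two attribution methods explain the trained encoder; both yield T × 28
maps aligned with the input:

* **Sensitivity analysis (SA).** (A_c)_{tj} = |∂f(s)_c / ∂s_{tj}| — the
  absolute input gradient of embedding component c, computed by
  back-propagation through the whole encoder *including* the final
  normalization (gradients through it are well-defined).
* **LRP-ε.** Relevance starts at the pre-normalization 128-unit layer as a
  one-hot vector at component c with value f(s)_c (the normalization stage
  has no weights, so the redistribution rule does not apply to it; a
  one-hot start is the only reading consistent with later averaging over
  components). Relevance is then redistributed layer by layer: neuron i
  receives the fraction x_i w_ij / (Σ_i x_i w_ij + b_j + ε·sign(·)) of
  neuron j's relevance, with convolutions treated as their equivalent
  sparse dense connections. Bias terms enter the denominator, so their
  relevance share is absorbed rather than pushed to the inputs; for
  bias-free layers at ε = 0 the rule conserves relevance exactly, which
  the tests assert to 1e-6. Default ε = 1e-7, added as ε·sign(denominator)
  to avoid cancelling small denominators.

Since individual embedding components have no fixed meaning, maps are
averaged over all 128 components, A(s) = (1/128) Σ_c A_c(s), and then over
all training unit steps of all subjects into the *common attribution map*
A_com — one population-level picture of where identity information lives.

## Region perturbation

To score a common map, all T × 28 positions are ordered by |relevance|
descending (ties in row-major order for reproducibility) and split into
five equal quintiles O1…O5; any remainder when L mod 5 ≠ 0 joins O5, the
least relevant tail. For each quintile, every test step is occluded at
those positions (entries set to exactly 0 — distinguishable from live
pressure, which is floored at δ = 0.01) and the *fixed* pipeline
(encoder, centroids, one-class SVMs) is re-evaluated. A random baseline
occludes the same number of uniformly drawn positions, redrawn per step
from a seeded stream. If the map is informative, occluding O1 should hurt
TPR at least as much as the baseline, and strictly more than occluding O5.
Models are deliberately not refitted on occluded shots: the question is
what the *trained* pipeline relies on.

# The synthetic data generator

The 40-subject insole cohort the method was designed around is private, so
the package ships a generator that emulates the *statistical structure*
the method consumes, not the biomechanics:

* each subject is a smooth per-channel template over one cycle — pressure
  channels are clipped sums of 2–4 random-phase sinusoids, exactly zero on
  the swing window (last 40% of the cycle, a typical swing fraction);
  acceleration/rotation channels are low-order random harmonic series of
  unit scale;
* a unit step is the template warped in time by a smooth monotone warp of
  up to ±5% of T, plus Gaussian noise (sd 0.1 against unit-scale signals),
  with pressure clipped at zero, re-zeroed on the swing window and floored
  at δ = 0.01;
* defaults are 40 subjects × 158 steps of T = 100 rows (one ≈1 s cycle at
  the 0.01 s sampling period), matching the cohort the protocol counts
  (1,480 / 1,580 / 3,160 test/training steps) are quoted for.

Raw three-level pressure quantization can be switched on
(`quantize = TRUE`) to mimic the discrete sensors, but is off by default
since the pipeline treats pressure as continuous after smoothing. What the
generator does *not* emulate: ground-reaction-force physics, left/right
asymmetries, fatigue drift, or session effects. Passing the end-to-end checks on this generator
demonstrates that the pipeline's machinery (losses, recognizer,
attributions, perturbation logic) is correct and that the method separates
subjects whose signatures differ by smooth template shape — it is not
evidence about accuracy on real insole data.

# Parameters that matter

| parameter | default | units / scale | why |
|---|---|---|---|
| T | 100 | rows | one ≈1 s gait cycle at 100 Hz |
| σ (smoothing) | 3 | samples | removes single-sample pressure glitches |
| swing threshold | 0.5 | summed 3-level pressure | swing = summed pressure below it |
| δ (pressure floor) | 0.01 | pressure units | keeps live zeros distinguishable from occlusion |
| α (margin) | 1.25 | squared embedding distance | reference margin |
| λ | 1.0 | — | reference loss weight |
| n (shots) | 10 | steps/subject | reference few-shot budget |
| γ, ν | 2.2, 0.06 | kernel width, box scale | reference recognizer setting |
| τ | −0.1 | decision value | reference acceptance threshold |
| ε (LRP) | 1e-7 | — | stabilizer; 0 turns conservation exact but risks 0/0 |

# Numerical and design choices

* **Convolution geometry.** Kernel 5, "same" padding, ReLU, and stride 2 in
  each conv layer (T: 100 → 50 → 25 → 13). The stride-2 pyramid is the
  standard design for signals of this length: it keeps the flattened
  feature map (3 × 1664) and the first dense layer well-conditioned, where
  a stride-1 stack would flatten 38,400 features into dense 256 with ~10M
  parameters serving no representational purpose. Transposed convolutions
  invert the geometry exactly (zero-stuffing + stride-1 convolution,
  right-padded to the target length).
* **Activations.** ReLU after every convolution and after dense 256; the
  dense 128 output layer is linear, then L2-normalized.
* **Training.** Adam (lr 1e-3), mini-batches of 64 random valid triplets
  (one triplet per anchor; no semi-hard mining), per-subject prototypes
  precomputed once from the training split, prototype term evaluated on
  the anchors. Default 2 epochs, each a full pass over the training
  anchors: on the synthetic reference data the triplet term reaches its
  floor within the first pass and a full split repetition evaluates at
  ACC ≈ 0.99, so longer schedules only polish the reconstruction term.
  All randomness (weights, triplet sampling) derives from one seed, and
  training is bit-reproducible given it.
* **Degenerate inputs.** All-zero inputs cannot be L2-normalized and raise
  an explicit error rather than returning NaN; ε = 0 LRP raises an error
  on an exactly-zero denominator; an empty unknown test set yields NaN TNR
  with a warning.
* **Tie-breaks.** Nearest-centroid ties go to the smallest subject id;
  relevance-magnitude ties keep row-major order.
* **Problem sizes in the checks.** The acceptance-style tests run the full
  protocol (40 × 158, 10 repetitions, retraining per repetition) and score
  region perturbation on the first repetition's pipeline with a common map
  averaged over 150 training steps and test subsets of 30 steps per
  subject; unit tests use 16-row steps and 4–8 subjects. These sizes are
  the package's reference configuration; all of them are plain arguments.

# Known limitations

* The encoder is trained from scratch per split repetition; there is no
  transfer across repetitions (`retrain = FALSE` exists but mixes encoder
  training subjects into later repetitions' test groups, weakening the
  open-set reading).
* The provisional-subject search does not fall through to the
  second-nearest centroid on rejection; a rejected known walker is simply
  a false negative.
* Attribution explains the *encoder*, not the OSVM decision; the common
  map aggregates over subjects and cannot support per-subject claims.
* Real three-level quantized pressure, sensor dropout and session effects
  are outside the generator's scope; conclusions on real recordings
  require real recordings.
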