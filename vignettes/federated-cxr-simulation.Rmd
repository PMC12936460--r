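---
title: "Simulating cross-silo federated learning for chest X-ray classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cross-silo federated learning for chest X-ray classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedcxr)
```

## The problem and the model

Hospitals hold chest radiographs they cannot share, yet a pneumonia
classifier benefits from all of them. Cross-silo federated learning
answers this by moving the model instead of the data: a central server
keeps a global model, each participating hospital (client) trains it on
its private images, and only parameter updates travel back. `fedcxr`
simulates this protocol end to end in a single process, with the sharding
step standing in for genuinely distributed data — exactly what
experimental federated studies do when they partition one pooled dataset
across simulated clients.

The base classifier is deliberately simple: a three-layer perceptron
(two ReLU hidden layers of 200 units, softmax output over
normal/pneumonia) fed flattened, 255-normalized grayscale images. The
local objective is the mean categorical cross-entropy; the local
optimizer is SGD with classical momentum and time-based learning-rate
decay; the server aggregates with data-proportional FedAvg and keeps, at
the end, the round whose global model attains the minimum loss on a
central held-out test set.

One communication round r computes, for clients $k = 1 \dots K$ holding
$n_k$ of the $n$ training images,

$$w_k^r = \mathrm{LocalUpdate}(w^{r-1}, D_k), \qquad
  w^r = \sum_{k=1}^{K} \frac{n_k}{n}\, w_k^r ,$$

and the final selection is $w^\* = w^{r^\*}$ with
$r^\* = \arg\min_r F(w^r)$, $F$ the test-set cross-entropy, earliest
round on ties. The local update itself runs $E$ epochs of mini-batch SGD
and returns the parameter snapshot of the epoch with the smallest
full-shard loss (again earliest on ties) — each client reports its best
local model rather than its last.

### Assumptions inherited from the setting

* **IID, equal shards.** `create_shards()` slices a seeded shuffle of the
  pooled training set into contiguous, near-equal parts (the first
  `n mod K` shards take the remainder image). Real hospital data would be
  neither equal-sized nor identically distributed; non-IID sharding is
  out of scope.
* **Full participation, no failures.** Every client participates in every
  round; there is no dropout, stragglers, compression, or secure
  aggregation.
* **Sequential "parallelism".** Clients run one after another in
  client-id order. The contract is that the aggregate is independent of
  client order (tested to 1e-10); actual concurrency is not simulated.
* **Central evaluation.** The global loss is computed on the single
  central test split, not as an aggregate of client training losses. The
  two readings of a "global loss" coincide in spirit but not numerically;
  evaluating on held-out data is what the round-wise
  accuracy-and-loss reporting of such studies describes, and it is the
  unambiguous choice.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `batch_size` | 32 | images per SGD step |
| `learning_rate` | 1e-4 | SGD step size λ |
| `momentum` | 0.9 | classical momentum β, dimensionless in [0, 1) |
| `decay` | 1e-6 | time-based rate decay per step (see below) |
| `epochs` | 10 | local passes E over a shard per round |
| `rounds` | 100 | communication rounds R |
| `n_clients` | 2 | participating silos (2–5 is the regime of interest) |
| `seed` | 42 | master seed; split, shards, init, shuffles derive from it |
| `split_ratio` | 0.9 | train fraction of the pooled data (90:10) |
| `image_size`, `channels` | 28×28, 1 | pipeline target shape |
| `hidden` | 200 | units per hidden layer |

The defaults are the full-scale study configuration. For desk-scale
experiments on the synthetic generator the package documentation and the
acceptance script use a second, smaller configuration — 600 images at
28×28×1, `learning_rate = 0.01`, `epochs = 5`, `rounds ≤ 30` — chosen
once so that a two-client run finishes in seconds while still exercising
every code path. At λ = 1e-4 the same runs converge, only across many
more rounds; raising λ is a problem-size adaptation, not a change of
method.

### Two ambiguities, resolved as configuration

* **Input geometry.** The pipeline this simulator models is described
  both as ingesting 28×28×3 images and as using a 224×224 input with a
  first-layer width of 50 176 — which equals 224² and therefore implies a
  single channel. The two statements cannot both hold, so `fedcxr` makes
  `image_size` and `channels` explicit configuration, defaults to
  28×28×1, and generates single-channel synthetic images (replicated
  when `channels = 3`).
* **"Decay".** Interpreted as the classic time-based learning-rate decay
  $\lambda_t = \lambda/(1 + \mathrm{decay}\cdot t)$ of the SGD optimizer
  family these hyperparameters come from, with $t$ the 0-based step
  counter. An L2 weight-penalty reading (`decay_mode = "l2"`, gradient
  $g + \mathrm{decay}\cdot w$ at constant rate) is provided as an
  alternative but is not the default.

Two further readings were fixed by the structure of the algorithm: the
loss is categorical cross-entropy (softmax outputs, one-hot labels, and
untrained two-class models plateauing at ≈ 0.69 ≈ ln 2 leave no other
natural choice), and best-local-model selection operates per epoch, since
the local loop is an epoch loop. A 100-client registry sometimes created
in such pipelines before selecting 2–5 participants is an implementation
artifact; `fedcxr` creates exactly the participating shards.

## The synthetic generator

`generate_dataset()` emulates the statistical skeleton of a two-class
CXR collection: 8-bit grayscale frames sharing a fixed vignette
background (darker borders, brighter centre — a crude lung-field), where
positive images additionally carry one bright elliptical opacity with a
Gaussian-feathered edge, centred uniformly in the central half of the
frame, with mild random eccentricity; Gaussian pixel noise is added to
both classes and values are clipped and rounded to 0–255. Class
prevalence, opacity intensity/radius, noise SD and seed are all
controllable, and identical specs reproduce byte-identical images.

Because the classes differ *only* by the patch, a one-parameter
mean-pixel threshold classifier (`threshold_baseline()`) is a valid
independent yardstick: at the default setting (intensity 120, noise SD
20) it separates held-out data essentially perfectly, and its accuracy
is non-decreasing in opacity intensity — both are tested. What the
generator does **not** emulate: anatomy, acquisition physics, scanner
and positioning variability, label noise, class overlap, or inter-site
distribution shift. Passing tests on this fixture therefore certify the
*mechanics* of the federated pipeline (sharding, optimization,
aggregation, selection, serialization), not clinical performance; the
headline accuracies of real-data federated pneumonia studies are
stochastic properties of external data and are deliberately not
reproduction targets.

## Numerical choices

* **Initialization.** Hidden weights are scaled-uniform
  (Glorot-style, $\pm\sqrt{6/(f_{in}+f_{out})}$) under the master seed;
  all biases and the whole output layer start at zero. The zero output
  layer makes the untrained network emit exactly uniform probabilities,
  so the initial two-class loss is exactly ln 2 and the initial
  prediction is the first vocabulary class everywhere — an analytic
  anchor the test-suite asserts to 1e-9.
* **Softmax stability.** Logits are max-shifted per row before
  exponentiation; probabilities are clipped below at 1e-12 inside the
  loss so confidently wrong predictions stay finite.
* **Tie-breaks.** Argmax prediction ties go to the earlier class index;
  argmin selection ties (epoch-level and round-level) go to the earliest
  index.
* **Determinism.** Seeds are derived arithmetically:
  `client_round_seed(seed, r, k)` for client k in round r, and
  `epoch_seed(s, e)` for epoch e within a local run, all below $2^{31}$.
  Summation runs in fixed client order, so whole runs are bit-reproducible
  and single-client federation is *bitwise* identical to centralized
  training (tested).
* **Degenerate inputs.** Prevalence 0 or 1 generates a one-class dataset;
  `normalize_pixels()` refuses non-integer or out-of-range pixels (so
  accidental double normalization fails loudly) but accepts an all-0/1
  image with a warning; empty datasets, empty histories, unknown labels
  and client ids, non-positive dimensions, and shape mismatches all raise
  errors naming the offender.
* **Resize semantics.** Bilinear interpolation, then rounding back to
  0–255 integers, keeping 8-bit semantics through the whole pipeline and
  making PNG write/load round trips exact.
* **Memory hygiene.** Client models are scaled and released round by
  round: at most `n_clients + 2` parameter sets are alive at once, and
  per-round global snapshots are retained only under
  `keep_round_params = TRUE`.

## Problem sizes used by the tests

Unit and property tests run on hand-sized nets (2–8 inputs, 3–20 hidden
units) and datasets of 10–600 images; the end-to-end convergence check
uses the 600-image synthetic set at 28×28×1 with two clients, five local
epochs and up to 30 rounds across five training seeds. These sizes were
chosen as the smallest at which each property is meaningfully exercised.

## Known limitations

* The MLP on flattened pixels is the studied baseline, not a competitive
  CXR classifier; no convolutional or transfer-learning backbones.
* No differential privacy, secure aggregation, client sampling, or
  communication constraints — the simulator measures learning dynamics
  only.
* Binary vocabularies only; multi-class extension would touch the data
  pipeline and the output layer but not the federation logic.
* Wall-clock times in the round history are informational and
  hardware-dependent; they are never asserted.
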