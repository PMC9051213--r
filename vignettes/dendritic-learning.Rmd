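---
title: "Dendritic learning: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic learning: models, algorithms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrilearn)
```

## The problem

Classical accounts of learning place all adaptation at synapses. The
dendritic-learning view instead treats the dendritic tree itself as the
adaptive element: each tree segment carries a weight and a nonlinear
amplification, and because every weight reaches the output through
exactly one route, credit assignment becomes local to that route. This
package implements the computational side of that programme: gradient
training of feedforward tree networks (TBP), the higher-order input
crosses that nonlinear segment amplification generates as a byproduct,
and a fully Hebbian alternative built from sign-perceptron committees.

## Input pipeline

Images arrive as `M × 784` uint8 matrices (IDX container, `read_idx()` /
`write_idx()`). Normalization is per example: the example's own pixel
mean is subtracted and the result divided by the example's own standard
deviation, so every input vector fed to a network has mean 0 and std 1.
Pixels that take a single value across **all training examples** carry no
information; they are set to exactly 0 in every (train and test) example.
Numerical choices here, made once:

* **Population standard deviation** (divide by `P`, not `P − 1`). The
  normalization statement fixes the target std at 1 and either
  convention achieves it under its own definition; the population form
  is used everywhere in the package (input normalization and per-unit
  weight initialization) so there is a single convention. A
  `sample_std` flag on `normalize_dataset()` switches the input side.
* **Masking after scaling**: examples are normalized first and masked
  pixels zeroed second, so the *unmasked* pixels retain the example's
  mean-0/std-1 statistics. The order is not dictated by the procedure's
  statement; this choice keeps the statistics interpretable.
* **Constant examples** (std 0) cannot be scaled; they are emitted as
  all-zeros with a warning. Real image data never triggers this;
  degenerate synthetic fixtures can.
* The zero-variance criterion is evaluated on **raw pixels** (values in
  `[0, 255]`), before any normalization — constancy on the raw scale is
  the natural reading, and per-example normalization could turn a
  constant raw pixel into a varying one, which would defeat the rule's
  purpose.

## Forward pass and the accumulative-field subtraction

The first hidden layer computes `z¹ = W¹ᵀx + b¹`, then subtracts a
running-average term:

`z¹_m ← z¹_m − Amp₁ · (1/(m−1)) Σ_{t<m} z¹_t`, with no modification for
the first presented example (`m = 1`). Activations are logistic
(`sigmoid()`, exponent clipped at ±500 so extreme fields saturate
instead of overflowing). Deeper layers are plain affine + sigmoid.

Three ambiguities had to be resolved:

* The accumulator stores **raw** (pre-subtraction) fields. The update
  equation overwrites `z¹` in place, which leaves raw-vs-adjusted open;
  the subtraction term is described as the field propagating from the
  input layer, which is the raw field.
* The accumulator **runs across epochs without reset** (no reset rule is
  stated); `reset_state_each_epoch = TRUE` on `train_network()` opts
  into per-epoch resetting.
* At **test time** the accumulator is frozen at its end-of-training
  value and the subtraction is still applied, keeping the train and test
  forward functions identical (`apply_field_subtraction = FALSE` on
  `predict_outputs()` disables it). The subtraction applies to the first
  hidden layer only; the printed field equations index layer 1 only.

## Cost, gradients and the momentum update

The cost is per-output binary cross-entropy (no softmax anywhere),
averaged over the batch, plus `α/(2η)·ΣW²` over weights (not biases).
Outputs are clipped to `[1e−12, 1 − 1e−12]` before the logarithms.

`gradients()` returns the **data-term** gradient only. The subtracted
running average is a function of past examples, so it is a constant with
respect to the current parameters and the backward pass is the textbook
one evaluated at the adjusted activations — this is verified against
central finite differences with the accumulator held fixed. Tree masks
are hard constraints: masked entries have exactly zero gradient and are
re-zeroed after every update.

The update is `V ← μV − η∇C`, `W ← (1−α)W + V`, `b ← b + V_b`, with
`V₀ = −η∇C_first` on the first step. Two printed descriptions of the
regularization coexist (the cost term and the `(1−α)` factor); for
`μ = 0` one multiplicative-decay step is *algebraically identical* to
one gradient-descent step on the full cost, since
`∂/∂W [α/(2η)·W²] = (α/η)W` and `−η·(α/η)W = −αW`. Implementing both at
once would double-count, so the decay factor is the single realization
and the test suite asserts the identity to machine precision. Biases
follow the printed bias update, which has no `(1−α)` factor — biases are
not decayed (and not masked).

Training is online (per-example updates) by default; `minibatch > 1`
averages gradients over the batch, matching the full-scale
50,000-example no-cross run which used minibatch 200. Example order is
reshuffled every epoch from the run seed (ordering is unstated in the
procedure; the accumulative-field state follows presentation order).
Exact reproduction of full-scale error rates may be sensitive to this
choice.

## Architectures

* `fftn_identifier` — 784 inputs in 49 non-overlapping blocks of 16
  consecutive row-major pixels, one sigmoid hidden unit per block, one
  sigmoid output. Ten such identifiers, trained independently (digit
  `d`'s output toward 1 on class `d`, else 0), form a bank; prediction
  is the argmax of the ten outputs (ties to the lowest digit). Random
  projections and the 56 × 14 layout are not presets; the mask machinery
  (`receptive_field_mask()`) is general.
* `fully_connected_2h` — 784 → 100 → 100 → 10, fully connected. Each
  output is still reached from any *weight* by one route, so TBP holds.
* `crosses_1h` — one hidden layer whose units each receive the 784
  regular inputs plus their own 10,000 order-3 input crosses.

Initialization everywhere: Gaussian(0, 1) draws; then, per unit, the
incoming weights are shifted and scaled to empirical mean 0 and std 1
(initial condition only; masked entries excluded and kept at zero); all
biases start at 1. The per-unit normalization statistics do not include
the bias.

## Input crosses

A cross is the product of three distinct pixels, `X_k·X_l·X_j`.
`generate_crosses()` assigns each hidden unit exactly `n_crosses`
triples (micro-canonical assignment), sampled independently per unit
(`share_units = TRUE` shares one set), with three rules enforced by
rejection sampling: indices within a triple are distinct (no squares),
triples are unique per unit **as unordered sets** (the product is
symmetric), and a triple whose product is zero on every training example
is excluded — in particular any triple touching a masked pixel. The
exclusion is evaluated on the normalized, masked inputs, i.e. the values
the network actually sees. After the initial per-unit weight
normalization the cross block is rescaled by `√(n_regular/n_crosses)`
(0.28 at full scale), so the cross channel enters with the same field
scale as the regular inputs.

The trainers use order 3; the algebra operations (`count_crosses()`,
`expand_amplifier()`) support general order.

## The amplification algebra

A dendritic segment amplifier `A(I) = I + I²` applied to summed influx
`I₁ + … + I_k` expands into `ΣIᵢ + ΣIᵢ² + 2·Σ_{i<j} IᵢIⱼ`: the mixed
terms are input crosses that emerge without any dedicated anatomical
connection. `expand_amplifier()` performs this expansion symbolically
for any polynomial amplifier with `A(0) = 0` and is tested to agree with
direct evaluation. For a **linear** amplifier `f(I) = gI`,
amplification commutes with the influx sum, so it can be shifted onto
the segment's incoming weights (`synapse_equivalence()`); for nonlinear
amplifiers no such synaptic rewriting exists and the function refuses.

## The Hebbian least-action committee

Each digit identifier is a committee of seven perceptrons with output
weights fixed at 1. A perceptron outputs +1 if its field `z = Wᵀx` is
strictly positive, else −1 (the printed step function emits {1, 0};
outputs are mapped to ±1 so the committee trains toward ±1 and the
update `η(y − a)X` is the classical ±2η Hebbian step — the only reading
on which the two printed equations are consistent). The field has **no
bias term**: the surrounding prose mentions one but the field equation
omits it, and the equation is followed.

On each presentation: if ≥ 5 of 7 members already output `y`, nothing
happens. Otherwise exactly one perceptron — wrong and of minimal |z| —
is updated by `W ← (1−α)W + η(y−a)X`. The decay therefore touches only
the updated perceptron and only on update steps, exactly as the update
equation states. All seven fields are read synchronously before the
update. With `α = 0` an update increases `y·z` of the updated perceptron
by exactly `2η‖x‖²` on the triggering example, an identity the tests
assert, alongside an exhaustive check of all 2⁷ output patterns.

Cross sets are per-perceptron (seven independent sets per identifier),
mirroring the per-hidden-unit assignment of the gradient-trained cross
network. No initial cross-weight rescale is printed for this
architecture; it is applied anyway for scale consistency with the
gradient path, behind `rescale_crosses = TRUE` (set `FALSE` for the
strictly literal initialization).

Prediction over the ten identifiers is the argmax of the committee
values (sum of the seven signs). Ties in the committee value are broken
by the larger summed local field, then by the lowest digit index.

## Ensembles and evaluation

A soft committee sums output activations across `Nc` replicas trained
from different initial weights and takes the argmax
(`soft_committee_predict()`); `Nc = 1` reduces to the single-network
rule. For identifier banks the per-identifier outputs are summed across
replicas *before* the across-identifier argmax, per the committee
formula. Committee replicas reuse the hyperparameters optimized for a
single run. `test_error()` is the plain misclassification fraction;
`error_summary()` reports the mean and **sample** standard deviation
across runs.

## The synthetic generator

`gen_images()` emulates the statistics the algorithms assume: 28 × 28
uint8 images in `[0, 255]` with class-conditional structure and a set of
pixels that are constant across the training set (to exercise
zero-variance masking). Class prototypes are smoothed random fields, not
digit glyphs — the algorithms need class structure, not legible shapes.
Default desk-scale conditions: 10 classes × 100 train + 50 test
examples, prototype contrast 80 and pixel-noise std 60 on the `[0, 255]`
scale, 10 constant pixels. The contrast/noise ratio was chosen once so
that a desk-scale run sits in the middle of its learning curve — small
training sets leave a clearly nonzero test error that falls as examples
are added — rather than saturating at zero error or collapsing to
chance; this is what makes the reported learning-curve fit informative.

What passing tests on this fixture do **not** show: anything about true
MNIST difficulty or error rates. Digit strokes are sparse, heavy-tailed
and spatially structured in ways smoothed Gaussian fields are not, and
the fixture deliberately does not imitate them. The full-scale printed
hyperparameter presets (`hyperparam_preset()`) are wired in for users
who point the CLI at real MNIST IDX files.

`gen_teacher_labels()` labels inputs by a random 7-perceptron majority
vote — a realizable target for the least-action learner, used for the
learnability checks. `gen_separable()` produces two Gaussian clouds with
controllable margin for the gradient trainers.

## Power-law learning curves

`fit_power_law()` fits `ε = c₀/n^ρ` by least squares in log–log space
and extrapolates via `predict()`. In the acceptance script, test errors
measured at 15/30/60 examples per digit feed the fit; a zero measured
error (possible on an easy draw of the fixture) is floored at half a
count on the test set, `1/(2·n_test)`, before taking logs — the standard
continuity correction for an otherwise undefined logarithm.

## Problem sizes and determinism

The test suite runs entirely at desk scale (8 × 8 fixtures for the
mechanics; 28 × 28, 100–1000 examples for end-to-end runs; 200-epoch
teacher–student runs at n = 100). These sizes were chosen as the
smallest at which each property is meaningfully exercised — receptive
fields still tile the image, cross sampling still faces exclusions,
committees still disagree. Every stochastic component (initialization,
shuffling, cross sampling, generators) draws from an explicit seed, and
two runs with the same seed and configuration are bit-identical,
including serialized checkpoints. Checkpoints store a JSON manifest plus
flat little-endian doubles, so reloading reproduces forward outputs
bit-exactly.

## Known limitations

* The three printed architectures are presets; the mask machinery is
  general but arbitrary-depth trees have no convenience constructors.
* The ten identifier outputs are updated synchronously; asynchronous or
  delay-based realizations of the ten updates are out of scope, as is
  any learning of the amplifier coefficients themselves.
* Hyperparameter search (the grid / sequential 1-D optimization recipe
  used to produce the printed tables) is documented but intentionally
  not automated — it is generic grid search, not a bespoke algorithm.
* Pure-R training loops are adequate for desk scale and for the printed
  overnight full-scale runs, but nothing here targets GPUs.
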