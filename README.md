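# dendrilearn

Learning algorithms for **dendritic learning** — the hypothesis that a
neuron's adaptation lives on dendritic tree segments (weights plus
nonlinear amplification) rather than solely at synapses. The package
implements, as reusable and tested R code:

- **Tree backpropagation (TBP)** on feedforward tree networks (FFTNs):
  exact backpropagation through sigmoid layers where each weight reaches
  an output by exactly one route, including the non-overlapping
  16-pixel receptive-field identifier tree (784 → 49 → 1).
- **Momentum training with multiplicative decay**:
  `V ← μV − η∇C`, `W ← (1−α)W + V`, `b ← b + V_b`, with
  `V₀ = −η∇C_first`. The `(1−α)` factor realizes the quadratic penalty
  `α/(2η)·ΣW²` of the cross-entropy cost exactly.
- **Accumulative-average-field subtraction**: the first hidden layer's
  field for example *m* is reduced by
  `Amp₁ · mean(z¹ of the previous m−1 examples)` (never for *m* = 1).
- **Order-3 input crosses** `X_k·X_l·X_j` of distinct pixels, assigned
  micro-canonically (the same count per hidden unit, 10,000 at full
  scale), with identically-zero crosses excluded and initial cross
  weights rescaled by `√(784/10000) = 0.28`.
- **Dendritic-amplification algebra**: symbolic expansion of a segment
  amplifier `A(I) = I + I²` over summed synaptic influx (mixed monomials
  are self-emerging input crosses), and the equivalence that shifts a
  linear amplification `f(I) = gI` onto the segment's synapses.
- **Hebbian least-action committees**: per-digit committees of seven
  sign perceptrons with fixed unit output weights; an update fires only
  when fewer than 5 of 7 members are correct and touches exactly the
  wrong perceptron with minimal |local field|:
  `W ← (1−α)W + η(y−a)X`.
- **Soft-committee ensembles** (`argmax_j Σ_s a_j,s` over replicas),
  test-error evaluation, and **power-law learning-curve fits**
  `ε = c₀ / (examples/digit)^ρ`.
- **IDX (MNIST-dialect) I/O**, per-example input normalization (mean 0,
  std 1) with train-derived zero-variance masking, and a **synthetic
  image generator** so everything runs without downloads.

## Worked example

Train the 10-identifier tree bank on a synthetic digit fixture and
evaluate it, single and as a 3-replica soft committee:

```r
library(dendrilearn)

d     <- gen_images(synthetic_spec(seed = 1))       # 10 classes, 28x28
mask  <- zero_variance_mask(d$train)
train <- normalize_dataset(d$train, mask)
test  <- normalize_dataset(d$test,  mask)

hp <- hyperparams(eta = 0.02, mu = 0.9, alpha = 1e-4, amp1 = 0.1,
                  epochs = 10, seed = 1001)
bank <- train_identifier_bank("fftn_identifier", train, hp, n_classes = 10)
test_error(bank, test)
#> [1] 0.036

banks <- lapply(1:3, function(r) {
  hp_r <- hp; hp_r$seed <- 1000L * r + 1L
  train_identifier_bank("fftn_identifier", train, hp_r, n_classes = 10)
})
test_error(banks, test)   # soft committee over 3 replicas
#> [1] 0.012
```

The single bank misclassifies 3.6% of the held-out synthetic digits; the
soft committee of three independently initialized replicas cuts that to
1.2% — the ensemble benefit the committee decision rule is designed for.
The Hebbian least-action bank on the same fixture:

```r
heb <- train_hebbian(train, hebbian_hyperparams(epochs = 20, seed = 8))
test_error(heb, test)
#> [1] 0.028
```

Power-law learning-curve fit from test errors measured at increasing
training sizes:

```r
fit <- fit_power_law(c(15, 30, 60), c(0.636, 0.398, 0.206))
fit
#> <power_law_fit> error = 5.9372 / n^0.8132 (3 points)
predict(fit, 100)    # extrapolated error at 100 examples/digit
#> [1] 0.1403467
```

The printed hyperparameter presets for the full-scale runs are wired in
(`hyperparam_preset()`), e.g. `"crosses-15pd"` =
(η = 0.0079, μ = 0.63, α = 0.00018, Amp₁ = 0.07, 200 epochs). Full-scale
MNIST reproduction (the `fftn-mnist-bench` recipe) is a matter of
pointing the CLI at the MNIST IDX files with those presets; it is a
multi-hour run and not part of the test suite.

## Command line

A thin CLI wraps the exported functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "dendrilearn.R", package="dendrilearn"))') \
  fixtures --out fx --seed 1
# ... normalize / crosses / train / eval — run `help` for usage
```

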