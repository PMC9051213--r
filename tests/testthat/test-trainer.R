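test_that("cost matches closed forms and an independent scalar oracle", {
  params <- init_params("fully_connected_2h", seed = 1, n_inputs = 6,
                        n_hidden = 4, n_out = 10)
  hp0 <- hyperparams(eta = 0.1, alpha = 0)
  y <- c(1, rep(0, 9))
  # a = y exactly (after clipping) -> vanishing data term
  expect_lt(cost(params, y, y, hp0)$data_term, 1e-10)
  # all outputs at 0.5 -> 10 log 2 regardless of targets
  expect_equal(cost(params, rep(0.5, 10), y, hp0)$data_term, 10 * log(2),
               tolerance = 1e-12)
  # straight-line reimplementation incl. the quadratic penalty
  hp <- hyperparams(eta = 0.05, alpha = 0.01)
  set.seed(2)
  a <- matrix(runif(30, 0.05, 0.95), 3, 10)
  t3 <- matrix(rbinom(30, 1, 0.3), 3, 10)
  manual_data <- 0
  for (m in 1:3) for (j in 1:10) {
    manual_data <- manual_data - (t3[m, j] * log(a[m, j]) +
                                    (1 - t3[m, j]) * log(1 - a[m, j]))
  }
  manual_data <- manual_data / 3
  manual_l2 <- hp$alpha / (2 * hp$eta) *
    (sum(params$layers[[1]]$W^2) + sum(params$layers[[2]]$W^2) +
       sum(params$layers[[3]]$W^2))
  rep_ <- cost(params, a, t3, hp)
  expect_equal(rep_$data_term, manual_data, tolerance = 1e-12)
  expect_equal(rep_$l2_term, manual_l2, tolerance = 1e-12)
  expect_equal(rep_$total, rep_$data_term + rep_$l2_term)
})

test_that("analytic gradients match central finite differences", {
  # plain 10-4-3 network, Amp1 in {0, 0.1}
  params <- init_params("fully_connected_2h", seed = 3, n_inputs = 10,
                        n_hidden = 4, n_out = 3)
  params$layers <- params$layers[c(1, 3)]  # 10-4-3: single hidden layer
  params$masks <- params$masks[c(1, 3)]
  params$layers[[2]]$W <- matrix(rnorm(12), 4, 3)
  set.seed(4)
  x <- rnorm(10)
  y <- c(1, 0, 1)
  for (amp1 in c(0, 0.1)) {
    hp <- hyperparams(eta = 0.1, amp1 = amp1)
    state <- running_field_state(4)
    if (amp1 > 0) {
      for (k in 1:5) {  # accumulate five examples first
        state <- forward(params, rnorm(10), state = state, hp = hp,
                         training = TRUE)$state
      }
    }
    fw <- forward(params, x, state = state, hp = hp, training = FALSE)
    analytic <- flatten_grads(gradients(params, fw, y))
    numeric <- numeric_gradient(params, x, y, state, hp)
    expect_lt(max_rel_err(analytic, numeric), 1e-6)
  }
})

test_that("gradients respect tree masks, including the masked 32-unit case", {
  params <- init_params("fftn_identifier", seed = 5, n_inputs = 32,
                        block_size = 16)  # 32 -> 2 blocks of 16 -> 1
  hp <- hyperparams(eta = 0.1, amp1 = 0.1)
  state <- running_field_state(2)
  set.seed(6)
  for (k in 1:5) {
    state <- forward(params, rnorm(32), state = state, hp = hp,
                     training = TRUE)$state
  }
  x <- rnorm(32)
  fw <- forward(params, x, state = state, hp = hp, training = FALSE)
  grads <- gradients(params, fw, 1)
  expect_true(all(grads[[1]]$dW[!params$masks[[1]]] == 0))
  numeric <- numeric_gradient(params, x, 1, state, hp)
  # the tree mask is a hard constraint: compare on the live coordinates
  live <- flatten_mask(params)
  expect_lt(max_rel_err(flatten_grads(grads)[live], numeric[live]), 1e-6)
})

test_that("momentum updates reduce to the printed special cases", {
  params <- init_params("fully_connected_2h", seed = 7, n_inputs = 5,
                        n_hidden = 3, n_out = 2)
  x <- rnorm(5); y <- c(1, 0)
  fw <- forward(params, x)
  grads <- gradients(params, fw, y)

  # mu = 0, alpha = 0: vanilla gradient descent
  hp <- hyperparams(eta = 0.2, mu = 0, alpha = 0)
  step <- momentum_step(params, grads, momentum_state(params), hp)
  for (l in seq_along(params$layers)) {
    expect_equal(step$params$layers[[l]]$W,
                 params$layers[[l]]$W - 0.2 * grads[[l]]$dW,
                 tolerance = 1e-15)
    expect_equal(step$params$layers[[l]]$b,
                 params$layers[[l]]$b - 0.2 * grads[[l]]$db,
                 tolerance = 1e-15)
  }

  # zero gradient, mu = 0.9: velocity decays geometrically
  zero_grads <- lapply(grads, function(g)
    list(dW = 0 * g$dW, db = 0 * g$db))
  hp9 <- hyperparams(eta = 0.2, mu = 0.9, alpha = 0)
  ms <- momentum_state(params)
  st <- momentum_step(params, grads, ms, hp9)  # V0 = -eta * grad
  v0 <- st$mstate$V[[1]]
  for (k in 1:3) st <- momentum_step(st$params, zero_grads, st$mstate, hp9)
  expect_equal(st$mstate$V[[1]], 0.9^3 * v0, tolerance = 1e-12)
})

test_that("the (1 - alpha) decay is exactly one gradient step on the full cost", {
  set.seed(8)
  for (case in 1:100) {
    params <- init_params("fully_connected_2h", seed = case, n_inputs = 4,
                          n_hidden = 3, n_out = 2)
    hp <- hyperparams(eta = runif(1, 0.01, 0.5), mu = 0,
                      alpha = runif(1, 0.0001, 0.05))
    x <- rnorm(4); y <- rbinom(2, 1, 0.5)
    fw <- forward(params, x)
    grads <- gradients(params, fw, y)
    step <- momentum_step(params, grads, momentum_state(params), hp)
    for (l in seq_along(params$layers)) {
      # d/dW of alpha/(2 eta) W^2 is (alpha/eta) W; one GD step on the
      # full cost is W - eta * (grad_data + (alpha/eta) W)
      full_step <- params$layers[[l]]$W -
        hp$eta * (grads[[l]]$dW + (hp$alpha / hp$eta) * params$layers[[l]]$W)
      expect_equal(step$params$layers[[l]]$W, full_step, tolerance = 1e-15)
    }
  }
})

test_that("training drives the cost down on separable data and reaches high accuracy", {
  sep <- gen_separable(n = 120, dim = 12, margin = 2, seed = 9)
  data <- structure(list(inputs = sep$X, labels = sep$y,
                         mask = rep(FALSE, 12)), class = "normalized_dataset")
  params <- init_params("fully_connected_2h", seed = 10, n_inputs = 12,
                        n_hidden = 6, n_out = 1)
  hp <- hyperparams(eta = 0.05, mu = 0, alpha = 0, epochs = 20, seed = 10)
  model <- train_network(params, data, sep$y, hp)
  costs <- model$history$data_cost
  expect_lt(costs[20], costs[1])
  expect_true(all(diff(costs[1:20]) < 1e-6))  # monotone decrease
  expect_gte(model$history$train_acc[20], 0.99)
})

test_that("identifier training is separable across digits and masks survive training", {
  fx <- desk_fixture(n_classes = 3)
  hp <- hyperparams(eta = 0.02, mu = 0.5, alpha = 1e-4, amp1 = 0.1,
                    epochs = 10, seed = 11)
  bank <- train_identifier_bank("fftn_identifier", fx$train, hp,
                                n_classes = 3,
                                n_inputs = ncol(fx$train$inputs),
                                block_size = 16)
  # masked entries still exactly zero after training
  for (m in bank) {
    expect_true(all(m$params$layers[[1]]$W[!m$params$masks[[1]]] == 0))
  }
  # independence: retraining identifier 2 alone reproduces it bit-for-bit
  hp2 <- hp; hp2$seed <- hp$seed + 1L
  params2 <- init_params("fftn_identifier", seed = hp2$seed,
                         n_inputs = ncol(fx$train$inputs), block_size = 16)
  solo <- train_network(params2, fx$train,
                        as.numeric(fx$train$labels == 1L), hp2)
  expect_identical(solo$params, bank[[2]]$params)
  expect_identical(solo$history, bank[[2]]$history)
})

test_that("fixed seeds give bit-identical training runs", {
  fx <- desk_fixture()
  hp <- hyperparams(eta = 0.02, mu = 0.7, alpha = 1e-4, amp1 = 0.05,
                    epochs = 3, seed = 12)
  run <- function() {
    params <- init_params("fftn_identifier", seed = 12,
                          n_inputs = ncol(fx$train$inputs), block_size = 16)
    train_network(params, fx$train, as.numeric(fx$train$labels == 0L), hp)
  }
  a <- run(); b <- run()
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
  expect_identical(a$state, b$state)
})

test_that("power-law fits recover exact generating parameters and reject bad input", {
  n <- c(15, 30, 60, 90)
  eps <- 0.5 / n^0.3
  fit <- fit_power_law(n, eps)
  expect_equal(fit$c0, 0.5, tolerance = 1e-10)
  expect_equal(fit$rho, 0.3, tolerance = 1e-10)
  expect_equal(predict(fit, 5000), 0.5 / 5000^0.3, tolerance = 1e-10)
  expect_error(fit_power_law(15, 0.5), "at least two")
  expect_error(fit_power_law(c(10, 20), c(-0.1, 0.2)), "positive")
  td <- suppressWarnings(tidy(fit))  # exact fit: vcov warns, estimates stand
  expect_identical(td$term, c("c0", "rho"))
  expect_equal(td$estimate, c(0.5, 0.3), tolerance = 1e-10)
  expect_gt(suppressWarnings(glance(fit))$r.squared, 0.999)
})

test_that("noisy power-law estimates are self-consistent at larger samples", {
  set.seed(13)
  n <- rep(c(15, 30, 60, 90), 3)
  eps <- 0.5 / n^0.3 * exp(rnorm(length(n), sd = 0.05))
  fit_small <- fit_power_law(n, eps)
  n_big <- rep(c(15, 30, 60, 90), 30)
  eps_big <- 0.5 / n_big^0.3 * exp(rnorm(length(n_big), sd = 0.05))
  fit_big <- fit_power_law(n_big, eps_big)
  se_big <- tidy(fit_big)$std.error[2]
  expect_lt(abs(fit_small$rho - fit_big$rho),
            4 * sqrt(tidy(fit_small)$std.error[2]^2 + se_big^2))
})
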