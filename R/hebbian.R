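# Per-digit committees of seven sign perceptrons with fixed unit output
# weights, trained by the least-action rule: an update fires only when
# fewer than 5 of 7 members answer correctly, and touches exactly the
# erring perceptron with minimal |local field|.

#' Initialize a perceptron committee
#'
#' Each of `n_perceptrons` sign units gets its own weight vector over the
#' regular inputs plus (optionally) its own cross set; weights are drawn
#' Gaussian(0, 1), per-unit normalized to mean 0 / std 1, and the cross
#' block rescaled by `sqrt(n_regular / n_crosses)` unless disabled. Output
#' weights are fixed at 1 and never change. The perceptron field carries
#' no bias term.
#'
#' @param n_inputs Number of regular inputs.
#' @param seed Integer seed.
#' @param crosses Optional `cross_index_set` with one entry per
#'   perceptron.
#' @param n_perceptrons Committee size (odd; default 7).
#' @param rescale_crosses Apply the cross-weight rescale (default `TRUE`).
#' @return A `perceptron_committee`: `W` (fan_in x n_perceptrons),
#'   `crosses`, `n_regular`.
#' @export
perceptron_committee <- function(n_inputs, seed, crosses = NULL,
                                 n_perceptrons = 7L, rescale_crosses = TRUE) {
  fan_in <- n_inputs + if (is.null(crosses)) 0L else crosses$n_crosses
  if (!is.null(crosses)) {
    stopifnot(length(crosses$per_unit) == n_perceptrons,
              crosses$n_regular == n_inputs)
  }
  W <- withr::with_seed(seed, {
    W <- matrix(stats::rnorm(fan_in * n_perceptrons), fan_in, n_perceptrons)
    for (j in seq_len(n_perceptrons)) {
      W[, j] <- (W[, j] - mean(W[, j])) / pop_sd(W[, j])
    }
    W
  })
  if (!is.null(crosses) && rescale_crosses) {
    cross_rows <- (n_inputs + 1L):fan_in
    W[cross_rows, ] <- rescale_cross_weights(W[cross_rows, , drop = FALSE],
                                             n_inputs, crosses$n_crosses)
  }
  structure(list(W = W, crosses = crosses, n_regular = as.integer(n_inputs)),
            class = "perceptron_committee")
}

# Per-perceptron expanded inputs: fan_in x n_perceptrons matrix (each
# perceptron has its own cross set), or the plain vector when no crosses.
committee_inputs <- function(committee, x) {
  stopifnot(length(x) == committee$n_regular)
  if (is.null(committee$crosses)) return(x)
  vapply(seq_len(ncol(committee$W)),
         function(j) c(x, cross_inputs(x, committee$crosses, j)),
         numeric(nrow(committee$W)))
}

#' Perceptron fields and sign outputs
#'
#' The step is strict: output +1 iff `z > 0`, else -1 (a zero field counts
#' as -1).
#'
#' @param committee A [perceptron_committee()].
#' @param x Regular input vector (crosses are expanded internally).
#' @return List `z` (local fields) and `a` (outputs in `{-1, +1}`).
#' @export
perceptron_outputs <- function(committee, x) {
  xe <- committee_inputs(committee, x)
  z <- if (is.matrix(xe)) colSums(committee$W * xe) else
    drop(crossprod(committee$W, xe))
  list(z = z, a = ifelse(z > 0, 1, -1))
}

#' One least-action presentation
#'
#' If at least 5 of the 7 perceptrons already output the desired `y`, the
#' committee is untouched. Otherwise the single wrong perceptron with the
#' minimal absolute local field is updated by
#' `W <- (1 - alpha) * W + eta * (y - a) * X` with `a` its current +/-1
#' output (so the Hebbian step has magnitude `2 * eta`); decay touches
#' only that perceptron, only on update steps. All fields are read
#' synchronously before any update.
#'
#' @param committee A [perceptron_committee()].
#' @param x Regular input vector.
#' @param y Desired output, -1 or +1.
#' @param hp A [hebbian_hyperparams()].
#' @param gate Minimum number of correct members that suppresses the
#'   update (default 5; a committee of 1 with `gate = 1` is the classical
#'   perceptron rule with decay).
#' @return List `committee`, `updated` (perceptron index or `NA` for a
#'   no-op), `n_correct`.
#' @export
least_action_step <- function(committee, x, y, hp, gate = 5L) {
  stopifnot(y %in% c(-1, 1))
  po <- perceptron_outputs(committee, x)
  correct <- po$a == y
  if (sum(correct) >= gate) {
    return(list(committee = committee, updated = NA_integer_,
                n_correct = sum(correct)))
  }
  wrong <- which(!correct)
  j <- wrong[which.min(abs(po$z[wrong]))]
  xe <- committee_inputs(committee, x)
  xj <- if (is.matrix(xe)) xe[, j] else xe
  committee$W[, j] <- (1 - hp$alpha) * committee$W[, j] +
    hp$eta * (y - po$a[j]) * xj
  list(committee = committee, updated = j, n_correct = sum(correct))
}

#' Hebbian hyperparameters
#'
#' Defaults are the optimized digit-identifier settings
#' (`eta = 0.05`, `alpha = 2e-4`).
#'
#' @param eta Learning rate.
#' @param alpha Decay constant in `[0, 1)`.
#' @param epochs Passes over the training set.
#' @param seed RNG seed for shuffling.
#' @return A `hebbian_hyperparams` list.
#' @export
hebbian_hyperparams <- function(eta = 0.05, alpha = 2e-4, epochs = 50L,
                                seed = 1L) {
  stopifnot(eta > 0, alpha >= 0, alpha < 1, epochs >= 1)
  structure(list(eta = eta, alpha = alpha, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "hebbian_hyperparams")
}

#' Train one committee by the least-action rule
#'
#' Per-example presentations in a seeded shuffled order, `epochs` passes.
#'
#' @param committee A [perceptron_committee()].
#' @param X Matrix of regular inputs (examples in rows).
#' @param y Vector of +/-1 labels.
#' @param hp A [hebbian_hyperparams()].
#' @param gate Passed to [least_action_step()].
#' @return List `committee`, `history` (data.frame: epoch, train_error,
#'   n_updates).
#' @export
train_committee <- function(committee, X, y, hp, gate = 5L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(-1, 1)))
  history <- data.frame(epoch = integer(0), train_error = numeric(0),
                        n_updates = integer(0))
  withr::with_seed(hp$seed, {
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(nrow(X))
      n_updates <- 0L
      for (i in ord) {
        step <- least_action_step(committee, X[i, ], y[i], hp, gate = gate)
        committee <- step$committee
        if (!is.na(step$updated)) n_updates <- n_updates + 1L
      }
      preds <- committee_predict_values(committee, X)
      train_error <- mean(sign_or_neg(preds) != y)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_error = train_error,
                                           n_updates = n_updates))
      if (train_error == 0 && n_updates == 0L) break
    }
  })
  list(committee = committee, history = history)
}

sign_or_neg <- function(v) ifelse(v > 0, 1, -1)

#' Committee values over a dataset
#'
#' The committee value for an example is the sum of the 7 sign outputs
#' (an odd integer in `-7 ... +7`).
#'
#' @param committee A [perceptron_committee()].
#' @param X Matrix of regular inputs.
#' @return Numeric vector of committee values.
#' @export
committee_predict_values <- function(committee, X) {
  vapply(seq_len(nrow(X)), function(i) {
    sum(perceptron_outputs(committee, X[i, ])$a)
  }, numeric(1L))
}

#' Train the 10-identifier Hebbian bank
#'
#' One committee per class, labels mapped to +1 for the identifier's class
#' and -1 otherwise; identifiers are fully independent (disjoint seeds,
#' disjoint cross sets when `crosses_per_class` is given).
#'
#' @param data A `normalized_dataset` with labels `0..n_classes-1`.
#' @param hp A [hebbian_hyperparams()]; identifier `d` uses seed
#'   `hp$seed + 101 * d`.
#' @param n_classes Number of identifiers.
#' @param crosses_per_class Optional list (length `n_classes`) of
#'   `cross_index_set`s, one per identifier, each with one entry per
#'   perceptron.
#' @param n_perceptrons Committee size.
#' @return A `hebbian_bank`: list of `list(committee, history)` per class.
#' @export
train_hebbian <- function(data, hp, n_classes = 10L, crosses_per_class = NULL,
                          n_perceptrons = 7L) {
  bank <- lapply(seq_len(n_classes) - 1L, function(d) {
    hp_d <- hp
    hp_d$seed <- hp$seed + 101L * d
    cr <- if (is.null(crosses_per_class)) NULL else crosses_per_class[[d + 1L]]
    committee <- perceptron_committee(ncol(data$inputs), seed = hp_d$seed,
                                      crosses = cr,
                                      n_perceptrons = n_perceptrons)
    y <- ifelse(data$labels == d, 1, -1)
    train_committee(committee, data$inputs, y, hp_d)
  })
  structure(bank, class = "hebbian_bank")
}

#' Predict digits from a Hebbian identifier bank
#'
#' Per identifier, the committee value is the sum of its 7 sign outputs;
#' the predicted class is the argmax over identifiers. Ties go to the
#' identifier with the larger summed local field, then to the lowest class
#' index.
#'
#' @param bank A `hebbian_bank` from [train_hebbian()].
#' @param X Matrix of regular inputs.
#' @return Integer vector of predicted classes (0-based).
#' @export
predict_hebbian <- function(bank, X) {
  vapply(seq_len(nrow(X)), function(i) {
    vals <- numeric(length(bank))
    fields <- numeric(length(bank))
    for (d in seq_along(bank)) {
      po <- perceptron_outputs(bank[[d]]$committee, X[i, ])
      vals[d] <- sum(po$a)
      fields[d] <- sum(po$z)
    }
    best <- which(vals == max(vals))
    if (length(best) > 1L) best <- best[order(-fields[best])][1L]
    as.integer(best - 1L)
  }, integer(1L))
}
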